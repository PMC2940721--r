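# Shared in-code fixtures: hand-built site tables and random model instances
# for DP-vs-enumeration checks.

mk_sites <- function(tf, start, len = 5L, llr = 0, llr_max = 0, strand = "+") {
  d <- data.frame(tf = tf, start = as.integer(start),
                  length = as.integer(rep_len(len, length(tf))),
                  strand = rep_len(strand, length(tf)),
                  llr = rep_len(llr, length(tf)),
                  llr_max = rep_len(llr_max, length(tf)),
                  stringsAsFactors = FALSE)
  d <- d[order(d$start, d$tf), ]
  rownames(d) <- NULL
  class(d) <- c("binding_sites", "data.frame")
  d
}

# Random model instance: mixed activator/repressor TFs, homotypic and
# heterotypic cooperativity, overlapping sites allowed, q in [0, 5].
# coop_min = 1 restricts to cooperative (omega >= 1) interactions, the regime
# of the monotonicity properties; the default also draws anti-cooperative
# weights to stress the partition functions.
rand_instance <- function(n_sites, n_tf = 3, span = 80L, coop = TRUE,
                          activators_only = FALSE, coop_min = 0.3,
                          overlaps = TRUE) {
  tfs <- paste0("T", seq_len(n_tf))
  roles <- setNames(sample(c("activator", "repressor"), n_tf, TRUE), tfs)
  if (activators_only) roles[] <- "activator"
  if (!any(roles == "activator")) roles[1] <- "activator"
  starts <- if (overlaps) sort(sample.int(span, n_sites, TRUE)) - 1L
            else sort(sample.int(span, n_sites)) * 10L
  sites <- mk_sites(sample(tfs, n_sites, TRUE), starts,
                    len = sample(4:8, n_sites, TRUE),
                    llr = -runif(n_sites, 0, 2))
  alpha <- setNames(ifelse(roles == "activator",
                           1 + runif(n_tf, 0, 5), runif(n_tf, 0.05, 0.95)), tfs)
  omega <- if (coop)
    setNames(runif(2, coop_min, 8),
             c(paste0(tfs[1], ":", tfs[1]), paste0(tfs[1], ":", tfs[2])))
  params <- model_params(
    binding_k = setNames(runif(n_tf, 0.1, 5), tfs), alpha = alpha,
    omega = omega, beta = setNames(runif(n_tf, 0, 4), tfs),
    q_btm = runif(1, 0.01, 1), coop_range = 20,
    d_r = sample(c(0, 10, 30, 100), 1))
  list(sites = sites, params = params, roles = roles,
       conc = setNames(runif(n_tf, 0, 2), tfs))
}

max_rel_err <- function(a, b) {
  max(abs(a$z_on - b$z_on) / abs(b$z_on),
      abs(a$z_off - b$z_off) / abs(b$z_off),
      abs(a$expression - b$expression) / max(abs(b$expression), 1e-300))
}

# small ready-made simulated study shared by evaluation/conservation tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(n_crms = 6, rng_seed = 1)
    cache
  }
})
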