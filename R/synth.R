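#' Build a PWM from a consensus word
#'
#' Each position gives its consensus base probability `specificity`, the
#' remainder split evenly over the other three bases. `specificity = 0.25`
#' yields a fully uninformative motif.
#'
#' @param consensus DNA string over A, C, G, T.
#' @param specificity consensus-base probability in (0, 1].
#' @param name motif name; defaults to the consensus.
#' @param background background base distribution.
#' @return a [pwm()] object.
#' @export
make_pwm <- function(consensus, specificity = 0.85, name = consensus,
                     background = rep(0.25, 4)) {
  stopifnot(specificity > 0, specificity <= 1)
  idx <- match(strsplit(toupper(consensus), "")[[1]], BASES)
  if (anyNA(idx)) stop("consensus must be over A, C, G, T")
  spec <- min(specificity, 1 - 3e-9)       # keep all probabilities positive
  probs <- matrix((1 - spec) / 3, length(idx), 4)
  probs[cbind(seq_along(idx), idx)] <- spec
  pwm(name, probs, background)
}

#' Synthetic concentration gradient
#'
#' Emulates spatial TF concentration profiles over expression bins: a
#' decreasing sigmoid (`anterior`), an increasing sigmoid (`posterior`), a
#' Gaussian bump (`stripe`) or a constant (`flat`). Values lie in `[0, 1]`.
#'
#' @param kind `"anterior"`, `"posterior"`, `"stripe"` or `"flat"`.
#' @param bins number of bins (>= 2).
#' @param midpoint sigmoid midpoint as a fraction of the axis.
#' @param steepness sigmoid steepness (fraction of the axis).
#' @param center,width stripe center and standard deviation (fractions).
#' @param level constant level for `flat`.
#' @return numeric vector of length `bins`.
#' @export
make_gradient <- function(kind = c("anterior", "posterior", "stripe", "flat"),
                          bins, midpoint = 0.45, steepness = 0.08,
                          center = 0.5, width = 0.08, level = 0.5) {
  kind <- match.arg(kind)
  stopifnot(bins >= 2)
  x <- (seq_len(bins) - 0.5) / bins
  switch(kind,
         anterior = 1 / (1 + exp((x - midpoint) / steepness)),
         posterior = 1 / (1 + exp(-(x - midpoint) / steepness)),
         stripe = exp(-(x - center)^2 / (2 * width^2)),
         flat = rep(level, bins))
}

# Degrade the consensus word until its LLR falls to ~frac * llr_max: greedily
# apply the single-base substitution landing closest to the target from
# above, stopping at the word nearest the target.
degrade_word <- function(pwm, frac) {
  m <- llr_matrix(pwm)
  idx <- apply(m, 1, which.max)
  target <- frac * llr_max(pwm)
  cur <- sum(m[cbind(seq_along(idx), idx)])
  repeat {
    if (cur <= target) break
    best <- NULL; best_llr <- -Inf
    for (pos in seq_along(idx)) {
      for (b in seq_len(4)[-idx[pos]]) {
        cand <- cur - m[pos, idx[pos]] + m[pos, b]
        if (cand < cur && cand > best_llr) { best_llr <- cand; best <- c(pos, b) }
      }
    }
    if (is.null(best)) break
    # stop if overshooting the target further than staying put
    if (best_llr < target && (cur - target) <= (target - best_llr)) break
    idx[best[1]] <- best[2]
    cur <- best_llr
  }
  paste(BASES[idx], collapse = "")
}

#' Synthesize a CRM sequence with planted binding sites
#'
#' Background bases are drawn i.i.d. from the background distribution; each
#' planted site is a word whose LLR is degraded from the consensus to
#' approximately `strength` times the optimal LLR, embedded on the forward
#' strand.
#'
#' @param site_plan data.frame with columns `tf`, `position` (0-based start)
#'   and `strength` (fraction of the optimal LLR in (0, 1]).
#' @param pwms named list of [pwm()] objects covering the planned TFs.
#' @param length CRM length in bp.
#' @param rng_seed seed for the background sequence.
#' @param background background base distribution.
#' @return DNA string of the requested length.
#' @export
make_crm <- function(site_plan, pwms, length, rng_seed,
                     background = rep(0.25, 4)) {
  pw <- setNames(pwms, vapply(pwms, `[[`, "", "name"))
  if (nrow(site_plan)) {
    w <- vapply(site_plan$tf, function(tf) pw[[tf]]$width, numeric(1))
    ends <- site_plan$position + w
    if (any(site_plan$position < 0) || any(ends > length))
      stop("planted site outside the sequence")
    ord <- order(site_plan$position)
    if (any(ends[ord][-base::length(ord)] > site_plan$position[ord][-1]))
      stop("planted sites overlap")
  }
  chars <- with_seed(rng_seed,
                     sample(BASES, length, replace = TRUE, prob = background))
  for (k in seq_len(nrow(site_plan))) {
    p <- pw[[site_plan$tf[k]]]
    word <- degrade_word(p, site_plan$strength[k])
    chars[(site_plan$position[k] + 1):(site_plan$position[k] + p$width)] <-
      strsplit(word, "")[[1]]
  }
  paste(chars, collapse = "")
}

default_true_params <- function(mode = "direct") {
  model_params(
    binding_k = c(actA = 10, actP = 10, repS1 = 10, repS2 = 10),
    alpha = c(actA = 6, actP = 6, repS1 = 0.2, repS2 = 0.25),
    beta = if (mode == "srr") c(repS1 = 5, repS2 = 5) else NULL,
    q_btm = 0.05, mode = mode)
}

#' Simulate a complete synthetic dataset
#'
#' Builds a regulatory system in the regime of a spatial-patterning study:
#' four TFs (two activators on opposing sigmoid gradients, two repressors on
#' stripe gradients), PWMs of width 8, ~1 kb CRMs with 4-8 planted sites of
#' strength 0.6-1.0, and 60-bin profiles. Observed expression profiles are
#' the model's own predictions under `true_params`, rescaled per CRM to
#' maximum 1, with optional truncated Gaussian noise. Fully reproducible from
#' `rng_seed`.
#'
#' @param n_crms number of CRMs.
#' @param true_params generating [model_params()]; defaults to a
#'   direct-interaction multiplicative model.
#' @param noise_sd Gaussian noise standard deviation (profiles are clipped to
#'   `[0, 1]`).
#' @param rng_seed master seed.
#' @param bins profile length.
#' @param crm_length CRM length in bp.
#' @param specificity PWM consensus-base probability.
#' @return list: `dataset` (a [crm_dataset()]), `pwms`, `true_params`,
#'   `plans` (per-CRM planted-site data.frames).
#' @export
simulate_dataset <- function(n_crms = 10, true_params = default_true_params(),
                             noise_sd = 0, rng_seed = 1, bins = 60,
                             crm_length = 1000, specificity = 0.85) {
  tfs <- data.frame(
    name = c("actA", "actP", "repS1", "repS2"),
    role = c("activator", "activator", "repressor", "repressor"),
    stringsAsFactors = FALSE)
  consensi <- with_seed(derive_seed(rng_seed, 1L), vapply(seq_len(4), function(i)
    paste(sample(BASES, 8, replace = TRUE), collapse = ""), character(1)))
  pwms <- Map(function(cs, nm) make_pwm(cs, specificity, name = nm),
              consensi, tfs$name)
  names(pwms) <- tfs$name
  conc <- rbind(actA = make_gradient("anterior", bins),
                actP = make_gradient("posterior", bins),
                repS1 = make_gradient("stripe", bins, center = 0.35, width = 0.09),
                repS2 = make_gradient("stripe", bins, center = 0.65, width = 0.09))
  plans <- list(); seqs <- character(n_crms)
  names(seqs) <- sprintf("crm%02d", seq_len(n_crms))
  for (i in seq_len(n_crms)) {
    plan <- with_seed(derive_seed(rng_seed, 100L + i), {
      n_sites <- sample(4:8, 1)
      # each CRM is driven mainly by one of the two activators, so profiles
      # are spatially patterned rather than uniformly activated
      primary <- sample(c("actA", "actP"), 1)
      prob <- c(actA = 0.1, actP = 0.1, repS1 = 0.25, repS2 = 0.25)
      prob[primary] <- 0.4
      repeat {
        tf_draw <- sample(tfs$name, n_sites, replace = TRUE, prob = prob)
        if (sum(tf_draw == primary) >= 2) break
      }
      slots <- seq(10L, crm_length - 20L, by = 16L)
      data.frame(tf = tf_draw,
                 position = sort(sample(slots, n_sites)),
                 strength = runif(n_sites, 0.6, 1),
                 stringsAsFactors = FALSE)
    })
    plans[[names(seqs)[i]]] <- plan
    seqs[i] <- make_crm(plan, pwms, crm_length, derive_seed(rng_seed, 200L + i))
  }
  params_pred <- true_params
  sites_list <- lapply(seqs, annotate_sites, pwms = pwms)
  roles <- setNames(tfs$role, tfs$name)
  expr <- t(vapply(names(seqs), function(nm)
    predict_profile(sites_list[[nm]], params_pred, conc, roles),
    numeric(bins)))
  # rescale each CRM's profile to max 1 (observed profiles are relative)
  mx <- apply(expr, 1, max)
  expr <- expr / ifelse(mx > 0, mx, 1)
  if (noise_sd > 0)
    expr <- with_seed(derive_seed(rng_seed, 300L), {
      pmin(pmax(expr + matrix(rnorm(length(expr), sd = noise_sd),
                              nrow(expr)), 0), 1)
    })
  list(dataset = crm_dataset(seqs, expr, conc, tfs), pwms = pwms,
       true_params = true_params, plans = plans)
}

#' Synthetic ortholog alignment with planted site turnover
#'
#' Produces a gap-free alignment of a CRM across several species: neutral
#' substitutions are applied outside the planted site windows at
#' `mutation_rate` per base, planted sites are kept intact except the named
#' lineage-specific losses, which are ablated by replacing the window with
#' the PWM's anti-consensus word.
#'
#' @param seq reference CRM sequence.
#' @param site_plan data.frame with columns `tf` and `position` naming the
#'   planted windows (as given to [make_crm()]).
#' @param pwms named list of [pwm()] objects.
#' @param species total number of sequences (reference included).
#' @param mutation_rate per-base substitution probability outside sites.
#' @param planted_losses data.frame with columns `species` (2..species) and
#'   `site` (row of `site_plan`) naming the losses.
#' @param rng_seed seed for the neutral substitutions.
#' @return named character vector (`ref`, `species2`, ...) of equal-length
#'   sequences, a valid gap-free alignment.
#' @export
make_ortholog_alignment <- function(seq, site_plan, pwms, species = 6,
                                    mutation_rate = 0.05,
                                    planted_losses = NULL, rng_seed = 1) {
  pw <- setNames(pwms, vapply(pwms, `[[`, "", "name"))
  L <- nchar(seq)
  in_site <- rep(FALSE, L)
  for (k in seq_len(nrow(site_plan))) {
    w <- pw[[site_plan$tf[k]]]$width
    in_site[(site_plan$position[k] + 1):(site_plan$position[k] + w)] <- TRUE
  }
  anti_word <- function(p) {
    m <- llr_matrix(p)
    paste(BASES[apply(m, 1, which.min)], collapse = "")
  }
  ref_chars <- strsplit(toupper(seq), "")[[1]]
  out <- setNames(character(species),
                  c("ref", paste0("species", seq_len(species))[-1]))
  out[1] <- seq
  for (s in 2:species) {
    chars <- with_seed(derive_seed(rng_seed, 1000L + s), {
      ch <- ref_chars
      hit <- which(!in_site & runif(L) < mutation_rate)
      for (pos in hit) ch[pos] <- sample(setdiff(BASES, ch[pos]), 1)
      ch
    })
    if (!is.null(planted_losses)) {
      lost <- planted_losses$site[planted_losses$species == s]
      for (k in lost) {
        p <- pw[[site_plan$tf[k]]]
        chars[(site_plan$position[k] + 1):(site_plan$position[k] + p$width)] <-
          strsplit(anti_word(p), "")[[1]]
      }
    }
    out[s] <- paste(chars, collapse = "")
  }
  out
}
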