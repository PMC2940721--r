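#' Average-correlation objective
#'
#' Mean over CRMs of the Pearson correlation between predicted and observed
#' expression profiles. A CRM whose predicted or observed profile is constant
#' across bins contributes 0 (correlation undefined there; flat predictions
#' are thereby penalized, not fatal). Scale- and offset-invariant per CRM.
#'
#' @param params a [model_params()].
#' @param dataset a [crm_dataset()].
#' @param sites_list per-CRM `binding_sites` (from [annotate_dataset()]).
#' @return average CC (numeric scalar).
#' @export
objective_avg_cc <- function(params, dataset, sites_list) {
  pred <- predict_dataset(dataset, sites_list, params)
  mean(profile_cc(pred, dataset$expr))
}

# rowwise Pearson CC with the constant-vector-scores-0 convention
profile_cc <- function(pred, obs) {
  vapply(seq_len(nrow(pred)), function(i) {
    p <- pred[i, ]; o <- obs[i, ]
    if (sd(p) == 0 || sd(o) == 0) return(0)
    cor(p, o)
  }, numeric(1))
}

#' Sum-of-squared-errors objective with per-CRM scaling
#'
#' For each CRM a free non-negative scale `s` is fitted in closed form
#' (`s = max(0, <pred, obs> / <pred, pred>)`) before squaring the residuals,
#' so only profile shapes are compared -- observed profiles are on an
#' arbitrary 0-to-1 scale. Returns the total over CRMs.
#'
#' @inheritParams objective_avg_cc
#' @return total SSE (numeric scalar).
#' @export
objective_sse <- function(params, dataset, sites_list) {
  pred <- predict_dataset(dataset, sites_list, params)
  sum(vapply(seq_len(nrow(pred)), function(i)
    scaled_sse(pred[i, ], dataset$expr[i, ]), numeric(1)))
}

scaled_sse <- function(p, o) {
  pp <- sum(p * p)
  s <- if (pp == 0) 0 else max(0, sum(p * o) / pp)
  sum((s * p - o)^2)
}

#' Fitting options
#'
#' @param objective `"cc"`, `"sse"` or `"alternate"` (Nelder-Mead on CC
#'   alternating with quasi-Newton on SSE, the default).
#' @param restarts number of random restarts (best kept).
#' @param rng_seed integer seed governing the random starts and any fold
#'   shuffling.
#' @param maxit_simplex,maxit_bfgs iteration caps per optimizer stage.
#' @param cycles CC/SSE alternation cycles per restart.
#' @param cv_folds folds for [cross_validate()].
#' @param bounds list of random-start ranges (log-uniform draws):
#'   `binding_k`, `alpha_act` (as alpha - 1), `alpha_rep`, `omega` (as
#'   omega - 1), `beta`, `q_btm`.
#' @return list of class `"fit_options"`.
#' @export
fit_options <- function(objective = c("alternate", "cc", "sse"), restarts = 5,
                        rng_seed = 1, maxit_simplex = 400, maxit_bfgs = 100,
                        cycles = 2, cv_folds = 10,
                        bounds = list(binding_k = c(1e-3, 1e3),
                                      alpha_act = c(1e-2, 99),
                                      alpha_rep = c(1e-3, 0.999),
                                      omega = c(1e-2, 99),
                                      beta = c(1e-2, 100),
                                      q_btm = c(1e-4, 1))) {
  structure(list(objective = match.arg(objective), restarts = restarts,
                 rng_seed = rng_seed, maxit_simplex = maxit_simplex,
                 maxit_bfgs = maxit_bfgs, cycles = cycles, cv_folds = cv_folds,
                 bounds = bounds),
            class = "fit_options")
}

# ---- parameter transforms -------------------------------------------------
# Free parameters live in an unconstrained space: log for positives,
# log(alpha - 1) for activators (alpha > 1), logit for repressor alpha in
# (0, 1), log(omega - 1) for cooperativity weights (omega >= 1). Role bounds
# therefore hold by construction for any optimizer iterate.

param_template <- function(dataset, settings) {
  roles <- tf_roles(dataset)
  tfs <- dataset$tfs$name
  list(tfs = tfs, roles = roles,
       coop_pairs = settings$coop_pairs %||% character(0),
       mode = settings$mode %||% "direct",
       n_ma = settings$n_ma %||% Inf,
       coop_range = settings$coop_range %||% 50,
       d_r = settings$d_r %||% 250,
       q_btm_fixed = settings$q_btm_fixed %||% NULL,
       block_repressors = isTRUE(settings$block_repressors))
}

theta_length <- function(tmpl) {
  n <- 2 * length(tmpl$tfs) + length(tmpl$coop_pairs)
  if (tmpl$mode == "srr") n <- n + sum(tmpl$roles == "repressor")
  if (is.null(tmpl$q_btm_fixed)) n <- n + 1
  n
}

theta_to_params <- function(theta, tmpl) {
  tfs <- tmpl$tfs
  k <- exp(theta[seq_along(tfs)])
  names(k) <- tfs
  off <- length(tfs)
  a <- numeric(length(tfs)); names(a) <- tfs
  for (i in seq_along(tfs)) {
    x <- theta[off + i]
    a[i] <- if (tmpl$roles[[tfs[i]]] == "activator") 1 + exp(x) else plogis(x)
  }
  off <- off + length(tfs)
  omega <- NULL
  if (length(tmpl$coop_pairs)) {
    omega <- 1 + exp(theta[off + seq_along(tmpl$coop_pairs)])
    names(omega) <- tmpl$coop_pairs
    off <- off + length(tmpl$coop_pairs)
  }
  beta <- NULL
  if (tmpl$mode == "srr") {
    reps <- tfs[tmpl$roles[tfs] == "repressor"]
    beta <- exp(theta[off + seq_along(reps)])
    names(beta) <- reps
    off <- off + length(reps)
  }
  q_btm <- if (is.null(tmpl$q_btm_fixed)) exp(theta[off + 1]) else tmpl$q_btm_fixed
  model_params(binding_k = k, alpha = a, omega = omega, beta = beta,
               q_btm = q_btm, coop_range = tmpl$coop_range, d_r = tmpl$d_r,
               n_ma = tmpl$n_ma, mode = tmpl$mode,
               block_repressors = tmpl$block_repressors)
}

params_to_theta <- function(params, tmpl) {
  tfs <- tmpl$tfs
  th <- log(unname(params$binding_k[tfs]))
  th <- c(th, vapply(tfs, function(tf) {
    a <- params$alpha[[tf]]
    if (tmpl$roles[[tf]] == "activator") log(a - 1) else qlogis(a)
  }, numeric(1)))
  if (length(tmpl$coop_pairs))
    th <- c(th, log(unname(params$omega[tmpl$coop_pairs]) - 1))
  if (tmpl$mode == "srr") {
    reps <- tfs[tmpl$roles[tfs] == "repressor"]
    th <- c(th, log(unname(params$beta[reps])))
  }
  if (is.null(tmpl$q_btm_fixed)) th <- c(th, log(params$q_btm))
  unname(th)
}

random_theta <- function(tmpl, bounds) {
  lu <- function(rng, n = 1) exp(runif(n, log(rng[1]), log(rng[2])))
  tfs <- tmpl$tfs
  th <- log(lu(bounds$binding_k, length(tfs)))
  th <- c(th, vapply(tfs, function(tf) {
    if (tmpl$roles[[tf]] == "activator") log(lu(bounds$alpha_act))
    else qlogis(lu(bounds$alpha_rep))
  }, numeric(1)))
  if (length(tmpl$coop_pairs)) th <- c(th, log(lu(bounds$omega, length(tmpl$coop_pairs))))
  if (tmpl$mode == "srr")
    th <- c(th, log(lu(bounds$beta, sum(tmpl$roles == "repressor"))))
  if (is.null(tmpl$q_btm_fixed)) th <- c(th, log(lu(bounds$q_btm)))
  unname(th)
}

#' Fit model parameters to a dataset
#'
#' Maximum-agreement training: from each random start (log-uniform within the
#' option bounds, deterministic given `rng_seed`), runs `cycles` rounds of a
#' Nelder-Mead simplex stage followed by a quasi-Newton (BFGS, numerical
#' gradients) stage in the unconstrained parameter space, alternating the
#' average-CC and scaled-SSE objectives when `objective = "alternate"`. The
#' restart with the best primary objective (average CC, or SSE when
#' `objective = "sse"`) is returned.
#'
#' @param dataset a [crm_dataset()].
#' @param sites_list per-CRM `binding_sites` (from [annotate_dataset()]).
#' @param settings model-structure settings: list with any of `mode`
#'   ("direct"/"srr"), `n_ma`, `coop_range`, `d_r`, `coop_pairs` (character
#'   vector of "TF1:TF2"), `q_btm_fixed`, `block_repressors`.
#' @param options a [fit_options()].
#' @return list of class `"fit_result"`: `params`, `train_cc`, `train_sse`,
#'   `per_crm_cc`, `trace` (per stage objective values), `seed`.
#' @export
fit_model <- function(dataset, sites_list, settings = list(),
                      options = fit_options()) {
  tmpl <- param_template(dataset, settings)
  neg_cc <- function(th) {
    v <- try(objective_avg_cc(theta_to_params(th, tmpl), dataset, sites_list),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e6 else -v
  }
  sse_fn <- function(th) {
    v <- try(objective_sse(theta_to_params(th, tmpl), dataset, sites_list),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e6 else v
  }
  primary <- switch(options$objective, sse = sse_fn, neg_cc)
  stage1 <- switch(options$objective, sse = sse_fn, neg_cc)
  stage2 <- switch(options$objective, cc = neg_cc, sse_fn)

  best <- NULL; best_val <- Inf; trace <- list()
  n_ok <- 0
  for (r in seq_len(options$restarts)) {
    th <- with_seed(derive_seed(options$rng_seed, r),
                    random_theta(tmpl, options$bounds))
    if (!is.finite(primary(th)) || primary(th) >= 1e6) {
      trace[[length(trace) + 1L]] <- list(restart = r, stage = "start", value = NA_real_)
      next
    }
    n_ok <- n_ok + 1
    for (cyc in seq_len(options$cycles)) {
      o1 <- optim(th, stage1, method = "Nelder-Mead",
                  control = list(maxit = options$maxit_simplex))
      th <- o1$par
      trace[[length(trace) + 1L]] <-
        list(restart = r, stage = paste0("simplex", cyc), value = o1$value)
      o2 <- optim(th, stage2, method = "BFGS",
                  control = list(maxit = options$maxit_bfgs, ndeps = rep(1e-4, length(th))))
      th <- o2$par
      trace[[length(trace) + 1L]] <-
        list(restart = r, stage = paste0("bfgs", cyc), value = o2$value)
    }
    val <- primary(th)
    if (val < best_val) { best_val <- val; best <- th }
  }
  if (n_ok == 0)
    stop("non-finite objective at every random start (", options$restarts,
         " restarts, seed ", options$rng_seed, ")")
  params <- theta_to_params(best, tmpl)
  pred <- predict_dataset(dataset, sites_list, params)
  per_cc <- profile_cc(pred, dataset$expr)
  names(per_cc) <- rownames(pred)
  structure(list(params = params, train_cc = mean(per_cc),
                 train_sse = objective_sse(params, dataset, sites_list),
                 per_crm_cc = per_cc,
                 trace = do.call(rbind, lapply(trace, as.data.frame)),
                 seed = options$rng_seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: train avg CC %.4f (SSE %.4f), %d CRMs\n",
              x$train_cc, x$train_sse, length(x$per_crm_cc)))
  print(x$params)
  invisible(x)
}

#' k-fold cross-validation
#'
#' Shuffles the CRMs into `options$cv_folds` folds (deterministic given
#' `rng_seed`), fits on each training split and predicts the held-out CRMs
#' with the fitted parameters. The CVCC is the average held-out CC over all
#' CRMs; it depends on the partition, which is returned.
#'
#' @inheritParams fit_model
#' @return list: `cvcc`, `per_crm_cc` (held-out CC per CRM), `folds`
#'   (fold assignment), `fits` (per-fold `fit_result`s).
#' @export
cross_validate <- function(dataset, sites_list, settings = list(),
                           options = fit_options()) {
  n <- length(dataset$seqs)
  k <- options$cv_folds
  if (k > n) stop("cv_folds (", k, ") exceeds the number of CRMs (", n, ")")
  folds <- with_seed(derive_seed(options$rng_seed, 99991L),
                     sample(rep_len(seq_len(k), n)))
  names(folds) <- names(dataset$seqs)
  per_cc <- setNames(numeric(n), names(dataset$seqs))
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- names(folds)[folds == f]
    train <- names(folds)[folds != f]
    if (length(hold) < 1) stop("empty fold ", f)
    dtrain <- crm_dataset(dataset$seqs[train],
                          dataset$expr[train, , drop = FALSE],
                          dataset$conc, dataset$tfs)
    fit <- fit_model(dtrain, sites_list[train], settings, options)
    fits[[f]] <- fit
    roles <- tf_roles(dataset)
    for (nm in hold) {
      p <- predict_profile(sites_list[[nm]], fit$params, dataset$conc, roles)
      o <- dataset$expr[nm, ]
      per_cc[nm] <- if (sd(p) == 0 || sd(o) == 0) 0 else cor(p, o)
    }
  }
  list(cvcc = mean(per_cc), per_crm_cc = per_cc, folds = folds, fits = fits)
}
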