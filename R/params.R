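#' Model parameters
#'
#' Collects every free parameter and structural setting of the thermodynamic
#' model.
#'
#' * `binding_k`: per-TF lumped binding constant `K(S_max) * nu`; the weight
#'   of the TF's optimal site at relative concentration 1.
#' * `alpha`: per-TF BTM-interaction weight; `> 1` for activators, in `(0, 1)`
#'   for repressors (direct-interaction mode). In SRR mode only activator
#'   alphas enter the model.
#' * `omega`: cooperativity weights, named `"TF1:TF2"`; applies to adjacent
#'   bound sites of declared partner pairs whose edge-to-edge gap `d`
#'   satisfies `0 < d <= coop_range`.
#' * `beta`: per-repressor weight of the bound-effective (chromatin-closing)
#'   state, SRR mode only.
#' * `q_btm`: statistical weight of BTM binding at the promoter; sets the
#'   basal expression `q_btm / (1 + q_btm)`.
#' * `d_r`: repression range in bp (SRR); default 250. `d_r = 10`
#'   approximates repression by competitive binding.
#' * `n_ma`: maximum number of bound activators simultaneously contacting the
#'   BTM. `Inf` is the multiplicative-effect model (every bound activator
#'   contributes its alpha as a factor); `1` the additive-effect model
#'   (`Q = sum alpha_i` over bound activators); intermediate values limit the
#'   contact count.
#' * `mode`: `"direct"` (repressors interact with the BTM via `alpha < 1`) or
#'   `"srr"` (short-range repression: three-state repressor sites, `beta`
#'   weights, activator exclusion within `d_r`).
#'
#' @param binding_k named positive numeric vector (one per TF).
#' @param alpha named positive numeric vector (one per TF).
#' @param omega named numeric vector of cooperativity weights or NULL.
#' @param beta named non-negative numeric vector (per repressor) or NULL.
#' @param q_btm positive scalar.
#' @param coop_range cooperativity distance cutoff `d_c` in bp.
#' @param d_r repression range in bp.
#' @param n_ma positive integer or `Inf`.
#' @param mode `"direct"` or `"srr"`.
#' @param block_repressors logical; if TRUE a bound-effective repressor also
#'   blocks other repressor sites within `d_r` (off by default: only activator
#'   sites are quenched).
#' @return object of class `"model_params"`.
#' @export
model_params <- function(binding_k, alpha, omega = NULL, beta = NULL,
                         q_btm = 0.1, coop_range = 50, d_r = 250,
                         n_ma = Inf, mode = c("direct", "srr"),
                         block_repressors = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(binding_k), !is.null(names(binding_k)), all(binding_k > 0))
  stopifnot(is.numeric(alpha), !is.null(names(alpha)), all(alpha > 0))
  if (!setequal(names(binding_k), names(alpha)))
    stop("binding_k and alpha must cover the same TFs")
  if (!is.null(omega)) {
    stopifnot(is.numeric(omega), !is.null(names(omega)), all(omega > 0))
    if (!all(grepl(":", names(omega))))
      stop("omega names must be 'TF1:TF2' pairs")
  }
  if (!is.null(beta)) stopifnot(is.numeric(beta), !is.null(names(beta)), all(beta >= 0))
  stopifnot(q_btm > 0, d_r >= 0, coop_range >= 0)
  if (!(is.infinite(n_ma) || (n_ma >= 1 && n_ma == floor(n_ma))))
    stop("n_ma must be a positive integer or Inf")
  structure(list(binding_k = binding_k, alpha = alpha[names(binding_k)],
                 omega = omega, beta = beta, q_btm = q_btm,
                 coop_range = coop_range, d_r = d_r, n_ma = n_ma, mode = mode,
                 block_repressors = block_repressors),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Thermodynamic model parameters (mode=%s, n_ma=%s)\n", x$mode,
              format(x$n_ma)))
  cat("  binding_k:", paste(sprintf("%s=%.4g", names(x$binding_k), x$binding_k),
                            collapse = " "), "\n")
  cat("  alpha:    ", paste(sprintf("%s=%.4g", names(x$alpha), x$alpha),
                            collapse = " "), "\n")
  if (length(x$omega))
    cat("  omega:    ", paste(sprintf("%s=%.4g", names(x$omega), x$omega),
                              collapse = " "), sprintf(" (range %g bp)", x$coop_range), "\n")
  if (length(x$beta))
    cat("  beta:     ", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                              collapse = " "), sprintf(" (d_r %g bp)", x$d_r), "\n")
  cat(sprintf("  q_btm: %.4g (basal expression %.4g)\n", x$q_btm,
              x$q_btm / (1 + x$q_btm)))
  invisible(x)
}

# omega weight for a TF pair, defaulting to 1 (no interaction)
omega_of <- function(params, tf1, tf2) {
  if (!length(params$omega)) return(1)
  key1 <- paste(tf1, tf2, sep = ":")
  key2 <- paste(tf2, tf1, sep = ":")
  if (key1 %in% names(params$omega)) unname(params$omega[key1])
  else if (key2 %in% names(params$omega)) unname(params$omega[key2])
  else 1
}

#' CRM dataset container
#'
#' Bin-aligned bundle of CRM sequences with observed expression profiles and
#' TF concentration profiles, as used for training and evaluation.
#'
#' @param seqs named character vector of CRM sequences.
#' @param expr numeric matrix (CRM x bins) of observed expression in `[0, 1]`;
#'   rownames must match `names(seqs)`.
#' @param conc numeric matrix (TF x bins) of relative TF concentrations in
#'   `[0, 1]`.
#' @param tfs data.frame with columns `name` and `role`
#'   (activator/repressor), one row per TF; rownames of `conc` must match.
#' @return object of class `"crm_dataset"`.
#' @export
crm_dataset <- function(seqs, expr, conc, tfs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  expr <- as.matrix(expr); conc <- as.matrix(conc)
  if (!identical(sort(rownames(expr)), sort(names(seqs))))
    stop("expr rownames must match CRM names")
  expr <- expr[names(seqs), , drop = FALSE]
  if (ncol(expr) != ncol(conc))
    stop("expression and concentration profiles must share the bin count")
  if (!all(tfs$name %in% rownames(conc)))
    stop("missing concentration profile for TF(s): ",
         paste(setdiff(tfs$name, rownames(conc)), collapse = ", "))
  conc <- conc[tfs$name, , drop = FALSE]
  if (any(conc < 0) || any(expr < 0)) stop("profiles must be non-negative")
  structure(list(seqs = seqs, expr = expr, conc = conc,
                 tfs = as.data.frame(tfs), bins = ncol(expr)),
            class = "crm_dataset")
}

#' @export
print.crm_dataset <- function(x, ...) {
  cat(sprintf("CRM dataset: %d CRMs x %d bins, %d TFs (%s)\n",
              length(x$seqs), x$bins, nrow(x$tfs),
              paste(sprintf("%s[%s]", x$tfs$name, substr(x$tfs$role, 1, 1)),
                    collapse = ", ")))
  invisible(x)
}

#' Restrict a dataset to a bin window
#'
#' Trims observed and concentration profiles to columns `from..to` (1-based,
#' inclusive). With 100-bin anterior-posterior profiles, `from = 21, to = 80`
#' keeps the 60 bins between 20% and 80% egg length.
#'
#' @param dataset a [crm_dataset()].
#' @param from,to 1-based inclusive column indices.
#' @return trimmed [crm_dataset()].
#' @export
trim_bins <- function(dataset, from, to) {
  stopifnot(from >= 1, to <= dataset$bins, from <= to)
  crm_dataset(dataset$seqs, dataset$expr[, from:to, drop = FALSE],
              dataset$conc[, from:to, drop = FALSE], dataset$tfs)
}

# role lookup helper
tf_roles <- function(dataset) setNames(dataset$tfs$role, dataset$tfs$name)

#' Annotate binding sites on every CRM of a dataset
#'
#' @param dataset a [crm_dataset()].
#' @param pwms list of [pwm()] objects (names must match the dataset's TFs).
#' @param threshold_frac LLR threshold fraction, default 0.4.
#' @return named list of `binding_sites` data.frames, one per CRM.
#' @export
annotate_dataset <- function(dataset, pwms, threshold_frac = 0.4) {
  lapply(dataset$seqs, annotate_sites, pwms = pwms, threshold_frac = threshold_frac)
}
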