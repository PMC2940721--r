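#' Evaluate a model on a dataset
#'
#' Computes per-CRM Pearson CC between predicted and observed profiles, the
#' average CC, and the number of CRMs predicted accurately (CC strictly above
#' 0.65).
#'
#' @param params a [model_params()].
#' @param dataset a [crm_dataset()].
#' @param sites_list per-CRM `binding_sites`.
#' @param cc_threshold accuracy cut-off on the per-CRM CC (strict `>`).
#' @return list of class `"model_report"`: `per_crm_cc`, `avg_cc`,
#'   `n_accurate`, `pred` (CRM x bins prediction matrix).
#' @export
evaluate_model <- function(params, dataset, sites_list, cc_threshold = 0.65) {
  pred <- predict_dataset(dataset, sites_list, params)
  cc <- profile_cc(pred, dataset$expr)
  names(cc) <- rownames(pred)
  structure(list(per_crm_cc = cc, avg_cc = mean(cc),
                 n_accurate = sum(cc > cc_threshold),
                 cc_threshold = cc_threshold, pred = pred),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Model report: avg CC %.4f over %d CRMs; %d with CC > %.2f\n",
              x$avg_cc, length(x$per_crm_cc), x$n_accurate, x$cc_threshold))
  invisible(x)
}

#' In-silico knock-down of a TF
#'
#' Re-predicts the dataset with the named TF's concentration set to 0 in
#' every bin (no refitting) and evaluates the perturbed predictions. The drop
#' in CC relative to [evaluate_model()] visualizes the TF's contribution to
#' the model.
#'
#' @inheritParams evaluate_model
#' @param tf_name TF to knock down.
#' @return a `"model_report"` for the perturbed model.
#' @export
knockdown <- function(params, dataset, sites_list, tf_name, cc_threshold = 0.65) {
  if (!tf_name %in% dataset$tfs$name)
    stop("unknown TF: ", tf_name)
  kd <- dataset
  kd$conc[tf_name, ] <- 0
  evaluate_model(params, kd, sites_list, cc_threshold)
}

#' Best-K average-CC curves
#'
#' For each model, sorts CRMs by that model's own CC (descending) and reports
#' the mean CC of its top K CRMs for K = 1..#CRMs. A companion model (e.g. a
#' knock-down of its parent) is averaged over the *same* K CRMs as its
#' parent, so the curve shows the perturbation's effect on the parent's best
#' predictions.
#'
#' @param reports named list of `"model_report"` objects.
#' @param companions optional named list mapping a companion report name to
#'   its parent's name, e.g. `list("DI-kd" = "DI")`.
#' @return data.frame with columns `K` and one column per model.
#' @export
best_k_curve <- function(reports, companions = list()) {
  stopifnot(length(reports) >= 1)
  n <- length(reports[[1]]$per_crm_cc)
  out <- data.frame(K = seq_len(n))
  orders <- lapply(reports, function(r) order(r$per_crm_cc, decreasing = TRUE))
  for (nm in names(reports)) {
    parent <- companions[[nm]] %||% nm
    ord <- orders[[parent]]
    cc <- reports[[nm]]$per_crm_cc[ord]
    out[[nm]] <- cumsum(cc) / seq_len(n)
  }
  out
}

#' Compare two models on the same dataset
#'
#' Per-CRM difference in CC (model B minus model A), with a per-CRM one-sided
#' significance estimate from a seeded bootstrap over bins (bin indices are
#' resampled with replacement, both models' CCs recomputed on the resampled
#' bins, and the tail probability of no improvement taken). Per-CRM p-values
#' are combined across CRMs by Fisher's method. The bin bootstrap + Fisher
#' combination is this package's convention for the improvement test. Also
#' reports the descriptive better/worse counts under the visual criterion
#' (winner CC >= 0.65 and |delta CC| >= 0.05).
#'
#' @param report_a,report_b `"model_report"` objects for the two models,
#'   evaluated on identical CRMs and bins (B is the candidate improvement).
#' @param dataset the [crm_dataset()] both were evaluated on.
#' @param n_boot bootstrap replicates per CRM.
#' @param rng_seed seed for the bin resampling.
#' @return list: `per_crm` data.frame (`crm`, `cc_a`, `cc_b`, `delta_cc`,
#'   `p`), `combined_p` (Fisher), `n_better`, `n_worse`.
#' @export
compare_models <- function(report_a, report_b, dataset, n_boot = 200,
                           rng_seed = 1) {
  crms <- names(report_a$per_crm_cc)
  if (!identical(crms, names(report_b$per_crm_cc)))
    stop("models were evaluated on different CRM sets")
  nb <- ncol(report_a$pred)
  boot_cc <- function(p, o, idx) {
    if (sd(p[idx]) == 0 || sd(o[idx]) == 0) 0 else cor(p[idx], o[idx])
  }
  per <- with_seed(rng_seed, {
    do.call(rbind, lapply(crms, function(nm) {
      pa <- report_a$pred[nm, ]; pb <- report_b$pred[nm, ]
      o <- dataset$expr[nm, ]
      delta <- report_b$per_crm_cc[[nm]] - report_a$per_crm_cc[[nm]]
      wins <- 0L
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nb, nb, replace = TRUE)
        if (boot_cc(pb, o, idx) - boot_cc(pa, o, idx) <= 0) wins <- wins + 1L
      }
      data.frame(crm = nm, cc_a = report_a$per_crm_cc[[nm]],
                 cc_b = report_b$per_crm_cc[[nm]], delta_cc = delta,
                 p = (wins + 1) / (n_boot + 1), stringsAsFactors = FALSE)
    }))
  })
  rownames(per) <- NULL
  x2 <- -2 * sum(log(per$p))
  combined_p <- pchisq(x2, df = 2 * nrow(per), lower.tail = FALSE)
  better <- sum(per$cc_b >= 0.65 & per$delta_cc >= 0.05)
  worse <- sum(per$cc_a >= 0.65 & per$delta_cc <= -0.05)
  list(per_crm = per, combined_p = combined_p,
       n_better = better, n_worse = worse)
}
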