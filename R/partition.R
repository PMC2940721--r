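#' Statistical weight of a single bound site
#'
#' The contribution `q(S)` of one occupied site to a configuration's weight:
#' `binding_k[tf] * conc * exp(llr - llr_max)` (Berg-von Hippel mismatch
#' form). The optimal site at relative concentration 1 has weight
#' `binding_k[tf]`.
#'
#' @param site one-row `binding_sites` data.frame (or list with `tf`, `llr`,
#'   `llr_max`).
#' @param params a [model_params()].
#' @param conc relative TF concentration (scalar, `>= 0`).
#' @return numeric weight.
#' @export
site_weight <- function(site, params, conc) {
  stopifnot(conc >= 0)
  k <- params$binding_k[[site$tf]]
  if (is.null(k)) stop("no binding_k for TF ", site$tf)
  unname(k * conc * exp(site$llr - site$llr_max))
}

# per-site q values for one bin: named conc vector (one entry per TF)
site_q <- function(sites, params, concs) {
  if (nrow(sites) == 0) return(numeric(0))
  missing <- setdiff(unique(sites$tf), names(concs))
  if (length(missing))
    stop("missing concentration for TF(s): ", paste(missing, collapse = ", "))
  unname(params$binding_k[sites$tf] * concs[sites$tf] * exp(sites$llr - sites$llr_max))
}

check_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("tf", "start", "length", "llr", "llr_max") %in% names(sites)))
  if (nrow(sites) > 1 && is.unsorted(sites$start)) stop("sites must be sorted by start")
  invisible(sites)
}

# edge-to-edge gap between site intervals (0 when abutting or overlapping)
site_gap <- function(sites, i, j) {
  a <- min(i, j); b <- max(i, j)
  if (sites$start[a] > sites$start[b]) { tmp <- a; a <- b; b <- tmp }
  max(0, sites$start[b] - (sites$start[a] + sites$length[a]))
}

sites_overlap <- function(sites, i, j) {
  s1 <- sites$start[i]; e1 <- s1 + sites$length[i]
  s2 <- sites$start[j]; e2 <- s2 + sites$length[j]
  s1 < e2 && s2 < e1
}

# omega factor for an adjacent bound pair (gap rule: 0 < d <= coop_range)
adj_omega <- function(sites, i, j, params) {
  g <- site_gap(sites, i, j)
  if (g <= 0 || g > params$coop_range) return(1)
  omega_of(params, sites$tf[i], sites$tf[j])
}

#' Statistical weight of one binding-site configuration
#'
#' For an explicit set of bound sites, returns the TF-DNA weight `W` (product
#' of site weights and cooperativity factors over adjacent bound partner
#' pairs) and the TF-BTM weight `Q` under the chosen activation mode:
#' multiplicative (`n_ma = Inf`): product of alpha over all bound TFs
#' (direct-interaction convention); limited contact (finite `n_ma`): product
#' of repressor alphas times the sum, over non-empty contact subsets of bound
#' activators of size at most `n_ma`, of the product of their alphas (1 for
#' an empty activator set). With `n_ma = 1` this is `sum(alpha_i)` over bound
#' activators, the additive-effect model.
#'
#' @param sites `binding_sites` data.frame sorted by start.
#' @param bound integer indices (rows of `sites`) of the bound sites.
#' @param params a [model_params()].
#' @param concs named per-TF concentration vector (one bin).
#' @param roles named character vector of TF roles (`"activator"` /
#'   `"repressor"`); required for finite `n_ma`.
#' @return list with elements `W` and `Q`.
#' @export
config_weight <- function(sites, bound, params, concs, roles = NULL) {
  check_sites(sites)
  bound <- sort(as.integer(bound))
  if (length(bound) >= 2) {
    for (k in seq_len(length(bound) - 1))
      if (sites_overlap(sites, bound[k], bound[k + 1]))
        stop("bound sites overlap: rows ", bound[k], " and ", bound[k + 1])
  }
  q <- site_q(sites, params, concs)
  W <- prod(q[bound])
  if (length(bound) >= 2)
    for (k in seq_len(length(bound) - 1))
      W <- W * adj_omega(sites, bound[k], bound[k + 1], params)
  a <- unname(params$alpha[sites$tf[bound]])
  if (is.infinite(params$n_ma)) {
    Q <- prod(a)
  } else {
    if (is.null(roles)) stop("roles required for finite n_ma")
    is_act <- roles[sites$tf[bound]] == "activator"
    Q <- prod(a[!is_act]) * contact_sum(a[is_act], params$n_ma)
  }
  list(W = W, Q = Q)
}

# sum over non-empty subsets of size <= n_ma of prod(alphas); 1 if none bound
contact_sum <- function(alphas, n_ma) {
  m <- length(alphas)
  if (m == 0) return(1)
  tot <- 0
  for (mask in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(idx) <= n_ma) tot <- tot + prod(alphas[idx])
  }
  tot
}

partition_result <- function(z_on, z_off, q_btm) {
  if (!is.finite(z_on) || !is.finite(z_off))
    stop("partition function overflow: non-finite Z (weights too large)")
  structure(list(z_on = z_on, z_off = z_off,
                 expression = q_btm * z_on / (q_btm * z_on + z_off)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Z_ON = %.6g, Z_OFF = %.6g, expression = %.6g\n",
              x$z_on, x$z_off, x$expression))
  invisible(x)
}

# shared preparation for the Rcpp DPs
dp_inputs <- function(sites, params, concs) {
  tfs <- names(params$binding_k)
  tfi <- match(sites$tf, tfs) - 1L
  if (anyNA(tfi)) stop("site TF not in model parameters")
  omega_m <- matrix(1, length(tfs), length(tfs))
  if (length(params$omega)) {
    for (nm in names(params$omega)) {
      pr <- strsplit(nm, ":")[[1]]
      i <- match(pr[1], tfs); j <- match(pr[2], tfs)
      if (is.na(i) || is.na(j)) stop("omega pair ", nm, " names unknown TF")
      omega_m[i, j] <- omega_m[j, i] <- params$omega[[nm]]
    }
  }
  conc_m <- if (is.matrix(concs)) concs[tfs, , drop = FALSE]
            else matrix(concs[tfs], ncol = 1)
  if (anyNA(conc_m)) stop("missing concentration for TF(s): ",
                          paste(setdiff(tfs, rownames(concs) %||% names(concs)),
                                collapse = ", "))
  list(start = as.integer(sites$start),
       end = as.integer(sites$start + sites$length),
       tfi = tfi,
       qbase = unname(params$binding_k[sites$tf] * exp(sites$llr - sites$llr_max)),
       conc = conc_m,
       alpha = unname(params$alpha[tfs]),
       omega = omega_m)
}

#' Exact partition function, direct-interaction model
#'
#' Dynamic program implementing the nearest-occupied-site recurrences
#' `Z_OFF(i) = q(i) (1 + sum_j omega(i,j) Z_OFF(j))` and
#' `Z_ON(i) = q(i) alpha_f(i) (1 + sum_j omega(i,j) Z_ON(j))` over the
#' non-overlapping sites `j` left of `i`, with totals `1 + sum_i Z(i)` (the
#' constant 1 is the all-unbound configuration). Expression is
#' `q_btm Z_ON / (q_btm Z_ON + Z_OFF)`. Runs in `O(n * w)` time where `w` is
#' the number of sites within the cooperativity range.
#'
#' @param sites `binding_sites` data.frame sorted by start.
#' @param params a [model_params()] (multiplicative activation, `mode`
#'   "direct").
#' @param concs named per-TF concentration vector.
#' @return a `partition_result` with `z_on`, `z_off`, `expression`.
#' @export
partition_direct <- function(sites, params, concs) {
  check_sites(sites)
  if (nrow(sites) == 0) return(partition_result(1, 1, params$q_btm))
  inp <- dp_inputs(sites, params, concs)
  r <- dp_direct_cpp(inp$start, inp$end, inp$tfi, inp$qbase, inp$conc,
                     inp$alpha, inp$omega, params$coop_range, params$q_btm)
  partition_result(r$z_on[1], r$z_off[1], params$q_btm)
}

#' Exact partition function, limited-contact activation
#'
#' Direct-interaction model in which at most `n_ma` bound activators
#' simultaneously contact the BTM. The DP adds a contact-count dimension;
#' each bound activator either contacts the BTM (factor alpha) or not
#' (factor 1), the all-no-contact assignment being excluded whenever at least
#' one activator is bound. `n_ma = 1` yields the additive-effect model
#' `Q = sum(alpha_i)`; repressors contribute their alpha multiplicatively
#' regardless of mode.
#'
#' @inheritParams partition_direct
#' @param roles named TF role vector (`"activator"` / `"repressor"`).
#' @return a `partition_result`.
#' @export
partition_limited_contact <- function(sites, params, concs, roles) {
  check_sites(sites)
  n_ma <- params$n_ma
  if (is.infinite(n_ma)) stop("n_ma must be finite; use partition_direct for the multiplicative model")
  if (n_ma < 1) stop("n_ma must be >= 1")
  if (nrow(sites) == 0) return(partition_result(1, 1, params$q_btm))
  inp <- dp_inputs(sites, params, concs)
  is_act <- as.integer(roles[sites$tf] == "activator")
  if (anyNA(is_act)) stop("missing role for TF(s)")
  r <- dp_limited_cpp(inp$start, inp$end, inp$tfi, is_act, inp$qbase, inp$conc,
                      inp$alpha, inp$omega, params$coop_range, params$q_btm,
                      as.integer(n_ma))
  partition_result(r$z_on[1], r$z_off[1], params$q_btm)
}

#' Brute-force partition function by configuration enumeration
#'
#' Enumerates every bound/unbound assignment of the sites (and, for finite
#' `n_ma`, every activator contact subset), discards assignments with
#' overlapping bound sites, and sums `W` and `W * Q` exactly. Serves as the
#' independent oracle for the dynamic programs; refuses more than 20 sites.
#'
#' @inheritParams partition_limited_contact
#' @return a `partition_result`.
#' @export
brute_force_partition <- function(sites, params, concs, roles = NULL) {
  check_sites(sites)
  n <- nrow(sites)
  if (n > 20) stop("brute force refused for n > 20 sites")
  z_off <- 0; z_on <- 0
  masks <- if (n == 0) 0L else 0:(2^n - 1)
  for (mask in masks) {
    bound <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(bound) >= 2)
      for (k in seq_len(length(bound) - 1))
        if (sites_overlap(sites, bound[k], bound[k + 1])) { ok <- FALSE; break }
    if (!ok) next
    wq <- config_weight(sites, bound, params, concs, roles)
    z_off <- z_off + wq$W
    z_on <- z_on + wq$W * wq$Q
  }
  partition_result(z_on, z_off, params$q_btm)
}

#' Predict a CRM's expression profile across bins
#'
#' Evaluates the partition function at every bin with that bin's TF
#' concentrations and returns the predicted expression (BTM occupancy). The
#' model variant is taken from `params` (`mode`, `n_ma`).
#'
#' @param sites `binding_sites` for the CRM.
#' @param params a [model_params()].
#' @param conc TF x bins concentration matrix (rownames = TF names), e.g.
#'   `dataset$conc`.
#' @param roles named TF role vector; required unless mode is "direct" with
#'   `n_ma = Inf`.
#' @return numeric vector of per-bin expression values in (0, 1).
#' @export
predict_profile <- function(sites, params, conc, roles = NULL) {
  check_sites(sites)
  stopifnot(is.matrix(conc))
  missing <- setdiff(unique(sites$tf), rownames(conc))
  if (length(missing))
    stop("missing concentration for TF(s): ", paste(missing, collapse = ", "))
  nb <- ncol(conc)
  if (params$mode == "srr") {
    vapply(seq_len(nb), function(b)
      partition_srr(sites, params, setNames(conc[, b], rownames(conc)),
                    roles)$expression, numeric(1))
  } else if (nrow(sites) == 0) {
    rep(params$q_btm / (1 + params$q_btm), nb)
  } else {
    inp <- dp_inputs(sites, params, conc)
    r <- if (is.infinite(params$n_ma)) {
      dp_direct_cpp(inp$start, inp$end, inp$tfi, inp$qbase, inp$conc,
                    inp$alpha, inp$omega, params$coop_range, params$q_btm)
    } else {
      is_act <- as.integer(roles[sites$tf] == "activator")
      if (anyNA(is_act)) stop("missing role for TF(s)")
      dp_limited_cpp(inp$start, inp$end, inp$tfi, is_act, inp$qbase, inp$conc,
                     inp$alpha, inp$omega, params$coop_range, params$q_btm,
                     as.integer(params$n_ma))
    }
    if (any(!is.finite(r$expression)))
      stop("partition function overflow: non-finite Z (weights too large)")
    as.numeric(r$expression)
  }
}

#' Predict expression profiles for every CRM in a dataset
#'
#' @param dataset a [crm_dataset()].
#' @param sites_list named list of `binding_sites`, one per CRM (e.g. from
#'   [annotate_dataset()]).
#' @param params a [model_params()].
#' @return CRM x bins matrix of predicted expression.
#' @export
predict_dataset <- function(dataset, sites_list, params) {
  roles <- tf_roles(dataset)
  out <- t(vapply(names(dataset$seqs), function(nm)
    predict_profile(sites_list[[nm]], params, dataset$conc, roles),
    numeric(dataset$bins)))
  rownames(out) <- names(dataset$seqs)
  out
}
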