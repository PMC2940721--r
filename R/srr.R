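#' Exact partition function, short-range repression model
#'
#' Under short-range repression ("quenching") a bound repressor does not
#' interact with the BTM. Each repressor site has three states: unbound,
#' bound-only (weight `q`), and bound-effective (weight `beta_R * q`), the
#' latter closing the surrounding chromatin: no activator site whose
#' edge-to-edge distance from the repressor site is at most `d_r` may be
#' bound in the same configuration. `Q` collects activator alphas only,
#' according to the activation mode (`n_ma`).
#'
#' The DP sweeps sites left to right. Because adjacent bound sites never
#' overlap, the ends of bound sites increase along a configuration, so the
#' constraint state reduces to the identities of the last bound site (for
#' overlap and cooperativity), the last bound activator (to admit future
#' bound-effective repressors) and the last bound-effective repressor (to
#' admit future activators); states agreeing on this triple are merged, which
#' keeps the computation polynomial in the site count.
#'
#' @param sites `binding_sites` data.frame sorted by start.
#' @param params a [model_params()] with `mode = "srr"`, `beta` defined for
#'   every repressor.
#' @param concs named per-TF concentration vector (one bin).
#' @param roles named TF role vector (`"activator"` / `"repressor"`).
#' @return a `partition_result`.
#' @export
partition_srr <- function(sites, params, concs, roles) {
  check_sites(sites)
  if (is.null(roles)) stop("roles required for the SRR model")
  srr_check_beta(sites, params, roles)
  n <- nrow(sites)
  if (n == 0) return(partition_result(1, 1, params$q_btm))
  limited <- is.finite(params$n_ma)
  nc <- if (limited) params$n_ma + 1L else 1L

  z <- srr_forward(sites, params, concs, roles, nc, limited)
  z_off <- z$off
  if (!limited) {
    z_on <- z$on
  } else {
    # exclude the zero-contact assignment of configurations with >= 1 bound
    # activator: subtract Z_OFF and add back the activator-free mass
    rep_rows <- which(roles[sites$tf] == "repressor")
    z_noact <- if (length(rep_rows) == 0) 1 else
      srr_forward(sites[rep_rows, , drop = FALSE], params, concs, roles,
                  1L, FALSE)$off
    z_on <- z$on - (z_off - z_noact)
  }
  partition_result(z_on, z_off, params$q_btm)
}

srr_check_beta <- function(sites, params, roles) {
  reps <- unique(sites$tf[roles[sites$tf] == "repressor"])
  missing <- setdiff(reps, names(params$beta))
  if (length(missing))
    stop("repressor(s) lacking beta: ", paste(missing, collapse = ", "))
}

# Forward state-merging DP. State key "j|a|e": indices (0 = none) of the last
# bound site, last bound activator, last bound-effective repressor. Values:
# off = sum of W over configurations with that frontier; on = sum of W times
# the activator contribution to Q (multiplicative: product of contacted
# alphas; limited: vector over contact counts 0..n_ma).
srr_forward <- function(sites, params, concs, roles, nc, limited) {
  n <- nrow(sites)
  q <- site_q(sites, params, concs)
  act <- unname(roles[sites$tf] == "activator")
  beta <- unname(ifelse(act, 0, params$beta[sites$tf]))
  s0 <- sites$start
  e0 <- sites$start + sites$length
  alpha <- unname(params$alpha[sites$tf])
  d_r <- params$d_r
  block_rep <- isTRUE(params$block_repressors)

  on0 <- numeric(nc); on0[1] <- 1
  states <- list(`0|0|0` = list(off = 1, on = on0))
  for (i in seq_len(n)) {
    snapshot <- states
    for (key in names(snapshot)) {
      st <- snapshot[[key]]
      idx <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      j <- idx[1]; a <- idx[2]; e <- idx[3]
      if (j > 0 && e0[j] > s0[i]) next                     # overlaps last bound
      wfac <- q[i]
      if (j > 0) {
        g <- s0[i] - e0[j]
        if (g > 0 && g <= params$coop_range)
          wfac <- wfac * omega_of(params, sites$tf[i], sites$tf[j])
      }
      add_state <- function(key2, off_add, on_add) {
        cur <- states[[key2]]
        if (is.null(cur)) cur <- list(off = 0, on = numeric(nc))
        cur$off <- cur$off + off_add
        cur$on <- cur$on + on_add
        states[[key2]] <<- cur
      }
      if (act[i]) {
        if (e > 0 && s0[i] - e0[e] <= d_r) next            # quenched
        on_new <- if (!limited) st$on * alpha[i] else {
          v <- st$on                                        # no contact
          v[-1] <- v[-1] + alpha[i] * st$on[-nc]            # contact
          v
        }
        add_state(paste(i, i, e, sep = "|"), st$off * wfac, on_new * wfac)
      } else {
        blocked <- block_rep && e > 0 && s0[i] - e0[e] <= d_r
        if (!blocked)                                       # bound-only
          add_state(paste(i, a, e, sep = "|"), st$off * wfac, st$on * wfac)
        if (!blocked && (a == 0 || s0[i] - e0[a] > d_r))    # bound-effective
          add_state(paste(i, a, i, sep = "|"),
                    st$off * wfac * beta[i], st$on * wfac * beta[i])
      }
    }
  }
  off <- 0; on <- 0
  for (st in states) {
    off <- off + st$off
    on <- on + sum(st$on)
  }
  list(off = off, on = on)
}

#' Brute-force SRR partition function
#'
#' Enumerates every assignment of activator sites to {unbound, bound} and
#' repressor sites to {unbound, bound-only, bound-effective}, keeps the
#' legitimate configurations (no overlapping bound sites; no bound activator
#' within `d_r` of a bound-effective repressor), and sums `W` and `W * Q`
#' exactly. Oracle for [partition_srr()]; refuses state spaces above `3^13`.
#'
#' @inheritParams partition_srr
#' @return a `partition_result`.
#' @export
brute_force_srr <- function(sites, params, concs, roles) {
  check_sites(sites)
  srr_check_beta(sites, params, roles)
  n <- nrow(sites)
  act <- unname(roles[sites$tf] == "activator")
  n_states <- prod(ifelse(act, 2, 3))
  if (n_states > 3^13) stop("brute force refused: state space too large")
  q <- site_q(sites, params, concs)
  beta <- unname(ifelse(act, 0, params$beta[sites$tf]))
  alpha <- unname(params$alpha[sites$tf])
  d_r <- params$d_r
  block_rep <- isTRUE(params$block_repressors)
  n_ma <- params$n_ma

  gap_ok <- function(i, j) {                  # edge-to-edge distance > d_r
    if (sites_overlap(sites, i, j)) return(FALSE)
    site_gap(sites, i, j) > d_r
  }

  z_off <- 0; z_on <- 0
  nlev <- ifelse(act, 2L, 3L)
  state <- integer(n)
  repeat {
    bound <- which(state > 0)
    eff <- which(state == 2L)
    ok <- TRUE
    if (length(bound) >= 2)
      for (k in seq_len(length(bound) - 1))
        if (sites_overlap(sites, bound[k], bound[k + 1])) { ok <- FALSE; break }
    if (ok && length(eff)) {
      for (a_i in bound[act[bound] & state[bound] == 1L])
        for (e_i in eff)
          if (!gap_ok(a_i, e_i)) { ok <- FALSE; break }
      if (ok && block_rep)
        for (r_i in bound[!act[bound]])
          for (e_i in setdiff(eff, r_i))
            if (!gap_ok(r_i, e_i)) { ok <- FALSE; break }
    }
    if (ok) {
      W <- prod(q[bound]) * prod(beta[eff])
      if (length(bound) >= 2)
        for (k in seq_len(length(bound) - 1))
          W <- W * adj_omega(sites, bound[k], bound[k + 1], params)
      a_bound <- alpha[bound[act[bound]]]
      Q <- if (is.infinite(n_ma)) prod(a_bound) else contact_sum(a_bound, n_ma)
      z_off <- z_off + W
      z_on <- z_on + W * Q
    }
    # next mixed-radix state
    k <- 1L
    while (k <= n) {
      state[k] <- state[k] + 1L
      if (state[k] < nlev[k]) break
      state[k] <- 0L
      k <- k + 1L
    }
    if (k > n) break
  }
  partition_result(z_on, z_off, params$q_btm)
}

#' Repression by competitive binding
#'
#' The competition hypothesis -- repressors act only by occupying sites that
#' overlap or abut activator sites -- is the SRR model with the repression
#' range collapsed to ~10 bp. Convenience wrapper calling [partition_srr()]
#' with `d_r = 10`.
#'
#' @inheritParams partition_srr
#' @return a `partition_result`.
#' @export
competition_mode <- function(sites, params, concs, roles) {
  params$d_r <- 10
  partition_srr(sites, params, concs, roles)
}
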