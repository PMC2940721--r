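# Short-range repression: three-state sites, quenching legitimacy, limits

srr_params <- function(..., d_r = 100) {
  model_params(binding_k = c(A = 1, R = 1), alpha = c(A = 2, R = 1),
               beta = c(R = 1), q_btm = 0.1, d_r = d_r, mode = "srr", ...)
}
AR_ROLES <- c(A = "activator", R = "repressor")

test_that("the five legitimate configurations of an A/R pair are summed", {
  # activator (q=1, alpha=2) and repressor (q=1, beta=1) 50 bp apart, d_r=100:
  # legitimate configs {empty; A; R-only; R-eff; A+R-only}
  s <- mk_sites(c("A", "R"), c(0, 55))
  r <- partition_srr(s, srr_params(), c(A = 1, R = 1), AR_ROLES)
  expect_equal(r$z_off, 5)
  expect_equal(r$z_on, 7)
  expect_equal(r$expression, 0.7 / 5.7)
  bf <- brute_force_srr(s, srr_params(), c(A = 1, R = 1), AR_ROLES)
  expect_equal(bf$z_off, 5); expect_equal(bf$z_on, 7)
})

test_that("SRR DP equals three-state enumeration on random instances", {
  set.seed(31)
  for (k in 1:60) {
    inst <- rand_instance(sample(1:9, 1))
    p <- inst$params; p$mode <- "srr"
    bf <- brute_force_srr(inst$sites, p, inst$conc, inst$roles)
    dp <- partition_srr(inst$sites, p, inst$conc, inst$roles)
    expect_lt(max_rel_err(dp, bf), 1e-9)
    # limited-contact activation inside SRR
    pl <- p; pl$n_ma <- sample(1:3, 1)
    bfl <- brute_force_srr(inst$sites, pl, inst$conc, inst$roles)
    dpl <- partition_srr(inst$sites, pl, inst$conc, inst$roles)
    expect_lt(max_rel_err(dpl, bfl), 1e-9)
  }
})

test_that("SRR without repressor sites is identical to DirectInt", {
  set.seed(37)
  for (k in 1:10) {
    inst <- rand_instance(sample(1:8, 1), activators_only = TRUE)
    p <- inst$params; p$mode <- "srr"
    rs <- partition_srr(inst$sites, p, inst$conc, inst$roles)
    rd <- partition_direct(inst$sites, inst$params, inst$conc)
    expect_equal(rs$z_off, rd$z_off, tolerance = 1e-13)
    expect_equal(rs$z_on, rd$z_on, tolerance = 1e-13)
  }
})

test_that("beta = 0 reduces the repressor to pure site competition", {
  # with no effective state mass the repressor only competes for overlaps,
  # matching DirectInt with its alpha forced to 1
  set.seed(41)
  for (k in 1:10) {
    inst <- rand_instance(sample(2:8, 1))
    p <- inst$params
    p$mode <- "srr"
    p$beta[] <- 0
    rs <- partition_srr(inst$sites, p, inst$conc, inst$roles)
    pd <- inst$params
    pd$alpha[inst$roles[names(pd$alpha)] == "repressor"] <- 1
    rd <- partition_direct(inst$sites, pd, inst$conc)
    expect_equal(rs$z_off, rd$z_off, tolerance = 1e-12)
    expect_equal(rs$z_on, rd$z_on, tolerance = 1e-12)
  }
})

test_that("a repressor with an empty d_r neighborhood is expression-neutral", {
  p <- srr_params(d_r = 50)
  s <- mk_sites(c("A", "R"), c(0, 300))
  with_r <- partition_srr(s, p, c(A = 1, R = 2), AR_ROLES)
  without <- partition_srr(mk_sites("A", 0), p, c(A = 1, R = 2), AR_ROLES)
  expect_equal(with_r$expression, without$expression, tolerance = 1e-12)
})

test_that("d_r = 0 represses only through state mass, never exclusion", {
  s <- mk_sites(c("A", "R"), c(0, 55))
  p <- srr_params(d_r = 0)
  r <- partition_srr(s, p, c(A = 1, R = 1), AR_ROLES)
  # all 6 joint configs legitimate: z_off = (1+q_A)(1+q_R(1+beta)) = 6
  expect_equal(r$z_off, 6)
  expect_equal(r$z_on, (1 + 2) * (1 + 1 * (1 + 1)))
})

test_that("large beta approaches deletion of the quenched activator sites", {
  # repressor quenches the first activator only; at beta -> inf the model
  # behaves as if that site were absent and the repressor factor cancels
  p <- model_params(binding_k = c(A = 2, R = 1), alpha = c(A = 3, R = 1),
                    beta = c(R = 1e8), q_btm = 0.1, d_r = 60, mode = "srr")
  s <- mk_sites(c("A", "R", "A"), c(0, 40, 300))
  r <- partition_srr(s, p, c(A = 1, R = 1), AR_ROLES)
  reduced <- partition_direct(mk_sites("A", 300),
                              model_params(binding_k = c(A = 2), alpha = c(A = 3),
                                           q_btm = 0.1), c(A = 1))
  expect_equal(r$expression, reduced$expression, tolerance = 1e-4)
})

test_that("expression is monotone non-increasing in beta and repressor dose", {
  # cooperativity is excluded here: a repressor that cooperatively stabilizes
  # an activator can raise expression as its occupancy grows
  set.seed(43)
  for (k in 1:10) {
    inst <- rand_instance(sample(2:7, 1), coop = FALSE, overlaps = FALSE)
    p <- inst$params; p$mode <- "srr"
    reps <- names(inst$roles)[inst$roles == "repressor"]
    if (!length(reps)) next
    ex_beta <- vapply(c(0, 0.5, 1, 4, 16), function(b) {
      pp <- p; pp$beta[reps] <- b
      partition_srr(inst$sites, pp, inst$conc, inst$roles)$expression
    }, numeric(1))
    expect_true(all(diff(ex_beta) <= 1e-12))
    ex_conc <- vapply(seq(0, 2, length.out = 6), function(v) {
      cc <- inst$conc; cc[reps] <- v
      partition_srr(inst$sites, p, cc, inst$roles)$expression
    }, numeric(1))
    expect_true(all(diff(ex_conc) <= 1e-12))
  }
})

test_that("competition_mode is partition_srr at d_r = 10", {
  s <- mk_sites(c("A", "R"), c(0, 8), len = 6)
  p <- srr_params()
  r1 <- competition_mode(s, p, c(A = 1, R = 1), AR_ROLES)
  p10 <- p; p10$d_r <- 10
  r2 <- partition_srr(s, p10, c(A = 1, R = 1), AR_ROLES)
  expect_identical(r1$z_on, r2$z_on)
  expect_identical(r1$z_off, r2$z_off)
  # distal activator is untouched at d_r = 10
  sfar <- mk_sites(c("A", "R"), c(0, 200), len = 6)
  rfar <- competition_mode(sfar, p, c(A = 1, R = 1), AR_ROLES)
  rdel <- competition_mode(mk_sites("A", 0, len = 6), p, c(A = 1, R = 1), AR_ROLES)
  expect_equal(rfar$expression, rdel$expression, tolerance = 1e-12)
})

test_that("a repressor lacking beta is reported", {
  s <- mk_sites(c("A", "R"), c(0, 55))
  p <- srr_params()
  p$beta <- c(X = 1)
  expect_error(partition_srr(s, p, c(A = 1, R = 1), AR_ROLES), "R")
})
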