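# Site weights, configuration weights and the direct-interaction /
# limited-contact partition functions against enumeration

test_that("site_weight follows the mismatch form", {
  p <- model_params(binding_k = c(A = 3), alpha = c(A = 2))
  s <- mk_sites("A", 0)
  expect_equal(site_weight(as.list(s[1, ]), p, 1), 3)
  expect_equal(site_weight(as.list(s[1, ]), p, 0), 0)
  s2 <- mk_sites("A", 0, llr = -2)
  expect_equal(site_weight(as.list(s2[1, ]), p, 0.5), 3 * 0.5 * exp(-2))
})

test_that("config_weight multiplies site, cooperativity and alpha terms", {
  p <- model_params(binding_k = c(A = 1), alpha = c(A = 2),
                    omega = c("A:A" = 5), coop_range = 50)
  s <- mk_sites(c("A", "A"), c(0, 10))
  expect_equal(config_weight(s, integer(0), p, c(A = 1)), list(W = 1, Q = 1))
  p1 <- model_params(binding_k = c(A = 2), alpha = c(A = 3))
  expect_equal(config_weight(mk_sites("A", 0), 1, p1, c(A = 1)), list(W = 2, Q = 3))
  # two adjacent cooperating activators: W = q*q*omega = 5, Q = alpha^2 = 4
  expect_equal(config_weight(s, c(1, 2), p, c(A = 1)), list(W = 5, Q = 4))
  # overlapping bound pair is a contract violation
  sov <- mk_sites(c("A", "A"), c(0, 3))
  expect_error(config_weight(sov, c(1, 2), p, c(A = 1)), "overlap")
})

test_that("partition_direct reproduces hand enumerations", {
  p <- model_params(binding_k = c(A = 1), alpha = c(A = 2), q_btm = 0.1)
  r0 <- partition_direct(mk_sites(character(0), integer(0)), p, c(A = 1))
  expect_equal(r0$z_on, 1); expect_equal(r0$z_off, 1)
  expect_equal(r0$expression, 0.1 / 1.1)
  r1 <- partition_direct(mk_sites("A", 0), p, c(A = 1))
  expect_equal(r1$z_off, 2); expect_equal(r1$z_on, 3)
  expect_equal(r1$expression, 0.3 / 2.3)
  r2 <- partition_direct(mk_sites(c("A", "A"), c(0, 10)), p, c(A = 1))
  expect_equal(r2$z_off, 4); expect_equal(r2$z_on, 9)
  pr <- model_params(binding_k = c(R = 1), alpha = c(R = 0.5), q_btm = 0.1)
  r3 <- partition_direct(mk_sites("R", 0), pr, c(R = 1))
  expect_equal(r3$z_on, 1.5)
  expect_lt(r3$expression, 0.1 / 1.1)  # repression below basal
})

test_that("overlapping sites exclude joint binding", {
  p <- model_params(binding_k = c(A = 2), alpha = c(A = 2), q_btm = 0.1)
  s <- mk_sites(c("A", "A"), c(0, 3))
  r <- brute_force_partition(s, p, c(A = 1))
  expect_equal(r$z_off, 1 + 2 + 2)  # both-bound configuration dropped
  expect_equal(partition_direct(s, p, c(A = 1))$z_off, r$z_off)
})

test_that("direct DP equals enumeration on random instances", {
  set.seed(11)
  for (k in 1:60) {
    inst <- rand_instance(sample(1:10, 1))
    bf <- brute_force_partition(inst$sites, inst$params, inst$conc, inst$roles)
    dp <- partition_direct(inst$sites, inst$params, inst$conc)
    expect_lt(max_rel_err(dp, bf), 1e-9)
  }
})

test_that("limited-contact DP matches subset enumeration and hand case", {
  # n_ma = 1, two activators alpha = 2: Q values {empty:1, single:2, both:4}
  p <- model_params(binding_k = c(A = 1), alpha = c(A = 2), q_btm = 0.1, n_ma = 1)
  s <- mk_sites(c("A", "A"), c(0, 10))
  roles <- c(A = "activator")
  r <- partition_limited_contact(s, p, c(A = 1), roles)
  expect_equal(r$z_off, 4); expect_equal(r$z_on, 9)
  set.seed(13)
  for (k in 1:40) {
    inst <- rand_instance(sample(1:8, 1))
    pl <- inst$params; pl$n_ma <- sample(1:3, 1)
    bf <- brute_force_partition(inst$sites, pl, inst$conc, inst$roles)
    dp <- partition_limited_contact(inst$sites, pl, inst$conc, inst$roles)
    expect_lt(max_rel_err(dp, bf), 1e-9)
  }
})

test_that("activation mode is irrelevant without activator sites", {
  p <- model_params(binding_k = c(R = 2), alpha = c(R = 0.4), q_btm = 0.2, n_ma = 2)
  s <- mk_sites(c("R", "R"), c(0, 12))
  roles <- c(R = "repressor")
  lim <- partition_limited_contact(s, p, c(R = 1.5), roles)
  pm <- p; pm$n_ma <- Inf
  dir <- partition_direct(s, pm, c(R = 1.5))
  expect_equal(lim$z_on, dir$z_on)
  expect_equal(lim$z_off, dir$z_off)
})

test_that("neutral TFs (alpha = 1) give exactly basal expression", {
  set.seed(17)
  for (k in 1:10) {
    inst <- rand_instance(sample(1:8, 1))
    p <- inst$params
    p$alpha[] <- 1
    r <- partition_direct(inst$sites, p, inst$conc)
    expect_equal(r$z_on, r$z_off)
    expect_equal(r$expression, p$q_btm / (1 + p$q_btm), tolerance = 1e-12)
  }
})

test_that("omega = 1 everywhere equals the cooperativity-free model bitwise", {
  set.seed(19)
  inst <- rand_instance(8)
  p1 <- inst$params
  p1$omega[] <- 1
  p0 <- inst$params
  p0$omega <- NULL
  r1 <- partition_direct(inst$sites, p1, inst$conc)
  r0 <- partition_direct(inst$sites, p0, inst$conc)
  expect_identical(r1$z_on, r0$z_on)
  expect_identical(r1$z_off, r0$z_off)
})

test_that("saturation reaches the multiplicative and additive closed forms", {
  q_btm <- 0.1
  for (n in c(2, 4)) {
    alpha <- 3
    sites <- mk_sites(rep("A", n), seq(0, by = 10, length.out = n))
    pm <- model_params(binding_k = c(A = 1e6), alpha = c(A = alpha), q_btm = q_btm)
    rm_ <- partition_direct(sites, pm, c(A = 1))
    expect_equal(rm_$expression, q_btm * alpha^n / (q_btm * alpha^n + 1),
                 tolerance = 1e-4)
    pa <- pm; pa$n_ma <- 1
    ra <- partition_limited_contact(sites, pa, c(A = 1), c(A = "activator"))
    expect_equal(ra$expression, q_btm * n * alpha / (q_btm * n * alpha + 1),
                 tolerance = 1e-4)
  }
})

test_that("expression responds monotonically to TF concentrations", {
  # the guarantee needs the plain setting: no cooperativity (a repressor can
  # cooperatively stabilize an activator) and no overlapping sites (a weak
  # activator can competitively displace a strong one)
  set.seed(23)
  grid <- seq(0, 2, length.out = 9)
  for (k in 1:20) {
    inst <- rand_instance(sample(2:8, 1), coop = FALSE, overlaps = FALSE)
    for (tf in names(inst$conc)) {
      ex <- vapply(grid, function(v) {
        cc <- inst$conc; cc[tf] <- v
        partition_direct(inst$sites, inst$params, cc)$expression
      }, numeric(1))
      d <- diff(ex)
      if (inst$roles[tf] == "activator") expect_true(all(d >= -1e-12))
      else expect_true(all(d <= 1e-12))
    }
  }
})

test_that("predict_profile handles basal bins, stitching and missing TFs", {
  p <- model_params(binding_k = c(A = 2), alpha = c(A = 3), q_btm = 0.1)
  s <- mk_sites(c("A", "A"), c(0, 10))
  conc <- matrix(c(0, 0.5, 1), 1, dimnames = list("A", NULL))
  prof <- predict_profile(s, p, conc)
  expect_equal(prof[1], 0.1 / 1.1)  # zero concentration -> basal
  # bins are independent: stitched single-bin calls agree
  single <- vapply(1:3, function(b)
    partition_direct(s, p, conc[, b])$expression, numeric(1))
  expect_equal(prof, single)
  expect_true(all(diff(prof) >= 0))  # activator dose response
  bad <- matrix(1, 1, 3, dimnames = list("B", NULL))
  expect_error(predict_profile(s, p, bad), "A")
})

test_that("unsorted site tables are rejected", {
  p <- model_params(binding_k = c(A = 1), alpha = c(A = 2))
  s <- mk_sites(c("A", "A"), c(10, 0))
  s <- s[c(2, 1), ]  # break ordering deliberately
  s$start <- c(10L, 0L)
  expect_error(partition_direct(s, p, c(A = 1)), "sorted")
})
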