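# Evolutionary conservation filters over synthetic ortholog alignments

cons_fixture <- function(seed = 21, losses = data.frame(species = 4, site = 1)) {
  pwms <- list(make_pwm("ACGTAGCA", 0.9, name = "tfX"),
               make_pwm("GGATCCTT", 0.9, name = "tfY"))
  plan <- data.frame(tf = c("tfX", "tfY", "tfX"),
                     position = c(40, 120, 210),
                     strength = c(1, 0.9, 0.85), stringsAsFactors = FALSE)
  seq <- make_crm(plan, pwms, 300, rng_seed = seed)
  aln <- make_ortholog_alignment(seq, plan, pwms, species = 6,
                                 mutation_rate = 0.03,
                                 planted_losses = losses, rng_seed = seed)
  list(pwms = pwms, plan = plan, seq = seq, aln = aln)
}

test_that("n_species = 1 returns the unfiltered reference annotation", {
  fx <- cons_fixture()
  ref_sites <- annotate_sites(fx$seq, fx$pwms, 0.4)
  got <- filter_strict(fx$aln, fx$pwms, n_species = 1)
  expect_equal(got$start, ref_sites$start)
  expect_equal(got$llr, ref_sites$llr)
})

test_that("a lineage-specific loss is removed by the strict filter only", {
  fx <- cons_fixture()
  strict <- filter_strict(fx$aln, fx$pwms, n_species = 6)
  turnover <- filter_turnover(fx$aln, fx$pwms, n_species = 6)  # >= 4 of 6
  # the planted site at position 40 was ablated in species 4
  expect_false(any(strict$start == 40 & strict$tf == "tfX"))
  expect_true(any(turnover$start == 40 & turnover$tf == "tfX"))
  # min_species = n_species reduces turnover to strict
  expect_equal(filter_turnover(fx$aln, fx$pwms, 6, min_species = 6), strict)
})

test_that("filters are nested in stringency", {
  set.seed(33)
  for (k in 1:15) {
    fx <- cons_fixture(seed = 400 + k, losses = NULL)
    prev <- NULL
    for (ns in 1:6) {
      cur <- filter_strict(fx$aln, fx$pwms, n_species = ns)
      if (!is.null(prev)) {
        key <- function(d) paste(d$tf, d$start)
        expect_true(all(key(cur) %in% key(prev)))  # strict(n+1) within strict(n)
        tur <- filter_turnover(fx$aln, fx$pwms, n_species = ns)
        expect_true(all(key(cur) %in% key(tur)))   # turnover is laxer
      }
      prev <- cur
    }
  }
})

test_that("a gap inside the aligned window breaks conservation", {
  fx <- cons_fixture(losses = NULL)
  aln <- fx$aln
  # punch a gap into species3 inside the first planted window
  substr(aln["species3"], 42, 42) <- "-"
  sc <- site_conservation(aln, fx$pwms)
  row <- which(sc$sites$start == 40 & sc$sites$tf == "tfX")
  expect_false(sc$conserved[row, "species3"])
  expect_true(sc$conserved[row, "species2"])
})

test_that("alignment round-trips through aligned FASTA", {
  fx <- cons_fixture()
  f <- tempfile(fileext = ".fa")
  write_alignment(fx$aln, f)
  back <- read_alignment(f)
  expect_identical(unname(back), unname(fx$aln))
  expect_identical(names(back), names(fx$aln))
})

test_that("strict filtering of turned-over functional sites degrades the fit", {
  # expression is driven by planted sites; losing a functional site to the
  # strict filter must hurt predictions relative to the turnover filter
  pwms <- list(make_pwm("ACGTAGCA", 0.9, name = "actHead"),
               make_pwm("GGATCCTT", 0.9, name = "actTail"))
  roles <- c(actHead = "activator", actTail = "activator")
  tfs <- data.frame(name = c("actHead", "actTail"),
                    role = "activator", stringsAsFactors = FALSE)
  params <- model_params(binding_k = c(actHead = 20, actTail = 20),
                         alpha = c(actHead = 6, actTail = 6), q_btm = 0.05)
  conc <- rbind(actHead = make_gradient("anterior", 40),
                actTail = make_gradient("posterior", 40))
  seqs <- character(4); names(seqs) <- paste0("c", 1:4)
  alns <- list()
  for (i in 1:4) {
    # the anterior activator's sites undergo a lineage-specific loss; the
    # posterior activator's site is fully conserved
    plan <- data.frame(tf = c("actHead", "actHead", "actTail"),
                       position = c(30, 90, 150),
                       strength = c(1, 0.95, 0.9), stringsAsFactors = FALSE)
    seqs[i] <- make_crm(plan, pwms, 220, rng_seed = 600 + i)
    alns[[i]] <- make_ortholog_alignment(seqs[i], plan, pwms, species = 6,
                                         mutation_rate = 0.02,
                                         planted_losses = data.frame(species = 3,
                                                                     site = 1:2),
                                         rng_seed = 700 + i)
  }
  expr <- t(sapply(seq_along(seqs), function(i)
    predict_profile(annotate_sites(seqs[i], pwms), params, conc, roles)))
  expr <- expr / apply(expr, 1, max)
  rownames(expr) <- names(seqs)
  ds <- crm_dataset(seqs, expr, conc, tfs)
  sites_strict <- lapply(alns, filter_strict, pwms = pwms, n_species = 6)
  sites_turn <- lapply(alns, filter_turnover, pwms = pwms, n_species = 6)
  names(sites_strict) <- names(sites_turn) <- names(seqs)
  cc_strict <- evaluate_model(params, ds, sites_strict)$avg_cc
  cc_turn <- evaluate_model(params, ds, sites_turn)$avg_cc
  expect_lt(cc_strict, cc_turn)
  expect_gt(cc_turn, 0.95)  # turnover filter retains the functional sites
})
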