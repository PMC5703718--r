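test_that("profile emissions are pseudocount-smoothed column frequencies", {
  p <- build_profile("ACGT", pseudocount = 1)
  expect_equal(p$length, 4)
  # single sequence, pseudocount 1: (1+1)/(1+4) observed, 1/(1+4) others
  expect_equal(unname(p$match_emissions["A", 1]), 0.4)
  expect_equal(unname(p$match_emissions["C", 1]), 0.2)
  expect_equal(unname(colSums(p$match_emissions)), rep(1, 4))
  # two identical sequences give the same profile as one
  p2 <- build_profile(c("ACGT", "ACGT"), pseudocount = 1)
  expect_equal(unname(p2$match_emissions["A", 1]), (2 + 1) / (2 + 4))
  p1dup <- build_profile(c("ACGT", "ACGT"))
  expect_equal(dim(p1dup$match_emissions), dim(p$match_emissions))
  # pseudocount -> 0 approaches indicator distributions
  p0 <- build_profile("ACGT", pseudocount = 1e-9)
  expect_gt(unname(p0$match_emissions["A", 1]), 1 - 1e-8)
  # multi-sequence smoothing oracle at pseudocount 1: (count+1)/(n+4)
  p3 <- build_profile(c("AAG", "AAT", "ACG"), pseudocount = 1)
  expect_equal(unname(p3$match_emissions[, 1]), c(4, 1, 1, 1) / 7)
  expect_equal(unname(p3$match_emissions[, 2]), c(3, 2, 1, 1) / 7)
  # gap-majority columns are dropped; all-gap input errors
  pg <- build_profile(c("A-G", "A-T", "ACG", "A--"))
  expect_equal(pg$length, 2)
  expect_error(build_profile(c("--", "--")), "gap")
})

test_that("forward log-odds equals exhaustive path enumeration on small cases", {
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(1:4, 1); n <- sample(1:4, 1)
    prof <- build_profile(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = ""),
                          pseudocount = runif(1, 0.2, 2))
    sq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    got <- forward_score(prof, sq)
    want <- enum_forward(prof, sq)
    expect_lt(abs(got - want) / max(1, abs(want)), 1e-9)
  }
})

test_that("forward score separates consensus matches from the null", {
  set.seed(1)
  cons <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  sharp <- build_profile(cons, pseudocount = 0.05)
  expect_gt(forward_score(sharp, cons), 10)
  # a profile equal to the background is score-neutral for any sequence
  uniform <- build_profile(cons, pseudocount = 1e9)
  rnd <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  expect_lt(abs(forward_score(uniform, rnd)), 0.1 * nchar(rnd))
  # N residues score as background
  expect_equal(forward_score(uniform, "NNNNN"), forward_score(uniform, "ACGTA"),
               tolerance = 1e-9)
  expect_error(forward_score(sharp, ""), "empty")
})

test_that("sharpening a profile toward the scored sequence never lowers its score", {
  set.seed(10)
  sq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  pcs <- c(5, 2, 1, 0.5, 0.2, 0.05) # decreasing pseudocount = sharper columns
  scores <- vapply(pcs, function(pc)
    forward_score(build_profile(sq, pseudocount = pc), sq), numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("delta score is antisymmetric in the two profiles and calls by sign", {
  set.seed(2)
  mt_src <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  fl_src <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  mt_prof <- build_profile(mt_src)
  fl_prof <- build_profile(fl_src)
  d1 <- delta_score(mt_src, mt_prof, fl_prof)
  expect_gt(d1$delta, 0)
  expect_equal(d1$call, "recent")
  expect_equal(d1$delta, d1$score_mt - d1$score_flank)
  d2 <- delta_score(mt_src, fl_prof, mt_prof)
  expect_equal(d2$delta, -d1$delta)
  expect_equal(d2$call, "old")
  d3 <- delta_score(fl_src, mt_prof, fl_prof)
  expect_lt(d3$delta, 0)
  amb <- delta_score(mt_src, mt_prof, fl_prof, tolerance = 1e9)
  expect_equal(amb$call, "ambiguous")
})

test_that("flank profiles fall back to the pooled consensus when N-rich", {
  set.seed(3)
  clean <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  own_ok <- flank_profile_for(clean)
  expect_equal(own_ok$source, "own")
  gappy <- paste0(strrep("N", 150), substr(clean, 1, 100))
  others <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 120 + 10 * i, replace = TRUE),
          collapse = ""), character(1))
  fb <- flank_profile_for(gappy, others)
  expect_equal(fb$source, "consensus")
  # recomputation oracle: consensus equals a profile over right-padded others
  w <- max(nchar(others))
  padded <- vapply(others, function(s)
    paste0(s, strrep("-", w - nchar(s))), character(1), USE.NAMES = FALSE)
  want <- build_profile(padded)
  expect_equal(fb$profile$match_emissions, want$match_emissions)
  expect_error(flank_profile_for(gappy, character(0)), "no usable")
})

test_that("insertion age and delta score are strongly anticorrelated", {
  cfg <- simulation_config(seed = 11, n_chromosomes = 2,
                           chromosome_lengths = 200000, n_insertions = 30,
                           age_grid = seq(0, 0.25, by = 0.05),
                           frag_len_range = c(600L, 600L),
                           n_pure_mt_contigs = 0, n_partial_mt_contigs = 0,
                           re_density = 0.5)
  sim <- simulate_genome(cfg)
  tn <- truth_as_numts(sim$truth, nchar(sim$mt))
  d <- date_numts(numts_sequences(tn, sim$nuclear),
                  mt_counterpart_sequences(tn, sim$mt),
                  flank_sequences(tn, sim$nuclear, sim$repeats))
  d$age <- tn$age[match(d$numts_id, tn$id)]
  rho <- stats::cor(d$age, d$delta, method = "spearman")
  expect_lte(rho, -0.5)
  expect_true(all(d$call[d$age == 0] == "recent"))
})
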