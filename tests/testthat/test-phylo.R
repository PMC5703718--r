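test_that("K2P distance matches the closed form and handles gaps and saturation", {
  expect_equal(k2p("ACGTACGT", "ACGTACGT")$d, 0)
  # worked case: 100 columns, 10 transitions, no transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  r <- k2p(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.8))
  # pairwise deletion of gap/N columns
  rg <- k2p("AC-TN", "ACGTA")
  expect_equal(rg$n_sites, 3)
  # saturation raises a classed error
  expect_error(k2p(strrep("A", 10), strrep("G", 10)),
               class = "numtsome_saturation")
})

test_that("K2P agrees with an independent implementation and with JC at P = 2Q", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 600
    a <- sample(c("a", "c", "g", "t"), n, replace = TRUE)
    b <- a
    idx <- sample.int(n, 60)
    b[idx] <- sample(c("a", "c", "g", "t"), 60, replace = TRUE)
    m <- rbind(a, b)
    rownames(m) <- c("x", "y")
    want <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
    got <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))$d
    expect_equal(got, want, tolerance = 1e-9)
  }
  # JC-like behaviour when transitions and transversions are proportionate
  P <- 0.08; Q <- 0.04 # P = 2Q, total p = 0.12
  n <- 1000
  a <- rep("A", n)
  b <- c(rep("G", P * n), rep("C", Q * n / 2), rep("T", Q * n / 2),
         rep("A", n * (1 - P - Q)))
  d_k2p <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))$d
  d_jc <- -0.75 * log(1 - 4 / 3 * (P + Q))
  expect_lt(abs(d_k2p - d_jc), 0.01)
})

test_that("NJ solves the three-point case exactly and recovers additive trees", {
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  co3 <- ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)]
  expect_equal(unname(co3), unname(D3), tolerance = 1e-9)
  # additive 4-taxon matrix from the tree ((A:2,B:3):1,(C:4,D:5))
  D4 <- matrix(c(0, 5, 7, 8,
                 5, 0, 8, 9,
                 7, 8, 0, 9,
                 8, 9, 9, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(D4)
  co4 <- ape::cophenetic.phylo(t4)[rownames(D4), colnames(D4)]
  expect_equal(unname(co4), unname(D4), tolerance = 1e-9)
  # AB|CD split present
  sp <- species_pattern(t4, c(A = "g1", B = "g1", C = "g2", D = "g2"))
  expect_true(all(sp$pattern == "monophyletic"))
  expect_error(nj_tree(D4[1:2, 1:2]), "3 taxa")
  Dbad <- D4; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("NJ matches the reference implementation's topology on random matrices", {
  set.seed(29)
  for (rep in 1:5) {
    n <- 7
    pts <- matrix(runif(n * 3), n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(mine, ref), 0)
  }
})

test_that("NJ on simulated K2P alignments recovers the generating topology", {
  true_tree <- ape::read.tree(
    text = "(((t1:0.05,t2:0.05):0.05,(t3:0.05,t4:0.05):0.05):0.05,((t5:0.05,t6:0.05):0.05,(t7:0.05,t8:0.05):0.05):0.05);")
  hits <- 0
  for (rep in 1:5) {
    set.seed(100 + rep)
    dat <- phangorn::simSeq(true_tree, l = 1000, type = "DNA",
                            Q = c(1, 4, 1, 1, 4, 1)) # transition-biased rates
    m <- as.character(dat)
    aln <- apply(m, 1, paste, collapse = "")
    tr <- nj_tree(k2p_matrix(aln))
    if (phangorn::RF.dist(tr, true_tree) == 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("species patterns match brute-force bipartition enumeration", {
  t_mono <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- species_pattern(t_mono, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(all(sp$pattern == "monophyletic"))
  t_mix <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  sp2 <- species_pattern(t_mix, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(all(sp2$pattern == "intermingled"))
  t_one <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,c1:1):1);")
  sp3 <- species_pattern(t_one, c(a1 = "A", a2 = "A", b1 = "B", c1 = "C"))
  expect_equal(sp3$pattern[sp3$species == "B"], "not assessable")
  set.seed(37)
  for (rep in 1:15) {
    nt <- sample(5:10, 1)
    tr <- ape::rtree(nt)
    species <- setNames(sample(c("x", "y", "z"), nt, replace = TRUE),
                        tr$tip.label)
    got <- species_pattern(tr, species)
    want <- bf_monophyly(tr, species)
    got <- got[match(want$species, got$species), ]
    expect_equal(got$pattern, want$pattern)
    # invariance to leaf order and rerooting
    rot <- species_pattern(ape::root(tr, outgroup = tr$tip.label[1],
                                     resolve.root = TRUE), species)
    rot <- rot[match(want$species, rot$species), ]
    expect_equal(rot$pattern, want$pattern)
  }
})

test_that("strict-clock calibration scales heights to the age window", {
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  tt <- calibrate(tr, c("a", "b", "c", "d"), age_window = c(95, 105))
  root_age <- tt$ages$age[tt$ages$node == tt$calibration_node]
  expect_equal(root_age, 100)
  expect_equal(tt$rate, 0.10 / 100)
  inner <- tt$ages[tt$ages$height > 0 & tt$ages$node != tt$calibration_node, ]
  expect_equal(unique(inner$age), 50)
  expect_equal(unique(inner$age_lo), 47.5)
  expect_equal(unique(inner$age_hi), 52.5)
  # degenerate window gives point ages
  tt0 <- calibrate(tr, c("a", "b", "c", "d"), age_window = c(100, 100))
  expect_equal(tt0$ages$age_lo, tt0$ages$age_hi)
  expect_error(calibrate(tr, c("nope"), c(95, 105)), "not found")
  # ages are monotone from root to tips on random trees
  set.seed(47)
  for (rep in 1:10) {
    rtr <- ape::rtree(8)
    cal <- calibrate(rtr, rtr$tip.label, age_window = c(90, 110))
    ages <- cal$ages$age
    for (e in seq_len(nrow(cal$tree$edge))) {
      expect_gte(ages[cal$tree$edge[e, 1]], ages[cal$tree$edge[e, 2]] - 1e-9)
    }
  }
  # Newick with age annotations round-trips through ape
  path <- withr::local_tempfile(fileext = ".nwk")
  write_timetree(tt, path)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
})
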