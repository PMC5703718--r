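toy_numts <- function(chrom = "chr1", start = 5000, end = 6000, strand = "+",
                      id = "N1") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("flanks are strand-aware and clipped at contig ends", {
  lens <- c(chr1 = 100000)
  fp <- flanks(toy_numts(), lens)
  expect_equal(c(fp$five_prime$start, fp$five_prime$end), c(3000, 5000))
  expect_equal(c(fp$three_prime$start, fp$three_prime$end), c(6000, 8000))
  fm <- flanks(toy_numts(strand = "-"), lens)
  expect_equal(c(fm$five_prime$start, fm$five_prime$end), c(6000, 8000))
  expect_equal(c(fm$three_prime$start, fm$three_prime$end), c(3000, 5000))
  fc <- flanks(toy_numts(start = 500, end = 900), lens)
  expect_equal(c(fc$five_prime$start, fc$five_prime$end), c(0, 500))
  fe <- flanks(toy_numts(start = 99000, end = 99500), lens)
  expect_equal(c(fe$three_prime$start, fe$three_prime$end), c(99500, 100000))
})

test_that("repeat counting per class uses >=1 bp overlap, boundaries count twice", {
  lens <- c(chr1 = 100000)
  nm <- toy_numts()
  inside <- data.frame(chrom = "chr1", start = 5200, end = 5400, name = "r1")
  res <- count_re(nm, inside, lens)
  expect_equal(res$n_re[res$class == "numts_locus"], 1)
  expect_equal(sum(res$n_re), 1)
  straddle <- data.frame(chrom = "chr1", start = 4900, end = 5100, name = "r2")
  res2 <- count_re(nm, straddle, lens)
  expect_equal(res2$n_re[res2$class == "five_prime_flank"], 1)
  expect_equal(res2$n_re[res2$class == "numts_locus"], 1)
  expect_equal(res2$re_per_numts[res2$class == "numts_locus"], 1)
})

test_that("repeat counts match a per-base brute-force scan on random fixtures", {
  set.seed(41)
  lens <- c(chr1 = 50000, chr2 = 50000)
  for (rep in 1:15) {
    k <- sample(2:6, 1)
    st <- sample.int(40000, k) + 3000
    nm <- data.frame(id = paste0("N", 1:k),
                     chrom = sample(names(lens), k, replace = TRUE),
                     start = st, end = st + sample(200:2000, k, replace = TRUE),
                     strand = sample(c("+", "-"), k, replace = TRUE))
    nr <- sample(1:12, 1)
    rs <- sample.int(49000, nr)
    reps <- data.frame(chrom = sample(names(lens), nr, replace = TRUE),
                       start = rs, end = rs + sample(50:900, nr, replace = TRUE),
                       name = "RE")
    got <- count_re(nm, reps, lens)
    fl <- flanks(nm, lens)
    bf_count <- function(regions) {
      sum(vapply(seq_len(nrow(reps)), function(i) {
        any(regions$chrom == reps$chrom[i] & regions$start < reps$end[i] &
              regions$end > reps$start[i])
      }, logical(1)))
    }
    expect_equal(got$n_re[got$class == "five_prime_flank"], bf_count(fl$five_prime))
    expect_equal(got$n_re[got$class == "numts_locus"],
                 bf_count(nm[, c("chrom", "start", "end")]))
    expect_equal(got$n_re[got$class == "three_prime_flank"], bf_count(fl$three_prime))
  }
})

test_that("interval subtraction produces the per-base set difference", {
  a <- data.frame(chrom = "c", start = 0, end = 100)
  b <- data.frame(chrom = "c", start = 40, end = 60)
  got <- interval_subtract(a, b)
  expect_equal(got$start, c(0, 60))
  expect_equal(got$end, c(40, 100))
  disjoint <- data.frame(chrom = "c", start = 500, end = 600)
  expect_equal(interval_subtract(a, disjoint)[, c("start", "end")],
               a[, c("start", "end")])
  set.seed(61)
  for (rep in 1:20) {
    na <- sample(1:8, 1); nb <- sample(0:8, 1)
    sa <- sample.int(3000, na); sb <- if (nb) sample.int(3000, nb) else integer(0)
    a <- data.frame(chrom = sample(c("c1", "c2"), na, replace = TRUE),
                    start = sa, end = sa + sample(10:500, na, replace = TRUE))
    b <- data.frame(chrom = sample(c("c1", "c2"), nb, replace = TRUE),
                    start = sb, end = sb + sample(20:400, nb, replace = TRUE))
    got <- interval_subtract(a, b)
    want <- bf_subtract(a, b, 5000)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # containment: output within the union of a, never overlapping b
    if (nrow(got)) {
      merged_a <- do.call(rbind, lapply(unique(a$chrom), function(cn) {
        ai <- a[a$chrom == cn, ]
        r <- IRanges::reduce(IRanges::IRanges(ai$start + 1L, ai$end))
        data.frame(chrom = cn, start = IRanges::start(r) - 1L,
                   end = IRanges::end(r))
      }))
      for (i in seq_len(nrow(got))) {
        expect_true(any(merged_a$chrom == got$chrom[i] &
                          merged_a$start <= got$start[i] &
                          merged_a$end >= got$end[i]))
        if (nrow(b)) {
          expect_false(any(b$chrom == got$chrom[i] & b$start < got$end[i] &
                             b$end > got$start[i]))
        }
      }
    }
  }
})

test_that("the repeat-free subset drops NumtS with repeats in locus or 1-kb flanks", {
  lens <- c(chr1 = 100000)
  nm <- rbind(toy_numts(id = "N1"),
              toy_numts(start = 20000, end = 21000, id = "N2"),
              toy_numts(start = 40000, end = 40500, id = "N3"))
  none <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character())
  expect_equal(nrow(re_free_subset(nm, none, lens)), 3)
  reps <- rbind(
    data.frame(chrom = "chr1", start = 4500, end = 4700, name = "flank_re"),
    data.frame(chrom = "chr1", start = 20400, end = 20500, name = "locus_re"))
  kept <- re_free_subset(nm, reps, lens)
  expect_equal(kept$id, "N3")
  # brute-force filter agreement on a random fixture
  set.seed(71)
  st <- sample.int(80000, 8) + 2000
  nmr <- data.frame(id = paste0("N", 1:8), chrom = "chr1", start = st,
                    end = st + 400, strand = "+")
  rs <- sample.int(90000, 15)
  rr <- data.frame(chrom = "chr1", start = rs, end = rs + 300, name = "RE")
  got <- re_free_subset(nmr, rr, lens)$id
  want <- nmr$id[vapply(seq_len(8), function(i) {
    lo <- nmr$start[i] - 1000; hi <- nmr$end[i] + 1000
    !any(rr$start < hi & rr$end > lo)
  }, logical(1))]
  expect_equal(got, want)
})

test_that("spearman matrix handles monotone data, ties, transforms and constants", {
  x <- 1:10
  r <- spearman_matrix(data.frame(a = x, b = x^3 + 1))
  expect_equal(r$rho, 1)
  r2 <- spearman_matrix(data.frame(a = x, b = -x))
  expect_equal(r2$rho, -1)
  # ties: Pearson on average ranks, computed by hand
  a <- c(1, 2, 2, 4, 5); b <- c(3, 3, 1, 5, 4)
  ra <- rank(a); rb <- rank(b)
  want <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  r3 <- spearman_matrix(data.frame(a = a, b = b))
  expect_equal(r3$rho, want)
  # invariance under strictly monotone transforms
  set.seed(5)
  u <- runif(20); v <- runif(20)
  base_rho <- spearman_matrix(data.frame(u = u, v = v))$rho
  tr_rho <- spearman_matrix(data.frame(u = exp(3 * u), v = v^3))$rho
  expect_equal(tr_rho, base_rho)
  # constant variable is reported missing
  rc <- spearman_matrix(data.frame(a = x, b = rep(2, 10)))
  expect_true(is.na(rc$rho))
  # Bonferroni adjustment over the number of pairs
  rm3 <- spearman_matrix(data.frame(a = x, b = x + rnorm(10), c = rnorm(10)),
                         alpha = 0.05)
  expect_equal(attr(rm3, "alpha_adj"), 0.05 / 3)
  expect_equal(nrow(rm3), 3)
})

test_that("assembly statistics correlation reads a TSV and reports pairs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(species = paste0("sp", 1:8), n_numts = c(52, 59, 1, 43, 46, 5, 7, 21),
                   contig_n50 = c(20, 15, 90, 40, 33, 80, 70, 50),
                   gap_bp = c(1e5, 2e5, 1e3, 5e4, 8e4, 2e3, 4e3, 3e4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep_ <- assembly_stats_correlation(path)
  expect_equal(nrow(rep_), 3)
  expect_true(all(abs(rep_$rho) <= 1))
})
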