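hsp_row <- function(chrom, g_start, g_end, strand = "+", mt_start = 0,
                    mt_end = NULL) {
  if (is.null(mt_end)) mt_end <- mt_start + (g_end - g_start)
  data.frame(mt_start = mt_start, mt_end = mt_end, chrom = chrom,
             g_start = g_start, g_end = g_end, strand = strand,
             pct_identity = 95, aln_len = g_end - g_start, mismatches = 0L,
             gap_opens = 0L, bitscore = 100, evalue = 1e-10,
             stringsAsFactors = FALSE)
}

test_that("occupancy is the interval union over contig length, removal strictly above 0.80", {
  lens <- c(ctgA = 1000, ctgB = 1000, ctgC = 1000)
  h <- rbind(hsp_row("ctgA", 0, 850),          # 0.85 -> removed
             hsp_row("ctgB", 100, 900),        # exactly 0.80 -> kept
             hsp_row("ctgC", 0, 600),          # overlapping pair, union 900
             hsp_row("ctgC", 400, 900))
  res <- occupancy_filter(h, lens)
  rep_ <- res$report[order(res$report$contig), ]
  expect_equal(rep_$occupancy, c(0.85, 0.80, 0.90))
  expect_equal(rep_$removed, c(TRUE, FALSE, TRUE))
  expect_equal(sort(unique(res$hsps$chrom)), "ctgB")
  expect_error(occupancy_filter(hsp_row("nope", 0, 10), lens), "nope")
})

test_that("union occupancy matches a per-base brute-force oracle on random sets", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    s <- sample.int(5000, n)
    e <- s + sample(10:900, n, replace = TRUE)
    h <- do.call(rbind, lapply(seq_len(n), function(i)
      hsp_row("ctg", s[i], e[i])))
    res <- occupancy_filter(h, c(ctg = 6000))
    expect_equal(res$report$occupied_bp, bf_union_width(s, e, 6000))
  }
})

test_that("random and unknown chromosomes are dropped case-insensitively", {
  h <- rbind(hsp_row("chr1_random", 0, 100), hsp_row("chrUn_GL000220", 0, 100),
             hsp_row("chr1", 0, 100))
  res <- chrom_filter(h)
  expect_equal(res$hsps$chrom, "chr1")
  expect_equal(sum(res$report$n_dropped), 2)
})

test_that("the 2-kb merge rule is inclusive at 2000 bp and strand-aware", {
  base <- rbind(hsp_row("chr1", 1000, 2000), hsp_row("chr1", 4000, 5000))
  expect_equal(nrow(assemble_numts(base)), 1)          # gap 2000 merges
  wide <- rbind(hsp_row("chr1", 1000, 2000), hsp_row("chr1", 4001, 5000))
  expect_equal(nrow(assemble_numts(wide)), 2)          # gap 2001 does not
  opp <- rbind(hsp_row("chr1", 1000, 2000),
               hsp_row("chr1", 2100, 3000, strand = "-"))
  expect_equal(nrow(assemble_numts(opp)), 2)           # opposite strand never
  # a single repeat spanning a 3-kb gap bridges it
  far <- rbind(hsp_row("chr1", 1000, 2000), hsp_row("chr1", 5000, 6000))
  reps <- data.frame(chrom = "chr1", start = 2000, end = 5000,
                     name = "LINE", stringsAsFactors = FALSE)
  expect_equal(nrow(assemble_numts(far, reps)), 1)
  # two repeats each covering >= 90% is not "a unique RE"
  reps2 <- rbind(reps, data.frame(chrom = "chr1", start = 2050, end = 5000,
                                  name = "SINE"))
  expect_equal(nrow(assemble_numts(far, reps2)), 2)
  # bridging can be disabled
  expect_equal(nrow(assemble_numts(far, reps,
                                   assemble_config(repeat_bridge = FALSE))), 2)
})

test_that("assembled NumtS form a partition with correct extents and mt unions", {
  h <- rbind(hsp_row("chr1", 100, 600, mt_start = 1000),
             hsp_row("chr1", 1500, 2400, mt_start = 1400),
             hsp_row("chr1", 9000, 9500, mt_start = 0),
             hsp_row("chr2", 50, 200, mt_start = 7000))
  nm <- assemble_numts(h)
  expect_equal(sort(unlist(nm$members)), 1:4)                  # partition
  expect_equal(sum(vapply(nm$members, length, integer(1))), nrow(h))
  first <- nm[nm$chrom == "chr1" & nm$start == 100, ]
  expect_equal(first$end, 2400)
  expect_equal(first$n_members, 2)
  iv <- first$mt_intervals[[1]]
  expect_equal(unname(iv[, "start"]), 1000)   # [1000,1500)+[1400,2300) merged
  expect_equal(unname(iv[, "end"]), 2300)
  expect_match(nm$id, "^NumtS_chr[12]_\\d+$")
})

test_that("re-assembling already assembled singletons changes nothing", {
  set.seed(23)
  h <- random_hsps(30)
  nm <- assemble_numts(h)
  singles <- do.call(rbind, lapply(seq_len(nrow(nm)), function(i)
    hsp_row(nm$chrom[i], nm$start[i], nm$end[i], nm$strand[i])))
  # gaps between assembled NumtS on one strand exceed the merge rule unless
  # the neighbouring NumtS is on the other strand; filter to one strand
  nm2 <- assemble_numts(singles)
  key <- function(d) sort(sprintf("%s:%s:%s:%s", d$chrom, d$start, d$end, d$strand))
  # every original cluster remains a cluster or merges only with an
  # opposite-strand-free neighbour; with no repeats, same-strand gaps > 2000
  same_strand_gap_ok <- TRUE
  for (g in split(nm, paste(nm$chrom, nm$strand))) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] - g$end[-nrow(g)] <= 2000))
      same_strand_gap_ok <- FALSE
  }
  if (same_strand_gap_ok) expect_equal(key(nm2), key(nm))
})

test_that("sweep assembly equals the brute-force transitive closure", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(2:30, 1)
    h <- random_hsps(n)
    reps <- if (rep %% 2 == 0) {
      k <- sample(1:5, 1)
      st <- sample.int(60000, k)
      data.frame(chrom = paste0("chr", sample(1:2, k, replace = TRUE)),
                 start = st, end = st + sample(500:3500, k, replace = TRUE),
                 name = "RE", stringsAsFactors = FALSE)
    } else NULL
    nm <- assemble_numts(h, reps)
    sorted <- attr(nm, "hsps")
    got <- integer(nrow(sorted))
    for (i in seq_len(nrow(nm))) got[nm$members[[i]]] <- i
    want <- bf_merge_partition(sorted, reps)
    expect_equal(partition_key(got), partition_key(want))
  }
})
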