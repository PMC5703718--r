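# Independent brute-force oracles used across the test files.  Each one is
# deliberately naive (per-base scans, exhaustive enumeration) and shares no
# code with the implementation it checks.

# per-base union width of half-open intervals
bf_union_width <- function(start, end, max_len = max(c(end, 1L))) {
  covered <- logical(max_len)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) covered[(start[i] + 1L):end[i]] <- TRUE
  }
  sum(covered)
}

# per-base coverage counting on the circular mt genome
bf_coverage <- function(iv, L) {
  counts <- integer(L)
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1]; e <- iv[i, 2]
    pos <- if (s < e) (s + 1L):e else c(seq_len(e), if (s < L) (s + 1L):L)
    if (s == e) pos <- integer(0)
    counts[pos] <- counts[pos] + 1L
  }
  counts
}

# threshold-run hotspot enumeration on the circle (returns sorted run keys)
bf_hotspot_keys <- function(counts, thr) {
  L <- length(counts)
  hot <- counts >= thr
  if (!any(hot)) return(character(0))
  if (all(hot)) return(sprintf("0:%d", L))
  runs <- list()
  # walk the circle starting just after a cold position
  start0 <- which(!hot)[1]
  p <- start0
  cur <- NULL
  for (k in seq_len(L)) {
    idx <- ((start0 - 1L + k - 1L) %% L) + 1L
    if (hot[idx] && is.null(cur)) cur <- idx - 1L
    if (!hot[idx] && !is.null(cur)) {
      runs[[length(runs) + 1L]] <- c(cur, idx - 1L)
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- c(cur, start0 - 1L)
  keys <- vapply(runs, function(r) {
    e <- if (r[2] == 0L) length(counts) else r[2]
    sprintf("%d:%d", r[1], if (r[1] < e) e else r[2])
  }, character(1))
  sort(keys)
}

# transitive-closure merge oracle: pairwise rule + repeated relaxation
bf_merge_partition <- function(hsps, repeats, max_gap = 2000, cover = 0.9) {
  n <- nrow(hsps)
  merges <- function(i, j) {
    if (hsps$chrom[i] != hsps$chrom[j] || hsps$strand[i] != hsps$strand[j])
      return(FALSE)
    if (hsps$g_start[i] > hsps$g_start[j] ||
        (hsps$g_start[i] == hsps$g_start[j] && i > j)) { t <- i; i <- j; j <- t }
    gap <- hsps$g_start[j] - hsps$g_end[i]
    if (gap <= max_gap) return(TRUE)
    if (is.null(repeats) || nrow(repeats) == 0L) return(FALSE)
    r <- repeats[repeats$chrom == hsps$chrom[i], , drop = FALSE]
    if (nrow(r) == 0L) return(FALSE)
    ov <- pmin(r$end, hsps$g_start[j]) - pmax(r$start, hsps$g_end[i])
    sum(ov >= cover * gap) == 1L
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (comp[i] != comp[j] && merges(i, j)) {
          old <- comp[j]; comp[comp == old] <- comp[i]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# canonical partition signature for comparing partitions
partition_key <- function(groups) {
  sets <- split(seq_along(groups), groups)
  paste(sort(vapply(sets, function(s) paste(s, collapse = ","), character(1))),
        collapse = "|")
}

# per-base interval subtraction
bf_subtract <- function(a, b, max_len = 100000L) {
  out <- list()
  for (cn in unique(a$chrom)) {
    inA <- logical(max_len); inB <- logical(max_len)
    ai <- a[a$chrom == cn, ]; bi <- b[b$chrom == cn, ]
    for (i in seq_len(nrow(ai))) if (ai$end[i] > ai$start[i])
      inA[(ai$start[i] + 1L):ai$end[i]] <- TRUE
    for (i in seq_len(nrow(bi))) if (bi$end[i] > bi$start[i])
      inB[(bi$start[i] + 1L):bi$end[i]] <- TRUE
    keep <- inA & !inB
    r <- rle(keep)
    e <- cumsum(r$lengths); s <- e - r$lengths
    if (any(r$values))
      out[[length(out) + 1L]] <- data.frame(chrom = cn, start = s[r$values],
                                            end = e[r$values])
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

# exhaustive path-enumeration forward oracle (mirrors the documented model)
enum_forward <- function(profile, seq) {
  code <- c(A = 0, C = 1, G = 2, T = 3)
  x <- unname(code[strsplit(toupper(seq), "")[[1]]]) + 1
  n <- length(x); L <- profile$length
  odds <- profile$match_emissions / profile$background
  t <- as.list(profile$transitions)
  recM <- function(j, i) {
    if (j == L) return(t$ME + t$MI * (if (i < n) recI(L, i + 1) else 0))
    t$MM * (if (i < n) odds[x[i + 1], j + 1] * recM(j + 1, i + 1) else 0) +
      t$MI * (if (i < n) recI(j, i + 1) else 0) +
      t$MD * recD(j + 1, i)
  }
  recI <- function(j, i) {
    if (j == L) return(t$IE + t$II * (if (i < n) recI(L, i + 1) else 0))
    t$IM * (if (i < n) odds[x[i + 1], j + 1] * recM(j + 1, i + 1) else 0) +
      t$II * (if (i < n) recI(j, i + 1) else 0)
  }
  recD <- function(j, i) {
    if (j == L) return(t$DE)
    t$DM * (if (i < n) odds[x[i + 1], j + 1] * recM(j + 1, i + 1) else 0) +
      t$DD * recD(j + 1, i)
  }
  total <- 0
  for (s in 0:n) {
    total <- total +
      t$BM * (if (s < n) odds[x[s + 1], 1] * recM(1, s + 1) else 0) +
      t$BI * (if (s < n) recI(0, s + 1) else 0) +
      t$BD * recD(1, s)
  }
  log(total)
}

# tip set below the child end of each edge, by naive edge-list traversal
bf_monophyly <- function(tree, species) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  sides <- lapply(seq_len(nrow(tree$edge)), function(e)
    sort(desc_tips(tree$edge[e, 2])))
  keys <- vapply(sides, paste, character(1), collapse = "\r")
  comp_keys <- vapply(sides, function(s)
    paste(sort(setdiff(tree$tip.label, s)), collapse = "\r"), character(1))
  sp <- species[tree$tip.label]
  res <- vapply(unique(sp), function(s) {
    leaves <- sort(tree$tip.label[sp == s])
    if (length(leaves) < 2) return("not assessable")
    if (length(leaves) == nt) return("monophyletic")
    k <- paste(leaves, collapse = "\r")
    if (k %in% keys || k %in% comp_keys) "monophyletic" else "intermingled"
  }, character(1))
  data.frame(species = unique(sp), pattern = unname(res),
             stringsAsFactors = FALSE)
}

# random HSP table generator for merge-rule property tests
random_hsps <- function(n, n_chrom = 2, span = 60000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(span, n)
  len <- sample(100:2500, n, replace = TRUE)
  data.frame(
    mt_start = sample.int(15000, n) - 1L, mt_end = 0L,
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    g_start = start, g_end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    pct_identity = runif(n, 80, 100), aln_len = len,
    mismatches = 0L, gap_opens = 0L, bitscore = len * 1.9,
    evalue = 1e-10, stringsAsFactors = FALSE) -> h
  h$mt_end <- h$mt_start + pmin(len, 500L)
  h
}

# shared small end-to-end fixture, built once per test run
.fixture_env <- new.env(parent = emptyenv())
small_pipeline_fixture <- function() {
  if (is.null(.fixture_env$res)) {
    cfg <- simulation_config(seed = 42, n_chromosomes = 2,
                             chromosome_lengths = 120000, n_insertions = 8,
                             mt_length = 12000, n_pure_mt_contigs = 1,
                             n_partial_mt_contigs = 2,
                             partial_occupancy = c(0.85, 0.5))
    .fixture_env$res <- run_pipeline(config = cfg)
  }
  .fixture_env$res
}
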