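# Interval algebra for repeat-element co-occurrence in NumtS loci and
# flanks, plus Spearman correlation reporting.

#' Flank specification
#'
#' @param flank_len flank length in bp (2000 for the repeat co-occurrence
#'   analysis; 1000 for the repeat-free dating subset).
#' @param clip_at_contig_ends clip flanks at `[0, chrom length)`.
#' @return an object of class `flank_spec`.
#' @export
flank_spec <- function(flank_len = 2000L, clip_at_contig_ends = TRUE) {
  if (flank_len < 0) stop("flank_len must be non-negative")
  structure(list(flank_len = as.integer(flank_len),
                 clip_at_contig_ends = isTRUE(clip_at_contig_ends)),
            class = "flank_spec")
}

#' Strand-aware flanking regions of NumtS
#'
#' 5' and 3' are defined relative to the NumtS strand: for a minus-strand
#' NumtS the 5' flank lies genomically downstream.
#'
#' @param numts assembled NumtS table (needs `chrom`, `start`, `end`,
#'   `strand`, `id`).
#' @param chrom_lengths named lengths of the chromosomes.
#' @param spec a [flank_spec()].
#' @return list with `five_prime` and `three_prime` BED-style data frames
#'   (`chrom`, `start`, `end`, `name` = NumtS id); zero-width clipped
#'   flanks are retained with `start == end`.
#' @export
flanks <- function(numts, chrom_lengths, spec = flank_spec()) {
  chrom_lengths <- unlist(chrom_lengths)
  f <- spec$flank_len
  up <- data.frame(chrom = numts$chrom,
                   start = numts$start - f, end = numts$start,
                   name = numts$id, stringsAsFactors = FALSE)
  down <- data.frame(chrom = numts$chrom,
                     start = numts$end, end = numts$end + f,
                     name = numts$id, stringsAsFactors = FALSE)
  if (spec$clip_at_contig_ends && nrow(up)) {
    lens <- as.numeric(chrom_lengths[numts$chrom])
    up$start <- pmax(0L, up$start)
    down$end <- pmin(as.integer(lens), down$end)
    down$start <- pmin(down$start, down$end)
    up$end <- pmax(up$end, up$start)
  }
  minus <- numts$strand == "-"
  five <- up; three <- down
  if (any(minus)) {
    five[minus, ] <- down[minus, ]
    three[minus, ] <- up[minus, ]
  }
  list(five_prime = five, three_prime = three)
}

# count repeat intervals overlapping (>= 1 bp) any interval of a region set
count_overlapping <- function(regions, repeats) {
  if (nrow(repeats) == 0L || nrow(regions) == 0L) return(0L)
  hit <- rep(FALSE, nrow(repeats))
  for (cn in unique(regions$chrom)) {
    r <- which(repeats$chrom == cn)
    if (!length(r)) next
    g <- regions[regions$chrom == cn, , drop = FALSE]
    q <- IRanges::IRanges(start = repeats$start[r] + 1L, end = repeats$end[r])
    s <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    hit[r] <- hit[r] | IRanges::overlapsAny(q, s)
  }
  sum(hit)
}

#' Repeat-element counts in NumtS loci and flanks
#'
#' For each region class (5' flank, NumtS locus, 3' flank) counts the
#' repeat intervals overlapping the class by at least 1 bp; a repeat
#' straddling a boundary is counted in every class it touches.  Counts are
#' also normalised by the number of NumtS.
#'
#' @param numts assembled NumtS table.
#' @param repeats BED-style repeat data frame.
#' @param chrom_lengths named chromosome lengths.
#' @param spec a [flank_spec()].
#' @return data frame with one row per class: `class`, `n_re`,
#'   `re_per_numts`.
#' @export
count_re <- function(numts, repeats, chrom_lengths, spec = flank_spec()) {
  fl <- flanks(numts, chrom_lengths, spec)
  locus <- data.frame(chrom = numts$chrom, start = numts$start,
                      end = numts$end, stringsAsFactors = FALSE)
  n <- max(1L, nrow(numts))
  counts <- c(five_prime_flank = count_overlapping(fl$five_prime, repeats),
              numts_locus = count_overlapping(locus, repeats),
              three_prime_flank = count_overlapping(fl$three_prime, repeats))
  data.frame(class = names(counts), n_re = as.integer(counts),
             re_per_numts = as.numeric(counts) / nrow(numts),
             stringsAsFactors = FALSE)
}

#' Subtract one interval set from another
#'
#' Set difference `a \ b` as maximal disjoint intervals, per chromosome
#' (the interval analogue of a BED subtract operation).
#'
#' @param a,b BED-style data frames (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @return BED-style data frame of `a` with all `b` bases removed.
#' @export
interval_subtract <- function(a, b) {
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  out <- lapply(unique(a$chrom), function(cn) {
    ai <- a[a$chrom == cn, , drop = FALSE]
    bi <- b[b$chrom == cn, , drop = FALSE]
    ra <- IRanges::IRanges(start = ai$start + 1L, end = ai$end)
    rb <- IRanges::IRanges(start = bi$start + 1L, end = bi$end)
    d <- IRanges::setdiff(ra, rb)
    if (length(d) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    data.frame(chrom = cn, start = IRanges::start(d) - 1L,
               end = IRanges::end(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Repeat-free NumtS subset for dating
#'
#' NumtS with zero repeat overlap in their own locus and in both flanking
#' regions (1 kb by default, the dating configuration): the subset whose
#' compositional comparison with the mitochondrion is not confounded by
#' repeat content.
#'
#' @param numts assembled NumtS table.
#' @param repeats BED-style repeat data frame.
#' @param chrom_lengths named chromosome lengths.
#' @param spec a [flank_spec()]; default 1000-bp flanks.
#' @return the subset of `numts` rows.
#' @export
re_free_subset <- function(numts, repeats, chrom_lengths,
                           spec = flank_spec(1000L)) {
  if (nrow(numts) == 0L) return(numts)
  fl <- flanks(numts, chrom_lengths, spec)
  keep <- vapply(seq_len(nrow(numts)), function(i) {
    regions <- data.frame(
      chrom = rep(numts$chrom[i], 3L),
      start = c(fl$five_prime$start[i], numts$start[i], fl$three_prime$start[i]),
      end = c(fl$five_prime$end[i], numts$end[i], fl$three_prime$end[i]),
      stringsAsFactors = FALSE)
    count_overlapping(regions, repeats) == 0L
  }, logical(1))
  out <- numts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hsps") <- attr(numts, "hsps")
  out
}

#' Spearman correlation matrix with Bonferroni-adjusted threshold
#'
#' Rank correlation (average ranks for ties) for every variable pair, with
#' two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' The significance threshold `alpha` is Bonferroni-adjusted by the number
#' of pairs tested.  Constant variables yield `NA` correlations.
#'
#' @param table data frame of numeric variables (rows = observations).
#' @param alpha family-wise significance level (default 0.05).
#' @return an object of class `correlation_report`: data frame `var1`,
#'   `var2`, `rho`, `p`, `significant`, with attributes `alpha`,
#'   `alpha_adj`, `n_tests`.
#' @export
spearman_matrix <- function(table, alpha = 0.05) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[, num, drop = FALSE]
  vars <- names(table)
  if (length(vars) < 2L) stop("need at least two numeric variables")
  pairs <- utils::combn(vars, 2L)
  n_tests <- ncol(pairs)
  alpha_adj <- alpha / n_tests
  rows <- lapply(seq_len(n_tests), function(k) {
    x <- table[[pairs[1, k]]]; y <- table[[pairs[2, k]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("fewer than 3 paired observations for ",
                     pairs[1, k], " vs ", pairs[2, k])
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
      rho <- NA_real_; p <- NA_real_
    } else {
      rho <- stats::cor(rank(x), rank(y))
      tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k], rho = rho, p = p,
               significant = !is.na(p) & p < alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "alpha_adj") <- alpha_adj
  attr(out, "n_tests") <- n_tests
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Correlate NumtS content with assembly statistics
#'
#' Reads a TSV of per-species NumtS counts and assembly contiguity
#' statistics (columns such as `species`, `n_numts`, `contig_n50`,
#' `scaffold_n50`, `l50`, `gap_bp`) and returns the Spearman matrix over
#' all numeric columns.
#'
#' @param path TSV path or a data frame.
#' @param alpha family-wise significance level.
#' @return a [spearman_matrix()] report.
#' @export
assembly_stats_correlation <- function(path, alpha = 0.05) {
  df <- if (is.character(path))
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else as.data.frame(path)
  spearman_matrix(df, alpha = alpha)
}
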