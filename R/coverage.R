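# Per-base occurrence of mitochondrial positions across nuclear genomes,
# profile layering, hotspot calling and per-genome summaries.

# Normalise input records (HSPs, truth records or assembled NumtS) into a
# two-column matrix of mt intervals.  mt_start > mt_end flags a fragment
# spanning the circular origin; assembled NumtS contribute each merged
# member interval.
mt_intervals_of <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.null(x$mt_intervals)) {
    return(do.call(rbind, lapply(x$mt_intervals, function(m)
      cbind(m[, "start"], m[, "end"]))))
  }
  cbind(x$mt_start, x$mt_end)
}

#' Per-base coverage profile along the circular mitochondrial genome
#'
#' `counts[p]` is the number of input records whose mitochondrial interval
#' contains position `p` (0-based).  Intervals with `mt_start > mt_end`
#' wrap across the origin and increment both ends of the circle.  The
#' implementation is a difference array with one cumulative sum.
#'
#' @param x HSP data frame, truth records, an assembled NumtS table (each
#'   member mt interval counts once), or a two-column matrix of intervals.
#' @param mt_length mitochondrial genome length.
#' @param label profile label (genome pair name).
#' @return an object of class `coverage_profile`: list with `mt_length`,
#'   `counts` (integer vector of length `mt_length`) and `label`.
#' @export
mt_coverage <- function(x, mt_length, label = "coverage") {
  iv <- mt_intervals_of(x)
  L <- as.integer(mt_length)
  diffarr <- integer(L + 1L)
  if (!is.null(iv) && nrow(iv) > 0) {
    s <- as.integer(iv[, 1]); e <- as.integer(iv[, 2])
    if (any(s < 0 | s >= L | e < 0 | e > L))
      stop("mt interval outside [0, mt_length] after unwrapping")
    wrap <- s > e | (s == e & FALSE)
    for (i in which(!wrap)) {
      diffarr[s[i] + 1L] <- diffarr[s[i] + 1L] + 1L
      diffarr[e[i] + 1L] <- diffarr[e[i] + 1L] - 1L
    }
    for (i in which(wrap)) {
      # [s, L) plus [0, e)
      diffarr[s[i] + 1L] <- diffarr[s[i] + 1L] + 1L
      diffarr[L + 1L] <- diffarr[L + 1L] - 1L
      diffarr[1L] <- diffarr[1L] + 1L
      diffarr[e[i] + 1L] <- diffarr[e[i] + 1L] - 1L
    }
  }
  counts <- cumsum(diffarr[seq_len(L)])
  structure(list(mt_length = L, counts = as.integer(counts), label = label),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile '%s': mt_length=%d, max=%d, mean=%.2f\n",
              x$label, x$mt_length, max(x$counts), mean(x$counts)))
  invisible(x)
}

#' Layer several coverage profiles
#'
#' Stacks per-position counts of profiles sharing one mt length and adds
#' across-label mean and max summaries (the numeric content of a layered
#' transparency plot).
#'
#' @param profiles named list of [mt_coverage()] profiles.
#' @return list with `matrix` (positions x labels), `mean` and `max`
#'   per-position summaries.
#' @export
layer_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  L <- unique(vapply(profiles, function(p) p$mt_length, integer(1)))
  if (length(L) != 1L) stop("profiles have mixed mt_length")
  labs <- vapply(seq_along(profiles), function(i) {
    if (!is.null(names(profiles)) && nzchar(names(profiles)[i]))
      names(profiles)[i] else profiles[[i]]$label
  }, character(1))
  m <- vapply(profiles, function(p) p$counts, integer(L))
  colnames(m) <- labs
  list(matrix = m, mean = rowMeans(m), max = apply(m, 1, max))
}

#' Plot layered coverage profiles
#'
#' Side-effect-free area plot writer: draws each profile as a translucent
#' polygon with mt locus boundaries as vertical lines, to a PNG file.
#'
#' @param profiles named list of coverage profiles.
#' @param locus_map optional locus BED data frame for boundary lines.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_coverage <- function(profiles, locus_map = NULL, path) {
  lay <- layer_profiles(profiles)
  grDevices::png(path, width = 1200, height = 500)
  on.exit(grDevices::dev.off())
  L <- nrow(lay$matrix)
  graphics::plot(NULL, xlim = c(0, L), ylim = c(0, max(lay$matrix, 1)),
                 xlab = "mtDNA position (bp)", ylab = "per-base occurrence",
                 main = "NumtS coverage of the mitochondrial genome")
  cols <- grDevices::hcl.colors(ncol(lay$matrix), "Dark 3", alpha = 0.35)
  for (k in seq_len(ncol(lay$matrix))) {
    graphics::polygon(c(0, seq_len(L) - 0.5, L), c(0, lay$matrix[, k], 0),
                      col = cols[k], border = NA)
  }
  if (!is.null(locus_map))
    graphics::abline(v = locus_map$end, col = "black", lty = 3)
  graphics::legend("topleft", legend = colnames(lay$matrix), fill = cols,
                   bty = "n")
  invisible(path)
}

#' Call coverage hotspots
#'
#' Maximal runs of positions whose count reaches the threshold, annotated
#' with the mt loci they overlap.  Runs touching both ends of the circle
#' are joined and reported once (with `mt_start > mt_end`).
#'
#' @param profile a [mt_coverage()] profile.
#' @param threshold absolute count, or if `quantile = TRUE` a quantile of
#'   the nonzero counts (default: 0.99 quantile).
#' @param locus_map optional locus BED data frame.
#' @param quantile interpret `threshold` as a quantile.
#' @return data frame `mt_start`, `mt_end`, `peak`, `loci`.
#' @export
call_hotspots <- function(profile, threshold = 0.99, locus_map = NULL,
                          quantile = threshold < 1) {
  counts <- profile$counts
  L <- profile$mt_length
  thr <- if (quantile) {
    nz <- counts[counts > 0]
    if (length(nz) == 0L) Inf else as.numeric(stats::quantile(nz, threshold, type = 7))
  } else threshold
  if (thr <= 0) stop("threshold must be positive")
  hot <- counts >= thr
  if (!any(hot)) {
    return(data.frame(mt_start = integer(), mt_end = integer(),
                      peak = integer(), loci = character(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  # join a run ending at L with a run starting at 0 (circular)
  if (nrow(runs) > 1L && runs$start[1] == 0L && runs$end[nrow(runs)] == L) {
    runs$start[1] <- runs$start[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  peak <- vapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    if (s < e) max(counts[(s + 1L):e]) else max(counts[c(seq_len(e), (s + 1L):L)])
  }, numeric(1))
  loci <- vapply(seq_len(nrow(runs)), function(i) {
    if (is.null(locus_map)) return(NA_character_)
    s <- runs$start[i]; e <- runs$end[i]
    segs <- if (s < e) list(c(s, e)) else list(c(s, L), c(0L, e))
    hitn <- unique(unlist(lapply(segs, function(sg)
      locus_map$name[locus_map$start < sg[2] & locus_map$end > sg[1]])))
    paste(hitn, collapse = ",")
  }, character(1))
  data.frame(mt_start = runs$start, mt_end = runs$end,
             peak = as.integer(peak), loci = loci, stringsAsFactors = FALSE)
}

#' Per-genome NumtS summary
#'
#' Headline statistics of a NumtS compilation, normalised to nuclear genome
#' size.
#'
#' @param numts assembled NumtS table ([assemble_numts()]).
#' @param genome_size total nuclear genome length (bp).
#' @return one-row data frame: `n_hsps`, `n_numts`, `numts_per_Mb`,
#'   `total_numts_bp`, `percent_of_genome`, `mean_length`, `mean_identity`
#'   (means are `NA` for an empty compilation).
#' @export
genome_summary <- function(numts, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  hsps <- attr(numts, "hsps")
  n_hsps <- if (!is.null(hsps)) nrow(hsps) else sum(numts$n_members)
  n <- nrow(numts)
  total_bp <- if (n) sum(numts$end - numts$start) else 0
  data.frame(
    n_hsps = n_hsps, n_numts = n,
    numts_per_Mb = n / (genome_size / 1e6),
    total_numts_bp = total_bp,
    percent_of_genome = 100 * total_bp / genome_size,
    mean_length = if (n) total_bp / n else NA_real_,
    mean_identity = if (n) mean(numts$mean_identity) else NA_real_)
}

#' Write a coverage profile as TSV
#' @param layered result of [layer_profiles()] or a single profile.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(layered, path) {
  if (inherits(layered, "coverage_profile"))
    layered <- layer_profiles(setNames(list(layered), layered$label))
  df <- data.frame(position = seq_len(nrow(layered$matrix)) - 1L,
                   layered$matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
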