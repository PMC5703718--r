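# Shared helpers: BED I/O in the package-wide 0-based half-open convention,
# sequence utilities, and interval primitives.

#' Read a BED file
#'
#' Reads BED3/BED6 into a data frame with 0-based half-open coordinates
#' (BED's native convention, kept unchanged).  `track` and `browser` header
#' lines are skipped.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser)\\b", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(text = lines, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write a BED file
#'
#' Writes a data frame of 0-based half-open intervals as BED, optionally with
#' a UCSC `track` header line.
#'
#' @param df data frame with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` are written when present.
#' @param path output path.
#' @param track_line optional track header line (written verbatim).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, track_line = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  if (nrow(df) > 0) {
    write.table(df[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N (case preserved as upper).
#' @return reverse-complemented character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Union length of a set of half-open intervals, as integer bp.
interval_union_width <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# Merge half-open intervals into maximal disjoint ones; returns matrix cols
# start, end (0-based half-open).
reduce_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Evaluate `expr` under a fixed RNG seed, restoring RNG state afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Draw a random iid DNA string of length n with the given base probabilities.
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# sample one element from a vector of values (safe for length-1 vectors,
# where base::sample() would treat the value as a range)
resample1 <- function(x) x[sample.int(length(x), 1L)]

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
}
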