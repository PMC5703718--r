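# HSP production: BLAST tabular I/O and the built-in seed-and-extend aligner.

#' Detection parameters for the built-in aligner
#'
#' Scoring and filtering parameters for [find_hsps()].  The aligner is a
#' self-contained seed-and-extend nucleotide search (exact word seeding on
#' both strands, gapped X-drop extension, banded realignment for per-hit
#' statistics); it is not a BLAST clone, and its e-values use fixed
#' Karlin-Altschul parameters for the default +1/-2 scheme
#' (lambda = 1.33, K = 0.621), so they are approximate and intended only
#' for thresholding.
#'
#' @param evalue_max maximum e-value retained (default 1e-3).
#' @param word_size exact-match seed length (>= 8).
#' @param xdrop score drop-off terminating extension (score units).
#' @param match,mismatch match reward and mismatch penalty.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @param max_hits cap on reported HSPs per run.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(evalue_max = 1e-3, word_size = 11L, xdrop = 25L,
                             match = 1L, mismatch = -2L, gap_open = 2L,
                             gap_extend = 2L, max_hits = 200000L) {
  if (evalue_max <= 0) stop("evalue_max must be positive")
  if (word_size < 8L) stop("word_size must be at least 8")
  p <- list(evalue_max = evalue_max, word_size = as.integer(word_size),
            xdrop = as.integer(xdrop), match = as.integer(match),
            mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            max_hits = as.integer(max_hits),
            ka_lambda = 1.33, ka_k = 0.621)
  class(p) <- "detection_params"
  p
}

.hsp_cols <- c("mt_start", "mt_end", "chrom", "g_start", "g_end", "strand",
               "pct_identity", "aln_len", "mismatches", "gap_opens",
               "bitscore", "evalue")

empty_hsps <- function() {
  data.frame(mt_start = integer(), mt_end = integer(), chrom = character(),
             g_start = integer(), g_end = integer(), strand = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             bitscore = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

sort_hsps <- function(hsps) {
  hsps <- hsps[order(hsps$chrom, hsps$g_start, hsps$g_end), , drop = FALSE]
  rownames(hsps) <- NULL
  hsps
}

#' Read BLAST tabular (outfmt 6) output as HSPs
#'
#' Parses the standard 12-column dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), with the
#' mitochondrial genome as the query.  BLAST's 1-based inclusive coordinates
#' are converted to 0-based half-open; subject rows with `send < sstart` are
#' normalised to `strand = "-"` with ordered coordinates.
#'
#' @param path file path.
#' @return HSP data frame sorted by (`chrom`, `g_start`).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(empty_hsps())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("malformed BLAST tabular row at line ", bad[1], ": expected 12 columns")
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, c(3:10, 11, 12), drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  badnum <- which(apply(num, 1, function(r) any(is.na(r))))
  if (length(badnum))
    stop("malformed BLAST tabular row at line ", badnum[1],
         ": non-numeric field")
  sstart <- num[, 7]; send <- num[, 8]
  minus <- send < sstart
  hsps <- data.frame(
    mt_start = as.integer(num[, 5] - 1), mt_end = as.integer(num[, 6]),
    chrom = m[, 2],
    g_start = as.integer(ifelse(minus, send, sstart) - 1),
    g_end = as.integer(ifelse(minus, sstart, send)),
    strand = ifelse(minus, "-", "+"),
    pct_identity = num[, 1], aln_len = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_opens = as.integer(num[, 4]),
    bitscore = num[, 10], evalue = num[, 9],
    stringsAsFactors = FALSE)
  attr(hsps, "query") <- m[1, 1]
  sort_hsps(hsps)
}

#' Write HSPs as BLAST tabular (outfmt 6)
#'
#' Inverse of [read_blast_tab()]: emits 12 columns with 1-based inclusive
#' coordinates; minus-strand hits are encoded BLAST-style with
#' `sstart > send`.
#'
#' @param hsps HSP data frame.
#' @param path output path.
#' @param query query sequence name for column 1 (default `"chrM"` or the
#'   name recorded when the HSPs were read).
#' @return `path`, invisibly.
#' @export
write_hsp_tab <- function(hsps, path, query = NULL) {
  if (is.null(query)) query <- attr(hsps, "query")
  if (is.null(query)) query <- "chrM"
  if (nrow(hsps) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  minus <- hsps$strand == "-"
  out <- data.frame(
    qseqid = query, sseqid = hsps$chrom,
    pident = sprintf("%.3f", hsps$pct_identity),
    length = hsps$aln_len, mismatch = hsps$mismatches,
    gapopen = hsps$gap_opens,
    qstart = hsps$mt_start + 1L, qend = hsps$mt_end,
    sstart = ifelse(minus, hsps$g_end, hsps$g_start + 1L),
    send = ifelse(minus, hsps$g_start + 1L, hsps$g_end),
    evalue = format(hsps$evalue, digits = 3, scientific = TRUE),
    bitscore = sprintf("%.1f", hsps$bitscore),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Find HSPs between a mitochondrial query and nuclear subjects
#'
#' Built-in similarity search: exact `word_size`-mer seeding on both strands
#' of each subject, gapped X-drop extension, banded global realignment of
#' each extended interval for identity/mismatch/gap statistics, and
#' Karlin-Altschul e-value thresholding.  The mitochondrial query is treated
#' as circular by scanning its doubled sequence; rotation-duplicate hits are
#' collapsed and hits running across the origin are split at position 0.
#'
#' @param nuclear named character vector (or `DNAStringSet`) of subject
#'   sequences over A/C/G/T/N.
#' @param mt mitochondrial genome sequence (character scalar or the list
#'   returned by [generate_mt()]).
#' @param params a [detection_params()].
#' @return HSP data frame sorted by (`chrom`, `g_start`).
#' @export
find_hsps <- function(nuclear, mt, params = detection_params()) {
  if (is.list(mt) && !is.null(mt$seq)) mt <- mt$seq
  if (methods::is(nuclear, "DNAStringSet")) {
    nms <- names(nuclear)
    nuclear <- as.character(nuclear)
    names(nuclear) <- nms
  }
  if (is.null(names(nuclear)) || any(!nzchar(names(nuclear))))
    stop("subject sequences must be named")
  mt <- toupper(as.character(mt))
  df <- .detect_hsps_cpp(names(nuclear), toupper(unname(nuclear)), mt,
                         params$word_size, params$match, params$mismatch,
                         params$gap_open, params$gap_extend, params$xdrop,
                         params$evalue_max, params$ka_lambda, params$ka_k,
                         params$max_hits)
  df$mt_start <- as.integer(df$mt_start)
  df$mt_end <- as.integer(df$mt_end)
  df$g_start <- as.integer(df$g_start)
  df$g_end <- as.integer(df$g_end)
  df$aln_len <- as.integer(df$aln_len)
  df$mismatches <- as.integer(df$mismatches)
  df$gap_opens <- as.integer(df$gap_opens)
  attr(df, "query") <- "chrM"
  sort_hsps(df)
}
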