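# UCSC-style annotation tracks and the NumtS/mt mismatch records.

#' Write the four NumtS annotation tracks
#'
#' Emits the UCSC-style custom tracks of a NumtS compilation:
#' `numts.bed` (nuclear positions of the purged HSPs), `assembled_numts.bed`
#' (merged NumtS), `numts_on_mitochondrion.bed` (the NumtS projected onto
#' mt coordinates) and, when mismatch records are supplied,
#' `numts_mismatches.tsv`.  Names cross-reference the nuclear and mt
#' tracks: every assembled NumtS id appears in the mt track and vice
#' versa.  All BED output is 0-based half-open and sorted.
#'
#' @param numts assembled NumtS table ([assemble_numts()]).
#' @param hsps purged HSP data frame (defaults to the HSPs stored on
#'   `numts`).
#' @param mt_length mitochondrial genome length (for the mt track header).
#' @param outdir output directory (created if needed).
#' @param mismatches optional named list of [mismatch_records()] results to
#'   write as the mismatch track.
#' @return named vector of file paths, invisibly.
#' @export
write_tracks <- function(numts, hsps = attr(numts, "hsps"), mt_length,
                         outdir, mismatches = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(numts = file.path(outdir, "numts.bed"),
             assembled = file.path(outdir, "assembled_numts.bed"),
             on_mt = file.path(outdir, "numts_on_mitochondrion.bed"))

  # HSP track: members named after their NumtS so tracks cross-reference
  hsp_rows <- list()
  mt_rows <- list()
  for (i in seq_len(nrow(numts))) {
    m <- numts$members[[i]]
    hsp_rows[[i]] <- data.frame(
      chrom = hsps$chrom[m], start = hsps$g_start[m], end = hsps$g_end[m],
      name = sprintf("%s_hsp%d", numts$id[i], seq_along(m)),
      score = pmin(1000L, as.integer(round(10 * hsps$pct_identity[m]))),
      strand = hsps$strand[m], stringsAsFactors = FALSE)
    iv <- numts$mt_intervals[[i]]
    mt_rows[[i]] <- data.frame(
      chrom = "chrM", start = iv[, "start"], end = iv[, "end"],
      name = numts$id[i], score = 0L, strand = numts$strand[i],
      stringsAsFactors = FALSE)
  }
  hsp_bed <- if (length(hsp_rows)) do.call(rbind, hsp_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  hsp_bed <- hsp_bed[order(hsp_bed$chrom, hsp_bed$start), , drop = FALSE]
  write_bed(hsp_bed, paths["numts"],
            track_line = "track name=NumtS description=\"Nuclear positions of purged mtDNA HSPs\"")

  asm <- data.frame(chrom = numts$chrom, start = numts$start, end = numts$end,
                    name = numts$id,
                    score = pmin(1000L, as.integer(round(10 * numts$mean_identity))),
                    strand = numts$strand, stringsAsFactors = FALSE)
  asm <- asm[order(asm$chrom, asm$start), , drop = FALSE]
  write_bed(asm, paths["assembled"],
            track_line = "track name=AssembledNumtS description=\"Merged NumtS\"")

  mt_bed <- if (length(mt_rows)) do.call(rbind, mt_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  mt_bed <- mt_bed[order(mt_bed$chrom, mt_bed$start), , drop = FALSE]
  write_bed(mt_bed, paths["on_mt"],
            track_line = sprintf(
              "track name=NumtSonMito description=\"NumtS on the mitochondrial genome (length %d); coordinates 0-based half-open on the mt plus strand\"",
              as.integer(mt_length)))

  if (!is.null(mismatches)) {
    paths <- c(paths, mismatch = file.path(outdir, "numts_mismatches.tsv"))
    rows <- lapply(names(mismatches), function(id) {
      r <- mismatches[[id]]$records
      if (nrow(r) == 0L) return(NULL)
      cbind(numts_id = id, r, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(numts_id = character(), type = character(),
                 mt_pos = integer(), mt_base = character(),
                 nuc_base = character())
    write.table(out, paths["mismatch"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Mismatch records between a NumtS and its mitochondrial counterpart
#'
#' Global Needleman-Wunsch alignment (match +1, mismatch -2, gap open 4,
#' gap extend 2, via Biostrings) of the NumtS sequence against its mt
#' source region, reporting each substitution as (mt position, mt base,
#' nuclear base) and each indel as a gap record, plus a CIGAR-style edit
#' string with the mt sequence as reference.  `mt_offset` shifts reported
#' positions to absolute mt coordinates.
#'
#' @param numts_seq nuclear NumtS sequence (oriented to the mt plus
#'   strand).
#' @param mt_counterpart_seq mitochondrial source sequence.
#' @param mt_offset 0-based mt coordinate of the counterpart's first base.
#' @return list with `records` (data frame `type`, `mt_pos`, `mt_base`,
#'   `nuc_base`), `cigar`, `n_mismatches`.
#' @export
mismatch_records <- function(numts_seq, mt_counterpart_seq, mt_offset = 0L) {
  if (nchar(numts_seq) == 0L || nchar(mt_counterpart_seq) == 0L)
    stop("sequences must be nonempty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(numts_seq)),
    subject = Biostrings::DNAString(toupper(mt_counterpart_seq)),
    type = "global", substitutionMatrix = sm,
    gapOpening = 4, gapExtension = 2)
  nuc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  mtc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  mt_pos <- as.integer(mt_offset)
  recs <- list()
  ops <- character(length(nuc))
  for (k in seq_along(nuc)) {
    if (mtc[k] == "-") {            # insertion in the NumtS
      ops[k] <- "I"
      recs[[length(recs) + 1L]] <- data.frame(
        type = "ins", mt_pos = mt_pos, mt_base = "-", nuc_base = nuc[k],
        stringsAsFactors = FALSE)
    } else if (nuc[k] == "-") {     # deletion from the mt source
      ops[k] <- "D"
      recs[[length(recs) + 1L]] <- data.frame(
        type = "del", mt_pos = mt_pos, mt_base = mtc[k], nuc_base = "-",
        stringsAsFactors = FALSE)
      mt_pos <- mt_pos + 1L
    } else {
      ops[k] <- "M"
      if (nuc[k] != mtc[k]) {
        recs[[length(recs) + 1L]] <- data.frame(
          type = "sub", mt_pos = mt_pos, mt_base = mtc[k], nuc_base = nuc[k],
          stringsAsFactors = FALSE)
      }
      mt_pos <- mt_pos + 1L
    }
  }
  r <- rle(ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(type = character(), mt_pos = integer(),
               mt_base = character(), nuc_base = character(),
               stringsAsFactors = FALSE)
  list(records = records, cigar = cigar,
       n_mismatches = sum(records$type == "sub"))
}

#' Enumerate intra- and interspecies compilation jobs
#'
#' Every genome's mtDNA is searched against its own nuclear genome (one
#' intraspecies compilation per label) and against every other nuclear
#' genome (`n * (n - 1)` interspecies compilations), named
#' `<mt_label>__on__<nuclear_label>`.
#'
#' @param labels character vector of genome labels.
#' @return data frame `mt_label`, `nuclear_label`, `type`, `name`.
#' @export
cross_compilation_schedule <- function(labels) {
  stopifnot(length(labels) >= 1L, !anyDuplicated(labels))
  grid <- expand.grid(mt_label = labels, nuclear_label = labels,
                      stringsAsFactors = FALSE)
  grid$type <- ifelse(grid$mt_label == grid$nuclear_label,
                      "intraspecies", "interspecies")
  grid$name <- paste0(grid$mt_label, "__on__", grid$nuclear_label)
  grid[order(grid$type == "interspecies", grid$mt_label, grid$nuclear_label), ,
       drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
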