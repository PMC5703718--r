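# Profile-HMM insertion dating: a NumtS that still resembles its
# mitochondrial source scores higher against a mitochondrion-derived
# profile than against a profile of its own flanking regions; once the
# fragment has compositionally homogenised with the nuclear background the
# difference turns negative.  All scores are natural-log odds (nats)
# against an iid background null.

.default_transitions <- c(BM = 0.90, BI = 0.05, BD = 0.05,
                          MM = 0.90, MI = 0.05, MD = 0.05,
                          IM = 0.70, II = 0.30,
                          DM = 0.70, DD = 0.30,
                          ME = 0.95, IE = 0.70, DE = 1.00)

#' Build a profile HMM from aligned sequences
#'
#' Match columns are alignment columns with at least 50% residues; their
#' emission probabilities are pseudocount-smoothed column frequencies,
#' `(count + pseudocount) / (n + 4 * pseudocount)`.  A single-sequence
#' input yields a profile heavily smoothed toward the background.  Insert
#' states emit the background distribution; transition probabilities are
#' fixed (see Details).
#'
#' @details Transition scheme: `B->M1 0.90 | I0 0.05 | D1 0.05`;
#' `M->M 0.90 | M->I 0.05 | M->D 0.05` (last column `M->E 0.95`);
#' `I->M 0.70 | I->I 0.30`; `D->M 0.70 | D->D 0.30` (last `D->E 1`).
#'
#' @param seqs character vector of aligned sequences (equal length; `-` or
#'   `.` for gaps), or a single unaligned sequence.
#' @param pseudocount Dirichlet smoothing weight (default 1).
#' @param background base frequencies of the null model (A, C, G, T).
#' @return an object of class `profile_hmm`: list with `length`,
#'   `match_emissions` (4 x L matrix, rows A/C/G/T), `insert_emissions`,
#'   `transitions`, `background`, `pseudocount`.
#' @export
build_profile <- function(seqs, pseudocount = 1,
                          background = rep(0.25, 4)) {
  if (length(seqs) == 0L || all(!nzchar(seqs))) stop("empty profile input")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  mat[mat == "."] <- "-"
  resid_frac <- colMeans(matrix(mat %in% c("A", "C", "G", "T"),
                                nrow = nrow(mat)))
  is_match <- resid_frac >= 0.5
  if (!any(is_match)) stop("no match columns: alignment is all gaps")
  cols <- which(is_match)
  L <- length(cols)
  bases <- c("A", "C", "G", "T")
  em <- matrix(0, nrow = 4, ncol = L, dimnames = list(bases, NULL))
  n <- nrow(mat)
  for (j in seq_len(L)) {
    cnt <- table(factor(mat[, cols[j]], levels = bases))
    em[, j] <- (as.numeric(cnt) + pseudocount) /
      (sum(cnt) + 4 * pseudocount)
    # columns may hold gaps/N below the 50% threshold: renormalise over the
    # residues actually counted plus pseudocounts
  }
  background <- background / sum(background)
  structure(list(length = L, match_emissions = em,
                 insert_emissions = background,
                 transitions = .default_transitions,
                 background = background, pseudocount = pseudocount),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm: %d match columns, pseudocount %g\n",
              x$length, x$pseudocount))
  invisible(x)
}

#' Glocal forward log-odds score of a sequence against a profile
#'
#' Log-space forward algorithm over the match/insert/delete lattice: the
#' whole profile must be traversed, while any prefix or suffix of the
#' sequence may be left unaligned at zero cost (it is emitted by the
#' background null).  The returned value is the natural-log odds (nats) of
#' the sequence under the profile relative to the iid background; `N`
#' residues score as background.
#'
#' @param profile a [build_profile()] object.
#' @param seq character scalar over A/C/G/T/N.
#' @return log-odds score in nats.
#' @export
forward_score <- function(profile, seq) {
  stopifnot(inherits(profile, "profile_hmm"))
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) == 0L) stop("empty sequence")
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  enc <- unname(code[chars])
  enc[is.na(enc)] <- -1L
  lo <- log(profile$match_emissions / profile$background)
  .forward_score_cpp(lo, as.integer(enc), profile$transitions)
}

#' Score difference between mitochondrial and flank profiles
#'
#' The dating statistic: `delta = score_mt - score_flank`, positive for
#' relatively recent insertions (still mitochondrion-like), negative for
#' old ones (homogenised toward the flanking nuclear composition).
#'
#' @param numts_seq the NumtS nucleotide sequence.
#' @param mt_profile profile built from the mitochondrial counterpart.
#' @param flank_profile profile built from the flanking regions.
#' @param id NumtS identifier carried into the result.
#' @param tolerance |delta| below which the call is `"ambiguous"`
#'   (default 0).
#' @return one-row data frame `numts_id`, `score_mt`, `score_flank`,
#'   `delta`, `call`.
#' @export
delta_score <- function(numts_seq, mt_profile, flank_profile,
                        id = "NumtS", tolerance = 0) {
  s_mt <- forward_score(mt_profile, numts_seq)
  s_fl <- forward_score(flank_profile, numts_seq)
  d <- s_mt - s_fl
  call <- if (abs(d) <= tolerance) "ambiguous" else if (d > 0) "recent" else "old"
  data.frame(numts_id = id, score_mt = s_mt, score_flank = s_fl,
             delta = d, call = call, stringsAsFactors = FALSE)
}

# Right-pad sequences with gaps to a common length (deterministic pooled
# "consensus" alignment surrogate for unaligned flank sets).
pad_to_common_length <- function(seqs) {
  w <- max(nchar(seqs))
  vapply(seqs, function(s)
    paste0(s, strrep("-", w - nchar(s))), character(1), USE.NAMES = FALSE)
}

#' Flank profile with consensus fallback
#'
#' Builds the flanking-region profile for one NumtS from its own two
#' (repeat-subtracted) flank sequences.  If the assembly-gap fraction
#' (`N` bases) of the concatenated flanks exceeds `gap_fraction_max`, the
#' flanks are unusable and a consensus profile over all other NumtS flank
#' sequences (right-padded to a common length) is used instead.
#'
#' @param own_flanks character vector with the NumtS's flank sequences.
#' @param other_flanks character vector of all other NumtS flank sequences
#'   (used only for the fallback).
#' @param gap_fraction_max maximum tolerated N fraction (default 0.3).
#' @param pseudocount passed to [build_profile()].
#' @param target_length optional profile length (bp).  The score difference
#'   against the mitochondrial profile is only meaningful when both
#'   profiles have comparable length, so the flank profile is trained on a
#'   window of the concatenated flanks truncated to the NumtS length
#'   (profiles of mismatched length differ by delete-path costs that
#'   swamp the compositional signal).
#' @return list with `profile` (a `profile_hmm`) and `source`
#'   (`"own"` or `"consensus"`).
#' @export
flank_profile_for <- function(own_flanks, other_flanks = character(0),
                              gap_fraction_max = 0.3, pseudocount = 1,
                              target_length = NULL) {
  fit_len <- function(s) {
    if (is.null(target_length) || nchar(s) <= target_length) s
    else substr(s, 1L, target_length)
  }
  own <- paste(own_flanks, collapse = "")
  n_frac <- if (nchar(own) == 0L) 1 else
    sum(strsplit(toupper(own), "")[[1]] == "N") / nchar(own)
  if (n_frac <= gap_fraction_max && nchar(own) > 0L) {
    return(list(profile = build_profile(fit_len(own), pseudocount = pseudocount),
                source = "own"))
  }
  if (length(other_flanks) == 0L || all(!nzchar(other_flanks)))
    stop("no usable flanking sequences anywhere")
  pooled <- pad_to_common_length(vapply(other_flanks, fit_len, character(1),
                                        USE.NAMES = FALSE))
  list(profile = build_profile(pooled, pseudocount = pseudocount),
       source = "consensus")
}

#' Date a set of NumtS by profile-score difference
#'
#' Convenience driver: for each NumtS, builds the single-sequence profile
#' of its mitochondrial counterpart, the flank profile (with consensus
#' fallback), and reports the [delta_score()] table.
#'
#' @param numts_seqs named character vector of NumtS sequences.
#' @param mt_counterparts named character vector of the corresponding
#'   mitochondrial source sequences.
#' @param flank_seqs named list: per NumtS, character vector of its
#'   (repeat-subtracted) flank sequences.
#' @param gap_fraction_max N-fraction above which the consensus flank
#'   profile is used.
#' @param tolerance ambiguity band for the call.
#' @return data frame with one row per NumtS (`numts_id`, `score_mt`,
#'   `score_flank`, `delta`, `call`, `flank_source`).
#' @export
date_numts <- function(numts_seqs, mt_counterparts, flank_seqs,
                       gap_fraction_max = 0.3, tolerance = 0) {
  ids <- names(numts_seqs)
  stopifnot(!is.null(ids), setequal(ids, names(mt_counterparts)),
            setequal(ids, names(flank_seqs)))
  rows <- lapply(ids, function(id) {
    mt_prof <- build_profile(mt_counterparts[[id]])
    fl <- flank_profile_for(flank_seqs[[id]],
                            unlist(flank_seqs[setdiff(ids, id)]),
                            gap_fraction_max = gap_fraction_max,
                            target_length = nchar(numts_seqs[[id]]))
    r <- delta_score(numts_seqs[[id]], mt_prof, fl$profile, id = id,
                     tolerance = tolerance)
    r$flank_source <- fl$source
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
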