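# Purging of contamination/artefact contigs and assembly of HSPs into NumtS.

#' Purge configuration
#'
#' @param occupancy_max contigs whose mtDNA occupancy is strictly greater
#'   than this fraction are removed (default 0.80; "higher than 80%" is a
#'   strict inequality, so a contig at exactly 0.80 is kept).
#' @param excluded_chrom_patterns case-insensitive substrings; HSPs on
#'   chromosomes matching any of them (random/unplaced/unknown sequences)
#'   are dropped.
#' @return an object of class `purge_config`.
#' @export
purge_config <- function(occupancy_max = 0.80,
                         excluded_chrom_patterns = c("random", "chrun", "unknown")) {
  if (occupancy_max <= 0 || occupancy_max > 1)
    stop("occupancy_max must lie in (0, 1]")
  structure(list(occupancy_max = occupancy_max,
                 excluded_chrom_patterns = tolower(excluded_chrom_patterns)),
            class = "purge_config")
}

#' Remove contigs dominated by mitochondrial sequence
#'
#' Computes, per contig, the occupancy percentage: the width of the union of
#' HSP subject intervals divided by the contig length.  Contigs whose
#' occupancy exceeds `config$occupancy_max` are removed together with all
#' their HSPs (they are mitochondrial contamination or assembly artefacts
#' rather than genuine nuclear loci).  The union, not the summed HSP
#' lengths, is used so overlapping hits cannot push occupancy past 1.
#'
#' @param hsps HSP data frame.
#' @param contig_lengths named numeric vector or list of contig lengths;
#'   every HSP's `chrom` must be present.
#' @param config a [purge_config()].
#' @return list with `hsps` (kept rows) and `report`, a data frame with one
#'   row per contig carrying HSPs: `contig`, `length`, `occupied_bp`,
#'   `occupancy`, `n_hsps`, `removed`.
#' @export
occupancy_filter <- function(hsps, contig_lengths, config = purge_config()) {
  contig_lengths <- unlist(contig_lengths)
  if (nrow(hsps) == 0L) {
    return(list(hsps = hsps,
                report = data.frame(contig = character(), length = numeric(),
                                    occupied_bp = numeric(), occupancy = numeric(),
                                    n_hsps = integer(), removed = logical())))
  }
  missing <- setdiff(unique(hsps$chrom), names(contig_lengths))
  if (length(missing))
    stop("no length known for contig(s): ", paste(missing, collapse = ", "))
  by_chrom <- split(seq_len(nrow(hsps)), hsps$chrom)
  report <- do.call(rbind, lapply(names(by_chrom), function(cn) {
    idx <- by_chrom[[cn]]
    occ_bp <- interval_union_width(hsps$g_start[idx], hsps$g_end[idx])
    len <- as.numeric(contig_lengths[[cn]])
    data.frame(contig = cn, length = len, occupied_bp = occ_bp,
               occupancy = occ_bp / len, n_hsps = length(idx),
               removed = occ_bp / len > config$occupancy_max,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  drop_contigs <- report$contig[report$removed]
  kept <- hsps[!(hsps$chrom %in% drop_contigs), , drop = FALSE]
  rownames(kept) <- NULL
  list(hsps = kept, report = report)
}

#' Drop HSPs on random and unknown chromosomes
#'
#' Case-insensitive substring matching of chromosome names against the
#' configured exclusion patterns.
#'
#' @param hsps HSP data frame.
#' @param config a [purge_config()].
#' @return list with `hsps` (kept rows) and `report`, counts dropped per
#'   pattern.
#' @export
chrom_filter <- function(hsps, config = purge_config()) {
  lc <- tolower(hsps$chrom)
  dropped_by <- vapply(config$excluded_chrom_patterns, function(p)
    sum(grepl(p, lc, fixed = TRUE)), integer(1))
  excl <- Reduce(`|`, lapply(config$excluded_chrom_patterns, function(p)
    grepl(p, lc, fixed = TRUE)), rep(FALSE, nrow(hsps)))
  kept <- hsps[!excl, , drop = FALSE]
  rownames(kept) <- NULL
  list(hsps = kept,
       report = data.frame(pattern = config$excluded_chrom_patterns,
                           n_dropped = dropped_by, stringsAsFactors = FALSE))
}

#' Assembly configuration
#'
#' @param max_gap HSPs on the same chromosome and strand are merged when
#'   their genomic gap is at most this many bp (default 2000, inclusive).
#' @param repeat_bridge when `TRUE`, a gap longer than `max_gap` still
#'   merges if exactly one repeat interval covers at least
#'   `bridge_cover_min` of its length (a single repeat element intermingled
#'   between the two hits).
#' @param bridge_cover_min minimum fraction of the gap one repeat must
#'   cover to bridge it (default 0.9).
#' @return an object of class `assemble_config`.
#' @export
assemble_config <- function(max_gap = 2000L, repeat_bridge = TRUE,
                            bridge_cover_min = 0.9) {
  if (max_gap < 0) stop("max_gap must be non-negative")
  structure(list(max_gap = as.integer(max_gap),
                 repeat_bridge = isTRUE(repeat_bridge),
                 bridge_cover_min = bridge_cover_min),
            class = "assemble_config")
}

# Does the pair (end1, start2) merge? Overlap always merges; otherwise the
# gap must be <= max_gap, or bridged by exactly one repeat covering >= 90%.
pair_merges <- function(end1, start2, chrom, rep_start, rep_end, config) {
  gap <- start2 - end1
  if (gap <= config$max_gap) return(TRUE) # includes overlap (gap <= 0)
  if (!config$repeat_bridge || length(rep_start) == 0L) return(FALSE)
  ov <- pmin(rep_end, start2) - pmax(rep_start, end1)
  sum(ov >= config$bridge_cover_min * gap) == 1L
}

#' Assemble HSPs into NumtS
#'
#' Transitively merges same-chromosome, same-strand HSPs whose genomic gap
#' is at most `max_gap` bp, or whose gap is covered (to at least 90% of its
#' length) by exactly one repeat element.  Overlapping HSPs always merge;
#' opposite-strand neighbours never do.  Merging conditions only on genomic
#' distance and orientation; the mitochondrial intervals of the members are
#' carried along as a union for reporting.
#'
#' @param hsps HSP data frame (sorted or sortable by `chrom`, `g_start`).
#' @param repeats optional BED-style data frame of repeat elements
#'   (`chrom`, `start`, `end`); `NULL` disables repeat bridging.
#' @param config an [assemble_config()].
#' @return data frame of NumtS with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `n_members`, `mean_identity`, plus list-columns `members`
#'   (integer row indices into the sorted input) and `mt_intervals`
#'   (two-column matrix of merged mt intervals per NumtS).  Attribute
#'   `"hsps"` stores the sorted input.
#' @export
assemble_numts <- function(hsps, repeats = NULL, config = assemble_config()) {
  hsps <- sort_hsps(hsps)
  n <- nrow(hsps)
  if (n == 0L) {
    out <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_members = integer(), mean_identity = numeric(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    out$mt_intervals <- list()
    attr(out, "hsps") <- hsps
    return(out)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  max_rep <- if (!is.null(repeats) && nrow(repeats)) max(repeats$end - repeats$start) else 0
  limit <- max(config$max_gap, ceiling(max_rep / config$bridge_cover_min))

  groups <- split(seq_len(n), paste(hsps$chrom, hsps$strand))
  for (idx in groups) {
    idx <- idx[order(hsps$g_start[idx])]
    cn <- hsps$chrom[idx[1]]
    if (!is.null(repeats) && nrow(repeats)) {
      r <- repeats[repeats$chrom == cn, , drop = FALSE]
      rs <- r$start; re <- r$end
    } else {
      rs <- integer(0); re <- integer(0)
    }
    k <- length(idx)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        gap_lo <- hsps$g_start[j] - hsps$g_end[i]
        if (gap_lo > limit) break # later b only start further right
        if (pair_merges(hsps$g_end[i], hsps$g_start[j], cn, rs, re, config))
          unite(i, j)
      }
    }
  }

  comp <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (cid in unique(comp)) {
    m <- which(comp == cid)
    m <- m[order(hsps$g_start[m])]
    mti <- reduce_intervals(hsps$mt_start[m], hsps$mt_end[m])
    out[[length(out) + 1L]] <- data.frame(
      chrom = hsps$chrom[m[1]], start = min(hsps$g_start[m]),
      end = max(hsps$g_end[m]), strand = hsps$strand[m[1]],
      n_members = length(m),
      mean_identity = mean(hsps$pct_identity[m]),
      stringsAsFactors = FALSE)
    attr(out[[length(out)]], "members") <- m
    attr(out[[length(out)]], "mt_intervals") <- mti
  }
  members <- lapply(out, attr, "members")
  mt_intervals <- lapply(out, attr, "mt_intervals")
  res <- do.call(rbind, out)
  o <- order(res$chrom, res$start)
  res <- res[o, , drop = FALSE]
  members <- members[o]
  mt_intervals <- mt_intervals[o]
  rownames(res) <- NULL
  counts <- stats::ave(seq_len(nrow(res)), res$chrom, FUN = seq_along)
  res$id <- sprintf("NumtS_%s_%d", res$chrom, counts)
  res$members <- members
  res$mt_intervals <- mt_intervals
  res <- res[, c("id", "chrom", "start", "end", "strand", "n_members",
                 "mean_identity", "members", "mt_intervals")]
  attr(res, "hsps") <- hsps
  res
}
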