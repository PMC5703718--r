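# End-to-end pipeline driver and sequence extraction helpers.

#' Extract the genomic sequence of each NumtS
#'
#' @param numts assembled NumtS table.
#' @param nuclear named character vector of chromosome sequences.
#' @param orient_to_mt reverse-complement minus-strand NumtS so all
#'   sequences read in mt plus-strand orientation.
#' @return named character vector keyed by NumtS id.
#' @export
numts_sequences <- function(numts, nuclear, orient_to_mt = TRUE) {
  out <- vapply(seq_len(nrow(numts)), function(i) {
    s <- substr(nuclear[[numts$chrom[i]]], numts$start[i] + 1L, numts$end[i])
    if (orient_to_mt && numts$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
  names(out) <- numts$id
  out
}

#' Extract the mitochondrial counterpart sequence of each NumtS
#'
#' Concatenates the merged mt intervals of each NumtS (in mt coordinate
#' order) from the mitochondrial genome.
#'
#' @param numts assembled NumtS table.
#' @param mt mitochondrial genome sequence.
#' @return named character vector keyed by NumtS id.
#' @export
mt_counterpart_sequences <- function(numts, mt) {
  out <- vapply(seq_len(nrow(numts)), function(i) {
    iv <- numts$mt_intervals[[i]]
    paste(vapply(seq_len(nrow(iv)), function(k)
      substr(mt, iv[k, "start"] + 1L, iv[k, "end"]), character(1)),
      collapse = "")
  }, character(1))
  names(out) <- numts$id
  out
}

#' Repeat-subtracted flank sequences for dating
#'
#' Extracts both flanks of each NumtS, removes repeat-annotated bases
#' ([interval_subtract()]) and concatenates the remaining segments.
#'
#' @param numts assembled NumtS table.
#' @param nuclear named character vector of chromosome sequences.
#' @param repeats BED-style repeats (may be empty).
#' @param spec a [flank_spec()]; dating uses 1-kb flanks.
#' @return named list of character vectors (one per NumtS).
#' @export
flank_sequences <- function(numts, nuclear, repeats = NULL,
                            spec = flank_spec(1000L)) {
  chrom_lengths <- vapply(nuclear, nchar, integer(1))
  fl <- flanks(numts, chrom_lengths, spec)
  get_seq <- function(bed_row) {
    seg <- data.frame(chrom = bed_row$chrom, start = bed_row$start,
                      end = bed_row$end, stringsAsFactors = FALSE)
    if (!is.null(repeats) && nrow(repeats)) seg <- interval_subtract(seg, repeats)
    if (nrow(seg) == 0L) return("")
    paste(vapply(seq_len(nrow(seg)), function(k)
      substr(nuclear[[seg$chrom[k]]], seg$start[k] + 1L, seg$end[k]),
      character(1)), collapse = "")
  }
  out <- lapply(seq_len(nrow(numts)), function(i)
    c(five = get_seq(fl$five_prime[i, ]), three = get_seq(fl$three_prime[i, ])))
  names(out) <- numts$id
  out
}

#' Run the full NumtS pipeline on a (synthetic or supplied) genome
#'
#' Stages, in dependency order: simulate (or accept sequences), detect
#' HSPs, purge (occupancy then chromosome-name filters), assemble,
#' coverage + hotspots, repeat statistics, tracks, and optionally
#' profile-HMM dating of the repeat-free subset.  Per-stage record counts
#' are logged via `message()`.
#'
#' @param sim a [simulate_genome()] result, or `NULL` to simulate from
#'   `config`.
#' @param config [simulation_config()] used when `sim` is `NULL`.
#' @param detection [detection_params()].
#' @param purge [purge_config()].
#' @param assembly [assemble_config()].
#' @param outdir optional directory for track and report files.
#' @param run_dating also run the dating stage (slower).
#' @return list with `sim`, `hsps_raw`, `hsps`, `purge_report`,
#'   `chrom_report`, `numts`, `coverage`, `hotspots`, `summary`,
#'   `re_counts`, `dating` (or `NULL`), `paths`.
#' @export
run_pipeline <- function(sim = NULL, config = simulation_config(),
                         detection = detection_params(),
                         purge = purge_config(),
                         assembly = assemble_config(),
                         outdir = NULL, run_dating = FALSE) {
  if (is.null(sim)) {
    message("simulate: seed ", config$seed)
    sim <- simulate_genome(config)
  }
  chrom_lengths <- vapply(sim$nuclear, nchar, integer(1))
  message("detect: ", length(sim$nuclear), " subject sequences, mt length ",
          nchar(sim$mt))
  hsps_raw <- find_hsps(sim$nuclear, sim$mt, detection)
  message("detect: ", nrow(hsps_raw), " HSPs")
  occ <- occupancy_filter(hsps_raw, chrom_lengths, purge)
  message("purge/occupancy: removed ", sum(occ$report$removed), " contigs, ",
          nrow(hsps_raw) - nrow(occ$hsps), " HSPs")
  chf <- chrom_filter(occ$hsps, purge)
  message("purge/chrom: dropped ", nrow(occ$hsps) - nrow(chf$hsps), " HSPs")
  numts <- assemble_numts(chf$hsps, repeats = sim$repeats, config = assembly)
  message("assemble: ", nrow(numts), " NumtS from ", nrow(chf$hsps), " HSPs")
  covprof <- mt_coverage(chf$hsps, nchar(sim$mt), label = "intraspecies")
  hot <- call_hotspots(covprof, locus_map = sim$locus_map)
  message("coverage: max per-base occurrence ", max(covprof$counts),
          "; ", nrow(hot), " hotspot(s)")
  summ <- genome_summary(numts, sum(chrom_lengths))
  re_counts <- count_re(numts, sim$repeats, chrom_lengths)
  dating <- NULL
  if (run_dating) {
    subset <- re_free_subset(numts, sim$repeats, chrom_lengths)
    message("dating: ", nrow(subset), " repeat-free NumtS")
    if (nrow(subset) > 0) {
      dating <- date_numts(
        numts_sequences(subset, sim$nuclear),
        mt_counterpart_sequences(subset, sim$mt),
        flank_sequences(subset, sim$nuclear, sim$repeats))
    }
  }
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_tracks(numts, chf$hsps, nchar(sim$mt), outdir)
    write.table(occ$report, file.path(outdir, "purge_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_profile_tsv(covprof, file.path(outdir, "coverage.tsv"))
    write_bed(data.frame(chrom = "chrM", start = pmin(hot$mt_start, hot$mt_end),
                         end = pmax(hot$mt_start, hot$mt_end),
                         name = paste0("hotspot_", seq_len(nrow(hot)))),
              file.path(outdir, "hotspots.bed"))
    paths <- c(paths, purge_report = file.path(outdir, "purge_report.tsv"),
               coverage = file.path(outdir, "coverage.tsv"),
               hotspots = file.path(outdir, "hotspots.bed"))
  }
  list(sim = sim, hsps_raw = hsps_raw, hsps = chf$hsps,
       purge_report = occ$report, chrom_report = chf$report, numts = numts,
       coverage = covprof, hotspots = hot, summary = summ,
       re_counts = re_counts, dating = dating, paths = paths)
}

#' View simulator truth records as a NumtS-like table
#'
#' Converts ground-truth records into the shape of an assembled NumtS
#' table (`id`, `chrom`, `start`, `end`, `strand`, `mt_intervals`) so
#' sequence extraction and dating can run directly on planted fragments.
#' Origin-spanning mt intervals are split at position 0.
#'
#' @param truth truth data frame from [plant_numts()].
#' @param mt_length mitochondrial genome length.
#' @return NumtS-style data frame.
#' @export
truth_as_numts <- function(truth, mt_length) {
  L <- as.integer(mt_length)
  out <- truth[, c("chrom", "start", "end", "strand")]
  out$id <- sprintf("truth_%d", seq_len(nrow(truth)))
  out$mt_intervals <- lapply(seq_len(nrow(truth)), function(i) {
    s <- truth$mt_start[i]; e <- truth$mt_end[i]
    if (s < e) cbind(start = s, end = e)
    else rbind(cbind(start = s, end = L), cbind(start = 0L, end = e))
  })
  if (!is.null(truth$age)) out$age <- truth$age
  out[, c("id", setdiff(names(out), "id"))]
}

#' Match assembled NumtS to ground-truth records
#'
#' Greedy 1:1 matching of truth records to assembled NumtS on the same
#' chromosome by reciprocal overlap; reports boundary errors.
#'
#' @param numts assembled NumtS table.
#' @param truth truth records from the simulator.
#' @return data frame with one row per truth record: `matched` plus
#'   `start_error`/`end_error` (bp; `NA` when unmatched) and the matched
#'   NumtS id.
#' @export
match_truth <- function(numts, truth) {
  used <- rep(FALSE, nrow(numts))
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    cand <- which(!used & numts$chrom == truth$chrom[i] &
                    numts$start < truth$end[i] & numts$end > truth$start[i])
    if (length(cand) == 0L) {
      return(data.frame(matched = FALSE, numts_id = NA_character_,
                        start_error = NA_real_, end_error = NA_real_))
    }
    ov <- pmin(numts$end[cand], truth$end[i]) -
      pmax(numts$start[cand], truth$start[i])
    j <- cand[which.max(ov)]
    used[j] <<- TRUE
    data.frame(matched = TRUE, numts_id = numts$id[j],
               start_error = abs(numts$start[j] - truth$start[i]),
               end_error = abs(numts$end[j] - truth$end[i]))
  })
  cbind(truth, do.call(rbind, rows))
}
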