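# Synthetic genome generator: nuclear + mitochondrial genome pairs with
# planted, age-stratified NumtS, repeat annotations, contamination contigs
# and machine-readable ground truth.

#' Simulation configuration
#'
#' Builds the configuration object for [simulate_genome()].  Planted
#' fragments decay under a Kimura two-parameter (K2P) substitution process:
#' `age` is the expected substitution load in substitutions/site, and
#' `kappa` the transition/transversion rate ratio.  Indels are single-base
#' events accumulating at `indel_rate` events per site per unit of
#' substitution load, so an age-0 fragment is an exact (strand-aware) copy
#' of its mitochondrial source.
#'
#' @param seed integer RNG seed; identical configurations generate
#'   byte-identical output.
#' @param mt_length mitochondrial genome length (bp), at least 1000.
#' @param n_chromosomes number of background nuclear chromosomes.
#' @param chromosome_lengths lengths (bp) of the chromosomes; recycled to
#'   `n_chromosomes`.
#' @param n_insertions number of NumtS to plant.
#' @param age_grid ages (substitutions/site) sampled uniformly per insertion.
#' @param kappa transition/transversion rate ratio of the decay process.
#' @param indel_rate single-base indel events per site per unit substitution
#'   load (default 0.1, i.e. one indel per ten substitutions).
#' @param re_density expected repeat elements per 2-kb flank.
#' @param n_pure_mt_contigs contigs that are verbatim mtDNA fragments
#'   (occupancy 1), emulating mitochondrial contamination reads assembled
#'   into their own contigs.
#' @param n_partial_mt_contigs contigs with partial mtDNA content.
#' @param partial_occupancy fraction(s) in (0, 1] of each partial contig
#'   occupied by mtDNA; recycled to `n_partial_mt_contigs`.
#' @param frag_len_range min/max planted fragment length (bp).
#' @param hotspot_fraction fraction of insertions whose mitochondrial origin
#'   is drawn from the control-region locus (which abuts the circular
#'   origin), creating a coverage hotspot.
#' @param n_loci number of named mitochondrial loci tiling the mt genome.
#' @param min_separation minimum background distance (bp) between planted
#'   insertion points on the same chromosome; keeps independently planted
#'   NumtS from merging during assembly.
#' @param n_close_pairs number of additional planted fragment pairs 3 kb
#'   apart, each later bridged by a single repeat element to exercise the
#'   repeat-bridging merge rule (default 0).
#' @param gc background GC content of the nuclear chromosomes.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              mt_length = 16000L,
                              n_chromosomes = 5L,
                              chromosome_lengths = 400000L,
                              n_insertions = 50L,
                              age_grid = c(0, 0.05, 0.10, 0.15),
                              kappa = 4,
                              indel_rate = 0.1,
                              re_density = 1,
                              n_pure_mt_contigs = 3L,
                              n_partial_mt_contigs = 4L,
                              partial_occupancy = c(0.85, 0.85, 0.5, 0.5),
                              frag_len_range = c(300L, 5000L),
                              hotspot_fraction = 0.4,
                              n_loci = 15L,
                              min_separation = 8000L,
                              n_close_pairs = 0L,
                              gc = 0.5) {
  cfg <- list(seed = as.integer(seed), mt_length = as.integer(mt_length),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_lengths = rep_len(as.integer(chromosome_lengths),
                                           as.integer(n_chromosomes)),
              n_insertions = as.integer(n_insertions),
              age_grid = as.numeric(age_grid), kappa = kappa,
              indel_rate = indel_rate, re_density = re_density,
              n_pure_mt_contigs = as.integer(n_pure_mt_contigs),
              n_partial_mt_contigs = as.integer(n_partial_mt_contigs),
              partial_occupancy = rep_len(as.numeric(partial_occupancy),
                                          max(1L, as.integer(n_partial_mt_contigs))),
              frag_len_range = as.integer(frag_len_range),
              hotspot_fraction = hotspot_fraction,
              n_loci = as.integer(n_loci),
              min_separation = as.integer(min_separation),
              n_close_pairs = as.integer(n_close_pairs),
              gc = gc)
  if (cfg$mt_length < 1000L) stop("mt_length must be at least 1000 bp")
  if (any(cfg$chromosome_lengths <= 0L)) stop("chromosome lengths must be positive")
  if (any(cfg$age_grid < 0)) stop("age_grid values must be non-negative")
  if (any(cfg$partial_occupancy <= 0 | cfg$partial_occupancy > 1))
    stop("partial_occupancy must lie in (0, 1]")
  if (cfg$hotspot_fraction < 0 || cfg$hotspot_fraction > 1)
    stop("hotspot_fraction must lie in [0, 1]")
  class(cfg) <- "simulation_config"
  cfg
}

# Canonical mt locus names; the control region ("CR") is placed last so it
# abuts the circular origin, as the vertebrate D-loop does.
.mt_locus_names <- c("12S", "16S", "ND1", "ND2", "COX1", "COX2", "ATP8",
                     "ATP6", "COX3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                     "CYTB", "CR")

#' Generate a mitochondrial genome with a named locus map
#'
#' @param config a [simulation_config()].
#' @return list with `seq` (character scalar) and `locus_map`, a BED-style
#'   data frame of named locus intervals tiling `[0, mt_length)` without
#'   overlap.  The control-region locus is last, ending at the origin.
#' @export
generate_mt <- function(config) {
  n_loci <- config$n_loci
  if (n_loci > length(.mt_locus_names))
    stop("at most ", length(.mt_locus_names), " loci are supported")
  if (config$mt_length < 50L * n_loci)
    stop("mt_length too small to host ", n_loci, " loci")
  with_seed(config$seed + 1000L, {
    seq <- random_dna(config$mt_length)
    # proportional tiling; CR gets a short allocation like a real D-loop
    nm <- c(.mt_locus_names[seq_len(n_loci - 1L)], "CR")
    wts <- rep(1, n_loci)
    wts[nm == "CR"] <- 0.6
    bounds <- round(cumsum(wts) / sum(wts) * config$mt_length)
    start <- c(0L, as.integer(bounds[-n_loci]))
    end <- as.integer(bounds)
    list(seq = seq,
         locus_map = data.frame(chrom = "chrM", start = start, end = end,
                                name = nm, stringsAsFactors = FALSE))
  })
}

# Extract a (possibly origin-spanning) fragment from the circular mt genome.
extract_mt_fragment <- function(mt, mt_start, len) {
  L <- nchar(mt)
  stopifnot(len <= L)
  doubled <- paste0(mt, mt)
  substr(doubled, mt_start + 1L, mt_start + len)
}

# K2P per-site mutation probabilities at substitution load d with ts/tv rate
# ratio kappa: rates alpha (transition) and beta (each transversion), with
# d = (alpha + 2 beta) t and kappa = alpha/beta.
k2p_site_probs <- function(d, kappa) {
  if (d == 0) return(c(ts = 0, tv = 0))
  b <- d / (kappa + 2)
  a <- kappa * b
  p_ts <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
  p_tv <- 0.5 - 0.5 * exp(-4 * b) # both transversion targets combined
  c(ts = p_ts, tv = p_tv)
}

.transition_of <- c(A = "G", C = "T", G = "A", T = "C")
.transversions_of <- list(A = c("C", "T"), C = c("A", "G"),
                          G = c("C", "T"), T = c("A", "G"))

# Mutate a sequence under K2P at the given substitution load, then apply
# single-base indels (expected count = n_sites * indel_rate * age).
mutate_fragment <- function(seq, age, kappa, indel_rate) {
  if (age == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  pr <- k2p_site_probs(age, kappa)
  u <- runif(n)
  ts_idx <- which(u < pr["ts"])
  tv_idx <- which(u >= pr["ts"] & u < pr["ts"] + pr["tv"])
  if (length(ts_idx)) bases[ts_idx] <- .transition_of[bases[ts_idx]]
  if (length(tv_idx)) {
    pick <- runif(length(tv_idx)) < 0.5
    bases[tv_idx] <- mapply(function(b, p) .transversions_of[[b]][p + 1L],
                            bases[tv_idx], as.integer(pick))
  }
  n_ind <- rpois(1L, n * indel_rate * age)
  if (n_ind > 0) {
    for (k in seq_len(n_ind)) {
      pos <- sample.int(length(bases), 1L)
      if (runif(1) < 0.5 && length(bases) > 1L) {
        bases <- bases[-pos] # deletion
      } else {
        bases <- append(bases, sample(c("A", "C", "G", "T"), 1L), after = pos)
      }
    }
  }
  paste(bases, collapse = "")
}

#' Plant NumtS into nuclear background chromosomes
#'
#' Draws fragments from the circular mitochondrial genome (the configured
#' hotspot fraction starts within the control-region locus), decays each
#' under K2P substitutions plus single-base indels according to its age,
#' reverse-complements minus-strand insertions, and splices them into the
#' background.
#'
#' @param nuclear named character vector of background chromosome sequences.
#' @param mt the result of [generate_mt()] (list with `seq` and `locus_map`).
#' @param config a [simulation_config()].
#' @return list with `nuclear` (sequences with insertions) and `truth`, a
#'   data frame of ground-truth records in genomic coordinate order:
#'   `chrom`, `start`, `end` (0-based half-open, final coordinates),
#'   `strand`, `mt_start`, `mt_end` (plus-strand mt coordinates;
#'   `mt_start > mt_end` flags an origin-spanning fragment), `age`.
#' @export
plant_numts <- function(nuclear, mt, config) {
  with_seed(config$seed + 2000L, {
    L <- config$mt_length
    lm <- mt$locus_map
    cr <- lm[lm$name == "CR", , drop = FALSE]
    n_total <- config$n_insertions + 2L * config$n_close_pairs
    chrom_names <- names(nuclear)
    chrom_len <- vapply(nuclear, nchar, integer(1))

    # insertion points in original background coordinates, with separation
    pts <- vector("list", length(chrom_names))
    names(pts) <- chrom_names
    draw_point <- function() {
      for (try in 1:2000) {
        ci <- sample(seq_along(chrom_names), 1L, prob = chrom_len)
        p <- sample.int(chrom_len[ci] - 1L, 1L)
        if (all(abs(pts[[ci]] - p) >= config$min_separation) || length(pts[[ci]]) == 0L) {
          pts[[ci]] <<- c(pts[[ci]], p)
          return(c(ci, p))
        }
      }
      stop("requested insertions exceed available background space")
    }

    recs <- vector("list", n_total)
    n_hot <- round(config$hotspot_fraction * config$n_insertions)
    # hotspot insertions all contain a ~100-bp focal "seeding unit" in the
    # middle of the control region, so per-base occurrence peaks inside it
    focal_w <- 100L
    focal_start <- cr$start + (cr$end - cr$start - focal_w) %/% 2L
    focal_end <- focal_start + focal_w
    for (k in seq_len(config$n_insertions)) {
      len <- resample1(config$frag_len_range[1]:config$frag_len_range[2])
      if (k <= n_hot && nrow(cr) == 1L) {
        mt_start <- resample1((focal_end - len):focal_start) %% L
      } else {
        mt_start <- sample.int(L, 1L) - 1L
      }
      cp <- draw_point()
      recs[[k]] <- list(ci = cp[1], point = cp[2], mt_start = mt_start, len = len,
                        strand = sample(c("+", "-"), 1L),
                        age = resample1(config$age_grid))
    }
    if (config$n_close_pairs > 0L) {
      # pairs 3 kb apart on the same chromosome and strand (age 0, plus)
      for (k in seq_len(config$n_close_pairs)) {
        cp <- draw_point()
        ci <- cp[1]; p <- cp[2]
        p2 <- p + 3000L
        if (p2 >= chrom_len[ci]) p2 <- p - 3000L
        pts[[ci]] <- c(pts[[ci]], p2)
        for (pp in sort(c(cp[2], p2))) {
          i <- config$n_insertions + 2L * (k - 1L) + match(pp, sort(c(cp[2], p2)))
          len <- resample1(500:1500)
          recs[[i]] <- list(ci = ci, point = pp,
                            mt_start = sample.int(L, 1L) - 1L, len = len,
                            strand = "+", age = 0)
        }
      }
    }

    # materialise fragments
    frags <- lapply(recs, function(r) {
      f <- extract_mt_fragment(mt$seq, r$mt_start, r$len)
      f <- mutate_fragment(f, r$age, config$kappa, config$indel_rate)
      if (r$strand == "-") f <- revcomp(f)
      f
    })

    # splice per chromosome, accumulating final coordinates
    truth <- list()
    out <- nuclear
    for (ci in seq_along(chrom_names)) {
      idx <- which(vapply(recs, function(r) r$ci, numeric(1)) == ci)
      if (length(idx) == 0L) next
      idx <- idx[order(vapply(recs[idx], function(r) r$point, numeric(1)))]
      segs <- character(0)
      prev <- 0L
      offset <- 0L
      bg <- nuclear[[ci]]
      for (i in idx) {
        r <- recs[[i]]
        f <- frags[[i]]
        segs <- c(segs, substr(bg, prev + 1L, r$point))
        g_start <- r$point + offset
        g_end <- g_start + nchar(f)
        segs <- c(segs, f)
        offset <- offset + nchar(f)
        prev <- r$point
        e <- r$mt_start + r$len
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = g_start, end = g_end,
          strand = r$strand, mt_start = r$mt_start,
          mt_end = if (e <= L) e else e - L,
          age = r$age, stringsAsFactors = FALSE)
      }
      segs <- c(segs, substr(bg, prev + 1L, nchar(bg)))
      out[[ci]] <- paste(segs, collapse = "")
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(nuclear = out, truth = truth)
  })
}

#' Plant mitochondrial contamination contigs
#'
#' Emulates assembly artefacts: contigs entirely composed of mtDNA and
#' contigs with a known fraction of mtDNA content.
#'
#' @param mt result of [generate_mt()].
#' @param config a [simulation_config()].
#' @return list with `contigs` (named character vector) and `labels`, a data
#'   frame recording each contig's true mtDNA occupancy.
#' @export
plant_contamination <- function(mt, config) {
  with_seed(config$seed + 3000L, {
    L <- config$mt_length
    contigs <- character(0)
    labels <- list()
    for (k in seq_len(config$n_pure_mt_contigs)) {
      len <- resample1(5000:min(15000, L - 1L))
      start <- sample.int(L, 1L) - 1L
      contigs[[paste0("scaffold_pure_", k)]] <- extract_mt_fragment(mt$seq, start, len)
      labels[[length(labels) + 1L]] <- data.frame(
        contig = paste0("scaffold_pure_", k), occupancy = 1.0,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$n_partial_mt_contigs)) {
      p <- config$partial_occupancy[k]
      clen <- 20000L
      mlen <- as.integer(round(p * clen))
      start <- sample.int(L, 1L) - 1L
      frag <- extract_mt_fragment(mt$seq, start, min(mlen, L))
      # if the requested mt content exceeds one full mt copy, tile fragments
      while (nchar(frag) < mlen) {
        start2 <- sample.int(L, 1L) - 1L
        frag <- paste0(frag, extract_mt_fragment(mt$seq, start2,
                                                 min(mlen - nchar(frag), L)))
      }
      bg_len <- clen - mlen
      off <- if (bg_len > 0) sample.int(bg_len + 1L, 1L) - 1L else 0L
      seqc <- paste0(random_dna(off), frag, random_dna(bg_len - off))
      contigs[[paste0("scaffold_part_", k)]] <- seqc
      labels[[length(labels) + 1L]] <- data.frame(
        contig = paste0("scaffold_part_", k), occupancy = p,
        stringsAsFactors = FALSE)
    }
    list(contigs = contigs,
         labels = if (length(labels)) do.call(rbind, labels) else
           data.frame(contig = character(), occupancy = numeric()))
  })
}

#' Plant repeat-element annotations in NumtS flanks
#'
#' Places repeat intervals inside the 2-kb flanks of truth records at the
#' configured density.  When the configuration requests close pairs, each
#' pair's 3-kb gap is bridged by exactly one spanning repeat so the
#' repeat-bridging assembly rule is exercised.
#'
#' @param chrom_lengths named lengths of the (post-insertion) chromosomes.
#' @param truth truth records from [plant_numts()].
#' @param config a [simulation_config()].
#' @return BED-style data frame `chrom`, `start`, `end`, `name` of repeats,
#'   clipped to chromosome bounds.
#' @export
plant_repeats <- function(chrom_lengths, truth, config) {
  with_seed(config$seed + 4000L, {
    classes <- c("SINE_Alu", "LINE_L1", "LTR_ERVL", "Simple_repeat")
    out <- list()
    flank <- 2000L
    if (config$re_density > 0 && nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        cl <- chrom_lengths[[truth$chrom[i]]]
        for (side in c("up", "down")) {
          fs <- if (side == "up") max(0L, truth$start[i] - flank) else truth$end[i]
          fe <- if (side == "up") truth$start[i] else min(cl, truth$end[i] + flank)
          if (fe - fs < 120L) next
          n <- rpois(1L, config$re_density)
          for (j in seq_len(n)) {
            len <- resample1(100:800)
            len <- min(len, fe - fs)
            st <- fs + sample.int(fe - fs - len + 1L, 1L) - 1L
            out[[length(out) + 1L]] <- data.frame(
              chrom = truth$chrom[i], start = st, end = st + len,
              name = sample(classes, 1L), stringsAsFactors = FALSE)
          }
        }
      }
    }
    # bridge each close pair's gap with exactly one spanning repeat
    if (config$n_close_pairs > 0L && nrow(truth) > 1L) {
      tr <- truth[order(truth$chrom, truth$start), ]
      for (i in seq_len(nrow(tr) - 1L)) {
        gap <- tr$start[i + 1L] - tr$end[i]
        same <- tr$chrom[i + 1L] == tr$chrom[i]
        if (same && gap > 2000L && gap <= 3000L) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = tr$chrom[i], start = tr$end[i], end = tr$start[i + 1L],
            name = "LINE_L1_bridge", stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out) == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        stringsAsFactors = FALSE))
    }
    rep_df <- do.call(rbind, out)
    rep_df$start <- pmax(0L, rep_df$start)
    for (i in seq_len(nrow(rep_df)))
      rep_df$end[i] <- min(rep_df$end[i], chrom_lengths[[rep_df$chrom[i]]])
    rep_df <- rep_df[rep_df$end > rep_df$start, , drop = FALSE]
    rep_df <- rep_df[order(rep_df$chrom, rep_df$start), , drop = FALSE]
    rownames(rep_df) <- NULL
    rep_df$name <- paste0(rep_df$name, "_", seq_len(nrow(rep_df)))
    rep_df
  })
}

#' Simulate a complete synthetic genome pair
#'
#' Orchestrates [generate_mt()], background chromosome generation,
#' [plant_numts()], [plant_contamination()] and [plant_repeats()].  All
#' randomness derives from `config$seed`; the same configuration always
#' produces byte-identical sequences and annotations.
#'
#' @param config a [simulation_config()].
#' @return list with elements `nuclear` (named chromosome + contig
#'   sequences), `mt` (mt sequence), `locus_map`, `truth`, `repeats`,
#'   `contig_labels` and `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  mt <- generate_mt(config)
  background <- with_seed(config$seed + 5000L, {
    gcp <- config$gc / 2
    atp <- (1 - config$gc) / 2
    setNames(
      vapply(config$chromosome_lengths, function(n)
        random_dna(n, prob = c(atp, gcp, gcp, atp)), character(1)),
      paste0("chr", seq_len(config$n_chromosomes)))
  })
  planted <- plant_numts(background, mt, config)
  contam <- plant_contamination(mt, config)
  nuclear <- c(planted$nuclear, contam$contigs)
  chrom_lengths <- vapply(nuclear, nchar, integer(1))
  repeats <- plant_repeats(as.list(chrom_lengths), planted$truth, config)
  list(nuclear = nuclear, mt = mt$seq, locus_map = mt$locus_map,
       truth = planted$truth, repeats = repeats,
       contig_labels = contam$labels, config = config)
}

#' Write a simulation to disk
#'
#' Writes nuclear and mt FASTA, truth/repeats/locus-map BED, and contig
#' labels TSV into `dir`.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return named vector of paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(nuclear = file.path(dir, "nuclear.fa"),
             mt = file.path(dir, "chrM.fa"),
             truth = file.path(dir, "truth.bed"),
             repeats = file.path(dir, "repeats.bed"),
             locus_map = file.path(dir, "mt_loci.bed"),
             contig_labels = file.path(dir, "contig_labels.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$nuclear), paths["nuclear"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(chrM = sim$mt)), paths["mt"])
  tb <- sim$truth
  tb$name <- sprintf("truth_%d|mt:%d-%d|age:%g", seq_len(nrow(tb)),
                     tb$mt_start, tb$mt_end, tb$age)
  tb$score <- 0L
  write_bed(tb[, c("chrom", "start", "end", "name", "score", "strand")],
            paths["truth"])
  write_bed(sim$repeats, paths["repeats"])
  write_bed(sim$locus_map, paths["locus_map"])
  write.table(sim$contig_labels, paths["contig_labels"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
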