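# NumtS phylogeny: K2P distances, neighbor joining, species cluster
# patterns, and strict-clock node calibration.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing a gap or `N` in either sequence are removed
#' (pairwise deletion).  With `P` the transition and `Q` the transversion
#' proportion over the retained columns, the distance is
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions/site.
#'
#' @param seq_a,seq_b aligned sequences of equal length.
#' @return list of class `k2p_distance` with `P`, `Q`, `d`, `n_sites`.
#'   Saturated pairs (non-positive logarithm argument) raise an error of
#'   class `numtsome_saturation`.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  valid <- c("A", "C", "G", "T")
  keep <- a %in% valid & b %in% valid
  n <- sum(keep)
  if (n == 0L) stop("no comparable columns after pairwise deletion")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop(structure(class = c("numtsome_saturation", "error", "condition"),
                   list(message = sprintf(
                     "K2P distance undefined (saturation): P=%.3f Q=%.3f", P, Q),
                     call = sys.call(-1))))
  }
  d <- -0.5 * log(arg1 * sqrt(arg2))
  structure(list(P = P, Q = Q, d = d, n_sites = n), class = "k2p_distance")
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param aln named character vector of aligned sequences (or
#'   `DNAStringSet`).
#' @return symmetric matrix of K2P distances.
#' @export
k2p_matrix <- function(aln) {
  if (methods::is(aln, "DNAStringSet")) {
    nm <- names(aln); aln <- as.character(aln); names(aln) <- nm
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- k2p(aln[[i]], aln[[j]])$d
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion, with ties broken toward
#' the lexicographically smallest pair of labels; negative branch lengths
#' are clamped to zero with a warning.  Returns an unrooted `ape::phylo`
#' tree.
#'
#' @param d symmetric numeric matrix with zero diagonal and `n >= 3` rows,
#'   labelled dimnames.
#' @return an unrooted tree of class `phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) stop("distance matrix has NA/NaN entries")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  labels <- rownames(d)
  # newick fragment per active node
  node_str <- labels
  # sort-key label per active node for deterministic tie-breaks
  node_key <- labels
  active <- seq_len(n)
  D <- d
  clamped <- FALSE
  fmt <- function(x) sprintf("%.10g", x)
  while (length(active) > 3L) {
    r <- length(active)
    Ri <- rowSums(D[active, active, drop = FALSE])
    names(Ri) <- as.character(active)
    best <- NULL; bestq <- Inf; bestkey <- NULL
    for (ii in seq_len(r - 1)) {
      for (jj in (ii + 1):r) {
        i <- active[ii]; j <- active[jj]
        q <- (r - 2) * D[i, j] - Ri[as.character(i)] - Ri[as.character(j)]
        key <- paste(sort(c(node_key[i], node_key[j])), collapse = "\r")
        if (q < bestq - 1e-12 ||
            (abs(q - bestq) <= 1e-12 && !is.null(bestkey) && key < bestkey)) {
          bestq <- q; best <- c(i, j); bestkey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (Ri[as.character(i)] - Ri[as.character(j)]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0 || vj < 0) clamped <- TRUE
    vi <- max(0, vi); vj <- max(0, vj)
    new <- length(node_str) + 1L
    node_str[new] <- paste0("(", node_str[i], ":", fmt(vi), ",",
                            node_str[j], ":", fmt(vj), ")")
    node_key[new] <- min(node_key[i], node_key[j])
    D <- rbind(D, 0); D <- cbind(D, 0)
    for (k in setdiff(active, c(i, j)))
      D[new, k] <- D[k, new] <- (D[i, k] + D[j, k] - D[i, j]) / 2
    active <- c(setdiff(active, c(i, j)), new)
  }
  # final three nodes: closed-form three-point branch lengths
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  if (any(c(va, vb, vc) < 0)) clamped <- TRUE
  va <- max(0, va); vb <- max(0, vb); vc <- max(0, vc)
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  nwk <- paste0("(", node_str[a], ":", fmt(va), ",", node_str[b], ":",
                fmt(vb), ",", node_str[c3], ":", fmt(vc), ");")
  ape::read.tree(text = nwk)
}

# tip labels below each internal edge of an unrooted tree (one side of each
# nontrivial bipartition)
tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  lapply(parts, function(p) tree$tip.label[p])
}

#' Species clustering pattern on a NumtS tree
#'
#' A species is monophyletic on the unrooted tree iff some edge
#' bipartition separates exactly its leaves from all others; otherwise its
#' NumtS are intermingled with other species.  Species with a single leaf
#' are not assessable.
#'
#' @param tree a `phylo` tree.
#' @param species named character vector mapping leaf label to species.
#' @return data frame `species`, `n_leaves`, `pattern` (one of
#'   `"monophyletic"`, `"intermingled"`, `"not assessable"`).
#' @export
species_pattern <- function(tree, species) {
  stopifnot(all(tree$tip.label %in% names(species)))
  tips <- tree$tip.label
  parts <- tree_bipartitions(ape::unroot(tree))
  parts <- c(parts, as.list(tips)) # tip edges split {leaf} vs the rest
  sides <- c(parts, lapply(parts, function(p) setdiff(tips, p)))
  keys <- vapply(sides, function(p) paste(sort(p), collapse = "\r"), character(1))
  sp <- species[tips]
  out <- lapply(unique(sp), function(s) {
    leaves <- tips[sp == s]
    pattern <- if (length(leaves) < 2L) {
      "not assessable"
    } else if (length(leaves) == length(tips)) {
      "monophyletic"
    } else if (paste(sort(leaves), collapse = "\r") %in% keys) {
      "monophyletic"
    } else "intermingled"
    data.frame(species = s, n_leaves = length(leaves), pattern = pattern,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strict-clock calibration of a tree to absolute time
#'
#' Roots the tree (midpoint by default), measures each internal node's
#' height above the tips as the maximum root-to-tip path below it, and
#' rescales so that the calibration node (identified by a set of leaves:
#' their most recent common ancestor) sits at the midpoint of the supplied
#' age window.  Per-node age intervals follow from the window endpoints.
#'
#' @param tree a `phylo` tree with branch lengths in substitutions/site.
#' @param calibration_leaves character vector of leaf labels whose MRCA is
#'   the calibration node.
#' @param age_window two ages in Mya, e.g. `c(95, 105)`; the node is fixed
#'   at the midpoint.
#' @param root_with optional outgroup leaf label(s) for rooting instead of
#'   midpoint rooting.
#' @return list of class `timetree`: `tree` (rooted), `ages` data frame
#'   (`node`, `height`, `age`, `age_lo`, `age_hi` in Mya),
#'   `rate` (substitutions/site/Myr), `calibration_node`.
#' @export
calibrate <- function(tree, calibration_leaves, age_window = c(95, 105),
                      root_with = NULL) {
  stopifnot(length(age_window) == 2L)
  age_window <- sort(as.numeric(age_window))
  rooted <- if (!is.null(root_with)) {
    ape::root(tree, outgroup = root_with, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
  if (!all(calibration_leaves %in% rooted$tip.label))
    stop("calibration node not found: leaves missing from tree")
  nt <- length(rooted$tip.label)
  cal_node <- if (length(calibration_leaves) == 1L) {
    match(calibration_leaves, rooted$tip.label)
  } else {
    ape::getMRCA(rooted, calibration_leaves)
  }
  depths <- ape::node.depth.edgelength(rooted) # root-to-node path lengths
  max_tip_depth_below <- numeric(nt + rooted$Nnode)
  max_tip_depth_below[seq_len(nt)] <- depths[seq_len(nt)]
  for (e in ape::postorder(rooted)) { # children aggregated before parents
    p <- rooted$edge[e, 1]; ch <- rooted$edge[e, 2]
    max_tip_depth_below[p] <- max(max_tip_depth_below[p],
                                  max_tip_depth_below[ch])
  }
  height <- max_tip_depth_below - depths # node height above deepest tip below
  h_cal <- height[cal_node]
  if (h_cal <= 0) stop("calibration node has zero height; cannot scale")
  mid <- mean(age_window)
  rate <- h_cal / mid
  nodes <- seq_len(nt + rooted$Nnode)
  ages <- data.frame(node = nodes, height = height,
                     age = height / rate,
                     age_lo = height * age_window[1] / h_cal,
                     age_hi = height * age_window[2] / h_cal)
  structure(list(tree = rooted, ages = ages, rate = rate,
                 calibration_node = cal_node),
            class = "timetree")
}

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf("timetree: %d tips, clock rate %.4g subst/site/Myr\n",
              length(x$tree$tip.label), x$rate))
  invisible(x)
}

#' Write a calibrated tree as Newick with node ages as comments
#'
#' Internal node labels carry `[&age=...]` style annotations.
#'
#' @param tt a [calibrate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timetree <- function(tt, path) {
  tr <- tt$tree
  nt <- length(tr$tip.label)
  ages <- tt$ages$age[(nt + 1):(nt + tr$Nnode)]
  tr$node.label <- sprintf("[&age=%.2f]", ages)
  ape::write.tree(tr, file = path)
  invisible(path)
}
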