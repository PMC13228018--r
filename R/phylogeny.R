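# Neighbor-joining phylogeny of concatenated Mer proteins with
# Jukes-Cantor-corrected protein distances and nonparametric bootstrap
# supports.  Trees are ape "phylo" objects throughout; supports live in
# node.label as integer percentages.

#' Construct a protein alignment object
#'
#' @param seqs Named character vector of equal-length aligned amino-acid
#'   sequences (20-letter alphabet plus \code{-} and \code{X}).
#' @param spans Optional \code{data.frame} (\code{protein},
#'   \code{start}, \code{end}; 1-based inclusive column spans) recording
#'   the source proteins of a concatenation.
#' @return Object of class \code{protein_alignment}.
#' @export
protein_alignment <- function(seqs, spans = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("protein_alignment: sequences must have unique names")
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop("protein_alignment: sequences must have equal length")
  }
  if (is.null(spans)) {
    spans <- data.frame(protein = "all", start = 1L, end = w,
                        stringsAsFactors = FALSE)
  }
  structure(list(names = names(seqs), seqs = seqs, spans = spans,
                 width = w), class = "protein_alignment")
}

#' Read / write aligned FASTA
#'
#' @param path FASTA file of equal-length protein sequences.
#' @return A \code{protein_alignment}.
#' @export
read_alignment <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_alignment requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  protein_alignment(seqs)
}

#' @rdname read_alignment
#' @param aln A \code{protein_alignment}.
#' @export
write_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$names), aln$seqs[aln$names]))
  writeLines(lines, path)
  invisible(path)
}

#' Concatenate per-protein alignments
#'
#' Columns are appended in the order the alignments are given
#' (canonically MerR, MerT, MerP, MerA); taxa missing from a protein are
#' padded with gaps and flagged with a warning.  Per-protein column
#' spans are recorded.
#'
#' @param alignments Named list of \code{protein_alignment}.
#' @return A \code{protein_alignment} over the union of taxa.
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa_sets <- lapply(alignments, function(a) a$names)
  taxa <- sort(unique(unlist(taxa_sets)))
  if (length(Reduce(intersect, taxa_sets)) == 0L) {
    stop("concatenate_alignments: no taxa shared across proteins")
  }
  padded <- vapply(names(alignments), function(p) {
    a <- alignments[[p]]
    missing <- setdiff(taxa, a$names)
    if (length(missing)) {
      warning("taxa missing from ", p, ", padded with gaps: ",
              paste(missing, collapse = ", "))
    }
    out <- stats::setNames(rep(strrep("-", a$width), length(taxa)), taxa)
    out[a$names] <- a$seqs
    out
  }, character(length(taxa)))
  if (length(taxa) == 1L) padded <- matrix(padded, nrow = 1L,
                                           dimnames = list(taxa, names(alignments)))
  widths <- vapply(alignments, function(a) a$width, numeric(1))
  ends <- cumsum(widths)
  spans <- data.frame(protein = names(alignments),
                      start = c(1L, utils::head(ends, -1L) + 1L),
                      end = ends, stringsAsFactors = FALSE,
                      row.names = NULL)
  seqs <- stats::setNames(apply(padded, 1L, paste, collapse = ""), taxa)
  protein_alignment(seqs, spans)
}

#' Jukes-Cantor protein distances
#'
#' For every taxon pair, the proportion p of differing sites over
#' columns where neither sequence has a gap or X (pairwise deletion),
#' corrected for multiple hits with the 20-state Jukes-Cantor formula
#' d = -(19/20) ln(1 - 20 p / 19).  Pairs at or beyond the saturation
#' point p >= 19/20 receive \code{ceiling} and are flagged.
#'
#' @param aln A \code{protein_alignment} with >= 2 taxa.
#' @param ceiling Distance assigned to saturated pairs (default 5).
#' @return List of class \code{mer_distmat}: \code{d} (symmetric
#'   matrix), \code{p} (uncorrected proportions), \code{saturated}
#'   (logical matrix), \code{model = "JC-protein"}.
#' @export
jc_protein_distance <- function(aln, ceiling = 5.0) {
  stopifnot(inherits(aln, "protein_alignment"))
  n <- length(aln$names)
  if (n < 2L) stop("jc_protein_distance: need at least 2 taxa")
  chars <- do.call(rbind, strsplit(aln$seqs[aln$names], ""))
  rownames(chars) <- aln$names
  ok <- chars != "-" & chars != "X" & chars != "x"
  d <- p <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  sat <- matrix(FALSE, n, n, dimnames = list(aln$names, aln$names))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0L) {
        stop("jc_protein_distance: no comparable columns for pair ",
             aln$names[i], " / ", aln$names[j])
      }
      pij <- sum(chars[i, comp] != chars[j, comp]) / m
      p[i, j] <- p[j, i] <- pij
      if (pij >= 19 / 20) {
        d[i, j] <- d[j, i] <- ceiling
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -(19 / 20) * log(1 - 20 * pij / 19)
      }
    }
  }
  structure(list(d = d, p = p, saturated = sat, model = "JC-protein"),
            class = "mer_distmat")
}

# Newick-safe number formatting (full double precision).
#' @noRd
fmt_bl <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree
#'
#' Classical neighbor joining: iteratively join the pair minimizing
#' Q_ij = (n - 2) d_ij - sum_k d_ik - sum_k d_jk, with branch lengths
#' from the standard split formula (negative lengths clipped to 0 and
#' flagged).  Ties in Q are broken by the lexicographically smallest
#' label pair, making the output deterministic.
#'
#' @param d Symmetric distance matrix with >= 3 labeled taxa, or a
#'   \code{mer_distmat}.
#' @return An unrooted \code{ape::phylo}; attribute
#'   \code{"clipped_branches"} counts negative lengths clipped to 0.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "mer_distmat")) d <- d$d
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor_joining: need at least 3 taxa")
  labels <- rownames(d)
  stopifnot(!is.null(labels), !anyDuplicated(labels))
  clipped <- 0L
  clip <- function(x) {
    if (x < 0) { clipped <<- clipped + 1L; 0 } else x
  }
  # active clusters: newick fragment + representative (lexicographically
  # smallest member) label for tie-breaking
  frag <- stats::setNames(as.list(labels), labels)
  reps <- labels
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(reps[ij[1L]], reps[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    best <- cand[order(key)[1L], ]
    i <- best[[1L]]; j <- best[[2L]]
    li <- clip(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clip(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frag[[i]], ":", fmt_bl(li), ",",
                       frag[[j]], ":", fmt_bl(lj), ")")
    new_rep <- min(reps[i], reps[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], list(new_frag))
    reps <- c(reps[keep], new_rep)
    D <- D2
  }
  # terminal three-cluster star via the three-point formulas
  la <- clip((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clip((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clip((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", frag[[1L]], ":", fmt_bl(la), ",",
                frag[[2L]], ":", fmt_bl(lb), ",",
                frag[[3L]], ":", fmt_bl(lc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clipped_branches") <- clipped
  tree
}

# Canonical bipartition keys of an unrooted tree: for every internal
# edge, the tip set on the side NOT containing the alphabetically first
# taxon, sorted and collapsed to one string.  Trivial splits excluded.
#' @noRd
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1L) next
    keys <- c(keys, paste(side, collapse = "\r"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes Jukes-Cantor
#' distances and the NJ tree per replicate, and attaches to the
#' full-data tree the percentage of replicates containing each of its
#' bipartitions.  Replicates in which a pair has no comparable columns
#' are skipped and counted (warning when > 1\% skipped).
#'
#' @param aln A \code{protein_alignment} with >= 4 taxa.
#' @param n_reps Number of bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param ceiling Saturation ceiling passed to
#'   \code{\link{jc_protein_distance}}.
#' @return The full-data NJ tree (\code{ape::phylo}) with integer
#'   percent supports in \code{node.label}; attributes
#'   \code{"supports"} (named numeric, by bipartition key),
#'   \code{"n_valid"} and \code{"n_skipped"}.
#' @export
bootstrap_support <- function(aln, n_reps = 10000, seed = 1,
                              ceiling = 5.0) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (length(aln$names) < 4L) {
    stop("bootstrap_support: need >= 4 taxa for informative supports")
  }
  full_d <- jc_protein_distance(aln, ceiling = ceiling)
  full_tree <- neighbor_joining(full_d)
  full_keys <- tree_splits(full_tree)
  counts <- stats::setNames(rep(0L, length(full_keys)), full_keys)
  chars <- do.call(rbind, strsplit(aln$seqs[aln$names], ""))
  rownames(chars) <- aln$names
  w <- ncol(chars)
  set.seed(seed)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(w, w, replace = TRUE)
    rep_aln <- protein_alignment(
      stats::setNames(apply(chars[, cols, drop = FALSE], 1L, paste,
                            collapse = ""), aln$names))
    dr <- tryCatch(jc_protein_distance(rep_aln, ceiling = ceiling),
                   error = function(e) NULL)
    if (is.null(dr)) { skipped <- skipped + 1L; next }
    keys <- tree_splits(neighbor_joining(dr))
    hit <- full_keys %in% keys
    counts[hit] <- counts[hit] + 1L
  }
  n_valid <- n_reps - skipped
  if (skipped > 0.01 * n_reps) {
    warning("bootstrap_support: ", skipped, " of ", n_reps,
            " replicates skipped (incomparable pairs)")
  }
  supports <- if (n_valid > 0) 100 * counts / n_valid else counts * NA
  # attach supports to the full tree's internal nodes
  tree <- full_tree
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  parts <- ape::prop.part(tree)
  node_lab <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "\r")
    if (key %in% names(supports)) {
      node_lab[k] <- as.character(round(supports[[key]]))
    }
  }
  tree$node.label <- node_lab
  attr(tree, "supports") <- supports
  attr(tree, "n_valid") <- n_valid
  attr(tree, "n_skipped") <- skipped
  tree
}

#' Root a tree on an outgroup
#'
#' Outgroup rooting changes the displayed root without changing any
#' bipartition.
#'
#' @param tree An \code{ape::phylo}.
#' @param outgroup Tip label to root on.
#' @return Rooted \code{ape::phylo}.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' not in tree")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Write / read Newick
#'
#' Standard Newick with branch lengths and integer supports as internal
#' node labels; round-trips topology, branch lengths and supports.
#'
#' @param tree An \code{ape::phylo}.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(ape::write.tree(tree, digits = 17), path)
  invisible(path)
}

#' @rdname write_newick
#' @return \code{read_newick}: an \code{ape::phylo}.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("malformed Newick in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in '", path, "'")
  tree
}
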