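# Lifestyle-associated gene (LAG) classification from a gene-family
# presence/absence matrix: families present in >= 60% of the genomes of
# a lifestyle are restrictive LAGs, families in [40%, 60%) are lax, and
# families meeting a threshold in two or more lifestyles are shared.
# Threshold comparisons are exact rational comparisons of presence
# counts against lifestyle sizes, so printed boundaries (59/100 vs
# 60/100) never leak through floating point.

#' LAG thresholds
#'
#' @param restrictive_min Minimum within-lifestyle prevalence for a
#'   restrictive LAG (default 0.60).
#' @param lax_min Minimum prevalence for a lax LAG; the lax band is the
#'   half-open interval [lax_min, restrictive_min) (default 0.40).
#' @return List of class \code{lag_thresholds}.
#' @export
lag_thresholds <- function(restrictive_min = 0.60, lax_min = 0.40) {
  stopifnot(0 < lax_min, lax_min < restrictive_min, restrictive_min <= 1)
  structure(list(restrictive_min = restrictive_min, lax_min = lax_min),
            class = "lag_thresholds")
}

#' Per-family, per-lifestyle prevalence
#'
#' @param matrix Binary genomes x families matrix (0/1), genome ids as
#'   row names.
#' @param labels Lifestyle label per genome: named character vector or
#'   vector aligned with the matrix rows.
#' @return List of class \code{lag_prevalence}: \code{counts}
#'   (families x lifestyles presence counts), \code{n_genomes}
#'   (genomes per lifestyle), \code{fraction} (counts / n),
#'   \code{matrix}, \code{labels}.
#' @export
lag_prevalence <- function(matrix, labels) {
  m <- as.matrix(matrix)
  if (!all(m %in% c(0L, 1L))) {
    stop("lag_prevalence: matrix must be binary 0/1")
  }
  if (!is.null(names(labels)) && !is.null(rownames(m))) {
    missing_lab <- setdiff(rownames(m), names(labels))
    if (length(missing_lab)) {
      stop("lag_prevalence: no lifestyle label for genome(s): ",
           paste(missing_lab, collapse = ", "))
    }
    labels <- labels[rownames(m)]
  }
  if (length(labels) != nrow(m) || anyNA(labels)) {
    stop("lag_prevalence: need one non-missing label per genome")
  }
  labels <- as.character(labels)
  lifestyles <- sort(unique(labels))
  counts <- vapply(lifestyles, function(ls)
    colSums(m[labels == ls, , drop = FALSE]), numeric(ncol(m)))
  counts <- matrix(counts, ncol(m), length(lifestyles),
                   dimnames = list(colnames(m), lifestyles))
  n <- vapply(lifestyles, function(ls) sum(labels == ls), numeric(1))
  structure(list(counts = counts, n_genomes = n,
                 fraction = sweep(counts, 2L, n, "/"),
                 matrix = m, labels = stats::setNames(labels, rownames(m))),
            class = "lag_prevalence")
}

# Exact rational comparison count/n >= threshold without float leakage:
# thresholds are snapped to rationals over 1e6.
#' @noRd
frac_ge <- function(count, n, threshold) {
  count * 1e6 >= round(threshold * 1e6) * n
}

#' Classify lifestyle-associated gene families
#'
#' Per family and lifestyle: restrictive iff prevalence >=
#' \code{restrictive_min}, lax iff \code{lax_min} <= prevalence <
#' \code{restrictive_min}, else none; shared iff the family reaches a
#' class in two or more lifestyles.
#'
#' @param prev A \code{\link{lag_prevalence}}.
#' @param thresholds A \code{\link{lag_thresholds}}.
#' @return List of class \code{lag_table}: \code{class} (families x
#'   lifestyles, \code{"restrictive"}/\code{"lax"}/\code{"none"}),
#'   \code{shared} (logical per family), \code{fraction},
#'   \code{thresholds}, plus the prevalence object.
#' @export
classify_lags <- function(prev, thresholds = lag_thresholds()) {
  stopifnot(inherits(prev, "lag_prevalence"),
            inherits(thresholds, "lag_thresholds"))
  cls <- matrix("none", nrow(prev$counts), ncol(prev$counts),
                dimnames = dimnames(prev$counts))
  for (ls in colnames(prev$counts)) {
    n <- prev$n_genomes[[ls]]
    cnt <- prev$counts[, ls]
    restrictive <- frac_ge(cnt, n, thresholds$restrictive_min)
    lax <- !restrictive & frac_ge(cnt, n, thresholds$lax_min)
    cls[restrictive, ls] <- "restrictive"
    cls[lax, ls] <- "lax"
  }
  shared <- rowSums(cls != "none") >= 2L
  structure(list(class = cls, shared = shared,
                 fraction = prev$fraction, thresholds = thresholds,
                 prevalence = prev), class = "lag_table")
}

#' Summarize LAG classes and focal-genome carriage
#'
#' Counts restrictive/lax families per lifestyle, both including shared
#' families and with shared families separated out, and reports the
#' fraction of each lifestyle's restrictive LAGs present in a focal
#' genome.
#'
#' @param table A \code{\link{classify_lags}} result.
#' @param focal_genome Genome id present in the underlying matrix.
#' @return List with \code{counts} (data frame: lifestyle, class,
#'   n_total, n_exclusive), \code{n_shared},
#'   \code{focal_restrictive_fraction} (per lifestyle) and
#'   \code{focal_genome}.
#' @export
lag_summary <- function(table, focal_genome) {
  stopifnot(inherits(table, "lag_table"))
  m <- table$prevalence$matrix
  if (!focal_genome %in% rownames(m)) {
    stop("lag_summary: unknown genome id '", focal_genome, "'")
  }
  lifestyles <- colnames(table$class)
  rows <- list()
  focal_frac <- stats::setNames(rep(NA_real_, length(lifestyles)),
                                lifestyles)
  for (ls in lifestyles) {
    for (cl in c("restrictive", "lax")) {
      in_class <- table$class[, ls] == cl
      rows[[length(rows) + 1L]] <- data.frame(
        lifestyle = ls, class = cl,
        n_total = sum(in_class),
        n_exclusive = sum(in_class & !table$shared),
        stringsAsFactors = FALSE)
    }
    restr <- rownames(table$class)[table$class[, ls] == "restrictive"]
    if (length(restr)) {
      focal_frac[[ls]] <- mean(m[focal_genome, restr] == 1L)
    }
  }
  list(counts = do.call(rbind, rows),
       n_shared = sum(table$shared),
       focal_restrictive_fraction = as.list(focal_frac),
       focal_genome = focal_genome)
}
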