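# Permutation-based multivariate statistics, implemented from first
# principles so that every permutation procedure is seedable and, for
# small designs, exhaustively enumerable.

#' Bray-Curtis dissimilarity matrix
#'
#' d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), bounded in [0, 1].
#' Two all-zero rows are at distance 0 by convention.
#'
#' @param counts Non-negative genome x category matrix (rows are
#'   samples).
#' @return Symmetric matrix with zero diagonal, row/col names from
#'   \code{counts}.
#' @export
bray_curtis <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("bray_curtis: negative entries")
  n <- nrow(m)
  if (n < 2L) stop("bray_curtis: need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      denom <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <-
        if (denom == 0) 0 else sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  d
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering (default average linkage / UPGMA) with a
#' Newick export of the dendrogram.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param linkage \code{"average"}, \code{"complete"} or
#'   \code{"single"}.
#' @return List with the \code{hclust} object, the \code{linkage} used
#'   and \code{newick} (heights as branch lengths).
#' @export
hcluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  h <- stats::hclust(stats::as.dist(d), method = linkage)
  phy <- ape::as.phylo(h)
  list(hclust = h, linkage = linkage,
       newick = ape::write.tree(phy))
}

# Sum-of-squares decomposition of a squared-distance matrix under a
# grouping.  SS_total = (1/n) sum_{i<j} d_ij^2; SS_within sums the
# analogous per-group terms.
#' @noRd
permanova_ss <- function(D2, labels) {
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1L) {
      sub <- D2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' @noRd
permanova_F <- function(ss, n, g) {
  (ss[["between"]] / (g - 1)) / (ss[["within"]] / (n - g))
}

# All distinct arrangements of a label multiset (exhaustive null).
#' @noRd
multiset_permutations <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- table(factor(labels, levels = uniq))
  n <- length(labels)
  rec <- function(remaining, prefix) {
    if (sum(remaining) == 0L) return(list(prefix))
    out <- list()
    for (k in seq_along(uniq)) {
      if (remaining[k] > 0L) {
        r2 <- remaining
        r2[k] <- r2[k] - 1L
        out <- c(out, rec(r2, c(prefix, uniq[k])))
      }
    }
    out
  }
  rec(as.integer(counts), character(0))
}

#' @noRd
count_multiset_permutations <- function(labels) {
  counts <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
}

#' PERMANOVA (one factor)
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: pseudo-F from the sum-of-squares decomposition of squared
#' distances, R^2 = SS_between / SS_total, and a permutation p-value.
#' When the number of distinct label arrangements is at most
#' \code{exhaustive_limit} the null is enumerated exactly; otherwise
#' \code{n_perm} random label permutations are drawn and
#' p = (b + 1) / (m + 1) with b the permuted statistics >= observed.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Group label per row of \code{d} (>= 2 groups, none
#'   covering all samples).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive_limit Enumerate exactly when the distinct
#'   arrangement count is at most this (default 10000).
#' @return List of class \code{mer_permanova}: \code{pseudo_F},
#'   \code{R2}, \code{p_value}, \code{n_permutations},
#'   \code{exhaustive}, \code{seed}, \code{ss} (total/within/between).
#' @export
permanova <- function(d, labels, n_perm = 10000, seed = 1,
                      exhaustive_limit = 10000) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  g <- length(tab)
  if (g < 2L) stop("permanova: need at least 2 groups")
  if (any(tab == n)) stop("permanova: a group contains all samples")
  D2 <- d^2
  ss <- permanova_ss(D2, labels)
  F_obs <- permanova_F(ss, n, g)
  R2 <- ss[["between"]] / ss[["total"]]
  eps <- 1e-12
  n_distinct <- count_multiset_permutations(labels)
  if (n_distinct <= exhaustive_limit) {
    perms <- multiset_permutations(labels)
    F_all <- vapply(perms, function(p)
      permanova_F(permanova_ss(D2, p), n, g), numeric(1))
    p <- mean(F_all >= F_obs - eps)
    out <- list(pseudo_F = F_obs, R2 = R2, p_value = p,
                n_permutations = length(perms), exhaustive = TRUE,
                seed = seed, ss = ss)
  } else {
    set.seed(seed)
    b <- 0L
    # vectorized over groups via indicator quadratic forms
    lev <- names(tab)
    for (r in seq_len(n_perm)) {
      pl <- sample(labels)
      ssw <- 0
      for (gl in lev) {
        idx <- pl == gl
        ng <- sum(idx)
        if (ng > 1L) {
          ssw <- ssw + sum(D2[idx, idx]) / (2 * ng)
        }
      }
      F_perm <- ((ss[["total"]] - ssw) / (g - 1)) / (ssw / (n - g))
      if (F_perm >= F_obs - eps) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
    out <- list(pseudo_F = F_obs, R2 = R2, p_value = p,
                n_permutations = n_perm, exhaustive = FALSE,
                seed = seed, ss = ss)
  }
  class(out) <- "mer_permanova"
  out
}

#' Homogeneity of multivariate dispersion
#'
#' Embeds the dissimilarity matrix by principal coordinate analysis,
#' measures each sample's distance to its group centroid (axes with
#' negative eigenvalues contribute negatively to the squared distance,
#' floored at 0), and tests equality of mean dispersions across groups
#' with a one-way ANOVA F statistic whose null distribution is obtained
#' by permuting group labels over the distances.
#'
#' @inheritParams permanova
#' @return List of class \code{mer_dispersion}: \code{group_dispersions}
#'   (mean distance to centroid per group), \code{distances},
#'   \code{F_stat}, \code{p_value}, \code{n_permutations}, \code{seed},
#'   \code{degenerate} (all dispersions zero).
#' @export
beta_dispersion <- function(d, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  g <- length(tab)
  if (g < 2L) stop("beta_dispersion: need at least 2 groups")
  if (any(tab == n)) stop("beta_dispersion: a group contains all samples")
  emb <- pcoa_embed(d)   # keeps negative-eigenvalue axes
  dist_to_centroid <- numeric(n)
  for (gl in names(tab)) {
    idx <- which(labels == gl)
    cen_pos <- colMeans(emb$pos[idx, , drop = FALSE])
    sq <- rowSums(sweep(emb$pos[idx, , drop = FALSE], 2L, cen_pos)^2)
    if (ncol(emb$neg) > 0L) {
      cen_neg <- colMeans(emb$neg[idx, , drop = FALSE])
      sq <- sq - rowSums(sweep(emb$neg[idx, , drop = FALSE], 2L,
                               cen_neg)^2)
    }
    dist_to_centroid[idx] <- sqrt(pmax(sq, 0))
  }
  group_disp <- tapply(dist_to_centroid, labels, mean)
  anova_F <- function(y, lab) {
    gm <- mean(y)
    means <- tapply(y, lab, mean)
    ns <- tapply(y, lab, length)
    ssb <- sum(ns * (means - gm)^2)
    ssw <- sum((y - means[lab])^2)
    if (ssw <= 0) return(NA_real_)
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  F_obs <- anova_F(dist_to_centroid, labels)
  if (is.na(F_obs) || all(dist_to_centroid == 0)) {
    out <- list(group_dispersions = as.list(group_disp),
                distances = dist_to_centroid, F_stat = NA_real_,
                p_value = 1, n_permutations = 0L, seed = seed,
                degenerate = TRUE)
    class(out) <- "mer_dispersion"
    return(out)
  }
  set.seed(seed)
  b <- 0L
  eps <- 1e-12
  for (r in seq_len(n_perm)) {
    F_perm <- anova_F(dist_to_centroid, sample(labels))
    if (!is.na(F_perm) && F_perm >= F_obs - eps) b <- b + 1L
  }
  out <- list(group_dispersions = as.list(group_disp),
              distances = dist_to_centroid, F_stat = F_obs,
              p_value = (b + 1) / (n_perm + 1),
              n_permutations = n_perm, seed = seed, degenerate = FALSE)
  class(out) <- "mer_dispersion"
  out
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (g - 1 df),
#' plus Dunn's z for every group pair from mean ranks with tie
#' correction, two-sided normal p-values and Bonferroni adjustment over
#' all pairs.
#'
#' @param values Numeric vector of observations.
#' @param labels Group label per observation (>= 2 groups).
#' @param alpha Significance level recorded in the result (default
#'   0.05).
#' @return List of class \code{mer_ranktest}: \code{H}, \code{df},
#'   \code{p_value}, \code{pairwise} (data frame: group pair, Dunn z,
#'   raw and Bonferroni-adjusted p).
#' @export
kruskal_dunn <- function(values, labels, alpha = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("kruskal_dunn: need at least 2 groups")
  if (any(tab == 0L)) stop("kruskal_dunn: empty group")
  N <- length(values)
  if (N < 2L) stop("kruskal_dunn: need at least 2 observations")
  r <- rank(values)            # mid-ranks for ties
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  mean_ranks <- tapply(r, labels, mean)
  ns <- tapply(r, labels, length)
  H <- (12 / (N * (N + 1))) *
    sum(ns * (mean_ranks - (N + 1) / 2)^2)
  C <- 1 - tie_term / (N^3 - N)
  H <- if (C > 0) H / C else 0
  df <- length(tab) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  groups <- sort(names(tab))
  pairs <- utils::combn(groups, 2L)
  k <- ncol(pairs)
  sigma2 <- (N * (N + 1) / 12) - tie_term / (12 * (N - 1))
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   z = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    se <- sqrt(sigma2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    pr <- 2 * stats::pnorm(-abs(z))
    pw$z[i] <- z
    pw$p_raw[i] <- pr
    pw$p_adj[i] <- min(1, pr * k)
  }
  structure(list(H = H, df = df, p_value = p, pairwise = pw,
                 alpha = alpha), class = "mer_ranktest")
}

#' Dual Pearson/Spearman correlation report
#'
#' Computes Pearson's r (t-approximation p-value) and Spearman's rho
#' (Pearson correlation of mid-ranks, t-approximation p-value) and
#' reports the association only when both p-values fall below
#' \code{alpha} — the conservative dual-significance rule.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param alpha Significance level for the dual rule (default 0.05).
#' @param exact_permutation Use the exact permutation null for both
#'   p-values (only for n <= 10).
#' @return List of class \code{mer_correlation}: \code{pearson_r},
#'   \code{pearson_p}, \code{spearman_rho}, \code{spearman_p},
#'   \code{reported}, \code{degenerate} (zero variance in x or y).
#' @export
dual_correlation <- function(x, y, alpha = 0.05,
                             exact_permutation = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                reported = FALSE, degenerate = TRUE, alpha = alpha)
    class(out) <- "mer_correlation"
    return(out)
  }
  t_p <- function(r) {
    r <- min(1, max(-1, r))
    if (abs(r) >= 1) return(0)
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  r <- stats::cor(x, y)
  rho <- stats::cor(rank(x), rank(y))
  if (exact_permutation) {
    if (n > 10L) stop("exact permutation null only supported for n <= 10")
    perms <- multiset_permutations(as.character(seq_len(n)))
    idx <- lapply(perms, as.integer)
    r_null <- vapply(idx, function(p) stats::cor(x, y[p]), numeric(1))
    rho_null <- vapply(idx, function(p)
      stats::cor(rank(x), rank(y)[p]), numeric(1))
    pr <- mean(abs(r_null) >= abs(r) - 1e-12)
    ps <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    pr <- t_p(r)
    ps <- t_p(rho)
  }
  out <- list(pearson_r = r, pearson_p = pr, spearman_rho = rho,
              spearman_p = ps, reported = (pr < alpha && ps < alpha),
              degenerate = FALSE, alpha = alpha)
  class(out) <- "mer_correlation"
  out
}

# Double-centered PCoA embedding; keeps positive and negative axes
# separately (used by both pcoa_ordination and beta_dispersion).
#' @noRd
pcoa_embed <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  pos_axes <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  neg_axes <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), length(neg))
  rownames(pos_axes) <- rownames(neg_axes) <- rownames(d)
  list(pos = pos_axes, neg = neg_axes,
       eigenvalues = e$values,
       pos_values = e$values[pos], neg_values = e$values[neg])
}

# Fix axis signs so the largest-magnitude loading/coordinate on each
# axis is positive (makes ordinations reproducible up to nothing).
#' @noRd
fix_signs <- function(coords, loadings = NULL) {
  ref <- if (is.null(loadings)) coords else loadings
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(ref[, j]))
    if (ref[i, j] < 0) {
      coords[, j] <- -coords[, j]
      if (!is.null(loadings)) loadings[, j] <- -loadings[, j]
    }
  }
  list(coords = coords, loadings = loadings)
}

#' Principal component analysis of scaled abundances
#'
#' PCA by eigendecomposition of the correlation structure: columns are
#' centered and scaled to unit sample SD (constant columns dropped with
#' a warning).  Axis signs are fixed so each axis's largest-magnitude
#' loading is positive.
#'
#' @param x Samples x variables matrix.
#' @return List of class \code{mer_ordination}: \code{coordinates},
#'   \code{explained} (variance fractions), \code{loadings},
#'   \code{method = "PCA"}.
#' @export
pca_ordination <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("pca_ordination: need at least 2 rows and 2 columns")
  }
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("pca_ordination: dropping constant column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  fx <- fix_signs(p$x, p$rotation)
  structure(list(coordinates = fx$coords, explained = expl,
                 loadings = fx$loadings, method = "PCA"),
            class = "mer_ordination")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers -d^2/2, eigendecomposes, and returns coordinates on
#' the positive-eigenvalue axes.  Bray-Curtis matrices are generally
#' non-Euclidean; the mass of negative eigenvalues is reported rather
#' than corrected away.
#'
#' @param d Symmetric dissimilarity matrix.
#' @return List of class \code{mer_ordination}: \code{coordinates},
#'   \code{explained} (fractions of the positive eigenvalue total),
#'   \code{negative_eigenvalue_mass} (|sum of negative| / sum of
#'   absolute eigenvalues), \code{method = "PCoA"}.
#' @export
pcoa_ordination <- function(d) {
  emb <- pcoa_embed(d)
  if (ncol(emb$pos) == 0L) stop("pcoa_ordination: no positive axes")
  expl <- emb$pos_values / sum(emb$pos_values)
  neg_mass <- if (length(emb$neg_values))
    sum(abs(emb$neg_values)) / sum(abs(emb$eigenvalues)) else 0
  fx <- fix_signs(emb$pos)
  structure(list(coordinates = fx$coords, explained = expl,
                 negative_eigenvalue_mass = neg_mass, method = "PCoA"),
            class = "mer_ordination")
}
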