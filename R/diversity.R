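# Alpha/beta diversity and unconstrained ordination used to characterise
# effluent versus sessile communities across phases. Index and distance
# computations are delegated to vegan; classical metric scaling to
# stats::cmdscale.

check_counts_vector <- function(counts) {
  if (length(counts) == 0 || any(!is.finite(counts))) {
    domain_error("counts must be a finite, non-empty vector")
  }
  if (any(counts < 0)) domain_error("counts must be non-negative")
  if (sum(counts) <= 0) domain_error("at least one count must be positive")
  invisible(counts)
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over taxa with positive counts, where
#' `p_i = count_i / total`. Natural logarithm by default (the convention
#' of the ecology tooling this mirrors); the base is configurable because
#' the index is sometimes reported in bits or decits.
#'
#' @param counts Non-negative abundance vector with at least one positive
#'   entry (fractional abundances allowed).
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Shannon index (scalar).
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts_vector(counts)
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Simpson index
#'
#' The Gini-Simpson form `1 - sum p_i^2` by default (in `[0, 1)`, higher =
#' more diverse); `variant = "dominance"` returns the plain dominance sum
#' `sum p_i^2`.
#'
#' @param counts Non-negative abundance vector with at least one positive
#'   entry.
#' @param variant `"gini"` (default) or `"dominance"`.
#' @return Simpson index (scalar).
#' @export
simpson <- function(counts, variant = c("gini", "dominance")) {
  variant <- match.arg(variant)
  check_counts_vector(counts)
  g <- as.numeric(vegan::diversity(counts, index = "simpson"))
  if (variant == "gini") g else 1 - g
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 * sum min(a_i, b_i) / (sum a + sum b)`, in `[0, 1]`.
#'
#' @param a,b Non-negative abundance vectors of equal length.
#' @return Bray-Curtis dissimilarity (scalar).
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) {
    validation_error("vectors must have equal length (%d vs %d)",
                     length(a), length(b))
  }
  if (any(a < 0) || any(b < 0)) domain_error("abundances must be non-negative")
  if (sum(a) + sum(b) <= 0) {
    domain_error("both samples are empty; dissimilarity undefined")
  }
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared dissimilarity matrix and eigendecomposes it,
#' retaining up to `k` axes with positive eigenvalues. For a
#' Euclidean-embeddable input the inter-point distances of the full
#' coordinate set reproduce the input distances.
#'
#' @param d Dissimilarity matrix (square symmetric, zero diagonal) or a
#'   `dist` object.
#' @param k Maximum number of axes to retain (`>= 1`).
#' @return Object of class `pcoa_ordination` with elements `points`
#'   (samples x axes), `eig` (all eigenvalues, descending) and
#'   `prop_explained` (share of the positive-eigenvalue sum per retained
#'   axis).
#' @export
pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) validation_error("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) {
    validation_error("distance matrix must be symmetric")
  }
  if (max(abs(diag(m))) > 1e-8) {
    validation_error("distance matrix must have a zero diagonal")
  }
  if (any(m < 0)) validation_error("dissimilarities must be non-negative")
  if (k < 1) validation_error("k must be >= 1")
  n <- nrow(m)
  # cmdscale warns when fewer than k eigenvalues are positive; axis
  # retention is handled explicitly below, so the warning is redundant
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = min(k, n - 1), eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig), 0) * 1e-12
  npos <- sum(eig > tol)
  if (npos == 0) {
    pts <- matrix(0, n, 1, dimnames = list(rownames(m), "Axis1"))
    return(structure(list(points = pts, eig = eig,
                          prop_explained = 0), class = "pcoa_ordination"))
  }
  keep <- min(k, npos, ncol(sc$points))
  pts <- sc$points[, seq_len(keep), drop = FALSE]
  colnames(pts) <- sprintf("Axis%d", seq_len(keep))
  rownames(pts) <- rownames(m)
  structure(list(points = pts, eig = eig,
                 prop_explained = eig[seq_len(keep)] / sum(eig[eig > tol])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination> %d samples, %d axes (%.1f%% of positive inertia)\n",
              nrow(x$points), ncol(x$points), 100 * sum(x$prop_explained)))
  invisible(x)
}

#' Rank-based group comparison
#'
#' Two-sided Wilcoxon rank-sum (exactly two groups) or Kruskal-Wallis
#' (two or more groups) with the standard tie correction. For a total
#' sample size of at most 10 without ties the Wilcoxon p-value is exact;
#' otherwise the usual asymptotic approximation is used. The pipeline
#' reports these descriptively and never gates decisions on them.
#'
#' @param values_by_group Named list of numeric vectors, one per group,
#'   each non-empty.
#' @param method `"wilcoxon_rank_sum"` or `"kruskal_wallis"`.
#' @return List with `method`, `statistic`, `p_value`, `n`.
#' @export
group_compare <- function(values_by_group,
                          method = c("wilcoxon_rank_sum", "kruskal_wallis")) {
  method <- match.arg(method)
  g <- lapply(values_by_group, as.numeric)
  if (length(g) < 2) validation_error("need at least two groups")
  if (any(vapply(g, length, 0L) < 1)) {
    validation_error("every group needs at least one observation")
  }
  all_vals <- unlist(g, use.names = FALSE)
  if (method == "wilcoxon_rank_sum") {
    if (length(g) != 2) {
      validation_error("wilcoxon_rank_sum requires exactly two groups")
    }
    exact <- length(all_vals) <= 10 && !any(duplicated(all_vals))
    ht <- suppressWarnings(
      stats::wilcox.test(g[[1]], g[[2]], alternative = "two.sided",
                         exact = exact, correct = !exact))
  } else {
    grp <- factor(rep(seq_along(g), vapply(g, length, 0L)))
    ht <- stats::kruskal.test(all_vals, grp)
  }
  list(method = method,
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n = length(all_vals))
}
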