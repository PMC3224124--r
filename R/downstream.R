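# Downstream statistics: clustering of frequency profiles and
# cross-platform agreement (correlations, directional concordance).

#' Correlation distance matrix between gene frequency rows
#'
#' `d(a, b) = 1 - r(a, b)` with `r` the Pearson correlation of the two
#' genes' across-group frequency vectors; distances lie in `[0, 2]`. Rows
#' with zero variance carry no correlation information: their distance to
#' everything is defined as 1 and they are flagged in the
#' `"zero_variance_rows"` attribute.
#'
#' @param freq_matrix genes x groups numeric matrix (>= 2 columns).
#' @return a symmetric distance matrix with zero diagonal.
#' @export
pearson_distance_matrix <- function(freq_matrix) {
  stopifnot(is.matrix(freq_matrix), ncol(freq_matrix) >= 2L)
  sds <- apply(freq_matrix, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(t(freq_matrix)))
  d <- 1 - r
  d[is.na(d)] <- 1
  if (any(flat)) {
    d[flat, ] <- 1
    d[, flat] <- 1
  }
  diag(d) <- 0
  attr(d, "zero_variance_rows") <- rownames(freq_matrix)[flat]
  d
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Standard agglomerative clustering with average linkage; for a metric
#' input the merge heights are non-decreasing and there are n - 1 merges for
#' n leaves. Leaf order is made deterministic (within each merge, the
#' subtree containing the smallest original leaf index comes first) so
#' serialized output is byte-stable.
#'
#' @param dist_matrix symmetric distance matrix (e.g.
#'   [pearson_distance_matrix()]), or a `dist`.
#' @return an object of class `c("est_dendrogram", "hclust")`.
#' @export
cluster_average <- function(dist_matrix) {
  d <- if (inherits(dist_matrix, "dist")) dist_matrix else
    as.dist(dist_matrix)
  hc <- hclust(d, method = "average")
  # deterministic orientation: subtree with the smallest leaf first
  n <- length(hc$order)
  min_leaf <- integer(n - 1L)
  for (k in seq_len(n - 1L)) {
    ml <- function(v) if (v < 0L) -v else min_leaf[v]
    a <- ml(hc$merge[k, 1L]); b <- ml(hc$merge[k, 2L])
    if (b < a) {
      hc$merge[k, ] <- hc$merge[k, 2:1]
      tmp <- a; a <- b; b <- tmp
    }
    min_leaf[k] <- min(a, b)
  }
  # recompute leaf order from the re-oriented merges
  expand <- function(v) if (v < 0L) -v else
    c(expand(hc$merge[v, 1L]), expand(hc$merge[v, 2L]))
  hc$order <- expand(n - 1L)
  class(hc) <- c("est_dendrogram", "hclust")
  hc
}

#' Cut a dendrogram into k clusters
#'
#' Cuts below the k - 1 highest merges.
#'
#' @param dendrogram a [cluster_average()] result.
#' @param k number of clusters (1 <= k <= n leaves).
#' @return named integer cluster labels.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k > n || k < 1L) {
    stop("k must lie in 1..", n, call. = FALSE)
  }
  cutree(structure(dendrogram, class = "hclust"), k = k)
}

#' Export a dendrogram as Newick with merge heights
#'
#' @param dendrogram a [cluster_average()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(structure(dendrogram, class = "hclust"))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Per-gene log2 frequency ratios
#'
#' `log2((f_stress + pseudo) / (f_control + pseudo))`. The pseudo-count
#' (default 0.5 per-10k) keeps genes observed on only one side finite.
#'
#' @param f_stress,f_control non-negative per-10k frequency vectors.
#' @param pseudo pseudo-count added to both sides (must be > 0 whenever a
#'   zero frequency is present).
#' @return numeric log2 ratios.
#' @export
log2_ratio_table <- function(f_stress, f_control, pseudo = 0.5) {
  stopifnot(length(f_stress) == length(f_control),
            all(f_stress >= 0), all(f_control >= 0))
  if (pseudo <= 0 && any(f_stress == 0 | f_control == 0)) {
    stop("pseudo must be > 0 when zero frequencies are present",
         call. = FALSE)
  }
  log2((f_stress + pseudo) / (f_control + pseudo))
}

#' Directional concordance between two log-ratio vectors
#'
#' Counts the Cartesian quadrants of the paired ratios: concordance is the
#' fraction of genes whose response direction (up/down) agrees between the
#' two platforms, `(n++ + n--) / n`. Genes with a ratio of exactly zero on
#' either axis have no direction and are excluded from the quadrant counts
#' (reported separately). Spearman is computed on midranks, Pearson on the
#' values.
#'
#' @param ratios_a,ratios_b paired finite log2 ratios (>= 3 non-zero pairs).
#' @return a `concordance_report`: list with `n`, `concordance`,
#'   `spearman_r`, `pearson_r`, `quadrants` (named `++`, `+-`, `-+`, `--`),
#'   `n_zero_excluded`.
#' @export
concordance <- function(ratios_a, ratios_b) {
  stopifnot(length(ratios_a) == length(ratios_b),
            all(is.finite(ratios_a)), all(is.finite(ratios_b)))
  nonzero <- ratios_a != 0 & ratios_b != 0
  a <- ratios_a[nonzero]
  b <- ratios_b[nonzero]
  if (length(a) < 3L) {
    stop("need at least 3 non-zero pairs for correlations", call. = FALSE)
  }
  quad <- c(`++` = sum(a > 0 & b > 0), `+-` = sum(a > 0 & b < 0),
            `-+` = sum(a < 0 & b > 0), `--` = sum(a < 0 & b < 0))
  structure(list(
    n = length(a),
    concordance = unname((quad["++"] + quad["--"]) / length(a)),
    spearman_r = cor(a, b, method = "spearman"),
    pearson_r = cor(a, b, method = "pearson"),
    quadrants = quad,
    n_zero_excluded = sum(!nonzero)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> n =", x$n,
      sprintf("(+%d zero-excluded)", x$n_zero_excluded), "\n")
  cat("  concordance:", sprintf("%.3f", x$concordance),
      " spearman:", sprintf("%.3f", x$spearman_r),
      " pearson:", sprintf("%.3f", x$pearson_r), "\n")
  cat("  quadrants: ", paste(names(x$quadrants), x$quadrants,
                             sep = "=", collapse = "  "), "\n")
  invisible(x)
}
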