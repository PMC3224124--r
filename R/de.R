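# Differential expression on tag counts.
#
# Two tests, the classical digital-northern pair:
# * a multigroup chi-squared goodness-of-fit statistic with expectations
#   proportional to library sizes (df = g - 1), for comparisons of more than
#   two groups;
# * the exact Audic-Claverie (AC) test for pairs of libraries, based on the
#   conditional distribution of the second count given the first:
#   p(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)).
# Filters (minimum total ESTs; singleton removal for AC) and Bonferroni
# control mirror standard tag-count practice.

#' Test configuration for tag-count DE
#'
#' @param min_total_ests minimum summed ESTs across groups for the
#'   chi-squared test (default 4).
#' @param min_per_side minimum count in at least one side for the pairwise
#'   AC test (default 2: singletons are removed).
#' @param alpha significance level (chi-squared family default 0.001; for
#'   the AC family the conventional 0.01 with Bonferroni).
#' @param multiple_testing `"NONE"` or `"BONFERRONI"`.
#' @param m number of tests for Bonferroni; `NULL` = number of genes
#'   actually tested after filtering.
#' @return a named list.
#' @export
de_config <- function(min_total_ests = 4L, min_per_side = 2L, alpha = 0.001,
                      multiple_testing = c("NONE", "BONFERRONI"), m = NULL) {
  multiple_testing <- match.arg(multiple_testing)
  stopifnot(alpha > 0, alpha < 1, is.null(m) || m >= 1)
  list(min_total_ests = as.integer(min_total_ests),
       min_per_side = as.integer(min_per_side), alpha = alpha,
       multiple_testing = multiple_testing, m = m)
}

#' Multigroup chi-squared test on tag counts
#'
#' Goodness-of-fit statistic `sum((c_j - e_j)^2 / e_j)` with expectations
#' `e_j = sum(c) * N_j / sum(N)` proportional to library sizes, compared to
#' the chi-squared distribution with `g - 1` degrees of freedom. No
#' continuity correction is applied.
#'
#' @param counts per-group counts of one gene (length g >= 2).
#' @param totals per-group library sizes (all > 0).
#' @return list with `statistic` and `p_value`.
#' @export
chi2_multigroup <- function(counts, totals) {
  stopifnot(length(counts) == length(totals), length(counts) >= 2L,
            all(totals > 0))
  e <- sum(counts) * totals / sum(totals)
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat,
       p_value = pchisq(stat, df = length(counts) - 1L, lower.tail = FALSE))
}

# log p(k | x) for k = 0..kmax under the AC conditional distribution
.ac_log_terms <- function(x, kvec, log_r, log_1pr) {
  kvec * log_r + lchoose(x + kvec, kvec) - (x + kvec + 1) * log_1pr
}

.logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Exact Audic-Claverie p-value for a pair of tag counts
#'
#' Given `x` tags among `N1` observations in one library and `y` among `N2`
#' in the other, computes the conditional tail probabilities of
#' `p(k | x) = (N2/N1)^k * C(x+k, k) / (1 + N2/N1)^(x+k+1)` and returns the
#' two-sided significance `min(1, 2 * min(P(K <= y), P(K >= y)))` (the
#' doubled smaller tail, capped at 1), or the smaller tail alone when
#' `two_sided = FALSE`. All summation is done in log space; the smaller tail
#' is always summed directly, so values far below machine epsilon are exact
#' to ~1e-13 relative.
#'
#' Because which library supplies the conditioning count is arbitrary, the
#' pair is first put into a canonical orientation (swap the two sides so
#' that `N1 <= N2`, ties broken by `x <= y`); the significance is therefore
#' exactly symmetric: `audic_claverie_p(x, y, N1, N2) ==
#' audic_claverie_p(y, x, N2, N1)`.
#'
#' @param x,y non-negative integer counts (vectorized, recycled).
#' @param N1,N2 positive library sizes.
#' @param two_sided doubled-tail convention (default TRUE; a single run then
#'   reports enrichment on both sides).
#' @return p-value(s) in `[0, 1]`.
#' @export
audic_claverie_p <- function(x, y, N1, N2, two_sided = TRUE) {
  if (any(x != floor(x)) || any(y != floor(y)) || any(x < 0) || any(y < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(N1 > 0, N2 > 0)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (N1 > N2) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
  } else if (N1 == N2) {
    swap <- x > y
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
  }
  log_r <- log(N2) - log(N1)
  log_1pr <- log1p(N2 / N1)
  vapply(seq_len(n), function(i) {
    .ac_one(x[i], y[i], log_r, log_1pr, two_sided)
  }, numeric(1L))
}

.ac_one <- function(x, y, log_r, log_1pr, two_sided) {
  # conditional mode of k given x
  mode_k <- floor((x + 1) * exp(log_r - log_1pr) / (1 - exp(log_r - log_1pr)))
  if (!is.finite(mode_k) || mode_k < 0) mode_k <- 0
  if (y <= mode_k) {
    # lower tail is the small one: sum k = 0..y directly
    lower <- exp(.logsumexp(.ac_log_terms(x, 0:y, log_r, log_1pr)))
    upper <- if (y == 0) 1 else
      max(0, 1 - exp(.logsumexp(.ac_log_terms(x, 0:(y - 1), log_r, log_1pr))))
  } else {
    # upper tail is the small one: sum k = y.. until terms vanish
    upper <- .ac_upper_direct(x, y, log_r, log_1pr)
    lower <- max(0, 1 - .ac_upper_direct(x, y + 1, log_r, log_1pr))
  }
  if (two_sided) min(1, 2 * min(lower, upper)) else min(lower, upper)
}

# sum_{k >= y} p(k | x), for y beyond the conditional mode (terms decrease)
.ac_upper_direct <- function(x, y, log_r, log_1pr) {
  block <- 256L
  total_log <- -Inf
  k0 <- y
  repeat {
    kvec <- k0:(k0 + block - 1L)
    lt <- .ac_log_terms(x, kvec, log_r, log_1pr)
    total_log <- .logsumexp(c(total_log, lt))
    # stop once the next term can no longer move the sum
    if (lt[block] < total_log - 40) break
    k0 <- k0 + block
    if (k0 > y + 1e6) break  # defensive; never reached for sane inputs
  }
  exp(total_log)
}

#' Apply multiple-testing control to DE results
#'
#' Under `"BONFERRONI"`, a gene is significant iff its raw p-value is below
#' `alpha / m`; the effective cutoff is recorded (e.g. alpha 0.01 over
#' ~3,333 tests gives the conventional 3.0e-6 tag-count cutoff). Under
#' `"NONE"` the cutoff is `alpha` itself.
#'
#' @param results a data.table with a `p_value` column (one family of
#'   tests).
#' @param config a [de_config()]; `config$m` defaults to `nrow(results)`.
#' @return `results` with `significant` flags, plus attributes `cutoff` and
#'   `m`.
#' @export
apply_multiple_testing <- function(results, config = de_config()) {
  results <- as.data.table(results)
  m <- if (is.null(config$m)) nrow(results) else config$m
  cutoff <- switch(config$multiple_testing,
                   NONE = config$alpha,
                   BONFERRONI = config$alpha / max(m, 1L))
  results[, significant := p_value < cutoff]
  setattr(results, "cutoff", cutoff)
  setattr(results, "m", m)
  results[]
}

#' Chi-squared DE across the groups of a frequency profile
#'
#' Tests every gene with at least `min_total_ests` pooled ESTs; filtered
#' genes are reported with `tested = FALSE` and a reason instead of a
#' p-value.
#'
#' @param profile a [build_group_profiles()] result (>= 2 groups).
#' @param config a [de_config()].
#' @return a data.table: `gene_id`, per-group counts, `statistic`,
#'   `p_value`, `tested`, `filter_reason`, `significant` (at the configured
#'   cutoff).
#' @export
de_chi2 <- function(profile, config = de_config()) {
  counts <- profile$counts
  stopifnot(ncol(counts) >= 2L)
  totals <- profile$group_sizes
  total_c <- rowSums(counts)
  tested <- total_c >= config$min_total_ests
  e <- outer(total_c, totals / sum(totals))
  stat <- rowSums((counts - e)^2 / e)
  res <- data.table(gene_id = rownames(counts))
  for (g in colnames(counts)) set(res, j = paste0("count_", g),
                                  value = counts[, g])
  res[, statistic := fifelse(tested, stat, NA_real_)]
  res[, p_value := fifelse(
    tested, pchisq(stat, df = ncol(counts) - 1L, lower.tail = FALSE),
    NA_real_)]
  res[, tested := tested]
  res[, filter_reason := fifelse(tested, NA_character_,
                                 sprintf("fewer than %d ESTs in dataset",
                                         config$min_total_ests))]
  out <- apply_multiple_testing(res[tested == TRUE], config)
  res[, significant := FALSE]
  res[tested == TRUE, significant := out$significant]
  setattr(res, "cutoff", attr(out, "cutoff"))
  setattr(res, "m", attr(out, "m"))
  res[]
}

#' Pairwise Audic-Claverie DE between two profile groups
#'
#' Tests every gene with at least `min_per_side` ESTs in one or both groups
#' (singletons removed), applies the configured multiple-testing control,
#' and calls the enrichment direction of significant genes from the
#' per-10k frequencies.
#'
#' @param profile a [build_group_profiles()] result.
#' @param group_a,group_b the two group labels to compare.
#' @param config a [de_config()] (conventionally `alpha = 0.01`,
#'   `multiple_testing = "BONFERRONI"`).
#' @param two_sided see [audic_claverie_p()].
#' @return a data.table: `gene_id`, `count_a`, `count_b`, `freq_a`,
#'   `freq_b`, `p_value`, `tested`, `significant`, `direction`
#'   (`"GROUP_A_ENRICHED"`, `"GROUP_B_ENRICHED"` or `NA`); attributes
#'   `cutoff` and `m`.
#' @export
de_audic_claverie <- function(profile, group_a, group_b,
                              config = de_config(alpha = 0.01,
                                                 multiple_testing = "BONFERRONI"),
                              two_sided = TRUE) {
  stopifnot(all(c(group_a, group_b) %in% colnames(profile$counts)))
  x <- profile$counts[, group_a]
  y <- profile$counts[, group_b]
  N1 <- profile$group_sizes[[group_a]]
  N2 <- profile$group_sizes[[group_b]]
  tested <- pmax(x, y) >= config$min_per_side
  res <- data.table(gene_id = rownames(profile$counts),
                    count_a = x, count_b = y,
                    freq_a = profile$freq[, group_a],
                    freq_b = profile$freq[, group_b],
                    tested = tested, p_value = NA_real_)
  if (any(tested)) {
    res[tested == TRUE,
        p_value := audic_claverie_p(count_a, count_b, N1, N2,
                                    two_sided = two_sided)]
  }
  out <- apply_multiple_testing(res[tested == TRUE], config)
  res[, significant := FALSE]
  res[tested == TRUE, significant := out$significant]
  res <- call_pairwise_enrichment(res)
  setattr(res, "cutoff", attr(out, "cutoff"))
  setattr(res, "m", attr(out, "m"))
  res[]
}

#' Call enrichment direction for significant pairwise results
#'
#' Direction is assigned by comparing per-10k frequencies between the two
#' sides; a significant gene with exactly equal frequencies would contradict
#' the test and raises an error.
#'
#' @param results pairwise results with `freq_a`, `freq_b`, `significant`.
#' @return `results` with a `direction` column.
#' @export
call_pairwise_enrichment <- function(results) {
  results <- as.data.table(results)
  if (any(results$significant & results$freq_a == results$freq_b)) {
    stop("significant gene with equal frequencies: impossible under the test",
         call. = FALSE)
  }
  results[, direction := fifelse(
    !significant, NA_character_,
    fifelse(freq_a > freq_b, "GROUP_A_ENRICHED", "GROUP_B_ENRICHED"))]
  results[]
}
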