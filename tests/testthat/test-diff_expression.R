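test_that("chi-squared statistic matches hand computation", {
  perfect <- chi2_multigroup(c(30, 60, 90), c(1000, 2000, 3000))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  hand <- chi2_multigroup(c(10, 0), c(1000, 1000))
  expect_equal(hand$statistic, 10)  # e = (5, 5); 25/5 + 25/5
  expect_equal(hand$p_value, pchisq(10, df = 1, lower.tail = FALSE))
  expect_equal(round(hand$p_value, 5), 0.00157)
})

test_that("chi-squared with g = 2 approaches the two-proportion z-test", {
  # asymptotic check: the goodness-of-fit statistic over the two observed
  # cells approaches the squared pooled two-proportion z statistic as the
  # per-library tag fraction becomes small (they differ by a factor
  # ~ (1 - p_pool), since the absent class is not a cell here)
  x1 <- 300; x2 <- 200; n1 <- 1e6; n2 <- 9e5
  st <- chi2_multigroup(c(x1, x2), c(n1, n2))$statistic
  p_pool <- (x1 + x2) / (n1 + n2)
  z <- (x1 / n1 - x2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  expect_equal(st, z^2, tolerance = 1e-3)
})

test_that("de_chi2 excludes genes under the minimum-EST filter", {
  counts <- matrix(c(3, 0, 0, 0,   10, 0, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gSmall", "gBig"), paste0("G", 1:4)))
  prof <- structure(list(counts = counts,
                         freq = counts / 1000 * 1e4,
                         group_sizes = setNames(rep(1000, 4), paste0("G", 1:4)),
                         members = list(), normalized_groups = character()),
                    class = "frequency_profile")
  res <- de_chi2(prof, de_config(min_total_ests = 4L))
  expect_false(res$tested[res$gene_id == "gSmall"])
  expect_match(res$filter_reason[res$gene_id == "gSmall"], "fewer than 4")
  expect_true(res$tested[res$gene_id == "gBig"])
})

test_that("AC p-values agree with the frozen exact-rational oracle", {
  or <- load_ac_oracle()
  # vectorized call only valid per (N1, N2) block; loop the blocks
  for (blk in split(or, paste(or$N1, or$N2))) {
    got <- audic_claverie_p(blk$x, blk$y, blk$N1[1], blk$N2[1])
    rel_err <- abs(got - blk$p_two_sided) / pmax(blk$p_two_sided, 1e-300)
    expect_lt(max(rel_err), 1e-10)
  }
})

test_that("AC agrees with a direct-summation oracle on random cases", {
  set.seed(47)
  for (i in 1:40) {
    x <- sample(0:50, 1L); y <- sample(0:50, 1L)
    N1 <- sample(c(500, 1000, 5000, 20000), 1L)
    N2 <- sample(c(500, 1000, 5000, 20000), 1L)
    want <- oracle_ac_two_sided(x, y, N1, N2)
    if (want < 1e-8) next  # complement form loses precision below this
    expect_equal(audic_claverie_p(x, y, N1, N2), want, tolerance = 1e-10)
  }
  expect_equal(audic_claverie_p(2, 0, 100, 100),
               oracle_ac_two_sided(2, 0, 100, 100), tolerance = 1e-10)
})

test_that("AC symmetry, caps and monotonicity", {
  expect_equal(audic_claverie_p(7, 7, 500, 500), 1)
  expect_equal(audic_claverie_p(0, 0, 900, 900), 1)
  set.seed(53)
  for (i in 1:20) {
    x <- sample(0:40, 1L); y <- sample(0:40, 1L)
    N1 <- sample(1000:50000, 1L); N2 <- sample(1000:50000, 1L)
    expect_equal(audic_claverie_p(x, y, N1, N2),
                 audic_claverie_p(y, x, N2, N1))
  }
  # monotone: p non-increasing as y moves away from the two-sided argmax
  # (within one count of the conditional mode)
  x <- 20; N1 <- 10000; N2 <- 20000
  mode_k <- floor((x + 1) * N2 / N1)
  all_y <- audic_claverie_p(x, 0:(3 * mode_k), N1, N2)
  ym <- which.max(all_y) - 1L
  expect_lte(abs(ym - mode_k), 1L)
  expect_true(all(diff(all_y[(ym + 1):length(all_y)]) <= 1e-12))
  expect_true(all(diff(rev(all_y[1:(ym + 1)])) <= 1e-12))
  expect_error(audic_claverie_p(1.5, 2, 100, 100), "integers")
})

test_that("Bonferroni control reproduces the conventional tag cutoff", {
  res <- data.frame(gene_id = paste0("g", 1:5),
                    p_value = c(1e-7, 1e-5, 0.5, 1, 2.9e-6))
  out <- apply_multiple_testing(res, de_config(alpha = 0.01,
                                               multiple_testing = "BONFERRONI",
                                               m = 3333))
  expect_equal(attr(out, "cutoff"), 0.01 / 3333)
  expect_equal(round(attr(out, "cutoff"), 9), 3.0e-6)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE, TRUE))

  out1 <- apply_multiple_testing(res, de_config(alpha = 0.01,
                                                multiple_testing = "BONFERRONI",
                                                m = 1))
  expect_equal(attr(out1, "cutoff"), 0.01)
  all_null <- apply_multiple_testing(
    data.frame(p_value = rep(1, 10)),
    de_config(alpha = 0.05, multiple_testing = "NONE"))
  expect_equal(sum(all_null$significant), 0L)
})

test_that("enrichment direction follows the frequencies", {
  res <- data.table::data.table(
    gene_id = c("up", "down", "ns"),
    freq_a = c(30, 1, 5), freq_b = c(2, 9, 5),
    significant = c(TRUE, TRUE, FALSE))
  out <- call_pairwise_enrichment(res)
  expect_equal(out$direction, c("GROUP_A_ENRICHED", "GROUP_B_ENRICHED", NA))
  bad <- data.table::data.table(gene_id = "x", freq_a = 5, freq_b = 5,
                                significant = TRUE)
  expect_error(call_pairwise_enrichment(bad), "impossible")
})

test_that("singleton filtering and direction calls run end to end", {
  fx <- end_to_end_fixture("root_vs_nonroot", seed = 19)
  prof <- build_group_profiles(collapse_clones(group_clones(fx$catalog)),
                               fx$catalog$libraries)
  res <- de_audic_claverie(prof, "root", "non_root",
                           de_config(alpha = 0.01,
                                     multiple_testing = "BONFERRONI",
                                     m = 3333))
  # singletons are not tested
  singles <- res[res$count_a <= 1 & res$count_b <= 1, ]
  expect_false(any(singles$tested))
  # every significant gene has a direction consistent with its frequencies
  sig <- res[res$significant == TRUE, ]
  expect_true(all(!is.na(sig$direction)))
  expect_true(all((sig$freq_a > sig$freq_b) ==
                    (sig$direction == "GROUP_A_ENRICHED")))
})
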