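distinct_sheet <- function(genes, lib = "L1", batch = 1L, plate = 1L,
                           direction = "5") {
  structure(list(library_id = lib, batch = batch, plate = plate,
                 direction = direction, slots = genes),
            class = "plate_sheet")
}

test_that("match matrices: identity, disjoint sets, nulls never match", {
  genes <- sprintf("g%03d", 0:95)
  M <- match_matrix(genes, genes)
  expect_true(all(diag(M$cells)))
  expect_equal(sum(M$cells), 96L)  # distinct ids -> exactly the diagonal

  M2 <- match_matrix(genes, paste0("other_", genes))
  expect_false(any(M2$cells))

  withnull <- genes; withnull[5] <- NA
  M3 <- match_matrix(withnull, withnull)
  expect_false(M3$cells[5, 5])
  expect_equal(sum(M3$cells), 95L)

  # shift by +1: full off-diagonal at offset 1, verified cell by cell
  shifted <- c(genes[-1], "tail")
  M4 <- match_matrix(genes, shifted)
  for (i in 1:20) expect_true(M4$cells[i + 1, i])
  segs <- detect_diagonals(M4)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$offset, -1L)
  expect_equal(segs$n_matches, 95L)
})

test_that("detect_diagonals finds identity and piecewise-slip segments", {
  genes <- sprintf("g%03d", 0:95)
  segs <- detect_diagonals(match_matrix(genes, genes))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$offset, 0L)
  expect_equal(segs$length, 96L)

  # wells 0-39 align at offset 0, wells 40-95 at offset +1 (well slip:
  # the 5' well A9 gene appearing at the 3' well A10, scaled up)
  b <- rep(NA_character_, 96L)
  b[1:40] <- genes[1:40]
  b[42:96] <- genes[41:95]
  segs2 <- detect_diagonals(match_matrix(genes, b))
  expect_equal(sort(segs2$offset), c(0L, 1L))
  expect_equal(segs2[segs2$offset == 1L, ]$n_matches, 55L)

  # a lone shared null is not a match: the diagonal run has a gap there
  a <- c("x", NA, "y", "z", "w")
  seg <- detect_diagonals(match_matrix(a, a), min_run = 2L,
                          exclude_abundant = FALSE)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_matches, 4L)  # the NA cell is never a match
})

test_that("detect_diagonals equals brute-force enumeration", {
  set.seed(19)
  for (trial in 1:12) {
    n <- sample(20:96, 1L)
    pool <- sprintf("g%02d", 1:25)
    a <- sample(pool, n, replace = TRUE)
    b <- sample(pool, n, replace = TRUE)
    a[runif(n) < 0.15] <- NA
    b[runif(n) < 0.15] <- NA
    min_run <- sample(2:5, 1L)
    max_gap <- sample(0:3, 1L)
    M <- match_matrix(a, b)
    got <- detect_diagonals(M, min_run = min_run, max_gap = max_gap,
                            exclude_abundant = FALSE)
    want <- oracle_diagonals(M$cells, min_run, max_gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_i, want$start_i)
      expect_equal(got$offset, want$offset)
      expect_equal(got$n_matches, want$n_matches)
    }
  }
})

test_that("classification covers the threshold bands and is symmetric", {
  genes <- sprintf("g%03d", 0:95)
  f <- distinct_sheet(genes, direction = "5")
  r <- distinct_sheet(genes, direction = "3")
  expect_equal(classify_relation(f, r)$kind, "CORRECT_PAIR")
  expect_equal(classify_relation(r, f)$kind, "CORRECT_PAIR")

  # swap candidate: complementary directions, different annotated plates
  r4 <- distinct_sheet(genes, plate = 4L, direction = "3")
  rel <- classify_relation(f, r4)
  expect_equal(rel$kind, "SWAP_CANDIDATE")
  rel_flip <- classify_relation(r4, f)
  expect_equal(rel_flip$kind, rel$kind)
  expect_equal(rel_flip$matched_fraction, rel$matched_fraction)

  # same-direction duplicate
  f2 <- distinct_sheet(genes, plate = 2L, direction = "5")
  expect_equal(classify_relation(f, f2)$kind, "DUPLICATE")

  # well slip: offset changes mid-plate
  slipped <- rep(NA_character_, 96L)
  slipped[1:40] <- genes[1:40]
  slipped[42:96] <- genes[41:95]
  rs <- distinct_sheet(slipped, direction = "3")
  expect_equal(classify_relation(f, rs)$kind, "WELL_SLIP")

  # partial duplicate band
  half <- c(genes[1:48], paste0("other_", 49:96))
  p2 <- distinct_sheet(half, plate = 2L, direction = "5")
  expect_equal(classify_relation(f, p2)$kind, "PARTIAL_DUPLICATE")

  # low-evidence: too few comparable wells
  sparse_a <- distinct_sheet(c(genes[1:5], rep(NA, 91L)))
  sparse_b <- distinct_sheet(c(genes[1:5], rep(NA, 91L)), plate = 2L)
  rel_low <- classify_relation(sparse_a, sparse_b)
  expect_equal(rel_low$kind, "UNMATCHED")
  expect_true(rel_low$low_evidence)
})

test_that("random unrelated plates stay near the collision expectation", {
  # matched fraction of unrelated plates ~ per-cell collision probability
  # sum(p_g^2) of the abundance distribution; far below t_partial
  set.seed(29)
  tr <- simulate_transcriptome(n_genes = 5000L)
  p <- tr$probs[, 1L]
  collision <- sum(p^2)
  fracs <- replicate(20, {
    a <- sample(names(p), 96L, prob = p, replace = TRUE)
    b <- sample(names(p), 96L, prob = p, replace = TRUE)
    mean(a == b)
  })
  expect_lt(mean(fracs), collision + 3 * sqrt(collision / (96 * 20)))
  rel <- classify_relation(
    distinct_sheet(sample(names(p), 96L, prob = p, replace = TRUE)),
    distinct_sheet(sample(names(p), 96L, prob = p, replace = TRUE),
                   plate = 2L))
  expect_equal(rel$kind, "UNMATCHED")
})

test_that("clean libraries yield exactly the annotated pairs", {
  fx <- end_to_end_fixture("clean", seed = 4)
  rels <- scan_catalog(fx$catalog)
  expect_equal(sum(rels$kind == "CORRECT_PAIR"), 8L)  # 2 batches x 4 plates
  expect_true(all(rels$kind %in% c("CORRECT_PAIR", "UNMATCHED")))
})

test_that("single-direction libraries produce no pairs and no false calls", {
  set.seed(31)
  tr <- simulate_transcriptome(n_genes = 2000L)
  sim <- simulate_library(tr$probs[, 1L],
                          library_plan("L1", "leaf", orientation = "5",
                                       n_batches = 2L))
  rels <- scan_catalog(est_catalog(sim$reads, sim$library))
  expect_equal(sum(rels$kind != "UNMATCHED"), 0L)
})

test_that("an injected duplicated plate is recovered and the plan removes it", {
  set.seed(37)
  tr <- simulate_transcriptome(n_genes = 2000L)
  sim <- simulate_library(tr$probs[, 1L],
                          library_plan("L1", "leaf", bidirectional = 1,
                                       misannotation = 0))
  cat0 <- est_catalog(sim$reads, sim$library)
  inj <- inject_errors(cat0, list(list(type = "PLATE_DUPLICATE",
                                       library = "L1", batch = 1L,
                                       plate = 2L)))
  rels <- scan_catalog(inj$catalog)
  plan <- build_correction_plan(rels)
  expect_length(plan$duplicates, 1L)
  expect_setequal(unlist(plan$duplicates[[1]]),
                  c("L1|b01|p2", "L1|b02|p1"))
  corrected <- apply_correction_plan(inj$catalog, plan)
  delta <- attr(corrected, "read_delta")
  expect_equal(delta$removed, 192L)  # one bidirectional plate's reads
  # unique clones return to the generator truth
  tab <- collapse_clones(group_clones(inj$catalog, plan))
  expect_equal(tab$totals$total_unique, sim$truth$n_unique_clones)
})

test_that("plans never increase counts and leave untouched plates alone", {
  fx <- end_to_end_fixture("table2_mixed", seed = 9)
  plan <- build_correction_plan(scan_catalog(fx$catalog))
  corrected <- apply_correction_plan(fx$catalog, plan)
  expect_true(all(attr(corrected, "read_delta")$removed >= 0L))
  # the corrected unique totals return to the generator truth: 2 batches x
  # 4 plates x 96 wells per library, minus the 48 berry wells that the
  # partial duplication overwrote with re-picked clones
  tab <- collapse_clones(group_clones(fx$catalog, plan))
  expect_equal(tab$totals$total_unique[tab$totals$library_id == "LEAF01"],
               768L)
  expect_equal(tab$totals$total_unique[tab$totals$library_id == "BERRY01"],
               720L)
  # untouched plate: LEAF01 batch 2 plate 3 is never injected or planned
  before <- fx$catalog$reads[fx$catalog$reads$library_id == "LEAF01" &
                               fx$catalog$reads$batch == 2L &
                               fx$catalog$reads$plate == 3L, ]
  after <- corrected$reads[corrected$reads$library_id == "LEAF01" &
                             corrected$reads$batch == 2L &
                             corrected$reads$plate == 3L, ]
  expect_equal(nrow(after), nrow(before))
  expect_setequal(after$read_id, before$read_id)
})

test_that("empty relation lists yield empty plans", {
  plan <- build_correction_plan(NULL)
  expect_length(plan$actions, 0L)
  reads <- full_plate_reads()
  cat0 <- est_catalog(reads)
  corrected <- apply_correction_plan(cat0, plan)
  expect_equal(nrow(corrected$reads), nrow(cat0$reads))
  expect_equal(attr(corrected, "read_delta")$removed, 0L)
})

test_that("contradictory duplicate evidence excludes the component", {
  genes <- sprintf("g%03d", 0:95)
  other <- sprintf("h%03d", 0:95)
  mixed <- c(genes[1:90], other[91:96])
  # A ~ B and A ~ C but B !~ C at full threshold is impossible for honest
  # content; fabricate relations directly to exercise the guard
  rel <- rbind(
    classify_relation(distinct_sheet(genes, plate = 1L),
                      distinct_sheet(genes, plate = 2L)),
    classify_relation(distinct_sheet(genes, plate = 1L),
                      distinct_sheet(mixed, plate = 3L)))
  rel$kind <- "DUPLICATE"
  expect_warning(plan <- build_correction_plan(rel), "contradictory")
  expect_length(plan$unresolved, 1L)
  expect_true(all(vapply(plan$actions, function(a) a$type, "") ==
                    "EXCLUDE_PLATE"))
})
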