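test_that("transcriptome simulation: DE scaling, determinism, errors", {
  tr0 <- simulate_transcriptome(n_genes = 1000L, groups = c("A", "B"),
                                seed = 1)
  expect_equal(tr0$probs[, "A"], tr0$probs[, "B"])  # no DE -> identical
  expect_equal(colSums(tr0$probs), c(A = 1, B = 1))

  fc <- list(A = c(G00007 = 8))
  tr1 <- simulate_transcriptome(n_genes = 1000L, groups = c("A", "B"),
                                fold_changes = fc, seed = 1)
  ratio <- (tr1$probs["G00007", "A"] / tr1$probs["G00007", "B"])
  # 8-fold before renormalization drift; drift is the total mass inflation
  expect_equal(ratio * (1 + 7 * tr0$probs["G00007", "A"]), 8,
               tolerance = 1e-12)

  tr2 <- simulate_transcriptome(n_genes = 1000L, groups = c("A", "B"),
                                fold_changes = fc, seed = 1)
  expect_identical(tr1$probs, tr2$probs)
  expect_error(simulate_transcriptome(10L, fold_changes = list(A = c(bad = 2)),
                                      groups = "A"), "unknown gene")
})

test_that("library simulation obeys the plate arithmetic", {
  tr <- simulate_transcriptome(n_genes = 500L, seed = 3)
  sim <- simulate_library(tr$probs[, 1L],
                          library_plan("L1", "leaf", n_batches = 4L,
                                       bidirectional = 1), seed = 3)
  expect_equal(sim$truth$n_unique_clones, 1536L)  # 4 x 4 x 96
  expect_equal(nrow(sim$reads), 3072L)            # one 5' + one 3' each
  # one clone per well, no reuse
  expect_equal(anyDuplicated(sim$truth$clones[, c("batch", "plate",
                                                  "well_index")]), 0L)
  # byte-identical catalogs under the same seed
  sim2 <- simulate_library(tr$probs[, 1L],
                           library_plan("L1", "leaf", n_batches = 4L,
                                        bidirectional = 1), seed = 3)
  expect_identical(sim$reads, sim2$reads)
})

test_that("generator truth equals redundancy collapse on clean catalogs", {
  for (s in c(2, 9)) {
    tr <- simulate_transcriptome(n_genes = 400L, seed = s)
    sim <- simulate_library(tr$probs[, 1L],
                            library_plan("L1", "leaf", n_batches = 2L),
                            seed = s)
    tab <- collapse_clones(group_clones(est_catalog(sim$reads, sim$library)))
    expect_equal(tab$totals$total_unique, sim$truth$n_unique_clones)
  }
})

test_that("normalization flattening raises the singleton fraction", {
  tr <- simulate_transcriptome(n_genes = 5000L, seed = 13)
  singleton_fraction <- function(gamma, seed) {
    sim <- simulate_library(tr$probs[, 1L],
                            library_plan("LN", "root", n_batches = 4L,
                                         orientation = "5",
                                         misannotation = 0,
                                         gamma = gamma), seed = seed)
    counts <- table(sim$truth$clones$true_gene)
    sum(counts == 1L) / length(counts)
  }
  # paired seeds: flattened libraries find more singletons at equal depth
  diffs <- vapply(1:5, function(s) {
    singleton_fraction(0.5, s) - singleton_fraction(1, s)
  }, numeric(1L))
  expect_true(all(diffs > 0))
})

test_that("well-slip injection reproduces the A9/A10 signature", {
  tr <- simulate_transcriptome(n_genes = 3000L, seed = 17)
  sim <- simulate_library(tr$probs[, 1L],
                          library_plan("L1", "leaf", bidirectional = 1,
                                       misannotation = 0), seed = 17)
  cat0 <- est_catalog(sim$reads, sim$library)
  inj <- inject_errors(cat0, list(list(
    type = "WELL_SLIP", library = "L1", batch = 1L, plate = 1L,
    start_well = "A9", offset = 1L)))
  sheets <- build_plate_sheets(inj$catalog, "L1")
  s5 <- sheets[["L1|b01|p1|5"]]$slots
  s3 <- sheets[["L1|b01|p1|3"]]$slots
  a9 <- well_order_index("A", 9) + 1L
  expect_equal(s5[a9], s3[a9 + 1L])        # A9 (5') == A10 (3')
  expect_equal(s5[a9 + 1L], s3[a9 + 2L])   # A10 (5') == A11 (3')
  expect_true(is.na(s3[a9]))               # the slipped-over well is empty
  expect_equal(s5[1:8], s3[1:8])           # before the slip: aligned
})

test_that("duplication adds reads but leaves the clone truth unchanged", {
  tr <- simulate_transcriptome(n_genes = 800L, seed = 23)
  sim <- simulate_library(tr$probs[, 1L],
                          library_plan("L1", "leaf", bidirectional = 1,
                                       misannotation = 0), seed = 23)
  cat0 <- est_catalog(sim$reads, sim$library)
  inj <- inject_errors(cat0, list(list(type = "PLATE_DUPLICATE",
                                       library = "L1", batch = 1L,
                                       plate = 3L)))
  expect_equal(nrow(inj$catalog$reads), nrow(cat0$reads) + 192L)
  expect_equal(inj$truth$expected[[1]]$type, "DUPLICATE")
  # a pair swap makes annotated 3f truly pair with 4r
  inj2 <- inject_errors(cat0, list(list(type = "PAIR_SWAP", library = "L1",
                                        batch = 1L, plates = c(3L, 4L))))
  sheets <- build_plate_sheets(inj2$catalog, "L1")
  expect_equal(sheets[["L1|b01|p3|5"]]$slots,
               sheets[["L1|b01|p4|3"]]$slots)
  expect_equal(nrow(inj2$catalog$reads), nrow(cat0$reads))
})

test_that("fixtures are seed-deterministic and reject unknown scenarios", {
  f1 <- end_to_end_fixture("clean", seed = 8)
  f2 <- end_to_end_fixture("clean", seed = 8)
  expect_identical(f1$catalog$reads, f2$catalog$reads)
  expect_error(end_to_end_fixture("nope", seed = 1), "valid")
  td <- withr::local_tempdir()
  f3 <- end_to_end_fixture("clean", seed = 8, dir = td)
  expect_true(file.exists(f3$paths$catalog))
  expect_true(file.exists(f3$paths$truth))
  reread <- read_est_catalog(f3$paths$catalog, f3$paths$libraries)
  expect_equal(nrow(reread$reads), nrow(f1$catalog$reads))
})
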