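# Synthetic EST catalogs with exact ground truth.
#
# The generator emulates the structure of clone-named dbEST libraries: a
# transcriptome with log-normal abundances, clones picked into 96-well
# plates grouped in batches (generally four plates, I-IV, per batch), ~80%
# of plates sequenced bidirectionally, a per-read gene-misannotation rate
# calibrated so clone pairs disagree ~8% of the time, optional normalization
# flattening (p' proportional to p^gamma),
# and a taxonomy of injectable bookkeeping errors (well slips, plate
# duplication/triplication, pair swaps, partial duplications, cross-library
# plate copies). Every stochastic choice is recorded in a truth ledger so
# detectors and estimators can be scored exactly.

#' Simulate per-group transcriptome sampling probabilities
#'
#' Gene abundances are log-normal (default sdlog 1.5 over 5,000 genes,
#' which yields singleton fractions comparable to real normalized libraries
#' when combined with gamma ~ 0.5 flattening). Designated DE genes have
#' their baseline probability multiplied by a fold change in their group,
#' then each group's vector is renormalized.
#'
#' @param n_genes number of genes.
#' @param meanlog,sdlog log-normal abundance parameters.
#' @param groups character vector of group labels (>= 1).
#' @param fold_changes named list: group label -> named numeric vector of
#'   fold changes (names are gene ids `G00001`...).
#' @param baseline_share optional named numeric: gene id -> fixed baseline
#'   sampling probability (remaining genes share the rest proportionally to
#'   their drawn abundance).
#' @param seed optional integer seed.
#' @return a `transcriptome_model`: list with `gene_ids`, `probs` (genes x
#'   groups probability matrix, columns sum to 1), `fold_changes`.
#' @export
simulate_transcriptome <- function(n_genes = 5000L, meanlog = 0,
                                   sdlog = 1.5, groups = "A",
                                   fold_changes = NULL,
                                   baseline_share = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  ab <- rlnorm(n_genes, meanlog, sdlog)
  if (any(ab <= 0) || anyNA(ab)) stop("nonpositive abundance", call. = FALSE)
  p <- ab / sum(ab)
  if (!is.null(baseline_share)) {
    fixed <- match(names(baseline_share), gene_ids)
    if (anyNA(fixed)) stop("unknown gene id in baseline_share", call. = FALSE)
    if (sum(baseline_share) >= 1) stop("baseline shares must sum to < 1",
                                       call. = FALSE)
    p[fixed] <- 0
    p <- p / sum(p) * (1 - sum(baseline_share))
    p[fixed] <- baseline_share
  }
  probs <- matrix(p, nrow = n_genes, ncol = length(groups),
                  dimnames = list(gene_ids, groups))
  for (g in names(fold_changes)) {
    fc <- fold_changes[[g]]
    idx <- match(names(fc), gene_ids)
    if (anyNA(idx)) stop("unknown gene id in fold_changes", call. = FALSE)
    probs[idx, g] <- probs[idx, g] * fc
    probs[, g] <- probs[, g] / sum(probs[, g])
  }
  structure(list(gene_ids = gene_ids, probs = probs,
                 fold_changes = fold_changes),
            class = "transcriptome_model")
}

#' Describe one synthetic library's sequencing plan
#'
#' @param library_id library identifier.
#' @param group_label tissue/condition group.
#' @param stem clone-name library stem (letters, must end in a letter).
#' @param n_batches batches of plates (default 1).
#' @param plates_per_batch plates per batch (default 4, plates I-IV).
#' @param bidirectional fraction of plates sequenced from both 5' and 3'
#'   ends (default 0.8, drawn per plate); ignored unless
#'   `orientation = "both"`.
#' @param misannotation per-read probability that the assigned gene id is
#'   flipped to a random other gene. The default 0.04 reproduces the ~7-9%
#'   *within-clone* disagreement rate real bidirectional libraries show
#'   (two reads conflict when either is flipped: `2q(1-q) + q^2` is about
#'   0.08 at q = 0.04).
#' @param orientation `"both"`, `"5"`, `"3"`, or `"n.d."` (unknown
#'   direction).
#' @param normalized normalization flag; when TRUE clone sampling uses
#'   `p^gamma` (renormalized), flattening abundance differences.
#' @param gamma flattening exponent in (0, 1]; 1 = unnormalized.
#' @return a `library_plan` list.
#' @export
library_plan <- function(library_id, group_label, stem = "SYN",
                         n_batches = 1L, plates_per_batch = 4L,
                         bidirectional = 0.8, misannotation = 0.04,
                         orientation = "both", normalized = FALSE,
                         gamma = 1) {
  stopifnot(gamma > 0, gamma <= 1, bidirectional >= 0, bidirectional <= 1,
            misannotation >= 0, misannotation <= 1,
            grepl("[A-Za-z]$", stem))
  structure(list(library_id = library_id, group_label = group_label,
                 stem = stem, n_batches = as.integer(n_batches),
                 plates_per_batch = as.integer(plates_per_batch),
                 bidirectional = bidirectional,
                 misannotation = misannotation, orientation = orientation,
                 normalized = normalized, gamma = gamma),
            class = "library_plan")
}

#' Simulate one plated library
#'
#' Clones are drawn i.i.d. from the (possibly flattened) abundance vector
#' and placed at the next free well (one clone per well, no reuse across
#' batches); bidirectional plates emit one 5' and one 3' read per clone.
#' With probability `misannotation` a read's gene id is flipped to a random
#' other gene; misannotated reads get a lower-mean confidence score so
#' confidence-based arbitration has signal.
#'
#' @param probs named probability vector over gene ids (one transcriptome
#'   group column).
#' @param plan a [library_plan()].
#' @param seed optional integer seed.
#' @return list with `$reads` (catalog rows), `$library` (metadata row),
#'   `$truth` (clone -> true gene table, plate table, plan).
#' @export
simulate_library <- function(probs, plan, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(probs)
  p <- probs^plan$gamma
  p <- p / sum(p)
  plates <- CJ(batch = seq_len(plan$n_batches),
               plate = seq_len(plan$plates_per_batch))
  plates[, bidirectional := switch(plan$orientation,
                                   both = runif(.N) < plan$bidirectional,
                                   rep(FALSE, .N))]
  n_clones <- nrow(plates) * 96L
  clone_gene <- sample(genes, n_clones, replace = TRUE, prob = p)
  wells <- data.table(
    batch = rep(plates$batch, each = 96L),
    plate = rep(plates$plate, each = 96L),
    well_index = rep(0:95, nrow(plates)),
    true_gene = clone_gene,
    bidir = rep(plates$bidirectional, each = 96L))
  base_dir <- switch(plan$orientation, both = "5", `5` = "5", `3` = "3",
                     "unknown")
  reads <- rbind(
    copy(wells)[, direction := base_dir],
    wells[bidir == TRUE][, direction := "3"])
  setorder(reads, batch, plate, well_index, direction)
  n <- nrow(reads)
  # misannotation: symmetric random flip to one of the other genes
  flip <- runif(n) < plan$misannotation
  wrong <- sample(genes, n, replace = TRUE)
  # redraw collisions with the true gene so "wrong" really is wrong
  while (any(bad <- flip & wrong == reads$true_gene)) {
    wrong[bad] <- sample(genes, sum(bad), replace = TRUE)
  }
  reads[, gene_id := fifelse(flip, wrong, true_gene)]
  reads[, confidence := round(fifelse(flip, runif(n, 100, 700),
                                      runif(n, 400, 1000)), 1)]
  reads[, `:=`(well_row = LETTERS[well_index %/% 12L + 1L],
               well_col = well_index %% 12L + 1L)]
  dir_suffix <- c(`5` = ", 5'end", `3` = ", 3'end", unknown = "")
  reads[, clone_name := paste0(
    sprintf("%s%02d%s-%s%d", plan$stem, batch, .PLATE_ROMAN[plate],
            well_row, well_col), dir_suffix[direction])]
  reads[, read_id := sprintf("%s_r%06d", plan$library_id, seq_len(.N))]
  reads[, library_id := plan$library_id]
  out_cols <- c("read_id", "library_id", "clone_name", "direction",
                "gene_id", "confidence")
  truth <- list(
    clones = wells[, .(batch, plate, well_index, true_gene)],
    plates = plates,
    n_unique_clones = n_clones,
    plan = plan)
  list(reads = reads[, out_cols, with = FALSE],
       library = data.table(library_id = plan$library_id,
                            group_label = plan$group_label,
                            orientation = plan$orientation,
                            normalized = plan$normalized),
       truth = truth)
}

.rebuild_names <- function(rr, sel) {
  dir_suffix <- c(`5` = ", 5'end", `3` = ", 3'end", unknown = "")
  rr[sel, `:=`(well_row = LETTERS[well_index %/% 12L + 1L],
               well_col = well_index %% 12L + 1L)]
  rr[sel, clone_name := paste0(
    sprintf("%s%02d%s-%s%d", stem, batch, .PLATE_ROMAN[plate],
            well_row, well_col), dir_suffix[direction])]
  rr
}

.copy_plate <- function(rr, lib, batch_, plate_, dst_lib, dst_stem,
                        dst_batch, dst_plate, direction = NULL, tag) {
  sel <- rr$library_id == lib & rr$batch == batch_ & rr$plate == plate_ &
    !is.na(rr$well_index)
  if (!is.null(direction)) sel <- sel & rr$direction == direction
  cp <- copy(rr[sel])
  if (nrow(cp) == 0L) stop("injection source plate has no reads",
                           call. = FALSE)
  cp[, `:=`(library_id = dst_lib, stem = dst_stem, batch = dst_batch,
            plate = dst_plate)]
  cp[, read_id := sprintf("%s_%s%04d", dst_lib, tag, seq_len(.N))]
  .rebuild_names(cp, rep(TRUE, nrow(cp)))
  cp
}

#' Inject plate-level bookkeeping errors into a catalog
#'
#' Each injection is applied literally to an already-generated catalog so
#' the truth stays exact:
#' * `WELL_SLIP(library, batch, plate, start_well, offset)` - shifts the 3'
#'   plate's well labels by `offset` from `start_well` onward (reads pushed
#'   past H12 are dropped);
#' * `PLATE_DUPLICATE(library, batch, plate, dst_batch, dst_plate)` -
#'   appends a copy of the plate's reads under a new plate annotation;
#' * `PLATE_TRIPLICATE(...)` - two such copies;
#' * `PAIR_SWAP(library, batch, plates = c(a, b))` - exchanges the two
#'   plates' 3' annotations, so annotated `af` truly pairs with `br`;
#' * `PARTIAL_DUPLICATE(library, batch, plate, dst_batch, dst_plate,
#'   fraction)` - overwrites the first `round(96 * fraction)` wells of an
#'   existing plate with the source plate's clones;
#' * `CROSS_LIBRARY_COPY(library, batch, plate, dst_library)` - appends a
#'   single-direction (3') copy of the plate to another library under that
#'   library's stem.
#'
#' @param catalog an [est_catalog()].
#' @param injections list of injection specs (lists with `$type` and the
#'   parameters above).
#' @return list with `$catalog` (corrupted) and `$truth` - the resolved
#'   injections plus, for scoring, the plate nodes / sheets each detector
#'   should flag (`$expected`).
#' @export
inject_errors <- function(catalog, injections) {
  rr <- copy(catalog$reads)
  expected <- list()
  resolved <- list()
  node <- function(lib, b, p) sprintf("%s|b%02d|p%d", lib, b, p)
  for (inj in injections) {
    type <- inj$type
    if (type == "WELL_SLIP") {
      start_idx <- well_order_index(substr(inj$start_well, 1L, 1L),
                                    as.integer(substring(inj$start_well, 2L)))
      sel <- rr$library_id == inj$library & rr$batch == inj$batch &
        rr$plate == inj$plate & rr$direction == "3" &
        !is.na(rr$well_index) & rr$well_index >= start_idx
      if (!any(sel)) stop("WELL_SLIP target has no 3' reads", call. = FALSE)
      rr[sel, well_index := well_index + inj$offset]
      rr <- rr[!(rr$library_id == inj$library & rr$batch == inj$batch &
                   rr$plate == inj$plate & rr$direction == "3" &
                   !is.na(rr$well_index) &
                   (rr$well_index > 95L | rr$well_index < 0L))]
      sel2 <- rr$library_id == inj$library & rr$batch == inj$batch &
        rr$plate == inj$plate & rr$direction == "3" & !is.na(rr$well_index)
      rr <- .rebuild_names(rr, sel2)
      expected[[length(expected) + 1L]] <- list(
        type = "WELL_SLIP",
        sheet = sheet_id(inj$library, inj$batch, inj$plate, "3"))
    } else if (type %in% c("PLATE_DUPLICATE", "PLATE_TRIPLICATE")) {
      n_copies <- if (type == "PLATE_TRIPLICATE") 2L else 1L
      dst_batch <- if (!is.null(inj$dst_batch)) inj$dst_batch else
        max(rr[rr$library_id == inj$library & !is.na(rr$batch), batch]) + 1L
      dst_plates <- if (!is.null(inj$dst_plate)) inj$dst_plate else
        seq_len(n_copies)
      stopifnot(length(dst_plates) == n_copies)
      st <- rr[rr$library_id == inj$library & rr$batch == inj$batch &
                 rr$plate == inj$plate, stem][1L]
      nodes <- node(inj$library, inj$batch, inj$plate)
      for (ci in seq_len(n_copies)) {
        cp <- .copy_plate(rr, inj$library, inj$batch, inj$plate,
                          inj$library, st, dst_batch, dst_plates[ci],
                          tag = sprintf("dup%02d%d", dst_batch, ci))
        rr <- rbind(rr, cp)
        nodes <- c(nodes, node(inj$library, dst_batch, dst_plates[ci]))
      }
      expected[[length(expected) + 1L]] <- list(
        type = if (n_copies == 1L) "DUPLICATE" else "TRIPLICATE",
        nodes = nodes)
    } else if (type == "PAIR_SWAP") {
      pa <- inj$plates[1L]; pb <- inj$plates[2L]
      sel_a <- rr$library_id == inj$library & rr$batch == inj$batch &
        rr$plate == pa & rr$direction == "3" & !is.na(rr$well_index)
      sel_b <- rr$library_id == inj$library & rr$batch == inj$batch &
        rr$plate == pb & rr$direction == "3" & !is.na(rr$well_index)
      if (!any(sel_a) || !any(sel_b)) {
        stop("PAIR_SWAP targets need 3' reads on both plates", call. = FALSE)
      }
      rr[sel_a, plate := pb]
      rr[sel_b, plate := pa]
      rr <- .rebuild_names(rr, sel_a | sel_b)
      expected[[length(expected) + 1L]] <- list(
        type = "SWAP",
        pairs = list(
          c(five = sheet_id(inj$library, inj$batch, pa, "5"),
            three = sheet_id(inj$library, inj$batch, pb, "3")),
          c(five = sheet_id(inj$library, inj$batch, pb, "5"),
            three = sheet_id(inj$library, inj$batch, pa, "3"))))
    } else if (type == "PARTIAL_DUPLICATE") {
      k <- round(96 * inj$fraction)
      src <- rr[rr$library_id == inj$library & rr$batch == inj$batch &
                  rr$plate == inj$plate & !is.na(rr$well_index) &
                  rr$well_index < k]
      src_gene <- src[direction == direction[1L]][order(well_index)]
      gmap <- setNames(src_gene$gene_id, src_gene$well_index)
      sel <- rr$library_id == inj$library & rr$batch == inj$dst_batch &
        rr$plate == inj$dst_plate & !is.na(rr$well_index) &
        rr$well_index < k &
        as.character(rr$well_index) %chin% names(gmap)
      if (!any(sel)) stop("PARTIAL_DUPLICATE destination has no reads",
                          call. = FALSE)
      rr[sel, gene_id := gmap[as.character(well_index)]]
      expected[[length(expected) + 1L]] <- list(
        type = "PARTIAL",
        nodes = c(node(inj$library, inj$batch, inj$plate),
                  node(inj$library, inj$dst_batch, inj$dst_plate)))
    } else if (type == "CROSS_LIBRARY_COPY") {
      dst_stem <- rr[rr$library_id == inj$dst_library & !is.na(rr$stem),
                     stem][1L]
      dst_batch <- max(rr[rr$library_id == inj$dst_library &
                            !is.na(rr$batch), batch]) + 1L
      cp <- .copy_plate(rr, inj$library, inj$batch, inj$plate,
                        inj$dst_library, dst_stem, dst_batch, 1L,
                        direction = "3", tag = sprintf("xl%02d", dst_batch))
      rr <- rbind(rr, cp)
      expected[[length(expected) + 1L]] <- list(
        type = "CROSS_LIBRARY",
        exclude_node = node(inj$dst_library, dst_batch, 1L),
        src_node = node(inj$library, inj$batch, inj$plate))
    } else {
      stop("unknown injection type: ", type, call. = FALSE)
    }
    resolved[[length(resolved) + 1L]] <- inj
  }
  out <- structure(list(reads = rr[], libraries = catalog$libraries),
                   class = "est_catalog")
  list(catalog = out, truth = list(injections = resolved,
                                   expected = expected))
}

#' Generate a named end-to-end scenario
#'
#' Scenarios (all sized to run the full pipeline in well under a minute):
#' * `"clean"` - one bidirectional 2-batch library, no injected errors;
#' * `"table2_mixed"` - a leaf and a berry library carrying one instance of
#'   every injectable error class;
#' * `"root_vs_nonroot"` - count-scale root (18,109 clones) vs non-root
#'   (291,233 clones) libraries with 50 genes enriched 8-fold in root,
#'   baseline abundances chosen so expected root counts span ~10-60 (the
#'   range real root-enriched tag tables report); no plate metadata (the
#'   comparison needs only counts);
#' * `"four_group_de"` - four tissue/stress groups, 40 genes enriched
#'   8-fold per group, for clustering recovery.
#'
#' @param scenario one of the names above.
#' @param seed integer seed; identical seeds give byte-identical catalogs.
#' @param dir optional directory; when given, `catalog.tsv`,
#'   `libraries.tsv` and `truth.json` are written there.
#' @return list with `$catalog`, `$truth`, and (if written) `$paths`.
#' @export
end_to_end_fixture <- function(scenario, seed = 1L, dir = NULL) {
  scenarios <- c("clean", "table2_mixed", "root_vs_nonroot", "four_group_de")
  if (!scenario %in% scenarios) {
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(scenarios, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  out <- switch(scenario,
                clean = .fixture_clean(),
                table2_mixed = .fixture_table2(),
                root_vs_nonroot = .fixture_root(),
                four_group_de = .fixture_four_group())
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(catalog = file.path(dir, "catalog.tsv"),
                  libraries = file.path(dir, "libraries.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_est_catalog(out$catalog, paths$catalog, paths$libraries)
    jsonlite::write_json(out$truth, paths$truth, auto_unbox = TRUE,
                         dataframe = "rows", force = TRUE)
    out$paths <- paths
  }
  out
}

.fixture_clean <- function() {
  tr <- simulate_transcriptome(n_genes = 2000L)
  plan <- library_plan("CLEAN01", "leaf", stem = "CLNA", n_batches = 2L,
                       bidirectional = 1)
  sim <- simulate_library(tr$probs[, 1L], plan)
  list(catalog = est_catalog(sim$reads, sim$library),
       truth = list(scenario = "clean", library = sim$truth$n_unique_clones,
                    expected = list()))
}

.fixture_table2 <- function() {
  tr <- simulate_transcriptome(n_genes = 2000L)
  leaf <- simulate_library(tr$probs[, 1L],
                           library_plan("LEAF01", "leaf", stem = "LFA",
                                        n_batches = 2L, bidirectional = 1))
  berry <- simulate_library(tr$probs[, 1L],
                            library_plan("BERRY01", "berry", stem = "BRA",
                                         n_batches = 2L, bidirectional = 1))
  catalog <- est_catalog(rbind(leaf$reads, berry$reads),
                         rbind(leaf$library, berry$library))
  injections <- list(
    list(type = "WELL_SLIP", library = "LEAF01", batch = 1L, plate = 1L,
         start_well = "A9", offset = 1L),
    list(type = "PAIR_SWAP", library = "LEAF01", batch = 1L,
         plates = c(3L, 4L)),
    list(type = "PLATE_DUPLICATE", library = "LEAF01", batch = 2L,
         plate = 1L),
    list(type = "PLATE_TRIPLICATE", library = "BERRY01", batch = 1L,
         plate = 2L),
    list(type = "PARTIAL_DUPLICATE", library = "BERRY01", batch = 2L,
         plate = 1L, dst_batch = 2L, dst_plate = 2L, fraction = 0.5),
    list(type = "CROSS_LIBRARY_COPY", library = "BERRY01", batch = 2L,
         plate = 3L, dst_library = "LEAF01"))
  inj <- inject_errors(catalog, injections)
  inj$truth$scenario <- "table2_mixed"
  list(catalog = inj$catalog, truth = inj$truth)
}

# reads without plate metadata, drawn in one multinomial per library
.counts_library <- function(probs, library_id, group_label, size,
                            normalized = FALSE) {
  counts <- as.vector(stats::rmultinom(1L, size, probs))
  genes <- rep(names(probs), counts)
  data.table(
    read_id = sprintf("%s_r%06d", library_id, seq_len(size)),
    library_id = library_id, clone_name = NA_character_,
    direction = "5", gene_id = genes,
    confidence = 900)
}

.fixture_root <- function() {
  n_de <- 50L
  de_genes <- sprintf("G%05d", 1:n_de)
  baseline <- setNames(seq(7e-5, 4e-4, length.out = n_de), de_genes)
  tr <- simulate_transcriptome(
    n_genes = 5000L, groups = c("root", "non_root"),
    fold_changes = list(root = setNames(rep(8, n_de), de_genes)),
    baseline_share = baseline)
  root <- .counts_library(tr$probs[, "root"], "ROOT01", "root", 18109L,
                          normalized = TRUE)
  nr_sizes <- c(NONROOT01 = 100000L, NONROOT02 = 100000L,
                NONROOT03 = 91233L)
  nonroot <- rbindlist(lapply(names(nr_sizes), function(lib) {
    .counts_library(tr$probs[, "non_root"], lib, "non_root", nr_sizes[[lib]])
  }))
  libs <- data.table(
    library_id = c("ROOT01", names(nr_sizes)),
    group_label = c("root", rep("non_root", 3L)),
    orientation = "5",
    normalized = c(TRUE, rep(FALSE, 3L)))
  list(catalog = est_catalog(rbind(root, nonroot), libs),
       truth = list(scenario = "root_vs_nonroot", de_genes = de_genes,
                    fold = 8, sizes = c(root = 18109L, non_root = 291233L)))
}

.fixture_four_group <- function() {
  groups <- c("leaf", "stressed_leaf", "berry", "stressed_berry")
  n_per <- 40L
  de <- list()
  shares <- numeric()
  for (gi in seq_along(groups)) {
    ids <- sprintf("G%05d", (gi - 1L) * n_per + seq_len(n_per))
    de[[groups[gi]]] <- setNames(rep(8, n_per), ids)
    shares <- c(shares, setNames(seq(4e-4, 2e-3, length.out = n_per), ids))
  }
  tr <- simulate_transcriptome(n_genes = 2000L, groups = groups,
                               fold_changes = de, baseline_share = shares)
  reads <- rbindlist(lapply(seq_along(groups), function(gi) {
    .counts_library(tr$probs[, groups[gi]], sprintf("LIB%02d", gi),
                    groups[gi], 5000L)
  }))
  libs <- data.table(library_id = sprintf("LIB%02d", seq_along(groups)),
                     group_label = groups, orientation = "5",
                     normalized = FALSE)
  list(catalog = est_catalog(reads, libs),
       truth = list(scenario = "four_group_de", de_genes = de,
                    groups = groups))
}
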