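# Dot-plot plate curation.
#
# Two plate sheets (ordered 96-slot gene-id vectors) are compared by a binary
# match matrix, exactly as a dot plot compares two nucleotide sequences:
# M[i, j] is TRUE when slot i of one sheet and slot j of the other carry the
# same gene id. A correctly paired 5'/3' plate shows up as the main diagonal;
# "well slips" appear as off-diagonals or piecewise diagonals; duplicated,
# swapped, or cross-library plates appear as strong diagonals between sheets
# that should not match at all. Identity is judged solely on assigned gene
# ids - no sequence content is consulted.

#' Default thresholds for the plate QC scan
#'
#' `min_run` matched wells seed a diagonal, at most `max_gap` consecutive
#' mismatched/empty cells are tolerated inside a run, `t_full` and
#' `t_partial` split matched fractions into full / partial duplication, and
#' pairs with fewer than `min_comparable` jointly non-empty wells are left
#' unclassified. Genes filling more than `abundant_frac` of a sheet's wells
#' are too common to be evidence on their own and cannot seed a run.
#'
#' @param min_run minimum matched wells per diagonal segment (default 4).
#' @param max_gap maximum consecutive non-matching cells inside a run (2).
#' @param t_full matched fraction at/above which plates are duplicates (0.8).
#' @param t_partial matched fraction at/above which plates partially
#'   duplicate (0.3).
#' @param min_comparable minimum jointly non-empty wells (10).
#' @param abundant_frac sheet-occupancy fraction above which a gene cannot
#'   seed a segment (0.1).
#' @return a named list of thresholds.
#' @export
qc_thresholds <- function(min_run = 4L, max_gap = 2L, t_full = 0.80,
                          t_partial = 0.30, min_comparable = 10L,
                          abundant_frac = 0.10) {
  list(min_run = as.integer(min_run), max_gap = as.integer(max_gap),
       t_full = t_full, t_partial = t_partial,
       min_comparable = as.integer(min_comparable),
       abundant_frac = abundant_frac)
}

#' Gene-ID match matrix between two well-ordered sheets
#'
#' @param seq_a,seq_b character vectors of gene-id-or-`NA` slots (a
#'   `plate_sheet$slots` vector, or any ordered gene-id list).
#' @return a `match_matrix`: list with the logical `cells` matrix
#'   (`length(seq_a)` x `length(seq_b)`; `NA` slots never match anything,
#'   including other `NA`s) and the two input sequences.
#' @export
match_matrix <- function(seq_a, seq_b) {
  if (inherits(seq_a, "plate_sheet")) seq_a <- seq_a$slots
  if (inherits(seq_b, "plate_sheet")) seq_b <- seq_b$slots
  stopifnot(length(seq_a) > 0L, length(seq_b) > 0L)
  cells <- outer(seq_a, seq_b, `==`)
  cells[is.na(cells)] <- FALSE
  structure(list(cells = cells, seq_a = seq_a, seq_b = seq_b),
            class = "match_matrix")
}

# abundant gene ids: > abundant_frac of a sheet's slots
.abundant_genes <- function(slots, frac) {
  tb <- table(slots[!is.na(slots)])
  names(tb)[tb > frac * length(slots)]
}

#' Detect diagonal runs in a match matrix
#'
#' Finds all maximal diagonal runs of matches with at least `min_run` matched
#' cells, tolerating up to `max_gap` consecutive non-matching cells inside a
#' run. Runs on different offsets (`offset = j - i`) are separate segments,
#' so a well slip whose offset changes mid-plate is reported as a piecewise
#' chain of segments. With `exclude_abundant`, matches of genes occupying
#' more than `abundant_frac` of either sheet may extend a run but at least
#' two rarer matches must be present for the segment to be reported (highly
#' abundant transcripts fill many wells and paint spurious diagonals).
#'
#' @param M a [match_matrix()].
#' @param min_run,max_gap,abundant_frac see [qc_thresholds()].
#' @param exclude_abundant apply the abundant-gene seeding rule (default
#'   TRUE).
#' @return a data.table of segments: `start_i`, `start_j`, `end_i`, `end_j`
#'   (1-based), `offset`, `length` (span including tolerated gaps),
#'   `n_matches`, and a list column `match_i` of matched row positions.
#' @export
detect_diagonals <- function(M, min_run = 4L, max_gap = 2L,
                             exclude_abundant = TRUE, abundant_frac = 0.10) {
  cells <- M$cells
  hits <- which(cells, arr.ind = TRUE)
  empty <- data.table(start_i = integer(), start_j = integer(),
                      end_i = integer(), end_j = integer(),
                      offset = integer(), length = integer(),
                      n_matches = integer(), match_i = list())
  if (nrow(hits) == 0L) return(empty)
  seedable <- rep(TRUE, nrow(hits))
  if (exclude_abundant) {
    ab <- union(.abundant_genes(M$seq_a, abundant_frac),
                .abundant_genes(M$seq_b, abundant_frac))
    if (length(ab)) seedable <- !(M$seq_a[hits[, 1L]] %chin% ab)
  }
  dt <- data.table(i = hits[, 1L], j = hits[, 2L], seed = seedable)
  dt[, offset := j - i]
  setorder(dt, offset, i)
  segs <- dt[, {
    brk <- c(TRUE, diff(i) - 1L > max_gap)
    run <- cumsum(brk)
    by_run <- split(seq_len(.N), run)
    keep <- vapply(by_run, function(ix) {
      length(ix) >= min_run && sum(seed[ix]) >= 2L
    }, logical(1L))
    by_run <- by_run[keep]
    if (length(by_run)) {
      rbindlist(lapply(by_run, function(ix) data.table(
        start_i = i[ix[1L]], end_i = i[ix[length(ix)]],
        n_matches = length(ix), match_i = list(i[ix]))))
    } else NULL
  }, by = offset]
  if (nrow(segs) == 0L) return(empty)
  segs[, `:=`(start_j = start_i + offset, end_j = end_i + offset,
              length = end_i - start_i + 1L)]
  setcolorder(segs, c("start_i", "start_j", "end_i", "end_j", "offset",
                      "length", "n_matches", "match_i"))
  setorder(segs, offset, start_i)
  segs[]
}

.empty_relation <- function() {
  data.table(plate_a = character(), plate_b = character(),
             library_a = character(), library_b = character(),
             kind = character(), matched_fraction = numeric(),
             n_matched = integer(), n_comparable = integer(),
             offsets = character(), offset_map = character(),
             spans = character(), low_evidence = logical())
}

#' Classify the relationship between two plate sheets
#'
#' Computes the matched fraction (matched wells over wells where *both*
#' sheets are non-empty, after piecewise best-offset alignment) and
#' classifies:
#' * `CORRECT_PAIR` - complementary 5'/3' sheets of the same annotated plate
#'   matching at/above `t_full` on a single zero offset;
#' * `WELL_SLIP` - same, but on non-zero or changing offsets;
#' * `SWAP_CANDIDATE` - complementary-direction match at/above `t_full`
#'   between *differently* annotated plates (resolved to a re-pairing or a
#'   duplication by [build_correction_plan()]);
#' * `DUPLICATE` - any other match at/above `t_full` (same-direction, or
#'   across libraries - relabelled `CROSS_LIBRARY_DUPLICATE` by
#'   [scan_cross_library()]);
#' * `PARTIAL_DUPLICATE` - matched fraction in `[t_partial, t_full)`;
#' * `UNMATCHED` otherwise, with a low-evidence flag when fewer than
#'   `min_comparable` wells could be compared.
#'
#' Classification is symmetric in its two arguments.
#'
#' @param sheet_a,sheet_b `plate_sheet` objects.
#' @param segments optional precomputed [detect_diagonals()] output for
#'   `match_matrix(sheet_a, sheet_b)`.
#' @param thresholds a [qc_thresholds()] list.
#' @return a one-row `plate relation` data.table (see [scan_library()]).
#' @export
classify_relation <- function(sheet_a, sheet_b, segments = NULL,
                              thresholds = qc_thresholds()) {
  th <- thresholds
  # canonical orientation: 5' sheet first when directions are complementary,
  # else lexicographic by sheet id, so classify(a,b) == classify(b,a)
  id_a <- sheet_id(sheet_a$library_id, sheet_a$batch, sheet_a$plate,
                   sheet_a$direction)
  id_b <- sheet_id(sheet_b$library_id, sheet_b$batch, sheet_b$plate,
                   sheet_b$direction)
  comp <- setequal(c(sheet_a$direction, sheet_b$direction), c("5", "3"))
  flip <- if (comp) sheet_a$direction == "3" else id_a > id_b
  if (flip) {
    tmp <- sheet_a; sheet_a <- sheet_b; sheet_b <- tmp
    tmp <- id_a; id_a <- id_b; id_b <- tmp
    segments <- NULL  # recompute in canonical orientation
  }
  if (is.null(segments)) {
    segments <- detect_diagonals(match_matrix(sheet_a, sheet_b),
                                 min_run = th$min_run, max_gap = th$max_gap,
                                 abundant_frac = th$abundant_frac)
  }
  a <- sheet_a$slots
  b <- sheet_b$slots
  n <- length(a)
  if (nrow(segments)) {
    matched_i <- unique(unlist(segments$match_i))
    primary <- segments$offset[which.max(segments$n_matches)]
    off <- rep(primary, n)
    for (s in seq_len(nrow(segments))) {
      off[segments$start_i[s]:segments$end_i[s]] <- segments$offset[s]
    }
  } else {
    matched_i <- integer()
    primary <- 0L
    off <- rep(0L, n)
  }
  i <- seq_len(n)
  j <- i + off
  comparable <- !is.na(a) & j >= 1L & j <= length(b) & !is.na(b[pmin(pmax(j, 1L), length(b))])
  n_comp <- sum(comparable)
  mf <- if (n_comp > 0L) min(1, length(matched_i) / n_comp) else 0
  offs <- sort(unique(segments$offset))
  same_plate <- sheet_a$library_id == sheet_b$library_id &&
    sheet_a$batch == sheet_b$batch && sheet_a$plate == sheet_b$plate
  same_lib <- sheet_a$library_id == sheet_b$library_id
  low <- FALSE
  if (n_comp < th$min_comparable) {
    kind <- "UNMATCHED"; low <- TRUE
  } else if (mf >= th$t_full) {
    kind <- if (same_plate && comp) {
      if (length(offs) == 1L && offs == 0L) "CORRECT_PAIR" else "WELL_SLIP"
    } else if (!same_lib) {
      "DUPLICATE"
    } else if (comp) {
      "SWAP_CANDIDATE"
    } else {
      "DUPLICATE"
    }
  } else if (mf >= th$t_partial) {
    kind <- "PARTIAL_DUPLICATE"
  } else {
    kind <- "UNMATCHED"
  }
  # slip offset map, recorded against the 5' sheet's 0-based well indices
  omap <- if (nrow(segments)) {
    paste(sprintf("%d:%d", segments$start_i - 1L, segments$offset),
          collapse = ";")
  } else ""
  spans <- if (nrow(segments)) {
    paste(sprintf("%d-%d:%d", segments$start_i - 1L, segments$end_i - 1L,
                  segments$offset), collapse = ";")
  } else ""
  data.table(plate_a = id_a, plate_b = id_b,
             library_a = sheet_a$library_id, library_b = sheet_b$library_id,
             kind = kind, matched_fraction = mf,
             n_matched = length(matched_i), n_comparable = n_comp,
             offsets = paste(offs, collapse = ","), offset_map = omap,
             spans = spans, low_evidence = low)
}

#' Scan all plate pairs within one library
#'
#' Classifies every unordered pair of sheets of a library, including
#' cross-batch pairs (a plate duplicated into a later batch still matches).
#'
#' @param sheets the [build_plate_sheets()] list for one library.
#' @param thresholds a [qc_thresholds()] list.
#' @return a data.table of plate relations (one row per pair), columns as in
#'   [classify_relation()].
#' @export
scan_library <- function(sheets, thresholds = qc_thresholds()) {
  if (length(sheets) < 2L) return(.empty_relation())
  nm <- names(sheets)
  out <- vector("list", length(nm) * (length(nm) - 1L) / 2L)
  k <- 0L
  for (x in seq_along(nm)) {
    for (y in seq_len(x - 1L)) {
      k <- k + 1L
      out[[k]] <- classify_relation(sheets[[nm[y]]], sheets[[nm[x]]],
                                    thresholds = thresholds)
    }
  }
  rbindlist(out)
}

#' Scan a whole catalog's plates, within and across libraries
#'
#' Convenience wrapper: builds sheets for every library with plate metadata,
#' runs [scan_library()] per library plus [scan_cross_library()], and
#' returns the combined relation table.
#'
#' @param catalog an [est_catalog()].
#' @param thresholds a [qc_thresholds()] list.
#' @return a data.table of plate relations.
#' @export
scan_catalog <- function(catalog, thresholds = qc_thresholds()) {
  sheets <- lapply(setNames(nm = catalog$libraries$library_id),
                   function(l) tryCatch(build_plate_sheets(catalog, l),
                                        error = function(e) NULL))
  sheets <- Filter(Negate(is.null), sheets)
  rbind(rbindlist(lapply(sheets, scan_library, thresholds = thresholds)),
        scan_cross_library(sheets, thresholds = thresholds))
}

#' Scan plate pairs across libraries
#'
#' Compares every sheet of every library against all sheets of all *other*
#' libraries; inter-library hits at the duplicate threshold are reported as
#' `CROSS_LIBRARY_DUPLICATE` (a plate's clones physically originating from a
#' different library).
#'
#' @param sheets_by_library a named list: library id -> its
#'   [build_plate_sheets()] list.
#' @param thresholds a [qc_thresholds()] list.
#' @return a data.table of cross-library plate relations (non-UNMATCHED rows
#'   only).
#' @export
scan_cross_library <- function(sheets_by_library,
                               thresholds = qc_thresholds()) {
  libs <- names(sheets_by_library)
  out <- list()
  k <- 0L
  for (x in seq_along(libs)) {
    for (y in seq_len(x - 1L)) {
      for (sa in sheets_by_library[[libs[y]]]) {
        for (sb in sheets_by_library[[libs[x]]]) {
          rel <- classify_relation(sa, sb, thresholds = thresholds)
          if (rel$kind != "UNMATCHED") {
            k <- k + 1L
            out[[k]] <- rel
          }
        }
      }
    }
  }
  if (k == 0L) return(.empty_relation())
  rels <- rbindlist(out)
  rels[kind %chin% c("DUPLICATE", "SWAP_CANDIDATE"),
       kind := "CROSS_LIBRARY_DUPLICATE"]
  rels[]
}

# ---- correction plan -------------------------------------------------------

.node_of <- function(sheet_ids) sub("\\|[53]$", "", sheet_ids)
.node_dir <- function(sheet_ids) sub("^.*\\|", "", sheet_ids)

# union-find over character labels
.components <- function(nodes, edge_a, edge_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (e in seq_along(edge_a)) {
    ra <- find(edge_a[e]); rb <- find(edge_b[e])
    if (ra != rb) parent[[ra]] <- rb
  }
  split(nodes, vapply(nodes, find, character(1L)))
}

#' Build a count-correction plan from classified plate relations
#'
#' Converts the relation report of [scan_library()] /
#' [scan_cross_library()] into an ordered list of corrective actions:
#' * duplicated / triplicated plates (connected components carrying
#'   same-direction duplicate evidence) are collapsed to one retained
#'   physical plate (`MERGE_DUPLICATE`; the lowest batch/plate annotation is
#'   kept);
#' * pure complementary-direction components with a consistent perfect
#'   pairing become `REPAIR_PAIRING` actions so clone grouping pairs the
#'   true 5'/3' partners;
#' * `WELL_SLIP` relations become `REALIGN_WELLS` offset maps (the 3' sheet
#'   is realigned to its 5' partner);
#' * cross-library duplicates are excluded from the recipient library
#'   (`EXCLUDE_PLATE`) - the copy lacking an in-library correct pairing, or
#'   the lexicographically larger library id on ties;
#' * partial duplications exclude only the overlapping wells of the dropped
#'   plate;
#' * components whose duplicate evidence is contradictory (a plate matching
#'   two plates that do not match each other) are excluded wholesale with a
#'   warning.
#'
#' Applying a plan can only remove or relabel reads, never add them, and
#' each physical plate is retained at most once.
#'
#' @param relations a data.table of plate relations (rbind of in-library and
#'   cross-library scans).
#' @return a `correction_plan`: list with `$actions` (list of typed
#'   actions, each carrying the relations that justify it), plus convenience
#'   views `$duplicates`, `$swaps`, `$slips`, `$cross_library`,
#'   `$unresolved`.
#' @export
build_correction_plan <- function(relations) {
  plan <- list(actions = list(), duplicates = list(), swaps = list(),
               slips = character(), cross_library = character(),
               unresolved = list())
  if (is.null(relations) || nrow(relations) == 0L) {
    return(structure(plan, class = "correction_plan"))
  }
  rel <- as.data.table(relations)

  # well slips -> realign the 3' sheet onto its 5' partner
  for (s in which(rel$kind == "WELL_SLIP")) {
    three <- rel$plate_b[s]  # canonical order puts 5' in plate_a
    parts <- strsplit(rel$offset_map[s], ";", fixed = TRUE)[[1L]]
    kv <- do.call(rbind, strsplit(parts, ":", fixed = TRUE))
    map <- data.table(from_i = as.integer(kv[, 1L]),
                      offset = as.integer(kv[, 2L]))
    plan$actions[[length(plan$actions) + 1L]] <- list(
      type = "REALIGN_WELLS", sheet = three, map = map,
      provenance = rel[s])
    plan$slips <- c(plan$slips, three)
  }

  # cross-library duplicates -> exclude the recipient copy
  xl <- rel[kind == "CROSS_LIBRARY_DUPLICATE"]
  if (nrow(xl)) {
    correct_nodes <- .node_of(
      unlist(rel[kind %chin% c("CORRECT_PAIR", "WELL_SLIP"),
                 c(plate_a, plate_b)]))
    for (nodepair in split(xl, paste(pmin(.node_of(xl$plate_a),
                                          .node_of(xl$plate_b)),
                                     pmax(.node_of(xl$plate_a),
                                          .node_of(xl$plate_b))))) {
      na_ <- .node_of(nodepair$plate_a[1L])
      nb_ <- .node_of(nodepair$plate_b[1L])
      a_paired <- na_ %chin% correct_nodes
      b_paired <- nb_ %chin% correct_nodes
      drop <- if (a_paired && !b_paired) nb_
      else if (b_paired && !a_paired) na_
      else if (sub("\\|.*$", "", na_) > sub("\\|.*$", "", nb_)) na_ else nb_
      if (drop %chin% plan$cross_library) next
      plan$actions[[length(plan$actions) + 1L]] <- list(
        type = "EXCLUDE_PLATE", node = drop, reason = "cross_library",
        provenance = nodepair)
      plan$cross_library <- c(plan$cross_library, drop)
    }
  }

  # in-library duplicate / swap components over physical plates
  high <- rel[kind %chin% c("DUPLICATE", "SWAP_CANDIDATE") &
                library_a == library_b]
  if (nrow(high)) {
    ea <- .node_of(high$plate_a)
    eb <- .node_of(high$plate_b)
    comps <- .components(unique(c(ea, eb)), ea, eb)
    for (comp in comps) {
      if (length(comp) < 2L) next
      in_comp <- ea %chin% comp | eb %chin% comp
      edges <- high[in_comp]
      same_dir <- any(.node_dir(edges$plate_a) == .node_dir(edges$plate_b))
      if (same_dir || edges[, any(.node_of(plate_a) == .node_of(plate_b))]) {
        # duplication: require every node pair to be connected
        pairs_seen <- unique(paste(pmin(.node_of(edges$plate_a),
                                        .node_of(edges$plate_b)),
                                   pmax(.node_of(edges$plate_a),
                                        .node_of(edges$plate_b))))
        need <- utils::combn(sort(comp), 2L)
        want <- paste(need[1L, ], need[2L, ])
        if (all(want %chin% pairs_seen)) {
          keep <- sort(comp)[1L]
          drop <- setdiff(sort(comp), keep)
          plan$actions[[length(plan$actions) + 1L]] <- list(
            type = "MERGE_DUPLICATE", keep = keep, drop = drop,
            provenance = edges)
          plan$duplicates[[length(plan$duplicates) + 1L]] <-
            list(keep = keep, drop = drop)
        } else {
          warning("contradictory duplicate evidence among plates ",
                  paste(comp, collapse = ", "), "; excluding all",
                  call. = FALSE)
          for (nd in sort(comp)) {
            plan$actions[[length(plan$actions) + 1L]] <- list(
              type = "EXCLUDE_PLATE", node = nd, reason = "unresolved",
              provenance = edges)
          }
          plan$unresolved[[length(plan$unresolved) + 1L]] <- comp
        }
      } else {
        # pure complementary evidence: resolve as pairing repairs
        fives <- edges$plate_a  # canonical order: 5' first
        threes <- edges$plate_b
        consistent <- !anyDuplicated(fives) && !anyDuplicated(threes)
        if (consistent) {
          for (e in seq_len(nrow(edges))) {
            plan$actions[[length(plan$actions) + 1L]] <- list(
              type = "REPAIR_PAIRING", five = fives[e], three = threes[e],
              provenance = edges[e])
            plan$swaps[[length(plan$swaps) + 1L]] <-
              c(five = fives[e], three = threes[e])
          }
        } else {
          warning("inconsistent pairing evidence among plates ",
                  paste(comp, collapse = ", "), "; excluding all",
                  call. = FALSE)
          for (nd in sort(comp)) {
            plan$actions[[length(plan$actions) + 1L]] <- list(
              type = "EXCLUDE_PLATE", node = nd, reason = "unresolved",
              provenance = edges)
          }
          plan$unresolved[[length(plan$unresolved) + 1L]] <- comp
        }
      }
    }
  }

  # partial duplications: drop only the overlapping wells of the later plate
  part <- rel[kind == "PARTIAL_DUPLICATE" & library_a == library_b]
  if (nrow(part)) {
    merged_away <- unlist(lapply(plan$duplicates, `[[`, "drop"))
    for (pp in split(part, paste(pmin(.node_of(part$plate_a),
                                      .node_of(part$plate_b)),
                                 pmax(.node_of(part$plate_a),
                                      .node_of(part$plate_b))))) {
      na_ <- .node_of(pp$plate_a[1L]); nb_ <- .node_of(pp$plate_b[1L])
      if (na_ == nb_) next
      keep <- min(na_, nb_); drop <- max(na_, nb_)
      if (drop %chin% merged_away) next
      # wells covered by the matched segment spans, on the dropped side
      widx <- integer()
      for (e in seq_len(nrow(pp))) {
        parts <- strsplit(pp$spans[e], ";", fixed = TRUE)[[1L]]
        if (!length(parts) || !nzchar(parts[1L])) next
        for (sp in parts) {
          m <- regmatches(sp, regexec("^([0-9]+)-([0-9]+):(-?[0-9]+)$",
                                      sp))[[1L]]
          if (length(m) == 0L) next
          kv <- as.integer(m[-1L])
          drop_is_b <- .node_of(pp$plate_b[e]) == drop
          rng <- kv[1L]:kv[2L]
          widx <- c(widx, if (drop_is_b) rng + kv[3L] else rng)
        }
      }
      widx <- sort(unique(widx[widx >= 0L & widx <= 95L]))
      plan$actions[[length(plan$actions) + 1L]] <- list(
        type = "MERGE_DUPLICATE", keep = keep, drop = drop,
        wells = widx, partial = TRUE, provenance = pp)
      plan$duplicates[[length(plan$duplicates) + 1L]] <-
        list(keep = keep, drop = drop, partial = TRUE)
    }
  }
  structure(plan, class = "correction_plan")
}

#' @export
print.correction_plan <- function(x, ...) {
  cat("<correction_plan> ", length(x$actions), " action(s)\n", sep = "")
  for (a in x$actions) {
    cat("  ", a$type, ": ",
        switch(a$type,
               MERGE_DUPLICATE = paste("keep", a$keep, "drop",
                                       paste(a$drop, collapse = ",")),
               REPAIR_PAIRING = paste(a$five, "<->", a$three),
               REALIGN_WELLS = a$sheet,
               EXCLUDE_PLATE = paste(a$node, "(", a$reason, ")")),
        "\n", sep = "")
  }
  invisible(x)
}

.node_fields <- function(node) {
  parts <- strsplit(node, "|", fixed = TRUE)[[1L]]
  list(library_id = parts[1L],
       batch = as.integer(sub("^b", "", parts[2L])),
       plate = as.integer(sub("^p", "", parts[3L])))
}

.sheet_fields <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1L]]
  list(library_id = parts[1L],
       batch = as.integer(sub("^b", "", parts[2L])),
       plate = as.integer(sub("^p", "", parts[3L])),
       direction = parts[4L])
}

#' Apply a correction plan to a catalog
#'
#' Actions are applied in a fixed order: pairing repairs (relabel the 3'
#' plate so true partners share a clone identity), well realignments (undo
#' slips), then merges/exclusions (drop the redundant copies). Clone names
#' of relabelled reads are rewritten canonically. The per-library read-count
#' delta is attached as attribute `"read_delta"`; counts never increase.
#'
#' @param catalog an [est_catalog()].
#' @param plan a [build_correction_plan()] result.
#' @return the corrected `est_catalog`.
#' @export
apply_correction_plan <- function(catalog, plan) {
  rr <- copy(catalog$reads)
  before <- rr[, .N, by = library_id]

  repairs <- Filter(function(a) a$type == "REPAIR_PAIRING", plan$actions)
  if (length(repairs)) {
    # simultaneous relabelling of 3' plates
    new_plate <- rr$plate
    new_batch <- rr$batch
    touched <- rep(FALSE, nrow(rr))
    for (a in repairs) {
      f5 <- .sheet_fields(a$five)
      f3 <- .sheet_fields(a$three)
      sel <- rr$library_id == f3$library_id & rr$batch == f3$batch &
        rr$plate == f3$plate & rr$direction == "3" & !is.na(rr$well_index)
      new_plate[sel] <- f5$plate
      new_batch[sel] <- f5$batch
      touched <- touched | sel
    }
    rr[, plate := new_plate]
    rr[, batch := new_batch]
    if (any(touched)) {
      rr[touched, clone_name := sprintf(
        "%s%02d%s-%s%d, 3'end", stem, batch, .PLATE_ROMAN[plate],
        well_row, well_col)]
    }
  }

  for (a in Filter(function(x) x$type == "REALIGN_WELLS", plan$actions)) {
    f3 <- .sheet_fields(a$sheet)
    map <- a$map[order(from_i)]
    # piecewise regions on the 3' sheet: wells in [from_j_s, from_j_{s+1})
    # get that segment's offset subtracted, all from one index snapshot
    from_j <- map$from_i + map$offset
    sel_sheet <- rr$library_id == f3$library_id & rr$batch == f3$batch &
      rr$plate == f3$plate & rr$direction == f3$direction &
      !is.na(rr$well_index)
    idx0 <- rr$well_index[sel_sheet]
    region <- findInterval(idx0, from_j)
    shifts <- c(0L, map$offset)[region + 1L]
    new_idx <- idx0 - shifts
    rr[sel_sheet, well_index := new_idx]
    rr <- rr[!(rr$library_id == f3$library_id & rr$batch == f3$batch &
                 rr$plate == f3$plate & rr$direction == f3$direction &
                 !is.na(rr$well_index) &
                 (rr$well_index < 0L | rr$well_index > 95L))]
    sel_sheet <- rr$library_id == f3$library_id & rr$batch == f3$batch &
      rr$plate == f3$plate & rr$direction == f3$direction &
      !is.na(rr$well_index)
    rr[sel_sheet, `:=`(well_row = LETTERS[well_index %/% 12L + 1L],
                       well_col = well_index %% 12L + 1L)]
    rr[sel_sheet, clone_name := sprintf(
      "%s%02d%s-%s%d, %s'end", stem, batch, .PLATE_ROMAN[plate],
      well_row, well_col, direction)]
  }

  for (a in Filter(function(x) x$type %in% c("MERGE_DUPLICATE",
                                             "EXCLUDE_PLATE"),
                   plan$actions)) {
    nodes <- if (a$type == "MERGE_DUPLICATE") a$drop else a$node
    for (nd in nodes) {
      f <- .node_fields(nd)
      sel <- rr$library_id == f$library_id & rr$batch == f$batch &
        rr$plate == f$plate & !is.na(rr$well_index)
      if (!is.null(a$wells)) sel <- sel & rr$well_index %in% a$wells
      rr <- rr[!sel]
    }
  }

  after <- rr[, .N, by = library_id]
  delta <- merge(before, after, by = "library_id", all.x = TRUE,
                 suffixes = c("_before", "_after"))
  delta[is.na(N_after), N_after := 0L]
  delta[, removed := N_before - N_after]
  stopifnot(all(delta$removed >= 0L))
  out <- structure(list(reads = rr[], libraries = catalog$libraries),
                   class = "est_catalog")
  setattr(out, "read_delta", delta[])
  out
}

#' Serialize a correction plan to JSON
#'
#' @param plan a `correction_plan`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_correction_plan <- function(plan, path) {
  acts <- lapply(plan$actions, function(a) {
    a$provenance <- NULL
    if (!is.null(a$map)) a$map <- as.data.frame(a$map)
    a
  })
  jsonlite::write_json(list(actions = acts), path, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Write a plate relation report to TSV
#'
#' @param relations relation table from the scans.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_relation_report <- function(relations, path) {
  cols <- setdiff(names(relations), character())
  fwrite(relations[, cols, with = FALSE], path, sep = "\t", quote = FALSE)
  invisible(path)
}
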