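# Redundancy collapse: reads -> unique clones.
#
# A clone picked into one well may be sequenced from the 5' end, the 3' end,
# or several times over; every such read observes the same transcript and
# must be counted exactly once. Clone identity is (library, stem, batch,
# plate, well) - never direction. Reads without plate metadata cannot be
# linked and each forms a singleton group.

#' Group catalog reads into clone groups
#'
#' @param catalog an [est_catalog()].
#' @param correction_plan optional [build_correction_plan()] output; its
#'   re-pairings, well realignments and exclusions are applied to the catalog
#'   before grouping so that true partners fall into the same group.
#' @return a `clone_groups` data.table, one row per clone group:
#'   `clone_key`, `library_id`, `multiplicity`, `resolved_gene_id`,
#'   `conflict` (>= 2 distinct non-missing gene ids among members),
#'   `read_ids` (comma-joined members).
#' @export
group_clones <- function(catalog, correction_plan = NULL) {
  if (!is.null(correction_plan)) {
    catalog <- apply_correction_plan(catalog, correction_plan)
  }
  rr <- copy(catalog$reads)
  rr[, has_clone := !is.na(well_index)]
  rr[, clone_key := fifelse(
    has_clone,
    sprintf("%s|%s|%02d|%d|%02d", library_id, stem, batch, plate, well_index),
    paste0("read:", read_id))]
  groups <- rr[order(-confidence, gene_id, read_id)][, .(
    library_id = library_id[1L],
    multiplicity = .N,
    resolved_gene_id = resolve_gene(gene_id, confidence, read_id),
    conflict = uniqueN(gene_id[!is.na(gene_id)]) >= 2L,
    read_ids = paste(sort(read_id), collapse = ",")
  ), by = clone_key]
  setattr(groups, "class", c("clone_groups", class(groups)))
  groups[]
}

#' Resolve a clone group's gene assignment
#'
#' Returns the non-missing gene id carried by the member read with the
#' greatest assignment confidence; ties are broken by lexicographically
#' smaller gene id, then smaller read id, so the result is deterministic and
#' invariant to member order. `NA` iff all members are unannotated.
#'
#' @param gene_ids character vector of member gene ids (may contain `NA`).
#' @param confidences numeric confidences, same length.
#' @param read_ids optional member read ids for the final tie-break.
#' @return a single gene id or `NA`.
#' @export
resolve_gene <- function(gene_ids, confidences, read_ids = NULL) {
  keep <- !is.na(gene_ids)
  if (!any(keep)) return(NA_character_)
  g <- gene_ids[keep]
  cf <- confidences[keep]
  rid <- if (is.null(read_ids)) g else read_ids[keep]
  o <- order(-cf, g, rid)
  g[o[1L]]
}

#' Collapse clone groups into a unique-clone table
#'
#' Each group contributes exactly one clone to its resolved gene (or to the
#' unannotated pool). The conservation identity
#' `total_unique + sum_k (k-1) * n_k == total reads` holds by construction
#' and is asserted.
#'
#' @param groups output of [group_clones()].
#' @return a `unique_clone_table`: list with data.tables `$per_gene`
#'   (`library_id`, `gene_id`, `unique_count`), `$totals` (`library_id`,
#'   `total_unique`, `total_reads`), `$histogram` (`library_id`, `k`,
#'   `n_groups`), and `$conflicts` (per-library, per-multiplicity conflict
#'   counts).
#' @export
collapse_clones <- function(groups) {
  totals <- groups[, .(total_unique = .N,
                       total_reads = sum(multiplicity)), by = library_id]
  hist <- groups[, .(n_groups = .N), by = .(library_id, k = multiplicity)]
  setorder(hist, library_id, k)
  excess <- hist[, sum((k - 1L) * n_groups), by = library_id]
  stopifnot(all(totals$total_unique + excess$V1 == totals$total_reads))
  per_gene <- groups[!is.na(resolved_gene_id),
                     .(unique_count = .N),
                     by = .(library_id, gene_id = resolved_gene_id)]
  setorder(per_gene, library_id, gene_id)
  conflicts <- groups[, .(n_groups = .N, n_conflicting = sum(conflict)),
                      by = .(library_id, k = multiplicity)]
  setorder(conflicts, library_id, k)
  structure(list(per_gene = per_gene, totals = totals, histogram = hist,
                 conflicts = conflicts),
            class = "unique_clone_table")
}

#' @export
print.unique_clone_table <- function(x, ...) {
  cat("<unique_clone_table>\n")
  for (i in seq_len(nrow(x$totals))) {
    cat("  ", x$totals$library_id[i], ": ", x$totals$total_reads[i],
        " reads -> ", x$totals$total_unique[i], " unique clones\n", sep = "")
  }
  invisible(x)
}

#' Gene-identity disagreement rate at a given multiplicity
#'
#' The fraction of clone groups of multiplicity `k` whose member reads were
#' assigned two or more distinct gene ids - e.g. 60 conflicting of 750
#' triplicated clones is 0.08. Exact fractions are reported (no rounding).
#'
#' @param groups output of [group_clones()].
#' @param k multiplicity of interest (k = 2 pairs, k = 3 triplets, ...).
#' @param library_id optional: restrict to one library.
#' @return the conflicting fraction in `[0, 1]`.
#' @export
disagreement_rate <- function(groups, k, library_id = NULL) {
  g <- groups
  if (!is.null(library_id)) {
    lib <- library_id
    g <- g[g$library_id == lib, ]
  }
  g <- g[g$multiplicity == k, ]
  if (nrow(g) == 0L) {
    stop("no clone groups of multiplicity ", k, call. = FALSE)
  }
  mean(g$conflict)
}

#' Write a unique-clone table to TSV
#'
#' @param tab a [collapse_clones()] result.
#' @param path output TSV (`library_id`, `gene_id`, `unique_count`).
#' @param histogram_path optional JSON path for the multiplicity histogram
#'   and conflict report.
#' @return `path`, invisibly.
#' @export
write_unique_clone_table <- function(tab, path, histogram_path = NULL) {
  fwrite(tab$per_gene, path, sep = "\t", quote = FALSE)
  if (!is.null(histogram_path)) {
    jsonlite::write_json(list(totals = tab$totals, histogram = tab$histogram,
                              conflicts = tab$conflicts),
                         histogram_path, dataframe = "rows")
  }
  invisible(path)
}
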