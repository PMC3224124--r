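# EST frequency profiles.
#
# A gene's expression is estimated as its share of the library's random
# clone observations: frequency per 10,000 = 1e4 * count / library size,
# where library size is the corrected unique-clone total (redundant reads of
# one clone count once; unannotated clones stay in the denominator).
# Same-type libraries are combined by the size-weighted mean of their
# frequencies, which is algebraically identical to pooling the counts.

#' Per-10,000 EST frequency
#'
#' @param count EST (unique clone) count of the gene in the library.
#' @param library_size total unique clones of the library (> 0).
#' @return `10000 * count / library_size`. Vectorized.
#' @export
gene_frequency <- function(count, library_size) {
  if (any(library_size <= 0)) {
    stop("library_size must be positive", call. = FALSE)
  }
  if (any(count < 0) || any(count > library_size)) {
    stop("count must lie in [0, library_size]", call. = FALSE)
  }
  10000 * count / library_size
}

#' Size-weighted mean of per-library frequencies
#'
#' Weights are the library unique-clone totals, which makes the combination
#' equal to the pooled-count frequency `1e4 * sum(c_i) / sum(n_i)` - the
#' maximum-likelihood choice under multinomial sampling.
#'
#' @param freqs per-library per-10k frequencies of one gene.
#' @param sizes matching library sizes (unique clones).
#' @return the combined per-10k frequency.
#' @export
combine_weighted <- function(freqs, sizes) {
  stopifnot(length(freqs) == length(sizes))
  if (sum(sizes) <= 0) stop("total library size must be > 0", call. = FALSE)
  sum(sizes * freqs) / sum(sizes)
}

#' Build per-group frequency profiles
#'
#' Pools the corrected unique-clone counts of each declared library group
#' (e.g. leaf / stressed leaf / berry / stressed berry, or root / non-root)
#' and computes per-10k frequencies against the pooled group size. Genes
#' absent from a group's libraries have count 0 there. Groups containing a
#' normalization-flattened library are flagged in the provenance: their
#' frequencies under-count abundant transcripts and over-count rare ones.
#'
#' @param unique_table a [collapse_clones()] result.
#' @param library_metadata data.table with `library_id`, `group_label`,
#'   optionally `normalized`.
#' @param groups which group labels to profile (default: all in the
#'   metadata).
#' @return a `frequency_profile`: list with `$counts` and `$freq`
#'   (gene x group matrices), `$group_sizes` (named pooled unique-clone
#'   totals), `$members` (library ids per group), and
#'   `$normalized_groups`.
#' @export
build_group_profiles <- function(unique_table, library_metadata,
                                 groups = NULL) {
  meta <- as.data.table(library_metadata)
  if (!"normalized" %in% names(meta)) meta[, normalized := FALSE]
  if (is.null(groups)) groups <- unique(meta$group_label)
  per_gene <- merge(unique_table$per_gene,
                    meta[, .(library_id, group_label)], by = "library_id")
  totals <- merge(unique_table$totals, meta[, .(library_id, group_label)],
                  by = "library_id")
  missing_groups <- setdiff(groups, totals$group_label)
  if (length(missing_groups)) {
    stop("group(s) with no member libraries: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(per_gene$gene_id))
  counts <- matrix(0L, nrow = length(genes), ncol = length(groups),
                   dimnames = list(genes, groups))
  pooled <- per_gene[group_label %chin% groups,
                     .(count = sum(unique_count)),
                     by = .(gene_id, group_label)]
  counts[cbind(match(pooled$gene_id, genes),
               match(pooled$group_label, groups))] <- pooled$count
  sizes <- vapply(groups, function(g) {
    sum(totals[group_label == g, total_unique])
  }, numeric(1L))
  freq <- sweep(counts, 2L, sizes, `/`) * 10000
  members <- lapply(setNames(groups, groups), function(g) {
    totals[group_label == g, library_id]
  })
  normalized_groups <- groups[vapply(groups, function(g) {
    any(meta[group_label == g, normalized], na.rm = TRUE)
  }, logical(1L))]
  structure(list(counts = counts, freq = freq, group_sizes = sizes,
                 members = members, normalized_groups = normalized_groups),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("<frequency_profile> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " groups\n", sep = "")
  for (g in colnames(x$counts)) {
    cat("  ", g, ": ", x$group_sizes[[g]], " unique clones",
        if (g %in% x$normalized_groups) "  [normalized: biased frequencies]",
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a frequency profile to TSV
#'
#' One row per gene; per group, a count column and a per-10k frequency
#' column (frequencies printed to one decimal, full precision is kept in
#' the object).
#'
#' @param profile a [build_group_profiles()] result.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_frequency_profile <- function(profile, path) {
  out <- data.table(gene_id = rownames(profile$counts))
  for (g in colnames(profile$counts)) {
    out[[paste0(g, "_count")]] <- profile$counts[, g]
    out[[paste0(g, "_per10k")]] <- round(profile$freq[, g], 1L)
  }
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
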