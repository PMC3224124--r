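# EST catalog container and I/O.
#
# A catalog is one row per sequencing read (read_id, library_id, raw clone
# name, direction, assigned gene id, assignment confidence) plus a library
# metadata table. Clone names are parsed eagerly into plate/well columns so
# downstream modules never re-parse.

#' Construct an EST catalog
#'
#' @param reads a data.frame with columns `read_id`, `library_id`,
#'   `clone_name` (may be `NA` for libraries without plate metadata),
#'   `direction` (`"5"`, `"3"`, `"unknown"` or `NA`; overridden by a
#'   direction suffix inside the clone name when present), `gene_id`
#'   (`NA`/empty = unannotated) and `confidence` (non-negative score).
#' @param libraries a data.frame with columns `library_id`, `group_label`,
#'   and optionally `orientation` (`"5"`, `"3"`, `"both"`, `"n.d."`) and
#'   `normalized` (logical). Defaults to one row per observed library with
#'   `group_label = library_id`.
#' @return an object of class `est_catalog`: a list with data.tables
#'   `$reads` (with parsed `stem`, `batch`, `plate`, `well_row`, `well_col`,
#'   `well_index` columns) and `$libraries`.
#' @export
est_catalog <- function(reads, libraries = NULL) {
  reads <- as.data.table(reads)
  req <- c("read_id", "library_id", "clone_name", "direction", "gene_id",
           "confidence")
  missing_cols <- setdiff(req, names(reads))
  if (length(missing_cols)) {
    stop("reads is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  reads <- reads[, req, with = FALSE]
  reads[, read_id := as.character(read_id)]
  reads[, library_id := as.character(library_id)]
  reads[, clone_name := as.character(clone_name)]
  reads[, gene_id := as.character(gene_id)]
  reads[gene_id == "", gene_id := NA_character_]
  reads[, confidence := as.numeric(confidence)]
  reads[, direction := as.character(direction)]
  if (anyDuplicated(reads$read_id)) {
    stop("read_id values must be unique within a catalog", call. = FALSE)
  }
  parsed <- parse_clone_names_dt(reads$clone_name)
  bad <- !is.na(parsed$parse_error)
  if (any(bad)) {
    stop("unparseable clone name(s), e.g. read ", reads$read_id[which(bad)[1L]],
         ": '", reads$clone_name[which(bad)[1L]], "' (",
         parsed$parse_error[which(bad)[1L]], ")", call. = FALSE)
  }
  reads <- cbind(reads, parsed[, !"parse_error"])
  # direction: suffix inside the clone name wins over the column
  reads[, direction := fifelse(!is.na(name_direction), name_direction,
                               fifelse(direction %chin% c("5", "3"),
                                       direction, "unknown"))]
  reads[, name_direction := NULL]
  if (is.null(libraries)) {
    libraries <- data.table(library_id = sort(unique(reads$library_id)))
    libraries[, group_label := library_id]
  }
  libraries <- as.data.table(libraries)
  if (!"orientation" %in% names(libraries)) libraries[, orientation := "both"]
  if (!"normalized" %in% names(libraries)) libraries[, normalized := FALSE]
  libraries[, library_id := as.character(library_id)]
  orphan <- setdiff(reads$library_id, libraries$library_id)
  if (length(orphan)) {
    stop("reads reference undeclared library id(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(reads = reads[], libraries = libraries[]),
            class = "est_catalog")
}

#' @export
print.est_catalog <- function(x, ...) {
  cat("<est_catalog> ", nrow(x$reads), " reads, ",
      nrow(x$libraries), " libraries\n", sep = "")
  tab <- x$reads[, .N, by = library_id]
  for (i in seq_len(nrow(tab))) {
    cat("  ", tab$library_id[i], ": ", tab$N[i], " reads\n", sep = "")
  }
  invisible(x)
}

#' Read an EST catalog from TSV
#'
#' The catalog file is UTF-8 tab-separated with header columns `read_id`,
#' `library_id`, `clone_name`, `direction`, `gene_id`, `confidence`; an empty
#' `gene_id` means the read is unannotated.
#'
#' @param path catalog TSV path.
#' @param libraries_path optional library-metadata TSV (see
#'   [read_library_metadata()]).
#' @return an [est_catalog()].
#' @export
read_est_catalog <- function(path, libraries_path = NULL) {
  reads <- fread(path, sep = "\t", colClasses = list(
    character = c("read_id", "library_id", "clone_name", "direction",
                  "gene_id")), na.strings = c("", "NA"))
  libs <- if (!is.null(libraries_path)) read_library_metadata(libraries_path)
  est_catalog(reads, libs)
}

#' Write an EST catalog to TSV
#'
#' Only the six interface columns are serialized; parsed plate/well columns
#' are reconstructed on read. Well positions are never written as indices.
#'
#' @param catalog an [est_catalog()].
#' @param path output TSV path.
#' @param libraries_path optional path for the library metadata TSV.
#' @return `path`, invisibly.
#' @export
write_est_catalog <- function(catalog, path, libraries_path = NULL) {
  cols <- c("read_id", "library_id", "clone_name", "direction", "gene_id",
            "confidence")
  fwrite(catalog$reads[, cols, with = FALSE], path, sep = "\t", na = "",
         quote = FALSE)
  if (!is.null(libraries_path)) {
    fwrite(catalog$libraries, libraries_path, sep = "\t", na = "",
           quote = FALSE)
  }
  invisible(path)
}

#' Read library metadata from TSV
#'
#' Columns: `library_id`, `group_label` (e.g. leaf / stressed_leaf / berry /
#' stressed_berry / root / non_root), optional `orientation`
#' (`"5"`/`"3"`/`"both"`/`"n.d."`) and `normalized` (logical flag for
#' normalization-flattened libraries, whose frequencies are biased).
#'
#' @param path metadata TSV path.
#' @return a data.table.
#' @export
read_library_metadata <- function(path) {
  libs <- fread(path, sep = "\t", na.strings = c("", "NA"))
  if (!all(c("library_id", "group_label") %in% names(libs))) {
    stop("library metadata needs columns library_id and group_label",
         call. = FALSE)
  }
  libs[, library_id := as.character(library_id)]
  libs[]
}

#' Validate an EST catalog file
#'
#' Checks structure (columns, unique read ids, parseable clone names,
#' declared libraries, well collisions) and returns a report rather than
#' stopping at the first problem.
#'
#' @param path catalog TSV path.
#' @param libraries_path optional metadata TSV.
#' @return a list with `ok` (logical) and `messages` (character vector).
#' @export
validate_est_catalog <- function(path, libraries_path = NULL) {
  msgs <- character()
  reads <- tryCatch(
    fread(path, sep = "\t", na.strings = c("", "NA"),
          colClasses = list(character = 1:5)),
    error = function(e) e)
  if (inherits(reads, "error")) {
    return(list(ok = FALSE, messages = paste("cannot read file:",
                                             conditionMessage(reads))))
  }
  req <- c("read_id", "library_id", "clone_name", "direction", "gene_id",
           "confidence")
  miss <- setdiff(req, names(reads))
  if (length(miss)) {
    return(list(ok = FALSE,
                messages = paste("missing column(s):",
                                 paste(miss, collapse = ", "))))
  }
  dup <- reads$read_id[duplicated(reads$read_id)]
  if (length(dup)) {
    msgs <- c(msgs, paste0(length(dup), " duplicated read_id value(s), e.g. ",
                           dup[1L]))
  }
  parsed <- parse_clone_names_dt(reads$clone_name)
  bad <- which(!is.na(parsed$parse_error))
  if (length(bad)) {
    msgs <- c(msgs, paste0(length(bad), " unparseable clone name(s), e.g. '",
                           reads$clone_name[bad[1L]], "' (",
                           parsed$parse_error[bad[1L]], ")"))
  }
  if (!is.null(libraries_path)) {
    libs <- read_library_metadata(libraries_path)
    orphan <- setdiff(reads$library_id, libs$library_id)
    if (length(orphan)) {
      msgs <- c(msgs, paste("undeclared library id(s):",
                            paste(orphan, collapse = ", ")))
    }
  }
  list(ok = length(msgs) == 0L, messages = msgs)
}

sheet_id <- function(library_id, batch, plate, direction) {
  sprintf("%s|b%02d|p%d|%s", library_id, batch, plate, direction)
}

#' Build per-plate gene-ID sheets for one library
#'
#' Materializes the ordered 96-slot gene-ID vector for every
#' (batch, plate, direction) observed in a library - the unit that the
#' dot-plot scan compares. Wells never observed are `NA`. When two reads
#' claim the same (well, direction) slot the higher-confidence gene id wins
#' (ties: lexicographically smaller read id) and a warning is emitted.
#' Reads with unknown direction participate in clone counting but not in
#' plate pairing, so they are excluded from sheets.
#'
#' @param catalog an [est_catalog()].
#' @param library_id which library to sheet.
#' @return a named list of `plate_sheet` objects (fields `library_id`,
#'   `batch`, `plate`, `direction`, `slots` - a 96-long character vector
#'   indexed A1..H12).
#' @export
build_plate_sheets <- function(catalog, library_id) {
  lib <- library_id
  rr <- catalog$reads[library_id == lib & !is.na(well_index) &
                        direction %chin% c("5", "3")]
  if (nrow(rr) == 0L) {
    stop("library ", lib, " has no reads with plate metadata; skip plate QC",
         call. = FALSE)
  }
  setorder(rr, batch, plate, direction, well_index, -confidence, read_id)
  coll <- rr[, .N, by = .(batch, plate, direction, well_index)][N > 1L]
  if (nrow(coll)) {
    warning(nrow(coll), " well slot collision(s) in library ", lib,
            "; resolved by confidence, then read id", call. = FALSE)
  }
  first <- rr[!duplicated(rr[, .(batch, plate, direction, well_index)])]
  out <- list()
  for (grp in split(first, by = c("batch", "plate", "direction"))) {
    slots <- rep(NA_character_, 96L)
    slots[grp$well_index + 1L] <- grp$gene_id
    sh <- structure(list(
      library_id = lib, batch = grp$batch[1L], plate = grp$plate[1L],
      direction = grp$direction[1L], slots = slots
    ), class = "plate_sheet")
    out[[sheet_id(lib, sh$batch, sh$plate, sh$direction)]] <- sh
  }
  out[order(names(out))]
}

#' @export
print.plate_sheet <- function(x, ...) {
  cat("<plate_sheet> ", sheet_id(x$library_id, x$batch, x$plate, x$direction),
      ": ", sum(!is.na(x$slots)), "/96 wells observed\n", sep = "")
  invisible(x)
}
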