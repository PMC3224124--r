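# Clone-name grammar
#
# dbEST-style clone names such as "CA48LN09IF-A9, 5'end" encode the physical
# sequencing workflow: library stem ("CA48LN"), zero-padded batch number
# ("09"), plate within the batch (Roman I-IV, Arabic 1-4 also accepted), an
# optional single run letter, the 96-well coordinate ("A9"), and an optional
# direction suffix ("5'end" / "3'end"). Stems must end in a letter so that
# the batch digits are unambiguous even when the stem itself contains digits.

.PLATE_ROMAN <- c("I", "II", "III", "IV")

.CLONE_RE <- paste0(
  "^\\s*",
  "(.*?[A-Za-z])",            # 1 stem (lazy, must end in a letter)
  "([0-9]{1,2})",             # 2 batch
  "(IV|III|II|I|[1-4])",      # 3 plate
  "([A-HJ-Za-hj-z]?)",        # 4 optional run letter (I excluded: plate token)
  "-",
  "([A-Ha-h])([0-9]{1,2})",   # 5,6 well row/col
  "\\s*(?:[,;]?\\s*([53])\\s*'?\\s*end\\.?)?", # 7 optional direction
  "\\s*$"
)

.parse_plate_token <- function(tok) {
  i <- match(toupper(tok), .PLATE_ROMAN)
  if (!is.na(i)) return(i)
  as.integer(tok)
}

#' Parse a dbEST-style clone name
#'
#' Decomposes a clone name such as `"CA48LN09IF-A9, 5'end"` into its library
#' stem, batch number, plate (1-4), 96-well coordinate, and read direction.
#' The direction suffix is optional; names without one get direction
#' `"unknown"`. Clone identity is `(stem, batch, plate, well)` - direction is
#' deliberately *not* part of identity, because 5' and 3' reads of one clone
#' observe the same transcript.
#'
#' @param raw a single clone-name string.
#' @return an object of class `clone_name`: a list with elements
#'   `stem`, `batch`, `plate` (integer 1-4), `well_row` (`"A"`-`"H"`),
#'   `well_col` (1-12), `direction` (`"5"`, `"3"` or `"unknown"`).
#' @examples
#' parse_clone_name("CA48LN09IF-A9, 5'end")
#' @seealso [format_clone_name()], [well_order_index()]
#' @export
parse_clone_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw), nzchar(raw))
  m <- regmatches(raw, regexec(.CLONE_RE, raw))[[1L]]
  if (length(m) == 0L) {
    stop("malformed clone name '", raw,
         "': expected <stem><batch digits><plate I-IV|1-4>[letter]-<well>[, 5'/3'end]",
         call. = FALSE)
  }
  col <- as.integer(m[7L])
  if (col < 1L || col > 12L) {
    stop("malformed clone name '", raw, "': well column ", col,
         " out of range 1-12", call. = FALSE)
  }
  batch <- as.integer(m[3L])
  if (batch < 1L) {
    stop("malformed clone name '", raw, "': batch must be >= 1", call. = FALSE)
  }
  structure(list(
    stem      = m[2L],
    batch     = batch,
    plate     = .parse_plate_token(m[4L]),
    well_row  = toupper(m[6L]),
    well_col  = col,
    direction = if (nzchar(m[8L])) m[8L] else "unknown"
  ), class = "clone_name")
}

#' Format a clone name canonically
#'
#' Inverse of [parse_clone_name()]: two-digit batch, Roman plate numeral, no
#' run letter, and a `", 5'end"` / `", 3'end"` suffix when the direction is
#' known. `format_clone_name(parse_clone_name(s))` is the canonical spelling
#' of `s`.
#'
#' @param clone a `clone_name` object (or a list with the same fields).
#' @return a single string.
#' @export
format_clone_name <- function(clone) {
  base <- sprintf("%s%02d%s-%s%d", clone$stem, clone$batch,
                  .PLATE_ROMAN[clone$plate], clone$well_row, clone$well_col)
  switch(as.character(clone$direction),
         "5" = paste0(base, ", 5'end"),
         "3" = paste0(base, ", 3'end"),
         base)
}

#' @export
print.clone_name <- function(x, ...) {
  cat("<clone_name>", format_clone_name(x), "\n")
  invisible(x)
}

#' Row-major index of a 96-well coordinate
#'
#' Wells are ordered A1, A2, ..., A12, B1, ..., H12, the order in which plate
#' sheets are laid out for the dot-plot scan. The index is 0-based: A1 -> 0,
#' A12 -> 11, B1 -> 12, H12 -> 95.
#'
#' @param well_row row letter `"A"`-`"H"` (or integer 1-8).
#' @param well_col column number 1-12.
#' @return integer in 0..95. Vectorized.
#' @export
well_order_index <- function(well_row, well_col) {
  row <- if (is.character(well_row)) match(toupper(well_row), LETTERS[1:8])
         else as.integer(well_row)
  col <- as.integer(well_col)
  if (anyNA(row) || any(row < 1L | row > 8L)) {
    stop("well row out of range A-H", call. = FALSE)
  }
  if (anyNA(col) || any(col < 1L | col > 12L)) {
    stop("well column out of range 1-12", call. = FALSE)
  }
  (row - 1L) * 12L + col - 1L
}

#' Well label for a 0-based well index
#'
#' @param index integer in 0..95 (vectorized).
#' @return labels such as `"A1"`, `"H12"`.
#' @export
well_label <- function(index) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L | index > 95L)) {
    stop("well index out of range 0-95", call. = FALSE)
  }
  paste0(LETTERS[index %/% 12L + 1L], index %% 12L + 1L)
}

# Vectorized parser used on whole catalogs; returns a data.table with one row
# per input (NA rows for NA input) and errors collected instead of thrown.
parse_clone_names_dt <- function(raw) {
  n <- length(raw)
  out <- data.table(
    stem = NA_character_, batch = NA_integer_, plate = NA_integer_,
    well_row = NA_character_, well_col = NA_integer_,
    well_index = NA_integer_, name_direction = NA_character_,
    parse_error = NA_character_
  )[rep(1L, max(n, 1L))][seq_len(n)]
  ok <- !is.na(raw) & nzchar(raw)
  if (!any(ok)) return(out)
  m <- regmatches(raw[ok], regexec(.CLONE_RE, raw[ok]))
  good <- lengths(m) > 0L
  idx <- which(ok)
  out[idx[!good], parse_error := "malformed clone name"]
  if (any(good)) {
    mm <- do.call(rbind, m[good])
    col <- as.integer(mm[, 7L])
    bad_col <- col < 1L | col > 12L
    i2 <- idx[good]
    out[i2[bad_col], parse_error := "well column out of range"]
    keep <- i2[!bad_col]
    if (length(keep)) {
      mk <- mm[!bad_col, , drop = FALSE]
      row <- toupper(mk[, 6L])
      colk <- as.integer(mk[, 7L])
      out[keep, `:=`(
        stem = mk[, 2L],
        batch = as.integer(mk[, 3L]),
        plate = vapply(mk[, 4L], .parse_plate_token, integer(1L)),
        well_row = row,
        well_col = colk,
        well_index = (match(row, LETTERS[1:8]) - 1L) * 12L + colk - 1L,
        name_direction = ifelse(nzchar(mk[, 8L]), mk[, 8L], NA_character_)
      )]
    }
  }
  out[]
}
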