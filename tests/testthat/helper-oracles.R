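# Independent oracles and small fixture builders shared across tests.
# Every oracle here deliberately uses a different algorithm (or code path)
# than the implementation it checks.

# ---- catalog builders ------------------------------------------------------

# one read row; defaults make a valid annotated 5' read
read_row <- function(read_id, clone, gene = "G1", conf = 500,
                     lib = "L1", direction = NA_character_) {
  data.frame(read_id = read_id, library_id = lib, clone_name = clone,
             direction = direction, gene_id = gene, confidence = conf,
             stringsAsFactors = FALSE)
}

# a full-plate catalog: 96 wells x requested directions, distinct genes
full_plate_reads <- function(stem = "SYN", batch = 1L, plate = "I",
                             directions = c("5", "3"), lib = "L1",
                             genes = sprintf("g%03d", 0:95)) {
  rows <- list()
  for (d in directions) {
    suffix <- if (d == "5") ", 5'end" else ", 3'end"
    for (i in 0:95) {
      wl <- estcurate::well_label(i)
      rows[[length(rows) + 1L]] <- read_row(
        sprintf("%s_%s_%s", lib, d, wl),
        sprintf("%s%02d%s-%s%s", stem, batch, plate, wl, suffix),
        gene = genes[i + 1L], lib = lib)
    }
  }
  do.call(rbind, rows)
}

# catalog realizing a prescribed multiplicity histogram: n_reads reads of
# which `pairs` clones are sequenced twice, `triplets` three times, `quads`
# four times, the remainder singletons
make_multiplicity_catalog <- function(n_reads, pairs, triplets, quads = 0L) {
  n_singletons <- n_reads - 2L * pairs - 3L * triplets - 4L * quads
  stopifnot(n_singletons >= 0L)
  ks <- rep(c(2L, 3L, 4L, 1L), c(pairs, triplets, quads, n_singletons))
  clone_of_group <- rep(seq_along(ks), ks)
  # residues mod 90 and mod 96 pin a group only within blocks of
  # lcm(90, 96) = 1440; the stem suffix separates the blocks
  clone_name <- paste0(
    "S", clone_of_group %/% 1440L,
    sprintf("HG%02d%s-%s", clone_of_group %% 90L + 1L,
            c("I", "II", "III", "IV")[clone_of_group %% 4L + 1L],
            estcurate::well_label(clone_of_group %% 96L)))
  reads <- data.frame(
    read_id = sprintf("r%07d", seq_len(sum(ks))),
    library_id = "LIB", clone_name = clone_name,
    direction = "5", gene_id = "g", confidence = 1,
    stringsAsFactors = FALSE)
  estcurate::est_catalog(reads)
}

# ---- brute-force diagonal enumeration --------------------------------------

# O(n^3) enumeration: for every cell and offset, grow runs cell by cell.
# Returns segments as (start_i, offset, n_matches) sorted, for comparison
# with detect_diagonals(..., exclude_abundant = FALSE).
oracle_diagonals <- function(cells, min_run, max_gap) {
  n_a <- nrow(cells); n_b <- ncol(cells)
  segs <- list()
  for (off in (-(n_a - 1L)):(n_b - 1L)) {
    i_range <- max(1L, 1L - off):min(n_a, n_b - off)
    m <- vapply(i_range, function(i) cells[i, i + off], logical(1L))
    if (!any(m)) next
    hit <- i_range[m]
    # split wherever the gap between successive matches exceeds max_gap
    grp <- cumsum(c(TRUE, diff(hit) - 1L > max_gap))
    for (g in split(hit, grp)) {
      if (length(g) >= min_run) {
        segs[[length(segs) + 1L]] <-
          c(start_i = g[1L], offset = off, n_matches = length(g))
      }
    }
  }
  if (!length(segs)) {
    return(data.frame(start_i = integer(), offset = integer(),
                      n_matches = integer()))
  }
  out <- as.data.frame(do.call(rbind, segs))
  out[order(out$offset, out$start_i), , drop = FALSE]
}

# ---- brute-force UPGMA -----------------------------------------------------

# textbook agglomeration on the raw matrix: repeatedly merge the closest
# pair, averaging distances weighted by cluster sizes. Returns merge heights
# sorted (merge-tree shape comparisons are done via cophenetic distances).
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        dd <- mean(d[active[[a]], active[[b]]])
        if (dd < bestd) { bestd <- dd; best <- c(b, a) }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(active[[best[1L]]], active[[best[2L]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  sort(heights)
}

# full cophenetic matrix from the same brute-force agglomeration
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        dd <- mean(d[active[[a]], active[[b]]])
        if (dd < bestd) { bestd <- dd; best <- c(b, a) }
      }
    }
    for (x in active[[best[1L]]]) for (y in active[[best[2L]]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    merged <- c(active[[best[1L]]], active[[best[2L]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  coph
}

# ---- direct-summation AC oracle -------------------------------------------

# plain double-precision summation of p(k|x) terms via the closed product
# form (no log space, no lchoose): independent of the package's log-space
# path. Valid while terms stay in double range (small x, y, moderate r).
oracle_ac_two_sided <- function(x, y, N1, N2) {
  if (N1 > N2 || (N1 == N2 && x > y)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
  }
  r <- N2 / N1
  pk <- function(k) {
    # C(x+k, k) * r^k / (1+r)^(x+k+1) built as a running product
    v <- 1 / (1 + r)^(x + 1)
    if (k > 0) for (j in 1:k) v <- v * (x + j) / j * r / (1 + r)
    v
  }
  terms <- vapply(0:max(y, x + 50, 200), pk, numeric(1L))
  lower <- sum(terms[1:(y + 1L)])
  upper <- 1 - if (y > 0) sum(terms[1:y]) else 0
  min(1, 2 * min(lower, upper))
}

# frozen exact-rational oracle grid (generated once with arbitrary-precision
# rational arithmetic; see the package's methods vignette)
load_ac_oracle <- function() {
  utils::read.delim(test_path("ac_oracle_exact.tsv"))
}
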