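# Pairwise alignment (PAF) records as a tibble. PAF coordinates are already
# 0-based half-open, matching the internal convention.

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "matches", "alen", "mapq")

#' Validate a PAF record table
#' @param tbl Data frame with the 12 mandatory PAF columns.
#' @return Tibble with coordinate invariants enforced.
#' @export
as_paf <- function(tbl) {
  tbl <- as_tibble(tbl)[, PAF_COLS]
  if (nrow(tbl) > 0) {
    ok <- tbl$qstart < tbl$qend & tbl$qend <= tbl$qlen &
      tbl$tstart < tbl$tend & tbl$tend <= tbl$tlen &
      tbl$matches <= tbl$alen & tbl$strand %in% c("+", "-")
    if (!all(ok)) {
      abort(sprintf("invalid PAF record at row %d", which(!ok)[1]))
    }
  }
  tbl
}

#' Read / write PAF alignments
#'
#' Reads the 12 mandatory tab-separated PAF columns; trailing SAM-style tags
#' are ignored. Coordinate invariants (`qstart < qend <= qlen`, etc.) are
#' enforced with the offending line number reported.
#'
#' @param path PAF file path.
#' @return `read_paf()` returns a tibble with columns `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`, `matches`,
#'   `alen`, `mapq`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_paf(tibble(qname = character(), qlen = numeric(),
                         qstart = numeric(), qend = numeric(),
                         strand = character(), tname = character(),
                         tlen = numeric(), tstart = numeric(),
                         tend = numeric(), matches = numeric(),
                         alen = numeric(), mapq = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("PAF line %d has fewer than 12 columns", which(nf < 12)[1]))
  }
  num_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  nums <- suppressWarnings(apply(mat[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums)) {
    bad <- which(apply(is.na(nums), 1, any))[1]
    abort(sprintf("non-integer coordinate on PAF line %d", bad))
  }
  tbl <- tibble(qname = mat[, 1], qlen = nums[, 1], qstart = nums[, 2],
                qend = nums[, 3], strand = mat[, 5], tname = mat[, 6],
                tlen = nums[, 4], tstart = nums[, 5], tend = nums[, 6],
                matches = nums[, 7], alen = nums[, 8], mapq = nums[, 9])
  bad <- which(!(tbl$qstart < tbl$qend & tbl$qend <= tbl$qlen &
                   tbl$tstart < tbl$tend & tbl$tend <= tbl$tlen))
  if (length(bad) > 0) {
    abort(sprintf("coordinate invariant violated on PAF line %d", bad[1]))
  }
  as_paf(tbl)
}

#' @rdname read_paf
#' @param paf PAF tibble.
#' @export
write_paf <- function(paf, path) {
  paf <- as_paf(paf)
  out <- paf |>
    dplyr::mutate(dplyr::across(c("qlen", "qstart", "qend", "tlen", "tstart",
                                  "tend", "matches", "alen", "mapq"),
                                ~ format(.x, scientific = FALSE, trim = TRUE)))
  readr::write_tsv(out[, PAF_COLS], path, col_names = FALSE)
  invisible(path)
}
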