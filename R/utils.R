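# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; file readers/writers convert at the boundary.

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse-complemented strings.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a global seed and a stage tag.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  (as.integer(seed) + sum(codes * seq_along(codes))) %% .Machine$integer.max
}

# stop unless all interval rows satisfy start < end
check_intervals <- function(start, end, what = "interval") {
  bad <- which(!(start < end))
  if (length(bad) > 0) {
    abort(sprintf("%s %d has start >= end (%s >= %s)",
                  what, bad[1], format(start[bad[1]], scientific = FALSE),
                  format(end[bad[1]], scientific = FALSE)))
  }
  invisible(TRUE)
}

# overlap width of [s1,e1) and [s2,e2); 0 when disjoint
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# distance from point p to interval [s,e): 0 if inside
point_gap <- function(p, s, e) {
  ifelse(p < s, s - p, ifelse(p >= e, p - e + 1, 0))
}
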