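# Sequence-level comparison of breakpoint region pairs: k-mer seeded gap-free
# local matching (the dot-plot underlying the 25%-identity screen), shared-TE-
# family reports, TIR/tandem-period/ORF structure of repeat consensus
# sequences, and consensus-coverage pileups.

#' Gap-free local matches between two sequences
#'
#' Exact `k`-mer seeds are grouped by diagonal, seeds closer than `max_gap`
#' are merged into one gap-free fragment, fragment ends are extended while
#' bases agree, and identity is computed over every column of the final span.
#' Both strands are searched (the second sequence also as its reverse
#' complement). Fragments shorter than `min_len` or below `min_identity` are
#' dropped.
#'
#' @param seq_a,seq_b DNA strings.
#' @param k Seed k-mer size (must not exceed either sequence length).
#' @param min_len Minimum fragment span (bp).
#' @param min_identity Minimum identity over the fragment span.
#' @param max_gap Maximum distance between seeds merged on one diagonal.
#' @param max_occ Skip k-mers occurring more than this many times in `seq_a`
#'   (guards hyper-repetitive seeds).
#' @param strands Strands to search, subset of `c("+", "-")`.
#' @return A `te_match_fragments` tibble: `a_start`, `a_end`, `b_start`,
#'   `b_end`, `strand`, `length`, `matches`, `identity` (0-based half-open
#'   coordinates on each input).
#' @export
local_matches <- function(seq_a, seq_b, k = 13, min_len = 100,
                          min_identity = 0.25, max_gap = 100, max_occ = 512,
                          strands = c("+", "-")) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) abort("empty sequence")
  if (k > min(nchar(seq_a), nchar(seq_b))) {
    abort("`k` exceeds a sequence length")
  }
  df <- .local_matches_cpp(toupper(seq_a), toupper(seq_b), as.integer(k),
                           as.integer(min_len), min_identity,
                           as.integer(max_gap), as.integer(max_occ),
                           "+" %in% strands, "-" %in% strands)
  out <- as_tibble(df)
  out <- dplyr::arrange(out, .data$a_start, .data$b_start)
  class(out) <- c("te_match_fragments", class(out))
  out
}

#' Open reading frames in six frames
#'
#' Scans ATG-to-stop spans on both strands; coordinates are 0-based half-open
#' on the input sequence, `length_aa` counts codons excluding the stop.
#'
#' @param seq DNA string.
#' @param min_aa Minimum ORF length in amino acids.
#' @return Tibble with `frame` (1-3 forward, 4-6 reverse), `start`, `end`,
#'   `length_aa`.
#' @export
find_orfs <- function(seq, min_aa = 100) {
  seq <- toupper(seq)
  n <- nchar(seq)
  scan_strand <- function(s, frame_offset) {
    res <- list()
    for (f in 0:2) {
      starts <- seq.int(1 + f, n - 2, by = 3)
      if (length(starts) == 0) next
      codons <- substring(s, starts, starts + 2)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      open_from <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open_from) && is_atg[i]) open_from <- i
        if (!is.na(open_from) && is_stop[i]) {
          aa <- i - open_from
          if (aa >= min_aa) {
            res[[length(res) + 1]] <- tibble(
              frame = frame_offset + f + 1,
              start = starts[open_from] - 1,
              end = starts[i] + 2,
              length_aa = aa)
          }
          open_from <- NA_integer_
        }
      }
    }
    dplyr::bind_rows(res)
  }
  fwd <- scan_strand(seq, 0)
  rev <- scan_strand(revcomp(seq), 3)
  if (nrow(rev) > 0) {
    # map reverse-strand coordinates back to the forward sequence
    tmp <- n - rev$end
    rev$end <- n - rev$start
    rev$start <- tmp
  }
  out <- dplyr::bind_rows(fwd, rev)
  if (nrow(out) == 0) {
    return(tibble(frame = integer(), start = numeric(), end = numeric(),
                  length_aa = numeric()))
  }
  dplyr::arrange(out, .data$frame, .data$start)
}

#' Structural self-analysis of a repeat consensus
#'
#' Reports the terminal-inverted-repeat (TIR) structure, tandem periodicity
#' and ORF content of a sequence: the TIR is the longest gap-free
#' opposite-strand self-match at or above `min_identity` between a 5' and a 3'
#' portion; the tandem period is the most common spacing between recurrences
#' of exact `k`-mers, reported when at least `min_support` recurrences agree
#' (the smallest period wins a tie, so a 167-bp unit is preferred over its
#' 334-bp double); ORFs of `min_aa`+ amino acids are listed in all six frames.
#'
#' @param seq DNA string (>= 50 bp).
#' @param k Seed size for matching and period detection.
#' @param min_tir_len Minimum TIR length to report.
#' @param min_identity Minimum TIR identity.
#' @param min_aa Minimum ORF length (amino acids).
#' @param min_support Minimum number of k-mer recurrences supporting a period.
#' @return A `te_structure` object with `tir_length`, `tir_identity`,
#'   `tandem_period`, `n_units`, `orfs` (tibble); `glance()` and `tidy()`
#'   methods are provided.
#' @export
self_structure <- function(seq, k = 13, min_tir_len = 50, min_identity = 0.8,
                           min_aa = 100, min_support = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 50) abort("sequence too short for structural analysis")

  frags <- local_matches(seq, seq, k = k, min_len = min_tir_len,
                         min_identity = min_identity, strands = "-")
  tir_length <- 0
  tir_identity <- NA_real_
  if (nrow(frags) > 0) {
    # keep one of each mirrored pair (a arm at or before the b arm); a
    # palindromic fragment covers both arms at once, so the arm length is at
    # most half the span from the 5' arm start to the 3' arm end
    cand <- frags[frags$a_start <= frags$b_start, ]
    if (nrow(cand) > 0) {
      arm <- pmin(cand$length, floor((cand$b_end - cand$a_start) / 2))
      best <- which.max(arm)
      if (arm[best] >= min_tir_len) {
        tir_length <- arm[best]
        tir_identity <- cand$identity[best]
      }
    }
  }

  # tandem period from spacings of recurring exact k-mers
  period <- NA_real_
  n_units <- NA_integer_
  if (n >= 2 * k) {
    starts <- 1:(n - k + 1)
    kmers <- substring(seq, starts, starts + k - 1)
    reps <- split(starts, kmers)
    reps <- reps[lengths(reps) >= 2]
    if (length(reps) > 0) {
      gaps <- unlist(lapply(reps, function(p) diff(sort(p))),
                     use.names = FALSE)
      gaps <- gaps[gaps >= 2]
      if (length(gaps) > 0) {
        tabs <- table(gaps)
        best_n <- max(tabs)
        if (best_n >= min_support) {
          modes <- as.integer(names(tabs)[tabs == best_n])
          period <- min(modes)
          # one recurrence per distinct k-mer per adjacent unit pair
          n_units <- as.integer(round(best_n / period)) + 1L
        }
      }
    }
  }

  orfs <- find_orfs(seq, min_aa = min_aa)
  structure(list(length = n, tir_length = tir_length,
                 tir_identity = tir_identity, tandem_period = period,
                 n_units = n_units, orfs = orfs),
            class = "te_structure")
}

#' @export
print.te_structure <- function(x, ...) {
  cat(sprintf(
    "sequence %d bp | TIR %d bp (identity %s) | tandem period %s | %d ORF(s)\n",
    x$length, x$tir_length,
    ifelse(is.na(x$tir_identity), "-", sprintf("%.2f", x$tir_identity)),
    ifelse(is.na(x$tandem_period), "none", paste0(x$tandem_period, " bp")),
    nrow(x$orfs)))
  invisible(x)
}

#' @rdname self_structure
#' @param x A `te_structure` object.
#' @param ... Unused.
#' @export
glance.te_structure <- function(x, ...) {
  tibble(length = x$length, tir_length = x$tir_length,
         tir_identity = x$tir_identity, tandem_period = x$tandem_period,
         n_orfs = nrow(x$orfs))
}

#' @rdname self_structure
#' @export
tidy.te_structure <- function(x, ...) x$orfs

#' TE families shared between two breakpoint regions
#'
#' Following the dot-plot screen, a family is reported when each region holds
#' at least one copy of `min_te_len`+ bp and at least one retained match
#' fragment overlaps a copy of the family in both regions. Copies shorter than
#' `min_te_len` are excluded before grouping.
#'
#' @param annotations Annotation tibble (absolute coordinates).
#' @param region_a,region_b One-row tibbles/lists with `chrom`, `start`,
#'   `end`.
#' @param fragments `te_match_fragments` from [local_matches()] run on the two
#'   region sequences (region-local coordinates).
#' @param min_te_len Minimum copy length (bp).
#' @return Tibble, one row per shared family: `family_id`, `order`,
#'   `superfamily`, `n_copies_a`, `n_copies_b`, `max_copy_length`,
#'   `all_breakpoints_hit`, `orientations`, and a nested `copies` tibble
#'   (`region`, `chrom`, `start`, `end`, `strand`, `length`,
#'   `divergence_pct`, `cons_start`, `cons_end`).
#' @export
shared_families <- function(annotations, region_a, region_b, fragments,
                            min_te_len = 100) {
  restrict <- function(region, tag) {
    a <- annotations[annotations$chrom == region$chrom &
                       annotations$end > region$start &
                       annotations$start < region$end, ]
    a$length <- a$end - a$start
    a <- a[a$length >= min_te_len, ]
    a$region <- tag
    a
  }
  aa <- restrict(region_a, "A")
  ab <- restrict(region_b, "B")
  shared <- intersect(unique(aa$family_id), unique(ab$family_id))
  if (length(shared) == 0 || nrow(fragments) == 0) {
    return(tibble(family_id = character(), order = character(),
                  superfamily = character(), n_copies_a = integer(),
                  n_copies_b = integer(), max_copy_length = numeric(),
                  all_breakpoints_hit = logical(), orientations = character(),
                  copies = list()))
  }
  # fragment coordinates in absolute frame
  fa_s <- region_a$start + fragments$a_start
  fa_e <- region_a$start + fragments$a_end
  fb_s <- region_b$start + fragments$b_start
  fb_e <- region_b$start + fragments$b_end

  out <- purrr::map(shared, function(fam) {
    ca <- aa[aa$family_id == fam, ]
    cb <- ab[ab$family_id == fam, ]
    # does any single fragment overlap a copy of fam in both regions?
    hit <- FALSE
    for (i in seq_along(fa_s)) {
      in_a <- any(ca$end > fa_s[i] & ca$start < fa_e[i])
      in_b <- any(cb$end > fb_s[i] & cb$start < fb_e[i])
      if (in_a && in_b) { hit <- TRUE; break }
    }
    if (!hit) return(NULL)
    copies <- dplyr::bind_rows(ca, cb)[, c("region", "chrom", "start", "end",
                                           "strand", "length",
                                           "divergence_pct", "cons_start",
                                           "cons_end")]
    tibble(family_id = fam, order = ca$order[1], superfamily = ca$superfamily[1],
           n_copies_a = nrow(ca), n_copies_b = nrow(cb),
           max_copy_length = max(copies$length),
           all_breakpoints_hit = TRUE,
           orientations = paste(sort(unique(copies$strand)), collapse = ""),
           copies = list(copies))
  })
  dplyr::bind_rows(out)
}

#' Count shared families with long copies in every breakpoint
#'
#' @param report Output of [shared_families()] (possibly several inversions
#'   bound together).
#' @param min_len Copies must reach this length (bp) in every region.
#' @return Number of families whose every breakpoint region holds at least
#'   one copy of `min_len`+ bp.
#' @export
count_long_shared <- function(report, min_len = 1000) {
  if (nrow(report) == 0) return(0L)
  ok <- purrr::map_lgl(report$copies, function(cp) {
    all(vapply(split(cp$length, cp$region), function(v) any(v >= min_len),
               logical(1)))
  })
  sum(ok)
}

#' Consensus-coverage pileup of genomic copies
#'
#' Depth of genomic hits at every consensus position; uncovered internal
#' stretches (e.g. a lost transposase region) show up as zero-depth runs.
#'
#' @param hits Tibble with `cons_start`, `cons_end` (0-based half-open on the
#'   consensus).
#' @param consensus_length Consensus length in bp.
#' @return A `te_consensus_coverage` tibble: `position` (0-based), `depth`.
#' @export
consensus_coverage <- function(hits, consensus_length) {
  hits <- hits[!is.na(hits$cons_start) & !is.na(hits$cons_end), ]
  if (nrow(hits) > 0 &&
      (min(hits$cons_start) < 0 || max(hits$cons_end) > consensus_length)) {
    abort("hit interval outside consensus bounds")
  }
  depth <- rep(0L, consensus_length)
  if (nrow(hits) > 0) {
    cov <- IRanges::coverage(
      IRanges::IRanges(hits$cons_start + 1, hits$cons_end),
      width = consensus_length)
    depth <- as.integer(cov)
  }
  out <- tibble(position = seq_len(consensus_length) - 1L, depth = depth)
  class(out) <- c("te_consensus_coverage", class(out))
  out
}
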