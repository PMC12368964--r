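# Mock-breakpoint resampling null: how often do two random regions of a
# chromosome share TE copies of the same family, across region sizes and
# minimum copy lengths?

#' Sample random non-overlapping region pairs
#'
#' Region starts are uniform on `[0, chrom_length - size]`; pairs whose
#' members overlap each other, or that intersect an exclusion interval, are
#' redrawn.
#'
#' @param chrom_length Chromosome length (bp).
#' @param size Region size (bp); `2 * size` must fit in the chromosome.
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param exclude Optional tibble of `start`, `end` intervals to avoid.
#' @param max_attempts Redraw budget per pair before failing.
#' @return Tibble with `pair`, `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
sample_region_pairs <- function(chrom_length, size, n, seed = 1,
                                exclude = NULL, max_attempts = 1000) {
  if (2 * size > chrom_length) {
    abort("chromosome too short for two non-overlapping regions")
  }
  hits_excl <- function(s) {
    !is.null(exclude) && nrow(exclude) > 0 &&
      any(exclude$end > s & exclude$start < s + size)
  }
  lim <- chrom_length - size
  # Uniform draw over non-overlapping pairs: place both starts on the
  # chromosome with the right region's footprint removed, then spread. This
  # is the distribution rejection sampling of overlapping pairs converges to,
  # and it terminates even in the forced-placement case chrom = 2 * size.
  M <- lim - size
  with_seed(seed, {
    res <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        u <- floor(runif(2, 0, M + 1))
        a <- min(u)
        b <- max(u) + size
        if (runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
        if (hits_excl(a) || hits_excl(b)) next
        res[i, ] <- c(a, b)
        ok <- TRUE
        break
      }
      if (!ok) abort("exclusion leaves no valid region placement")
    }
    tibble(pair = seq_len(n), a_start = res[, 1], a_end = res[, 1] + size,
           b_start = res[, 2], b_end = res[, 2] + size)
  })
}

#' Same-family TE count shared by a region pair
#'
#' Counts distinct families with at least one copy of `min_length`+ bp (full
#' annotation length) intersecting region A and at least one intersecting
#' region B (1-bp overlap counts). `statistic = "copy_pairs"` instead sums,
#' over those families, the number of copy pairs.
#'
#' @param annotations Annotation tibble.
#' @param region_a,region_b Lists/one-row tibbles with `chrom`, `start`,
#'   `end`.
#' @param min_length Minimum copy length (bp).
#' @param statistic "families" (default) or "copy_pairs".
#' @return A single count.
#' @export
shared_family_count <- function(annotations, region_a, region_b,
                                min_length = 0,
                                statistic = c("families", "copy_pairs")) {
  statistic <- match.arg(statistic)
  pick <- function(region) {
    a <- annotations[annotations$chrom == region$chrom &
                       annotations$end > region$start &
                       annotations$start < region$end, ]
    a[a$end - a$start >= min_length, ]
  }
  a <- pick(region_a)
  b <- pick(region_b)
  fams <- intersect(unique(a$family_id), unique(b$family_id))
  if (statistic == "families") return(length(fams))
  sum(vapply(fams, function(f) {
    sum(a$family_id == f) * sum(b$family_id == f)
  }, numeric(1)))
}

#' Resampling null for same-family TE sharing
#'
#' For every combination of region size and minimum TE length, draws `n_pairs`
#' mock breakpoint pairs and records the shared-family count of each,
#' yielding the expected count (and its full distribution) under random
#' placement.
#'
#' @param annotations Annotation tibble (one chromosome).
#' @param chrom Chromosome name.
#' @param n_pairs Number of mock pairs per grid cell.
#' @param region_sizes Region sizes (bp).
#' @param min_lengths Minimum TE copy lengths (bp).
#' @param seed Integer seed.
#' @param exclude Optional exclusion intervals (e.g. centromere calls).
#' @param statistic See [shared_family_count()].
#' @return A `te_null_grid` tibble: `size`, `min_length`, `mean_shared`,
#'   `distribution` (list of per-pair counts).
#' @export
run_null <- function(annotations, chrom, n_pairs = 1000,
                     region_sizes = seq(10000, 100000, by = 10000),
                     min_lengths = c(0, 100, 500, 1000, 2000), seed = 1,
                     exclude = NULL, statistic = "families") {
  cl <- chrom_lengths(annotations)
  if (!chrom %in% names(cl)) abort(paste0("unknown chromosome: ", chrom))
  L <- cl[[chrom]]
  ann <- annotations[annotations$chrom == chrom, ]
  ann$len <- ann$end - ann$start

  grid <- list()
  for (size in region_sizes) {
    pairs <- sample_region_pairs(L, size, n_pairs,
                                 seed = derive_seed(seed, paste0("sz", size)),
                                 exclude = exclude)
    # one overlap pass per side, reused for every min_length
    q_a <- IRanges::IRanges(pairs$a_start + 1, pairs$a_end)
    q_b <- IRanges::IRanges(pairs$b_start + 1, pairs$b_end)
    subj <- IRanges::IRanges(ann$start + 1, ann$end)
    ov_a <- IRanges::findOverlaps(q_a, subj)
    ov_b <- IRanges::findOverlaps(q_b, subj)
    tab_a <- tibble(pair = S4Vectors::queryHits(ov_a),
                    family_id = ann$family_id[S4Vectors::subjectHits(ov_a)],
                    len = ann$len[S4Vectors::subjectHits(ov_a)])
    tab_b <- tibble(pair = S4Vectors::queryHits(ov_b),
                    family_id = ann$family_id[S4Vectors::subjectHits(ov_b)],
                    len = ann$len[S4Vectors::subjectHits(ov_b)])
    for (ml in min_lengths) {
      if (statistic == "families") {
        fa <- dplyr::distinct(tab_a[tab_a$len >= ml, c("pair", "family_id")])
        fb <- dplyr::distinct(tab_b[tab_b$len >= ml, c("pair", "family_id")])
        both <- dplyr::inner_join(fa, fb, by = c("pair", "family_id"))
        counts <- dplyr::count(both, .data$pair)
      } else {
        fa <- dplyr::count(tab_a[tab_a$len >= ml, ], .data$pair,
                           .data$family_id, name = "na")
        fb <- dplyr::count(tab_b[tab_b$len >= ml, ], .data$pair,
                           .data$family_id, name = "nb")
        both <- dplyr::inner_join(fa, fb, by = c("pair", "family_id"))
        both$n <- both$na * both$nb
        counts <- both |>
          dplyr::group_by(.data$pair) |>
          dplyr::summarise(n = sum(.data$n), .groups = "drop")
      }
      dist <- rep(0, n_pairs)
      dist[counts$pair] <- counts$n
      grid[[length(grid) + 1]] <- tibble(
        size = size, min_length = ml, mean_shared = mean(dist),
        distribution = list(dist))
    }
  }
  out <- dplyr::bind_rows(grid)
  attr(out, "n_pairs") <- n_pairs
  attr(out, "chrom") <- chrom
  attr(out, "statistic") <- statistic
  class(out) <- c("te_null_grid", class(out))
  out
}

#' Compare observed breakpoint-pair sharing against the null grid
#'
#' Adds the observed shared-family count of the real breakpoint pair to every
#' grid cell, with an add-one empirical p-value
#' `(1 + #{mock >= observed}) / (n_pairs + 1)`.
#'
#' @param null_grid Output of [run_null()].
#' @param annotations Annotation tibble.
#' @param region_a,region_b The real breakpoint regions (`chrom`, `start`,
#'   `end`).
#' @return The grid with `observed` and `empirical_p` columns.
#' @export
compare_observed <- function(null_grid, annotations, region_a, region_b) {
  stat <- attr(null_grid, "statistic") %||% "families"
  obs <- vapply(null_grid$min_length, function(ml) {
    shared_family_count(annotations, region_a, region_b, min_length = ml,
                        statistic = stat)
  }, numeric(1))
  n_pairs <- attr(null_grid, "n_pairs") %||%
    length(null_grid$distribution[[1]])
  p <- vapply(seq_len(nrow(null_grid)), function(i) {
    (1 + sum(null_grid$distribution[[i]] >= obs[i])) / (n_pairs + 1)
  }, numeric(1))
  null_grid$observed <- obs
  null_grid$empirical_p <- p
  null_grid
}

#' @rdname run_null
#' @param x A `te_null_grid`.
#' @param ... Unused.
#' @export
tidy.te_null_grid <- function(x, ...) {
  out <- as_tibble(x)[, setdiff(names(x), "distribution")]
  out
}

#' @rdname run_null
#' @export
glance.te_null_grid <- function(x, ...) {
  tibble(n_cells = nrow(x), n_pairs = attr(x, "n_pairs"),
         chrom = attr(x, "chrom"),
         max_mean_shared = max(x$mean_shared))
}
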