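# Sliding-window TE density, centromere estimation/exclusion, and
# breakpoint-versus-background enrichment statistics.

#' Tile a chromosome set into nonoverlapping windows
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param size Window size in bp. The final partial window is kept and
#'   flagged.
#' @return Tibble with `chrom`, `start`, `end`, `index`, `partial`.
#' @export
tile_windows <- function(chrom_lengths, size = 50000) {
  if (size < 1) abort("`size` must be >= 1")
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chr) {
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    tibble(chrom = chr, start = starts, end = ends,
           index = seq_along(starts), partial = ends - starts < size)
  })
}

#' Per-window TE density track
#'
#' Density is the merged-coverage fraction of each window: distinct covered
#' bases / window length, for annotations passing the classification filter.
#'
#' @param annotations Annotation tibble.
#' @param windows Window tibble from [tile_windows()].
#' @param level One of "all", "order", "superfamily", "family".
#' @param name Group name(s) when `level != "all"`.
#' @return A `te_density_track` tibble: the windows plus `level`, `group`,
#'   `density`.
#' @export
density_track <- function(annotations, windows, level = "all", name = NULL) {
  ann <- filter_group(annotations, level, name)
  dens <- numeric(nrow(windows))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    a <- ann[ann$chrom == chr, ]
    if (nrow(a) == 0) next
    red <- IRanges::reduce(IRanges::IRanges(a$start + 1, a$end))
    w <- IRanges::IRanges(windows$start[wi] + 1, windows$end[wi])
    hits <- IRanges::findOverlaps(w, red)
    covered <- numeric(length(w))
    if (length(hits) > 0) {
      ov <- IRanges::width(IRanges::pintersect(
        w[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
      covered[as.integer(names(agg))] <- agg
    }
    dens[wi] <- covered / (windows$end[wi] - windows$start[wi])
  }
  out <- windows
  out$level <- level
  out$group <- if (is.null(name)) "all" else paste(name, collapse = "+")
  out$density <- dens
  class(out) <- c("te_density_track", class(out))
  out
}

#' Estimate putative centromeres from repeat density and motif hits
#'
#' Candidate windows are those whose combined interspersed + tandem repeat
#' density exceeds the chromosome mean by `z_threshold` standard deviations,
#' or that contain at least one hit of a known centromeric repeat motif.
#' Adjacent candidates (within `gap_windows`) are merged; each call records
#' which evidence channels supported it.
#'
#' @param interspersed,tandem `te_density_track` tibbles on the same tiling
#'   (typically 10-kb windows); `tandem` may be `NULL`.
#' @param motif_hits Optional tibble of motif hit intervals (`chrom`, `start`,
#'   `end`).
#' @param z_threshold Density peak threshold in SD units.
#' @param gap_windows Merge candidates separated by at most this many
#'   non-candidate windows.
#' @return Tibble of centromere calls: `chrom`, `start`, `end`,
#'   `density_evidence`, `motif_evidence`.
#' @export
estimate_centromere <- function(interspersed, tandem = NULL,
                                motif_hits = NULL, z_threshold = 3,
                                gap_windows = 1) {
  track <- as_tibble(interspersed)[, c("chrom", "start", "end", "density")]
  if (!is.null(tandem)) {
    if (nrow(tandem) != nrow(track)) {
      abort("interspersed and tandem tracks must share one tiling")
    }
    track$density <- track$density + tandem$density
  }
  out <- list()
  for (chr in unique(track$chrom)) {
    tw <- track[track$chrom == chr, ]
    mu <- mean(tw$density)
    sdv <- sd(tw$density)
    dens_cand <- !is.na(sdv) & sdv > 0 & tw$density > mu + z_threshold * sdv
    motif_cand <- rep(FALSE, nrow(tw))
    if (!is.null(motif_hits) && nrow(motif_hits) > 0) {
      mh <- motif_hits[motif_hits$chrom == chr, ]
      if (nrow(mh) > 0) {
        for (i in seq_len(nrow(tw))) {
          motif_cand[i] <- any(mh$end > tw$start[i] & mh$start < tw$end[i])
        }
      }
    }
    cand <- which(dens_cand | motif_cand)
    if (length(cand) == 0) next
    grp <- cumsum(c(1, diff(cand) > gap_windows + 1))
    for (g in unique(grp)) {
      idx <- cand[grp == g]
      out[[length(out) + 1]] <- tibble(
        chrom = chr, start = min(tw$start[idx]), end = max(tw$end[idx]),
        density_evidence = any(dens_cand[idx]),
        motif_evidence = any(motif_cand[idx]))
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  density_evidence = logical(), motif_evidence = logical()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

# split track windows into breakpoint / background classes
split_windows <- function(track, breakpoint_regions, exclude = NULL,
                          min_overlap = 1) {
  keep <- rep(TRUE, nrow(track))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      keep <- keep & !(track$chrom == exclude$chrom[i] &
                         track$end > exclude$start[i] &
                         track$start < exclude$end[i])
    }
  }
  is_bp <- rep(FALSE, nrow(track))
  for (i in seq_len(nrow(breakpoint_regions))) {
    ov <- overlap_bp(track$start, track$end,
                     breakpoint_regions$start[i], breakpoint_regions$end[i])
    is_bp <- is_bp | (track$chrom == breakpoint_regions$chrom[i] &
                        ov >= min_overlap)
  }
  list(keep = keep, is_bp = is_bp)
}

#' Breakpoint-versus-background density test (Student's t)
#'
#' Windows overlapping any breakpoint region form the breakpoint class; all
#' other non-excluded windows on the same chromosome form the background. The
#' two-sided pooled-variance Student's t-test compares their mean densities
#' (Welch available via `welch = TRUE`). Zero pooled variance with equal means
#' gives t = 0, p = 1; with unequal means the test is flagged degenerate.
#'
#' @param track `te_density_track` tibble.
#' @param breakpoint_regions Tibble with `chrom`, `start`, `end`.
#' @param exclude Optional centromere calls to drop from both classes.
#' @param alpha Significance level for the `significant` flag.
#' @param min_overlap Minimum window/region overlap (bp) to count a window as
#'   a breakpoint window.
#' @param welch Use Welch's unequal-variance t instead of the pooled test.
#' @return One-row tibble per chromosome: `group`, `chrom`, `n_bp`, `n_bg`,
#'   `mean_bp`, `mean_bg`, `t_stat`, `df`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
ttest_enrichment <- function(track, breakpoint_regions, exclude = NULL,
                             alpha = 0.05, min_overlap = 1, welch = FALSE) {
  cls <- split_windows(track, breakpoint_regions, exclude, min_overlap)
  out <- list()
  for (chr in unique(track$chrom)) {
    sel <- track$chrom == chr & cls$keep
    x <- track$density[sel & cls$is_bp]
    y <- track$density[sel & !cls$is_bp]
    if (length(x) < 2 || length(y) < 2) {
      abort(sprintf("insufficient windows on %s (%d breakpoint, %d background)",
                    chr, length(x), length(y)))
    }
    n1 <- length(x); n2 <- length(y)
    if (welch) {
      se <- sqrt(var(x) / n1 + var(y) / n2)
      df <- se^4 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
    } else {
      sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
    degenerate <- FALSE
    if (se == 0 || !is.finite(se)) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        t_stat <- 0; p <- 1
      } else {
        t_stat <- sign(mean(x) - mean(y)) * Inf
        p <- .Machine$double.xmin
        degenerate <- TRUE
      }
    } else {
      t_stat <- (mean(x) - mean(y)) / se
      p <- 2 * pt(-abs(t_stat), df)
      if (p == 0) p <- .Machine$double.xmin
    }
    out[[length(out) + 1]] <- tibble(
      group = track$group[1], chrom = chr, n_bp = n1, n_bg = n2,
      mean_bp = mean(x), mean_bg = mean(y), t_stat = t_stat, df = df,
      p_value = p, significant = p < alpha, degenerate = degenerate)
  }
  dplyr::bind_rows(out)
}

#' Two-SD density peak rule for breakpoint regions
#'
#' Chromosome mean and SD are computed over all non-excluded windows; a
#' breakpoint region is flagged when the mean density of its windows strictly
#' exceeds mean + 2 SD, and individual breakpoint windows exceeding the
#' threshold are counted as density peaks.
#'
#' @inheritParams ttest_enrichment
#' @param n_sd Number of SDs above the chromosome mean.
#' @return Tibble, one row per breakpoint region: `chrom`, `start`, `end`,
#'   `region_mean`, `chrom_mean`, `chrom_sd`, `threshold`, `flagged`,
#'   `n_peak_windows`.
#' @export
two_sd_peaks <- function(track, breakpoint_regions, exclude = NULL,
                         n_sd = 2, min_overlap = 1) {
  cls <- split_windows(track, breakpoint_regions, exclude, min_overlap)
  purrr::pmap_dfr(breakpoint_regions, function(chrom, start, end, ...) {
    sel <- track$chrom == chrom & cls$keep
    if (sum(sel) < 2) abort("insufficient windows for the 2-SD rule")
    mu <- mean(track$density[sel])
    sdv <- sd(track$density[sel])
    thr <- mu + n_sd * sdv
    in_region <- sel & overlap_bp(track$start, track$end, start, end) >=
      min_overlap
    rmean <- mean(track$density[in_region])
    tibble(chrom = chrom, start = start, end = end, region_mean = rmean,
           chrom_mean = mu, chrom_sd = sdv, threshold = thr,
           flagged = is.finite(rmean) && rmean > thr,
           n_peak_windows = sum(track$density[in_region] > thr))
  })
}
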