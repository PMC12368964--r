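# Inversion calling from whole-genome alignment blocks, split-read
# refinement, 100-kb breakpoint regions, syntenic projection onto the
# ancestral assembly, and interval-width summaries.

#' Call inversions and breakpoint intervals from PAF alignment blocks
#'
#' Alignment blocks are filtered (`min_block` target span, `min_mapq`) and
#' sorted along the target; every maximal run of "-" blocks flanked by "+"
#' blocks yields one inversion. Breakpoint interval A is the gap between the
#' preceding "+" block and the "-" run; interval B is the gap between the "-"
#' run and the following "+" block — the breakpoints live in the block gaps
#' and are always reported as ranges, never points (an empty gap becomes a
#' 2-bp range around the junction). A missing "+" anchor on one side produces
#' an open-ended interval reaching the chromosome edge, flagged rather than
#' dropped. Two inversions whose facing intervals are closer than `min_gap`
#' are merged into one double-inversion call whose shared middle interval is
#' labelled B (labels A, B, C).
#'
#' @param paf PAF tibble (one query/target genome pair).
#' @param min_block Minimum target span of a block (bp).
#' @param min_mapq Minimum mapping quality.
#' @param min_gap Merge adjacent inversions closer than this into a double
#'   inversion; `Inf` disables merging.
#' @return Tibble of breakpoint intervals on the target assembly: columns
#'   `inversion_id`, `chrom`, `label`, `start`, `end`, `haplotype`
#'   ("derived"), `open_ended`, `double`, `inv_start`, `inv_end`.
#' @export
call_inversions <- function(paf, min_block = 5000, min_mapq = 40,
                            min_gap = 1e5) {
  paf <- as_paf(paf)
  paf <- paf[paf$tend - paf$tstart >= min_block & paf$mapq >= min_mapq, ]
  out <- list()
  for (tn in unique(paf$tname)) {
    blocks <- paf[paf$tname == tn, ]
    blocks <- blocks[order(blocks$tstart, -blocks$matches,
                           -(blocks$tend - blocks$tstart)), ]
    st <- blocks$strand
    tlen <- blocks$tlen[1]
    runs <- rle(st)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    inv_runs <- which(runs$values == "-")
    if (length(inv_runs) == 0) next
    calls <- purrr::map(seq_along(inv_runs), function(j) {
      r <- inv_runs[j]
      first <- starts[r]; last <- ends[r]
      run_start <- min(blocks$tstart[first:last])
      run_end <- max(blocks$tend[first:last])
      left_anchor <- first > 1
      right_anchor <- last < nrow(blocks)
      lo_a <- if (left_anchor) max(blocks$tend[seq_len(first - 1)]) else 0
      hi_b <- if (right_anchor) {
        min(blocks$tstart[(last + 1):nrow(blocks)])
      } else tlen
      gap_interval <- function(lo, hi) {
        if (hi - lo < 2) {
          mid <- floor((lo + hi) / 2)
          c(max(0, mid - 1), min(tlen, mid + 1))
        } else c(lo, hi)
      }
      ia <- gap_interval(lo_a, run_start)
      ib <- gap_interval(run_end, hi_b)
      tibble(label = c("A", "B"),
             start = c(ia[1], ib[1]), end = c(ia[2], ib[2]),
             open_ended = c(!left_anchor, !right_anchor),
             inv_start = run_start, inv_end = run_end, run = j)
    })
    calls <- dplyr::bind_rows(calls)
    # merge adjacent inversions into double-inversion calls
    runs_tbl <- calls |>
      dplyr::distinct(.data$run, .data$inv_start, .data$inv_end)
    group <- seq_len(nrow(runs_tbl))
    if (nrow(runs_tbl) > 1 && is.finite(min_gap)) {
      for (j in 2:nrow(runs_tbl)) {
        if (runs_tbl$inv_start[j] - runs_tbl$inv_end[j - 1] < min_gap) {
          group[j] <- group[j - 1]
        }
      }
    }
    runs_tbl$group <- group
    for (g in unique(group)) {
      members <- runs_tbl$run[runs_tbl$group == g]
      sub <- calls[calls$run %in% members, ]
      if (length(members) == 1) {
        iv <- sub
        iv$label <- c("A", "B")
        dbl <- FALSE
      } else {
        # shared middle interval: union of inner-facing gaps
        firstB <- sub[sub$run == members[1] & sub$label == "B", ]
        lastA <- sub[sub$run == members[length(members)] & sub$label == "A", ]
        iv <- dplyr::bind_rows(
          sub[sub$run == members[1] & sub$label == "A", ],
          tibble(label = "B",
                 start = min(firstB$start, lastA$start),
                 end = max(firstB$end, lastA$end),
                 open_ended = FALSE,
                 inv_start = min(sub$inv_start), inv_end = max(sub$inv_end),
                 run = members[1]),
          sub[sub$run == members[length(members)] & sub$label == "B", ])
        iv$label <- c("A", "B", "C")
        dbl <- TRUE
      }
      out[[length(out) + 1]] <- tibble(
        inversion_id = sprintf("%s_inv%d", tn, g),
        chrom = tn, label = iv$label, start = iv$start, end = iv$end,
        haplotype = "derived", open_ended = iv$open_ended, double = dbl,
        inv_start = min(iv$inv_start), inv_end = max(iv$inv_end))
    }
  }
  if (length(out) == 0) {
    return(tibble(inversion_id = character(), chrom = character(),
                  label = character(), start = numeric(), end = numeric(),
                  haplotype = character(), open_ended = logical(),
                  double = logical(), inv_start = numeric(),
                  inv_end = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Refine breakpoint intervals with opposite-strand split reads
#'
#' A qualifying read has exactly two alignment segments on opposite strands,
#' each overlapping (within `slop`) a distinct candidate interval. The clip
#' position of a segment — the boundary adjacent to its split — marks the
#' breakpoint, so the refined interval is the tightest span consistent with
#' all clips. Refinement never widens: the result is intersected with the
#' input interval; with no qualifying reads the interval is returned unchanged
#' with `support = 0`; contradictory clips (negative span) leave the interval
#' unrefined with `conflict = TRUE`.
#'
#' @param segments PAF tibble of per-read alignment segments (`qname` groups a
#'   read).
#' @param intervals Breakpoint interval tibble from [call_inversions()].
#' @param slop Extra margin (bp) when matching segments to intervals.
#' @return `intervals` with refined `start`/`end` plus `support` and
#'   `conflict` columns.
#' @export
refine_with_clipped_reads <- function(segments, intervals, slop = 1000) {
  segments <- as_paf(segments)
  intervals <- as_tibble(intervals)
  intervals$support <- 0L
  intervals$conflict <- FALSE
  if (nrow(segments) == 0 || nrow(intervals) == 0) return(intervals)

  by_read <- split(segments, segments$qname)
  clips <- list()
  for (rd in by_read) {
    if (nrow(rd) != 2 || length(unique(rd$strand)) != 2) next
    hit <- integer(2)
    for (s in 1:2) {
      ov <- which(intervals$chrom == rd$tname[s] &
                    rd$tend[s] > intervals$start - slop &
                    rd$tstart[s] < intervals$end + slop)
      if (length(ov) == 0) { hit <- NULL; break }
      mids <- (intervals$start[ov] + intervals$end[ov]) / 2
      d <- pmin(abs(rd$tstart[s] - mids), abs(rd$tend[s] - mids))
      hit[s] <- ov[which.min(d)]
    }
    if (is.null(hit) || hit[1] == hit[2]) next
    for (s in 1:2) {
      iv <- hit[s]
      mid <- (intervals$start[iv] + intervals$end[iv]) / 2
      # the boundary closer to the interval is the clipped junction
      if (abs(rd$tend[s] - mid) <= abs(rd$tstart[s] - mid)) {
        clips[[length(clips) + 1]] <-
          tibble(interval = iv, side = "left", pos = rd$tend[s])
      } else {
        clips[[length(clips) + 1]] <-
          tibble(interval = iv, side = "right", pos = rd$tstart[s])
      }
    }
  }
  if (length(clips) == 0) return(intervals)
  clips <- dplyr::bind_rows(clips)
  for (iv in unique(clips$interval)) {
    cc <- clips[clips$interval == iv, ]
    lo <- if (any(cc$side == "left")) max(cc$pos[cc$side == "left"]) else NA
    hi <- if (any(cc$side == "right")) min(cc$pos[cc$side == "right"]) else NA
    if (is.na(lo)) lo <- hi
    if (is.na(hi)) hi <- lo
    if (lo > hi) {
      intervals$conflict[iv] <- TRUE
      next
    }
    if (hi - lo < 2) { lo <- lo - 1; hi <- hi + 1 }
    new_lo <- max(lo, intervals$start[iv])
    new_hi <- min(hi, intervals$end[iv])
    if (new_lo < new_hi) {
      intervals$start[iv] <- new_lo
      intervals$end[iv] <- new_hi
      intervals$support[iv] <- nrow(cc)
    } else {
      intervals$conflict[iv] <- TRUE
    }
  }
  intervals
}

#' Expand breakpoint intervals into fixed-width analysis regions
#'
#' Each interval's midpoint is extended by `flank` bp in both directions
#' (100-kb regions by default); regions truncated at a chromosome edge are
#' flagged `clamped`.
#'
#' @param intervals Breakpoint interval tibble (columns `chrom`, `start`,
#'   `end`; other columns carried through).
#' @param flank Flank size in bp on each side of the midpoint.
#' @param chrom_lengths Named chromosome lengths.
#' @return Tibble with `chrom`, `start`, `end`, `midpoint`, `clamped` plus the
#'   source interval columns prefixed `source_`.
#' @export
make_breakpoint_regions <- function(intervals, flank = 50000,
                                    chrom_lengths) {
  intervals <- as_tibble(intervals)
  mid <- floor((intervals$start + intervals$end) / 2)
  lo <- mid - flank
  hi <- mid + flank
  lens <- chrom_lengths[intervals$chrom]
  clamped <- lo < 0 | hi > lens
  col_or_na <- function(nm) {
    if (nm %in% names(intervals)) intervals[[nm]]
    else rep(NA_character_, nrow(intervals))
  }
  tibble(chrom = intervals$chrom,
         start = pmax(0, lo), end = pmin(unname(lens), hi),
         midpoint = mid, clamped = unname(clamped),
         source_label = col_or_na("label"),
         source_start = intervals$start, source_end = intervals$end,
         inversion_id = col_or_na("inversion_id"))
}

#' Project a breakpoint region onto the other haplotype's assembly
#'
#' All alignment blocks of `cross_paf` (query = the region's assembly,
#' target = the other assembly) intersecting the region on the query side are
#' projected through the block offset ("+" blocks keep orientation, "-"
#' blocks reverse it); the outer boundaries of the projections define the
#' syntenic region.
#'
#' @param region One-row tibble/list with `chrom`, `start`, `end`.
#' @param cross_paf PAF tibble mapping the region's assembly (query) onto the
#'   other assembly (target).
#' @return One-row tibble: `chrom` (target), `start`, `end`, `haplotype =
#'   "ancestral"`, `n_blocks`.
#' @export
project_syntenic_regions <- function(region, cross_paf) {
  cross_paf <- as_paf(cross_paf)
  blk <- cross_paf[cross_paf$qname == region$chrom &
                     cross_paf$qend > region$start &
                     cross_paf$qstart < region$end, ]
  if (nrow(blk) == 0) abort("unmappable region: no alignment block intersects")
  proj <- purrr::pmap_dfr(blk, function(qstart, qend, strand, tstart, tend,
                                        ...) {
    s <- max(qstart, region$start)
    e <- min(qend, region$end)
    if (strand == "+") {
      tibble(lo = tstart + (s - qstart), hi = tstart + (e - qstart))
    } else {
      tibble(lo = tend - (e - qstart), hi = tend - (s - qstart))
    }
  })
  tibble(chrom = blk$tname[1], start = min(proj$lo), end = max(proj$hi),
         haplotype = "ancestral", n_blocks = nrow(blk))
}

#' Summarise breakpoint interval widths
#'
#' Width is `end - start` on the coordinates as given (printed 1-based
#' inclusive ranges are subtracted directly); the standard deviation uses the
#' population divisor n.
#'
#' @param intervals Tibble with `start` and `end` columns.
#' @return An `interval_summary` object; `glance()` gives `n`, `mean_width`,
#'   `sd_width`, and `tidy()` the per-interval widths.
#' @examples
#' s <- summarize_intervals(data.frame(start = c(0, 10), end = c(100, 25)))
#' glance(s)
#' @export
summarize_intervals <- function(intervals) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) == 0) abort("no intervals to summarise")
  w <- intervals$end - intervals$start
  structure(list(n = length(w), widths = w, mean_width = mean(w),
                 sd_width = sqrt(mean((w - mean(w))^2))),
            class = "interval_summary")
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf("%d breakpoint intervals; mean width %s bp; SD %s bp\n",
              x$n, format(round(x$mean_width), big.mark = ","),
              format(round(x$sd_width), big.mark = ",")))
  invisible(x)
}

#' @rdname summarize_intervals
#' @param x An `interval_summary` object.
#' @param ... Unused.
#' @export
glance.interval_summary <- function(x, ...) {
  tibble(n = x$n, mean_width = x$mean_width, sd_width = x$sd_width)
}

#' @rdname summarize_intervals
#' @export
tidy.interval_summary <- function(x, ...) {
  tibble(interval = seq_len(x$n), width = x$widths)
}

#' Read / write a breakpoint coordinate table
#'
#' The TSV uses 1-based inclusive printed coordinates with columns
#' `chrom`, `label`, `start`, `end`, `haplotype`; widths for
#' [summarize_intervals()] are taken on these printed coordinates directly.
#'
#' @param path TSV path.
#' @return Tibble of breakpoint intervals.
#' @export
read_breakpoint_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), label = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    haplotype = readr::col_character()), progress = FALSE)
}

#' @rdname read_breakpoint_table
#' @param intervals Breakpoint interval tibble.
#' @export
write_breakpoint_table <- function(intervals, path) {
  readr::write_tsv(intervals[, c("chrom", "label", "start", "end",
                                 "haplotype")], path)
  invisible(path)
}
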