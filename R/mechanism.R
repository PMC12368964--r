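# Deciding between ectopic recombination and NHEJ from breakpoint-region
# evidence: shared-family chimeric TEs versus non-TE inverted duplications,
# with the signature closest to the breakpoints winning.

#' Find inverted duplications in and between breakpoint regions
#'
#' Opposite-strand gap-free local matches of at least `min_len` bp and
#' `min_identity` identity, searched within each region and between the two
#' regions. Each duplication records the fraction of its two copies covered by
#' TE annotations; a duplication with `te_overlap_fraction < te_threshold`
#' counts as non-TE-derived — the NHEJ signature.
#'
#' @param seq_a,seq_b Region sequences.
#' @param region_a,region_b Their absolute coordinates (`chrom`, `start`,
#'   `end`).
#' @param annotations Annotation tibble (absolute coordinates).
#' @param min_len Minimum duplication length (bp).
#' @param min_identity Minimum identity.
#' @param te_threshold TE-overlap fraction below which a duplication is
#'   non-TE-derived.
#' @return Tibble: `a_chrom`, `a_start`, `a_end`, `b_chrom`, `b_start`,
#'   `b_end`, `length`, `identity`, `te_overlap_fraction`, `non_te`,
#'   `comparison` ("within_A", "within_B", "between").
#' @export
find_inverted_duplications <- function(seq_a, seq_b, region_a, region_b,
                                       annotations, min_len = 300,
                                       min_identity = 0.8,
                                       te_threshold = 0.2) {
  te_frac <- function(chrom, s1, e1, chrom2, s2, e2) {
    cl <- chrom_lengths(annotations)
    covered <- 0
    for (iv in list(c(s1, e1, chrom), c(s2, e2, chrom2))) {
      s <- max(0, as.numeric(iv[1]))
      e <- min(cl[[iv[3]]], as.numeric(iv[2]))
      if (e > s) {
        covered <- covered +
          merged_coverage(annotations, iv[3], s, e)
      }
    }
    covered / ((e1 - s1) + (e2 - s2))
  }
  one <- function(sa, sb, ra, rb, tag) {
    fr <- local_matches(sa, sb, min_len = min_len,
                        min_identity = min_identity, strands = "-")
    if (tag != "between" && nrow(fr) > 0) {
      # self comparison: drop mirrored twins, keep a-arm before b-arm
      fr <- fr[fr$a_start < fr$b_start, ]
    }
    if (nrow(fr) == 0) return(NULL)
    tibble(a_chrom = ra$chrom, a_start = ra$start + fr$a_start,
           a_end = ra$start + fr$a_end,
           b_chrom = rb$chrom, b_start = rb$start + fr$b_start,
           b_end = rb$start + fr$b_end,
           length = fr$length, identity = fr$identity, comparison = tag)
  }
  out <- dplyr::bind_rows(
    one(seq_a, seq_a, region_a, region_a, "within_A"),
    one(seq_b, seq_b, region_b, region_b, "within_B"),
    one(seq_a, seq_b, region_a, region_b, "between"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(a_chrom = character(), a_start = numeric(),
                  a_end = numeric(), b_chrom = character(),
                  b_start = numeric(), b_end = numeric(), length = numeric(),
                  identity = numeric(), te_overlap_fraction = numeric(),
                  non_te = logical(), comparison = character()))
  }
  out$te_overlap_fraction <- purrr::pmap_dbl(
    out[, c("a_chrom", "a_start", "a_end", "b_chrom", "b_start", "b_end")],
    function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
      te_frac(a_chrom, a_start, a_end, b_chrom, b_start, b_end)
    })
  out$non_te <- out$te_overlap_fraction < te_threshold
  out
}

#' Score shared TE families as ectopic-recombination evidence
#'
#' A family qualifies when every breakpoint has at least one copy overlapping
#' or within `slop` of the breakpoint interval, the near-breakpoint copies
#' occur in opposite orientations, and the copies' consensus sub-intervals
#' overlap by at least half of the shorter one (chimeras from one
#' recombination event represent the same consensus portion). The family's
#' distance is the largest over breakpoints of the closest copy's distance to
#' the breakpoint midpoint; non-qualifying families stay listed with their
#' distances for ranking.
#'
#' @param report Output of [shared_families()] for one inversion.
#' @param intervals Breakpoint interval tibble (the inversion's intervals, in
#'   the same coordinate frame as the report's copies).
#' @param slop Copy-to-interval tolerance (bp).
#' @param min_cons_overlap Minimum consensus-interval overlap fraction.
#' @return Tibble: `family_id`, `qualifies`, `distance`, `near_all`,
#'   `opposite_orientation`, `cons_overlap_ok`.
#' @export
ectopic_evidence <- function(report, intervals, slop = 2000,
                             min_cons_overlap = 0.5) {
  if (nrow(report) == 0) {
    return(tibble(family_id = character(), qualifies = logical(),
                  distance = numeric(), near_all = logical(),
                  opposite_orientation = logical(),
                  cons_overlap_ok = logical()))
  }
  mids <- floor((intervals$start + intervals$end) / 2)
  purrr::pmap_dfr(report, function(family_id, copies, ...) {
    cp <- copies
    near <- purrr::map(seq_along(mids), function(i) {
      d <- point_gap(mids[i], cp$start, cp$end)
      near_iv <- cp$end > intervals$start[i] - slop &
        cp$start < intervals$end[i] + slop
      list(dist = if (any(near_iv)) min(d[near_iv]) else min(d),
           ok = any(near_iv),
           rows = which(near_iv))
    })
    near_all <- all(purrr::map_lgl(near, "ok"))
    distance <- max(purrr::map_dbl(near, "dist"))
    near_rows <- unique(unlist(purrr::map(near, "rows")))
    strands <- unique(cp$strand[near_rows])
    opposite <- length(strands) == 2
    # consensus-interval overlap between copies at different breakpoints
    cons_ok <- FALSE
    if (length(near) >= 2) {
      for (i in near[[1]]$rows) {
        for (j in setdiff(near_rows, near[[1]]$rows)) {
          a <- cp[i, ]; b <- cp[j, ]
          if (anyNA(c(a$cons_start, a$cons_end, b$cons_start, b$cons_end))) {
            next
          }
          ov <- overlap_bp(a$cons_start, a$cons_end, b$cons_start, b$cons_end)
          shorter <- min(a$cons_end - a$cons_start, b$cons_end - b$cons_start)
          if (shorter > 0 && ov / shorter >= min_cons_overlap) {
            cons_ok <- TRUE
          }
        }
      }
    }
    tibble(family_id = family_id,
           qualifies = near_all && opposite && cons_ok,
           distance = distance, near_all = near_all,
           opposite_orientation = opposite, cons_overlap_ok = cons_ok)
  })
}

#' Classify the inversion mechanism from breakpoint signatures
#'
#' With only ectopic evidence (qualifying shared families) the call is
#' ectopic recombination; with only NHEJ evidence (non-TE inverted
#' duplications) the call is NHEJ; with both, the signature closest to the
#' breakpoints wins, and distances within `tie_margin` give "ambiguous"; with
#' neither, "no_signal".
#'
#' @param ectopic Output of [ectopic_evidence()].
#' @param nhej Output of [find_inverted_duplications()]; only `non_te`
#'   duplications count as NHEJ evidence.
#' @param intervals Breakpoint interval tibble of the inversion.
#' @param tie_margin Distance difference (bp) treated as a tie.
#' @param inversion_id Label carried into the call.
#' @return A `mechanism_call` object; `glance()` returns the one-row summary
#'   and `tidy()` the evidence table.
#' @export
classify_mechanism <- function(ectopic, nhej, intervals, tie_margin = 5000,
                               inversion_id = NA_character_) {
  mids <- floor((intervals$start + intervals$end) / 2)
  ect <- ectopic[ectopic$qualifies, , drop = FALSE]
  d_e <- if (nrow(ect) > 0) min(ect$distance) else NA_real_
  nh <- nhej[nhej$non_te, , drop = FALSE]
  d_n <- NA_real_
  if (nrow(nh) > 0) {
    dup_dist <- purrr::pmap_dbl(nh, function(a_start, a_end, b_start, b_end,
                                             ...) {
      da <- min(vapply(mids, function(m) point_gap(m, a_start, a_end),
                       numeric(1)))
      db <- min(vapply(mids, function(m) point_gap(m, b_start, b_end),
                       numeric(1)))
      max(da, db)
    })
    d_n <- min(dup_dist)
  }
  label <- if (is.na(d_e) && is.na(d_n)) {
    "no_signal"
  } else if (is.na(d_n)) {
    "ectopic_recombination"
  } else if (is.na(d_e)) {
    "nhej"
  } else if (abs(d_e - d_n) <= tie_margin) {
    "ambiguous"
  } else if (d_e < d_n) {
    "ectopic_recombination"
  } else {
    "nhej"
  }
  structure(list(inversion_id = inversion_id, label = label,
                 d_ectopic = d_e, d_nhej = d_n,
                 decisive_distance = suppressWarnings(
                   min(d_e, d_n, na.rm = TRUE)),
                 ectopic_evidence = ectopic, nhej_evidence = nhej),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("inversion %s: %s (ectopic distance %s bp, NHEJ distance %s bp)\n",
              x$inversion_id %||% "?", x$label,
              ifelse(is.na(x$d_ectopic), "-", format(x$d_ectopic)),
              ifelse(is.na(x$d_nhej), "-", format(x$d_nhej))))
  invisible(x)
}

#' @rdname classify_mechanism
#' @param x A `mechanism_call`.
#' @param ... Unused.
#' @export
glance.mechanism_call <- function(x, ...) {
  tibble(inversion_id = x$inversion_id, label = x$label,
         d_ectopic = x$d_ectopic, d_nhej = x$d_nhej,
         decisive_distance = x$decisive_distance)
}

#' @rdname classify_mechanism
#' @export
tidy.mechanism_call <- function(x, ...) {
  dplyr::bind_rows(
    x$ectopic_evidence |>
      dplyr::transmute(signature = "ectopic", id = .data$family_id,
                       qualifies = .data$qualifies,
                       distance = .data$distance),
    x$nhej_evidence |>
      dplyr::transmute(signature = "nhej",
                       id = sprintf("dup_%d", dplyr::row_number()),
                       qualifies = .data$non_te,
                       distance = NA_real_))
}

#' Run the full mechanism decision for one simulated or real inversion
#'
#' Convenience wrapper: extracts the two breakpoint-region sequences,
#' dot-plots them, builds the shared-family report, scores both signature
#' classes and classifies.
#'
#' @param genome Derived genome string.
#' @param annotations Derived annotation tibble.
#' @param intervals Breakpoint interval tibble (two rows, same chromosome).
#' @param flank Region flank (bp).
#' @param min_te_len Minimum copy length for the shared-family report.
#' @param ... Passed to [classify_mechanism()].
#' @return A `mechanism_call`.
#' @export
call_mechanism <- function(genome, annotations, intervals, flank = 50000,
                           min_te_len = 100, ...) {
  cl <- chrom_lengths(annotations)
  regions <- make_breakpoint_regions(intervals, flank = flank,
                                     chrom_lengths = cl)
  ra <- regions[1, ]
  rb <- regions[2, ]
  seq_a <- substr(genome, ra$start + 1, ra$end)
  seq_b <- substr(genome, rb$start + 1, rb$end)
  frags <- local_matches(seq_a, seq_b, min_len = min_te_len,
                         min_identity = 0.25)
  rep <- shared_families(annotations, ra, rb, frags, min_te_len = min_te_len)
  ect <- ectopic_evidence(rep, intervals)
  dups <- find_inverted_duplications(seq_a, seq_b, ra, rb, annotations)
  inv_id <- if ("inversion_id" %in% names(intervals)) {
    intervals$inversion_id[1]
  } else NA_character_
  classify_mechanism(ect, dups, intervals, inversion_id = inv_id, ...)
}
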