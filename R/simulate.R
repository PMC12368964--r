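# Synthetic ancestral/derived genome pairs with TE insertions, an inversion
# created by ectopic recombination or NHEJ, optional centromere-like tandem
# block, truth annotations, truth alignments and breakpoint-spanning reads.
# Every generator is deterministic under its seed; a scenario uses one RNG
# stream with a documented draw order (background, consensus sequences, copy
# placements in call order, inversion geometry, reads).

#' Random background genome sequence
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc GC content as a fraction in \[0, 1\]; bases are i.i.d. with
#'   P(G) + P(C) = `gc`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A single DNA string.
#' @export
make_background <- function(length, gc = 0.45, seed = 1) {
  if (length < 1) abort("`length` must be >= 1")
  if (gc < 0 || gc > 1) abort("`gc` must lie in [0, 1]")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Construct a MITE-like consensus with tandem-unit TIRs
#'
#' Builds `TIR + linker + revcomp(TIR)` where the TIR is a tandem array of one
#' random `unit_len`-bp unit — the structure of a nonautonomous MITE whose
#' terminal inverted repeats are themselves tandem repeats. The construction
#' is redrawn until the consensus contains no open reading frame of
#' `max_orf_aa` codons or more, so the element is transposase-free by
#' construction.
#'
#' @param tir_len TIR length in bp; must be an integer multiple of `unit_len`.
#' @param unit_len Tandem repeat unit length in bp.
#' @param seed Integer seed.
#' @param linker_len Length of the internal linker between the two TIRs.
#' @param family_id,superfamily Classification metadata for the consensus.
#' @param max_orf_aa Redraw while any ORF reaches this many codons.
#' @return A one-row tibble with `family_id`, `order` ("MITE"),
#'   `superfamily`, `sequence`, `length`.
#' @export
make_mite_consensus <- function(tir_len = 501, unit_len = 167, seed = 1,
                                linker_len = 120, family_id = "sim-MITE-1",
                                superfamily = "hAT", max_orf_aa = 50) {
  if (tir_len %% unit_len != 0) {
    abort("`tir_len` must be an integer multiple of `unit_len`")
  }
  with_seed(seed, {
    for (attempt in 1:100) {
      unit <- paste(sample(c("A", "C", "G", "T"), unit_len, replace = TRUE),
                    collapse = "")
      tir <- strrep(unit, tir_len %/% unit_len)
      linker <- paste(sample(c("A", "C", "G", "T"), linker_len,
                             replace = TRUE), collapse = "")
      seq <- paste0(tir, linker, revcomp(tir))
      orfs <- find_orfs(seq, min_aa = max_orf_aa)
      if (nrow(orfs) == 0) {
        return(tibble(family_id = family_id, order = "MITE",
                      superfamily = superfamily, sequence = seq,
                      length = nchar(seq)))
      }
    }
    abort("could not build an ORF-free consensus in 100 attempts")
  })
}

#' Insert TE copies into a genome
#'
#' Each placement inserts the chosen consensus sub-interval (reverse
#' complemented on "-") at an insertion point of the input genome, with
#' i.i.d. substitutions at `divergence_rate`. Later placements and any
#' pre-existing annotations are shifted by the bases inserted before them, so
#' the returned annotations are valid on the returned genome with no liftover.
#'
#' @param genome DNA string.
#' @param consensus One-row tibble as returned by [make_mite_consensus()] or a
#'   row of [read_te_library()].
#' @param placements Tibble with `pos` (insertion point on the input genome,
#'   0-based), `strand`, and optional `cons_start`/`cons_end` (consensus
#'   sub-interval, default full length).
#' @param divergence_rate Per-base substitution probability in \[0, 1).
#' @param seed Integer seed.
#' @param annotations Existing annotation tibble to shift and extend.
#' @param chrom Chromosome name for new annotations.
#' @return List with `genome` (string) and `annotations` (tibble including the
#'   new copies with realized `divergence_pct`).
#' @export
insert_te_copies <- function(genome, consensus, placements,
                             divergence_rate = 0, seed = 1,
                             annotations = NULL, chrom = "chrSim") {
  if (divergence_rate < 0 || divergence_rate >= 1) {
    abort("`divergence_rate` must lie in [0, 1)")
  }
  placements <- as_tibble(placements)
  if (!"cons_start" %in% names(placements)) placements$cons_start <- 0
  if (!"cons_end" %in% names(placements)) {
    placements$cons_end <- consensus$length
  }
  if (anyDuplicated(placements$pos)) {
    dup <- placements$pos[duplicated(placements$pos)][1]
    abort(sprintf("overlapping placements: two insertions at position %d",
                  as.integer(dup)))
  }
  glen <- nchar(genome)
  if (any(placements$pos < 0 | placements$pos > glen)) {
    abort("placement outside genome bounds")
  }
  if (!is.null(annotations) && nrow(annotations) > 0) {
    for (p in placements$pos) {
      inside <- annotations$start < p & p < annotations$end
      if (any(inside)) {
        abort(sprintf(
          "placement at %d falls inside existing copy of %s [%d, %d)",
          as.integer(p), annotations$family_id[which(inside)[1]],
          as.integer(annotations$start[which(inside)[1]]),
          as.integer(annotations$end[which(inside)[1]])))
      }
    }
  }
  placements <- dplyr::arrange(placements, .data$pos)

  with_seed(seed, {
    pieces <- character(2 * nrow(placements) + 1)
    new_ann <- vector("list", nrow(placements))
    prev <- 0
    shift <- 0
    for (i in seq_len(nrow(placements))) {
      p <- placements$pos[i]
      cs <- placements$cons_start[i]
      ce <- placements$cons_end[i]
      if (cs < 0 || ce > consensus$length || cs >= ce) {
        abort("consensus sub-interval out of bounds")
      }
      copy <- substr(consensus$sequence, cs + 1, ce)
      if (placements$strand[i] == "-") copy <- revcomp(copy)
      n <- nchar(copy)
      realized <- 0
      if (divergence_rate > 0) {
        hit <- which(runif(n) < divergence_rate)
        if (length(hit) > 0) {
          v <- strsplit(copy, "")[[1]]
          alt <- vapply(v[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
          v[hit] <- alt
          copy <- paste(v, collapse = "")
          realized <- length(hit) / n
        }
      }
      pieces[2 * i - 1] <- substr(genome, prev + 1, p)
      pieces[2 * i] <- copy
      prev <- p
      new_ann[[i]] <- tibble(
        chrom = chrom, start = p + shift, end = p + shift + n,
        strand = placements$strand[i], family_id = consensus$family_id,
        order = consensus$order, superfamily = consensus$superfamily,
        divergence_pct = realized * 100, cons_start = cs, cons_end = ce,
        score = NA_real_, star = FALSE)
      shift <- shift + n
    }
    pieces[2 * nrow(placements) + 1] <- substr(genome, prev + 1, glen)
    out_genome <- paste(pieces, collapse = "")

    new_tbl <- dplyr::bind_rows(new_ann)
    if (!is.null(annotations) && nrow(annotations) > 0) {
      old <- annotations
      ins_pos <- placements$pos
      ins_len <- new_tbl$end - new_tbl$start
      shift_of <- function(x) {
        vapply(x, function(v) sum(ins_len[ins_pos <= v]), numeric(1))
      }
      old$start <- old$start + shift_of(old$start)
      old$end <- old$end + shift_of(old$end - 1)
      combined <- dplyr::bind_rows(old, new_tbl)
    } else {
      combined <- new_tbl
    }
    out_ann <- as_te_annotations(
      combined, chrom_lengths = setNames(nchar(out_genome), chrom))
    new_idx <- which(paste(out_ann$start, out_ann$end, out_ann$family_id,
                           out_ann$strand) %in%
                       paste(new_tbl$start, new_tbl$end, new_tbl$family_id,
                             new_tbl$strand))
    list(genome = out_genome, annotations = out_ann, new_idx = new_idx)
  })
}

#' Create an inversion by ectopic recombination between two TE copies
#'
#' Recombination between two same-family copies in inverted orientation
#' reverse-complements the intervening segment in place. The crossover happens
#' at homologous consensus coordinates (`offset_a`, `offset_b`) inside each
#' copy, so the two flanking copies become chimeras whose parts derive from
#' both parents — the hallmark ectopic-recombination signature. The two
#' crossover genome positions are the true breakpoints.
#'
#' @param genome DNA string.
#' @param annotations Annotation tibble on `genome`.
#' @param copy_a,copy_b Row indices into `annotations`; must be the same
#'   family, on opposite strands, with `copy_a` upstream of `copy_b`.
#' @param offset_a,offset_b Crossover position in consensus coordinates; the
#'   default is the midpoint of each copy's consensus interval.
#' @return List with `genome` (derived), `annotations` (derived, chimeric
#'   copies split), `true_breakpoints` (the two crossover positions),
#'   `mechanism = "ectopic"`.
#' @export
apply_ectopic_inversion <- function(genome, annotations, copy_a, copy_b,
                                    offset_a = NULL, offset_b = NULL) {
  a <- annotations[copy_a, ]
  b <- annotations[copy_b, ]
  if (a$family_id != b$family_id) {
    abort("ectopic inversion requires two copies of the same family")
  }
  if (a$strand == b$strand) {
    abort("ectopic inversion requires inverted orientation")
  }
  if (a$start >= b$start) abort("copy A must precede copy B")
  if (is.null(offset_a)) offset_a <- floor((a$cons_start + a$cons_end) / 2)
  if (is.null(offset_b)) offset_b <- floor((b$cons_start + b$cons_end) / 2)

  cons_to_genome <- function(copy, off) {
    if (off < copy$cons_start || off > copy$cons_end) {
      abort("crossover offset outside the copy's consensus interval")
    }
    if (copy$strand == "+") copy$start + (off - copy$cons_start)
    else copy$end - (off - copy$cons_start)
  }
  g1 <- cons_to_genome(a, offset_a)
  g2 <- cons_to_genome(b, offset_b)
  if (g1 >= g2) abort("crossover positions do not define a forward interval")

  derived <- paste0(substr(genome, 1, g1),
                    revcomp(substr(genome, g1 + 1, g2)),
                    substr(genome, g2 + 1, nchar(genome)))
  ann <- invert_annotations(annotations, g1, g2)
  list(genome = derived, annotations = ann,
       true_breakpoints = c(g1, g2), mechanism = "ectopic")
}

# Map annotations through an in-place inversion of [g1, g2); copies straddling
# a breakpoint are split into two chimera parts with consistent consensus
# sub-intervals.
invert_annotations <- function(annotations, g1, g2) {
  flip <- function(s, e) c(g1 + g2 - e, g1 + g2 - s)
  split_cons <- function(row, cut) {
    # cons coordinates covered by genome sub-intervals [start,cut) / [cut,end)
    if (row$strand == "+") {
      left <- c(row$cons_start, row$cons_start + (cut - row$start))
      right <- c(left[2], row$cons_end)
    } else {
      right <- c(row$cons_start, row$cons_start + (row$end - cut))
      left <- c(right[2], row$cons_end)
    }
    list(left = left, right = right)
  }
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    r <- annotations[i, ]
    if (r$end <= g1 || r$start >= g2) {
      out[[i]] <- r
    } else if (r$start >= g1 && r$end <= g2) {
      f <- flip(r$start, r$end)
      r$start <- f[1]; r$end <- f[2]
      r$strand <- if (r$strand == "+") "-" else "+"
      out[[i]] <- r
    } else if (r$start < g1 && r$end > g1) {
      cc <- split_cons(r, g1)
      left <- r; left$end <- g1
      left$cons_start <- cc$left[1]; left$cons_end <- cc$left[2]
      inner <- r; inner$start <- g1
      f <- flip(g1, min(r$end, g2))
      inner$start <- f[1]; inner$end <- f[2]
      inner$strand <- if (r$strand == "+") "-" else "+"
      inner$cons_start <- cc$right[1]; inner$cons_end <- cc$right[2]
      out[[i]] <- dplyr::bind_rows(left, inner)
    } else {
      cc <- split_cons(r, g2)
      f <- flip(max(r$start, g1), g2)
      inner <- r; inner$start <- f[1]; inner$end <- f[2]
      inner$strand <- if (r$strand == "+") "-" else "+"
      inner$cons_start <- cc$left[1]; inner$cons_end <- cc$left[2]
      right <- r; right$start <- g2
      right$cons_start <- cc$right[1]; right$cons_end <- cc$right[2]
      out[[i]] <- dplyr::bind_rows(inner, right)
    }
  }
  tbl <- dplyr::bind_rows(out)
  tbl <- tbl[tbl$end > tbl$start, ]
  as_te_annotations(tbl, chrom_lengths = chrom_lengths(annotations))
}

#' Create an inversion by non-homologous end joining
#'
#' The segment `[bp1, bp2)` is reverse-complemented in place and the
#' `dup_len`-bp block immediately upstream of `bp1` additionally reappears in
#' reverse complement on the `bp2` side of the junction — the inverted
#' duplication of (normally non-repetitive) flanking DNA that NHEJ repair
#' leaves at inversion breakpoints. The derived genome is `dup_len` bp longer
#' than the ancestral one.
#'
#' @param genome DNA string.
#' @param annotations Annotation tibble on `genome`.
#' @param bp1,bp2 Breakpoint positions (0-based), neither inside a TE copy.
#' @param dup_len Length of the duplicated block (>= 0).
#' @return List with `genome`, `annotations`, `true_breakpoints = c(bp1, bp2)`,
#'   `mechanism = "nhej"`, `duplication` (the two copy intervals).
#' @export
apply_nhej_inversion <- function(genome, annotations, bp1, bp2,
                                 dup_len = 910) {
  if (dup_len < 0) abort("`dup_len` must be >= 0")
  if (bp1 + dup_len >= bp2) {
    abort("duplicated block overlaps the second breakpoint")
  }
  if (bp1 - dup_len < 0) abort("duplicated block extends past the origin")
  inside <- annotations$start < bp1 & bp1 < annotations$end |
    annotations$start < bp2 & bp2 < annotations$end
  if (any(inside)) abort("NHEJ breakpoints must not fall inside a TE copy")
  dup_src <- c(bp1 - dup_len, bp1)
  te_on_dup <- any(annotations$end > dup_src[1] & annotations$start < dup_src[2])
  if (dup_len > 0 && te_on_dup) {
    abort("duplicated block overlaps a TE annotation; pick a TE-free site")
  }
  dup <- if (dup_len > 0) substr(genome, dup_src[1] + 1, dup_src[2]) else ""
  derived <- paste0(substr(genome, 1, bp1),
                    revcomp(substr(genome, bp1 + 1, bp2)),
                    if (dup_len > 0) revcomp(dup) else "",
                    substr(genome, bp2 + 1, nchar(genome)))
  ann <- invert_annotations(annotations, bp1, bp2)
  if (dup_len > 0) {
    shift <- ann$start >= bp2
    ann$end[ann$end > bp2 | shift] <- ann$end[ann$end > bp2 | shift] + dup_len
    ann$start[shift] <- ann$start[shift] + dup_len
  }
  cl <- setNames(nchar(derived), names(chrom_lengths(annotations))[1])
  ann <- as_te_annotations(ann, chrom_lengths = cl)
  list(genome = derived, annotations = ann,
       true_breakpoints = c(bp1, bp2), mechanism = "nhej",
       duplication = list(pos_a = dup_src,
                          pos_b = c(bp2, bp2 + dup_len)))
}

#' Exact truth alignment for a simulated inversion
#'
#' Emits the PAF records an error-free whole-genome aligner would produce for
#' an ancestral/derived pair differing by one inversion: forward - reverse -
#' forward blocks with exact coordinates (a single forward record when there
#' is no inversion).
#'
#' @param ancestral_len Ancestral genome length.
#' @param breakpoints `c(bp1, bp2)` or `NULL` for no inversion.
#' @param dup_len NHEJ duplication length inserted at the `bp2` junction.
#' @param qname,tname Query (ancestral) and target (derived) names.
#' @return PAF tibble (see [read_paf()]).
#' @export
emit_truth_alignment <- function(ancestral_len, breakpoints = NULL,
                                 dup_len = 0, qname = "ancestral",
                                 tname = "derived") {
  tlen <- ancestral_len + dup_len
  if (is.null(breakpoints)) {
    return(as_paf(tibble(
      qname = qname, qlen = ancestral_len, qstart = 0, qend = ancestral_len,
      strand = "+", tname = tname, tlen = tlen, tstart = 0,
      tend = ancestral_len, matches = ancestral_len, alen = ancestral_len,
      mapq = 60)))
  }
  b1 <- breakpoints[1]; b2 <- breakpoints[2]
  blocks <- tibble(
    qstart = c(0, b1, b2),
    qend = c(b1, b2, ancestral_len),
    strand = c("+", "-", "+"),
    tstart = c(0, b1, b2 + dup_len),
    tend = c(b1, b2, ancestral_len + dup_len))
  blocks <- blocks[blocks$qend > blocks$qstart, ]
  as_paf(tibble(
    qname = qname, qlen = ancestral_len, qstart = blocks$qstart,
    qend = blocks$qend, strand = blocks$strand, tname = tname, tlen = tlen,
    tstart = blocks$tstart, tend = blocks$tend,
    matches = blocks$qend - blocks$qstart,
    alen = blocks$qend - blocks$qstart, mapq = 60))
}

#' Simulate breakpoint-spanning reads with split-alignment truth
#'
#' Draws reads from the ancestral genome: half straddle a true breakpoint
#' (alternating between the two), half start uniformly. For each read the
#' truth records its origin and the exact split alignment onto the derived
#' genome — two opposite-strand segments whose clip positions sit at the
#' breakpoint for spanning reads, one segment otherwise.
#'
#' @param ancestral Ancestral genome string.
#' @param breakpoints `c(bp1, bp2)` true breakpoints.
#' @param n Number of reads.
#' @param read_len Read length (< distance between breakpoints).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param dup_len NHEJ duplication length (shifts derived coordinates past
#'   `bp2`).
#' @param tname Derived sequence name used in the segment table.
#' @return List with `reads` (tibble: `name`, `sequence`, `origin_start`,
#'   `origin_end`, `spans`) and `segments` (PAF tibble of the per-read
#'   alignment segments on the derived genome).
#' @export
simulate_spanning_reads <- function(ancestral, breakpoints, n = 40,
                                    read_len = 10000, error_rate = 0,
                                    seed = 1, dup_len = 0,
                                    tname = "derived") {
  L <- nchar(ancestral)
  if (read_len >= L) abort("`read_len` must be smaller than the genome")
  b1 <- breakpoints[1]; b2 <- breakpoints[2]
  with_seed(seed, {
    starts <- integer(n)
    spans <- character(n)
    for (i in seq_len(n)) {
      if (i %% 2 == 0) {
        starts[i] <- sample.int(L - read_len + 1, 1) - 1
        spans[i] <- "uniform"
      } else {
        b <- if (((i + 1) %/% 2) %% 2 == 1) b1 else b2
        lo <- max(0, b - read_len + 1, if (b == b2) b1 else 0)
        hi <- min(b - 1, L - read_len, if (b == b1) b2 - read_len else L)
        if (hi < lo) { lo <- max(0, b - read_len + 1); hi <- b - 1 }
        starts[i] <- lo + sample.int(hi - lo + 1, 1) - 1
        spans[i] <- if (b == b1) "bp1" else "bp2"
      }
    }
    seqs <- substring(ancestral, starts + 1, starts + read_len)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        v <- strsplit(s, "")[[1]]
        hit <- which(runif(length(v)) < error_rate)
        if (length(hit) > 0) {
          v[hit] <- vapply(v[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    names <- sprintf("read%04d", seq_len(n))
    reads <- tibble(name = names, sequence = seqs, origin_start = starts,
                    origin_end = starts + read_len, spans = spans)

    # exact projection of each read onto the derived genome
    seg_list <- purrr::map(seq_len(n), function(i) {
      r0 <- starts[i]; r1 <- starts[i] + read_len
      blocks <- tibble(qs = c(0, b1, b2), qe = c(b1, b2, L),
                       strand = c("+", "-", "+"),
                       ts = c(0, b1, b2 + dup_len))
      segs <- purrr::pmap(blocks, function(qs, qe, strand, ts) {
        s <- max(r0, qs); e <- min(r1, qe)
        if (s >= e) return(NULL)
        if (strand == "+") {
          tibble(qstart = s - r0, qend = e - r0, strand = "+",
                 tstart = ts + (s - qs), tend = ts + (e - qs))
        } else {
          tibble(qstart = s - r0, qend = e - r0, strand = "-",
                 tstart = b1 + b2 - e, tend = b1 + b2 - s)
        }
      })
      segs <- dplyr::bind_rows(segs)
      segs$qname <- names[i]
      segs
    })
    segs <- dplyr::bind_rows(seg_list)
    segments <- as_paf(tibble(
      qname = segs$qname, qlen = read_len, qstart = segs$qstart,
      qend = segs$qend, strand = segs$strand, tname = tname,
      tlen = L + dup_len, tstart = segs$tstart, tend = segs$tend,
      matches = segs$qend - segs$qstart, alen = segs$qend - segs$qstart,
      mapq = 60))
    list(reads = reads, segments = segments)
  })
}

#' Simulate annotation-only TE landscapes
#'
#' Places TE annotations on one chromosome without generating sequence —
#' the substrate for density/enrichment and resampling-null studies. Copies
#' are placed uniformly; optionally, extra copies of the same families are
#' piled into `enriched_regions` to plant a breakpoint density contrast.
#'
#' @param chrom_length Chromosome length (bp).
#' @param n_families,copies_per_family Background family structure.
#' @param len_range Copy length range (bp), sampled uniformly.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @param orders Orders to cycle over for the families.
#' @param enriched_regions Optional tibble with `start`, `end`.
#' @param enriched_copies,enriched_len Number and length of extra copies per
#'   enriched region.
#' @return Annotation tibble.
#' @export
simulate_te_annotations <- function(chrom_length, n_families = 5,
                                    copies_per_family = 20,
                                    len_range = c(200, 2000), seed = 1,
                                    chrom = "chrSim",
                                    orders = c("DNA", "LINE", "LTR"),
                                    enriched_regions = NULL,
                                    enriched_copies = 8,
                                    enriched_len = 1500) {
  with_seed(seed, {
    fams <- sprintf("sim-fam-%02d", seq_len(n_families))
    ords <- rep(orders, length.out = n_families)
    base <- purrr::map2_dfr(fams, ords, function(f, o) {
      len <- round(runif(copies_per_family, len_range[1], len_range[2]))
      start <- floor(runif(copies_per_family, 0, chrom_length - len))
      tibble(chrom = chrom, start = start, end = start + len,
             strand = sample(c("+", "-"), copies_per_family, replace = TRUE),
             family_id = f, order = o, superfamily = "Unknown")
    })
    extra <- NULL
    if (!is.null(enriched_regions) && nrow(enriched_regions) > 0) {
      extra <- purrr::pmap_dfr(enriched_regions, function(start, end, ...) {
        f <- sample(fams, enriched_copies, replace = TRUE)
        len <- pmin(enriched_len, end - start - 1)
        s <- floor(runif(enriched_copies, start, end - len))
        tibble(chrom = chrom, start = s, end = s + len,
               strand = sample(c("+", "-"), enriched_copies, replace = TRUE),
               family_id = f,
               order = ords[match(f, fams)], superfamily = "Unknown")
      })
    }
    as_te_annotations(dplyr::bind_rows(base, extra),
                      chrom_lengths = setNames(chrom_length, chrom))
  })
}

#' Simulate one complete inversion scenario
#'
#' Generates an ancestral genome with TE insertions and derives from it an
#' inverted haplotype, by ectopic recombination between two inverted-
#' orientation MITE copies (whose crossover points become the breakpoints) or
#' by NHEJ at TE-free positions with an inverted duplication of flanking DNA.
#' Truth annotations for both haplotypes, the exact whole-genome alignment,
#' and optional breakpoint-spanning reads are returned.
#'
#' The default geometry mirrors the study system this generator emulates: a
#' MITE family whose ~500-bp TIRs are tandem arrays of 167-bp units, divergent
#' background copies, breakpoints around 30% and 70% of the chromosome, an
#' optional centromere-like high-density tandem block, and a 910-bp NHEJ
#' duplication.
#'
#' @param seed Integer seed driving every draw.
#' @param mechanism "ectopic" or "nhej".
#' @param genome_length Background genome length (bp).
#' @param gc GC content of the background.
#' @param tir_len,unit_len,linker_len MITE consensus geometry.
#' @param n_extra_mites Additional scattered MITE copies.
#' @param n_bg_families,bg_copies Background family count and copies each.
#' @param divergence_rate Substitution rate applied to inserted copies.
#' @param dup_len NHEJ inverted-duplication length.
#' @param centromere Add a centromere-like tandem block at mid-chromosome.
#' @param centromere_len,centromere_unit Size and repeat unit length of that
#'   block.
#' @param n_reads,read_len,read_error Spanning-read simulation; `n_reads = 0`
#'   skips reads.
#' @param chrom Chromosome name.
#' @return A `sim_truth` list: `ancestral`, `derived` (strings),
#'   `annotations_ancestral`, `annotations_derived`, `true_breakpoints`,
#'   `mechanism`, `truth_paf`, `reads`, `centromere`, `config`.
#' @export
simulate_inversion_scenario <- function(seed = 1,
                                        mechanism = c("ectopic", "nhej"),
                                        genome_length = 1e6, gc = 0.45,
                                        tir_len = 501, unit_len = 167,
                                        linker_len = 120,
                                        n_extra_mites = 4,
                                        n_bg_families = 3, bg_copies = 8,
                                        divergence_rate = 0.02,
                                        dup_len = 910,
                                        centromere = FALSE,
                                        centromere_len = 40000,
                                        centromere_unit = 158,
                                        n_reads = 40, read_len = 10000,
                                        read_error = 0,
                                        chrom = "chrSim") {
  mechanism <- match.arg(mechanism)
  cfg <- as.list(environment())
  genome <- make_background(genome_length, gc, seed = derive_seed(seed, "bg"))
  ann <- NULL

  # intended breakpoint neighbourhoods on the background genome
  with_seed(derive_seed(seed, "geom"), {
    p1 <- round(genome_length * runif(1, 0.25, 0.35))
    p2 <- round(genome_length * runif(1, 0.65, 0.75))
  })
  cen_p <- round(genome_length / 2)

  mite <- make_mite_consensus(tir_len, unit_len,
                              seed = derive_seed(seed, "mite"),
                              linker_len = linker_len)

  # Every annotation in this scenario is an inserted block, so the current
  # position of a background base p is p plus the lengths of all blocks whose
  # insertion point was at or before p.
  shift_now <- function(p) {
    if (is.null(ann) || nrow(ann) == 0) return(p)
    lens <- ann$end - ann$start
    q <- ann$start - c(0, cumsum(lens))[seq_along(lens)]
    p + sum(lens[q <= p])
  }
  zones_now <- function() {
    z <- rbind(c(shift_now(p1), shift_now(p1)),
               c(shift_now(p2), shift_now(p2)))
    z <- z + cbind(rep(-5000, 2), rep(5000, 2))
    if (centromere) {
      z <- rbind(z, shift_now(cen_p) + c(-2000, centromere_len + 2000))
    }
    z
  }
  draw_positions <- function(k, sd_tag) {
    zones <- zones_now()
    hi <- nchar(genome) - 1000
    with_seed(derive_seed(seed, sd_tag), {
      out <- numeric(0)
      guard <- 0
      while (length(out) < k && guard < 10000) {
        guard <- guard + 1
        cand <- floor(runif(1, 1000, hi))
        bad <- any(cand >= zones[, 1] & cand <= zones[, 2]) ||
          (length(out) > 0 && min(abs(out - cand)) < 6000) ||
          (!is.null(ann) && nrow(ann) > 0 &&
             any(ann$start - 100 < cand & cand < ann$end + 100))
        if (!bad) out <- c(out, cand)
      }
      if (length(out) < k) abort("could not place TE copies without overlap")
      out
    })
  }

  # background families: old, divergent, fragmented copies — each insertion
  # is a random 300-900 bp portion of a 1.5-kb consensus
  for (f in seq_len(n_bg_families)) {
    cons <- tibble(
      family_id = sprintf("sim-bg-%02d", f), order = "LINE",
      superfamily = "Unknown",
      sequence = make_background(1500, gc, derive_seed(seed, paste0("bgfam", f))),
      length = 1500)
    pos <- draw_positions(bg_copies, paste0("bgpos", f))
    with_seed(derive_seed(seed, paste0("bgstr", f)), {
      strands <- sample(c("+", "-"), bg_copies, replace = TRUE)
      frag_len <- round(runif(bg_copies, 300, 900))
      frag_start <- floor(runif(bg_copies, 0, 1500 - frag_len))
    })
    ins <- insert_te_copies(genome, cons,
                            tibble(pos = pos, strand = strands,
                                   cons_start = frag_start,
                                   cons_end = frag_start + frag_len),
                            divergence_rate = min(0.15, divergence_rate * 4),
                            seed = derive_seed(seed, paste0("bgins", f)),
                            annotations = ann, chrom = chrom)
    genome <- ins$genome
    ann <- ins$annotations
  }

  # centromere-like tandem block
  cen_truth <- NULL
  if (centromere) {
    unit <- make_background(centromere_unit, 0.55, derive_seed(seed, "cenu"))
    n_units <- centromere_len %/% centromere_unit
    cons <- tibble(family_id = "sim-censat", order = "Satellite",
                   superfamily = "Unknown",
                   sequence = strrep(unit, n_units),
                   length = centromere_unit * n_units)
    cen_pos <- shift_now(cen_p)
    ins <- insert_te_copies(genome, cons, tibble(pos = cen_pos, strand = "+"),
                            divergence_rate = 0.01,
                            seed = derive_seed(seed, "cenins"),
                            annotations = ann, chrom = chrom)
    genome <- ins$genome
    ann <- ins$annotations
    cen_truth <- c(cen_pos, cen_pos + cons$length)
  }

  # scattered MITE copies away from the breakpoint zones
  if (n_extra_mites > 0) {
    extra_pos <- draw_positions(n_extra_mites, "mitepos")
    with_seed(derive_seed(seed, "mitestr"), {
      extra_str <- sample(c("+", "-"), length(extra_pos), replace = TRUE)
    })
    ins <- insert_te_copies(genome, mite,
                            tibble(pos = extra_pos, strand = extra_str),
                            divergence_rate = divergence_rate,
                            seed = derive_seed(seed, "miteins"),
                            annotations = ann, chrom = chrom)
    genome <- ins$genome
    ann <- ins$annotations
  }

  if (mechanism == "ectopic") {
    # Recombining partners inserted last at the (shifted) breakpoint zones,
    # each with an intact companion copy nearby — the tandem arrangement seen
    # at TE-mediated breakpoints, and a full-length copy that survives the
    # partners' becoming chimeras.
    q1 <- shift_now(p1)
    q2 <- shift_now(p2)
    placements <- tibble(pos = c(q1, q1 + 2000, q2 - 2000, q2),
                         strand = c("+", "-", "+", "-"))
    ins <- insert_te_copies(genome, mite, placements,
                            divergence_rate = divergence_rate,
                            seed = derive_seed(seed, "partnerins"),
                            annotations = ann, chrom = chrom)
    genome <- ins$genome
    ann <- ins$annotations
    # new rows come back sorted by start: partner A, companion, companion,
    # partner B
    idx <- ins$new_idx[order(ann$start[ins$new_idx])]
    ia <- idx[1]
    ib <- idx[4]
    inv <- apply_ectopic_inversion(genome, ann, ia, ib)
    dup_used <- 0
  } else {
    b1 <- shift_now(p1)
    b2 <- shift_now(p2)
    # nudge breakpoints off any annotation and keep the duplication TE-free
    nudge <- function(b) {
      while (any(ann$start - dup_len < b & b < ann$end + 1)) b <- b + 500
      b
    }
    b1 <- nudge(max(b1, dup_len + 1))
    b2 <- nudge(max(b2, b1 + dup_len + 10000))
    inv <- apply_nhej_inversion(genome, ann, b1, b2, dup_len = dup_len)
    dup_used <- dup_len
  }

  ancestral <- genome
  ann_anc <- ann
  if (centromere) {
    cen_rows <- inv$annotations[inv$annotations$family_id == "sim-censat", ]
    cen_truth <- c(min(cen_rows$start), max(cen_rows$end))
  }
  bp <- inv$true_breakpoints
  truth_paf <- emit_truth_alignment(nchar(ancestral), bp, dup_len = dup_used,
                                    qname = chrom, tname = chrom)
  reads <- NULL
  if (n_reads > 0) {
    reads <- simulate_spanning_reads(ancestral, bp, n = n_reads,
                                     read_len = read_len,
                                     error_rate = read_error,
                                     seed = derive_seed(seed, "reads"),
                                     dup_len = dup_used, tname = chrom)
  }
  structure(list(
    ancestral = ancestral, derived = inv$genome,
    annotations_ancestral = ann_anc, annotations_derived = inv$annotations,
    true_breakpoints = bp, mechanism = mechanism,
    truth_paf = truth_paf, reads = reads,
    duplication = inv$duplication, centromere = cen_truth,
    mite_family = mite$family_id, consensus = mite,
    chrom = chrom, config = cfg), class = "sim_truth")
}
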