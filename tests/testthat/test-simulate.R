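test_that("background generator is seeded and honours GC content", {
  expect_identical(make_background(10000, 0.5, seed = 1),
                   make_background(10000, 0.5, seed = 1))
  expect_false(identical(make_background(10000, 0.5, seed = 1),
                         make_background(10000, 0.5, seed = 2)))
  gc_only <- make_background(500, 1.0, seed = 3)
  expect_true(grepl("^[GC]+$", gc_only))
  # observed GC within 3 SD of the binomial expectation
  s <- make_background(1e6, 0.45, seed = 4)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.45e6), 3 * sqrt(1e6 * 0.45 * 0.55))
  expect_error(make_background(100, gc = 1.5), "gc")
})

test_that("MITE consensus has the constructed TIR-of-tandem-units shape", {
  expect_error(make_mite_consensus(600, 167), "multiple")
  m <- make_mite_consensus(501, 167, seed = 5, linker_len = 100)
  expect_equal(m$length, 2 * 501 + 100)
  s <- m$sequence
  expect_identical(substr(s, m$length - 500, m$length),
                   revcomp(substr(s, 1, 501)))
  # transposase-free by construction
  expect_equal(nrow(find_orfs(s, min_aa = 50)), 0)
  # downstream detector recovers the construction
  st <- self_structure(s)
  expect_gte(st$tir_length, 0.9 * 501)
  expect_equal(st$tandem_period, 167)
})

test_that("TE insertion bookkeeping: coordinates, shifts, divergence", {
  g <- make_background(20000, 0.5, seed = 6)
  cons <- tibble::tibble(family_id = "f", order = "DNA",
                         superfamily = "hAT",
                         sequence = make_background(1000, 0.5, seed = 7),
                         length = 1000)
  ins <- insert_te_copies(g, cons, tibble::tibble(pos = 5000, strand = "+"))
  expect_equal(nchar(ins$genome), 21000)
  expect_equal(ins$annotations$start, 5000)
  expect_equal(ins$annotations$end, 6000)
  # zero divergence: the copy is an exact consensus substring
  expect_identical(substr(ins$genome, 5001, 6000), cons$sequence)
  # minus strand inserts the reverse complement
  ins2 <- insert_te_copies(g, cons, tibble::tibble(pos = 5000, strand = "-"))
  expect_identical(substr(ins2$genome, 5001, 6000), revcomp(cons$sequence))
  # later placements shift by earlier insertions
  ins3 <- insert_te_copies(g, cons,
                           tibble::tibble(pos = c(2000, 8000),
                                          strand = c("+", "+")))
  expect_equal(ins3$annotations$start, c(2000, 9000))
  expect_identical(substr(ins3$genome, 9001, 10000), cons$sequence)
  # realized divergence within 3 SD of binomial(n, rate)
  cons2k <- tibble::tibble(family_id = "f", order = "DNA",
                           superfamily = "hAT",
                           sequence = make_background(2000, 0.5, seed = 8),
                           length = 2000)
  ins4 <- insert_te_copies(g, cons2k, tibble::tibble(pos = 100, strand = "+"),
                           divergence_rate = 0.1, seed = 9)
  mism <- ins4$annotations$divergence_pct / 100 * 2000
  expect_lt(abs(mism - 200), 3 * sqrt(2000 * 0.1 * 0.9))
  # duplicate insertion points are an error naming the position
  expect_error(insert_te_copies(g, cons,
                                tibble::tibble(pos = c(50, 50),
                                               strand = c("+", "-"))),
               "50")
})

test_that("ectopic inversion conserves length and is an involution", {
  g <- make_background(50000, 0.5, seed = 10)
  cons <- make_mite_consensus(334, 167, seed = 11, linker_len = 60)
  ins <- insert_te_copies(g, cons,
                          tibble::tibble(pos = c(10000, 40000),
                                         strand = c("+", "-")))
  idx <- ins$new_idx
  inv <- apply_ectopic_inversion(ins$genome, ins$annotations, idx[1], idx[2])
  expect_equal(nchar(inv$genome), nchar(ins$genome))
  expect_equal(inv$mechanism, "ectopic")
  # both breakpoints fall strictly inside same-family copies (ancestral frame)
  for (b in inv$true_breakpoints) {
    hit <- ins$annotations$start < b & b < ins$annotations$end
    expect_true(any(hit & ins$annotations$family_id == cons$family_id))
  }
  # applying the same inversion again restores the ancestral sequence
  back <- paste0(substr(inv$genome, 1, inv$true_breakpoints[1]),
                 revcomp(substr(inv$genome, inv$true_breakpoints[1] + 1,
                                inv$true_breakpoints[2])),
                 substr(inv$genome, inv$true_breakpoints[2] + 1,
                        nchar(inv$genome)))
  expect_identical(back, ins$genome)
  # same-strand copies are refused
  ins_same <- insert_te_copies(g, cons,
                               tibble::tibble(pos = c(10000, 40000),
                                              strand = c("+", "+")))
  expect_error(apply_ectopic_inversion(ins_same$genome, ins_same$annotations,
                                       ins_same$new_idx[1],
                                       ins_same$new_idx[2]),
               "inverted orientation")
})

test_that("NHEJ inversion adds an inverted duplication of dup_len bases", {
  g <- make_background(60000, 0.5, seed = 12)
  ann <- toy_annotations(2000, 3000, chrom = "chrSim", chrom_len = 60000)
  pure <- apply_nhej_inversion(g, ann, 10000, 40000, dup_len = 0)
  expect_equal(nchar(pure$genome), 60000)
  nh <- apply_nhej_inversion(g, ann, 10000, 40000, dup_len = 910)
  expect_equal(nchar(nh$genome), 60000 + 910)
  # the inserted block is the reverse complement of the block left of bp1
  expect_identical(substr(nh$genome, 40001, 40910),
                   revcomp(substr(g, 10000 - 910 + 1, 10000)))
  # breakpoints may not sit inside a TE copy
  expect_error(apply_nhej_inversion(g, ann, 2500, 40000, dup_len = 0),
               "TE")
  expect_error(apply_nhej_inversion(g, ann, 10000, 10500, dup_len = 910),
               "overlaps")
})

test_that("truth alignments partition both genomes around the inversion", {
  paf <- emit_truth_alignment(30000, c(10000, 20000))
  expect_equal(nrow(paf), 3)
  expect_equal(paf$strand, c("+", "-", "+"))
  expect_equal(sum(paf$qend - paf$qstart), 30000)
  expect_equal(sum(paf$tend - paf$tstart), 30000)
  expect_equal(paf$qstart, c(0, 10000, 20000))
  flat <- emit_truth_alignment(30000)
  expect_equal(nrow(flat), 1)
  expect_equal(flat$strand, "+")
  # NHEJ duplication leaves a target-side gap
  nh <- emit_truth_alignment(30000, c(10000, 20000), dup_len = 500)
  expect_equal(nh$tstart[3], 20500)
  expect_equal(nh$tlen[1], 30500)
})

test_that("spanning reads are seeded and split exactly at breakpoints", {
  g <- make_background(100000, 0.5, seed = 13)
  bp <- c(30000, 70000)
  r1 <- simulate_spanning_reads(g, bp, n = 30, read_len = 5000, seed = 14)
  r2 <- simulate_spanning_reads(g, bp, n = 30, read_len = 5000, seed = 14)
  expect_identical(r1$reads$sequence, r2$reads$sequence)
  # per-read segment lengths sum to the read length
  for (nm in unique(r1$segments$qname)) {
    seg <- r1$segments[r1$segments$qname == nm, ]
    expect_equal(sum(seg$qend - seg$qstart), 5000)
  }
  # spanning reads have two opposite-strand segments with a clip at the
  # breakpoint
  span <- r1$reads$name[r1$reads$spans == "bp1"]
  seg <- r1$segments[r1$segments$qname == span[1], ]
  expect_equal(nrow(seg), 2)
  expect_setequal(seg$strand, c("+", "-"))
  expect_true(any(abs(c(seg$tstart, seg$tend) - bp[1]) == 0))
})

test_that("scenario truth is internally consistent for both mechanisms", {
  for (mech in c("ectopic", "nhej")) {
    sim <- simulate_inversion_scenario(seed = 15, mechanism = mech,
                                       genome_length = 3e5, n_reads = 10)
    expect_equal(sim$mechanism, mech)
    dup <- if (mech == "nhej") sim$config$dup_len else 0
    expect_equal(nchar(sim$derived), nchar(sim$ancestral) + dup)
    bp <- sim$true_breakpoints
    ann <- sim$annotations_derived
    anc <- sim$annotations_ancestral
    if (mech == "ectopic") {
      # crossovers land strictly inside the recombining copies (ancestral
      # frame); in the derived frame the chimera halves abut at the junction
      for (b in bp) {
        expect_true(any(anc$start < b & b < anc$end &
                          anc$family_id == sim$mite_family))
        expect_true(any(ann$start <= b & b <= ann$end &
                          ann$family_id == sim$mite_family))
      }
    } else {
      expect_false(any(ann$start < bp[1] & bp[1] < ann$end))
    }
    # every true breakpoint lies inside a gap between truth alignment blocks
    paf <- sim$truth_paf
    for (b in bp) {
      expect_true(any(abs(c(paf$tstart, paf$tend) - b) <= 1))
    }
    # determinism of the whole scenario
    sim2 <- simulate_inversion_scenario(seed = 15, mechanism = mech,
                                        genome_length = 3e5, n_reads = 10)
    expect_identical(sim$derived, sim2$derived)
    expect_identical(sim$true_breakpoints, sim2$true_breakpoints)
  }
})
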