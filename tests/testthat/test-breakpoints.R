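test_that("PAF reader enforces the format and round trips", {
  path <- tempfile(fileext = ".paf")
  writeLines(c(
    "q\t1000\t0\t500\t+\tt\t2000\t100\t600\t480\t500\t60\ttp:A:P\tcm:i:50",
    "q\t1000\t500\t900\t-\tt\t2000\t1200\t1600\t390\t400\t60"), path)
  paf <- read_paf(path)
  expect_equal(nrow(paf), 2)
  expect_equal(ncol(paf), 12)   # tags dropped
  expect_equal(paf$tstart, c(100, 1200))

  writeLines("q\t1000\t0\t500\t+\tt\t2000\t100", path)
  expect_error(read_paf(path), "12 columns")

  writeLines("q\t1000\t500\t400\t+\tt\t2000\t100\t600\t480\t500\t60", path)
  expect_error(read_paf(path), "line 1")

  out <- tempfile(fileext = ".paf")
  write_paf(paf, out)
  expect_equal(read_paf(out), paf)
})

test_that("inversions are called from strand runs with gap intervals", {
  # +(0-10k), -(12k-20k), +(21k-30k) on a 30 kb target
  paf <- as_paf(tibble::tibble(
    qname = "q", qlen = 30000,
    qstart = c(0, 10000, 21000), qend = c(10000, 18000, 30000),
    strand = c("+", "-", "+"), tname = "t", tlen = 30000,
    tstart = c(0, 12000, 21000), tend = c(10000, 20000, 30000),
    matches = c(10000, 8000, 9000), alen = c(10000, 8000, 9000), mapq = 60))
  calls <- call_inversions(paf)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$label, c("A", "B"))
  expect_equal(calls$start, c(10000, 20000))
  expect_equal(calls$end, c(12000, 21000))
  expect_false(any(calls$open_ended))
  # intervals live in block gaps, disjoint from the synteny blocks
  for (i in 1:2) {
    expect_true(all(calls$end[i] <= paf$tstart | calls$start[i] >= paf$tend))
  }

  # all-forward alignments yield no inversion
  fwd <- paf
  fwd$strand <- "+"
  expect_equal(nrow(call_inversions(fwd)), 0)

  # missing right anchor: open-ended interval, not dropped
  open <- as_paf(paf[1:2, ])
  calls2 <- call_inversions(open)
  expect_true(calls2$open_ended[calls2$label == "B"])
  expect_equal(calls2$end[calls2$label == "B"], 30000)
})

test_that("simulated truth alignments recover the true breakpoints", {
  for (seed in 1:5) {
    sim <- simulate_inversion_scenario(seed = seed, mechanism = "ectopic",
                                       genome_length = 4e5, n_reads = 0)
    calls <- call_inversions(sim$truth_paf)
    expect_equal(nrow(calls), 2)
    for (i in 1:2) {
      expect_gte(sim$true_breakpoints[i], calls$start[i])
      expect_lte(sim$true_breakpoints[i], calls$end[i])
    }
  }
})

test_that("adjacent inversions merge into a double-inversion call", {
  paf <- as_paf(tibble::tibble(
    qname = "q", qlen = 100000,
    qstart = c(0, 10000, 30000, 50000, 80000),
    qend = c(10000, 30000, 50000, 80000, 100000),
    strand = c("+", "-", "+", "-", "+"), tname = "t", tlen = 100000,
    tstart = c(0, 10000, 30000, 50000, 80000),
    tend = c(10000, 30000, 50000, 80000, 100000),
    matches = 10000, alen = 10000, mapq = 60))
  merged <- call_inversions(paf, min_gap = 1e5)
  expect_equal(nrow(merged), 3)
  expect_equal(merged$label, c("A", "B", "C"))
  expect_true(all(merged$double))
  separate <- call_inversions(paf, min_gap = 1000)
  expect_equal(nrow(separate), 4)
  expect_false(any(separate$double))
})

test_that("clipped-read refinement collapses intervals and never widens", {
  sim <- simulate_inversion_scenario(seed = 23, mechanism = "ectopic",
                                     genome_length = 4e5, n_reads = 30,
                                     read_error = 0)
  calls <- call_inversions(sim$truth_paf)
  refined <- refine_with_clipped_reads(sim$reads$segments, calls)
  for (i in 1:2) {
    expect_lte(refined$end[i] - refined$start[i], 2)
    expect_lte(refined$end[i] - refined$start[i],
               calls$end[i] - calls$start[i])
    expect_gte(sim$true_breakpoints[i], refined$start[i])
    expect_lte(sim$true_breakpoints[i], refined$end[i])
    expect_gt(refined$support[i], 0)
  }
  # zero qualifying reads: unchanged with support 0
  none <- refine_with_clipped_reads(sim$reads$segments[0, ], calls)
  expect_equal(none$start, calls$start)
  expect_equal(none$support, c(0L, 0L))
})

test_that("breakpoint regions use midpoint +/- flank with clamping", {
  iv <- tibble::tibble(chrom = "chr1", label = "A",
                       start = 11296105, end = 11302315)
  reg <- make_breakpoint_regions(iv, flank = 50000,
                                 chrom_lengths = c(chr1 = 30e6))
  expect_equal(reg$midpoint, 11299210)
  expect_equal(reg$start, 11249210)
  expect_equal(reg$end, 11349210)
  expect_false(reg$clamped)
  expect_equal(reg$end - reg$start, 100000)
  # clamped at the chromosome start
  edge <- make_breakpoint_regions(
    tibble::tibble(chrom = "chr1", label = "A", start = 9000, end = 11000),
    flank = 50000, chrom_lengths = c(chr1 = 30e6))
  expect_equal(edge$start, 0)
  expect_true(edge$clamped)
})

test_that("syntenic projection maps regions through alignment blocks", {
  identity <- as_paf(tibble::tibble(
    qname = "der", qlen = 1e6, qstart = 0, qend = 1e6, strand = "+",
    tname = "anc", tlen = 1e6, tstart = 0, tend = 1e6,
    matches = 1e6, alen = 1e6, mapq = 60))
  region <- list(chrom = "der", start = 200000, end = 300000)
  pr <- project_syntenic_regions(region, identity)
  expect_equal(pr$start, 200000)
  expect_equal(pr$end, 300000)
  expect_equal(pr$haplotype, "ancestral")

  # a region fully inside an inverted block: reversed-order arithmetic
  minus <- as_paf(tibble::tibble(
    qname = "der", qlen = 1e6, qstart = 100000, qend = 500000, strand = "-",
    tname = "anc", tlen = 1e6, tstart = 100000, tend = 500000,
    matches = 4e5, alen = 4e5, mapq = 60))
  pr2 <- project_syntenic_regions(list(chrom = "der", start = 150000,
                                       end = 160000), minus)
  # hand-computed: t = tend - (q - qstart)
  expect_equal(pr2$start, 500000 - (160000 - 100000))
  expect_equal(pr2$end, 500000 - (150000 - 100000))

  expect_error(project_syntenic_regions(list(chrom = "der", start = 900000,
                                             end = 950000), minus),
               "unmappable")

  # project-project round trip contains the original midpoint
  back <- project_syntenic_regions(
    list(chrom = pr$chrom, start = pr$start, end = pr$end),
    as_paf(tibble::tibble(
      qname = "anc", qlen = 1e6, qstart = 0, qend = 1e6, strand = "+",
      tname = "der", tlen = 1e6, tstart = 0, tend = 1e6,
      matches = 1e6, alen = 1e6, mapq = 60)))
  expect_true(back$start <= 250000 && 250000 <= back$end)
})

test_that("interval summaries use end - start widths and divisor-n SD", {
  one <- summarize_intervals(tibble::tibble(start = 10, end = 250))
  g <- glance(one)
  expect_equal(g$mean_width, 240)
  expect_equal(g$sd_width, 0)
  expect_error(summarize_intervals(tibble::tibble(start = numeric(),
                                                  end = numeric())),
               "no intervals")
  s <- summarize_intervals(tibble::tibble(start = c(0, 0), end = c(100, 300)))
  expect_equal(glance(s)$sd_width, 100)  # population SD of {100, 300}
  expect_equal(tidy(s)$width, c(100, 300))
})
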