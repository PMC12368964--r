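test_that("local matching finds identities and reverse complements", {
  a <- make_background(3000, 0.5, seed = 41)
  fr <- local_matches(a, a)
  full <- fr[fr$strand == "+" & fr$length == 3000, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$identity, 1)
  fr2 <- local_matches(a, revcomp(a))
  full2 <- fr2[fr2$strand == "-" & fr2$length == 3000, ]
  expect_equal(nrow(full2), 1)
  expect_equal(full2$b_start, 0)
  expect_equal(full2$b_end, 3000)

  # two unrelated 5-kb sequences hold no 200-bp match
  x <- make_background(5000, 0.5, seed = 42)
  y <- make_background(5000, 0.5, seed = 43)
  expect_equal(nrow(local_matches(x, y, min_len = 200)), 0)

  expect_error(local_matches("ACGT", a), "k")
})

test_that("local matching is mirror-symmetric between the two inputs", {
  set.seed(44)
  a <- make_background(2000, 0.5, seed = 45)
  # b embeds a mutated piece of a, forward, plus a reverse-complement piece
  b <- paste0(make_background(500, 0.5, seed = 46),
              mutate_seq(substr(a, 301, 900), 0.05, 47),
              make_background(300, 0.5, seed = 48),
              revcomp(substr(a, 1201, 1700)))
  ab <- local_matches(a, b, min_len = 150)
  ba <- local_matches(b, a, min_len = 150)
  expect_equal(nrow(ab), nrow(ba))
  ab_key <- ab[order(ab$a_start), c("a_start", "a_end", "strand", "length")]
  ba_key <- ba[order(ba$b_start), c("b_start", "b_end", "strand", "length")]
  expect_equal(ab_key$a_start, ba_key$b_start)
  expect_equal(ab_key$a_end, ba_key$b_end)
  expect_equal(ab_key$strand, ba_key$strand)
  # identity of the mutated forward fragment is near 95%
  fwd <- ab[ab$strand == "+", ]
  expect_gt(max(fwd$identity), 0.90)
})

test_that("ORF scanning covers all six frames", {
  # 120-codon ORF embedded on the forward strand, frame 2
  set.seed(49)
  mid <- paste(sample(setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA", "ATG")), 119, replace = TRUE), collapse = "")
  orf <- paste0("ATG", mid, "TAA")
  seq <- paste0("G", orf, make_background(50, 0.5, seed = 50))
  found <- find_orfs(seq, min_aa = 100)
  expect_equal(nrow(found), 1)
  expect_equal(found$frame, 2)
  expect_equal(found$length_aa, 120)
  expect_equal(found$start, 1)
  # the same ORF on the reverse strand
  found_rc <- find_orfs(revcomp(seq), min_aa = 100)
  expect_equal(nrow(found_rc), 1)
  expect_gte(found_rc$frame, 4)
  expect_equal(found_rc$length_aa, 120)
})

test_that("structural self-analysis recovers TIRs, periods and ORF absence", {
  m <- make_mite_consensus(501, 167, seed = 51)
  st <- self_structure(m$sequence)
  expect_gte(st$tir_length, 450)
  expect_equal(st$tandem_period, 167)
  expect_equal(nrow(st$orfs), 0)
  g <- glance(st)
  expect_equal(g$tandem_period, 167)

  # plain tandem repeat: period 5, no TIR
  rep5 <- strrep("ACGTT", 40)
  st2 <- self_structure(rep5)
  expect_equal(st2$tandem_period, 5)
  expect_equal(st2$tir_length, 0)

  # random sequence: no TIR >= 50 bp, no period
  r <- make_background(2000, 0.5, seed = 52)
  st3 <- self_structure(r)
  expect_equal(st3$tir_length, 0)
  expect_true(is.na(st3$tandem_period))

  # S + revcomp(S) reports a TIR covering nearly all of S
  for (seed in 53:55) {
    s <- make_background(300, 0.5, seed = seed)
    st4 <- self_structure(paste0(s, revcomp(s)))
    expect_gte(st4$tir_length, 0.9 * 300)
  }
})

test_that("shared families require copies and matching fragments in both regions", {
  sim <- simulate_inversion_scenario(seed = 57, mechanism = "ectopic",
                                     genome_length = 4e5, n_reads = 0)
  calls <- call_inversions(sim$truth_paf)
  regions <- make_breakpoint_regions(
    calls, chrom_lengths = chrom_lengths(sim$annotations_derived))
  sa <- substr(sim$derived, regions$start[1] + 1, regions$end[1])
  sb <- substr(sim$derived, regions$start[2] + 1, regions$end[2])
  frags <- local_matches(sa, sb)
  rep <- shared_families(sim$annotations_derived, regions[1, ], regions[2, ],
                         frags)
  expect_true(sim$mite_family %in% rep$family_id)
  mite <- rep[rep$family_id == sim$mite_family, ]
  expect_true(mite$all_breakpoints_hit)
  expect_equal(mite$orientations, "+-")
  # every reported copy lies inside its breakpoint region
  cp <- mite$copies[[1]]
  for (i in seq_len(nrow(cp))) {
    reg <- if (cp$region[i] == "A") regions[1, ] else regions[2, ]
    expect_gte(cp$end[i], reg$start)
    expect_lte(cp$start[i], reg$end)
  }

  # a family present in only one region is excluded
  only_a <- toy_annotations(c(1000, 2000), c(1500, 2600),
                            families = c("solo", "solo"),
                            chrom = sim$chrom,
                            chrom_len = nchar(sim$derived))
  rep2 <- shared_families(only_a, regions[1, ], regions[2, ], frags)
  expect_false("solo" %in% rep2$family_id)

  # copies below the 100-bp rule are excluded
  short <- toy_annotations(
    c(regions$start[1] + 10, regions$start[2] + 10),
    c(regions$start[1] + 90, regions$start[2] + 90),
    families = "tiny", chrom = sim$chrom, chrom_len = nchar(sim$derived))
  rep3 <- shared_families(short, regions[1, ], regions[2, ], frags)
  expect_false("tiny" %in% rep3$family_id)
})

test_that("long-shared counting applies the length rule per region", {
  rep <- tibble::tibble(
    family_id = c("big", "small"),
    copies = list(
      tibble::tibble(region = c("A", "B"), length = c(1973, 5838)),
      tibble::tibble(region = c("A", "B"), length = c(999, 2000))))
  expect_equal(count_long_shared(rep, min_len = 1000), 1)
  expect_equal(count_long_shared(rep, min_len = 0), 2)
  expect_equal(count_long_shared(rep[0, ], min_len = 0), 0)
})

test_that("consensus coverage pileups match per-position counting", {
  cov <- consensus_coverage(
    tibble::tibble(cons_start = c(0, 1400), cons_end = c(600, 2000)), 2000)
  expect_equal(nrow(cov), 2000)
  expect_true(all(cov$depth[601:1400] == 0))
  expect_true(all(cov$depth[c(1:600, 1401:2000)] == 1))

  expect_equal(sum(consensus_coverage(
    tibble::tibble(cons_start = numeric(), cons_end = numeric()),
    500)$depth), 0)

  set.seed(58)
  s <- sample(0:900, 30, replace = TRUE)
  e <- pmin(s + sample(10:300, 30, replace = TRUE), 1000)
  cov2 <- consensus_coverage(tibble::tibble(cons_start = s, cons_end = e),
                             1000)
  brute <- integer(1000)
  for (i in seq_along(s)) {
    brute[(s[i] + 1):e[i]] <- brute[(s[i] + 1):e[i]] + 1L
  }
  expect_equal(cov2$depth, brute)

  expect_error(consensus_coverage(
    tibble::tibble(cons_start = 0, cons_end = 1200), 1000), "bounds")
})
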