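test_that("region pair sampling is seeded, uniform and respects exclusions", {
  # forced placement: only one non-overlapping configuration exists
  p <- sample_region_pairs(20000, 10000, 5, seed = 71)
  expect_true(all(abs(p$a_start - p$b_start) >= 10000))
  expect_true(all(p$a_end <= 20000 & p$b_end <= 20000))

  p1 <- sample_region_pairs(1e6, 10000, 50, seed = 72)
  p2 <- sample_region_pairs(1e6, 10000, 50, seed = 72)
  expect_identical(p1, p2)

  # uniformity: chi-square over 10 bins on 1e4 starts not rejected at 1%
  big <- sample_region_pairs(1e6, 1000, 5000, seed = 73)
  starts <- c(big$a_start, big$b_start)
  bins <- table(cut(starts, breaks = seq(0, 999000, length.out = 11),
                    include.lowest = TRUE))
  chi <- sum((bins - length(starts) / 10)^2 / (length(starts) / 10))
  expect_lt(chi, qchisq(0.99, df = 9))

  # exclusion zones are avoided; impossible exclusions error out
  excl <- tibble::tibble(start = 0, end = 900000)
  p3 <- sample_region_pairs(1e6, 10000, 20, seed = 74, exclude = excl)
  expect_true(all(p3$a_start >= 900000 - 10000))
  expect_error(sample_region_pairs(1e6, 10000, 5, seed = 75,
                                   exclude = tibble::tibble(start = 0,
                                                            end = 1e6)),
               "no valid region")
})

test_that("shared-family counts match a brute-force family scan", {
  ann <- toy_annotations(
    starts = c(100, 5000, 9000, 2000, 7000, 400),
    ends = c(1300, 6200, 9400, 2300, 8900, 500),
    families = c("f1", "f1", "f1", "f2", "f2", "f3"),
    chrom_len = 10000)
  ra <- list(chrom = "chr1", start = 0, end = 3000)
  rb <- list(chrom = "chr1", start = 5000, end = 10000)
  expect_equal(shared_family_count(ann, ra, rb, min_length = 0), 2)
  expect_equal(shared_family_count(ann, ra, rb, min_length = 500), 1)
  expect_equal(shared_family_count(ann, ra, rb, min_length = 5000), 0)
  # brute force over all families and thresholds
  for (ml in c(0, 100, 300, 1200)) {
    brute <- sum(vapply(unique(ann$family_id), function(f) {
      cp <- ann[ann$family_id == f & (ann$end - ann$start) >= ml, ]
      any(cp$end > ra$start & cp$start < ra$end) &&
        any(cp$end > rb$start & cp$start < rb$end)
    }, logical(1)))
    expect_equal(shared_family_count(ann, ra, rb, min_length = ml), brute)
  }
  empty <- toy_annotations(numeric(0), numeric(0), chrom_len = 10000)
  expect_equal(shared_family_count(empty, ra, rb), 0)
})

test_that("null grid means agree with exhaustive enumeration", {
  # toy genome small enough to integrate over all start positions
  ann <- toy_annotations(
    starts = c(20000, 150000, 90000, 230000),
    ends = c(22000, 152500, 90800, 231200),
    families = c("f1", "f1", "f2", "f2"),
    chrom_len = 3e5)
  sizes <- c(10000, 30000)
  mls <- c(0, 1000, 2000)
  grid <- run_null(ann, "chr1", n_pairs = 1000, region_sizes = sizes,
                   min_lengths = mls, seed = 76)
  tg <- tidy(grid)

  # exact expectation by enumerating start positions on a 100-bp lattice and
  # correcting for the non-overlap constraint via full pair enumeration on a
  # coarser lattice
  exact_mean <- function(size, ml) {
    step <- 500
    starts <- seq(0, 3e5 - size, by = step)
    hits <- sapply(unique(ann$family_id), function(f) {
      cp <- ann[ann$family_id == f & (ann$end - ann$start) >= ml, ]
      vapply(starts, function(s) {
        any(cp$end > s & cp$start < s + size)
      }, logical(1))
    })
    npair <- 0
    for (i in seq_along(starts)) {
      npair <- npair + sum(abs(starts - starts[i]) >= size)
    }
    # expected shared count: sum over families of P(present in both members)
    tot <- 0
    for (f in seq_len(ncol(hits))) {
      pa <- hits[, f]
      for (i in seq_along(starts)) {
        if (!pa[i]) next
        ok <- abs(starts - starts[i]) >= size
        tot <- tot + sum(pa & ok)
      }
    }
    tot / npair
  }
  for (size in sizes) {
    for (ml in mls) {
      mu <- exact_mean(size, ml)
      cell <- tg[tg$size == size & tg$min_length == ml, ]
      dist <- grid$distribution[[which(grid$size == size &
                                         grid$min_length == ml)]]
      se <- stats::sd(dist) / sqrt(length(dist))
      tol <- max(3 * se, 0.01)
      expect_lt(abs(cell$mean_shared - mu), tol + 1e-12)
    }
  }

  # monotonicity: nonincreasing in min_length, nondecreasing in size
  for (size in sizes) {
    v <- tg$mean_shared[tg$size == size]
    expect_true(all(diff(v) <= 0))
  }
  for (ml in mls) {
    v <- tg$mean_shared[tg$min_length == ml]
    expect_true(all(diff(v) >= 0))
  }
  # distributions have exactly n_pairs entries and mean = mean_shared
  expect_true(all(vapply(grid$distribution, length, integer(1)) == 1000))
  expect_equal(vapply(grid$distribution, mean, numeric(1)), tg$mean_shared)
})

test_that("observed comparisons use the add-one empirical p", {
  ann <- toy_annotations(
    starts = c(1000, 250000), ends = c(3000, 252000),
    families = c("f1", "f1"), chrom_len = 3e5)
  grid <- run_null(ann, "chr1", n_pairs = 200, region_sizes = 10000,
                   min_lengths = c(0, 5000), seed = 77)
  # observed regions hold the only long pair: p = 1/(n+1) when mock never ties
  obs <- compare_observed(grid, ann,
                          list(chrom = "chr1", start = 0, end = 10000),
                          list(chrom = "chr1", start = 245000, end = 255000))
  cell0 <- obs[obs$min_length == 0, ]
  expect_equal(cell0$observed, 1)
  expect_lte(cell0$empirical_p, (1 + sum(grid$distribution[[1]] >= 1)) / 201)
  # observed 0 gives p = 1
  cell5k <- obs[obs$min_length == 5000, ]
  expect_equal(cell5k$observed, 0)
  expect_equal(cell5k$empirical_p, 1)
})

test_that("ectopic scenarios beat the 1-kb null while short TEs do not", {
  # chromosome much longer than the 100-kb regions, as in real karyotypes
  sim <- simulate_inversion_scenario(seed = 78, mechanism = "ectopic",
                                     genome_length = 5e6, n_reads = 0)
  ann <- sim$annotations_derived
  calls <- call_inversions(sim$truth_paf)
  regions <- make_breakpoint_regions(calls,
                                     chrom_lengths = chrom_lengths(ann))
  grid <- run_null(ann, sim$chrom, n_pairs = 500,
                   region_sizes = 100000, min_lengths = c(0, 1000),
                   seed = 79)
  obs <- compare_observed(grid, ann, regions[1, ], regions[2, ])
  cell <- obs[obs$min_length == 1000, ]
  expect_gte(cell$observed, 1)
  expect_lte(cell$empirical_p, 0.05)
  expect_lt(cell$mean_shared, 0.2)
})
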