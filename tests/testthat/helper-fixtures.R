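# Shared fixture builders: everything is generated in code at test time.

# minimal annotation table on one chromosome
toy_annotations <- function(starts, ends, families = "famA", strands = "+",
                            chrom = "chr1", chrom_len = max(ends) + 1000,
                            orders = "DNA", superfamilies = "hAT") {
  as_te_annotations(
    tibble::tibble(chrom = chrom, start = starts, end = ends,
                   strand = rep_len(strands, length(starts)),
                   family_id = rep_len(families, length(starts)),
                   order = rep_len(orders, length(starts)),
                   superfamily = rep_len(superfamilies, length(starts))),
    chrom_lengths = stats::setNames(chrom_len, chrom))
}

# a RepeatMasker .out file with the standard three header lines
write_toy_rm_out <- function(lines, path = tempfile(fileext = ".out")) {
  header <- c(
    "   SW   perc perc perc  query    position in query          matching  repeat",
    "score   div. del. ins.  sequence begin end      (left)   repeat    class/family  begin end (left) ID",
    "")
  writeLines(c(header, lines), path)
  path
}

# brute-force per-base coverage oracle
brute_coverage <- function(starts, ends, region_start, region_end) {
  covered <- rep(FALSE, region_end - region_start)
  for (i in seq_along(starts)) {
    s <- max(starts[i], region_start)
    e <- min(ends[i], region_end)
    if (e > s) covered[(s - region_start + 1):(e - region_start)] <- TRUE
  }
  sum(covered)
}

# pooled-variance two-sample t oracle (textbook formula)
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# substitute a fraction of bases, never back to the original
mutate_seq <- function(seq, rate, seed) {
  set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  v[hit] <- vapply(v[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(v, collapse = "")
}
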