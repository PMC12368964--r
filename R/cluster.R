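# Wicker-style family / subfamily clustering of consensus sequences.

#' Pairwise similarity of two consensus sequences
#'
#' Identity and coverage are taken from the best gap-free local match between
#' the two sequences (either strand): identity over the matched columns,
#' coverage as the matched span over the shorter sequence length.
#'
#' @param seq_a,seq_b DNA strings.
#' @param ... Passed to [local_matches()].
#' @return One-row tibble: `identity`, `coverage`, `length`, `strand` (`NA`
#'   row when no match is found).
#' @export
consensus_pair_stats <- function(seq_a, seq_b, ...) {
  frags <- local_matches(seq_a, seq_b, min_len = 30, min_identity = 0.5, ...)
  if (nrow(frags) == 0) {
    return(tibble(identity = NA_real_, coverage = 0, length = 0L,
                  strand = NA_character_))
  }
  best <- frags[which.max(frags$length * frags$identity), ]
  tibble(identity = best$identity,
         coverage = best$length / min(nchar(seq_a), nchar(seq_b)),
         length = best$length, strand = best$strand)
}

#' Cluster TE consensus sequences into families or subfamilies
#'
#' Operationalises the 80-80-80 rule (family: both sequences >= 80 bp,
#' alignment identity >= 80%, alignment covering >= 80% of the shorter
#' sequence) and the stricter 80-95-98 rule (subfamily: identity >= 95%,
#' coverage >= 98%) with single-linkage clustering, so the subfamily partition
#' refines the family partition.
#'
#' @param library Tibble with `family_id` and `sequence` (see
#'   [read_te_library()]).
#' @param level "family" (80-80-80) or "subfamily" (80-95-98).
#' @param min_len,min_identity,min_coverage Override the rule thresholds.
#' @return Tibble `family_id`, `cluster` (integer partition labels).
#' @export
cluster_te_families <- function(library,
                                level = c("family", "subfamily"),
                                min_len = 80,
                                min_identity = NULL, min_coverage = NULL) {
  level <- match.arg(level)
  if (is.null(min_identity)) {
    min_identity <- if (level == "family") 0.80 else 0.95
  }
  if (is.null(min_coverage)) {
    min_coverage <- if (level == "family") 0.80 else 0.98
  }
  n <- nrow(library)
  if (n == 0) abort("empty library")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (nchar(library$sequence[i]) < min_len ||
            nchar(library$sequence[j]) < min_len) next
        st <- consensus_pair_stats(library$sequence[i], library$sequence[j])
        if (!is.na(st$identity) && st$identity >= min_identity &&
            st$coverage >= min_coverage) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble(family_id = library$family_id,
         cluster = as.integer(factor(roots, levels = unique(roots))))
}
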