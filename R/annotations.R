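# TE annotation container and file I/O (RepeatMasker .out, BED6+1, library
# FASTA). An annotation table is an ordinary tibble with the columns below and
# a `chrom_lengths` attribute; every function that needs chromosome bounds
# also accepts the lengths explicitly so dplyr pipelines that strip attributes
# keep working.

ANNOT_COLS <- c("chrom", "start", "end", "strand", "family_id", "order",
                "superfamily", "divergence_pct", "cons_start", "cons_end",
                "score", "star")

#' Build a validated TE annotation table
#'
#' Coordinates are 0-based half-open. Each row is one genomic TE copy with its
#' family/order/superfamily classification, percent divergence from consensus
#' and (optionally) the consensus interval it represents.
#'
#' @param tbl Data frame with at least `chrom`, `start`, `end`, `strand`,
#'   `family_id`. Missing classification columns are filled with "Unknown",
#'   missing numeric columns with `NA`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp). When
#'   omitted, lengths default to the maximum annotated end per chromosome.
#' @return A tibble sorted by (chrom, start) with attribute `chrom_lengths`.
#' @examples
#' as_te_annotations(
#'   data.frame(chrom = "chr1", start = 100, end = 600, strand = "+",
#'              family_id = "famA"),
#'   chrom_lengths = c(chr1 = 1000))
#' @export
as_te_annotations <- function(tbl, chrom_lengths = NULL) {
  tbl <- as_tibble(tbl)
  need <- c("chrom", "start", "end", "strand", "family_id")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("annotation table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"order" %in% names(tbl)) tbl$order <- "Unknown"
  if (!"superfamily" %in% names(tbl)) tbl$superfamily <- "Unknown"
  if (!"divergence_pct" %in% names(tbl)) tbl$divergence_pct <- NA_real_
  if (!"cons_start" %in% names(tbl)) tbl$cons_start <- NA_real_
  if (!"cons_end" %in% names(tbl)) tbl$cons_end <- NA_real_
  if (!"score" %in% names(tbl)) tbl$score <- NA_real_
  if (!"star" %in% names(tbl)) tbl$star <- FALSE

  if (nrow(tbl) > 0) {
    check_intervals(tbl$start, tbl$end, "annotation")
    if (!all(tbl$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'")
    }
    dv <- tbl$divergence_pct
    if (any(!is.na(dv) & (dv < 0 | dv > 100))) {
      abort("divergence_pct must lie in [0, 100]")
    }
    both <- !is.na(tbl$cons_start) & !is.na(tbl$cons_end)
    if (any(both & tbl$cons_start >= tbl$cons_end)) {
      abort("cons_start must be < cons_end")
    }
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- attr(tbl, "chrom_lengths")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(tbl$end, tbl$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  unknown <- setdiff(unique(tbl$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    abort(paste0("annotation on unknown chromosome: ",
                 paste(unknown, collapse = ", ")))
  }
  over <- tbl$end > chrom_lengths[tbl$chrom]
  if (any(over)) {
    abort(sprintf("annotation ends beyond chromosome length on %s",
                  tbl$chrom[which(over)[1]]))
  }
  tbl <- dplyr::arrange(tbl[, ANNOT_COLS], .data$chrom, .data$start)
  attr(tbl, "chrom_lengths") <- chrom_lengths
  tbl
}

#' Chromosome lengths attached to an annotation table
#' @param x Annotation tibble from [as_te_annotations()] or a reader.
#' @return Named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(x) attr(x, "chrom_lengths")

#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the standard whitespace-separated `.out` dialect (three header
#' lines). File coordinates are 1-based inclusive and are converted to the
#' package's 0-based half-open convention; strand "C" is mapped to "-"; the
#' repeat class "Order/Superfamily" is split (missing superfamily becomes
#' "Unknown"); the consensus interval respects the strand-dependent column
#' layout where the "(left)" parenthesised value swaps sides on minus-strand
#' lines. Lines flagged with a trailing `*` (lower-scoring overlap) are
#' retained and marked in the `star` column unless `drop_star = TRUE`.
#'
#' @param path Path to a `.out` file.
#' @param drop_star Drop `*`-flagged rows instead of marking them.
#' @return Annotation tibble (see [as_te_annotations()]); chromosome lengths
#'   are reconstructed from the query "(left)" column.
#' @export
read_repeatmasker_out <- function(path, drop_star = FALSE) {
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^\\s*SW", lines[1])) {
    lines <- lines[-seq_len(min(3, length(lines)))]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(as_te_annotations(
      tibble(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), family_id = character()),
      chrom_lengths = setNames(numeric(0), character(0))))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 14 | nf > 16)
  if (length(bad) > 0) {
    abort(sprintf("malformed .out line %d: expected 14-16 columns, found %d",
                  bad[1], nf[bad[1]]))
  }
  unparen <- function(x) suppressWarnings(as.numeric(gsub("[()]", "", x)))
  parse_row <- function(f, i) {
    strand <- f[9]
    if (!strand %in% c("+", "C")) {
      abort(sprintf("unknown strand symbol '%s' on .out line %d", strand, i))
    }
    cls <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    ord <- cls[1]
    sup <- if (length(cls) >= 2) cls[2] else "Unknown"
    if (strand == "+") {
      cs <- unparen(f[12]); ce <- unparen(f[13])
    } else {
      cs <- unparen(f[14]); ce <- unparen(f[13])
    }
    star <- f[length(f)] == "*"
    tibble(
      chrom = f[5],
      start = as.numeric(f[6]) - 1, end = as.numeric(f[7]),
      qleft = unparen(f[8]),
      strand = if (strand == "C") "-" else "+",
      family_id = f[10], order = ord, superfamily = sup,
      divergence_pct = as.numeric(f[2]),
      cons_start = cs - 1, cons_end = ce,
      score = as.numeric(f[1]), star = star)
  }
  tbl <- dplyr::bind_rows(purrr::imap(fields, parse_row))
  if (anyNA(tbl$start) || anyNA(tbl$end)) {
    abort("non-numeric genomic coordinate in .out file")
  }
  lens <- tbl |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end + .data$qleft), .groups = "drop")
  cl <- setNames(lens$len, lens$chrom)
  if (drop_star) tbl <- dplyr::filter(tbl, !.data$star)
  tbl$qleft <- NULL
  as_te_annotations(tbl, chrom_lengths = cl)
}

#' Write annotations back to RepeatMasker `.out` layout
#'
#' Emits the 1-based inclusive coordinate convention of the format, so a
#' read/write round trip preserves the file coordinates exactly.
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  cl <- chrom_lengths(annotations)
  header <- c(
    "   SW   perc perc perc  query    position in query          matching  repeat         position in repeat",
    "score   div. del. ins.  sequence begin end      (left)   repeat    class/family   begin end  (left)    ID",
    "")
  rows <- purrr::pmap_chr(annotations, function(chrom, start, end, strand,
                                                family_id, order, superfamily,
                                                divergence_pct, cons_start,
                                                cons_end, score, star, ...) {
    qleft <- cl[[chrom]] - end
    cls <- if (superfamily == "Unknown") order else paste0(order, "/", superfamily)
    cs <- if (is.na(cons_start)) 1 else cons_start + 1
    ce <- if (is.na(cons_end)) 1 else cons_end
    if (strand == "+") {
      rep_cols <- sprintf("%d %d (0)", cs, ce)
      strand_sym <- "+"
    } else {
      rep_cols <- sprintf("(0) %d %d", ce, cs)
      strand_sym <- "C"
    }
    paste(
      ifelse(is.na(score), 0, score),
      ifelse(is.na(divergence_pct), 0, divergence_pct),
      0, 0, chrom, start + 1, end, sprintf("(%d)", qleft), strand_sym,
      family_id, cls, rep_cols, 1, if (isTRUE(star)) "*" else "")
  })
  writeLines(c(header, trimws(rows, "right")), path)
  invisible(path)
}

#' Write / read annotations as BED6+1
#'
#' BED uses 0-based half-open coordinates, matching the internal convention.
#' The name column carries `family_id`; a 7th column carries
#' "order/superfamily". Fields BED cannot carry (divergence, consensus
#' interval) are dropped.
#'
#' @param annotations Annotation tibble.
#' @param path File path.
#' @return `write_te_bed()` returns `path` invisibly; `read_te_bed()` returns
#'   an annotation tibble.
#' @export
write_te_bed <- function(annotations, path) {
  out <- annotations |>
    dplyr::transmute(.data$chrom, start = .data$start, end = .data$end,
                     name = .data$family_id,
                     score = ifelse(is.na(.data$score), 0, .data$score),
                     strand = .data$strand,
                     class = paste0(.data$order, "/", .data$superfamily))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_te_bed
#' @param chrom_lengths Named numeric vector of chromosome lengths; a BED line
#'   on a chromosome absent from it is an error.
#' @export
read_te_bed <- function(path, chrom_lengths) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand", "class"),
                         col_types = "cnncncc", progress = FALSE)
  if (anyNA(tbl$start) || anyNA(tbl$end)) {
    abort("non-numeric coordinates in BED file")
  }
  unknown <- setdiff(unique(tbl$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    abort(paste0("BED line on unknown chromosome: ",
                 paste(unknown, collapse = ", ")))
  }
  cls <- stringr::str_split_fixed(tbl$class, "/", 2)
  cls[cls[, 2] == "", 2] <- "Unknown"
  as_te_annotations(
    tibble(chrom = tbl$chrom, start = tbl$start, end = tbl$end,
           strand = tbl$strand, family_id = tbl$name,
           order = cls[, 1], superfamily = cls[, 2],
           score = as.numeric(tbl$score)),
    chrom_lengths = chrom_lengths)
}

#' Read a TE consensus library from FASTA
#'
#' Headers follow the RepeatMasker library convention
#' `family_id#Order/Superfamily`; a missing superfamily becomes "Unknown".
#'
#' @param path FASTA file path.
#' @return Tibble with `family_id`, `order`, `superfamily`, `sequence`,
#'   `length`.
#' @export
read_te_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  parts <- stringr::str_split_fixed(hdr, "#", 2)
  cls <- stringr::str_split_fixed(parts[, 2], "/", 2)
  ord <- ifelse(cls[, 1] == "", "Unknown", cls[, 1])
  sup <- ifelse(cls[, 2] == "", "Unknown", cls[, 2])
  fam <- ifelse(parts[, 1] == "", hdr, parts[, 1])
  if (anyDuplicated(fam)) {
    abort("duplicate family_id in TE library")
  }
  tibble(family_id = fam, order = ord, superfamily = sup,
         sequence = as.character(ss), length = Biostrings::width(ss))
}

#' Write a TE consensus library to FASTA
#' @param library Tibble with `family_id`, `order`, `superfamily`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_te_library <- function(library, path) {
  ss <- Biostrings::DNAStringSet(library$sequence)
  names(ss) <- paste0(library$family_id, "#", library$order, "/",
                      library$superfamily)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# restrict annotations to rows passing an optional classification filter
filter_group <- function(annotations, level = "all", name = NULL) {
  level <- match.arg(level, c("all", "order", "superfamily", "family"))
  if (level == "all") return(annotations)
  col <- switch(level, order = "order", superfamily = "superfamily",
                family = "family_id")
  known <- unique(annotations[[col]])
  if (is.null(name) || !all(name %in% known)) {
    abort(paste0("unknown ", level, " name; known: ",
                 paste(sort(known), collapse = ", ")))
  }
  annotations[annotations[[col]] %in% name, ]
}

#' Merged TE coverage of a region
#'
#' Number of distinct bases of `region` covered by at least one annotation
#' passing the classification filter; overlapping annotations are merged so no
#' base is counted twice.
#'
#' @param annotations Annotation tibble.
#' @param chrom,start,end Region (0-based half-open) on one chromosome.
#' @param level,name Optional classification filter: `level` one of "all",
#'   "order", "superfamily", "family" and `name` the group name(s).
#' @param chrom_lengths Chromosome lengths; defaults to the table attribute.
#' @return Covered base pairs (single number).
#' @export
merged_coverage <- function(annotations, chrom, start, end,
                            level = "all", name = NULL,
                            chrom_lengths = NULL) {
  cl <- chrom_lengths %||% chrom_lengths(annotations)
  if (!chrom %in% names(cl)) abort(paste0("unknown chromosome: ", chrom))
  if (start < 0 || end > cl[[chrom]] || start >= end) {
    abort("region outside chromosome bounds")
  }
  ann <- filter_group(annotations, level, name)
  ann <- ann[ann$chrom == chrom & ann$end > start & ann$start < end, ]
  if (nrow(ann) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(pmax(ann$start, start) + 1,
                                         pmin(ann$end, end)))
  sum(IRanges::width(ir))
}

#' NTE50 and LTE50 library-quality metrics
#'
#' NTE50 is the number of largest TE copies required to annotate 50% of the
#' repetitive DNA; LTE50 is the length of the copy at which that threshold is
#' crossed. Total repetitive DNA sums raw annotation lengths without merging
#' overlaps, so the metric describes the annotation set itself.
#'
#' @param annotations Annotation tibble with at least one row.
#' @return One-row tibble: `total_repeat_bp`, `nte50`, `lte50`.
#' @examples
#' ann <- as_te_annotations(data.frame(
#'   chrom = "c", start = c(0, 2000, 4000, 6000),
#'   end = c(1000, 2500, 4300, 6200), strand = "+",
#'   family_id = "f"), chrom_lengths = c(c = 10000))
#' te_library_metrics(ann)  # nte50 = 1, lte50 = 1000
#' @export
te_library_metrics <- function(annotations) {
  if (nrow(annotations) == 0) abort("no annotations")
  len <- sort(annotations$end - annotations$start, decreasing = TRUE)
  total <- sum(len)
  k <- which(cumsum(len) >= total / 2)[1]
  tibble(total_repeat_bp = total, nte50 = k, lte50 = len[k])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
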