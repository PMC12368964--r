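# Stage orchestration: a YAML config drives the chain
# simulate -> find-breakpoints -> enrich -> null -> compare-pairs -> classify
# -> report, each stage writing TSV/JSON outputs plus a manifest into its own
# subdirectory. The R functions are the interface; each stage is a thin
# wrapper over the exported module functions.

PIPELINE_STAGES <- c("simulate", "find-breakpoints", "enrich", "null",
                     "compare-pairs", "classify", "report")

#' Read and validate a pipeline run configuration
#'
#' The YAML config holds a global `seed`, an `outdir`, and one optional block
#' per stage mirroring the corresponding function's arguments. Validation
#' errors are collected and reported together. Every random stage derives its
#' own sub-seed from the global seed and the stage name.
#'
#' @param path YAML file path.
#' @return Config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Config list (e.g. built inline).
#' @export
validate_run_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$seed)) problems <- c(problems, "missing global `seed`")
  if (is.null(cfg$outdir)) problems <- c(problems, "missing `outdir`")
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed %% 1 != 0)) {
    problems <- c(problems, "`seed` must be an integer")
  }
  for (f in c(cfg$paths$breakpoint_table, cfg$paths$annotations,
              cfg$paths$alignment)) {
    if (!is.null(f) && !file.exists(f)) {
      problems <- c(problems, paste0("missing input file: ", f))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid run config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  cfg$simulate <- cfg$simulate %||% list()
  cfg$stages <- cfg$stages %||% PIPELINE_STAGES
  cfg
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_manifest <- function(dir, stage, params, outputs) {
  manifest <- list(
    stage = stage, parameters = params,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f),
           md5 = unname(tools::md5sum(f)))
    }),
    package_version = as.character(utils::packageVersion("teinv")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_stage <- function(cfg, stage, file) {
  p <- file.path(cfg$outdir, stage, file)
  if (!file.exists(p)) {
    abort(sprintf("stage output '%s' missing: run stage '%s' first",
                  p, stage))
  }
  p
}

#' Run one pipeline stage
#'
#' @param name Stage name, one of `simulate`, `find-breakpoints`, `enrich`,
#'   `null`, `compare-pairs`, `classify`, `report`.
#' @param cfg Validated config list from [read_run_config()].
#' @return Invisibly, the list of files the stage wrote.
#' @export
run_stage <- function(name, cfg) {
  name <- match.arg(name, PIPELINE_STAGES)
  dir <- stage_dir(cfg, name)
  seed <- derive_seed(cfg$seed, name)
  files <- switch(
    name,
    "simulate" = {
      sim <- do.call(simulate_inversion_scenario,
                     c(list(seed = seed), cfg$simulate))
      fa <- file.path(dir, "genomes.fa")
      ss <- Biostrings::DNAStringSet(c(ancestral = sim$ancestral,
                                       derived = sim$derived))
      Biostrings::writeXStringSet(ss, fa)
      out_a <- file.path(dir, "annotations_ancestral.out")
      out_d <- file.path(dir, "annotations_derived.out")
      write_repeatmasker_out(sim$annotations_ancestral, out_a)
      write_repeatmasker_out(sim$annotations_derived, out_d)
      paf <- file.path(dir, "truth_alignment.paf")
      write_paf(sim$truth_paf, paf)
      segs <- file.path(dir, "read_segments.paf")
      if (!is.null(sim$reads)) write_paf(sim$reads$segments, segs)
      truth <- file.path(dir, "truth.json")
      jsonlite::write_json(list(
        true_breakpoints = sim$true_breakpoints, mechanism = sim$mechanism,
        chrom = sim$chrom, seed = seed,
        derived_length = nchar(sim$derived),
        ancestral_length = nchar(sim$ancestral)),
        truth, auto_unbox = TRUE, digits = NA)
      c(fa, out_a, out_d, paf, segs, truth)
    },
    "find-breakpoints" = {
      paf <- read_paf(require_stage(cfg, "simulate", "truth_alignment.paf"))
      calls <- call_inversions(paf)
      segs_path <- file.path(cfg$outdir, "simulate", "read_segments.paf")
      if (file.exists(segs_path)) {
        calls <- refine_with_clipped_reads(read_paf(segs_path), calls)
      }
      out <- file.path(dir, "breakpoints.tsv")
      readr::write_tsv(calls, out)
      out
    },
    "enrich" = {
      truth <- jsonlite::read_json(require_stage(cfg, "simulate", "truth.json"))
      ann <- read_repeatmasker_out(
        require_stage(cfg, "simulate", "annotations_derived.out"))
      calls <- readr::read_tsv(
        require_stage(cfg, "find-breakpoints", "breakpoints.tsv"),
        show_col_types = FALSE)
      regions <- make_breakpoint_regions(calls, chrom_lengths =
                                           chrom_lengths(ann))
      win <- tile_windows(chrom_lengths(ann), cfg$enrich$window %||% 50000)
      track <- density_track(ann, win)
      res <- ttest_enrichment(track, regions)
      peaks <- two_sd_peaks(track, regions)
      f1 <- file.path(dir, "density.tsv")
      f2 <- file.path(dir, "enrichment.tsv")
      f3 <- file.path(dir, "two_sd_peaks.tsv")
      readr::write_tsv(as_tibble(track), f1)
      readr::write_tsv(res, f2)
      readr::write_tsv(peaks, f3)
      c(f1, f2, f3)
    },
    "null" = {
      truth <- jsonlite::read_json(require_stage(cfg, "simulate", "truth.json"))
      ann <- read_repeatmasker_out(
        require_stage(cfg, "simulate", "annotations_derived.out"))
      calls <- readr::read_tsv(
        require_stage(cfg, "find-breakpoints", "breakpoints.tsv"),
        show_col_types = FALSE)
      regions <- make_breakpoint_regions(calls, chrom_lengths =
                                           chrom_lengths(ann))
      grid <- run_null(ann, truth$chrom,
                       n_pairs = cfg$null$n_pairs %||% 1000,
                       seed = derive_seed(cfg$seed, "null"))
      grid <- compare_observed(grid, ann, regions[1, ], regions[2, ])
      out <- file.path(dir, "null_grid.tsv")
      readr::write_tsv(tidy(grid), out)
      out
    },
    "compare-pairs" = {
      truth <- jsonlite::read_json(require_stage(cfg, "simulate", "truth.json"))
      fa <- Biostrings::readDNAStringSet(
        require_stage(cfg, "simulate", "genomes.fa"))
      derived <- as.character(fa[["derived"]])
      ann <- read_repeatmasker_out(
        require_stage(cfg, "simulate", "annotations_derived.out"))
      calls <- readr::read_tsv(
        require_stage(cfg, "find-breakpoints", "breakpoints.tsv"),
        show_col_types = FALSE)
      regions <- make_breakpoint_regions(calls, chrom_lengths =
                                           chrom_lengths(ann))
      sa <- substr(derived, regions$start[1] + 1, regions$end[1])
      sb <- substr(derived, regions$start[2] + 1, regions$end[2])
      frags <- local_matches(sa, sb)
      rep <- shared_families(ann, regions[1, ], regions[2, ], frags)
      f1 <- file.path(dir, "fragments.tsv")
      f2 <- file.path(dir, "shared_families.tsv")
      readr::write_tsv(as_tibble(frags), f1)
      readr::write_tsv(tidyr::unnest(rep, "copies", names_sep = "_"), f2)
      c(f1, f2)
    },
    "classify" = {
      truth <- jsonlite::read_json(require_stage(cfg, "simulate", "truth.json"))
      fa <- Biostrings::readDNAStringSet(
        require_stage(cfg, "simulate", "genomes.fa"))
      derived <- as.character(fa[["derived"]])
      ann <- read_repeatmasker_out(
        require_stage(cfg, "simulate", "annotations_derived.out"))
      calls <- readr::read_tsv(
        require_stage(cfg, "find-breakpoints", "breakpoints.tsv"),
        show_col_types = FALSE)
      mc <- call_mechanism(derived, ann, calls)
      out <- file.path(dir, "mechanism.json")
      jsonlite::write_json(list(
        inversion_id = mc$inversion_id, label = mc$label,
        d_ectopic = mc$d_ectopic, d_nhej = mc$d_nhej,
        true_mechanism = truth$mechanism),
        out, auto_unbox = TRUE, digits = NA)
      out
    },
    "report" = {
      needed <- list(
        breakpoints = require_stage(cfg, "find-breakpoints", "breakpoints.tsv"),
        enrichment = require_stage(cfg, "enrich", "enrichment.tsv"),
        shared = require_stage(cfg, "compare-pairs", "shared_families.tsv"),
        null = require_stage(cfg, "null", "null_grid.tsv"),
        mechanism = require_stage(cfg, "classify", "mechanism.json"))
      bp <- readr::read_tsv(needed$breakpoints, show_col_types = FALSE)
      summ <- glance(summarize_intervals(bp))
      out <- file.path(dir, "report.json")
      jsonlite::write_json(list(
        n_breakpoint_intervals = nrow(bp),
        mean_interval_width = summ$mean_width,
        sd_interval_width = summ$sd_width,
        inputs = lapply(needed, basename),
        mechanism = jsonlite::read_json(needed$mechanism)),
        out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      out
    })
  write_manifest(dir, name, list(seed = seed), as.list(files))
  invisible(files)
}

#' Run the configured pipeline end to end
#'
#' @param cfg Config list or path to a YAML config.
#' @return Invisibly, a named list of files per stage.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out <- lapply(cfg$stages, function(s) run_stage(s, cfg))
  names(out) <- cfg$stages
  invisible(out)
}
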