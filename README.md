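# teinv

Transposable-element (TE) signatures at chromosomal inversion breakpoints.

## What this package is for

Large inversions form mainly in two ways, and each leaves a diagnostic scar
at its breakpoints. **Ectopic recombination** between two same-family TE
copies in inverted orientation inverts the intervening segment and leaves two
chimeric TE copies, one spanning each breakpoint, representing the same
portion of the family consensus in opposite orientations. **Non-homologous
end joining (NHEJ)** inverts the segment between two double-strand breaks and
leaves a short inverted duplication of non-repetitive flanking DNA.

`teinv` is for genome biologists who have two haplotype assemblies (or an
assembly pair from two populations), a whole-genome alignment, a repeat
annotation, and want to answer: *where exactly are the inversion breakpoints,
are TEs enriched there beyond chance, and which mechanism most likely created
the inversion?* The motivating system is the four large polymorphic
inversions of Atlantic cod (chromosomes 1, 2, 7, 12); the package ships their
published breakpoint coordinate table as example data, and all machinery is
general.

The analysis chain:

1. **Breakpoint calling** — inversions from PAF synteny blocks
   (`call_inversions()`), interval refinement with opposite-strand split
   reads (`refine_with_clipped_reads()`), 100-kb analysis regions
   (`make_breakpoint_regions()`), projection onto the non-inverted haplotype
   (`project_syntenic_regions()`).
2. **Enrichment statistics** — sliding-window TE density
   (`density_track()`), centromere estimation and exclusion
   (`estimate_centromere()`), pooled-variance Student's t-tests of breakpoint
   versus background windows (`ttest_enrichment()`), and the descriptive
   2-SD density-peak rule (`two_sd_peaks()`). For a chromosome with windows
   of density `x`, breakpoint windows `x_bp` and background `x_bg`:

       t = (mean(x_bp) - mean(x_bg)) / (s_p * sqrt(1/n_bp + 1/n_bg)),

   with `s_p` the pooled SD and `n_bp + n_bg - 2` degrees of freedom.
3. **Resampling null** — expected count of families with ≥ `L`-bp copies in
   both members of random 10–100 kb region pairs, 1,000 mock pairs per cell
   (`run_null()`), with add-one empirical p for the observed breakpoint pair
   (`compare_observed()`).
4. **Repeat structure** — gap-free seed-and-extend dot plots
   (`local_matches()`), TIR/tandem-period/ORF architecture
   (`self_structure()`), consensus pileups (`consensus_coverage()`),
   80-80-80 / 80-95-98 family and subfamily clustering
   (`cluster_te_families()`), NTE50/LTE50 annotation metrics
   (`te_library_metrics()`).
5. **Mechanism classification** — non-TE inverted duplications
   (`find_inverted_duplications()`) versus chimeric shared families
   (`ectopic_evidence()`), decided by the nearest-signature rule
   (`classify_mechanism()`, or end-to-end `call_mechanism()`).
6. **Synthetic truth** — `simulate_inversion_scenario()` generates
   ancestral/derived genome pairs with MITE families (501-bp TIRs of 167-bp
   tandem units), divergent background copies, a known mechanism, exact truth
   alignments and breakpoint-spanning reads; it is the test substrate for
   every stage.

I/O covers RepeatMasker `.out`, BED6+1, PAF, FASTA libraries
(`family#Order/Superfamily` headers) and TSV breakpoint tables. Functions
take data frames and return tibbles, so stages chain with the pipe;
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` functions cover the
result types.

## Worked example

```r
library(teinv)

# published breakpoint ranges bundled as example data
bp <- read_breakpoint_table(system.file("extdata", "cod_breakpoints.tsv",
                                        package = "teinv"))
summarize_intervals(bp)
#> 9 breakpoint intervals; mean width 16,862 bp; SD 21,417 bp

# a seeded synthetic inversion created by ectopic recombination between
# two MITE copies, plus its exact alignment and spanning reads
sim <- simulate_inversion_scenario(seed = 42, mechanism = "ectopic",
                                   genome_length = 1e6)
sim$true_breakpoints
#> [1] 327454 694808

calls <- call_inversions(sim$truth_paf)
refined <- refine_with_clipped_reads(sim$reads$segments, calls)
refined[, c("label", "start", "end", "support")]
#> # A tibble: 2 × 4
#>   label  start    end support
#> 1 A     327453 327455      20
#> 2 B     694807 694809      20

call_mechanism(sim$derived, sim$annotations_derived, refined)
#> inversion chrSim_inv1: ectopic_recombination (ectopic distance 0 bp,
#> NHEJ distance - bp)

self_structure(sim$consensus$sequence)
#> sequence 1122 bp | TIR 501 bp (identity 1.00) | tandem period 167 bp | 0 ORF(s)
```

The alignment alone brackets each breakpoint; twenty error-free spanning
reads collapse both intervals to 2 bp around the true positions. The
mechanism call finds the planted family's chimeric copies overlapping both
breakpoints in opposite orientations with matching consensus portions
(distance 0) and no competing non-TE inverted duplication. The consensus
report shows the MITE architecture: 501-bp terminal inverted repeats built of
167-bp tandem units and no open reading frame.

A YAML-driven stage runner (`run_pipeline()` / `run_stage()`) chains
simulate → find-breakpoints → enrich → null → compare-pairs → classify →
report, writing TSV/JSON outputs and a hash-carrying manifest per stage.

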