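# neoloopscan

Hi-C analysis of 3D-genome alterations in multi-sample disease cohorts —
built for the kind of question leukemia genomics asks: which compartments
switch, which TAD boundaries and domain scores change, which chromatin loops
are gained or lost between patient groups, where are the translocations, and
which genes are dysregulated by the rearrangement-induced "neo-loops" that
mediate enhancer hijacking.

The package covers the full path from contact records to biology:

- **Contact matrices** — binning of pairs-format records, Knight–Ruiz
  balancing (inner–outer Newton iteration with Sinkhorn fallback),
  distance-decay expectation, cis-depth normalization.
- **Compartments** — per-chromosome first eigenvector of the Pearson
  correlation of observed/expected at 100 kb; group consensus by the strict
  over-70% majority rule; A↔B switch calling between groups.
- **Domains** — insulation-score boundaries (1-Mb window, 200-kb delta span,
  0.1 noise threshold at 40-kb bins), consensus TADs (boundaries detected in
  ≥2 conditions), domain scores
  `D = intra-TAD contacts / all contacts touching the TAD`, and differential
  tests (Welch t, BH FDR < 0.01, effect above a quantile of all effects).
- **Loops** — four-background (donut / lower-left / horizontal / vertical)
  Poisson enrichment calling with BH over all scanned pixels, merge distances
  15/20 kb at 5/10-kb resolution; APA normalized by contributing loop count;
  distance-stratified differential loops (150-kb split, FDR < 0.1); CTCF
  motif-orientation classification (convergent / tandem / divergent).
- **Rearrangements** — coarse-to-fine Poisson scan of trans matrices with
  control filtering; single-bp breakpoint refinement from bridge-linker-free
  chimeric reads (modal coordinate, support strictly > 3); reassembled
  derivative-chromosome maps with an invertible coordinate transform;
  neo-loop detection on junction-spanning pixels with ≥2× control
  enrichment; event annotation (nearest gene, coding/noncoding, 100-kb
  novelty rule, FPKM > 1 and ≥2× control upregulation rule).
- **Integration** — virtual 4C, region-interaction statistics, Fisher-combined
  structural p (D-score × loop change) correlated with expression log fold
  change, and one-sided Wilcoxon tests of DEG log fold changes per
  structural class.
- **Synthetic cohorts** — a seeded generator planting all of the above with
  known truth (power-law decay `(d+1)^-1`, checkerboard compartments, TAD
  blocks, focal peaks, clonal junctions with decay `(d_A+d_B+1)^-1`, chimeric
  and decoy reads, negative-binomial expression coupled to structure), so
  every pipeline claim is testable as planted-truth recovery.

## Worked example

Simulate a small cohort with a planted translocation and run the whole
pipeline:

```r
library(neoloopscan)
manifest <- run_pipeline(list(simulate = demo_cohort_config()),
                         seed = 1, out_dir = "demo_out")
manifest$stages$sv
#> $elapsed_s
#> [1] 86.46
#> $n_events
#> [1] 4
#> $n_refined
#> [1] 4
#> $n_neoloops
#> [1] 2
```

All four case samples carry the planted chr1–chr2 translocation; each is
detected as an interchromosomal block, refined to the exact planted base
pair from its six chimeric reads (`demo_out/events.tsv` lists
`chr1 6543210 left chr2 4567890 right` per sample), and the planted neo-loop
is recovered on the reassembled map in two of the four per-sample maps
(per-sample depth limits the rest; the dedicated fixtures in the test suite
recover 10/10 events and the neo-loop at full clonal fraction). Compartment
switch calls, differential boundary/D-score/loop tables and the
DEG–structure association land in `demo_out/` as TSVs, with MD5 checksums in
`demo_out/manifest.json` — rerunning with the same seed reproduces them
byte-identically.

Single steps work standalone:

```r
g  <- genome_model(c(chr1 = 2e7))
sp <- structure_spec(loops = data.frame(chrom = "chr1", pos1 = 3.005e6,
                                        pos2 = 3.305e6, enrich = 5))
cm <- bin_contacts(simulate_contact_map(g, sp, cis_depth = 5e6, seed = 44), g, 1e4)
call_loops(cm, fdr = 0.1)[, c("chrom", "start1", "start2", "obs", "q")]
#>   chrom  start1  start2 obs            q
#> 1  chr1 3000000 3300000 117 2.869544e-40
```

A thin CLI wraps the same functions: `exec/neoloopscan simulate|run
--config cfg.json --seed 7 --out DIR`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
models, every tunable parameter with its default and rationale, what the
synthetic cohorts do and do not emulate, and known limitations.
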