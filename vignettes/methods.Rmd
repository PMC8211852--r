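---
title: "Models and methods behind neoloopscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoloopscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

neoloopscan analyses multi-sample Hi-C cohorts for three-dimensional genome
alterations: A/B compartment switches, differential TAD boundaries and domain
scores, differential chromatin loops, interchromosomal translocations with
single-base-pair breakpoint refinement, translocation-mediated neo-loops on
reassembled derivative-chromosome maps, and the association of all of these
with differential gene expression. Because patient Hi-C data of this kind are
access-restricted, the package ships a synthetic-cohort generator with planted
ground truth; every analytical claim the test suite makes is a recovery claim
against that truth or an exact oracle on a toy input.

# The synthetic contact model

A simulated cis contact map assigns bin pair $(i, j)$ at distance $d = |i-j|$
bins the Poisson intensity

$$\lambda_{ij} = s \,(d + 1)^{\alpha}\; C_{ij}\, T_{ij}\, L_{ij},$$

with decay exponent $\alpha = -1$ (the canonical power-law slope of
intrachromosomal contact frequency), a compartment factor $C_{ij}$ equal to
the checkerboard strength when bins share an A/B label and its inverse when
they differ, a TAD factor $T_{ij}$ applied when both bins fall inside one
planted domain, and a focal loop factor $L_{ij}$ at planted peak pixels. The
`(d+1)` form caps the decay at one bin and keeps the diagonal finite. The
scale $s$ is set so the expected cis total matches the requested depth, and
counts are drawn per bin pair as Poisson, then expanded to records at bin
midpoints. All generators draw from per-sample streams derived from one root
seed, so cohorts are bit-reproducible; structure placement is configuration-
driven and identical across seeds.

Default depths follow the protocol the package emulates: bulk BL-Hi-C maps
that reach a maximum usable resolution of roughly 3.5 kb, i.e. on the order
of 0.25 cis contacts per bp. Per-sample fixtures therefore use about 0.08-0.25
contacts per bp depending on the analysis, and loop calling operates on pooled
condition maps (as the underlying study pooled samples per condition), about
0.6 contacts per bp after pooling. Differential analyses use 4 samples per
group. The simulator does not model trans background contacts away from
rearrangement junctions, restriction fragments, read-level errors, or
copy-number variation: passing tests demonstrate recovery of planted structure
under Poisson sampling noise, not robustness to every artifact of real
libraries.

A clonal rearrangement adds junction-spanning contacts with intensity
$s f (d_A + d_B + 1)^{\alpha}$, where $d_A, d_B$ are the bin offsets of the
two anchors from their breakpoints and $f \in [0,1]$ is the clonal fraction;
planted neo-loops multiply this junction background at chosen anchor pairs.
Chimeric reads are emitted with both segments exactly at the breakpoint
coordinates and the bridge-linker flag unset; decoy religation reads at random
positions carry the flag set, exercising the linker filter. Segment strands
encode the fused flanks ('+' on the first chromosome means its left flank
fuses; '+' on the second means its right flank fuses), and breakpoint-side
inference inverts this convention by majority vote.

# Matrix model and balancing

Contacts are binned with `floor((pos - 1)/binsize)` on 1-based positions;
internal coordinates are 0-based half-open bins, and all text I/O converts
explicitly (pairs 1-based, BED 0-based). Cis matrices are stored as full
symmetric sparse matrices with the diagonal counted once.

Balancing is the Knight-Ruiz inner-outer Newton iteration (conjugate-gradient
inner solves) with a plain Sinkhorn fallback on non-convergence, authored
in-package because no installed R package exposes the algorithm. Weights
solve $w_i \sum_j M_{ij} w_j = 1$ on unmasked bins; the default tolerance is
a relative row-sum deviation of 1e-6 within 300 outer iterations. Bins with
zero marginal, or marginal below the first-percentile order statistic of the
nonzero marginals, are masked before balancing — an explicit rule for
sparse-bin handling, using the type-1 (order-statistic) quantile so that
dense, fully supported matrices are never masked. Balancing satisfies the
usual invariances (unit weights on an already balanced matrix; weights of
$cM$ equal weights of $M$ divided by $\sqrt{c}$), which the tests assert.

Cross-sample comparability uses cis-depth normalization: each matrix is
scaled to a common cis total (default 1e6), leaving within-matrix ratios
untouched.

# Compartments

The compartment track is the first eigenvector of the Pearson correlation
matrix of the observed/expected cis matrix at 100-kb bins, computed per
chromosome. The eigenvector sign is arbitrary, so it is oriented positively
against a supplied per-bin activity proxy; the pipeline uses gene density,
and any proxy (GC content, expression coverage) serves on real data. Positive
values are A. Group consensus follows the strict over-70% majority rule: a
bin is A (or B) only when more than 70% of the group's samples agree — 7 of
10 is "other", 3 of 4 is A. Bins masked in at least half of a group's
samples are dropped. Switches are bins with opposite A/B consensus in the
two groups; bins labeled "other" in either group never switch, which makes
the switch table antisymmetric under group exchange.

# Insulation, TADs, domain scores

The insulation score of a bin is the mean contact value in the square window
offset diagonally at the bin (1 Mb window at 40-kb bins, i.e. 25x25),
log2-normalized by the chromosome mean, with the mean metric and a 0.1 noise
threshold — mirroring the standard insulation-caller parameterization. The
delta track is the mean insulation over the 200-kb span left of the bin minus
the span right of it; boundaries sit where delta crosses zero downward and
the local delta amplitude exceeds the noise threshold, taking the lower-
insulation bin of the crossing pair. Adjacent crossings within one bin keep
the stronger.

TADs are intervals between consecutive boundaries detected in at least two
conditions (each group's pooled map plus the overall pool), after merging
boundaries within one bin to the position of maximal pooled strength;
domains shorter than 3 bins are discarded. Boundary bins belong to neither
flanking domain, so adjacent TADs are disjoint and their domain scores share
no contacts — without this, enriching one domain mechanically depresses its
neighbour's score through the shared edge bin.

The domain score of a TAD in a sample is the sum of contacts with both
anchors inside the TAD divided by the sum of cis contacts with at least one
anchor inside it, diagonal included; it is bounded in (0, 1] and invariant
under global scaling. Differential calls at both the boundary and the
domain-score level use a two-sided Welch t-test across samples with
Benjamini-Hochberg correction, flagged only when FDR < 0.01 *and* the effect
exceeds a quantile of all effects (the 50% quantile of absolute
insulation-difference for boundaries, the 70% quantile of absolute log2 fold
change for domain scores). The per-sample boundary statistic — the delta
amplitude at the merged boundary bin — is this package's explicit definition
of a relative insulation value; the boundary-scoring tool the original
workflow delegated to does not publish its formula, so the substitute is
validated against planted truth only.

# Loop calling

Loops are focal enrichments over four local background estimates: a donut
ring (outer radius 5 bins, inner 2), the lower-left quadrant of that ring,
and 3-wide horizontal and vertical stripes. Each background yields a Poisson
rate for the center pixel after scaling by the distance-decay expectation;
the pixel p-value is the worst of the four upper tails, and candidates must
also exceed 1.75x the donut and lower-left rates and 1.5x the stripe rates.
BH correction runs over the full count of scanned in-band pixels (2 bins to
2 Mb separation), not merely the prescreened candidates — this is what keeps
a pure-decay null map free of calls. Calls within the per-resolution merge
distance (15 kb at 5-kb bins, 20 kb at 10-kb bins) collapse to the strongest
pixel, and a coarser-resolution call within the merge distance of a finer
one is absorbed by the finer call. This is a deliberate simplification of
the published donut-filter caller (no lambda-chunking, no k-norm thresholds);
the acceptance surface — planted-peak recovery with a clean null — is the
design target. Because the Poisson tails sharpen with depth, the call set is
not literally invariant under global count scaling; what is invariant, and
what the tests assert, is that every call survives doubling and that the
planted peaks remain the top-ranked calls.

Aggregate peak analysis sums observed/expected submatrices centered on each
loop (flank 10 bins), divides by the number of contributing loops, and
reports the center pixel over the mean of the four 3x3 corner blocks. Loops
closer to the diagonal than flank + 2 bins are excluded.

Differential loops quantify each union-set loop per sample as the
depth-normalized 3x3 anchor-neighborhood sum, test groups with a Welch t on
log2(x + 1), and correct within two distance strata split at 150 kb (anchor
midpoint separation), concatenating strata afterwards; the split guards the
test against the distance-dependence of count variance. The count-model test
of the adapted published method is replaced by the log-scale t-test; the
permutation-null acceptance test (flagged fraction at most 1.5x the nominal
FDR over five label permutations) keeps that substitution auditable.

CTCF orientation classification selects the highest-scoring motif within a
pad of each anchor; a loop is convergent when the upstream anchor motif is
'+' and the downstream '-' in native orientation. For anchors inside
inverted rearrangement fragments the motif strand is flipped back to native
orientation before classification. Summary fractions are reported over loops
with motifs at both anchors, and additionally over all loops, since the two
denominators answer different questions.

# Translocations and neo-loops

Interchromosomal blocks are detected by a coarse-to-fine Poisson scan of
trans matrices (1 Mb, then 100 kb inside candidate blocks) against a uniform
trans background estimated from the sample's own trans totals with a one-count
pseudofloor — a deliberately simplified stand-in for the iterative
expected-model of the published breakpoint finder, preserving its acceptance
surface (planted recovery plus control filtering). Eight-connected
significant pixels form blocks; any candidate whose block is also significant
in a control sample is flagged control-present and excluded downstream.

Breakpoints refine to single-bp coordinates from chimeric reads: linker-
positive reads are religation products and are discarded; the modal exact
coordinate pair among reads whose segments fall within the block (plus a
100-kb window) becomes the breakpoint when supported by strictly more than
three reads. Fused flanks come from segment-strand majorities; ties leave
the candidate unrefined.

The reassembled map extracts the two fused fragments (2-Mb flanks snapped to
the bin grid, clipped at chromosome ends), reverses fragments whose fused
flank faces away from the junction, and maps cis and cross contacts through
an invertible coordinate transform into one square matrix. Neo-loop detection
runs the same four-background caller restricted to junction-spanning pixels,
then requires at least 2-fold enrichment over the control-average map built
with the identical transform (3x3 neighborhoods, both maps depth-scaled); a
zero control neighborhood skips the comparison and flags the call. Anchors
map back to native coordinates and are flagged for overlap with pre-existing
loop anchors and CTCF motifs. The original study recorded neo-loops manually
from interactive heatmaps; automation with a 2x control-enrichment default is
this package's documented substitute, and only two-fragment events are
modeled.

Event annotation reports, per breakpoint: the nearest gene and distance, a
coding/noncoding flag (inside any gene body), the consensus compartment label
at the breakpoint bin, novelty under the 100-kb rule (novel unless a known
breakpoint lies within 100 kb), and the nearest gene's expression status —
upregulated when its FPKM in the carrier sample exceeds 1 and is at least
twice the mean of breakpoint-free controls, with the symmetric rule for
downregulation.

# Integration with expression

Virtual 4C is the viewpoint bin's row of the depth-normalized 10-kb matrix;
group profiles are sample means, and region-level interaction scores are
means over region bins (a mean, not a sum, so scores are comparable across
region lengths), tested between groups with Welch t and BH across regions.

Per-gene structural evidence combines the D-score-change and
loop-strength-change p-values by Fisher's method (chi-square, 2k degrees of
freedom; a missing component passes the other through); the method is a
parameter, with Stouffer's signed combination as the alternative, because the
source workflow names no method. The signed structural score is
-log10(combined p) times the sign of the smaller-p component's direction, and
its Pearson correlation with expression log fold change is the summary
statistic. The coupling generator used for validation derives the signed
score first and draws log fold changes conditional on it at a planted
correlation, so the planted value is the population correlation of exactly
the quantity the estimator measures.

DEG association applies the read filters (exclude a gene when more than 20%
of samples have fewer than 5 reads — the stricter reading of an ambiguous
filter sentence, exposed as parameters — or mean reads below 2) and DE
thresholds (FDR < 0.01, fold change > 2) to a supplied DE table; `de_table()`
provides a moment-estimate stand-in for synthetic cohorts, while real cohorts
should bring statistics from a dedicated DE caller. Genes link to compartment
bins and boundaries by gene-body bin overlap, to domain scores through the
TSS-containing TAD, and to loops through a TSS +/- 5 kb promoter window
overlapping an anchor. Each structural class is tested against structurally
stable genes with a one-sided Wilcoxon rank-sum test, oriented up for
B-to-A, D-score-increased and loop-enhanced classes.

# Pipeline and reproducibility

`run_pipeline()` executes simulate/load, binning and balancing, compartments,
domains, loops, structural variants and integration in order, writing
per-stage tables and a manifest with parameters, seed and MD5 checksums of
every output; identical configuration and seed reproduce identical checksums.
The bundled demo configuration (`demo_cohort_config()`) is a two-chromosome
(16 + 12 Mb), 4 + 4-sample cohort carrying planted compartment flips, a
case-only boundary, a domain-score gain, enhanced loops, and a clonal
translocation with one neo-loop; it completes all stages in about two minutes
on one CPU. Test fixtures use 12-50 Mb single- or two-chromosome genomes:
sizes at which every planted-recovery criterion is measurable while the whole
suite stays inside a routine desk-scale run.

# Known limitations

Only two-fragment rearrangements are modeled; multi-way events and
copy-number structure are out of scope. The trans background away from
junctions is empty by design, so block-detection specificity against, e.g.,
mappability artifacts is untested. The loop caller's simplifications mean
its absolute sensitivity is not comparable to the published tool's on real
data — planted-recovery performance is the supported claim. Real-data
compartment orientation requires a user-supplied activity proxy; no GC-based
fallback is bundled.
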