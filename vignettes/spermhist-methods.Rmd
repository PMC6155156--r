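---
title: "Methods: histone retention analysis in purified sperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone retention analysis in purified sperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During spermatogenesis most histones are replaced by protamines, but mature
spermatozoa retain a small histone residue whose genomic placement matters for
epigenetic inheritance. Bulk sperm preparations (cauda-epididymal "total
sperm", or motility-selected swim-up sperm) are not homogeneous: roughly 10%
of cells have not completed the histone-to-protamine exchange (HRunCS) and
carry far more histone per cell than the completed majority (HRCS). Bulk
histone ChIP signal from such preparations is therefore dominated by the
contaminating minority. This package implements the downstream analysis that
compares histone H3 binding between purified HRCS and total sperm, and the
arithmetic of the contamination argument itself.

## The contamination mixture model

Let `f` be the HRunCS cell fraction and `h_un / h_c` the per-cell histone
content ratio. With bulk measurements normalized per cell (fixed cell numbers
per lane), the bulk total : HRCS histone ratio is

    R = (1 - f) + f * (h_un / h_c)

`forward_ratio()` evaluates this; `invert_ratio()` solves for `h_un / h_c =
(R - (1 - f)) / f` and for the contamination share `f * (h_un/h_c) / R`. With
`f = 0.10` and a measured `R = 5` (a 5:1 western-blot ratio), the per-cell
ratio is 41 and the share is 0.82: most bulk histone comes from the 10%
minority. `f = 0` is non-identifiable and `R < 1 - f` is flagged as an
inconsistent measurement. `recover_from_noisy()` adds a percentile bootstrap
over replicate `R` measurements; the seed is mandatory, and because the
approximate inputs (`f ~ 0.10`, `R ~ 5`) make the point value soft, the
sensible report is the inferred ratio over a range of `f`, not 41 as a
biological constant.

## Peak screening

`enrichment_screen()` is a deliberately simple stand-in for a peak caller, not
a MACS2 re-implementation: per coverage bin, fold change on RPM-scaled counts
with the input floored at a pseudocount of 1 read (avoids infinite FC), an
upper-tail Poisson p-value with the mean set to the depth-rescaled input
count, Benjamini–Hochberg adjustment across bins ("FDR" is otherwise
unspecified; BH is our documented choice), retention at `FDR < 0.01` and
`FC > 5` (the published filter), and merging of adjacent retained bins (peak
score = mean bin FC). Fold change is exactly invariant to rescaling both
depths by a constant; Poisson tail significance is not, so retention
decisions are only guaranteed stable away from the significance boundary —
the property test uses well-separated signal for exactly this reason. The
screen is not expected to reproduce the published genome-scale peak counts
(10,988 / 1,320), which depend on the raw reads and caller internals.

## Genomic compartments

Compartments follow the published definitions: promoter = "1 kb around the
TSS", read as TSS ± 1000 bp (2 kb total; the commonest reading of that
phrase — configurable via `promoter_flank`); upstream = strand-aware
`[TSS - 5 kb, promoter)`; downstream = `[TES, TES + 5 kb)`; exons and introns
from gene bodies; the remainder intergenic, split into repeat/unique by
repeat overlap. Precedence promoter > exon > intron > upstream > downstream >
intergenic resolves every base to exactly one class, and up/downstream
windows exclude the promoter, so the classes partition each chromosome
exactly (`check_partition()` asserts length conservation and empty pairwise
intersections; windows are clipped at chromosome bounds). Peaks are assigned
by the class of their midpoint base — deterministic, order-independent and
cheap; a maximal-overlap rule is available via `assign = "max_overlap"`
because the paper does not state which was used. Enrichment is
`fraction(peaks in class) / fraction(genome in class)`.

## CpG island o/e

`compute_oe()` uses the Gardiner-Garden & Frommer convention
`oe = N_CpG * L / (N_C * N_G)`, with `N` bases excluded from all counts and
from `L` so masked sequence does not deflate the ratio; `N_C * N_G = 0` is an
undefined-o/e error, not 0 or infinity. Real annotations ship precomputed
o/e values whose exact upstream convention is unknown; for synthetic data the
convention is irrelevant because islands are constructed with an exact
planted CG count (below). Distribution comparisons use the two-sided Wilcoxon
rank-sum test — exact for small untied samples, normal approximation with
continuity and tie correction otherwise — and box statistics (median,
quartiles, 1.5 × IQR whiskers, outliers).

## Target-gene categories

A gene is a target iff a peak overlaps its promoter window; linkage is
promoter-only, matching the promoter-centric published summaries. Overlap
percentages are reported rounded to the nearest integer (966/1320 prints as
73%), with raw fractions retained. Categories: `H` = HRCS targets; remaining
total-sperm targets split into `PH` ("potential" HRCS targets with moderate
HRCS signal) vs `TS` by comparing the mean HRCS RPM over the gene's
total-sperm promoter peak(s) with a reference level. The published threshold
for "moderate" is unstated, so it is surfaced, not hidden: the default rule
is `S >= k * B` with `B` the genome-wide mean HRCS RPM and `k = 2`; an
alternative quantile rule (`S` above the q-th percentile of per-promoter
HRCS signal) is available. Categorization is monotone in `k` by
construction.

## TSS matrices and profiles

`build_tss_matrix()` counts coverage in 50-bp bins over a window centered on
each anchor, normalized to reads per million mapped reads. "3 kb around the
TSS" is read as a 3 kb total window (TSS ± 1.5 kb, 60 bins); ± 3 kb is one
config change away since the phrase is ambiguous. Minus-strand rows are
reversed so column 1 is always 5'-most; the flip is a plain reversal, hence
an involution. Anchors whose window leaves the chromosome are zero-padded and
flagged rather than dropped, keeping row sets identical across samples for
side-by-side heatmaps. Conservation (matrix total = RPM-normalized raw
counts in the windows) and invariance to joint depth rescaling are tested
properties. Heatmap export orders rows by decreasing mean signal (ties by
name) or by a supplied list.

## Methylation and expression dynamics

Region methylation is the unweighted mean of per-site CG levels (the stated
"averaging the methylation levels of CG sites"); a coverage-weighted variant
sits behind a flag, and `min_coverage` (default 1 — no published filter)
gates sites. Regions without qualifying sites are reported missing, not
dropped silently. Cross-sample agreement uses plain Pearson correlation with
pairwise-complete observations (at least 3 pairs). Assembly liftover is out
of scope: all region lists must arrive on one assembly.

Expression dynamics restrict the gene universe to genes above the FPKM
threshold (strict `> 10`) at a conditioning stage — the oocyte, as the
published legend implies; a toggle disables conditioning. For each category
and stage the fraction of the conditioned universe above threshold is
reported. Note that with conditioning enabled, raising the threshold changes
the universe too, so threshold-monotonicity of the fractions only holds for a
fixed universe; the property test therefore fixes the universe.

## The synthetic world

`generate_dataset()` builds a toy genome whose statistical structure matches
what the analysis assumes, with every planted parameter recorded in a truth
record:

* **Layout.** Genes occupy a 16-kb slot grid (4-kb bodies, three exons), so
  neighbouring promoter/upstream/downstream windows never collide and each
  slot keeps a guaranteed-intergenic strip. The last chromosome (`chrX`)
  carries genes at half the autosomal density, emulating the depleted sex
  chromosome. Defaults (4 chromosomes × 1.5 Mb, 120 genes, 40/60 peaks) are
  desk-scale stand-ins: the real genome-scale numbers need the deposited raw
  data and are not reproduced here.
* **Peaks.** Placement is constructive: exactly `round(fraction * n)` peaks
  are centered on TSSs (promoter fraction 0.65 by default, near the published
  69%/64%) and the rest go to intergenic strips, every third one inside a
  planted repeat. The recovered promoter fraction therefore equals the
  planted one exactly, and convergence tests are meaningful.
* **Sequence.** Background sequence is generated CG-free (every CG destroyed
  by a terminating swap pass), and each promoter CGI is assembled with an
  exact count of planted CG dinucleotides at 65% GC, so its o/e is known in
  closed form (`k·L/(n_C·n_G)`) and `annotate_cgis()` must reproduce it to
  the last digit. HRCS-target CGIs draw their o/e around 1.2, others around
  0.6, giving the published direction of the o/e contrast. A consequence:
  all methylation CG sites live inside CGIs.
* **Coverage.** Poisson background (5 reads/bin of 50 bp) plus promoter
  signal: strong at `H` promoters and moderate (~4× background) at `PH`
  promoters in the HRCS track; strong, broader signal at all total-target
  promoters in the HRunCS track (breadth is a parameter,
  `hruncs_peak_halfwidth`, because no measurement pins it down). The total
  track is the literal mixture `(1-f)·h_c·HRCS + f·h_un·HRunCS` with
  `f = 0.10`, `h_un/h_c = 41`, so flat unit tracks close the 5:1 bulk ratio
  exactly.
* **Methylation.** Per-site underlying levels Beta(0.5, 5) in peak-bearing
  CGIs and Beta(5, 1.5) elsewhere ("predominantly in lower methylation
  regions", qualitatively); both samples draw binomial counts around the same
  underlying level, so cross-sample correlation is high by construction.
* **Expression.** Log-normal FPKM (sdlog 0.5) around stage means: `H`/`PH`
  genes 30 at oocyte decaying to 1 after the four-cell stage, `TS` genes
  staying moderate, background genes at 8. This reproduces the published
  shape (post-ZGA suppression of HRCS targets) without asserting real
  magnitudes.

What a green test establishes: the operations implement their definitions and
recover planted structure. What it does not establish: behaviour on real
genomes (repeat structure, CGI length distributions, mappability,
fragment-level noise, inter-replicate variability), none of which the
generator emulates.

## Numerical choices and degenerate inputs

All interval arithmetic is 0-based half-open end to end, BED-native, with
conversion to 1-based closed only inside the IRanges-backed helpers; overlap
means ≥ 1 shared base, strand-blind (no minimum-overlap rule is published).
Empty query sets make overlap fractions undefined and error explicitly, as do
empty o/e samples, `f = 0` inversions, inconsistent `R < 1 - f`, fewer than
3 correlation pairs or bootstrap replicates, windows not divisible by the bin
width, and peaks on chromosomes missing from an annotation (offenders are
listed). Ties in heatmap ordering break lexicographically by row name;
pipeline reports store content hashes of every output, and reruns with the
same config and seed are byte-identical (timing is deliberately kept out of
the on-disk report).

## Known limitations

The enrichment screen ignores fragment-size modelling and local background;
the mixture model treats bulk measurements as per-cell normalized and exact;
the synthetic genome has no repeats outside the planted ones and no CG sites
outside CGIs; promoter windows are symmetric; and the published per-cell
ratio 41 is an inference from approximate inputs, not a measured constant.
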