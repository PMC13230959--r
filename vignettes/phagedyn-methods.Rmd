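---
title: "Models and methods behind phagedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phagedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedyn)
```

phagedyn packages the computational core of a longitudinal phage–host
population study: an oyster pathogen (*Vibrio crassostreae*) structured
into clades, its lytic and temperate phages, the mobile genetic elements
(MGEs) that shuttle genes between strains, and droplet digital PCR
(ddPCR) time series tracking clade and phage abundances through a
sampling season. This vignette explains each model, its assumptions, the
parameters that matter and the design choices made where the design was
genuinely open. Every empirical statement here is one the package's test
suite or acceptance script computes itself.

## Intergenomic similarity and taxon ranks

Two phage genomes a and b are compared by the fraction of identically
aligned nucleotides:

$$\mathrm{sim}(a,b) = 100\,\frac{I_{ab} + I_{ba}}{L_a + L_b},$$

where $I_{xy}$ counts identical positions over a non-overlapping set of
local alignment fragments of x against y and $L$ are genome lengths.
This is the convention popularized by viral intergenomic-distance
calculators built on blastn. phagedyn uses its own deterministic,
dependency-free aligner:

* exact k-mer anchors (k = 11) seed candidate diagonals;
* each anchored diagonal window is scored +1 per match, −1 per
  mismatch, and all maximal scoring segments (Ruzzo–Tompa) become
  gapless fragments — ambiguous bases (N) never count as matches;
* fragments shorter than 30 bp are discarded (suppressing spurious
  micro-matches), the rest are selected greedily by descending
  identical-position count, with later fragments trimmed to the
  positions not yet covered in either genome, re-applying the floor.

The aligner is verified in the test suite against an exhaustive
dynamic-programming oracle (every diagonal, every segment; plus a full
Smith–Waterman with gaps on small pairs). Because the synthetic genome
model is substitution-only, gapless fragments are exact there; on real
genomes with indels the similarity is a lower bound, which is the
conservative direction for threshold clustering. Numeric agreement with
blastn-based pipelines on real genomes is not claimed — only
threshold-level agreement on controlled divergence bands.

Taxon ranks come from complete-linkage hierarchical clustering of
$100 - \mathrm{sim}$ distances, cut at 30 (genus, similarity ≥ 70) and
5 (species, similarity ≥ 95) — the ICTV-style thresholds. Complete
linkage makes cluster membership equivalent to *every* pair passing the
threshold, and cutting one dendrogram at two heights guarantees that
species nest inside genera. Cluster labels are assigned by the
lexicographically smallest member, so output is deterministic.

## Synthetic phage families

`simulate_phage_family()` plants a taxonomy using a star phylogeny per
species nested in a star per genus, with site-independent substitutions
uniform over the three alternative bases and no indels. Divergence
parameters are *observed pairwise* divergences: branch substitution
probabilities are derived by inverting the Jukes–Cantor-style identity
$1 - D = \tfrac14 + \tfrac34\prod_i(1 - \tfrac{4p_i}{3})$, so planted
bands land where configured even for large divergences where back
mutations matter. Defaults — 0.02 within species, 0.15 within genus,
0.45 between genera — put expected similarities near 98, 85 and below
60: comfortably on the correct sides of the 95/70 thresholds. The
default family (3 genera × 2 species × 2 genomes of 5 kb) is sized so
the clustering-recovery suite can afford 20 independent seeds; the bands,
not the genome length, are what the recovery result depends on. The
generator does not emulate recombination, mosaicism or indels, so
perfect partition recovery on simulated families shows the clustering
logic is correct — not that real phage taxonomy is this clean.

## Clade-diagnostic SNPs and ddPCR primer design

Given an allele matrix over strains (the product of any variant caller,
or of the package's aligned simulator), each polymorphic site is scored
per target clade:

* sensitivity = fraction of target-clade strains with a call that carry
  the alternate allele;
* specificity = fraction of non-target strains with a call that do not.

Missing calls leave both numerator and denominator. "Optimal" is read
strictly — both exactly 1.0 in a core gene — because only
fully-diagnostic sites guarantee clade-specific amplicons;
`filter_optimal_snps()` exposes relaxation thresholds for noisier data.
Retained sites become nodes of a proximity graph with edges up to a
300 bp horizon (one amplicon length — more distant pairs cannot share
an assay), weighted by distance. The weights delimit candidate windows;
they do not otherwise enter selection, since no published weighting rule
exists for this step.

`design_primers()` enumerates primer windows of 25–40 bp containing at
least two retained positions, pairs them into amplicons of 180–300 bp
measured from forward start to reverse end (primers included — the
standard assay convention), and requires an 18–30 bp probe window
strictly between the primers containing at least one retained position
(probes are dye-labelled in multiplex assays, so a discriminating
position under the probe is the minimal defensible requirement; no
published probe criterion exists). Ranking is by total specific
positions in the primers (descending), then amplicon length
(ascending), then leftmost coordinates — fully deterministic and
verified against brute-force enumeration of every window pair. Primer
thermodynamics (Tm, GC clamp, dimers) are deliberately not modelled:
the selection criteria here are purely positional and every output row
is flagged `thermo = "unchecked"` for downstream chemistry screening.

The population simulator plants, per clade, a seven-SNP diagnostic
cluster with exactly this geometry (triplets 12 bp apart at both ends
of a ~255 bp span, one interior probe site) plus scattered private
SNPs, so end-to-end recovery — from genomes through scoring, filtering,
graph and design — is testable against construction.

## Pangenome plasticity and the MGE census

Persistent gene families are those present in ≥ 90% of strains
(inclusive). Regions of genomic plasticity (RGPs) are re-implemented
from the concept: maximal runs of consecutive non-persistent genes
spanning ≥ 3 kb with ≥ 3 genes, both configurable; the published
pangenome tool's scoring internals are not reproduced, since what the
downstream census needs is the flexible-genome intervals. RGPs are
classified by the first matching rule in a fixed precedence — plasmid
origin → full satellite segment → prophage (viral call, or
complete/high/medium/low quality with ≥ 1 viral gene) → integrase →
unclassified — the order in which the rules are stated for the original
census; classification is total, exclusive and order-invariant.
Upstream detectors (geNomad, checkV, SatelliteFinder, PADLOC, bakta)
are consumed as annotation flags, never re-implemented; the synthetic
population emits flag tables with known class truth.

Prophage predictions are retained only strictly above class-specific
sizes (Caudoviricetes 25 kb, Tectiliviricetes 10 kb, Faserviricetes
4 kb). Cargo screens use per-database identity/coverage minima
(metal/biocide and virulence 70/50, AMR 30/50), with coverage defined
as the aligned fraction of the reference sequence. Cargo density is
hits per kbp, compared across MGE classes and the non-mobile remainder
by a Kruskal–Wallis H-test (tie-corrected), Dunn's pairwise z-tests,
Benjamini–Hochberg adjustment over all pairs, and a compact letter
display at α = 0.05 built by insert-and-absorb over the
non-significance graph, with groups ordered by median so lettering is
deterministic. Dunn's test and the letter display are implemented in
the package (no installed R implementation applies to plain group
vectors); BH is verified in the tests against a from-scratch step-up
oracle and the omnibus test is calibration-checked under the null.

## Gene repertoire relatedness and plasmid inference

For two protein repertoires A and B,

$$\mathrm{wGRR}(A,B) = 100\,\frac{\sum_{(p,q)\in\mathrm{BBH}} \mathrm{id}(p,q)}{\min(|A|,|B|)},$$

with bidirectional best hits under global alignment identity
(identical residues / alignment length, unit match score) and a 0.35
identity floor before BBH resolution — the floor mirrors common wGRR
practice and is configurable; it is not printed in the original
protocol. The min-cardinality denominator is adopted from the usual
wGRR definition. Ties break lexicographically. A plasmid family is
present in a strain when the maximum wGRR against the family references
*strictly* exceeds 50, and the argmax reference is the closest plasmid.
Read remapping and consensus reconstruction are out of scope: the
operation consumes repertoires, and the simulator produces "remapped"
repertoires by mutating references. Copy number is mean element depth
over mean chromosomal depth.

## ddPCR quantification and time series

Each well is accepted with ≥ 10,000 droplets (inclusive). Poisson
partitioning gives $\lambda = -\ln(1 - f)$ copies per droplet from the
positive fraction f; with the default 0.85 nL droplets and 20 µL
reactions this inverts exactly the binomial droplet model the simulator
uses, and the quantification limit is 1 copy per reaction. Replicate
summaries are geometric: mean and 95% t-interval on the log10 scale,
back-transformed; non-positive values are excluded (and counted) by
default, with an optional substitute-at-LOQ mode — the original
protocol suppresses error bars below LOQ but states no imputation, so
both behaviours are exposed. Interval coverage is verified by
simulation (95% ± 1.5% at 2,000 trials).

Correlation analyses run on per-date means of log10 replicate values.
The ACF is the biased, n-denominator ("unadjusted") estimator with
PACF via Durbin–Levinson, both to a default lag of 10 sampling dates;
the CCF is the standard sample cross-correlation over ±10 lags with the
argmax reported, and `ccf_series(a, b)` at lag k equals
`ccf_series(b, a)` at −k. Lags are counted in sampling dates, not
calendar days, matching how the original series were analysed. For the
uneven calendar, the floating-mean (generalized) Lomb–Scargle
periodogram is implemented directly (no installed R package provides
it): frequencies from 1/T to n/(2T) at 5× oversampling, power
normalized by total variance so it lies in [0, 1], with a classical
independent-frequencies false-alarm level available. It agrees with an
FFT oracle in the even-sampling limit and recovers planted periods
within one grid step. Trends use `stats::smooth.spline` with the
generalized cross-validation criterion. The coefficient of variation
is computed on log10 quantifications by default (the scale on which
the series are analysed); a raw-scale option exists.

The series simulator draws 35 unevenly spaced dates (1–4 day gaps, the
cadence of a summer sampling season) with 10 replicates per date,
log-normal replicate noise (default sd 0.4 log10 units), optional
sinusoidal seasonality and optional lag-coupling of one series to
another — the statistical skeleton of a phage tracking its host clade.
It does not model overdispersion beyond log-normality, nor inhibition
or multiplex cross-talk in the wells; recovery results certify the
estimators, not the ecology.

## Determinism and degenerate inputs

Every generator takes a seed and is bit-reproducible; every analysis
stage is deterministic, with ties broken lexicographically or by fixed
orderings. Degenerate inputs fail loudly: empty sequences, duplicate
FASTA IDs, unsorted gene tables, constant series for correlation or
periodogram analysis, groups with fewer than two observations,
non-positive chromosomal depths, saturated wells (flagged, with an
infinite point estimate rather than a silent cap).

## Problem sizes

The shipped defaults are desk-scale choices made once: 12-genome phage
families of 5 kb, 4-clade populations of 40 strains with 40 core genes
of 900 bp, 35-date series with 10 replicates, 20-seed recovery suites,
and 2,000-replicate calibration runs. They are stated here as the
package's own testing conditions; all are parameters, and nothing in
the implementation depends on them.
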