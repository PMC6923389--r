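---
title: "Methods: low-VAF somatic calling and clonality analysis in adenomyosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-VAF somatic calling and clonality analysis in adenomyosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenoclone)
library(tibble)
```

`adenoclone` analyses targeted deep sequencing (TDS) of uterine
adenomyosis and related tissues, where somatic mutations live at variant
allele fractions (VAF) of 0.1–20% and must be separated from a
sequencing noise floor of similar order at individual positions. This
vignette records the statistical model, the tunable parameters, what the
synthetic generators do and do not emulate, and the numerical and design
choices made where more than one reasonable option existed.

## The position-local noise model

Deep amplicon sequencing has strongly position- and allele-specific
substitution error: some positions are nearly clean, others carry a
stable artefactual non-reference fraction of up to a few tenths of a
percent. A single genome-wide error rate is therefore useless at the
VAFs of interest. The caller instead works *locally*:

1. For a lesion sample with VAF profile $a_{y,i}$ and a matched control
   (blood or adjacent normal tissue) with profile $n_{y,i}$, the
   per-position difference statistic is
   $$d_i = \max_{y \in \{A,C,G,T\}} \left| a_{y,i} - n_{y,i} \right|.$$
   Both strands are pooled; N bases, deletions and reference skips never
   enter the depth. The bar is an absolute value: noise enriched in the
   control must count symmetrically, otherwise the background model
   would be biased low.
2. For each candidate position $j$, the background is the set
   $\{d_k : k = j-K, \dots, j-1, j+1, \dots, j+K\}$ — position $j$ is
   always excluded from its own window, and windows truncate at the
   amplicon boundary rather than padding (padding would invent data).
   With window mean $\mu_j$ and SD $\sigma_j$, the null is
   $X \sim N(\mu_j, \sigma_j^2)$.
3. A somatic call at $j$ requires all of
   $P(X > d_j) < \alpha$ (default 0.05), $d_j > d_\min$ (default 0.001),
   and every non-reference allele of the control at $j$ below
   `control_vaf_max` (default 0.01). The three flags are reported
   separately (`p_pass`, `d_pass`, `control_pass`) so a failed call is
   always attributable.

### Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `alpha` | 0.05 | — | one-sided tail level of the local normal null |
| `d_min` | 0.001 | VAF fraction | floor on the effect size; suppresses significant-but-negligible differences at extreme depth |
| `control_vaf_max` | 0.01 | VAF fraction | germline/artefact guard: the control must be clean at the site |
| `K` | full region | positions | window half-width; the default uses the entire amplicon (length in bp) as the window, which is the intended operating point for ~250 bp amplicons |
| `sd_ddof` | 0 | — | population SD of the window; 1 gives the sample SD (the distinction is negligible at the default $K$, where a window holds ~250 values) |
| `bonferroni` | off | — | optional per-region multiple-testing correction; the core procedure tests each position (or each pre-registered candidate) uncorrected |

Degenerate cases are resolved deterministically: $\sigma_j = 0$ makes
the null a point mass ($p = 0$ if $d_j > \mu_j$, else $1$); a window
with fewer than two usable positions is an error when a position is
tested explicitly and an `NA` model when scanning. When the argmax
allele at a position is the reference (possible, since the reference
difference is minus the sum of the alternative differences), $d_j$
still uses the full max but the reported variant allele is the best
non-reference allele.

Two testing modes exist because practice needs both: scanning every
position of a region, and restricting to a pre-specified candidate list
(`positions =`). The statistic and thresholds are identical.

### Calibration: what the normal tail does and does not deliver

The normality assumption is on the *difference track*. When the noise
floor is substantial relative to its own spread (so $d$ is a shifted,
approximately Gaussian quantity), the test is well calibrated: on
directly generated Gaussian tracks the empirical `p_pass` rate at
$\alpha = 0.05$ is ~0.05 (the unit suite measures it on 10,000
positions).

On count-level nulls the picture is subtly different, and worth stating
precisely because it is a property of the method, not of any
implementation: with lesion and control exchangeable, each per-allele
difference is symmetric around zero, so $d$ is a *folded* (absolute)
maximum. Fitting a normal to $d$ itself and testing one-sided at 0.05
then rejects at the rate set by the folded distribution's true upper
tail — for a single folded-normal component this is
$2\,(1 - \Phi(0.798 + 1.645 \times 0.603)) \approx 0.073$, and
Monte-Carlo at depth 10,000 under the package's beta-heterogeneous
error model gives 0.070–0.075 across a wide range of dispersion
settings. The acceptance suite measures this rate on 10,000 simulated
null positions; the verdict rate (after `d_min` and the control guard)
is always bounded by it. Users who need strict 5% calibration on nulls
should lower `alpha` to ~0.034 or rely on the `d_min`/control guards,
which dominate in practice; the package keeps the published operating
point as its default.

Power is not delicate: at depth 10,000 a spiked variant at VAF 2.47%
(the bottom of the observed lesion VAF range) sits tens of background
SDs above the noise floor and is detected essentially always; the
acceptance suite verifies power > 0.9 over 500 simulated regions.

## Exome candidate filters

Candidates from exome calling are discarded when *any* of: total reads
< 100, mutant reads < 7, disease VAF < 0.024, germline VAF > 0.01,
single-strand support, or presence in a population database. All
violated rules are logged per candidate (not first-hit), filtering is
idempotent, and every threshold is configurable. Two recorded choices:

* Narrative summaries of this scheme sometimes state the mutant-read
  rule as "< 8"; the formal rule (discard below 7, i.e. require ≥ 7) is
  the default here, with the threshold exposed.
* Population-database membership is a precomputed boolean column, not a
  live lookup, keeping runs offline and versions explicit.

## Negative-panel hotspot cutoffs

Macro-dissected normal endometrium carries real low-VAF hotspot signal,
so hotspot calling uses an empirical detection threshold per hotspot
class: cutoff = panel mean + 3 × panel SD of the VAFs observed in a
negative panel (56 samples in the reference design). Percent is the
canonical unit in this module — cutoffs like 0.335% are meaningful at
the third decimal, and a silent factor-of-100 slip against fraction
units is the classic failure mode, so conversion happens only at module
boundaries. The SD is the population SD by default (`sd_ddof`
configurable); calls are strict (`VAF > cutoff`); a class pooling
several codons scores a sample by its maximum single alt-allele VAF
within the class (one genuinely mutant codon should suffice for
detection). Leave-one-out estimation is available for panels that
contain the tested sample; the default uses the full panel.

## Multi-region clonality

`build_matrix()` assembles the union of per-sample calls into a
mutation × sample VAF matrix. Presence per cell is, in order of
preference: the noise-caller verdict when a matched control exists,
otherwise a VAF threshold (hotspot cutoff or the configurable 1%
absolute default). Blood is displayed but never participates in sharing
computations. Cells not assayed in a sample are missing-flagged and
excluded rather than zero-filled.

Sharing classes are count-based over the *assayed* samples of the
dominant lesion tissue class (the class with most samples, typically
adenomyosis): present in all of them (and ≥ 2) is `ubiquitous` — the
early-acquired trunk pattern; exactly one lesion sample is `private`;
in between is `restricted`. Mutations absent from the dominant class
fall back to counts over all lesion samples. Two orthogonal flags
capture the biologically loaded patterns: `cross_lesion_shared`
(present in adenomyosis *and* endometriosis — evidence of a shared
clone of origin) and `normal_shared` (also present in normal
endometrium — evidence the clone predates the lesion). Flags sit on
top of, and never contradict, the count-based class.
`mutual_exclusivity()` reports the Jaccard fraction of mutations shared
between two tissue classes (0 for the adenomyosis/leiomyoma pattern).

## Bisulfite methylation

At a CpG, reads retaining C are methylated, reads converted to T are
unmethylated, anything else is uncallable and excluded from the
denominator: `freq = methylated / callable`, `NA` when callable is
zero. The per-sample amplicon summary is the unweighted mean over
defined CpGs (matching per-region reporting granularity); a
depth-weighted mean is available. Non-CpG cytosines provide the
conversion-rate QC (warning below 0.98 by default) — incomplete
conversion inflates apparent methylation by (1 − rate) at unmethylated
sites, which the generator reproduces exactly. Group comparisons are
Welch's *t* on per-sample means. The reference bisulfite design is 20
wild-type vs 11 mutated samples (one narrative passage says 13; the
plotted design's 11 is used for the synthetic design point, and the
discrepancy is simply noted).

## Cohort statistics

`fisher_exact()` implements the two-sided exact test by the
point-probability rule — sum the hypergeometric probabilities of all
tables (margins fixed) whose point probability does not exceed the
observed table's, with the standard `1 + 1e-7` tie tolerance. This is
the convention of mainstream implementations and is verified in the
tests both against exhaustive `choose()`-based enumeration (exact
agreement on every 2×2 table with total ≤ 40) and against
`stats::fisher.test`. The odds ratio reported is the sample
cross-product estimate, `NA`/`Inf`-flagged on empty margins.
`welch_t()` wraps `stats::t.test(var.equal = FALSE)` with deterministic
zero-variance handling (equal means → $t = 0, p = 1$). One recorded
inconsistency: recomputing the PR-immunohistochemistry table (13/26 vs
7/44) gives $p \approx 0.005$, not the sometimes-quoted 0.052; the
battery computes the value and nothing in the package pins the quoted
one. qPCR fold changes follow the comparative-Ct method:
$\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{reference}$,
$\Delta\Delta Ct$ relative to the mean control $\Delta Ct$, fold
$= 2^{-\Delta\Delta Ct}$.

## What the generators emulate

All generators are pure functions of their parameters and a seed, and
they restore the caller's RNG state.

* `simulate_amplicon()`: per-position multinomial reads over
  {A, C, G, T} at fixed depth, with per-(position, alt) error VAFs
  drawn from a beta distribution — mean `6.5e-4`, shape `0.57`
  (CV ≈ 1.3), capped at 0.01. These defaults are anchored to the
  negative-endometrium panel scale (per-hotspot VAF mean ~0.065%, SD
  ~0.09%), giving null difference tracks of ~0.03–0.3% magnitude. A
  matched pair shares the same per-position rates (the error floor is a
  property of the assay at that position), so the difference track
  reflects sampling noise around a common floor. Strand counts split
  binomially.
* `simulate_patient()`: clones with mutations and per-sample cell
  fractions placed across a multi-region design; heterozygous autosomal
  convention VAF = cell fraction / 2, times an optional `purity`
  multiplier that emulates bulk-tissue dilution vs micro-dissected
  epithelium. Blood is drawn from the pure noise process. Ground truth
  (expected VAF matrix, sharing classes and flags) is emitted alongside
  the counts by direct bookkeeping of the placement table.
* `simulate_negative_panel()`: null per-hotspot VAFs per panel sample
  (beta rate, binomial reads), on the sub-percent scale that yields
  0.1–0.5% cutoffs.
* `simulate_bisulfite()`: binomial methylated counts per CpG with the
  incomplete-conversion inflation described above, plus non-CpG sites
  for QC; small uncallable fraction per site.
* `simulate_cohort_metadata()`: Bernoulli mutation status and
  characteristics with status-dependent probabilities, so every true
  odds ratio is known.

What they deliberately do **not** emulate: PCR duplicates and UMI
structure, read-level artefacts (strand bias beyond binomial splitting,
context-specific deamination as in FFPE), overlapping-amplicon
reconciliation, alignment error, copy-number or purity variation within
a sample, and correlated errors between positions. Passing tests on
synthetic data therefore demonstrate the statistics behave as designed
under the stated model — not that the model captures every failure mode
of real libraries; on real data the control guards and panel cutoffs do
the corresponding work.

## Problem sizes used in the test and acceptance runs

Chosen to exercise the published design points at desk scale on one
CPU: null calibration on 40 × 250 bp amplicons at depth 10,000 (10,000
tested positions); power on 500 spiked regions at VAF 2.47%, depth
10,000; clonality recovery on 100 simulated six-region patients (trunk,
restricted, private and cross-lesion clones, depth 10,000, all VAFs
≥ 2%, scored against generator truth, ≥ 95% accuracy required); 2,000
threshold-straddling exome candidates against a rule-by-rule oracle;
1,000 bisulfite two-group draws (n = 20 vs 11, mean methylation 0.05 vs
0.5). Fisher enumeration sweeps every 2×2 table with total ≤ 40
(~250,000 tables).

## Known limitations

* Indels, multi-sample joint calling and CRAM input are out of scope;
  the caller is SNV-only over {A, C, G, T}.
* The per-cell presence rule for multi-region matrices is the
  noise-caller verdict or a VAF threshold; no per-cell posterior is
  computed, and no phylogeny or subclonal deconvolution is attempted —
  the deliverable is the VAF matrix and its sharing structure.
* The windowed null assumes the amplicon's other positions are
  mutation-free; a second true variant inside the window inflates
  $\mu_j, \sigma_j$ slightly (conservative). At the default $K$ this
  effect is ~1/250 per variant.
* One-sided testing without multiple-testing correction matches the
  published operating point; the Bonferroni option exists for scanning
  use.
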