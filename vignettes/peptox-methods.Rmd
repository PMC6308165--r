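---
title: "Methods: peptide cytotoxicity assays and pathway activation scoring"
author: "peptox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide cytotoxicity assays and pathway activation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptox)
```

# Scope

`peptox` packages the computational backbone of a cytotoxicity
characterization of a cationic host-defense (antimicrobial) peptide — the
kind of study that asks whether a membrane-active peptide kills tumor cells
selectively, by what mode (necrosis vs. caspase-dependent apoptosis), and
what transcriptional response surviving cells mount. Four analysis layers
are covered, each with a seeded synthetic-data generator so that every
stage can be tested against a known planted truth at desk scale:

1. **Sequence descriptors** — monoisotopic/average mass, protonated-ion
   m/z, Kyte–Doolittle GRAVY, basic-residue census.
2. **Plate assays** — hemolysis, LDH-release and MTT viability
   percentages, and 4-parameter logistic (4PL) IC50/HC50 fitting.
3. **Flow cytometry** — annexin V/PI quadrant fractions and a kinetic
   necrosis-vs-apoptosis signature.
4. **Transcriptomics** — probe aggregation, quantile normalization,
   case-to-normal ratios (CNR) and pathway activation strength (PAS).

# Peptide descriptors

Masses are residue-table sums: the neutral chain mass is the sum of
residue masses plus one water (monoisotopic 18.010565 Da, average
18.0153 Da); C-terminal amidation replaces the terminal −OH with −NH~2~
(−0.984016 Da monoisotopic). The proton mass is fixed at 1.007276 Da, so
the singly protonated ion is `M + 1.007276`. These standard constants
reproduce published MALDI-scale values to the printed decimal. Display
convention: monoisotopic to 1 decimal, average mass to the nearest
integer, GRAVY to 3 decimals; full precision is kept internally.

Two deliberate choices:

* **Basicity census includes His** alongside Arg and Lys, following the
  field's convention for cationicity of host-defense peptides, even though
  His is only weakly basic at pH 7.
* **The integer-rounded "average mass" of a natural peptide is computed on
  the free-acid form** by default. For the 27-residue goat cathelicidin
  used throughout the examples the free-acid average mass rounds to
  3365 Da, consistent with its published characterization; callers can ask
  for the amidated form explicitly via `cterm = "amide"`.

Only the 20 canonical residues are accepted; the parser reports the first
offending position. No pI, net-charge-vs-pH or secondary-structure
prediction is attempted.

# Plate assays and dose-response fitting

All three percent formulas are affine ratios of optical densities,

$$\%\; = 100 \cdot \frac{OD_{sample} - OD_{neg}}{OD_{pos} - OD_{neg}},$$

with the role of negative/positive control depending on the assay
(buffer vs. detergent lysis for hemolysis at 405 nm; spontaneous vs.
maximal release for LDH at 492 nm; blank vs. untreated cells for MTT at
570 nm). Results are **not clipped** to [0, 100]: noise can legitimately
push a well outside the band, and clipping would bias curve fits.
`outOfRange()` flags such wells. Degenerate controls (positive ≤ negative)
are an error, not a NaN.

Dose-response curves are fitted with the 4PL model on the log10-dose
scale,

$$y(x) = bottom + \frac{top - bottom}{1 + 10^{\,h\,(\log_{10}x - \log_{10}m)}},$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) over pooled
replicates — replicates are fitted jointly rather than averaged first, to
preserve the error structure. Initialization: plateaus from the extreme
per-dose means, midpoint from the dose nearest the half-response,
`h = ±1`; the midpoint is bounded within two decades of the tested range.
Exactly noiseless data can place this start on a singular-gradient knife
edge, so a single deterministically nudged restart is attempted before a
fit is declared non-convergent; the `converged` flag is honest either way.

Two midpoint summaries are reported: the **relative IC50** (the fitted
midpoint `m`, the headline number) and the **absolute IC50** (dose at
which the fitted curve crosses 50% of control), since "reduced by 50%"
phrasing is ambiguous between the two; for a 0–100% curve they coincide.
A midpoint past the largest tested dose is **censored** and labelled
`"> max dose"` — the "ND (>10)" convention for insensitive cell lines —
rather than extrapolated. `hc50()` short-circuits to the censored form
when hemolysis never reaches 50% at any tested dose. A response span
below 20 percentage points is refused as no-signal, and a trend in the
wrong direction (viability rising with dose) yields a warning and an
undefined midpoint.

The selectivity index is the plain ratio `IC50(normal) / IC50(tumor)`;
censored numerators propagate as lower bounds (`"> x"`).

# Cytometry quadrants and the death-mode signature

Events are classified by two fixed thresholds, one per channel; positivity
is strict (`> threshold`), so an event exactly on a gate is negative — a
deterministic tie-break that keeps tests exact. Gates come from
configuration or from `estimateGates()`, the 99.5th percentile of an
unstained-control cloud per channel; no density-based auto-gating is
attempted. The four fractions (AV−PI−, AV+PI−, AV+PI+, AV−PI+) always sum
to 1 by construction; AV−PI+ is kept as its own reported class rather than
merged into the necrotic count. "Dead" in all kinetic and inhibitor
comparisons means `1 − viable`.

The kinetic signature formalizes the qualitative distinction between
membranolytic necrosis and programmed apoptosis:

* **necrosis-like** — the dead fraction is flat in time at every
  concentration (range ≤ `time_tol`, default 10 points) while showing a
  strong concentration effect (range ≥ `conc_min_effect`, default 20
  points, at some time);
* **apoptosis-like** — the dead fraction climbs monotonically with
  incubation time by more than `time_tol` at some concentration;
* otherwise **inconclusive**.

Both tolerances are configurable because the underlying pattern is stated
qualitatively in the literature; the defaults are conservative round
numbers on the percentage scale. Caspase independence is a simple
tolerance test: killing unchanged (within `tol`, default 5 points) by a
pan-caspase inhibitor argues against caspase-dependent apoptosis.

# Pathway activation strength

The transcriptomic pipeline is: floor raw probe intensities at 1.0 (raw
intensity scale, preventing log and ratio blow-ups), **geometrically
average** the probes of each gene, **quantile-normalize** samples
(delegated to `limma::normalizeQuantiles(ties = TRUE)`: every sample's
sorted values become the across-sample mean of sorted values, ties
receiving the mean of their target quantiles), then form per-gene
**case-to-normal ratios** — the case sample's expression over the
*arithmetic* mean of the control group (geometric averaging is reserved
for probe replicates, where it is the stated processing step). Each
treated replicate is scored individually against the pooled controls; a
per-concentration mean profile can be added on top.

The pathway score for pathway $p$ is

$$PAS_p = \frac{\sum_{n} ARR_{np} \cdot \lg(CNR_n)}{N},$$

with $ARR \in \{-1, -0.5, 0, 0.5, 1\}$ the discrete activator/repressor
role of gene $n$ in pathway $p$ and "lg" read as log10 (any base only
rescales the score; log10 is the convention in this literature).
Positive PAS means activation relative to controls, negative repression.
$N$ counts the pathway genes **present in the dataset**, including
ARR = 0 genes (which contribute nothing to the numerator); genes absent
from the data are excluded from numerator and denominator alike, which
avoids spuriously shrinking scores for partially measured pathways. A
pathway with no measured genes is reported missing (`NA`), not zero.
Calls are sign-based only — PAS carries no null model, so no p-values are
attached, and none are implied.

Two exact identities make the engine testable: scaling every CNR by
$c > 0$ shifts PAS by exactly $\log_{10}(c)\sum ARR / N$, and PAS is
additive over disjoint gene subsets weighted by their sizes.

# Synthetic data and what the tests show

The expression generator emulates a peptide-treatment microarray design:
untreated controls plus treatment at 1.25, 2.5 and 5 µM, in triplicate,
with the full-scale default of 2016 genes in 334 pathways and a desk-scale
default of 200 genes / 20 pathways used throughout the test suite. Gene
baselines are log-normal (log2 mean 8, SD 2 — a typical array intensity
spread); measurement noise is Gaussian on the log2 scale (default SD 0.25
per gene-sample, 0.1 per probe-sample, ordinary microarray replicate
noise). Pathways are **disjoint gene blocks** with ARR weights drawn from
the five-value vocabulary; disjointness means a planted perturbation
cannot bleed into another pathway's score, which keeps the planted truth
analytically exact: multiplying each gene of a planted pathway by
$2^{lfc \cdot ARR}$ (activators up, repressors down, half-weight genes
with half the log effect) gives a noise-free PAS of exactly
$lfc \cdot \log_{10}(2) \sum ARR^2 / N$.

The zero-noise planted round trip is asserted on the un-normalized path
(aggregation → CNR → PAS): quantile normalization forces treated and
control columns onto a common distribution, so with a planted shift the
unperturbed genes near the perturbed ranks pick up tiny nonzero CNRs and
"all other pathways exactly zero" cannot hold through it. The full
pipeline *including* normalization is exercised instead by the end-to-end
recovery experiment: 50 seeded replicates of the desk-scale design with
one 2-fold up- and one 2-fold down-planted pathway, requiring ≥ 95%
correct signs and ≥ 95% separation of perturbed from unperturbed score
magnitudes.

The other generators follow the same planted-truth pattern: dose-response
data from a 4PL mean plus Gaussian noise (IC50 recovery is checked on 100
simulated datasets with midpoints spanning 0.5–50 µM and 5-point noise);
cytometry events as a four-component mixture of bivariate log-normal
clouds (default centres 10^1.5^/10^3^ AU, SD 0.15 log10 units — well
separated relative to gates at ~178 AU); plates back-computed from planted
percentages through the assay's own formula. Every generator is driven by
a single integer seed through an isolated RNG stream
(`withr::with_seed`), so identical calls are byte-identical and the
caller's RNG state is untouched.

What passing these tests does **not** show: the generators have no
spatial or GC-bias artifacts, no biological co-expression beyond the
pathway blocks, no plate-edge effects, no spectral spillover between
cytometry channels, and the cloud separation is idealized. Recovery under
these conditions demonstrates correctness of the estimators, not
robustness to every real-data pathology. Real wet-lab quantities (the
measured IC50 table, the ~100 µM half-hemolysis concentration, observed
quadrant percentages) enter only as planted truths in recovery tests —
they are facts about cells, not computable from sequence.

# Known limitations

* FCS, CEL and GEO series parsing are out of scope; tabular TSV exports
  are the interchange format (single dialect, `#` comments, byte-stable
  writers at 6 significant digits).
* Profile-likelihood confidence intervals for IC50, outlier-well
  rejection and plate-edge corrections are not implemented.
* PAS calls are sign-based; with no null model, small |PAS| values should
  be interpreted with the score magnitudes, not as significance.
* Gene identifiers are opaque case-sensitive strings; no symbol
  normalization is performed, by design.

# Session info

```{r}
sessionInfo()
```
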