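---
title: "Composition-level N-glycomics: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-level N-glycomics: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoprofiler)
```

# The problem

MALDI FT-ICR mass spectrometry of enzymatically released N-glycans yields,
per biological sample, a list of peaks: m/z, intensity and ionization mode.
This package turns such peak lists into biology in four stages:

1. **Composition assignment** — which monosaccharide composition and which
   ion species (adduct) explain an observed m/z;
2. **Quantification** — internal-standard-corrected relative abundances;
3. **Group comparison** — presence/absence and significance classification
   across a three-arm cohort (control strain, disease-model strain, treated
   model), producing the headline "modulated by treatment" counts;
4. **Behavior correlation** — a Pearson screen of glycan abundance against
   per-animal memory measures.

A composition here is a count vector over Hex, HexNAc, Fuc (generic
deoxyhexose), Neu5Ac, Neu5Gc and sulfate; linkage and branching are out of
scope — MS alone cannot resolve them, and the packaged tables are
composition-level.

# The mass model

The neutral monoisotopic mass is the residue-mass sum plus one water,

$$M = \sum_i n_i \, m_i + m_{\mathrm{H_2O}},$$

with residue masses derived from IUPAC atomic masses (free monosaccharide
minus water; sulfate as SO~3~). Ion m/z for an adduct that removes $s$
hydrogens and adds $r$ protons, $p$ Na^+^ and $q$ K^+^ is

$$m/z = \frac{M + p\,m_{\mathrm{Na^+}} + q\,m_{\mathrm{K^+}} + (r-s)\,m_{\mathrm{H^+}}}{|z|},
\qquad z = r + p + q - s.$$

The electron mass is ignored and hydrogen transfers use the proton mass
(1.00728 Da): the resulting error is below 0.6 ppm at m/z 1000, an order of
magnitude under the 10 ppm working tolerance. Mass error is expressed as
signed ppm of the theoretical value.

```{r}
man5 <- glycan_composition(Hex = 5, HexNAc = 2)
ion_mz(man5, "[M+Na]+")
```

This sodiated value is the one printed observed mass in the source tables
that agrees with theory to the printed precision; most printed masses carry
rounding or transcription offsets of 0.05–1.6 Da (and one is a whole hexose
off), which is why the packaged tables are treated as *data* and audited by
`mass_reconciliation()` rather than used as oracles for the mass model.

# Composition search

`enumerate_candidates()` performs an exhaustive search of the bounded
residue lattice (defaults Hex ≤ 15, HexNAc ≤ 10, Fuc ≤ 4, Neu5Ac ≤ 4,
Neu5Gc ≤ 4, S ≤ 2 — under 10^6^ points, so exhaustive enumeration is exact
and cheap) against every candidate adduct of the peak's ionization mode.
Candidates within tolerance are ordered by |ppm error|, ties broken by
fewer total residues then by the canonical composition string; the ordering
is deterministic and no heuristic changes the result set.
`assign_peaklist()` retains, per peak, the first candidate that passes the
plausibility filter, and reports unassigned peaks rather than dropping
them.

Two numerical facts shaped the defaults:

* **Exact isobars.** Hex + Neu5Ac and Fuc + Neu5Gc have the same elemental
  sum, hence exactly the same mass. Mass accuracy alone can never separate
  compositions related by this swap; the published workflow resolved
  composition identity by tandem MS, which is out of scope here. The
  default plausibility rules (below) remove the swap partner in the cases
  that matter for these tissues.
* **Charge-2 coincidences.** The composition lattice at twice the mass is
  dense on the ppm scale, so if doubly-charged adducts compete for every
  singly-charged peak, near-coincidences within 1–2 ppm are common and
  top-rank assignment degrades badly. On FT-ICR instruments charge state is
  read off the isotope spacing upstream of this package (isotope handling
  is an explicit non-goal), so the default candidate sets contain only the
  singly-charged species (`[M+Na]+`, `[M+K]+`, `[M+H]+`; `[M-H]-`,
  `[M-2H+Na]-`, `[M-3H+2Na]-`). The doubly-charged forms are a one-line
  opt-in for charge-deconvolved data.

An absolute tolerance override (`tol_da`) exists alongside the ppm window
solely because printed two-decimal masses cannot be matched at 10 ppm
fidelity; the scientific default stays at 10 ppm.

## The plausibility filter

The original biological filter is not published; the default rule-set is a
minimal Cooper-style stand-in, chosen so that **all 99 published
compositions pass** and implausible mass-match artifacts fail:

* fucose, sialic acids and sulfate require at least one HexNAc;
* sialic acids ≤ HexNAc + 1 (the antenna bound);
* fucoses ≤ HexNAc (attachment sites);
* at least one hexose;
* Neu5Ac and Neu5Gc do not co-occur (mixed sialylation is not observed in
  these tables, and this rule is what resolves the exact isobar above).

The rule engine is pluggable (`rules = "none"` disables it), so stricter or
laxer rule-sets can be swapped in without touching the search.

# Quantification conventions

Samples are doped with a fixed amount of β-cyclodextrin, located as the
most intense peak within ±0.5 Da of the published reference m/z (1157.25
positive, 1133.25 negative — the printed values, not the theoretical
cyclodextrin mass, which differs by ~0.1 Da). Corrected intensity is
**100 × raw / standard**: the standard maps to 100 and glycan abundances
land in the ~1–150 range of the published tables (the paper states the
scaling but not the constant). A missing standard is an error — the sample
must be excluded with a reason, never silently zeroed.

Group cells are mean and sample SD (n−1) over all replicates **including
zeros** for absent species, and a species is detectable in a group iff any
replicate is positive. This zeros-included convention is not arbitrary: a
single-nonzero triple {22.95, 0, 0} gives 7.65 ± 13.25, numerically
matching the published "7.65 ± 13.24"-style cells.

Dixon's Q-test (two-sided r10 statistic, tabulated critical values for
n = 3–10 at α = 0.05/0.01) screens replicate vectors for a single outlier.
Because the source does not state what was done with detected outliers, the
default policy is report-only; exclusion is an explicit option in the CLI.

# Group comparison

Significance uses the pooled-variance Student's t, computable from raw
replicates or directly from printed mean/SD/n cells (the two entry points
agree to machine precision), and one-way ANOVA for multi-group scans. Both
tails are always reported: at n = 3, several printed markers are
reproducible only one-tailed (e.g. the treated-vs-model marker on the
strongest cortex species: two-tailed p = 0.089, one-tailed p = 0.044), and
rather than guessing the original tail convention the reproduction report
lists such markers explicitly (`marker_reconciliation()`). Paper
reproduction therefore runs in *marker mode* — transcribed markers, exactly
as printed — while *recomputed mode* at α = 0.05 is the default for new
data. No multiple-testing correction is applied by default, mirroring the
source analysis; Benjamini–Hochberg is available opt-in.

Modulation classification is multi-label on detectability:
control-only (present in control, absent in model), model-only,
treatment-induced (absent in model, present in treated — which includes
species absent everywhere except the treated arm), treatment-suppressed
(present in model, absent in treated), plus the two significance
categories. "Modulated by treatment" is the union of induced, suppressed
and significantly-changed. On the packaged cortex table this yields
9 / 5 / 15 / 5 and 21 modulated, matching the published narrative exactly;
on the serum table the detectability rules yield 7 modulated where the
narrative counts 6 — one species is detectable in the model group and
undetectable after treatment yet missing from the published inhibited
list. The package reports both numbers and flags the row
(`fixture_flags()`) instead of forcing agreement.

# Behavior correlation

The discrimination index is the novel-object share of total exploration
time in percent; the same formula serves the 1 h and 24 h retention tests.
Pearson r carries a two-tailed p from the t transform on n − 2 df and a
95% interval via Fisher's z, $\tanh(\operatorname{atanh} r \pm
1.96/\sqrt{n-3})$. Correlations are computed across **all animals pooled**
(the published correlation figures state n = 8–9, which exceeds any single
arm's n = 3, so pooling is the only reading that reproduces the stated n;
the 3 × 3 design versus n = 8–9 discrepancy in the source is noted, not
resolved). The screen logs its test count and applies no multiplicity
correction, again mirroring the source.

# The synthetic cohort generator

`generate_cohort()` emulates the data this analysis assumes: per sample, an
internal-standard peak per mode plus one peak per species present in the
sample's arm, with

* multiplicative log-normal intensity noise, σ~log~ = 0.4 by default — MS
  intensities are positive and heteroskedastic, and the published SD
  magnitudes scale roughly with the means;
* Gaussian m/z jitter, 2 ppm by default, the calibrated accuracy class of
  the source instrument, well inside the 10 ppm search window;
* group sizes 3/3/3 by default, the published design;
* behavioral marginals Gaussian truncated at zero (counts rounded), with
  per-arm means shaped like the published deficit-and-rescue pattern;
* optionally, per-replicate Bernoulli dropout to emulate
  single-nonzero-replicate cells (off by default — the source gives no
  dropout model).

One (species, measure, r) correlation is planted through a shared latent
normal. Because the abundance is log-normal in that latent, the naive
construction attenuates the Pearson correlation by
$\sigma/\sqrt{e^{\sigma^2}-1}$ (≈ 0.96 at σ = 0.4); the generator inflates
the latent correlation by the inverse factor so the planted r **is** the
Pearson correlation of the emitted pair. Configurations where the required
latent correlation would exceed 1 are rejected.

`paper_shaped_config()` reproduces the *pattern census* of the cortex
table — 9 control-only, 5 model-only, 15 induced, 5 suppressed, 1 marked
fold-change species (treated baseline ≈ 2× model, mirroring the reported
treatment effect) and 8 ubiquitous species, 43 in all — using the distinct
(composition, adduct) pairs of the packaged table, with the one duplicated
pair replaced by its mass-consistent (Hex)9(HexNAc)2 reading. The census
counts are structural (detectability by construction, the significance
category from the ground-truth marker), so the end-to-end counts are
independent of the seed, exactly as the fixture path's are.

## What the generator does and does not emulate

It emulates peak-list-level structure: detectability patterns, abundance
scale, internal-standard scaling, ppm-scale mass error, and a
glycan–behavior association. It does **not** emulate isotope envelopes,
profile-mode spectra, baseline drift, ionization-efficiency differences
between glycan classes, inter-batch effects, or heavy-tailed contamination.
Passing tests on synthetic cohorts therefore validate the statistical
machinery and the assignment logic under the stated noise model — they do
not certify performance on raw instrument data, which arrives here only
after peak picking and calibration.

## Quantification route for synthetic cohorts

Synthetic validation uses two routes deliberately. De novo assignment
(`method = "denovo"`) is exercised on the default six-species panel, which
is free of exact isobars: top-rank recovery there is the mass model's
acceptance property (100% measured at 2 ppm jitter). Cohorts shaped like
the published panel are quantified by targeted matching
(`method = "targeted"`) against the discovered species list — mirroring the
published discovery-then-quantify workflow, where composition identity was
fixed once (with MS/MS confirmation) and then quantified per sample. Using
de novo assignment on that panel would stochastically mis-key the species
related by the exact isobar, which no mass-only method can avoid.

# Numerical choices and degenerate inputs

* Candidate ordering ties: fewer residues, then canonical string — the
  source never reports ties, so the break is a package convention chosen
  for reproducibility.
* Zero-range replicate vectors: Dixon returns a no-test result, not 0/0.
* All-identical groups: ANOVA returns a no-test result; the pooled t errors
  when both SDs are zero (stated precondition).
* |r| = 1: p = 0 and the Fisher interval degenerates to r; n = 3 yields a
  defined p but an undefined interval (NA), matching the z-transform's
  domain.
* Empty peak lists, missing columns, missing internal standards and
  unknown rule-set/group/species identifiers all raise typed, descriptive
  errors; empty input files parse to empty structures with a warning.

# Problem sizes used in the test suite

The suite validates properties at sizes chosen to make the statistics
informative while keeping the default run fast: 100 random instances for
the search-vs-brute-force equivalence (small bounds), 75-sample cohorts
(≈ 300 peaks) for top-rank recovery, 270-sample cohorts (> 1000 peaks) for
jitter calibration, and 200 seeded calibration cohorts of 30 animals per
planted r ∈ {0, 0.5, 0.9} for CI coverage and type-I calibration. The
coverage/type-I bands (95 ± 4%, 5 ± 3%) are read as inclusive and checked
on cohort counts to avoid floating-point edge effects.

# Known limitations

* Composition-level only: no linkage, branching or isomer resolution.
* Mass-only identification cannot separate exact elemental isobars; the
  plausibility rules resolve the observed cases but not the general
  problem.
* Dixon critical values are tabulated for n ≤ 10; larger replicate groups
  need a different outlier policy.
* The serum modulated-count discrepancy (7 by rule vs 6 by narrative) is
  reported, not adjudicated.
* Printed observed masses in the packaged tables are carried as-is,
  including a row whose printed mass contradicts its printed composition
  by one hexose; `fixture_flags()` is the authoritative list.
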