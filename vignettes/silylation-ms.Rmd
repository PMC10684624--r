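---
title: "Interpreting silylation series: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting silylation series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silylms)
```

## The problem

Polar natural products such as flavonoids are poor GC analytes until
their hydroxyls are silylated. Each derivatized site replaces one acidic
proton with a silyl group, shifting the elemental composition by a fixed
per-site delta: +C6H14Si for TBDMS (nominal +114 Da) and +C3H8Si for TMS
(nominal +72 Da). A compound with *s* silylatable sites therefore
produces a ladder of species at masses $M + n\Delta$, $n = 0..s$. This
package turns that ladder into three analysis tools:

1. **Prediction** — where the derivatization series and its EI fragments
   should appear, at unit or accurate resolution;
2. **Formula narrowing** — which candidate elemental compositions for an
   unknown are consistent with the whole series, not just one mass;
3. **Efficiency quantification** — how complete a derivatization
   reaction was, from the relative intensity of the underivatized
   residue.

## Mass and ion conventions

All masses derive from a fixed table of most-abundant-isotope masses
(C exactly 12, H 1.00782503, O 15.99491462, Si 27.97692653, ...).
Hard-coding the table, rather than deriving it from isotope-abundance
data, keeps every number in the package reproducible from the source
alone. Only monoisotopic and nominal (integer) masses are supported;
isotope patterns and average masses are out of scope because the
workflows this package serves use centroided monoisotopic peaks.

Ion m/z follows

$$ m/z \;=\; \frac{k\,M + \mathrm{mass}(\Delta_{\mathrm{adduct}}) - q\,m_e}{|q|} $$

with multimer count $k$, signed unit charge $q$ and the electron mass
$m_e = 0.00054858$ Da. The electron correction defaults **on** because it
is physically correct; it can be disabled for comparison with software
that omits it. Only singly charged species are modeled — multiply
charged ions are rare for the small molecules in scope. Published
"expected" values in this field often mix electron conventions and
vendor calibration corrections (lock-mass adjustment, centroiding
shifts), so externally printed m/z are compared at ±2 mDa rather than
to the fifth decimal, and reported mass errors from vendor software
should not be expected to reproduce exactly from raw
observed-minus-theoretical arithmetic. `mass_error()` always reports the
raw signed difference in mDa and ppm.

## Formula enumeration

`enumerate_formulas()` searches element count boxes exhaustively:
elements are ordered by decreasing mass and a recursive descent prunes
each branch by the residual-mass interval that the remaining elements
can still cover. This is exact (it provably visits every composition in
the box whose mass lies in the window) and fast at small-molecule scale,
and its simplicity lets the test suite compare it 1:1 against a naive
grid oracle. Key parameters:

- `tolerance_mda` (mDa, default 5): half-width of the match window.
  When reproducing vendor-style searches that kept candidates several
  mDa off, 10 mDa is a realistic setting; the default reflects a
  well-calibrated Q-TOF.
- `bounds` (default C 0–60, H 0–100, O 0–20, Si 0–6, N 0–5): generous
  cover for silylated natural products.
- `rdbe_range` / `require_integer_rdbe`: ring-plus-double-bond
  filtering with Si treated tetravalent,
  $\mathrm{RDBE} = 1 + C + Si - \tfrac{H+F+Cl}{2} + \tfrac{N+P}{2}$.
  **Off by default**: vendor candidate lists routinely contain
  chemically implausible rows, and the cross-check is expected to work
  on such lists as given rather than silently pre-filtering them.
- `max_candidates` (default 10000): exceeding the cap is an explicit
  error, never a silent truncation, so a too-loose tolerance cannot
  masquerade as a complete result.

## The series cross-check

`crosscheck()` is the package's inference core. Its survival rule for a
degree-0 candidate $F$:

- **(a) pairing** — for every observed ion hypothesized at degree
  $n>0$, $F + n\Delta$ must be present in that ion's candidate set.
  Matching is exact element-wise arithmetic, not a mass window: that is
  what makes the narrowing deterministic and auditable.
- **(b) silicon count** — if the parent is assumed Si-free (the default
  for natural products), $F$ must contain no Si and the degree-$n$
  partner exactly $n$ Si.
- **(c) site floors** — a compound seen derivatized $n$ times has at
  least $n$ silylatable sites; for hydroxyl-targeting reagents that
  means at least $n$ O atoms, and its neutral form needs at least $n$
  H (the replaced acidic protons). The floor defaults to the maximum
  observed degree and can be overridden via `min_sites`.

Constraints are checked in the order (a), (b), (c) and each eliminated
candidate records the first rule it failed, so the elimination report
explains *why* every candidate dropped out. Candidate sets may be
ion-form (the usual vendor output; the default) or neutral-form; with
ion-form candidates the H floor is applied after removing the adduct
proton. If several candidates survive, all are reported ranked by the
summed |mass error| along their chains — the tool never auto-picks one.
`candidates_from_table()` ingests externally printed candidate lists
verbatim, without m/z re-verification, because published tables are
inputs to be analyzed, not claims to be silently corrected.

## EI fragments

`predict_ei_fragments()` emits the molecular radical cation and one
fragment per characteristic α-cleavage loss. The methyl loss (−15
nominal) is treated as *generic* — small methyl losses are observed for
underivatized oxygenated species as well — while the t-butyl loss (−57)
requires at least one installed TBDMS group. A loss that is not
subtractable from the composition is omitted with a warning rather than
an error, since a partially applicable prediction set is still useful.
TMS carries a reporter ion at m/z 73.05 (Si(CH₃)₃⁺); TBDMS itself has
no reporter entry, but the EI simulator injects a trimethylsilyl
column-bleed peak at nominal 73 by default because that peak is
near-ubiquitous in silylation GC–MS and annotation code should be
robust to it.

## Efficiency statistics

`derivatization_ratio()` matches predicted quasi-molecular ions at
degrees $0..n_{max}$ against a (typically scan-averaged) peak list and
reports
$$ r = \frac{\text{summed intensity, degree } 0}{\text{summed intensity, degrees } \ge 1}. $$
Peak intensities of centroided lists stand in for integrated areas; the
statistic is invariant to uniform intensity scaling, so the proxy does
not bias the comparison between two runs of the same analyte. Two
degenerate outcomes are flagged explicitly instead of being divided
through: `complete-derivatization` (no underivatized signal, $r = 0$)
and `no-derivatized-signal` ($r$ undefined). `efficiency_factor()`
compares two runs as $r_{\mathrm{batch}} / r_{\mathrm{flow}}$, reported
raw and at 2 significant figures — the precision at which such
comparisons are honestly quotable.

Scan averaging (`average_spectra()`) merges pooled peaks within a
single-linkage window (default 5 mDa), reporting the intensity-weighted
mean m/z and the per-scan mean intensity (a peak absent from a scan
contributes zero). Single-linkage can chain peaks in pathological
inputs; for centroided HR-MS data with peaks separated by much more
than the window this is immaterial, and the simple rule is exactly
testable.

Nearest-peak annotation uses ±5 mDa for accurate-mass data and ±0.5 Da
for unit-resolution EI by default; if two peaks tie exactly, the more
intense one wins (deterministic and stated, rather than an arbitrary
index order).

## The synthetic-data generator

Raw spectra for silylation studies are rarely deposited, so
`simulate_esi()`/`simulate_ei()` generate peak lists with the
statistical structure the analysis assumes, with ground truth attached.
The ESI model: one peak per (degree, adduct) pair with positive weight;
m/z = theoretical + Gaussian calibration error
(`calibration_sigma_mda`, default 1 mDa — ~1–2 ppm at 500–900 m/z, a
realistic Q-TOF figure); intensity = base × weight × mean-one lognormal
noise (`intensity_cv`, default 0.10); plus uniform background peaks.
Gaussian m/z error and lognormal intensity noise are the simplest
standard models for calibration scatter and multiplicative detector
noise; they are explicit, documented assumptions, not fits to data.

The default `simulation_spec()` emulates a flow-derivatization HR-MS
experiment on quercetin: five sites, residual underivatized signal at
weight 0.366 against a dominant 4×-derivatized species at weight 1
(true ratio 0.366), deprotonated ions, and 25 scans — the scan count a
practitioner would average for a semi-quantitative intensity readout.

What the generator does **not** emulate: isotope envelopes, in-source
fragmentation, detector saturation, chromatographic peak shape, and
correlated (drifting) calibration error. Passing recovery tests on this
generator therefore demonstrate that the *inference pipeline* is
self-consistent — noiseless spectra return their generative ratio
exactly, and enumeration + cross-check at 5 mDa retains the true parent
for randomized parents with up to six sites — not that any real
instrument meets the noise model.

## Problem sizes and tests

The shipped tests run the enumeration oracle on grid boxes up to a few
tens of thousands of compositions, Monte-Carlo ratio recovery on 200
single-scan replicates at 2 mDa calibration error, and end-to-end
parent recovery on randomized 2–6-site parents; these sizes were chosen
so the full suite documents the package's statistical behaviour while
remaining quick enough to run on every change. All simulations are
seeded and fully reproducible.

## Known limitations

- No isotope-pattern scoring: candidates that an isotope envelope would
  separate are not distinguished.
- Only |q| = 1 adducts; no in-source fragments in ESI mode.
- The cross-check reasons over formulas only; it cannot distinguish
  isomers or say *which* hydroxyl silylates.
- Printed candidate tables are trusted as given; inconsistencies between
  a table's header m/z and the text it accompanies are surfaced to the
  user (both values are accepted as targets), never reconciled silently.
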