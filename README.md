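# silylms

Interpretation tools for mass spectra of silylated small molecules —
flavonoids and other polyphenols derivatized with TBDMS
(tert-butyldimethylsilyl, installed by MTBSTFA) or TMS (trimethylsilyl)
groups ahead of GC or ESI analysis.

Silylation replaces the acidic proton of each hydroxyl with a silyl
group, so every derivatized site shifts the composition by a fixed
delta (TBDMS: +C6H14Si, nominal +114; TMS: +C3H8Si, nominal +72). That
regular ladder is analytically precious: it confirms that derivatization
happened, counts the silylatable sites, and — because each candidate
elemental composition must pair up consistently across derivatization
degrees — can narrow the molecular formula of an unknown far beyond what
one accurate mass allows. `silylms` packages that calculus for people
doing natural-product structure work with GC–MS (EI) and HR-MS (ESI):

- **Formula arithmetic** — Hill-notation parsing/formatting,
  monoisotopic and nominal masses, element-wise combination.
- **Adduct calculus** — m/z under `[M+H]+`, `[M-H]-`, `[M+Na]+`,
  `[2M+Na]+` and the EI radical cation `[M]+.`, with electron-mass
  correction: `m/z = (k·M + Δ − q·mₑ)/|q|`; mass errors in mDa and ppm.
- **Formula enumeration** — every composition within element bounds
  whose ion m/z falls inside a tolerance window of an observed peak
  (exhaustive recursive descent with residual-mass pruning; optional
  RDBE filter).
- **Derivatization model** — reagents as data (per-site delta,
  characteristic EI losses −CH3/−C4H9, reporter ions), predicted m/z
  series over degrees, and the site-count constraint an observed maximum
  degree implies (n degrees ⇒ ≥ n hydroxyls ⇒ ≥ n O atoms).
- **Series cross-check** — the narrowing engine: a degree-0 candidate
  survives only if its partner `F + n·Δ` exists in every degree-n
  candidate set, with silicon-count and O/H-floor rules.
- **Spectrum tools** — CSV/MSP peak-list I/O, scan averaging, peak ↔
  prediction annotation, EI neutral-loss prediction, and
  underivatized:derivatized intensity ratios as a semi-quantitative
  derivatization-efficiency statistic.
- **Synthetic spectra** — seeded ESI and EI spectrum generators with
  known ground truth, so the whole pipeline is testable without
  instrument data.

## Worked example

Quercetin (C15H10O7, five phenolic hydroxyls) derivatized with TBDMS:

```r
library(silylms)

predict_series("C15H10O7", "TBDMS", 2:5, adduct = "[M]+.",
               resolution = "nominal")
#>   degree     formula  mz
#> 1      2 C27H38O7Si2 530
#> 2      3 C33H52O7Si3 644
#> 3      4 C39H66O7Si4 758
#> 4      5 C45H80O7Si5 872

monoisotopic_mass("C45H80O7Si5")
#> [1] 872.475

predict_ei_fragments("C45H80O7Si5", "TBDMS")
#>        label     formula  mz
#> 1      [M]+. C45H80O7Si5 872
#> 2   [M-CH3]+ C44H77O7Si5 857
#> 3 [M-C4H9]+  C41H71O7Si5 815
```

The EI spectrum of the fully derivatized species shows the molecular
radical cation at 872 with α-cleavage losses of a methyl (−15) and a
t-butyl (−57) radical.

Narrowing an unknown's formula from its derivatization series: given
five vendor-assigned candidate compositions each for the underivatized
`[M+H]+` ion and its once- and four-times-silylated partners,

```r
ions <- candidates_from_table(list(
  list(degree = 0, mz = 379.1179,
       formulas = c("C22H19O6", "C29H15O", "C11H23O14", "C15H23O11", "C18H19O9")),
  list(degree = 1, mz = 493.2097,
       formulas = c("C28H33O6Si", "C35H29OSi", "C17H37O14Si", "C21H37O11Si", "C32H33O3Si")),
  list(degree = 4, mz = 835.4821,
       formulas = c("C50H75O3Si4", "C43H79O8Si4", "C36H83O13Si4", "C39H79O11Si4", "C54H75Si4"))
))
crosscheck(ions, "TBDMS")
#> <crosscheck_result> 1 surviving parent formula(s) [ion form, reagent TBDMS]
#>   C15H23O11  (chain: 0x -> C15H23O11; 1x -> C21H37O11Si; 4x -> C39H79O11Si4)
#> eliminated:
#>   C22H19O6  [missing-pair at degree 4]
#>   C29H15O  [missing-pair at degree 4]
#>   C11H23O14  [missing-pair at degree 4]
#>   C18H19O9  [missing-pair at degree 1]
```

Only C15H23O11 (the `[M+H]+` ion of neutral C15H22O11) pairs correctly
at every degree — the degree-1 pairing alone leaves four candidates; the
degree-4 pairing plus the Si-count and O ≥ 4 rules leave one.

Derivatization efficiency, as the underivatized:derivatized intensity
ratio and the batch-vs-flow comparison:

```r
efficiency_factor(9.08, 0.366)
#> <efficiency_factor> 24.8087 raw (25 at 2 s.f.)
```

A batch run at 9.08:1 against a flow run at 0.366:1 makes the flow
reaction 25× more complete (2 significant figures).

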