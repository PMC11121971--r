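# oligodeg

Structure-based screening of oligoester marine biodegradability.

`oligodeg` is an R package for the molecular end of polyester eco-design:
instead of weathering plastic debris, it works with short, enzymatically
synthesizable oligomers — tetramer model structures of copolymers and
terpolymers built from industrial monomers (adipic acid, terephthalic acid,
2,5-furandicarboxylic acid, 1,4-butanediol, glycerol, erythritol, and an
oligoamide reference built on 2,5-bis(aminomethyl)furan) — and asks which
structural features make them biodegradable in seawater. It is aimed at
polymer chemists and environmental scientists running closed-bottle
(OECD-306-style) respirometry screens alongside QSPR-style modelling.

## What it computes

* **Tetramer model structures.** `build_oligomer()` condenses an
  alternating diacid/diol (or diamine) sequence into a canonical SMILES,
  eliminating one water per ester/amide bond, with lipase-like
  regiochemistry for polyols (primary hydroxyls esterified, secondary free)
  and configurable chain ends. `enumerate_tetramers()` generates all
  distinct tetramers over a monomer pool.

* **Molecular interaction field (MIF) descriptors.** From a seeded 3D
  conformer (RDKit distance geometry + MMFF94, via a bundled Python
  helper), grid fields for four probes (DRY, OH2, O, N1) yield the 18
  descriptors used for modelling: integy moments `IW1–IW4`, capacity
  factors `CW1–CW8` (hydrophilic volume over total surface), `logP`, polar
  and hydrophobic surface areas `PSA`/`HSA`, the acidity rule value
  `MpKaA`, and the polar/apolar attraction-energy difference and distance
  `EMDIF`/`EMDIS`.

* **Chemometrics.** Descriptor pretreatment, PCA (SVD), seeded K-means,
  and NIPALS PLS1 with leave-one-out cross-validation:
  `Q² = 1 − PRESS/TSS`, reported as computed (it may be negative).

* **Respirometry arithmetic.** Theoretical oxygen demand from elemental
  composition, blank correction, and degradation-degree time courses
  `Dt(t) = 100 · BOD(t) / (ThOD · c)` at the standard 100 mg/L test
  concentration.

* **ESI-MS oligomer arithmetic.** `Mn = ΣNᵢMᵢ/ΣNᵢ`,
  `Mw = ΣNᵢMᵢ²/ΣNᵢMᵢ`, dispersity `Đ = Mw/Mn`, plus Na⁺ adduct-series
  prediction and peak assignment for condensation mixtures.

* **Synthetic data.** Seeded generators for descriptor/response datasets
  with planted coefficients, first-order BOD uptake curves with blanks,
  and Flory chain-length peak lists with closed-form truth.

## Worked example

```r
library(oligodeg)

# a tetramer model structure and its condensation mass balance
build_oligomer(c("AA", "BDO", "AA", "BDO"))
#> <built_structure> AA-BDO-AA-BDO
#>   OCCCCOC(=O)CCCCC(=O)OCCCCOC(=O)CCCCC(=O)O
#>   C20H34O9  avg 418.48 g/mol, mono 418.2203 Da, 3 bonds

# degradation degree of a poly(butylene furanoate) respirometry series
degradation_degree(
  bod_series("BDO-FDCA", times = c(5, 10, 21), bod = c(9.45, 21.20, 34.10)),
  thod_value(2.24))
#> <biodegradation_result> BDO-FDCA: Dt5 4.22%, Dt10 9.46%, Dt21 15.22%

# mass summary of a sodiated oligomer spectrum
mass_summary(peak_list(c(475.4, 685.6, 895.8), c(100, 62, 20)))
#> <mass_summary> Mn 570.21, Mw 606.33, D 1.0633

# the full screening pipeline on the packaged reference tables
run_paper_reproduction(verbose = FALSE)
#> <run_report>
#>   structures: 11/12 canonical matches to the recorded SMILES
#>   PCA explained %: 69.1, 20.7, 3.6
#>   K-means (k=3) cluster sizes: 6/3/3
#>   PLS (n=11, 5 LV): R2 = 0.846, Q2 = -1.257
#>   PLS all-12 variant: R2 = 0.895, Q2 = -0.359
#>   table arithmetic: known_discrepancy=20, match=63, not_derivable=6
```

Reading the report: 11 of the 12 recorded tetramer SMILES are reproduced
canonically by the builder (the oligoamide row records a different end
group and is the documented exception). The degradation-degree and
dispersity arithmetic of the reference tables reproduces for every
internally consistent cell (63 matches; the 20 flagged cells are curated
inconsistencies of the source tables themselves, and the oligoamide table
prints no ThOD, hence 6 non-derivable cells). The PLS block regresses the
21-day degradation degree of the 11 ester tetramers on the in-house
18-descriptor matrix at 5 latent variables; with this engine's descriptor
values the fit is descriptive (R² 0.85) but not predictive under
leave-one-out (Q² < 0) — eleven molecules give cross-validation no room,
and the report states that rather than smoothing over it.

A thin command-line front end covering the same stages ships in
`inst/cli/oligodeg.R`
(`reproduce`, `descriptors`, `biodeg`, `msfit`, `simulate`).

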