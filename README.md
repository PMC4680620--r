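# accinfo

Quantifying the positional information a morphogen gradient carries — and
the part of it a noisy gene-regulatory readout can actually use.

## The problem

In gradient-mediated patterning, cells infer their position along an axis
from the local concentration of a morphogen. The standard measure of how
well this can work is the mutual information between position and
concentration ("positional information"). But that *raw* information is
read by promoters that are themselves noisy: every regulatory "access"
operation corrupts the signal with input noise of magnitude η₀. `accinfo`
distinguishes raw information from **accessible information** — the
information surviving one more noisy access — and shows why multi-tiered
patterning cascades (as in the *Drosophila* anterior–posterior segmentation
network: gap genes such as *hunchback* and *Krüppel* regulating pair-rule
genes such as *even-skipped*) make sense even though every extra tier loses
raw information.

It is aimed at quantitative/systems biologists who want to (i) reason about
direct vs. two-tier readout strategies with closed forms, (ii) estimate
mutual information for Gaussian-noise expression profiles numerically, and
(iii) run a neighbor-noise / idealized-profile analysis on per-nucleus
expression tables (real or synthetic).

## The model in brief

A noisy linear gradient ĉ = (x/L)·c_max + σ̂ is interpreted with three
toolkit operations — *access* (add Gaussian input noise η₀), *amplify*
(linear gain λ, or a dynamic-range-preserving zigzag fold), *average*
(divide fluctuation variance by N_eff). For a linear profile,
I(φ) = ln(φ/√(2πe)) with φ the dynamic-range-to-noise ratio, and

- raw, direct: I(c_max·√N_eff / σ₀)
- raw, two-tier: I(c_max·√N_eff / √(σ₀² + η₀²)) — the gain λ cancels
- accessible, direct: I(c_max / √(σ₀²/N_eff + η₀²))
- accessible, two-tier: I(c_max / √((σ₀² + η₀²)/N_eff + η₀²/λ²))

so an extra noisy tier is beneficial iff η₀²(1 − 1/N_eff − 1/λ²) > 0:
only with both averaging and amplification, and only because readout is
noisy. A zigzag fold costs exactly ln λ nats on its own but nothing jointly
with the gradient that disambiguates it.

## Worked example

```r
library(accinfo)

## when does a noisy amplifying tier help?
benefitCondition(eta0 = 1, nEff = 4, gain = 2)
#> $beneficial
#> [1] TRUE
#> $margin
#> [1] 0.5

accInfoDirect(1, sigma0 = 0.05, eta0 = 0.05, nEff = 16)
#> InfoResult [closed_form]: 1.5465 nats (2.2311 bits)
accInfoTwoTier(1, sigma0 = 0.05, eta0 = 0.05, nEff = 16, gain = 4)
#> InfoResult [closed_form]: 2.4138 nats (3.4824 bits)
```

The margin 0.5 (= η₀²(1 − 1/4 − 1/4)) is positive, and indeed the two-tier
readout delivers 3.48 bits of accessible information where the direct one
delivers 2.23: amplification dilutes the second access noise even though it
cannot add raw information.

The empirical pipeline runs end-to-end on synthetic embryos emulating the
Hb/Kr/Eve geometry (per-nucleus tables, 100 AP rows × 12 DV columns,
8 replicates):

```r
rep <- runPipeline(EmbryoSpec(), seed = 1)
round(rep$perGeneBits, 3)
#>    hb    kr   eve
#> 1.543 1.546 1.322
round(rep$crossingEta0, 4)
#> [1] 0.0457
```

Within the 0.37–0.47 region of interest the steeper-but-noisier Eve-like
channel carries the *least* positional information on its own (1.32 bits vs
1.54/1.55) — yet the triplet's accessible information stays above the
best-case bound of a hypothetically *noiseless* Hb/Kr pair once the readout
noise exceeds η₀* ≈ 0.046 (in units of the normalized expression maximum):
the extra noisy tier enlarges what the system can actually use.

Nucleus tables are `SummarizedExperiment`s (genes × nuclei with `x_ap` and
`dv_index` in `colData`) and round-trip through TSV
(`writeNucleusTable()` / `readNucleusTable()`); model and embryo
specifications load from YAML; reports serialize to JSON with explicit
`"Inf"` sentinels.

See the vignette (`vignettes/accessible-information.Rmd`) for the model,
the estimators (`miNumeric()`, `infoSmallNoise()`) and the numerical design
choices, including how closely the small-noise closed forms should be
expected to agree with the exact Monte-Carlo mutual information.

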