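# distractr

Item analysis for multiple-choice tests with a focus on the **ability-related
discriminatory power of distractors**: do non-solvers of different ability
prefer different wrong options? Items with that property are prime candidates
for nested logit IRT scaling, which recovers ability information from
distractor choices and improves measurement precision at the low end of the
scale. `distractr` is aimed at test developers screening candidate items in
pilot studies (N ≈ 100–500), where fitting a nested logit model directly is
not feasible.

## What it computes

For each item, after a 5% choice-frequency screen:

* **Cohen's ω_G** — ω_G = √(χ²_G / n) from the K × G contingency table of
  retained distractor × ability group over the item's non-solvers (G = 2 and
  G = 5 groups by score quantiles);
* **the canonical correlation R_CC** — between the distractor-choice
  indicator variables (one dropped) and non-solver total scores, via
  W = r₁₂′H₁⁻¹ and its singular value; identical to the correlation ratio η
  of scores over distractor groups;
* the traditional per-distractor indices: point-biserials
  **PB_D** = (M_D − M)/S · √(P_D/(1−P_D)) and **PB_DC** (the same contrast
  within D-choosers ∪ solvers), the Haladyna–Downing **ω_D**, and
  Goodman–Kruskal **γ** for rising selection ratios from the 2 × J table of
  solving probability by rest score.

Detection uses the conventional effect-size cutoffs 0.10 / 0.30 / 0.50;
R_CC > 0.30 is the recommended flag.

The package also contains the **2PNL simulator** (2PL solution stage +
nominal-response distractor stage, θ ~ N(0,1)) and a **Monte-Carlo study
harness** over the crossed design N {100,200,500} × items {10,20,50} ×
distractors {3,7} × difficulty × discrimination × NRM level (648 cells) that
estimates type-I error (zero-NRM cells) and power of the effect sizes, with
γ- and PB_DC-boundary conditions and empirical-substance diagnostics.

## Worked example

```r
library(distractr)

# a 10-item difficult test, 3 distractors, high distractor discrimination
resp <- example_item_data(2, n_persons = 10000, seed = 1)
scored <- score_responses(resp)
analyze_item(scored, 1)
#> item i01: 6865 non-solvers, 3 retained distractor(s) (0 below screen)
#>   R_CC = 0.375, omega_2 = 0.322, omega_5 = 0.371
#>   mean PB_DC = -0.49, mean gamma = 0.941
```

All three distractors pass the 5% screen; R_CC = 0.375 and ω₅ = 0.371 exceed
the 0.30 cutoff, flagging the item's distractor set as ability-discriminating
(the generating model used NRM slopes −1, 0, +1). The mean PB_DC of −0.49
confirms that solvers outscore distractor choosers. The matching zero-NRM
dataset (`example_item_data(1, ...)`) gives R_CC = 0.017, ω₂ = 0.017,
ω₅ = 0.026 — nothing to flag. Trace tables show why:

```r
round(trace_table(scored, 1), 2)   # options x 5 ability groups
#>       1    2    3    4    5
#> 0  0.08 0.22 0.32 0.46 0.68   # correct option rises with ability
#> 1  0.35 0.18 0.12 0.05 0.00   # lambda = -1 distractor falls steeply
#> 2  0.32 0.26 0.20 0.15 0.06
#> 3  0.25 0.33 0.36 0.34 0.25   # lambda = +1: non-monotone trace line
```

`analyze_items()` produces the one-row-per-item report, and
`distractor_report()` / `trace_report()` the per-distractor and long-format
trace tables.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/distractr.R", package = "distractr"))')
Rscript $CLI simulate --n 500 --items 10 --distractors 7 --nrm very_high --seed 7 --out sim
Rscript $CLI analyze --responses sim/responses.csv --key sim/key.csv --out report
Rscript $CLI study --cells typeI --reps 100 --seed 1 --out study
Rscript $CLI fixtures --seed 1 --out examples
```

Every command writes a JSON manifest; `study` writes per-cell CSVs and skips
completed cells on re-run. Exit codes: 0 ok, 2 validation error, 3 I/O error.

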