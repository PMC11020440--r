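# varfit — protein variant fitness from structure and evolution

`varfit` predicts the fitness effect of single amino-acid substitutions
and explains *why* a variant is predicted deleterious.  It is aimed at
protein scientists who have a multiple sequence alignment (MSA) of their
protein, optionally a 3D structure and scores from external
structure-based stability predictors, and want calibrated per-variant
fitness predictions plus an interpretable split into structural and
evolutionary contributions — the kind of output a deep mutational
scanning (DMS) experiment would be compared against.

## The model

The prediction for a substitution is a linear combination of eight
features,

    score = a1·RSA + a2·PoP + a3·MAE + a4·SNP
          + a5·PVS + a6·CI + a7·LOR + a8·PYF + a9,

on the DMS fitness scale (1 = wild-type-like, ≤ 0 = non-functional,
\> 1 = fitter than wild type).  RSA is the relative solvent accessibility
of the mutated residue (Shrake–Rupley ASA normalized by extended
Gly-X-Gly reference areas); PoP, MAE and SNP are scores of external
structure-based predictors ingested from CSV tables; PVS is a
PROVEAN-style mean substitution-score change against the aligned
homologs; CI is the conservation index of the column (Euclidean distance
between regularized column and alignment-wide amino-acid frequencies);
LOR is the logit difference of mutant and wild-type column frequencies;
and PYF is the statistical-energy change `E(wt) − E(mt)` under a Potts
model inferred from the MSA by pseudo-likelihood direct coupling
analysis.  The coefficients are fitted to experimental DMS fitness by
`varfit()` (OLS, or ridge on rank-deficient designs).

For a scored mutational landscape the package also reports z-scores `Z`,
`Z_str` and `Z_evo` — the raw score and its structural/evolutionary
blocks standardized over all mutations of the protein — which separate
"destabilizes the fold" from "evolutionarily forbidden" effects, plus
per-residue averages for structure colouring.  Evaluation utilities
implement the standard benchmark conventions: a hyper-complementing
filter (experimental fitness > 1.36 discarded), negative-fitness
flooring with standard-error exclusion (> 0.3), Kendall tau-b / Spearman /
Pearson / RMSD, and sensitivity, specificity, balanced accuracy and
AUC-ROC with the low-fitness-is-pathogenic orientation.

Everything the pipeline consumes can be generated synthetically with
known ground truth (`sample_profile_msa()`, `sample_potts_msa()`,
`make_toy_structure()`, `make_synthetic_dms()`), so the package is fully
testable offline.

## Worked example

Fit coefficients on a synthetic DMS training set and inspect the model:

```r
library(varfit)
train <- make_synthetic_dms(n = 2000, noise_sd = 0.1, seed = 42)
fit <- varfit(train)
summary(fit)
#> Linear variant-fitness model — ols fit, n = 2000
#>               Estimate Std. Error t value
#> RSA          2.017e-03  7.618e-05   26.48
#> PoP         -4.075e-02  1.454e-03  -28.02
#> MAE         -2.919e-02  2.235e-03  -13.06
#> SNP         -3.314e-02  2.216e-03  -14.96
#> PVS          5.870e-02  1.089e-03   53.90
#> CI          -4.015e-01  1.565e-02  -25.65
#> LOR          6.073e-02  1.090e-03   55.73
#> PYF          5.745e-02  2.185e-03   26.29
#> (Intercept)  8.934e-01  7.412e-03  120.53
#>
#> Residual sd 0.09906 on 1991 degrees of freedom
#> ...
#> Evolutionary block / structural block weight ratio: 2.88
```

The coefficient table reads like any regression summary; the last line is
the model's interpretability diagnostic — in feature-standard-deviation
units the evolutionary features carry about three times the weight of the
structural ones here.

Score a full single-site mutational landscape (19·L variants) through the
webserver-style workflow:

```r
dir <- tempfile("bundle")
paths <- cmd_simulate(dir, seed = 1)                  # MSA, PDB, tables
cmd_train(paths$training, file.path(dir, "coef.json"))
tab <- cmd_predict(paths$msa, file.path(dir, "coef.json"),
                   file.path(dir, "pred.csv"),
                   structure = paths$structure, chain = "A",
                   features = paths$features)
head(tab[, c("position", "wt", "mt", "RSA", "score", "Z", "Z_evo", "Z_str")], 4)
#>   position wt mt      RSA      score           Z       Z_evo     Z_str
#> 1        1  W  A 40.84744  0.2024851 -0.19592063 -0.50713801  1.138775
#> 2        1  W  C 40.84744  0.2332299 -0.09333025  0.29027361 -1.725229
#> 3        1  W  D 40.84744 -0.3099540 -1.90585026 -1.55498306 -1.997126
#> 4        1  W  E 40.84744  0.3939999  0.44313429  0.05424162  1.605353
```

Position 1 has RSA ≈ 41%, a partially exposed residue.  The W1D row
scores −0.31 (below 0: predicted non-functional), and both z-scores are
strongly negative — the substitution is both evolutionarily disfavoured
(`Z_evo` −1.55) and structurally destabilizing (`Z_str` −2.00) relative
to the average mutation of this protein.  W1A, in contrast, is mildly
deleterious mostly for evolutionary reasons.  The CSV written to
`pred.csv` carries per-variant RSA and ends with the four columns
`score`, `Z`, `Z_evo`, `Z_str`.

A shell entry point wrapping the same functions is installed at
`inst/exec/varfit` (`varfit predict|train|evaluate|simulate --key value ...`).

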