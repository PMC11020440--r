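---
title: "Methods: linear variant-fitness prediction from structure and evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear variant-fitness prediction from structure and evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfit)
```

## The model

`varfit` predicts the fitness effect of a single amino-acid substitution
as a linear combination of eight per-variant features:

$$\hat y \;=\; \alpha_1\,\mathrm{RSA} + \alpha_2\,\mathrm{PoP} +
\alpha_3\,\mathrm{MAE} + \alpha_4\,\mathrm{SNP} + \alpha_5\,\mathrm{PVS} +
\alpha_6\,\mathrm{CI} + \alpha_7\,\mathrm{LOR} + \alpha_8\,\mathrm{PYF} +
\alpha_9 .$$

The response is on the deep-mutational-scanning (DMS) fitness scale: 1
means the mutant behaves like the wild type, 0 or below means it is
non-functional, and values above 1 indicate variants fitter than the wild
type.  The prediction is deliberately **not clamped**: clamping would be a
hidden nonlinearity, and the interpretability z-scores below depend on the
raw linear value.  Only the separate clamped stability model
(`rescaled_pop()`, a double-ReLU that is algebraically a clamp to
$[0,1]$) bounds its output.

Three features are *structural*: PoP, MAE and SNP are scores of external
structure-based stability/deleteriousness predictors, ingested from CSV
feature tables (`load_feature_table()`) because those predictors are
independent tools, not part of this package.  RSA, the relative solvent
accessibility of the mutated residue, is computed internally.  Four
features are *evolutionary*, derived from a multiple sequence alignment
(MSA) of the query protein:

* **CI**, the conservation index of the mutated column: the Euclidean
  distance between the column's regularized amino-acid frequency vector
  and the alignment-wide vector, summed over the 20 standard amino acids.
  Frequencies are regularized with a pseudocount $\theta$ over 21 states
  (the gap counts as the 21st state in the frequencies, but is excluded
  from the CI sum):
  $f_i(a) = \frac{c_i(a)}{m}(1-\theta) + \frac{\theta}{21}$.
  The default $\theta = 0.01$ is small enough to leave observed
  frequencies essentially untouched while keeping every logit finite.
* **LOR**, the log-odds ratio
  $\mathrm{logit}\,f_i(mt) - \mathrm{logit}\,f_i(wt)$ with natural
  logarithms (the base is a convention; any base change is absorbed by
  $\alpha_7$).
* **PVS**, a PROVEAN-style substitution score: the mean, over homologs
  with a residue (not a gap) at the mutated column, of
  $s(mt, h_i) - s(wt, h_i)$ under a substitution matrix (BLOSUM62
  bundled, NCBI text format).  The pairwise alignments implicit in the
  MSA are reused rather than recomputed per variant.  This is a
  deliberate simplification of the original PROVEAN (no homolog
  clustering, no gap penalties); it is isolated behind
  `provean_score()` so the interpretation can be swapped.
* **PYF**, the statistical-energy change of a Potts model inferred from
  the MSA by pseudo-likelihood direct coupling analysis:
  $E(\mathrm{wt}) - E(\mathrm{mt})$, so that a coevolutionarily
  unfavourable substitution scores negative.  The raw energy difference
  is used; any scale that a downstream fitness mapping would apply is
  absorbed by $\alpha_8$.

## Coefficient fitting

`varfit()` fits $\alpha_1 \ldots \alpha_9$ by ordinary least squares on a
training table of variants with experimental DMS fitness (ridge with a
small penalty is available and is recommended automatically when the
design is rank-deficient).  The exact objective used by the original
predictor is not published, so both options are exposed; OLS is the
default.  `summary()` reports, besides the usual coefficient table, the
ratio of standardized coefficients (coefficient times feature standard
deviation, summed in absolute value) of the evolutionary block
(PVS, CI, LOR, PYF) to the structural block (PoP, MAE, SNP).  On real DMS
data this ratio is around 3 — evolutionary features carry most of the
predictive weight — and the synthetic training generator reproduces that
balance by construction.

Missing feature values (external predictors rarely cover every variant)
are median-imputed per feature over the protein's variant table
(`impute_missing()`), with imputation flags kept; absence is recorded as
`NA`, never as a silent zero.  A feature absent for *every* variant of a
landscape contributes zero to every score rather than blocking the run,
and stays flagged.

## Interpretability z-scores

For a scored landscape, the structural and evolutionary contributions are
$\mathrm{STR} = \alpha_2\mathrm{PoP} + \alpha_3\mathrm{MAE} +
\alpha_4\mathrm{SNP}$ and $\mathrm{EVO} = \alpha_5\mathrm{PVS} +
\alpha_6\mathrm{CI} + \alpha_7\mathrm{LOR} + \alpha_8\mathrm{PYF}$; RSA
and the intercept belong to neither block, so
$\mathrm{STR} + \mathrm{EVO} + \alpha_1\mathrm{RSA} + \alpha_9$ equals
the full score exactly (a tested identity).  Each of the raw score, STR
and EVO is standardized over all mutations of the protein,

$$Z = \frac{x - \mu[x]}{\sigma[x]},$$

using the **population** standard deviation: the single-site landscape of
a protein is a fixed finite set, not a sample.  The reference set
defaults to the complete landscape (19 substitutions at each of the $L$
positions); standardizing over a subset is possible but warned about,
because the z-scores are then relative to that subset.  Negative
$Z_{\mathrm{evo}}$ marks substitutions to residues rarely observed at the
position across evolution; negative $Z_{\mathrm{str}}$ marks
substitutions that destabilize the fold more than the average mutation.
`per_residue_summary()` averages the z-scores over the 19 substitutions
of each residue, the quantity typically painted onto a structure.

## Potts model inference

The coevolutionary model is a pairwise Markov random field over aligned
positions with $q = 21$ states — the gap is an ordinary state, since real
alignments contain gaps and removing them would distort column
statistics.  Fitting maximizes the weighted, $L_2$-regularized
pseudo-likelihood: each position's conditional distribution given the
rest of the sequence is a multinomial logistic model, fitted
independently (asymmetric PLM), after which the two estimates of each
coupling are averaged and the model is reported in the zero-sum gauge
(fields and couplings sum to zero over states).  Sequences are reweighted
by the standard redundancy rule (weight $=1/$ number of neighbours at
$\ge 80\%$ identity).  Defaults $\lambda_h = 0.01$ and
$\lambda_J = 0.01\,(N-1)$ follow common plmDCA-style scaling; all are
arguments.  The optimizer is deterministic: L-BFGS-B from a zero start
with projected-gradient tolerance $10^{-5}$, chosen for bit-reproducible
results over speed; exceeding the iteration budget is an error, never a
silent partial fit.

Because energy differences are gauge invariant, `variant_delta_fitness()`
is insensitive to the gauge choice (verified to $10^{-8}$ under random
gauge transformations) and is evaluated incrementally in $O(N)$ per
variant, which the tests check against full re-summation.

## Solvent accessibility

RSA uses Shrake–Rupley quadrature: near-uniform points on each heavy
atom's solvent-expanded sphere (deterministic golden-spiral layout;
probe radius 1.4 Å; Bondi element radii), counting points not buried in
any neighbour.  Shrake–Rupley was chosen over Lee–Richards because it is
simple and testable against closed forms: the isolated-sphere and
two-sphere analytic areas are reproduced within 0.5% at the default 960
points per atom.  Per-residue values converge to well under 1% per
doubling from about 2000 points; the default of 960 keeps a full-protein
calculation cheap at roughly 1–2% per-residue quadrature granularity,
which is far below the biological signal in RSA and can be raised via
`n_points`.  All chains of the input occlude each other (a multimer is
scored as the complex); isolated-chain values are obtained by scoring
chains separately, and the complex total can only be smaller — a tested
inequality.

RSA normalizes the residue ASA by its reference area in an extended
Gly-X-Gly tripeptide.  The bundled reference values are the
Tien et al. (2013) theoretical maxima; the reference used by the original
webserver's in-house program is unpublished, so numerically identical RSA
values are not claimed, and any custom table can be supplied.  RSA above
100% (possible for highly exposed conformations) is preserved in the
feature and clamped only in the report CSV.

## Evaluation methodology

`evaluate_predictions()` reproduces the benchmark conventions used to
assess fitness predictors on DMS data:

* hyper-complementing variants (experimental fitness **strictly above**
  1.36) are discarded — such variants, fitter than wild type in yeast
  complementation assays, are often deleterious in human;
* optionally, negative experimental fitness is floored at zero and
  variants with standard error **strictly above** 0.3 are removed (the
  convention for noisier assays);
* Kendall (tau-b — DMS data is heavily tied, so the tie-corrected variant
  is the defensible choice), Spearman and Pearson correlations plus RMSD;
* classification metrics with the fitness orientation fixed: a score
  *below* the threshold (default 0.5) calls the variant pathogenic;
  predictors with the opposite polarity are handled by a per-column
  polarity flag, and AUC-ROC uses the rank (Mann–Whitney) formulation,
  which handles ties by mid-ranks and equals trapezoidal ROC
  integration.

Both filter boundaries are strict inequalities, as worded in the
conventions they implement, and both filters are idempotent (tested).

## Synthetic data: what it emulates and what it does not

All tests run on generated inputs with known ground truth:

* `sample_profile_msa()` draws independent columns from Dirichlet
  profiles — it emulates per-column conservation structure, but **not**
  phylogenetic correlation between rows, so it cannot stress-test the
  sequence reweighting the way a real protein family would.
* `sample_potts_msa()` draws *exact* Boltzmann samples by enumerating the
  full state space (limited to $q^N \le 10^6$), making it a genuine
  oracle for inference tests; a Gibbs mode exists for larger systems and
  is clearly labelled approximate, so no acceptance property depends on
  mixing.
* `make_toy_structure()` writes idealized poly-residue helices and
  extended chains (backbone + CB, 3.8 Å consecutive CA–CA) and extended
  Gly-X-Gly tripeptides — enough geometry for accessibility and parsing
  tests, not a substitute for real side-chain packing.
* `make_synthetic_dms()` draws features on realistic scales (RSA in
  percent, stability scores in kcal/mol-like units) and computes fitness
  exactly from the linear model plus Gaussian noise (default sd 0.1,
  n = 2000 in the recovery studies), with the generating coefficients
  chosen so the evolutionary block carries about three times the
  standardized weight of the structural block.  Real DMS noise is
  heteroscedastic and features are correlated; passing recovery tests
  therefore demonstrates correctness of the fitting machinery, not
  real-data performance.

Every generator takes an explicit seed and restores the caller's RNG
state, so adding one call never shifts another's draws; identical seeds
give byte-identical fixture bundles.

## Numerical and design choices

* Nonstandard residues (B, Z, X, U, O, …) in alignments map to the gap
  state rather than being dropped, preserving depth and column register.
* A3M lowercase insertion columns are deleted: all features are defined
  per query position.
* A variant whose stated wild type disagrees with the query is an
  **error**, never a warning — silent coordinate drift is the classic
  variant-annotation bug.
* Altlocs resolve to the highest occupancy (ties: lexicographic id);
  hydrogens and waters are stripped before any calculation.
* Structure-to-sequence mapping is by alignment of the observed chain
  sequence to the query, so author residue numbering never leaks into
  variant coordinates; under 50% mappable query positions is treated as
  the wrong chain.
* Test problem sizes (e.g. Potts recovery at $N=3, q=3, m=5000$;
  coefficient recovery over 200 replicates of n = 2000) were chosen as
  the smallest systems in which the corresponding failure modes are
  detectable with comfortable margins.

## Known limitations

* The PROVEAN-style score simplifies the original algorithm (see above);
  the two agree in orientation but not numerically.
* The Potts fit is dense and in-memory; it is meant for the alignment
  sizes of single-protein analyses, not proteome-scale scans.
* mmCIF structures are not parsed (PDB only); accessibility ignores
  heteroatom ligands since waters and hydrogens are stripped and other
  HETATM records are kept only if they carry standard residue names.
* Shipped coefficients are always the product of this package's own
  training pipeline on stated data; no claim is made to reproduce the
  unpublished coefficients of the original webserver.

## Worked example

```{r example}
dir <- tempfile("bundle")
paths <- cmd_simulate(dir, seed = 3, L = 10, m = 50)
fit <- cmd_train(paths$training, file.path(dir, "coef.json"))
summary(fit)
tab <- cmd_predict(paths$msa, file.path(dir, "coef.json"),
                   file.path(dir, "pred.csv"),
                   structure = paths$structure, chain = "A",
                   features = paths$features)
head(tab[, c("position", "wt", "mt", "RSA", "score", "Z", "Z_evo", "Z_str")])
per_residue_summary(tab)[1:5, ]
```
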