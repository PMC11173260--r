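# enzTopt

Sequence-only prediction of enzyme optimal catalytic temperature (Topt)
with conserved-residue masking.

## What this is for

Determining the temperature at which an enzyme's activity peaks requires
expression, purification and activity assays across a temperature ladder —
far too slow for screening sequence databases. For users who need a quick
Topt estimate (e.g. when picking a thermostable phosphatase for an in
vitro enzymatic cascade), `enzTopt` regresses Topt directly on sequence
composition, with one twist drawn from how protein engineers treat
conserved residues: positions that are perfectly conserved across an
enzyme family are structurally and catalytically constrained, carry little
information about an individual member's temperature optimum, and dilute
the signal carried by the variable positions. The package therefore
aligns each EC-number group, removes the residues in fully conserved
alignment columns from every member ("rcaa" sequences), and fits the
regression on what remains.

## The method in brief

For a labeled dataset (id, EC number, Topt °C, sequence):

1. group by full EC number; drop sequences < 50 aa and singleton groups;
2. multiply align each group; a column is *conserved* when all members
   share one identical, non-gap residue; delete those residues from each
   member (members stripped below 50 aa are dropped from both the
   stripped and the paired full-sequence dataset);
3. families with too few conserved columns are split into sub-groups via
   a sequence similarity network (percent-identity edges, threshold
   chosen to minimise isolated nodes; singleton clusters dropped);
4. featurize with one of 12 descriptor combinations over amino-acid
   frequency f(t) = N(t)/N, dipeptide frequency F(rs) = N(rs)/(N−1),
   molecular weight, conjoint triads (343-d) and distribution
   descriptors (105-d); the default combination is amino-acid frequency +
   molecular weight (21-d);
5. evaluate by Monte Carlo cross-validation: temperature-stratified
   splits over [0,30,50,65,85,100] °C bins, rare-domain (Topt < 21 or
   > 64 °C) oversampling of the training partition to exact parity with
   the normal domain, training-set-only z-scoring, K-nearest-neighbour
   regression (uniform weights, Euclidean, K ≤ 15), mean R² = mean over
   iterations of 1 − SS_res/SS_tot;
6. predict for new sequences: assign the EC group of the top
   percent-identity training hit, strip the query positions matching the
   group's conserved columns, featurize, scale, predict.

OLS, random forest, AdaBoost.R2 and cross-validated lasso regressors are
registered alongside KNN; a paired exact Wilcoxon signed-rank test
compares models evaluated on identical splits.

## Worked example

The package ships a synthetic-family generator whose labels depend only
on variable-region composition, so the effect of conservation masking can
be measured against ground truth:

```r
library(enzTopt)

bench <- generateLabeledBenchmark(seed = 1)   # 5 families x 50 members
bench$set
#> EnzymeSet 'benchmark_seed1' with 250 record(s)
#>   sequence length: 200-200
#>   EC annotated: 250 | Topt labeled: 250

stripped <- lapply(groupByEC(bench$set), stripGroup)
stripped[["3.1.3.1"]]$map
#> ConservedMap: 150 conserved column(s) of 200 (threshold 1.00)

rcaa <- combineSets(lapply(stripped, `[[`, "rcaa"))      # masked sequences
orig <- combineSets(lapply(stripped, `[[`, "original"))  # same records, intact

spec <- modelSpec("knn", seed = 1)
plan <- splitPlan(seed = 1)
mccv(orig, comboId = 7, spec, plan)
#> MCCV (10 iterations, knn, combo 7): mean R2 = 0.781 (sd 0.095), mean RMSE = 10.9
mccv(rcaa, comboId = 7, spec, plan)
#> MCCV (10 iterations, knn, combo 7): mean R2 = 0.896 (sd 0.039), mean RMSE = 7.6
```

Both arms use identical record splits (splits depend only on labels and
seed), so the per-iteration R² values are validly paired: masking the 150
conserved scaffold residues lifts mean R² from 0.78 to 0.90 and cuts RMSE
from 10.9 to 7.6 °C on this benchmark, because the scaffold contributes
family-specific composition offsets that confound the temperature signal.
`predictTopt()` applies a trained bundle (`trainBundle()`) to novel
FASTA queries; `inst/scripts/enztopt.R` exposes the same steps as a
command line (`build`, `strip`, `featurize`, `train`, `evaluate`,
`predict`).

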