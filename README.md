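# fusionsig

Derive, apply, and evaluate a transcriptional signature of the
TMPRSS2–ERG gene fusion in prostate cancer.

The TMPRSS2–ERG fusion joins the androgen-responsive TMPRSS2 promoter to
the ERG transcription factor and occurs in more than half of prostate
adenocarcinomas, deregulating a broad downstream expression program. A
signature of that program can (i) call fusion-like pathway activity in
any expression cohort — including samples whose activation comes from
alternative ERG fusions — and (ii) stratify patients by prognosis.
`fusionsig` implements the full workflow for analysts working with
gene-by-sample expression matrices and clinical annotation, and ships a
synthetic-cohort generator so every stage can be validated without
access to any real cohort.

## The method

**Derivation.** For each gene *g*, fit the covariate-adjusted logistic
regression

  logit P(fusion⁺) = β₀ + β₁·expr_g + β₂·age + β₃·gleason

by maximum likelihood. Rank genes by the two-sided Wald p-value of β₁,
keep the *K* most significant (default *K* = 700), and assign each
selected gene the weight

  w_g = sign(β₁) · (−log₁₀ p_g) / max(−log₁₀ p)

so that all weights lie in [−1, 1], the strongest gene has |w| = 1, and
the sign encodes up-/down-regulation in fusion-positive tumors.

**Scoring.** Each sample is scored by a rank-based running-sum
statistic. Genes are ordered by descending expression in that sample;
walking down the ranking, a foreground CDF F(k) accumulates signature
weight magnitudes and a background CDF B(k) accumulates their
complement. The pre-score is D(k*) = F(k*) − B(k*) at the position of
maximal |F − B|; it is positive when signature genes concentrate at the
top of the ranking. Each pre-score is divided by the mean absolute
pre-score of seeded random permutations of the weights over genes, so a
score of ±1 means "no stronger than chance". The sample score is the
normalized up-set score minus the normalized down-set score, making the
score exactly antisymmetric under weight negation and invariant to any
monotone transform of the sample's expression.

**Evaluation.** Per configured clinical stratum: Wilcoxon rank-sum
comparison of scores by fusion status, ROC/AUC classification (pair
counting, ties = ½), median-split Kaplan–Meier survival curves with the
two-group log-rank test, and Spearman correlation of scores against
continuous covariates (ERG expression, immune-infiltration fractions,
mutation/CNV burdens, ...).

## Worked example

```r
library(fusionsig)

params <- simulation_params(n_genes = 500, n_samples = 120,
                            n_signal_genes = 60, seed = 42)
cohort <- simulate_cohort(params)

res <- derive_signature(cohort$expression, cohort$clinical, K = 60)
res$signature
#> <fusion_signature 'derived'> 60 genes (30 up, 30 down)
#>   gene     weight
#>  g0007  1.0000000
#>  g0001  0.9579237
#>  g0041 -0.9469643
#>  ...

scores <- score_samples(cohort$expression, res$signature,
                        n_permutations = 200, seed = 0)
round(head(scores), 3)
#> s0001 s0002 s0003 s0004 s0005 s0006
#> 6.451 6.045 6.688 6.652 6.668 6.121

evaluate_cohort(scores, cohort$clinical)
#> [all] n = 120
#>   Wilcoxon rank-sum (normal approx.): positive n=60 median=6.159 vs
#>     negative n=60 median=0.302; W=3600, p=3.56e-21
#>   fusion AUC = 1.0000
#>   median-split log-rank p = 6.61e-12
#> [fusion_positive] n = 60
#>   median-split log-rank p = 0.544
#> ...
```

Reading the output: fusion-positive samples score around 6 permutation
units above the null while fusion-negative samples sit near 0, so the
score classifies fusion status perfectly (AUC = 1) in this synthetic
cohort; because the generator ties the event hazard to the latent
fusion-pathway activity, a median split of the scores also separates
survival (log-rank p ≈ 7 × 10⁻¹²). Within the fusion-positive stratum
alone the split is uninformative (p ≈ 0.5), as expected when activity is
homogeneous within the group.

## Command-line use

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fusionsig", package = "fusionsig"))')
Rscript "$CLI" simulate --config sim.json --out-dir work/
Rscript "$CLI" derive   --expr work/expression.tsv --clinical work/clinical.tsv \
                        --top-k 700 --out work/signature.tsv
Rscript "$CLI" score    --expr work/expression.tsv --signature work/signature.tsv \
                        --n-perm 1000 --seed 0 --out work/scores.tsv
Rscript "$CLI" evaluate --scores work/scores.tsv --clinical work/clinical.tsv \
                        --out work/report.json
```

Formats: expression as TSV (first column gene id, header row of sample
ids) or GCT 1.2; clinical tables as TSV with columns `sample_id`,
`fusion_status` (`positive`/`negative`/`erg_other`), `age`, `gleason`,
`time`, `event`, plus any numeric covariate columns; signatures as
two-column `gene<TAB>weight` TSV. Every run writes a manifest JSON with
the parameters needed to reproduce its outputs byte-identically.

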