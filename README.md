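# omicblup

Multi-kernel BLUP for phenotype prediction from genomic and transcriptomic
data in panels of inbred lines.

## The problem

In a reference panel of fully inbred, fully genotyped lines, a line's
phenotype can be predicted from the phenotypes of related lines once
relatedness is quantified on a molecular layer. Gene expression is a
particularly interesting layer: interactions between loci (epistasis) that
an additive SNP kernel cannot see may act additively at the transcript
level, so a transcriptome kernel can capture genetic variance that genomic
BLUP misses. `omicblup` provides the five standard predictors built from
one linear mixed model,

y = 1μ + Σₖ uₖ + e,  uₖ ~ N(0, Kₖ σₖ²),  e ~ N(0, I σₑ²),

differing only in the kernels Kₖ:

* **gblup** — VanRaden genomic relationship matrix
  G = ZZ′ / (2Σ pⱼ(1−pⱼ)) from centered SNP dosages;
* **tblup** — linear expression kernel E = RR′ from column-standardized
  expression;
* **rkhs** — Gaussian expression kernel K(h)ᵢⱼ = exp(−‖rᵢ−rⱼ‖²/h), with the
  bandwidth h selected by grid search under cross-validation;
* **gtblup** — two kernels, G + E;
* **grblup** — two kernels, G + K(h).

Variance components are estimated by average-information REML (EM
fallback, non-negativity by projection, boundary estimates flagged);
held-out lines are predicted through kernel cross-blocks (equivalent to
Henderson's mixed-model equations with unobserved records). The package
also computes SNP-based narrow-sense heritability h²G = σ²g/(σ²g+σ²e) and
its omics-augmented broad-sense analogues
H² = (σ²g+σ²omics)/(σ²g+σ²omics+σ²e), runs replicated k-fold
cross-validation with Pearson predictive abilities on shared fold plans,
compares models by Tukey's HSD, and ships a simulator of inbred-line
genotypes, genotype-driven expression (including additive-by-additive
epistasis) and phenotypes with exact variance-share control.

Intended users: quantitative geneticists and biostatisticians exploring
multi-omics prediction models at panel scale (hundreds of lines), and
anyone needing a transparent, fully tested reference implementation of
one- and two-kernel REML/BLUP.

## Worked example

```r
library(omicblup)

# a synthetic panel: 200 inbred lines, 500 SNPs, 150 genes; phenotype with
# 40% additive, 30% expression-mediated, 30% residual variance
sim <- simulate_dataset(n_lines = 200, n_markers = 500, n_genes = 150,
                        seed = 42)

fit <- fit_model(sim$dataset, "gtblup", "trait")
fit
#> omicblup_fit [gtblup]: n = 200, loglik = -248.3533 (converged, 16 iterations)
#>   mu = 0.002937
#>   sigma2[g] = 0.1008
#>   sigma2[t] = 0.001854
#>   sigma2[e] = 0.2903
heritability(fit)
#> HGT2 = 0.2613

cv_gt <- run_cv(sim$dataset, "gtblup", "trait", k = 5, reps = 5, seed = 42)
cv_g  <- run_cv(sim$dataset, "gblup",  "trait", k = 5, reps = 5, seed = 42)
cv_gt
#> cv_result [gtblup]: 5 x 5-fold, mean ability 0.3677 (sd 0.1153)
cv_g
#> cv_result [gblup]: 5 x 5-fold, mean ability 0.2435 (sd 0.1239)

tukey_hsd(list(gblup = cv_g, gtblup = cv_gt))
#>               pair       diff        lwr         upr        p_adj
#> gblup gblup-gtblup -0.1242256 -0.1922929 -0.05615827 0.0006089274
```

Reading the output: the two-kernel model attaches 26% of the phenotypic
variance to the SNP + expression kernels (HGT2), and its mean predictive
ability over 25 cross-validation folds (5 replicates × 5 folds, identical
fold plans for both models) is 0.37 versus 0.24 for GBLUP alone — a
difference the Tukey-adjusted comparison calls significant (p ≈ 6e-4).
Because this panel's phenotype carries an expression-mediated variance
share, the transcriptome kernel adds genuine predictive signal, which is
exactly the regime the two-kernel models are designed for.

A thin command-line interface over the same functions is installed at
`system.file("cli", "omicblup.R", package = "omicblup")` with subcommands
`simulate`, `filter`, `kernel`, `fit`, `cv` and `compare`.

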