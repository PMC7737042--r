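# pairgwas

Decomposing the shared genetic basis of two correlated traits from GWAS
summary statistics.

Many pairs of complex traits — the flagship case being major depression (MD)
and the personality trait neuroticism (Neu) — are strongly genetically
correlated, which raises the question of whether they are noisy readouts of
one underlying liability or partially distinct architectures. `pairgwas`
implements the two complementary summary-statistics analyses that answer it:

1. **A Bayesian pairwise-GWAS segment scan.** The genome is split into
   approximately independent LD blocks; within each block the evidence for
   five causal models — *null*, *trait 1 only*, *trait 2 only*, *shared
   causal signal*, *two separate signals* — is aggregated from per-SNP
   Wakefield approximate Bayes factors, genome-wide model priors are
   estimated by empirical Bayes, and each segment is classified from its
   posterior model probabilities together with genome-wide-significance
   flags. Sample overlap between the two studies is handled by estimating
   the correlation of z-scores in segments unassociated with either trait
   and carrying it into the null and alternative models.
2. **Partial genetic correlations.** For any third trait *Y*, LD score
   regression yields the genetic covariance matrix among (*Y*, MD, Neu) on
   one shared variant set; the multiple regression
   `Y_g = b1·MD_g + b2·Neu_g + u_Y` on the standardised (correlation) scale
   then gives `b1 = MD·adjNeu` and `b2 = Neu·adjMD` — the association of *Y*
   with each focal trait after removing genetic overlap with the other —
   with block-jackknife standard errors, attenuation tests and
   Benjamini–Yekutieli FDR control.

The statistical core, in brief: a SNP with z-score `z`, effect-variance
`v = 1/n` and effect-size prior `N(0, W)` has approximate Bayes factor
`ABF = sqrt(1 − r) · exp(z² r / 2)` with `r = W/(v + W)`, averaged over
`W ∈ {0.01, 0.1, 0.5}`; bivariate versions use the density ratio of
`(z1, z2)` under null covariance `[[1, C], [C, 1]]` versus association
models that inflate the affected traits' variances by `W/v`. Regional
Bayes factors assume at most one causal variant per trait per segment,
uniform over SNPs. LDSC fits `E[χ²] = 1 + a + n·h²·ℓ/M` and
`E[z1 z2] = ρ_g·sqrt(n1 n2)·ℓ/M + intercept`.

A synthetic-data module generates two-trait segment studies (block AR(1)
LD, configurable per-segment causal models, sample overlap) and three-trait
polygenic studies (specified heritabilities and genetic correlations) with
exact LD scores and full ground truth, so every stage is testable end to
end without consortium data.

## Worked example

Simulate a 500-segment two-trait study at the package's design conditions
(70% null segments, 15% shared, strong causal signals) and run the scan:

```r
library(pairgwas)
sim  <- simulate_pair(pair_sim_config(n_segments = 500, seed = 7))
scan <- run_pairwise(sim$sumstats1, sim$sumstats2, sim$blocks)
#> Pairwise GWAS segment scan: 500 segments
#>   null z-score correlation C = -0.0054
#>   model priors: pi0=0.6858 pi1=0.0327 pi2=0.0483 pi3=0.1805 pi4=0.0527
#>   segment labels:
#>  TRAIT1_ONLY  TRAIT2_ONLY         BOTH     SEPARATE      NEITHER UNCLASSIFIED
#>           18           25           88           25          344            0
```

The estimated null correlation (−0.005) confirms the two simulated studies
share no samples; the priors recover the generating mixture (0.70, 0.05,
0.05, 0.15, 0.05); and the label counts recover the per-segment truth
(here 499/500 segments are labelled with their generating model).
`scan$segments` is the per-segment table — coordinates, SNP counts, log10
regional Bayes factors, posteriors, top SNPs and labels:

```r
head(subset(scan$segments, label == "TRAIT1_ONLY"), 3)
#>    block_id chrom   start     end      ppa1 top_snp1       top_p1       label
#> 1         0     1       0   50000 0.7830355     rs15 4.431914e-13 TRAIT1_ONLY
#> 19       18     1  900000  950000 0.8436079    rs902 4.805668e-17 TRAIT1_ONLY
#> 23       22     1 1100000 1150000 0.7579356   rs1143 1.358149e-20 TRAIT1_ONLY
```

For the partial-correlation stage, simulate the flagship three-trait
fixture — `rg(MD, Neu) = 0.68` and a trait Y constructed so that its true
`MD·adjNeu = 0.5` and `Neu·adjMD = 0`:

```r
tri <- simulate_tritrait(tri_sim_config(seed = 1))
res <- run_partial_rg(tri$sumstats, md = "MD", neu = "NEU",
                      ldscores = tri$ldscores)
round(as.data.frame(res)[, c("r_md", "r_neu", "md_adj_neu", "md_adj_neu_se",
                             "neu_adj_md", "neu_adj_md_se")], 3)
#>   r_md r_neu md_adj_neu md_adj_neu_se neu_adj_md neu_adj_md_se
#> 1 0.53  0.36      0.546         0.101     -0.023         0.102
res$label
#> [1] "MD_ADJ_SPECIFIC"
```

Y is genetically correlated with both focal traits (0.53, 0.36), but after
the multiple regression only the MD coefficient survives (0.55 ± 0.10 vs
−0.02 ± 0.10) — the analysis correctly reports that Y's link to Neu is
entirely explained by Neu's overlap with MD.

A thin command-line front-end over the same functions ships at
`inst/cli/pairgwas.R` with subcommands `munge`, `simulate-pair`,
`simulate-tri`, `pairwise` and `partial-rg`.

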