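---
title: "Decomposing the shared genetic basis of two correlated traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the shared genetic basis of two correlated traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairgwas)
```

`pairgwas` answers a single scientific question in two complementary ways:
when two traits — canonically major depression (MD) and neuroticism (Neu) —
are strongly genetically correlated, which parts of their genetic
architecture are shared and which are trait-specific? This vignette is the
package's own account of the models it fits, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices made where several were defensible.

## The pairwise segment model

The unit of analysis is an approximately independent LD block ("segment").
Within a segment with $k$ SNPs, five mutually exclusive causal models are
scored: $M_0$ no causal variant for either trait; $M_1$/$M_2$ one causal
variant for trait 1/trait 2 only; $M_3$ one causal variant shared by both
traits; $M_4$ two distinct causal variants, one per trait.

**Per-SNP evidence.** For one trait, a SNP with z-score $z$ and squared
standard error $v$ of the standardised effect has the Wakefield approximate
Bayes factor
$$\mathrm{ABF} = \sqrt{1 - r}\, \exp(z^2 r / 2), \qquad r = W/(v + W),$$
the exact marginal-likelihood ratio when the true standardised effect has a
$N(0, W)$ prior. When only z and n are available, $v = 1/n$
(standardised-genotype approximation). Evidence is averaged with equal
weight over $W \in \{0.01, 0.1, 0.5\}$, the conventional grid for this
analysis; it is configurable but deliberately not tuned per dataset.

**Sample overlap.** If the two studies share $N_s$ individuals with
phenotypic correlation $\rho$, their estimation errors are correlated
$C = N_s\rho/\sqrt{n_1 n_2}$ at every SNP. The bivariate Bayes factors are
density ratios of $(z_1, z_2)$ with null covariance
$[[1, C], [C, 1]]$; each affected trait adds $W/v_t$ to its diagonal entry.
With $C = 0$ the shared-model Bayes factor factorises exactly into the two
univariate ABFs — a property the tests pin to $10^{-10}$. $C$ is estimated
before the full scan: both traits are scored with a two-model
(null/associated) version of the machinery, segments with posterior
probability of association below 0.2 for *both* traits are retained, and
$C$ is the Pearson correlation of z-scores over their variants. z-scores
rather than betas are the default because the munged z-only dialect is the
common case; a `use_beta` flag covers the alternative reading.

**Regional aggregation.** At most one causal variant per trait per segment,
uniform over SNPs:
$\mathrm{RBF}_1 = \tfrac1k \sum_i \mathrm{BF}_1^{(i)}$ (similarly models 2
and 3) and
$\mathrm{RBF}_4 = \big[\sum_i \mathrm{BF}_1^{(i)} \sum_j \mathrm{BF}_2^{(j)}
- \sum_i \mathrm{BF}_1^{(i)}\mathrm{BF}_2^{(i)}\big]/\,k(k-1)$,
zero when $k = 1$. Everything is computed in log space with log-sum-exp;
the $M_4$ subtraction uses `log1p(-exp(·))` and the tests verify agreement
with brute-force enumeration over causal configurations for $k \le 6$ at
$10^{-10}$ relative.

**Priors and posteriors.** Genome-wide model priors maximise
$\sum_{\text{segments}} \log\big(\pi_0 + \sum_m \pi_m \mathrm{RBF}_m\big)$
over the simplex, via a softmax parameterisation and BFGS with analytic
gradient from five deterministic starting points (a multimodality guard
that keeps the pipeline fully reproducible). A flat likelihood — all RBFs
near 1 — is reported as non-identified rather than returning an arbitrary
interior point silently. Segments with fewer than `min_snps = 10` variants
are excluded from prior estimation (regional Bayes factors on near-empty
segments are unstable) but still scored. No penalisation term is placed on
the prior likelihood. Posteriors follow by Bayes' rule with
$\mathrm{RBF}_0 \equiv 1$.

**Classification.** A segment is `NEITHER` when its total association
posterior $1 - \mathrm{ppa}_0 < 0.2$ and it contains no genome-wide
significant variant ($p < 5\times10^{-8}$, configurable) for either trait;
this rule takes precedence. Otherwise the winning causal model decides:
`TRAIT1_ONLY` additionally requires a genome-wide hit for trait 1 and none
for trait 2 (symmetrically `TRAIT2_ONLY`); `BOTH` and `SEPARATE` follow the
argmax directly. "Total posterior probability of association" is read as
$1 - \mathrm{ppa}_0$, the only reading consistent with a five-model
posterior. Exact posterior ties yield `UNCLASSIFIED` — the classifier never
fabricates a winner.

One property worth stating precisely: raising $|z_1|$ at a single SNP is
guaranteed (and tested) to not decrease the segment's *combined* posterior
for models involving trait 1 ($\mathrm{ppa}_1 + \mathrm{ppa}_3 +
\mathrm{ppa}_4$) when $C = 0$. The per-model posteriors are *not*
individually monotone — a stronger trait-1 signal at a SNP where trait 2 is
also associated grows the shared-model evidence faster than the
trait-1-only evidence — and with $C \ne 0$ the null density itself moves
with $z$, so only the combined, independent-study version of the property
holds.

## LD score regression and partial correlations

Heritabilities and genetic covariances come from the standard LDSC
regressions, $E[\chi^2_j] = 1 + a + n h^2 \ell_j / M$ and
$E[z_{1j} z_{2j}] = \rho_g \sqrt{n_1 n_2}\, \ell_j / M + \text{intercept}$,
where the cross-trait intercept absorbs sample overlap — the reason LDSC
remains valid for overlapping cohorts. Weights follow the usual
heteroscedasticity-times-overcounting scheme in two steps: an unweighted
first pass supplies predicted means, then one weighted fit. The cross-trait
weights are constructed so that feeding the same study twice reproduces the
univariate fit *exactly*; the tests assert this identity at $10^{-10}$. No
$\chi^2$ cap is applied by default (synthetic data needs no outlier guard;
real-data users can filter upstream). Standard errors are delete-one-block
jackknives over 200 contiguous blocks of equal variant count after sorting
by (chromosome, position) — fully deterministic — and every reported SE is
exactly reproducible from the stored replicates.

For a third trait $Y$, all six unique entries of the genetic covariance
matrix among $(Y, \mathrm{MD}, \mathrm{Neu})$ are estimated on the
identical variant universe and jackknife partition, and the regression
$$Y_g = b_1\,\mathrm{MD}_g + b_2\,\mathrm{Neu}_g + u_Y$$
is solved on the correlation scale: $b = R_{xx}^{-1} r_{xy}$,
$u_Y = 1 - r_{xy}^\top b$. The standardised coefficients are reported as
the primary adjusted quantities ($\mathrm{MD{\cdot}adjNeu}$,
$\mathrm{Neu{\cdot}adjMD}$), with classical partial correlations — which
rescale by residual variances and differ analytically — as a secondary
column, so both conventions are recoverable. A full weighted
structural-equation fit would give identical point estimates for this
just-identified regression, so the package uses the direct matrix solve and
propagates uncertainty by recomputing the solve on every jackknife
replicate of the covariance matrix; this was a deliberate design choice in
favour of transparency and honest SEs over re-deriving a sampling
covariance of $S$.

Three tests are reported per trait and direction: unadjusted correlation
against zero, adjusted coefficient against zero, and a one-sided
attenuation test of $|r| - |b|$ using the paired-jackknife SE of the
difference (a sign-flipped adjusted estimate counts as attenuated and is
flagged). All p-values — across traits and all three test families — are
pooled into a single Benjamini–Yekutieli FDR family; the family structure
is configurable since no canonical choice exists. Pattern labels follow the
unadjusted/adjusted significance grid, with `POSSIBLE_*` variants when the
95% intervals of the two adjusted estimates overlap. Degenerate cases are
explicit: collinear predictors ($|r_{\mathrm{MD,Neu}}| \ge 0.999$),
non-positive-definite correlation matrices (tolerance $10^{-10}$ on the
smallest eigenvalue) and non-positive heritabilities all refuse loudly
rather than returning numbers.

## What the generators emulate — and what they do not

Both generators use AR(1) within-block LD, $\mathrm{corr}(i,j) =
\rho^{|i-j|}$: closed-form, always positive definite, and with LD scores
computed exactly from the generating matrix, which removes reference-panel
mismatch from every test. Positions are synthetic (one pseudo-chromosome
per 100 segments, 1 kb spacing) but emitted in valid sumstats/BED/LD-score
dialects so the real readers and writers are exercised. Overlap is modelled
at the noise level only — the error covariance that shared samples induce —
not via individual-level genotypes, which is sufficient to create the $C$
the pipeline must estimate at a tiny fraction of the cost.

The **pair generator** defaults are the study conditions the scan targets:
sample sizes 431,394 and 329,821 (a depression meta-analysis and a biobank
neuroticism study), 500–2000 segments of 50 SNPs, model prior
$(0.70, 0.05, 0.05, 0.15, 0.05)$, and causal non-centrality
$E[\chi^2] = 80$ at the causal SNP. Causal z-score means default to fixed
magnitude $\sqrt{\mathrm{effect\_scale} - 1}$ with random sign rather than
a Gaussian draw: with Gaussian effects of the same mean non-centrality,
roughly half of truly associated segments fall below genome-wide
significance, so the `*_ONLY` labels (which require a genome-wide hit)
could never be recovered reliably — the fixed-magnitude default makes
"strong signal" mean what the classification rules need it to mean.
`effect_dist = "normal"` restores Gaussian draws for
prior-misspecification experiments. The shared model places two
*independent* effects at the same SNP, exactly matching the analysis
model's assumption.

The **tri-trait generator** draws per-SNP standardised effects from the
infinitesimal model $N_3(0, \Sigma_g / M)$ with $\Sigma_g =
D^{1/2} R_g D^{1/2}$. Its default fixture is the flagship decomposition:
$r_g(\mathrm{MD},\mathrm{Neu}) = 0.68$ (matching the estimate the package's
methods produce on real depression/neuroticism data), $r_g(Y,\mathrm{MD}) =
0.5$ and $r_g(Y,\mathrm{Neu}) = 0.34$, so that analytically
$\mathrm{MD{\cdot}adjNeu} = 0.5$ and $\mathrm{Neu{\cdot}adjMD} = 0$
exactly. `ld_rho` cycles over $(0.2, 0.5, 0.8)$ across blocks by default:
a genome with a *spread* of LD scores is what separates the LDSC slope
from its intercept, and a single-$\rho$ genome leaves them barely
identified (an instructive failure mode, reproducible by setting a scalar
`ld_rho`).

What passing tests on these generators show is that the estimators are
correct and calibrated under their own assumptions. What they do not show:
robustness to real LD (long-range structure, the MHC), to mismatch between
analysis LD scores and the sumstats cohort, to case/control ascertainment
and liability-scale issues, to INFO/MAF artefacts, or to the multi-causal
segments that violate the one-variant-per-trait assumption. Real-data use
should treat those as open validation questions, not settled ones.

## Test design and problem sizes

The suite runs at desk scale by choice: prior recovery uses 2000 segments
(estimates within ±0.03 of the generating mixture), classification uses
500 segments (≥90% per-model recovery), overlap recovery uses 300 segments
with complete overlap ($\hat C$ within ±0.03 of 0.2), and the LDSC /
partial-correlation stages use 20,000-SNP, $n = 50{,}000$ studies. For the
across-seed LDSC calibration check, per-seed "within 2 jackknife SE"
interval checks are pooled over 10 seeds and ≥90% are required to pass:
demanding a clean sweep of forty nominal-95% intervals would fail a
perfectly calibrated estimator most of the time, whereas the pooled
coverage criterion passes it with high probability and still detects bias
or mis-scaled SEs. Everything is seeded; the full pipeline is byte-identical
across repeated runs, and `scripts/acceptance.R` re-derives the headline
numbers from scratch under any `--seed`.

## Known limitations

Beyond the generator caveats above: the scan assumes at most one causal
variant per trait per segment and offers no within-segment fine-mapping or
annotation-stratified priors; heritabilities are on the observed scale (no
liability conversion); the LDSC implementation reads a two-column LD-score
table rather than the multi-annotation dialect and implements neither
partitioned LDSC nor $\chi^2$ filtering; and strand-complement matching is
deliberately not attempted during allele alignment — ambiguous variants
should be dropped instead, for which `drop_strand_ambiguous()` is provided.
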