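---
title: "Two-sample MR screening with protein-ratio mediators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening with protein-ratio mediators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiomr)
```

## The problem

Chronic inflammation shapes the onset and progression of knee
osteoarthritis (KOA), but which circulating inflammatory proteins act
causally — and through what intermediate molecular changes — cannot be read
off observational associations. Two-sample Mendelian randomization (MR)
addresses this by using genetic variants as instrumental variables:
because alleles are assorted randomly at conception, a variant that
raises a protein level is a natural experiment on that protein, immune to
the confounding and reverse causation that plague cohort studies.

`ratiomr` implements a complete MR screening and mediation cascade for
this setting: a panel of quantitative protein exposures, a panel of
quantitative protein-*ratio* mediators (ratio QTLs, which capture the
relative abundance of protein pairs), and a binary disease outcome on the
log-odds scale. Every stage operates purely on GWAS summary statistics —
per-variant effect sizes, standard errors and p-values — so no
individual-level data are required.

## The estimators

**Instrument selection.** For each exposure, candidate instruments are
variants with association p strictly below $10^{-5}$, pruned by greedy LD
clumping (keep the most significant variant, discard same-chromosome
variants within $\pm 10{,}000$ kb whose $r^2$ with it is $\ge 0.001$, and
repeat), and finally filtered on instrument strength
$F = \hat\beta^2/\mathrm{SE}^2 > 10$. Ties in the clumping order are
broken lexicographically by rsid so that results are reproducible
regardless of input row order. Variants missing from the LD reference are
treated as uncorrelated, with a warning — reference panels never cover
every variant.

**Harmonization.** Exposure and outcome effects are placed on a shared
effect-allele frame by an inner join on rsid; swapped-allele rows have the
outcome beta negated, rows matching neither orientation are dropped and
counted, and palindromic (A/T, C/G) variants are always excluded — with
strand unknown and allele frequency optional in our data model, no
frequency-based rescue is attempted. Strand mismatches are treated as
unmatched rather than complemented; this is conservative, and the dropped
counters make any future policy change observable.

**IVW.** The headline causal estimate combines per-variant Wald ratios
$r_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$ with weights
$w_j = 1/\mathrm{se}(r_j)^2$, where
$\mathrm{se}(r_j) = \mathrm{se}_{Y,j}/|\hat\beta_{X,j}|$ is the
first-order delta-method SE:
$$\hat\beta_\mathrm{IVW} = \frac{\sum_j w_j r_j}{\sum_j w_j},\qquad
\mathrm{se}_\mathrm{fixed} = \Big(\sum_j w_j\Big)^{-1/2}.$$
Heterogeneity is summarized by Cochran's
$Q = \sum_j w_j (r_j - \hat\beta)^2$ on $n-1$ df. The default mode is
multiplicative random effects: the fixed SE is inflated by
$\sqrt{\max(1, Q/\mathrm{df})}$, the common two-sample MR convention that
widens intervals under heterogeneity but never narrows them below the
fixed-effect SE. P-values use a normal reference; with one instrument the
estimate degenerates to the Wald ratio and heterogeneity is reported as
absent.

**MR-Egger.** Directional pleiotropy is probed by weighted least squares
of outcome on exposure effects with a free intercept (weights
$1/\mathrm{se}_{Y,j}^2$), after orienting each row so the exposure effect
is non-negative. A nonzero intercept indicates that instruments affect
the outcome through paths other than the exposure. Coefficient SEs are
scaled by $\max(1, \hat\sigma)$ and tested against a t reference with
$n-2$ df. At least three instruments are required.

**Outlier detection and removal.** When the Egger intercept is
significant at $\alpha = 0.05$, a simulation-based outlier test
(MR-PRESSO-style) runs: the observed residual sum of squares around
leave-one-out IVW slopes is compared with a parametric null in which
outcome effects are redrawn about their leave-one-out fits and exposure
effects about their observed values; per-variant outlier p-values are
Bonferroni-adjusted, flagged variants are removed, and IVW is re-run on
the remainder. The test is conservative by construction — the parametric
draws add fresh noise on top of already-noisy observed values, so the
simulated RSS stochastically dominates and the null rejection rate sits
below the nominal 5%. All of its knobs (simulation count, $\alpha$, seed)
are configurable and every run is bit-reproducible under a fixed seed.
Flagged pairs are *labeled* pleiotropic and re-estimated, never silently
dropped: retaining a visibly imperfect pair with its diagnostics is more
informative than discarding it.

**Colocalization.** Whether a mediator and the outcome share a causal
variant in a region is assessed with Wakefield approximate Bayes factors.
For a variant with estimate $\hat\beta$, variance $V$ and effect prior
variance $W$,
$$\log \mathrm{ABF} = \tfrac12\log\frac{V}{V+W} +
\tfrac12 z^2 \frac{W}{V+W}, \qquad z = \hat\beta/\mathrm{se}.$$
Per-variant log-ABFs for the two traits are combined, entirely in log
space, into posterior probabilities of the five single-causal-variant
hypotheses (PPH0: neither trait associated; PPH1/PPH2: one trait only;
PPH3: both, distinct variants; PPH4: both, shared variant), with per-SNP
priors $p_1 = p_2 = 10^{-4}$ and $p_{12} = 10^{-5}$. The H3 sum over
ordered distinct pairs is computed as the log-difference of
$\exp(S_1+S_2)$ and $\exp(S_{12})$, floored at $-\infty$ when numerically
non-positive, and is structurally zero for single-variant regions.
PPH4 > 0.75 is the conventional evidence bar. Prior effect SDs default to
0.20 for quantitative traits and 0.15 for binary (log-odds) traits; the
region is $\pm 500$ kb around the exposure's smallest-p variant. Both
choices are configurable — in particular the window, since genome-wide
versus cis-region colocalization is a genuine analysis decision.
Mediators that fail the bar are retained but labeled "coloc not
established": an unproven shared variant does not rule a causal
relationship out.

**Screening cascade and mediation.** The pipeline mirrors the standard
two-step design: (1) forward IVW MR of every exposure on the outcome,
keeping pairs with $P_\mathrm{IVW} < 0.05$; (2) reverse MR with the roles
swapped, excluding pairs whose reverse p is strictly below 0.05 (a pair
with reverse p exactly 0.05 is retained); (3) the identical bidirectional
screen for the mediator panel; (4) for each surviving exposure,
exposure-to-mediator MR with the same bidirectional filter, then
mediator-to-outcome MR with Benjamini–Hochberg FDR correction *within
that exposure's mediator family* (families are keyed by exposure id, never
by protein name), keeping adjusted p < 0.05; (5) colocalization of each
survivor; and finally (6) the two-step mediated proportion
$$\text{proportion} = 100\cdot\frac{\beta_1 \beta_2}{\beta}\ \%,$$
where $\beta_1$ (exposure→mediator), $\beta_2$ (mediator→outcome) and
$\beta$ (total, exposure→outcome) are three *univariable* IVW estimates —
two-step MR, not multivariable MR. The proportion is signed: a negative
value means the mediated path opposes the total effect. Proportions are
reported to three decimals; no SE or CI is attached (a delta-method or
bootstrap interval is a possible extension, deliberately out of scope).
Exposures whose post-harmonization instrument count falls below 2 are
excluded with an explicit reason — a single-instrument causal estimate has
no internal consistency check. Forward significance uses raw p < 0.05 at
the first gate; FDR applies at the mediator family stage.

```{r mediation-example}
# the published two-step estimates bundled with the package
tab <- read.delim(system.file("extdata", "koa_mediation_estimates.tsv",
                              package = "ratiomr"), check.names = FALSE)
m <- mediation(tab$beta1[1], tab$beta2[1], tab$total_beta[1])
m$proportion
```

## The synthetic study

Because the real pQTL/rQTL/KOA summary files are external accessions, the
package ships a generator that emulates their statistical structure so
every stage is exercisable offline.

The default scenario, chosen once to mirror the study conditions at desk
scale: 500 variants in AR(1) LD blocks of 10 (adjacent correlation 0.5);
a quantitative exposure X with 20 instrument variants; a quantitative
ratio mediator R with 15 own variants; two decoy mediators (5 variants
each, no exposure path, no outcome effect) for specificity testing; a
binary outcome Y with 5 own variants (so reverse-direction analyses are
estimable, as they are for a real disease GWAS); 50,000 samples per
cohort with disjoint cohorts per trait (the two-sample assumption,
enforced by independent noise streams); outcome case fraction 0.1997
(4462 cases / 22,347 total, the benchmark KOA GWAS split). Causal
variants sit one per block on common alleles (MAF 0.2–0.5) with effect
magnitudes 0.07–0.12, giving instrument z-scores around 9–16 — strong
instruments, so weak-instrument bias is negligible against Monte-Carlo
error at this scale. True effects default to $\beta_1 = -0.1$,
$\beta_2 = 0.2$, direct $= -0.12$, hence total $-0.14$ and a true
mediated proportion of $14.286\%$; the identity
$\beta = \text{direct} + \beta_1\beta_2$ holds for every generated
scenario by construction.

Sampling noise follows the summary-statistics likelihood: observed
z-scores are drawn as $z \sim N(R\,z_\mathrm{true},\, R)$ with $R$ the LD
matrix, so each marginal estimate has its nominal SE
($s/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$, with $s = 1$ for
quantitative traits and $1/\sqrt{\phi(1-\phi)}$ for the binary outcome)
while estimates at linked variants are correlated, as they are in real
data where neighbouring variants are tested in the same samples.
Independent per-variant noise — the tempting shortcut — decouples the two
traits' observed association peaks within a region and badly distorts
colocalization behaviour.

The ratio mediator is simulated directly as one Gaussian trait (a
log-ratio collapses to a single quantitative variable); the binary
outcome is handled on the log-odds scale through the case-fraction SE
inflation rather than by simulating case-control genotypes — the pipeline
only ever consumes summary statistics. What the generator deliberately
does *not* emulate: population structure, relatedness, gene–environment
interaction, INDELs/multi-allelics, and real LD panel error. Passing
tests therefore demonstrate correctness of the estimators and cascade
logic under the stated sampling model, not robustness to those
real-data pathologies.

```{r scenario, eval = FALSE}
sc <- simulate_mediation_scenario(seed = 42)
cfg <- screen_config(seed = 42)
run_pipeline(list(exposures = list(sc$exposure),
                  mediators = c(list(sc$mediator), unname(sc$decoys)),
                  outcome = sc$outcome, ld = sc$ld),
             cfg, "reports")
```

## Numerical and design notes

* All coloc mixture arithmetic uses log-sum-exp; posteriors sum to 1
  within $10^{-9}$ for every input.
* The clumping window is measured center-to-center from the index
  variant ("10,000 kb" read as $\pm 10$ Mb); the F-statistic is computed
  per variant on the exposure association after clumping, not as a joint
  F.
* Degenerate inputs have defined behaviour rather than crashes: empty
  screens produce explicit empty report tables; `alpha = 0` closes every
  gate; a zero total effect flags the mediated proportion as undefined.
* Report tables are byte-deterministic under a fixed seed. The run
  manifest records the config snapshot, seed, per-gate counts and input
  digests; its `generated_at` timestamp is the single intentionally
  non-reproducible line.
* Validation problem sizes, chosen as desk-scale study conditions: null
  calibration uses 200 replicate screens (100-variant scenarios) and 200
  outlier-test replicates at 300 simulations each; recovery uses 300
  replicate 500-variant scenarios; colocalization scenarios use 200-SNP
  regions with causal z = 8.
* Known small-sample behaviour, measured and accepted rather than hidden:
  the IVW estimand carries a ~1% attenuation toward the null under these
  conditions, the joint product of first-order ratio dilution (noise in
  the exposure denominators) and winner's curse from selecting
  instruments in the same sample that estimates them — both properties of
  the standard two-sample MR design itself. The outlier test's global p
  is conservative under the null, as noted above.
* rsid-lexicographic tie-breaks, substream-spaced RNG seeds (nearby
  scenario seeds share no noise stream), and strict-inequality thresholds
  throughout make every screening decision reproducible and auditable.
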