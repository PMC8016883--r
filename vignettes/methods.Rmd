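---
title: "Detecting local genetic correlation with scan statistics: model, null machinery, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local genetic correlation scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Two traits measured in two GWAS cohorts are modeled with bivariate
random SNP effects on standardized genotypes:

$$ y_1 = X\beta + \epsilon, \qquad y_2 = Z\gamma + \delta, $$

with $\mathrm{var}(\beta_i) = h^2_1/M$, $\mathrm{var}(\gamma_i) =
h^2_2/M$, and $\mathrm{cov}(\beta_i, \gamma_i)$ nonzero only for SNPs
inside a set of small, unknown signal regions. The working z-scores
are the score statistics $z_t = X^\top y_t / \sqrt{n_t}$. The package
does not estimate a per-region correlation; it *detects* the regions
and reports the sign.

For a window $R$ of consecutive SNPs the scan statistic is

$$ Q(R) = \frac{\sum_{i \in R} z_{1i} z_{2i}}
               {\left(\sum_{i \in R} l_i\right)^{\theta}}, $$

with $l_i$ the reference-panel LD score of SNP $i$. The denominator
exists because the expected magnitude of $\sum z_{1i}z_{2i}$ grows
with local LD even under the null; without it the scanner favors
high-LD regions regardless of biology.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `theta_grid` | 0.40–0.70 by 0.05 | — | penalty exponents searched; 0 ignores LD, 1 collapses the optimum to single SNPs |
| `window_step` | 10 | SNPs | window lengths restricted to multiples of 10, ~10x fewer candidates at minimal resolution cost |
| `max_window` | data-driven | SNPs | cap C = average SNP count per 1 Mb, rounded up to a multiple of 10 |
| `n_mc` | 5000 | draws | Monte-Carlo null sample size; 500–1000 is adequate for desk-scale studies |
| `alpha` | 0.05 | — | per-block family-wise level: the null quantile is the empirical 95th percentile of max-|Q| draws |
| `fdr_q` | 0.05 | — | Benjamini–Hochberg level over candidates pooled across blocks |
| `merge_gap_bp` | 100000 | bp | FDR survivors closer than this are merged |
| `maf_min` | 0.01 (0.05 in simulations) | — | panel MAF filter during harmonization |
| `ld_window_bp` | 1e6 | bp | LD-score window, ±0.5 Mb around the focal SNP |
| `chunk_bp` | 1e6 | bp | sampler chunk size for the tridiagonal approximation |
| `h2_floor` | 0.05 | — | lower clip on $1 - h^2$ so environmental variance stays positive |
| `cond_max` | 1000 | — | TSVD condition cap (strict) for chunk-matrix inversion |

## The Monte-Carlo null

Under the null the stacked z-score pair is asymptotically Gaussian
with per-trait covariance $(n h^2/M)\,\widetilde{V^2} + (1-h^2)V$,
where $V$ is the panel LD matrix and
$\widetilde{V^2} = \big((n_{\mathrm{ref}}-1)V^2 - mV\big)/(n_{\mathrm{ref}}-2)$
corrects the finite-panel bias of $V^2$. Sample overlap contributes a
cross-trait term $aV$ with $a = \rho_e n_s/\sqrt{n_1 n_2}$, estimated
from the intercept of the cross-trait LD-score regression. The
covariance is split into two additive, separately sampled components:
independent per-trait draws with $(1-h^2-|a|)V$ on the diagonal, plus
one shared draw $w \sim N(0, |a|V)$ added to both traits with equal
signs when $a>0$ and opposite signs when $a<0$. A unit test verifies
this split algebraically against the direct covariance for both signs
rather than trusting the derivation.

Sampling is chunked: within each LD block, 1 Mb chunks are drawn
sequentially, each conditioned on its predecessor through the standard
conditional Gaussian (cross-chunk covariance beyond adjacent chunks,
and across block boundaries, is set to zero). Chunk inverses use a
truncated SVD keeping the largest rank with condition number < 1000;
conditional covariances are symmetrized and eigenvalue-floored at 0.
Each pseudo z-score vector is affinely standardized, genome-wide per
trait, to the observed mean and variance.

**A design decision that changed during implementation.** The original
plan applied the $\widetilde{V^2}$ correction separately per chunk
(with $m$ = chunk SNP count) and per adjacent chunk pair. The two
corrections are mutually inconsistent, and at desk scale the implied
tridiagonal covariance became materially indefinite (worst relative
negative eigenvalue near 1), which distorts conditional draws after
flooring. The package instead computes $\widetilde{V^2}$ once per LD
block (with $m$ = block SNP count) and slices consistent diagonal and
cross-chunk sub-blocks from it; with this convention the measured
flooring is zero at the scales the tests run. The correction itself is
still exposed as `vtilde_sq(V, n_ref, m_used)` with a free `m_used`.

The conditional-distribution expression in the source derivation
carries a stray trailing factor in its covariance term, which we read
as a typographical slip; the implementation uses the standard
conditional Gaussian covariance and is checked against a moment
oracle (empirical covariance of 50,000 draws versus the directly
assembled tridiagonal covariance at 4 Monte-Carlo standard errors).

## Scanning, significance, FDR, and theta

Per block: find the maximal-$|Q|$ window (ties: smallest start, then
smallest length); if it reaches the null 95% quantile, record it with
the add-one Monte-Carlo p-value $p = (1 + \#\{Q^{null}_{max} \ge
|Q|\})/(1+B)$, remove its SNPs, and rescan the surviving contiguous
runs. The null max-|Q| distribution is computed once per block and
reused across peel-off iterations.

**Which candidates enter the FDR step.** Two readings were open: pool
only the windows that pass the per-block screen, or pool every
maximal window the peel-off examined. The first reading makes
Benjamini–Hochberg vacuous — if all n pooled p-values are below the
screening level 0.05, the step-up at q = 0.05 always rejects all of
them — and in the desk-scale FDR study it produced empirical FDR near
0.13, dominated by lone sub-0.05 false candidates from null blocks
surviving BH automatically. The package therefore pools, per block,
the peel-off discoveries *plus the final, non-significant maximal
window*, so the BH denominator counts every examined block;
sub-threshold candidates can never themselves be rejected (their p
exceeds q) but they restore the multiplicity accounting across
blocks. With this reading the empirical FDR in the same study drops
to ~0. BH-passing screened survivors are then merged by the 100 kb
rule (merging after FDR; the merged region inherits its members'
smallest p-value and the q-stat of largest magnitude).

$\theta$ is selected by running the full scan for each grid value
*with the same pseudo-sample draws* (so the choice reflects only the
statistic's behavior), estimating the fraction $\pi(\theta)$ of the
global genetic covariance attributable to the detected regions via a
two-annotation stratified LD-score regression (detected regions vs.
the remaining genome), and taking $\hat\theta = \arg\max
|\pi(\theta)|$. Conventions: $\pi(\theta) = 0$ when nothing is
detected; ties break toward smaller $\theta$; if no grid value detects
anything the grid midpoint (0.55) is reported with an empty result.
$\pi$ is numerically unstable when the global covariance is near zero;
the fit is flagged (`unstable`) rather than silently truncated.

## LD-score regression internals

Heritability: weighted regression of $z^2$ on $l$ with an
unconstrained intercept; $\hat h^2 = \text{slope} \cdot M/n$. The
default two-step weighting uses $1/(1 + (n\hat h^2/M) l_i)$ from a
first-pass OLS fit. Cross-trait: regression of $z_1 z_2$ on $l$;
slope maps to $\hat\rho_g$ and the intercept is the overlap plug-in
$\rho_e n_s/\sqrt{n_1 n_2}$. Standard errors come from a 200-block
delete-one jackknife over contiguous SNP blocks. Two degenerate-design
conventions: with *constant* LD scores the two-column design is
collinear, so the heritability fit falls back to the
constrained-intercept form ($E[z^2]-1$ on $l$), and the cross fit
attributes the whole mean product to the intercept (the conservative
reading for the null sampler, which then treats the signal as overlap
rather than genetic sharing). Estimates are reported raw (no [0,1]
truncation); only the null sampler clips, keeping $1-h^2 \ge 0.05$.

Binary traits use the liability-threshold conversions to the observed
scale (`observed_scale`, exact closed forms). Because the pipeline
estimates heritability from the binary-trait z-scores themselves —
which already live on the observed scale — no conversion happens
inside `run_scan`; the conversions are exported for users bringing
externally estimated liability-scale quantities. One robustness
guard: the auto-estimated overlap intercept is clamped (with a
warning) into the range compatible with a valid variance split, since
at small scale its estimation noise can exceed the admissible bound.

## The synthetic world

Real reference panels and HAPGEN-style simulators are replaced by a
mosaic copying process: a pool of 16 founder haplotypes whose internal
LD comes from thresholded AR(1) Gaussians (correlation
$e^{-d/10^5\,\mathrm{bp}}$), from which each new haplotype copies
segments, switching founders between adjacent SNPs with probability
$1-e^{-d/10^5\,\mathrm{bp}}$. This produces positive, distance-decaying
short-range LD (adjacent-SNP $r^2 \approx 0.5$ at 5 kb spacing,
near-zero beyond ~0.5 Mb) and a realistic MAF spectrum after the 5%
simulation-scale MAF filter. What it does **not** emulate: long-range
LD, population structure and admixture, mutation/genotyping error, and
the empirical human recombination map — so a green calibration test
establishes correctness of the procedure under well-behaved LD, not
robustness to structure.

Scale defaults are a deliberate desk-scale reduction of the source
setting (336,532 SNPs / 100,000 individuals on chromosome 1 reduced to
2,000 SNPs across 10 Mb / 2,000 per cohort / 500-individual panel)
with the architecture *proportions* preserved: 30% of heritability on
~1.5% of SNPs in the enrichment model; signal-region model with
$p = 0.3$ of $h^2$ in the correlated regions, effect correlation
$\rho = 0.9$, and per-trait $h^2$ defaulting to 0.05 (the upper end of
the per-chromosome range explored in the calibration studies). Five
signal regions are kept; their size shrinks to 40 SNPs so the signal
fraction of the genome stays within an order of magnitude of the
original. The LDAK-style architecture is represented by a
MAF-weighted variance model ($\propto (p(1-p))^{0.75}$), a labeled
stand-in, not the exact LDAK weights.

## Numerical and procedural choices

- Coordinates: 1-based positions in memory, BED 0-based half-open on
  all file boundaries.
- Window cap ties at the TSVD cutoff retain the component (strict
  `< 1000`).
- The empirical null quantile is the order statistic at
  $\lceil 0.95 B \rceil$.
- One global seed fans out to per-stage child seeds through a fixed
  integer map, so stages can be rerun in isolation; all derived seeds
  stay below $2^{31}$.
- Duplicate SNP ids keep the first occurrence (warned); mismatched
  (non-swap) alleles and strand-ambiguous SNPs are dropped with no
  rescue attempt.
- `z` vectors and panel are re-oriented to the *panel's* allele
  coding after cross-study alignment: both z-scores flip together, so
  products are unchanged while cross-SNP signs stay consistent with
  the panel LD used by the null sampler.

## Calibration evidence and limitations

The acceptance tests reproduce, at desk scale: family-wise error of
the per-block screen on a global-null world (200 replicates, bound
$0.05 + 3\sqrt{0.05 \cdot 0.95/200}$); FDR of BH-passing regions with
planted signal in 2 of 10 blocks (100 replicates); hold-out coverage
of the null 95% quantile; and a property suite (exhaustive-search
equivalence, sampler moment matching, parameter recovery, the
whole-genome $\theta = 1$ covariance identity, antisymmetry, liability
constants, BH oracle equivalence, G-score hand cases, and power
monotonicity in $h^2$ over {0.01, 0.03, 0.05} with common random
numbers). Pilot runs place the family-wise rate near 0.06–0.07 at
$B = 1000$: the excess over the nominal 0.05 traces to Monte-Carlo
noise in the estimated null quantile (it persists when the true
heritabilities are supplied), shrinks with $B$, and sits within the
stated binomial allowance.

Known limitations: no analytic null (Monte-Carlo only); no per-region
correlation estimate; two traits only; $\pi(\theta)$ undefined in any
useful sense when global covariance vanishes; the desk-scale world has
short LD blocks, so the block-tridiagonal approximation is easier here
than on real chromosomes.
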