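---
title: "Probabilistic principal component models for spectral-bin data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic principal component models for spectral-bin data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probpca)
```

## The models

Binned NMR metabolomic data arrive as an $n \times p$ matrix of bin
intensities with $n \ll p$: tens of spectra over one or two hundred
0.04-ppm bin regions. Conventional PCA is the dominant analysis but has
no underlying statistical model, so there is no principled way to choose
the number of components, no uncertainty attached to scores or loadings,
and no route to extensions. This package works with the probabilistic
formulation instead.

**PPCA.** Each spectrum is modelled as
$x_i = W u_i + \mu + \epsilon_i$ with latent scores
$u_i \sim N_q(0, I)$ and isotropic noise
$\epsilon_i \sim N_p(0, \sigma^2 I)$, so marginally
$x_i \sim N_p(\mu,\, WW' + \sigma^2 I)$. The MLE of the $p \times q$
loadings matrix $W$ spans the conventional PCA subspace, so nothing
familiar is lost; what is gained is the latent posterior
$u_i \mid x_i \sim N_q(M^{-1}W'(x_i - \mu),\, \sigma^2 M^{-1})$ with
$M = W'W + \sigma^2 I$, whose covariance quantifies score uncertainty
(drawn as 95% posterior ellipses), and a likelihood on which model
selection and resampling inference can operate.

**PPCCA.** Subject covariates $C_i = (1, c_{i1}, \dots, c_{iL})'$ are
allowed to shift the latent means: $u_i \sim N_q(\delta_i, I)$ with
$\delta_i = \alpha C_i$. Row $k$ of the $q \times (L{+}1)$ matrix
$\alpha$ is the intercept and per-covariate slopes for latent dimension
$k$, directly interpretable as the covariate's effect on that principal
direction. The latent posterior mean becomes
$M^{-1}[W'(x_i - \mu) + \sigma^2 \delta_i]$: a sample's score reflects
both its spectrum and its covariates.

**MPPCA.** A $G$-component mixture in which component $g$ carries its
own loadings $W_g$ and mean $\mu_g$ while $\sigma^2$ is shared across
groups for parsimony. Fitting yields posterior membership
probabilities $\hat z_{ig}$, so clustering and per-group dimension
reduction happen simultaneously; samples are assigned by maximum
posterior probability.

## Estimation

PPCA and PPCCA are fitted by EM, MPPCA by the two-cycle AECM algorithm
(first cycle: membership E-step, then mixing proportions and means;
second cycle: membership plus latent scores, then loadings and the
shared noise variance). All likelihood evaluations go through the
$q$-dimensional Woodbury forms — no $p \times p$ matrix is ever
inverted — and when $p > 1.5\,n$ the PPCCA iteration runs in the
$\min(n,p)$-dimensional row space of the centred data, which is exact
because every EM iterate of $W$ lies in that subspace.

Convergence is assessed by Aitken's acceleration: the run stops when the
accelerated estimate of the limiting log-likelihood is within `tol`
(default `1e-4`) of the current value. EM's log-likelihood trace is
non-decreasing by construction, and the test suite asserts this with an
absolute slack of `1e-8` on every recorded trace.

Three numerical choices deserve mention:

* **Identifiability.** The likelihood determines $W$ only up to an
  orthogonal rotation. Every fitted loadings matrix is canonicalised to
  principal-axes form (SVD, columns by decreasing singular value, the
  largest-magnitude entry of each column positive), which makes the
  output coincide with conventional PCA loadings; for PPCCA the same
  rotation is applied to $\alpha$ so the fitted latent means are
  unchanged.
* **The PPCCA intercept.** The likelihood is flat along
  $(\alpha_0, \mu) \mapsto (\alpha_0 + a,\, \mu - W a)$, so jointly
  updating both would leave the intercept column of $\alpha$ at an
  arbitrary point of that ridge (and make its resampling variance
  meaningless). The package therefore fixes $\mu$ at the sample mean,
  exactly as in PPCA; on centred data the fitted intercepts are
  consequently near zero and the slopes carry the covariate story.
* **Noise floor.** $\sigma^2$ is floored at `1e-10`; touching the floor
  flags the fit as singular rather than failing, which feeds into model
  selection below.

## Model selection

Model choice — $q$, and for mixtures $(q, G)$ — maximises
$\mathrm{BIC} = 2\ell - K\log n$ over a fit grid
(`select_model()`). With $n \ll p$ the plain criterion is fragile: the
ML estimate of $\sigma^2$ can collapse towards zero for some grid
cells, producing divergent likelihoods and erratic BIC values. The
selection criterion therefore evaluates the likelihood at the MAP
estimate of $\sigma^2$ under a conjugate inverse-gamma prior, whose
M-step posterior mode is
$(\mathrm{RSS}/2 + b)\,/\,(np/2 + a + 1)$ — strictly positive, so the
criterion stays finite where the MLE degenerates, and indistinguishable
from plain BIC when $n$ is large (the test suite checks agreement to
0.1% at $n = 500$).

Two open choices and their defaults:

* **Prior hyperparameters** (unstated in the field's practice): shape
  $a = 3$ and scale $b = 2\bar v$ with $\bar v$ the mean per-bin sample
  variance — weakly informative, prior mode at half the data's average
  variance scale. Both are arguments of `sigma2_prior()`.
* **Parameter count $K$**: raw counts ($pq + p + 1$ for PPCA, plus
  $q(L{+}1)$ for PPCCA, $(G-1) + G(pq+p) + 1$ for MPPCA) by default;
  `count_params(convention = "rotation-corrected")` subtracts the
  $q(q-1)/2$ rotational redundancy, since the two conventions can
  select different $q$.

`proportion_variance()` reports the conventional eigenvalue ratio by
default; the model-based ratio
$\mathrm{tr}(WW')/(\mathrm{tr}(WW') + p\sigma^2)$ is available by
passing the fitted model.

## Jackknife inference

Loadings (and PPCCA regression parameters) get standard errors by
leave-one-out resampling: the model is refitted $n$ times with sample
$i$ removed, and
$\mathrm{SE}(\hat w_{jk}) = \sqrt{\tfrac{n-1}{n}\sum_i (w_{jk}^{-i} -
\bar w_{jk})^2}$, with 95% CIs as estimate $\pm\, 1.96\,$SE
(a $t$-quantile alternative is exposed via `ci = "t"`). Three details
matter far more than the formula:

* **Refit starts.** PPCCA refits are warm-started at the full-data
  estimates, which is what makes $n$ EM runs affordable. For plain PPCA
  the leave-one-out MLE is available in closed form, so each refit
  starts from the leave-one-out eigendecomposition — the same
  estimator, computed exactly and faster than travelling there by
  warm-started EM, whose rotational modes converge at rates around 0.99
  when $n \ll p$.
* **Canonicalisation and alignment.** Each leave-one-out fit is passed
  through the same canonicalisation as the full fit and then
  sign-aligned (optionally Procrustes-aligned) to the full-data
  loadings before the SE formula is applied. Without this, column sign
  flips make the SEs explode, and *with* alignment but *without*
  canonicalisation the SEs miss the wobble of the principal-axes basis
  itself, which simulation shows is a real component of the sampling
  variance of rotation-sensitive parameters.
* **Failures.** A refit that does not converge (or hits the noise
  floor) is excluded with a warning when at most 5% of refits are
  affected; beyond that the jackknife aborts.

Downstream, `significant_loadings()` intersects "CI excludes zero" with
an absolute-loading cutoff, `cutoff_frequency()` tabulates how many
significant bins survive each candidate cutoff (the choice of cutoff is
deliberately left to the analyst), and `group_bin_tests()` runs Welch
t-tests with Benjamini–Hochberg adjustment on the selected bins. Welch
and BH are defaults chosen where practice varies; both are arguments.

## Synthetic data: what it emulates and what it does not

`generate_ppca()`, `generate_ppcca()` and `generate_mppca()` draw from
the exact generative models with controlled spectra: random orthogonal
loading directions with fixed column norms
$\lVert w_j \rVert^2 = \mathrm{eigengap} \cdot \sigma^2 (q - j + 1)$,
so the population covariance eigenvalues sit at known heights above the
noise floor and recoverability of $q$ is a dial, not an accident.

Two fixtures mirror the shapes of real binned-NMR studies:

* `generate_urine_like()`: $18 \times 189$, 9 treated vs 9 control,
  five signal dimensions, 17 designated bins carrying the treatment
  direction with large PC1 loadings, and a body-weight covariate acting
  on dimension 2 only. Intensities are an exponentiated scaled Gaussian
  field — positive and log-normal-ish, a deliberate mild
  misspecification stressor, since real bin intensities are positive
  and skewed while the model is Gaussian. The latent effect sizes
  (group separation 4 latent sd on dimension 1; weight slope 2) and the
  eigen-structure spacing were chosen once, from conditioning analysis,
  so that the principal axes are stably identified at $n = 18$: with
  near-tied eigenvalues the leading axes mix and no bin-selection
  procedure can be expected to isolate the planted set.
* `generate_brain_like()`: $33 \times 164$ in four groups (8/8/9/8)
  with group means 12 noise-sd apart — far enough that a mixture fit at
  $G = 4$ should recover the partition exactly, which is what the
  acceptance suite requires.

Passing tests on these fixtures shows the estimation and inference
machinery does what it claims under the stated models plus mild
positivity distortion. It does not show robustness to what the
generators leave out: chemical-shift variation across samples, baseline
artefacts, peak overlap, heteroscedastic bin noise, or covariates
correlated with treatment.

## Simulation scales used by the test suite

The acceptance checks run at deliberately chosen scales: EM-vs-oracle
equivalence on twenty $50 \times 20$ datasets; covariate-effect
recovery and CI calibration over 200 replicates at
$n = 100, p = 30, q = 2$ (coverage is checked against a
[90%, 99%] band at the 95% nominal level); selection consistency over
50 replicates with the weakest signal eigenvalue at $17\sigma^2$ —
at $n = 50, p = 100$ the Marchenko–Pastur bulk edge sits near
$5.8\sigma^2$, so weaker spikes are information-theoretically invisible
and consistency should not be expected of any criterion below that
edge; and ten end-to-end runs on each study-shaped fixture. On small
$n \ll p$ problems the ML fit can capitalise on chance alignment
between covariates and latent scores, so occasional spurious covariate
significance on non-planted dimensions is expected behaviour at
$n = 18$, and the workflow checks target the planted dimension rather
than asserting a clean null everywhere.

## Known limitations

* Missing values are rejected, not imputed; EM-based imputation is
  possible in principle but out of scope.
* The mixture model shares one $\sigma^2$ across groups and one $q$;
  per-group noise or dimension is not offered.
* Covariates enter linearly and must be supplied numeric; categorical
  covariates need user-constructed dummies.
* Mixtures of PPCCA (covariates inside a mixture) are not implemented.
* The jackknife assumes the full-data fit is a stable optimum; on data
  where leave-one-out fits routinely fail to converge the SEs are not
  reported.
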