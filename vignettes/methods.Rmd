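---
title: "One-class VAE scoring and CRSD clustering: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class VAE scoring and CRSD clustering: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the generative model and scoring rule, the statistical
distance used for clustering latent posteriors, the synthetic data that
stands in for clinical images, and the numerical and design choices
that were genuinely open.

## 1. The one-class model

Cervical-cytology screening data are dominated by normal (NILM) cells;
abnormal labels are scarce and noisy. We therefore model the normal
class only. Each cell crop $x$ (a 64×64×3 window centred on the
nucleus) is assumed generated from a latent variable
$z \in \mathbb{R}^d$ with standard-normal prior $p(z)$, and a
probabilistic encoder approximates the posterior by a diagonal Gaussian
$q(z\mid x) = N(\mu(x), \mathrm{diag}\,\sigma^2(x))$. Latent draws use
the reparameterisation $z = \mu(x) + \sigma(x)\odot\epsilon$.

Training minimises the negative evidence lower bound with three
interchangeable objectives:

* plain VAE: $L_r + \mathrm{KL}(q(z\mid x)\,\|\,p(z))$;
* $\beta$-VAE: $L_r + \beta\,\mathrm{KL}$;
* $\beta$-TCVAE: $L_r + \alpha\,I_q(z;x) + \beta\,\mathrm{TC}(z) +
  \gamma \sum_j \mathrm{KL}(q(z_j)\|p(z_j))$,

where $\mathrm{TC}$ is the total correlation of the aggregate
posterior. Penalising the total correlation specifically pushes the
latent dimensions towards independence, which is what makes individual
dimensions interpretable (nucleus size, brightness, hue, ...) in
traversals.

The reconstruction term $L_r$ is a Gaussian likelihood with fixed unit
variance on $[0,1]$ pixels, i.e. half the summed squared error. A
Bernoulli likelihood is the common alternative for binarised images;
for continuous RGB stain data the Gaussian choice is conventional, and
nothing downstream depends on the constant it drops.

**Scoring.** The VAE objective nominally pulls the aggregate posterior
towards $N(0, I)$, but augmentation and finite training leave the
normal class displaced from the prior. The score therefore never uses
the prior: a full-covariance Gaussian $N(\hat\mu, \hat V)$ is estimated
from latent means of normal cells *held out from encoder training*
(`gaussian_x` in `vae_occ()`), and a cell is scored by the negative
log-likelihood of its latent under that fitted density. The scored
latent is the posterior mean by default (deterministic reports); a
sampled latent is available via `predict(..., score_latent =
"sample")`, since the literature is not explicit on this point.

**Threshold metrics.** The score is a ranking; AUROC needs no
threshold. When accuracy/F1/sensitivity/specificity are requested, the
threshold maximises Youden's J on a validation split (or, absent one,
on the evaluation scores), a standard choice where the original
procedure is unstated; it is configurable via `threshold =`.

## 2. The network and its training

No deep-learning framework is assumed. The encoder and decoder are
fully connected — one hidden ReLU layer of width 256 on each side, with
linear heads for $\mu$ and $\log\sigma^2$ and a sigmoid pixel output —
written directly in R with analytic gradients and an Adam optimiser
(learning rate $10^{-3}$, batch 64). The gradients of all three
objectives, including the total-correlation estimator, are verified
against finite differences in the test suite; that check, not
convention, is what makes the hand-derived training loop trustworthy.
A convolutional architecture would be the natural choice at larger
scale; for 64×64 crops and desk-scale sample sizes the dense network
trains in seconds per epoch on one CPU and is exactly differentiable by
hand, which we value more here than parameter efficiency.

The encoder outputs log-variance and $\sigma = \exp(\tfrac12
\log\sigma^2)$, guaranteeing positivity; log-variance is clamped to
$\pm 30$ purely as an overflow guard (inactive in practice, and the
clamp's zero-gradient region is accounted for in the backward pass).

**Total-correlation estimator.** The three $\beta$-TCVAE terms are
intractable exactly and are estimated from the minibatch by
importance-weighted sampling: the aggregate posterior at $z_i$ is
approximated by $\sum_j W_{ij}\, q(z_i \mid x_j)$ with weights that sum
to one per row — the own-sample component gets weight $1/N$ ($N$ the
dataset size, passed explicitly), one stratum element absorbs
$(N-M+1)/(N(M-1))$, and the remaining $M-2$ elements get $1/(M-1)$.
With these weights the estimator is exact in the full-batch limit, the
decomposition telescopes to $\log q(z\mid x) - \log p(z)$ per sample
(so at $\alpha=\beta=\gamma=1$ it matches the plain KL in expectation),
and a batch of prior-collapsed posteriors yields terms at numerical
zero. A batch of one sample leaves the estimator undefined and is
refused with guidance.

**Determinism.** All randomness (initialisation, shuffling,
augmentation draws, reparameterisation noise) flows from the single
`seed` in `vae_config()`; pure-R arithmetic on one thread makes
repeated fits bit-identical, which the tests assert.

## 3. Data handling and augmentation

Annotated cells are kept only if their centre lies at least 128 px from
every image border (half-open comparison: `margin <= c < side -
margin`), which guarantees a full 256-px window exists; the model input
is the centred 64×64 window, equal by construction to "crop 256 then
centre-crop 64". Coordinates are 0-based with x = column.

Three augmentation regimes mirror plausible microscope-acquisition
variation: `none`; `fa` — random horizontal/vertical flips (p = 0.5
each), rotation uniform in [0°, 360°), translation uniform within ±10%
of the side; `fab` — `fa` plus a multiplicative brightness factor
uniform in [0.8, 1.2]. The magnitudes are declared defaults
(configurable in `augmentation_mode()`), chosen to perturb pose and
illumination without distorting the data distribution the generative
model must learn. Geometry is applied as a *single* affine resampling
pass (flips, rotation about the image centre and translation composed
into one matrix, bilinear interpolation), so flips and axis-aligned
rotations are exact on the pixel grid. During training the transform is
applied to the larger source crop before the 64-px centre crop, so
rotation never imports background into the model's field of view; the
standalone `augment()` reflection-pads first for the same reason.

## 4. CRSD: distance between latent posteriors

Each image's representation is a distribution, not a point. For
densities $p, q$ and a reference $r$ the cross-entropy-based referenced
statistical distance is

$$ d(p, q; r) = \lvert \mathrm{CE}(r, q) - \mathrm{CE}(r, p) \rvert,
   \qquad \mathrm{CE}(r, q) = -\mathbb{E}_r[\log q], $$

summed over a finite reference set $R$. We fix the conventional sign
$\mathrm{CE} = -\int r \log q$ (so $\mathrm{CE}(r,q) \ge H(r)$ by
Gibbs' inequality); every property used — symmetry, non-negativity,
zero at $p = q$, triangle inequality — is invariant to that sign
choice. The function is a *pseudometric*: unit-covariance Gaussians
with means $+\mu$ and $-\mu$ are at distance zero from each other
against a reference centred at the origin, a case both the tests and
the acceptance script reproduce exactly. For Gaussians the
cross-entropy has the closed form
$\tfrac12[\log\det(2\pi\Sigma_q) + \mathrm{tr}(\Sigma_q^{-1}\Sigma_r) +
(\mu_r-\mu_q)^\top \Sigma_q^{-1} (\mu_r-\mu_q)]$, which
`crsd_matrix()` vectorises over diagonal posteriors.

Choices that were open:

* **Reference set** — the posteriors of the evaluated fold serve as
  their own references, tying $R$ to the data split; a seeded
  subsampling cap (`max_ref`) bounds the $O(n^2 |R|)$ cost for large
  folds.
* **Linkage** — average linkage for the CRSD run: Ward and centroid
  linkages require coordinates, which a precomputed pseudometric does
  not provide. The Euclidean agglomerative baseline uses Ward
  (`ward.D2`), the common library default for coordinate data.
* **Baselines** — k-means (10 restarts), spectral clustering
  (`kernlab::specc`) and DBSCAN (eps 0.5, minPts 5, the usual library
  defaults) all operate on posterior means as fixed points. DBSCAN is
  implemented in the package (no R implementation is available among
  the declared dependencies); noise points become singleton clusters so
  every sample carries a label in the entropy metrics.
* **Tie-breaking** — `stats::hclust` merges the first minimal entry in
  scan order, making the clustering deterministic for a given matrix.

Cluster quality uses the entropy-based homogeneity, completeness and
V-measure, with the standard degenerate conventions (single true class
$\Rightarrow h = 1$; single predicted cluster $\Rightarrow c = 1$).

## 5. The synthetic cell generator

`generate_population()` renders single-cell crops: an anti-aliased
elliptical nucleus (controllable radius, eccentricity, gray level,
orientation) on a cytoplasm disc of controllable hue, on a white
background, with multiplicative brightness, additive Gaussian pixel
noise, and clipping to $[0,1]$. The abnormal class defaults to nucleus
radius ×1.5, intensity −0.2 and eccentricity +0.2 relative to normal —
the enlarged, hyperchromatic, irregular nucleus that constitutes the
cytological abnormality signal. Normal phenotype defaults (radius
10 ± 1.5 px at a 256-px crop, intensity 0.45 ± 0.05, eccentricity
0.3 ± 0.1, hue uniform over [180°, 330°], brightness 1 ± 0.05, noise
0.02) were fixed once as a plausible stained-cell regime in which the
nucleus and its immediate surroundings fill the 64-px model window.

What this emulates: the factor structure a disentangling VAE should
recover (nucleus morphology, brightness, hue), a class contrast carried
by nucleus morphology, CRIC-style annotation tables, and deterministic
regeneration from a seed. What it does not emulate: staining texture
and chromatin patterns, overlapping cells and clumps, imaging artefacts,
multi-cell scenes, or the label noise of real cytology. Passing tests
on this generator therefore demonstrate that the pipeline's machinery
is correct and that it recovers a known morphological contrast; they do
not certify clinical performance, which requires real stained-cell
data at full training scale.

Latent-posterior fixtures (`generate_latent_fixture()`) provide the
analogous ground truth for the clustering stack: labelled mixture
components controlling both the spread of posterior means and the
per-point posterior standard deviations, so one can construct cases
where the uncertainty itself carries the group structure — there,
clustering distributions (Agg-SM) is compared directionally against
clustering their means (Agg-EM).

## 6. Numerical choices and degenerate inputs

* Covariance estimation is unbiased ($n-1$); with fewer than $d+1$
  samples the estimate falls back to its diagonal. A ridge of
  $10^{-6}\,\mathrm{tr}(V)/d$ (configurable) keeps $\hat V$ positive
  definite in small folds; a singular covariance without ridge is an
  error that suggests one.
* Scores and cross-entropies are evaluated through Cholesky factors and
  triangular solves; tests cross-check them against an independent
  solve/determinant route at $10^{-8}$ and against Monte-Carlo
  integration at three standard errors.
* AUROC uses midranks (Mann–Whitney), so ties and monotone transforms
  behave correctly; identical score multisets give exactly 0.5.
* KDE summaries (`pairwise_density_summary`) use the normal-reference
  bandwidth and a 100×100 grid over ±4 pooled standard deviations;
  groups with fewer than two samples are skipped with a warning.
* Traversals use the decoder mean (no sampling) on an inclusive
  10-point grid from −4 to +4 standard deviations, so figures are pure
  functions of `(center, stddevs, dim, steps, span)`.

## 7. Problem sizes in the shipped tests

The test-suite study conditions were fixed once: the end-to-end
one-class check trains the default configuration ($\beta$-TCVAE,
$\beta = 4$, $d = 8$, flip/affine/brightness augmentation) on 200
synthetic normal crops for 20 epochs and scores 30 held-out normals
against 60 abnormals, asserting AUROC ≥ 0.95 and strict improvement
over the same architecture with untrained weights; the directional
clustering comparison uses 60 posteriors in $d = 8$ over 10 seeds;
property suites use 1000 random Gaussian triples and $10^5$–$10^6$
Monte-Carlo draws. Smaller editions of the same pipeline (96-px crops,
32-px model window, 6 epochs) back the unit tests.

## 8. Known limitations

* The dense encoder trades representational power for exact
  hand-derived gradients; real Pap-smear data at full scale would
  favour a convolutional architecture and a GPU framework.
* The score is unimodal by construction: a single Gaussian over normal
  latents cannot represent strongly multi-modal normality.
* CRSD clustering costs $O(n^2|R|)$; beyond a few thousand posteriors
  the seeded reference subsampling is a practical necessity.
* Scores are not calibrated probabilities, and the model does not grade
  abnormality subtypes; retrieval of same-cluster images
  (`query_cluster`) is the intended aid for that judgement.
* Batch effects between cohorts shift latent distributions; the package
  deliberately re-estimates the normal-class Gaussian per cohort, but
  no latent-space batch correction is attempted.
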