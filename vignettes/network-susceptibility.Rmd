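---
title: "Network susceptibility models for case-control morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network susceptibility models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the two
susceptibility models, the spatial null, the harmonization step, the
synthetic cohort the validation suite runs on, and the numerical and design
choices that were genuinely open.

## The two models

Both models ask whether a regional alteration map — a case-control *t* map
of cortical thickness (CT), surface area (SA) or subcortical volume (SV)
over a fixed parcellation — is organized by normative connectome
architecture.

**Hub vulnerability.** Weighted degree centrality of region $j$ is the sum
of its connection weights, $g_j = \sum_k w_{jk}$, computed separately on the
cortico-cortical block (cortical maps) and the subcortico-cortical block
(subcortical maps) of an unthresholded connectivity matrix. The model
statistic is the Pearson correlation between the reduction-oriented
alteration map and the centrality map. Sign conventions matter and are fixed
package-wide: group *t* maps are *reduction-positive* (contrast control
minus patient), subject z maps are raw (negative = thinner than expected),
and every operation that mixes the two applies an explicit sign flip
(`subjectNetworkScores()` correlates $-z$ with centrality so the subject
score has the same orientation as the group statistic). Robustness variants
use eigenvector, betweenness and closeness centrality; the path-based
metrics interpret weights as strengths via the inverse-weight length
$\ell_{jk} = 1/w_{jk}$, the dominant convention in the field's toolboxes.

**Epicenter mapping.** For each seed region, the Pearson correlation between
its normative connectivity profile (the seed's full row of the
cortico-cortical block — including its own zero self-entry, the toolbox
convention; an excluding-self variant sits behind `excludeSelf = TRUE`) and
the cortical alteration map. Seeds are ranked by signed descending $r$
(all reported epicenters in the literature the package follows have positive
$r$, making signed and absolute ranking coincide in practice), and
significance requires the spin p-value to survive Bonferroni correction over
the number of seeds (68 cortical, 14 subcortical) at $\alpha = 0.05$.

## The spatial null

Parcel-level brain maps are spatially autocorrelated, so naive correlation
p-values are inflated. The spin permutation null rotates one map on the
cortical sphere: a uniformly random rotation (QR decomposition of a Gaussian
matrix, determinant fixed to $+1$) is applied to the left-hemisphere
centroids and its x-mirror to the right hemisphere, keeping the two
hemispheres anatomically matched; each parcel is then reassigned the value
of the nearest original centroid within its hemisphere (great-circle
distance), so values may repeat or drop. Subcortical structures have no
spherical embedding; their null shuffles labels uniformly.

P-values use the add-one rule, $p = (1 + \#\{|r_{null}| \ge |r_{obs}|\}) /
(n_{perm} + 1)$, so they are never zero; the default is two-tailed (the
tail is exposed as an argument since signed one-tailed tests are sometimes
wanted). The null index table is a first-class object (`SpinNull`) that can
be written to TSV and reused, so one null family serves every map
comparison in an analysis — this also makes repeated analyses cheaper and
exactly reproducible.

**Geometry.** Each hemisphere's parcel centroids live on its own *full*
unit sphere (a Fibonacci lattice; the right hemisphere is the x-mirror of
the left). This is the standard inflated-sphere representation a spin test
operates on, and it is essential for calibration: if centroids occupy only
a half-sphere cap, a uniform rotation pushes roughly half of them off the
cap, the nearest-centroid rule clamps them to the cap boundary, the rotated
map loses its spatial autocorrelation, and the test becomes
anticonservative. Distances between hemispheres (needed by the smoothing
kernel and the synthetic connectome) are computed homotopically: right
centroids are folded onto the left sphere via the mirror and a fixed
interhemispheric offset of 0.5 rad is added, so homotopic parcels are close
but not coincident.

## Harmonization

Multi-site morphometry carries scanner/site batch effects in both location
and scale. `combatFitTransform()` implements parametric empirical-Bayes
ComBat: per region, values are standardized under a covariate model, site
location ($\gamma$) and scale ($\delta$) effects are estimated and shrunk
toward normal / inverse-gamma priors whose hyperparameters are
moment-matched across regions (iterative joint solver, tolerance $10^{-6}$,
at most 100 iterations), and adjusted values are restored with covariate
effects re-added. Three commitments:

- **Diagnosis is always in the preservation design**, so removing site
  cannot remove the case-control effect estimated downstream.
- A **single-batch** table is returned unchanged — there is nothing to
  remove, and standardize/restore round-trips would otherwise inject pure
  numerical noise.
- The fitted `CombatModel` (EB estimates and hyperparameters) is returned
  for audit; `siteVarianceCheck()` quantifies residual site variance as the
  partial $R^2$ of the site factor in nested per-region linear models.

One property the canonical algorithm does *not* have is exact idempotence:
EB shrinkage leaves a residual batch effect of order
$\delta(\hat\gamma - \bar\gamma)/(\tau^2 n)$ that a second application
partially removes. On the validation cohorts this second-pass change is of
order $10^{-3}$ mm. The implementation agrees with the reference
implementation in the `sva` package to $\sim 10^{-9}$, confirming the
behaviour is intrinsic to empirical Bayes, not an implementation artifact.
Non-parametric EB (likelihood-weighted posterior over the leave-one-out
empirical prior) is available behind `parametric = FALSE`.

## Group and subject models

Per-region OLS (`value ~ diagnosis + age + sex`) yields the reduction-
positive *t* map with two-sided p-values, Benjamini-Hochberg q-values, and
Cohen's $d = t\sqrt{1/n_1 + 1/n_2}$. Covariates are fixed to age and sex;
no intracranial-volume correction is applied. Subject-level abnormality
maps fit the same covariate model in *controls only* and score each patient
as $z = (\text{observed} - \text{predicted})/\mathrm{SD}(\text{control
residuals})$ — raw residual SD, not a prediction-interval (w-score)
variant, a choice made explicit because the two differ slightly for
covariate values far from the control mean.

Subject network scores are per-patient correlations of the sign-flipped z
map with centrality (hub score) and with every seed's connectivity profile
(epicenter likelihoods). No per-subject permutation significance is
computed by default: group-level nulls do not transfer to single subjects,
and per-subject spins are expensive; the clinical value of the scores lies
in their covariation with symptoms, tested by `clinicalAssociation()` with
Bonferroni correction over the tests actually run (tests with fewer than 10
complete pairs are skipped and logged). Robustness of any statistic can be
assessed by `stabilityResample()` — repeated subsampling without
replacement, by default 100 rounds at 80% of the sample.

## Cross-disorder comparison

Epicenter maps of two disorders are compared two ways: map-level spatial
overlap (correlation of the two per-seed $r$ maps, spin or shuffle p), and
per-region differences of dependent overlapping correlations with Zou's
modified-asymptotic 95% CIs (the two correlations share the seed's
connectivity profile). The sample size entering the CI is the number of
parcels in the spatial correlation (68), *not* subject counts — the
comparison is between map-level correlations, and this choice is recorded
in the output metadata (`attr(x, "n")`). Classification follows set logic:
`unique:<D>` requires significance only in D *and* every pairwise CI
against the other disorders to exclude 0; `shared` requires significance in
at least two disorders with the corresponding CI including 0; regions
significant in a strict subset of more than one stage/disorder without CI
support fall to `none`. For three-way comparisons the smallest absolute
pairwise difference and its CI are reported per region.

Disease stages partition patients by duration of illness — first-episode
(≤ 1 month), early (> 1 month, < 2 years), chronic (> 20 years) — with all
controls retained in every subset; the divergent/convergent taxonomy over
stage-wise epicenter significance uses the same set logic.

## The synthetic cohort generator

Nothing in the package's validation relies on real participant data. The
generator (`GenerativeConfig()`, `generateParcellation()`,
`generateConnectome()`, `plantEffectMap()`, `generateCohort()`) emulates:

- a Desikan-Killiany-style layout (34 cortical parcels per hemisphere plus
  14 bilateral subcortical gray-matter structures: thalamus, caudate,
  putamen, pallidum, accumbens, amygdala, hippocampus);
- a hub-structured connectome: weights decay exponentially with geodesic
  centroid distance (rate 3.5 per radian), are multiplied by node gains
  (2.5 for a deterministic, hemispherically mirrored hub set covering 15%
  of parcels) and by lognormal edge noise (log-SD 0.1); functional and
  structural matrices share hubs and kernel but have independent noise;
  subcortical regions participate through interior pseudo-centroids (norm
  0.3) used only to define weights, never for spins;
- a planted effect map $\Delta_j = b_{epi}\,\bar c_{jE} + b_{hub}\,\tilde
  g_j + \varepsilon_j$ (clipped at 0), where $\bar c_{jE}$ is min-max
  normalized mean connectivity to the planted epicenter set $E$ (default:
  bilateral entorhinal) and $\tilde g_j$ min-max normalized degree;
  defaults $b_{epi} = 0.4$ mm, $b_{hub} = 0.2$ mm, spatial noise SD 0.03 mm;
- a 26-site cohort of 2439 patients and 2867 controls: control values are
  baseline (2.5 ± 0.15 mm) plus age (−0.005 mm/yr) and sex (+0.02 mm male)
  effects plus per-site location shifts (SD 0.1 mm) and residual-scale
  multipliers (0.8–1.25) on subject noise (SD 0.05 mm); patients
  additionally lose $s_i \Delta_j$ with lognormal severity $s_i$ (median 1,
  log-SD 0.1);
- clinical coupling: PANSS total $= 30 + 25\,s_i + \mathcal N(0, 8)$,
  clamped to the scale range and split into subscales at fixed proportions
  above the floor (positive 0.25, negative 0.30, general 0.45); duration of
  illness from a single gamma distribution (shape 0.55, scale 21 yr; mean
  ≈ 11.6 yr) so the first-episode, early and chronic windows are all
  populated — a deliberately non-literal simplification, since real
  multi-site duration distributions are site-structured; antipsychotic dose
  lognormal and independent of severity (so dose associations are null by
  construction).

For SV tables the same machinery runs on the subcortical scope with a
volume baseline and all mm-scale parameters multiplied by a single scale
factor.

**What the defaults are for — and what they are not.** The defaults are
calibrated so that the planted architecture is *identifiable end to end*:
both planted epicenters rank in the top 4 of 68 seeds in ≥ 90% of replicate
cohorts, hub vulnerability is detected with spin p < 0.05, and group- and
subject-level hub estimates agree within 0.1. Two choices make this
possible and should be read as validation conditions, not as claims about
real data: the deficit magnitudes (up to ~0.6 mm at severity 1) are larger
relative to the residual SD than real case-control differences, and the
severity spread is modest so the pooled patient variance does not compress
the group *t* map. Real subject-level data are far noisier — which is
precisely why the original application of these models found subject-level
correlations much smaller than group-level ones. Passing tests demonstrate
that the estimators recover truth under favourable signal-to-noise, that
their nulls are calibrated, and that the pipeline is internally consistent;
they do not certify effect sizes in any real cohort. The generator also
omits site-by-diagnosis interactions and realistic MRI noise physics.

## Numerical choices and degenerate inputs

- Connectivity matrices must be symmetric: asymmetry ≤ $10^{-6}$ is averaged
  out, anything larger is an integrity error. Negative functional weights
  are zeroed (not absolute-valued) at preprocessing; structural matrices
  only lose their diagonal.
- Region matching on file load is case-insensitive against canonical
  `<hemi>_<name>` names; row order never matters; missing or unknown
  regions are hard errors naming the regions.
- The "upper 10% hubs most affected" report uses the mean of the two rank
  positions (centrality, reduction-t), ties broken by centrality rank then
  region name; a rank-intersection variant is available behind a flag.
- Constant maps make correlations undefined and are rejected; all-zero
  connectivity rows exclude that seed from the epicenter ranking; patients
  with constant z maps are masked, not scored.
- Eigenvector centrality is the Perron vector scaled to unit maximum; on a
  disconnected graph it concentrates on the largest component and a warning
  is emitted. Closeness falls back to the harmonic variant (with a warning)
  when pairs are unreachable.
- `runPipeline()` derives each stage's sub-seed from the master seed keyed
  by stage name, so adding a stage never perturbs earlier stages'
  randomness; outputs are plain text and byte-reproducible, with MD5 hashes
  in the manifest. The pipeline and the exported stage functions *are* the
  package's orchestration interface; there is no shell entry point.

## Validation problem sizes

The test suite validates at two scales chosen to keep the whole suite deep
but quick: unit tests run on a 16 + 4-region parcellation with cohorts of
~120 subjects, while the whole-pipeline validation uses the full default
layout (68 + 14 regions, 26 sites, 2439 + 2867 subjects) with 1000-rotation
nulls, 100 replicate cohorts for recovery, 200 for each calibration check,
500 map pairs for spin-test type-I error, and 10,000 bootstrap resamples
against Zou's CIs. Brute-force oracles (power iteration, Floyd–Warshall
path enumeration, step-up BH by definition, percentile bootstrap) are
implemented independently in the test helpers.

## Known limitations

- The spin variant is the centroid nearest-neighbour one: values can repeat
  or drop under rotation, and parcels are points, not areas; vertex-level
  and variogram-matching nulls are out of scope.
- ComBat is the canonical parametric-EB variant; CovBat, longitudinal and
  GAM extensions are not implemented, nor is reference-batch mode.
- The mega-analytic pooled linear model is the only group model; per-site
  random-effects meta-analysis is approximated by subsetting and rerunning.
- Zou CIs are reported without spatial-autocorrelation correction (matching
  the convention of the reference R implementation); spin p-values are
  available only for map-level overlap tests.
- Synthetic geometry is schematic: Fibonacci lattices, not anatomy; the
  interhemispheric offset and subcortical pseudo-centroids are modelling
  conveniences.
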