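# NetSuscept

Network susceptibility models for case-control brain morphometry.

## The problem

Structural alterations in psychiatric and neurological disorders are
widespread but not uniformly distributed across the cortex, and a recurring
question in network neuroscience is whether the *connectome* shapes where
they appear. Two models formalize this:

- **Hub vulnerability** (nodal stress): regions with high normative network
  centrality show disproportionately large disease-related alteration.
  Operationally, the Pearson correlation between a regional alteration map
  (e.g. a case-control *t* map of cortical thickness over 68
  Desikan-Killiany parcels) and a normative weighted degree centrality map,

  *r* = cor(*t*, *g*),  with *g*ⱼ = Σₖ *w*ⱼₖ,

  tested against a **spin permutation null**: the alteration map is rotated
  on the cortical sphere (mirrored rotations for the two hemispheres,
  nearest-centroid reassignment), which preserves its spatial
  autocorrelation while breaking alignment with the centrality map.
  Subcortical maps use label shuffles instead of rotations.

- **Disease epicenter mapping**: a region is an epicenter candidate if its
  normative connectivity profile resembles the whole-brain alteration
  pattern — for every seed region *j*, *r*ⱼ = cor(**w**ⱼ, *t*), with seeds
  ranked by descending *r* and significance assessed by spin permutation
  with Bonferroni correction over seeds (68 cortical, 14 subcortical).
  Epicenters need not be hubs; they are often "feeder" nodes connected to
  hubs.

The package implements both models end to end for multi-site case-control
cohorts: empirical-Bayes **ComBat** harmonization across sites (with a
partial-R² site-variance audit), mass-univariate difference maps with FDR
control, weighted graph centrality (degree, eigenvector, betweenness,
closeness), subject-level abnormality z maps with per-patient network
scores and clinical association tests, disease-stage comparison, and
cross-disorder comparison using Zou's confidence intervals for dependent
overlapping correlations.

Because consortium-scale morphometry and normative connectomes are not
redistributable, the package ships a fully parameterized **synthetic cohort
generator**: a hub-structured connectome on a two-sphere cortical geometry,
a planted effect map combining connectivity-to-epicenter and degree
coupling, multi-site location/scale batch effects, and per-patient severity
coupled to symptom scores. Every downstream claim is validated against this
ground truth.

## Worked example

```r
library(NetSuscept)

parc  <- dkParcellation()                      # 68 + 14 synthetic DK layout
cfg   <- GenerativeConfig(seed = 2)            # 26 sites, 2439 + 2867 subjects
net   <- generateConnectome(parc, seed = 2)
truth <- plantEffectMap(net$functional, cfg)   # bilateral entorhinal epicenters
coh   <- generateCohort(parc, truth, cfg, seed = 3)

harm <- combatFitTransform(coh)                # EB ComBat, diagnosis preserved
cc   <- fitGroupDifference(harm$cohort)        # reduction-positive t map
fu   <- preprocessConnectivity(net$functional)
null <- buildSpinRotations(parc, 1000, seed = 4)

hubVulnerability(alterationMap(cc, "t"), degreeCentrality(fu), null)
#> HubVulnerability <functional degree, cortico-cortical>: r = 0.767, p = 0.000999 (1000 perms)

epi <- epicenterMap(alterationMap(cc, "t"), fu, null)
tab <- resultTable(epi)
head(tab[order(tab$rank), c("region", "r", "p_spin", "rank")], 3)
#>                       region         r      p_spin rank
#> 5               L_entorhinal 0.8058907 0.000999001    1
#> 39              R_entorhinal 0.6997776 0.003996004    2
#> 2  L_caudalanteriorcingulate 0.6493399 0.006993007    3
```

The hub-vulnerability line says: cortical thickness reductions concentrate
in high-degree regions (r = 0.77) beyond what spatial autocorrelation
explains (spin p at the 1/1001 floor). The epicenter table ranks the two
planted epicenter regions first — their connectivity profiles best match
the deficit pattern.

Subject-level scores and their symptom associations:

```r
zm <- subjectZScoreMaps(harm$cohort)           # per-patient abnormality maps
sc <- subjectNetworkScores(zm, degreeCentrality(fu), fu)
clinicalAssociation(sc, harm$cohort, variables = "panss_total",
                    includeEpicenters = FALSE)
```

`runPipeline(outDir, cfg, seed = 1)` executes all stages in order and
writes CSV/TSV/JSON outputs plus a manifest of MD5 hashes; runs are
byte-reproducible for a fixed seed.

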