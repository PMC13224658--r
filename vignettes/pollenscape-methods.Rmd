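---
title: "Models and methods behind pollenscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pollenscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenscape)
```

# The scientific problem

`pollenscape` analyses contemporary, pollen-mediated gene flow in clonal,
strictly self-incompatible forest herbs whose populations sit in small
forest patches scattered through an agricultural landscape and whose
pollen is moved by trapline-foraging bumblebees. Two generations are
genotyped at microsatellite (SSR) loci: adult shoot clusters (potential
pollen donors, a subset of which serve as pollen receptors whose berries
are collected) and the offspring germinated from those berries. The
pipeline answers three questions: how much pollination happens within
versus among forest patches, which shoot clusters act as effective pollen
donors, and how landscape composition and the orientation of linear
landscape elements shape pollen immigration and the genetic diversity of
the incoming pollen.

The package is organised as a chain of stages, each usable on its own:
genotype quality control (multilocus genotypes, clone removal, clonality
statistics), consensus paternity assignment, per-receptor pollen-flow
measures, buffer-based landscape metrics, and a model-selection/averaging
layer over zero-inflated mixed models. A synthetic-study generator with
complete ground truth closes the loop so that every stage is testable
without any external data.

# Genotype handling

A sample's multilocus genotype (MLG) is the tuple of its per-locus
unordered allele pairs; identical MLGs indicate clones (ramets of one
genet) or, rarely, chance identity. Missing data (allele code 0) make MLG
identity ambiguous. The default policy is *strict*: a sample with a
missing locus never equals a fully typed sample. This is conservative and
deterministic; a *tolerant* policy (equality over the loci typed in both,
grouped by single linkage) is available via the `policy` argument where
the marker panel has substantial dropout. Because the count of "repeated
MLGs" depends on a convention, `repeated_mlg_counts()` reports all three
readings: groups, samples involved, and redundant copies.

Deduplication mirrors field practice for clonal plants: within a
repeated-MLG group, adults that are not pollen receptors are removed
first and receptors are never removed; among equal-priority duplicates
the lexicographically smallest `sample_id` is kept so the result is
reproducible. Offspring are removed only as apparent twins — several
offspring of the *same* mother sharing one MLG — never because they match
an adult; offspring-parent MLG repeats are biologically expected and are
retained.

Mother-offspring conflicts are resolved before paternity: a locus at
which an offspring shares no allele with its recorded mother is reset to
missing, up to `max_mismatch` loci (default 1, the scale of conflict a
low per-locus genotyping error produces). Offspring exceeding the
tolerance are flagged incompatible and excluded from assignment rather
than silently repaired.

# Paternity model

For each forest patch separately (pollination is modelled patch by
patch), each offspring is assigned either one candidate donor — any adult
genotype of the patch, receptors included — or the UNSAMPLED label. The
per-locus likelihood of a candidate trio is an error mixture

$$L = (1 - e)\,T(g_o \mid g_m, g_f) + e\,P_{HWE}(g_o),$$

where $T$ is the Mendelian transmission probability, $e$ the per-locus
genotyping error (default 0.012, matching error rates of up to ~1.2%
estimated from repeat genotyping), and $P_{HWE}$ the Hardy-Weinberg
genotype probability. For the UNSAMPLED hypothesis the paternal allele is
integrated over population allele frequencies. Two implementation
decisions matter here:

* **Background frequencies are study-wide.** Immigrant pollen carries
  alleles that may be absent from the focal patch; estimating the HWE
  background from the patch's own adults would assign such alleles zero
  frequency and make *every* hypothesis impossible. Frequencies are
  therefore estimated from all adults in the study, and alleles unseen at
  a locus receive half the smallest observed frequency as a floor.
* **Self-incompatibility is a hard constraint.** With
  `selfing_allowed = FALSE` (default) any candidate whose MLG equals the
  mother's — the mother herself or one of her clone-mates — has
  likelihood zero.

The prior places probability `p_sampled` (default 0.5, uninformative) on
"the father is in the candidate set", spread uniformly over candidates,
and `1 - p_sampled` on UNSAMPLED. Note there is no sibship
reconstruction: unsampled fathers are integrated per offspring, without
latent shared-father clustering. This is a deliberate, documented
simplification — it is sufficient for the pipeline's downstream
statistics, which only need the within-patch/immigrant split, and it
makes the maximum-a-posteriori configuration exactly testable against
exhaustive enumeration.

The search over joint configurations is simulated annealing with
heat-bath updates: each sweep redraws every offspring's label from its
conditional posterior tempered by the current temperature (such proposals
are always accepted under Metropolis), with a geometric cooling schedule
(defaults: 200 sweeps, T0 = 2, cooling 0.95) and the best configuration
visited returned. Five independent runs are performed from seeds
`seed + 0..4` and an offspring-donor pair is accepted only if it appears
in at least two of the five runs (ties between donors yield UNASSIGNED).
This conservative consensus deliberately trades a little within-patch
signal for protection against overestimating pollen immigration. Support
counts are reported per offspring; they are analogous to, but not
numerically comparable with, the acceptance probabilities of
full-pedigree samplers.

# Pollen-flow measures

Per pollen receptor, `PF_within` is the proportion of its genotyped
offspring assigned to a donor of its own patch; UNASSIGNED offspring
count as immigrant pollen, so `1 - PF_within` is the pollen immigration
rate. Because within-patch fathers can be unsampled genets of
multi-genet clusters, `PF_within` is a lower bound on the true
within-patch proportion — the synthetic generator reproduces exactly this
bias, and the full-loop tests therefore compare *rankings* (Spearman)
rather than levels.

Allelic richness of the incoming pollen is rarefied to five offspring per
receptor with the exact hypergeometric formula at the gene-copy level
($g = 10$ copies; missing slots are excluded from a locus's copy count,
and a locus with fewer than $g$ typed copies is rarefied to what it has):

$$A_r(l) = \sum_i \left[1 - \binom{N_l - N_{li}}{g}\Big/\binom{N_l}{g}\right].$$

No resampling is involved. The per-receptor summary reports both the
mean over loci (the default, on the scale of "alleles per locus") and
the sum over loci, since either convention appears in the literature.
Receptors with fewer than five genotyped offspring are excluded from
rarefaction and flagged for exclusion from the landscape models; "five
berries" is operationalised as five genotyped offspring, the analysable
quantity.

# Landscape metrics

All geometry is planar and metric; inputs must be pre-projected. Around
each receptor, circular buffers of 50, 250 and 1000 m are analysed.
Percent cover uses an exact disc-polygon intersection (Green's theorem
with circular-arc substitution), so covers are rotation-invariant to
floating-point accuracy and the per-buffer covers (with `OTHER` defined
as the remainder) sum to 100 by construction. Linear elements are clipped
exactly to the disc.

The directional decomposition follows the receptor-axis convention: for
each clipped element piece, the axis is the unit vector from the receptor
to the piece's midpoint at half its arc length, and each segment vector
$v$ contributes $|v\cdot\hat u|$ to the parallel and $|v\cdot\hat n|$ to
the orthogonal length. The midpoint is taken *after* clipping — the axis
should be local to what a forager inside the buffer encounters — and a
piece crossing the buffer more than once gets its own axis per part; a
pre-clip axis convention would be a one-line change and is noted as the
main interpretive alternative. The orthogonal-to-parallel (O:P) ratio of
a type pools component sums over all pieces (rather than averaging
per-element ratios, which would weight short fragments equally with long
elements); when the pooled parallel length vanishes the ratio is capped
at `ratio_max` (default 1e3), and when no element of a type intersects
the buffer the metric is missing, not zero. Population counts (`N_P`)
count occupied populations intersecting the buffer, excluding the
receptor's own. A fixed availability matrix (e.g. semi-natural grassland
and rapeseed only at 1000 m, woody elements at 250/1000 m, `N_P` at
250/1000 m) is enforced; requesting an unavailable metric-radius pair is
an error rather than a silent `NA`.

# Statistical models

Landscape metrics are Box-Cox transformed (shift `1 - min(x)` for
non-positive metrics; exponent on the grid $[-2, 2]$ in steps of 0.05
maximising the profile normal log-likelihood) and standardised to mean 0,
sd 1, so averaged coefficients are comparable across metrics.

Three response families share one inference procedure, all with a forest
patch random intercept:

* counts of assigned offspring per shoot cluster — zero-inflated Poisson;
* `PF_within` — zero-inflated binomial with the number of genotyped
  offspring as trials (the weighting the proportion data implies);
* `A_r` — Gaussian linear mixed model.

The zero-inflated models have independent random intercepts $u_g, v_g$
in the conditional and zero-inflation components (no cross-component
correlation — the default of the model family used in this literature).
The marginal likelihood integrates both effects per group by adaptive
2-D Gauss-Hermite quadrature, 9 nodes per dimension by default: per
group, the integrand's mode is located by a damped Newton search and the
node grid is rescaled by the curvature there. Optimisation is
quasi-Newton (L-BFGS-B) with an analytic gradient obtained from the
posterior-weighted score identity at the quadrature nodes; up to three
starts are used (one informed by an ordinary GLM fit plus seeded random
restarts), stopping at the first convergence — restarting only on
failure keeps large recovery simulations affordable without changing
results for well-behaved fits. Standard errors come from the numerical
Hessian. The zero-inflation component models the probability of an extra
zero, so a positive coefficient there means *more* zeros — the opposite
direction to the conditional part. Unit tests cross-check the fits
against `glmmTMB` (an independent Laplace-approximation implementation)
and the likelihood against 31-node quadrature. The Gaussian family
delegates to `lme4::lmer` (ML for selection, REML for the reported
coefficients), with Wald t tests on residual degrees of freedom
$n - k$ — a documented simplification in place of Satterthwaite
approximations.

Inference proceeds in three steps. (1) *Screening*: each metric is fit
alone — separately in the conditional and zero-inflation components for
the zero-inflated families — and retained at Wald $p \le 0.15$;
area-based metrics are additionally probed with a quadratic term, kept
when it lowers the AICc, and linear-element metrics are probed for an
interaction with the O:P ratio of their own type. (2) *Collinearity*:
transformed metrics with pairwise $|r| > 0.7$ are marked mutually
exclusive. (3) *All-subsets selection and conditional averaging*: every
admissible subset (marginality — quadratics and interactions only with
their main effects — and exclusivity respected; at most 12 toggleable
terms) is fitted by ML; models within $\Delta AICc \le 2$ of the best
form the candidate set; Akaike weights are renormalised over that set;
each term is averaged conditionally over the models containing it with
Burnham-Anderson unconditional standard errors and normal 95% intervals.
Gaussian mixed models are refitted by REML before averaging. The AICc is
always $-2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting fixed effects
plus variance components; tests recompute the identity independently on
every emitted fit.

# The synthetic-study generator

The generator emulates the sampling design the pipeline targets, with
every stochastic stage driven by named substreams of one master seed so
stages can be regenerated independently. Its defaults are the study
conditions, not tuning knobs:

* a 5 km x 5 km window with nine forest patches on a jittered 3x3 grid;
* shoot-cluster counts per patch log-uniform on 24-689 (roughly 2000
  clusters in total); shoots per cluster zero-truncated negative binomial
  with size 0.30 and mean 2.5, giving ~85% of clusters under 10 shoots
  and a heavy tail of large clusters;
* size-dependent clonality: multi-shoot clusters are monoclonal with
  probability 0.62 / 0.46 / 0.28 in the <5 / 5-20 / >20 shoot classes,
  otherwise hold 2-4 genets; genotypes are Hardy-Weinberg draws at
  Dirichlet(1) frequencies over 7 loci totalling 97 alleles;
* one sampled shoot per cluster plus a 59-cluster multi-shoot subsample
  (all shoots for clusters of up to three shoots, up to six otherwise)
  for the clonality assessment — exactly the sampling that creates
  repeated MLGs for the deduplication stage to find;
* 6-14 receptors per patch; genotyped offspring per receptor
  zero-truncated negative binomial (size 1.2, mean 9.5) truncated at 41,
  matching a reported range of 1-41 with mean ~9.6 — a uniform draw on
  1-41 would have doubled the mean, so the negative binomial was chosen
  once from those three reported numbers;
* per-allele-slot genotyping error 0.012, each erroneous slot redrawn
  from the locus frequencies.

Mating is a trapline mechanism: each foraging route visits 10-30
clusters, moving to one of the five nearest within-patch clusters or
switching patch with probability `p_switch` (default 0.3); every visited
flower adds its genet to the forager's pollen load, and a visit to a
receptor still needing offspring draws a donor from the load with
geometric carryover weights $\kappa^{age}$ (default $\kappa = 0.5$,
age 0 = the previous visit) and sires one ovule iff the
self-incompatibility check passes — donor MLG different from the
receptor's, optionally extended by a gametophytic S-locus (off by
default, since S-alleles are hypothesised rather than measured in this
system). Route fidelity across bouts is not modelled by default
(`repeat_routes` provides fixed routes). The carryover and patch-switch
rates are free scenario knobs, not estimates — no quantitative field
values exist for them — and the scenario presets (`within_only`,
`trapline_mixed`, `high_carryover`, `orientation_parallel`,
`orientation_orthogonal`) are the named conditions the tests exercise.

What the generator does *not* emulate: pollinator energetics and
optimal-foraging behaviour, nest placement, multi-year dynamics, seed
dispersal, spatial autocorrelation of land use beyond the random grid,
and real GIS layer topologies. Passing the full-loop tests therefore
shows that the pipeline recovers the truth of *this* mating mechanism at
field-realistic sample sizes — it does not validate the ecological model
itself against field data.

# Numerical choices and degenerate inputs

* MLG keys are strings of sorted allele pairs — deterministic and
  order-independent by construction.
* The annealing uses Gumbel-max categorical draws, so runs are exactly
  reproducible from their seeds across platforms with identical RNG
  streams.
* Frequency floors (half the smallest observed frequency) keep immigrant
  alleles from zeroing out likelihoods; at `e = 0` impossible trios are
  still exactly `-Inf`.
* Buffers partially outside the mapped area count unmapped cover as
  `OTHER`; polygons are single rings (no holes).
* An element whose clipped midpoint coincides with the receptor has an
  undefined axis and is skipped with a warning.
* Zero-variance metrics are dropped (with a log entry) before
  transformation; non-convergent candidate fits are skipped and never
  enter a candidate set; a singular LMM (variance at zero) is flagged
  but retained, matching standard mixed-model practice.
* CSV artifacts are written via shortest round-trip floating-point
  formatting, so re-reading reproduces the doubles exactly; stage
  outputs are written atomically (temp file + rename) and the manifest
  records the config hash, seed and row counts needed to re-execute a
  run.

# Problem sizes used in the test-suite

The unit and property tests run on reduced study sizes chosen to keep
the full suite comfortably reproducible on a laptop: 12-30 clusters per
patch, 3-5 receptors per patch and a mean of 8 offspring per receptor
for simulation-based checks; 100 random instances with at most 10
offspring and 4 candidates for the exhaustive paternity oracle; 200
replicate data sets of 9 groups x 10 observations for the zero-inflated
recovery study; 20 seeds per foraging scenario for the end-to-end
directionality check; and 1000 replicates for the screening-calibration
check. The acceptance script runs the full default design (nine patches,
~2000 clusters) once. All of these sizes are stated in the tests
themselves.

# Known limitations

* No sibship reconstruction: families sharing an unsampled father are
  not pooled, which loses power relative to full-pedigree methods when
  many half-sib families have unsampled fathers.
* Assignment support counts are not calibrated probabilities.
* The LMM screening p-values use residual df rather than Satterthwaite;
  for the sample sizes targeted (about 79 receptors, 9 patches) the
  difference is negligible but it is a convention, not an approximation
  guarantee.
* Geometry supports single-ring polygons; multipolygons and holes must
  be split upstream.
* The O:P ratio cap (1e3) is arbitrary in the sense that any large
  finite value would do; it exists to keep Box-Cox transforms of the
  ratio finite.
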