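---
title: "Methods: from spectral features to exometabolite niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spectral features to exometabolite niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoniche)
```

# The analysis problem

Metabolic footprinting infers what a microbial strain consumes and
secretes by comparing the metabolite complement of its *spent* culture
medium against matched uninoculated *control* medium. When the medium
is supplemented with a complex, environmentally realistic metabolite
pool (for instance, pooled cell extracts of co-occurring strains), a
single untargeted LC--MS experiment interrogates hundreds of
metabolites at once -- including compounds with no library identity.
Doing this for a panel of sympatric isolates yields a substrate-use
profile per strain, and from those profiles one can ask the ecological
questions exoniche answers: how much of the available pool does each
strain use, how much overlap is there between strains, which
metabolites could fuel competition, which could fuel cross-feeding,
and which community-level dynamics (e.g. depletion of soil-water
metabolites after a wetting pulse) are unexplained by the isolates in
hand.

The pipeline has four analysis stages plus a simulation module; each
stage is exported on its own so intermediates can be inspected.

# Stage 1: resolving features into metabolites

An electrospray source turns one metabolite into several spectral
features: protonated/deprotonated and adducted molecules, multimers,
in-source fragments and heavy-isotope peaks. Counting each feature as
a metabolite would overstate the pool several-fold, so features are
first resolved into putative metabolites.

**Grouping.** Co-generated ions co-elute and their intensities rise
and fall together across samples. `group_coeluting_features()`
partitions the feature set by single-linkage transitive closure over a
pairwise gate: same ionisation mode, retention times within `rt_tol`
(default 0.3 min), and Pearson correlation of the raw intensity
vectors at least `corr_min` (default 0.9), computed over samples where
at least one of the pair was detected (at least 3 such samples
required). Correlation is computed on raw peak areas, not logs: areas
are the native quantity and zero (not detected) is a legitimate value
that a log transform cannot represent. Features detected in no sample
cannot be correlated and become singleton groups flagged `all_zero`.
Single linkage can, in principle, chain a group whose extreme members
are farther apart than `rt_tol`; the group retention time is reported
as the member mean, and the tolerance should be read as a pairwise
gate, not a group diameter.

**Ion typing.** Within a group, `assign_ion_types()` finds the
neutral mass that explains the most members through a rule table of
ion species (default: protonated, ammoniated, sodiated molecules and
proton-bound dimers in positive mode; deprotonated, acetated and
dimeric species in negative mode -- acetate because HILIC mobile
phases are ammonium acetate buffered). The m/z tolerance default of
0.02 Da matches the 20 mDa integration window typical of Q-TOF peak
integration. A member one ^13^C spacing (1.0034 Da) above an explained
member counts as a supporting M+1 isotopologue; this matters because
without it a lone isotope peak could anchor the neutral mass one
dalton too high. Members explained by no rule stay in the group as
`unassigned fragment` -- they co-elute and correlate, so they belong
to the metabolite, but they never become its quantifier unless
nothing better exists. Electron mass is neglected throughout the
adduct arithmetic; at ~0.5 mDa it is far below the tolerance.

**Characteristic ion.** Each group is quantified by one ion
(`select_characteristic_ion()`): the highest-median-intensity member
among primary species (protonated, deprotonated, ammoniated), falling
back to the highest-median member overall; ties break by lower m/z
then feature id so the choice is deterministic.

**Polarity merge.** Acquisition in fast polarity-switching mode
detects many metabolites in both modes. `merge_polarities()` merges a
positive and a negative group when their inferred neutral masses agree
within `mass_tol` (default 0.005 Da) and retention times within
`rt_tol`, greedily by mass agreement; a group with several admissible
partners merges with the nearest mass and is flagged. The merged
record keeps the brighter group's characteristic ion.

**Formula assignment.** `assign_formula()` enumerates all CHNOPS
compositions within a ppm window of the neutral mass (default 5 ppm;
element caps C40 H80 N20 O25 P5 S5) and ranks them by absolute ppm
error plus, when an M+1/M intensity ratio was measured, a weighted
isotope-fit term. Two chemistry filters are applied: RDBE must be a
non-negative integer (negative RDBE is impossible for a neutral
molecule; half-integer RDBE implies a radical -- the nitrogen rule),
and element ratios must fall in the empirical ranges of natural
products (H/C <= 6, N/C <= 1.3, O/C <= 1.2, P/C <= 0.3, S/C <= 0.8).
The ratio filter is what disambiguates the notorious near-isobars: at
342.1162 Da a dihexose (C12H22O11) is accompanied by nitrogen-rich
compositions within 0.05 ppm, all of which fail one of the two
filters. With an exact mass and an exact isotope ratio the true
composition scores 0 and cannot be beaten, which is why planted-truth
recovery of CHNO formulas below 500 Da is essentially perfect.

```{r formula-example}
assign_formula(147.0532, m1_ratio = 0.056)[1, c("formula", "score")]
```

# Stage 2: uptake / release classification

**Availability.** Only metabolites that were actually offered can be
scored for uptake. `filter_abundant()` keeps metabolites whose
characteristic ion reaches `min_area` (default 5,000 counts) in at
least one control-medium sample. The threshold is strict
(4,999 fails) and the "any single control sample" reading is the
default; a control-group-mean variant is available
(`mode = "group_mean"`).

**The test.** `classify_utilization()` compares spent against matched
control replicates with a two-sided pooled-variance Student's t-test
(`two_sample_t()`), the classical choice for small equal-variance
designs with n = 3. No multiple-testing correction is applied by
default, and no fold-change floor is imposed: a significant
directional change of any size counts. Significance tiers (\*, \*\*,
\*\*\*) map to p < 0.05, 0.01, 0.001. Degenerate inputs -- zero pooled
variance -- are resolved explicitly: equal means give p = 1, unequal
means give p = 0 with a `degenerate` flag, which makes the noiseless
simulation limit exact rather than NaN-ridden.

A metabolite undetected in the matched controls (all control areas
below `min_area`) cannot be scored for uptake; if its spent-medium
mean nevertheless reaches `detect_area` (default 1,000 counts) it is
called a release into a medium where it was never available
(`novel_release`), otherwise `not_available`. A caveat follows from
the rule itself: a metabolite sitting just below the availability
threshold but above `detect_area` in both control and spent medium
is called a release even if nothing changed. Such calls inflate the
released-novel set; they never enter the availability-filtered
utilization matrix on which all niche statistics are computed.

**Consensus.** With two medium formulations, `combine_across_media()`
scores use-in-any-medium: a directional call beats `unchanged`,
`not_available` is uninformative, and an uptake/release contradiction
resolves to the smaller p-value with a `conflict` flag. Increasing
alpha can only promote `unchanged` to a directional call, never the
reverse, so call sets are monotone in alpha.

# Stage 3: niche statistics

All fractions use the available (abundant) metabolite count as the
denominator -- released-novel metabolites were never on offer, so they
are excluded. Reported percentages round half away from zero (70 of
372 prints as 19%). The statistics are: per-isolate used fraction;
the shared-use histogram (how many isolates take up each metabolite,
with cumulative counts for "used by at least k" queries); the unused
fraction (histogram bin zero); competition candidates (taken up by at
least two isolates, released by none); cross-feeding candidates
(taken up by at least one isolate and released by a different one --
a single consensus call per isolate-metabolite pair makes the two
sets disjoint by construction); pairwise Jaccard and Simpson overlap
of uptake sets; and a bipartite isolate-metabolite graph exported as
GraphML and an edge table. Conflicted cells count as uptake when
their resolved call is uptake (default) or can be excluded.

# Stage 4: release breadth and wetting dynamics

`classify_release()` compares a strain's cell extract, its spent
minimal medium and the uninoculated control: metabolites present
intracellularly but absent outside (`extract_only`) argue against
lysis as the release mechanism, because lysis would spill everything.
Control means are subtracted from spent means (floored at zero)
before thresholding so medium background never reads as release; the
detection threshold (default 1,000 counts) is shared with the
classifier and deliberately conservative. Release breadth is
released / (released + extract_only). `rank_abundance_table()` emits
the mirror-plot ordering (descending extract abundance).

`timepoint_trend()` tests each soil-water metabolite between the
first and last sampling point after wetting (defaults: 3 min vs 18 h,
the middle 9 h point being available as an alternate endpoint) with
the same pooled t-test; `depleted` / `accumulated` require both
significance and direction. Water replenished mid-course dilutes the
later samples; the default `dilution_factor = 1` applies no
correction (matching the usual practice of reporting raw areas), and
a factor can be supplied where the replenishment volume is known --
factor 1 is verified to be the identity.
`unused_but_depleted()` maps soil-water metabolites onto the isolate
experiment by m/z, retention time and polarity (nearest-m/z with an
ambiguity flag) and returns depleted metabolites whose matrix column
holds no uptake call: depletion attributable only to organisms
outside the tested panel, a shortlist for targeted isolation.
`media_vs_soilwater_comparability()` quantifies whether supplemented
media offer environmentally realistic amounts: the fraction of
shared metabolites whose mean areas agree within one order of
magnitude.

# The synthetic study design

`synthetic_config()` fixes the simulated study at the design the
analysis targets: 470 metabolites, 372 of them abundant; 7 isolates
(isolate 1 playing the long-cultured phototroph with its own control
set); two supplemented media with n = 3 replicate controls and spent
cultures; per-isolate planted used fractions drawn from 13--35% of
the abundant set with 40% of it used by nobody; lognormal replicate
noise with CV 0.2; uptake multipliers 0.02--0.5 and release
multipliers 2--50; a soil-water time course of 8 replicates at 3 min,
9 h and 18 h with 65 of 400 metabolites depleted 5--50-fold. Base
areas are log-uniform between 10^2 and 10^6 counts, in two bands
(abundant 2x10^4--10^6, non-abundant 10^2--2x10^3) so that the
5,000-count availability filter separates the planted sets cleanly
even under noise.

Choices worth knowing about:

* **Noise structure.** Replicate noise is multiplicative lognormal
  (areas are positive and heteroscedastic) and is shared by all ion
  features of a metabolite within a sample, with a smaller
  independent per-feature term (CV 0.05) on top. The shared term is
  what makes co-generated features correlated -- with purely
  independent noise, features of a metabolite with equal means in
  every sample would be uncorrelated and ungroupable, which is not
  how chromatography behaves; with no per-feature term they would be
  perfectly correlated, which is not how detectors behave. The ratio
  of the two CVs puts the expected feature-feature correlation near
  0.94, deliberately close to the 0.9 grouping threshold so the
  grouping stage is genuinely exercised.
* **Ion envelopes** have 1--5 features: the primary adduct, up to two
  further same-mode species, an M+1 isotopologue at the
  formula-implied ratio (80% of metabolites), and the opposite-mode
  primary adduct for ~30% of metabolites, exercising the polarity
  merge. m/z values carry 1 ppm mass-accuracy noise; co-eluting
  features carry 0.01 min retention jitter.
* **Formulas** are CHNO, 80--900 Da, with integer non-negative RDBE
  and natural-product element ratios, so every planted formula is
  recoverable in principle.
* **What the generator does not emulate:** chromatographic peak
  shapes and integration artefacts, correlated (batch) drift,
  ion-suppression cross-talk between co-eluting metabolites,
  censoring subtleties near the detection floor beyond a hard
  threshold, and real adduct-abundance chemistry. Passing recovery
  tests on this generator therefore demonstrates the statistical
  logic of the pipeline under its stated noise model, not performance
  on any particular instrument's data.

Under these conditions the classifier's operating characteristics,
recomputed by `scripts/acceptance.R` on every run, are roughly 97%
sensitivity for planted uptake, 99% for planted release, and a ~5%
false positive rate on planted-unchanged metabolites at alpha = 0.05
-- consistent with the nominal test level, as the near-uniform null
p-value distribution (KS test) confirms. Resolution produces slightly
more records than planted metabolites (over-splitting when a feature
pair's sample correlation falls below 0.9) and occasionally collapses
two co-eluting, correlated metabolites into one record; both
behaviours are inherent to correlation-gated grouping at n = 54
samples, and both are visible in the acceptance report
(`n_metabolites_resolved`, `n_abundant`).

# Problem sizes and determinism

Everything is a pure function of its configuration including the
seed: regenerating with the same seed reproduces feature tables,
reports and exported files byte for byte. The default problem
(470 metabolites, 7 isolates, ~1,500 features, 54 samples) resolves,
classifies and summarises in well under a minute on one core; the
test suite exercises smaller instances (25--150 metabolites) for the
per-operation checks and the full default design for the
study-condition checks. Grouping cost is dominated by the number of
feature pairs within the retention-time window, so it scales with
feature density in time, not with the square of the feature count.

# Known limitations

* Grouping quality degrades when fewer than ~10 samples are
  available: sample correlations are then too noisy for a 0.9 gate,
  and the availability filter is the only guard against fragment
  records entering the matrix.
* The consensus rule treats media symmetrically; a metabolite used
  only in one medium counts as used, which is the intended reading
  but inflates use fractions relative to an "all media" rule.
* Cross-experiment matching is greedy nearest-m/z; dense retention
  regions can mismatch isomers, and flagged ambiguous matches should
  be reviewed before biological claims rest on them.
* The released-novel set is sensitive to the `detect_area` threshold
  (see the classification caveat above) and should be treated as
  candidates, not calls.
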