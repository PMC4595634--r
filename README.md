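# exoniche

Exometabolite niche partitioning from untargeted LC–MS footprinting.

Soil and biocrust bacteria live on a pool of hundreds of extracellular
metabolites, much of it of microbial origin. How that pool is divided —
which strains take up which compounds, which compounds nobody touches,
which could fuel competition or cross-feeding — is a niche-partitioning
question that *metabolic footprinting* answers experimentally: culture
each isolate in medium supplemented with an environmentally realistic
metabolite mixture, profile the spent medium by LC–MS, and compare
peak areas against uninoculated controls. `exoniche` is the analysis
side of that experiment, from the raw spectral-feature table to the
ecological statistics.

## What it computes

**Metabolite resolution.** One metabolite yields several redundant
ions (adducts, multimers, in-source fragments, isotopologues).
Features that co-elute (retention time within `rt_tol`) and whose
intensities correlate across samples (Pearson r ≥ `corr_min`) are
grouped by single-linkage closure; ion species are assigned from
characteristic mass differences (e.g. [M+H]⁺ vs [M+NH₄]⁺ differ by
17.0265 Da), giving each group a neutral mass M; groups detected in
both polarities are merged; CHNOPS molecular formulas are assigned by
exhaustive enumeration within a ppm window, scored by mass error plus
isotope-pattern fit, and filtered by the nitrogen rule (integer
RDBE ≥ 0) and natural-product element ratios.

**Uptake/release classification.** For each (isolate, metabolite,
medium), spent vs control replicate areas are compared with a
two-sided pooled-variance Student's t-test; significant depletion is
*uptake*, significant increase is *release*, and a metabolite absent
from controls but present in spent medium is a release into a medium
where it was never available. Only *available* metabolites —
characteristic ion ≥ 5,000 counts in at least one control sample —
enter the downstream statistics.

**Niche statistics.** Per-isolate used fraction of the available
pool, the shared-use histogram (how many isolates consume each
metabolite), the unused fraction, competition candidates (≥ 2
consumers, no producer), cross-feeding candidates (≥ 1 consumer and a
different producer), pairwise Jaccard/Simpson overlap of uptake sets,
and a bipartite isolate–metabolite network (GraphML).

**Release breadth & wetting dynamics.** Cell-extract vs
spent-minimal-medium comparison (metabolites confined to the extract
argue against lysis as the release route), and per-metabolite trend
tests across a soil-water wetting time course (3 min / 9 h / 18 h),
cross-referenced against isolate capabilities to flag depleted
metabolites that no tested isolate consumes.

**Synthetic experiments.** `generate_experiment()` and friends build
complete feature tables, metadata and planted ground truth with the
statistical structure above (lognormal replicate noise, adduct
envelopes, abundance bands, planted effect sizes), so every stage is
testable without instrument data.

## Worked example

A simulated four-isolate experiment, end to end:

```r
library(exoniche)

cfg <- pipeline_config(
  simulate = TRUE, out_dir = "out", seed = 1L,
  synthetic = list(n_metabolites = 120L, n_abundant = 95L,
                   n_isolates = 4L),
  assign_formulas = FALSE)
rep <- run_pipeline(cfg)

rep$n_metabolites            # 134  records resolved from 369 features
rep$n_abundant               # 94   available (>= 5,000 counts in a control)
rep$per_isolate_used_percent # 30 20 32 32  (% of the available pool)
rep$shared_use_histogram     #  0  1  2  3  4
                             # 38 22 20 11  3
rep$n_competition            # 23  metabolites: >= 2 consumers, no producer
rep$n_crossfeeding           # 15  metabolites: consumer + distinct producer
rep$n_depleted               # 23  soil-water metabolites down after wetting
rep$recovery$sensitivity_uptake  # 0.985 against the planted truth
```

Reading the numbers: 134 resolved records from 120 planted
metabolites reflects correlation-gated grouping occasionally
splitting an ion envelope; 94 of the 95 planted-available metabolites
pass the filter; each isolate consumes 20–32% of the pool while 38/94
(40%) of it is consumed by nobody — the planted niche structure. The
same objects are written to `out/` as TSV/JSON/GraphML
(`metabolites.tsv`, `calls.tsv`, `consensus.tsv`,
`utilization_matrix.tsv`, `niche_summary.json`, `bipartite.graphml`,
`timecourse.tsv`, `report.json`, …).

File-based runs replace `simulate` with `features=` and `metadata=`
paths (long or wide tables, TSV/CSV; see `?read_feature_table`), or
use the wrapper script `inst/scripts/exoniche-pipeline.R`. A YAML
config with the same keys is accepted via `--config` /
`read_pipeline_config()`.

## The vignette

`vignettes/exoniche-methods.Rmd` documents the model and its
assumptions: the grouping gate and its failure modes, the adduct and
formula chemistry filters, the decision rules and their degenerate
cases, what the synthetic generator does and does not emulate, and
the package's known limitations.
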