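# ndrscope

Promoter chromatin architecture profiling around transcription start
sites, for genomicists studying how ATP-dependent chromatin remodelers
(RSC, ISW1a and their relatives) shape nucleosome organization in compact
genomes.

In budding yeast, *open* (structured) promoters carry a nucleosome-
depleted region (NDR) just upstream of the TSS, flanked by positioned -1
and +1 nucleosomes and a phased downstream array; *closed* (unstructured)
promoters carry nucleosomes at gene-specific positions with no common
register.  Loss of RSC fills open-promoter NDRs and slides the +1
nucleosome upstream ("leftward", toward the NDR); additional loss of ISW1
partially restores the wild-type architecture.  `ndrscope` turns that
analysis into a tested pipeline:

* **annotation / tracks** — BED6/GFF3 transcript models with strand-aware
  TSS anchors; bedGraph / fixedStep wiggle tracks; paired-end
  mono-nucleosome fragments (120–180 bp) converted to Gaussian-smoothed
  dyad-density tracks; quantile normalization; occupancy scored as
  `log2((v + 0.1 m)/(1.1 m))` relative to the genome mean `m`, in 50 bp
  windows over ±800 bp around each TSS, with windows overlapping
  neighboring transcripts excluded.
* **profiles** — mutant/wild-type log2 ratio matrices; promoter
  clustering by a masked-distance k-means (k-means++ seeding, distance
  over valid windows scaled by the valid fraction, default k = 6, 20
  restarts, deterministic given a seed, clusters ordered by NDR gain);
  per-cluster mean profiles with bootstrap bands; per-gene TSS scores
  (mean or max over ±250 bp) and assay correlations.
* **architecture** — per-gene NDR calls (runs below -0.5 log2 flanked by
  occupied windows), sub-window +1 localization by cubic interpolation,
  `mut - wt` +1 shifts, NDR fill-in as the log ratio of aggregated NDR
  occupancy, double-mutant suppression indices
  `1 - effect_double/effect_single` per metric, and open/closed
  classification from NDR depth plus phasing autocorrelation.
* **enrichment** — promoter occupancy calling at a target FDR against
  per-gene circular-shift nulls of the matched input track
  (Benjamini–Hochberg); exact IUPAC scanning of promoter elements (TATA
  `TATAWAWR`, Reb1 `TTACCCG`, Rsc3 `CGCGC`, poly(A) runs); permutation
  enrichment of elements in gene categories; hypergeometric /
  permutation gene-set intersection tests.
* **expression** — HybMap-style tables: probe intensities median-scaled
  to non-hybridizing control probes, gene levels as probe medians
  averaged over replicates, class-wise log2 mutant/wild-type ratio
  summaries, and a screen for genes whose knockdown is suppressed in a
  double mutant.
* **synthetic_data** — a deterministic cohort generator (annotations,
  promoter sequences with planted elements, per-genotype fragments from
  an explicit dyad mixture model, ChIP + input tracks, probe tables) with
  full ground truth, including the infinite-fragment-limit value of every
  geometry metric computed from closed-form expected profiles.

The methods vignette (`vignettes/promoter-chromatin.Rmd`) documents the
models, defaults, and numerical choices in detail.

## Worked example

Generate a 300-gene cohort (200 mono-nucleosome fragments per gene and
genotype; RSC loss planted as a -40 bp +1 shift with 0.6 NDR fill
fraction, 50% suppressed in the double mutant), run the pipeline, and
compare with the recorded truth:

```r
library(ndrscope)
dir <- tempfile()
truth <- generateCohort(syntheticConfig(seed = 1), dir)
res <- runPipeline(dir, file.path(dir, "out"), seed = 1)
truthReport(truth, architecture = res$architecture,
            clusters = res$clusters, chipCalls = res$chipCalls,
            screen = res$screen)
```

which prints:

```
                   metric      value   n
            shift_bias_bp -0.3246753 154
            shift_rmse_bp  6.0838300 154
           fill_bias_log2  0.1270095 150
           fill_rmse_log2  0.5655872 150
           class_accuracy  0.9866667 300
 suppression_shift_median  0.6000000 154
  suppression_fill_median  0.3032434 150
              cluster_ari  0.6260736 300
           chip_precision  1.0000000 300
              chip_recall  1.0000000 300
            screen_recall  1.0000000  15
  screen_false_selections  0.0000000 285
```

Reading this: the planted -40 bp upstream shift of the +1 nucleosome is
recovered with -0.3 bp cohort bias and ~6 bp per-gene RMSE; NDR fill-in
is within 0.13 log2 of its analytic infinite-data value; open vs closed
promoters are classified with 98.7% accuracy; the per-gene
shift-suppression median (0.6) sits on the 10 bp interpolation grid next
to the planted 0.5; the fill-metric suppression median (0.303) matches
its analytic planted value (0.313 — nonlinear in the fill fraction, see
the vignette); all 300 ChIP-enriched promoters are recalled with no false
calls at 1% FDR; and all 15 planted expression-rescued genes are found
with zero false selections.  The cluster ARI compares six response
clusters against two planted architecture classes, so 1.0 is not
expected; k = 2 clustering recovers the classes exactly (see the test
suite).

A thin CLI over the same functions is installed at
`inst/scripts/ndrscope` (`simulate`, `score`, `cluster`, `ndr`,
`enrich`, `pipeline` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic cohort at the given seed, runs the full
simulate → score → cluster → ndr → enrich → expression chain through the
installed package, prints the recovery report above, and writes the JSON
report to `--out`.
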