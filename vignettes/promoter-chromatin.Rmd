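---
title: "Promoter chromatin architecture with ndrscope: models, estimators, and design notes"
author: "ndrscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin architecture with ndrscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndrscope)
```

# The problem

In compact eukaryotic genomes such as budding yeast, most promoters fall
into two architectural families.  *Open* (structured) promoters show a
stereotyped organization: a nucleosome-depleted region (NDR) just upstream
of the transcription start site (TSS), bracketed by well-positioned -1 and
+1 nucleosomes, with a phased, decaying nucleosomal array over the 5' gene
body.  *Closed* (unstructured) promoters carry nucleosomes too, but at
gene-specific positions that share no common register with the TSS, so
their composite profile looks flat.  ATP-dependent chromatin remodelers
shape these architectures antagonistically: RSC maintains the NDR by
pushing nucleosomes outward, while ISW1a tends to fill it in.  When RSC
activity is removed, open-promoter NDRs gain occupancy ("fill-in") and the
+1 nucleosome and the array behind it slide upstream toward the NDR
("leftward shift"); removing ISW1 as well partially restores the wild-type
picture (suppression).

`ndrscope` implements this analysis as a reusable pipeline: TSS-anchored
window scoring of occupancy tracks with neighbor masking, promoter
classification by masked k-means on mutant/wild-type response profiles,
per-gene NDR/+1 geometry and genotype-effect metrics, FDR-based calling of
remodeler-enriched promoters, permutation tests for promoter sequence
elements (TATA, Reb1, Rsc3, poly(A)), and HybMap-style expression ratios.
Because the original deposited data are not required, the package ships a
fully specified synthetic cohort generator with planted ground truth, and
validates the entire chain against it.

# Coordinate conventions

All internal coordinates are 0-based, half-open; conversions to the 1-based
conventions of GFF3 and wiggle happen only at parse/write boundaries.  The
TSS of a transcript is the 0-based position of its 5'-most base, so on the
minus strand `tes < tss`.  All promoter geometry uses *oriented offsets*:
signed bp relative to the TSS with negative values upstream of
transcription on the gene's own strand.  "Leftward/upstream" therefore
means the same thing for genes on either genomic strand.  One inherent
asymmetry is worth noting: because windows are half-open intervals on a
discrete genome, the genomic footprints of plus- and minus-strand windows
at the same oriented offset are mirror images offset by a single base pair;
the minus-strand footprint of oriented window $[o, o+w)$ is
$[\mathrm{tss}-o-w+1,\ \mathrm{tss}-o+1)$.

# The window frame and masking

Scoring uses a fixed `PromoterFrame`: `2*flank/window` windows of `window`
bp spanning oriented offsets $[-\mathrm{flank}, +\mathrm{flank})$; the
defaults (800 bp flank, 50 bp windows, 32 columns) can be replaced by a
20 bp window frame for sequencing-resolution work.  A window is masked when

* its genomic footprint overlaps, by at least 1 bp, the transcript span
  (TSS to TES) of *any* other transcript — the "neighboring genes"
  exclusion is taken conservatively as the full span, since no narrower
  footprint is canonical;
* it extends past either chromosome end; or
* more than 50% of its bases carry no data (relevant for array-style
  tracks with ~50 bp probe spacing).

The window score is the *mean* of defined per-bp values (not the sum or
max), so scores are comparable across window sizes.

# From fragments to occupancy

Paired-end mono-nucleosome fragments (120–180 bp after the standard MNase
size filter) are reduced to their midpoints — the dyad proxy — and
smoothed with a Gaussian kernel (default bandwidth 20 bp, truncated at six
bandwidths and renormalized so total mass equals the fragment count).
Larger bandwidths blur the NDR edges into the -1/+1 peaks and measurably
hurt open/closed classification; 20 bp is a good compromise at 200
fragments per gene.

Tracks are expressed relative to the genome average as
$\log_2((v+\varepsilon)/(m+\varepsilon))$ with pseudocount
$\varepsilon = 0.1\,m$, which bounds empty positions at
$\log_2(1/11) \approx -3.46$ without distorting typical signal, and leaves
the mean of $2^{\text{out}}$ at exactly 1.  For promoter profiles the
package takes the log of the window-mean (`log2RelativeToMean` on a linear
`WindowMatrix`) rather than window-averaging per-bp logs: at MNase sampling
depth the latter is biased downward in sparse windows by Jensen's
inequality.

# Ratio matrices and masked k-means

Response profiles are $\log_2((m+\varepsilon)/(w+\varepsilon))$ on linear
window scores, with a *symmetric* pseudocount (0.1 x the pooled mean valid
window score of both matrices) so that swapping mutant and wild type
negates every valid cell exactly.

Promoters are clustered (default $k = 6$) with Lloyd's algorithm under
k-means++ seeding and a masked distance: squared Euclidean over a
profile's valid windows, scaled by (total windows / valid windows).  This
neither imputes data into neighbor-masked promoters nor favors
heavily-masked ones.  Genes with fewer than half their windows valid are
set aside as unclustered but stay in the result.  The best of 20 restarts
by inertia is kept (ties broken by the lowest run index); runs are
deterministic given the seed, and rows are processed in canonical gene-id
order so permuting the input permutes the assignments identically.
Because raw k-means labels are arbitrary, clusters are relabeled by
descending mean centroid gain over the NDR zone $[-150, +50)$: cluster 1
always shows the strongest NDR fill-in.  Clustering operates on log2
ratios; linear ratios would let high-occupancy promoters dominate the
distance.

# NDR detection

An NDR is a run of contiguous valid windows below $\theta = -0.5$ log2
units (at least 2 windows long) inside the search zone $[-350, +50)$.  Two
refinements matter in practice:

* **Flanking.**  An NDR is by definition a depleted region flanked by the
  positioned -1 and +1 nucleosomes.  A candidate run is accepted only when
  the nearest valid window beyond each end of the depleted stretch is
  occupied ($\ge \theta$); depletion that runs off the profile edge, or
  continues past the zone boundary, is promoter-distal low-coverage ground
  (in the generator, literal intergenic vacuum), not an NDR.
* **Tie-breaking.**  Among equally long eligible runs the one whose
  midpoint is closest to the TSS wins, since the NDR is the depleted
  region *just upstream* of the TSS.

Both $\theta$ and the minimum run length are exposed; the defaults were
set so the generator's open promoters are detected and flat or closed
profiles are not.  Depth is the distance from the genome-mean reference
(0) down to the run minimum.

# The +1 nucleosome and shifts

The +1 position is found on a natural cubic spline through the valid
window centers, evaluated on a 10 bp grid over $[0, +300)$ restricted
downstream of the detected NDR end (so the -1 peak cannot be picked up).
The +1 is the *first* substantial interior local maximum — "substantial"
meaning within 70% of the zone's dynamic range above its minimum.  This
definition follows the biology (the +1 is the first nucleosome after the
NDR) and is far more robust than the global argmax, which locks onto the
+2 nucleosome whenever sampling noise makes it marginally taller (a +/-165
bp error for ~1 gene in 6 at 200 fragments/gene); the prominence floor in
turn keeps spline ripples at the NDR edge from being mistaken for the
peak.  The shift is `mut - wt` in oriented bp (negative = upstream, toward
the NDR).  Shift estimates are exactly equivariant under joint
integer-window translations of both profiles.

# Fill-in and suppression

The fill-in score contrasts occupancy over the NDR between genotypes.  Two
numerical choices deserve explanation:

* **Aggregate before the log.**  The score is
  $\log_2(\overline{2^{mut}}/\overline{2^{wt}})$ over the NDR windows, not
  the mean of per-window log differences.  The wild-type NDR is nearly
  empty (a handful of fragments), and the mean-of-logs estimator is
  Jensen-biased upward by +0.2–0.3 log2 at realistic depth; aggregating
  the linear occupancies first removes most of that bias while still
  recovering a uniform log2 offset exactly.
* **Stable window set.**  Fill is evaluated over the detected NDR extended
  to the surrounding run of below-genome-mean valid windows.  The
  detection threshold $\theta$ sits in the noisy flank of the NDR, so the
  raw detected interval gains and loses marginal windows with the
  wild-type noise — a selection that biases `(mut - wt)`.  The extended
  set is bounded by values far from its 0 criterion, so it is stable and
  equal to its infinite-data limit.

For cohort-level statements the composite fill (`compositeFillIn`) — the
log2 ratio of NDR occupancy summed over genes, exactly how composite
metagene profiles are read — is the centered estimator; per-gene scores
remain available for per-gene screens and the suppression index.

The suppression index is $1 - e_{double}/e_{single}$ per gene and per
metric (fill-in with a 0.3 log2 floor on the single-mutant effect; shift
with a 20 bp floor), 0 meaning no suppression and 1 full restoration.  It
is invariant under common rescaling of both effects.  Note that because
the planted double-mutant *parameters* interpolate linearly between
mutant and wild type, the index recovers the planted suppression exactly
on the shift metric, while on the log-scale fill metric the planted index
is itself a nonlinear function of the fill fraction; the generator
therefore records analytic per-metric planted indices and recovery is
judged against those.

# Open/closed classification

`structure_score = depth + phasing amplitude`, where the phasing
amplitude is the largest autocorrelation of the mean-subtracted profile
over the gene-body zone $[+50, +750)$ at nucleosome-repeat lags (140–220
bp; with 50 bp windows, lags of 3–4 windows), floored at 0.  A promoter
is *open* iff an NDR is present and the score reaches $\tau = 0.8$.  On
the default generator cohort this classifies promoters with >= 95%
accuracy; the errors are almost entirely open promoters whose NDR call is
lost to sampling noise and closed promoters whose shifted architecture
happens to leave a flanked depleted stretch near the TSS.

# Enrichment calling and permutation tests

Remodeler-enriched promoters are called from per-gene TSS scores (mean
log2 enrichment over +/-250 bp) against an empirical null built from >=
1000 circular per-chromosome shifts of a track, followed by
Benjamini–Hochberg control.  When the scoring window matrix is supplied,
each gene's null is evaluated over the same valid-window footprint as its
observed score; genes with partially masked TSS zones have noisier
scores, and a full-interval null would understate that variance and
inflate their significance.  Two null models are available: shifting the
matched input/control track (preferred — the null is then free of true
promoter enrichment) and shifting the chip track itself (conservative when
many promoters are truly enriched, because shifted windows land on them).
Empirical p-values use the plus-one rule and are never 0; calls at a
stricter FDR are always a subset of calls at a looser one.

Sequence elements default to standard yeast consensi — TATA box
`TATAWAWR`, Reb1 `TTACCCG`, Rsc3 `CGCGC` (presence calls), and poly(A)
tracts as counted runs of >= 5 consecutive A on either strand — scanned
exactly (IUPAC, greedy non-overlapping, `N` never matches) over the
oriented promoter region $[-500, +50)$.  Neither the site definitions nor
the scan region are canonical in the source literature; both are
configuration, not conclusions.  Category enrichment uses the mean
statistic against means of random same-size draws from the background
without replacement; gene-set intersections get a hypergeometric tail with
an optional label-shuffling cross-check.  Permutations preserve neither
promoter length nor GC composition — plain uniform resampling is used.

# Expression (HybMap-style)

Probe intensities are scaled per replicate to the median of the
non-hybridizing (zebrafish-style) control probes, which removes
per-hybridization gain exactly and is idempotent.  Gene level = median
over the gene's sense probes within a replicate (robust to single failing
probes; the summarizer is a package choice), then the mean over
replicates; antisense likewise.  "Mean mutant/wild-type ratio" is read as
the mean of per-replicate log2 ratios (replicates paired by index), with
ratio-of-means as the fallback for unpaired summaries.  The
suppressed-gene screen selects genes at least 1.5-fold down in the single
mutant (log2 <= -0.585) whose double mutant restores at least half of the
effect; both thresholds are explicit configuration, as the source analysis
did not state its own.  Antisense levels are computed but no antisense
change statistic is implemented.

# The synthetic cohort: a stated world

The generator emits a complete cohort — BED6 annotation with a gene-class
sidecar, chromosome sizes, promoter FASTA with planted elements,
per-genotype fragment BEDs, chip/input bedGraphs, per-genotype probe
tables, and a JSON ground truth — deterministically from one seed.

* **Layout.**  300 genes, 30 per chromosome, random strands, lengths
  800–2000 bp; intergenic gaps are a mixture of long spacings (75%,
  normal around 2.2 kb, floored at 1.6 kb = 2 flanks, so most promoters
  are unmasked) and short spacings (25%, uniform 0.4–1.4 kb) that
  deliberately exercise the neighbor-masking path.
* **Dyad model.**  Open promoters: Gaussian dyad components at -220 (-1)
  and +60 (+1) with sigma 20 bp, then phased peaks at +60+165k (k = 1..4)
  with sigma growing 5 bp per step and weight decaying x0.8; the NDR zone
  [-180, -20) carries a uniform baseline of 0.05 nucleosome-equivalents.
  Closed promoters: the same components and NDR zone, all translated by a
  per-gene uniform phase in [0, 165) — the whole architecture, including
  the (mostly filled, 0.6) NDR baseline, moves together, which is what
  "no consensus register with the TSS" means.  Fragments: 200 per gene
  and genotype, lengths normal(147, 10) clipped to [120, 180], midpoint
  at the sampled dyad.
* **Genotypes.**  RSC loss raises the open-promoter NDR baseline to
  $b + f(1-b)$ (fill fraction f = 0.6) and translates the +1 and
  everything downstream by s = -40 bp; ISW1 loss nudges gene-body
  components (downstream of the +1) by -10 bp; the double mutant applies
  $f(1-\sigma)$ and $s(1-\sigma)$ with suppression sigma = 0.5.
* **ChIP.**  Log2-enrichment tracks as 25 bp noise bins (SD 0.25) plus
  per-promoter plateaus over +/-200 bp; closed promoters get twice the
  open effect (1 vs 2 log2), matching the observation that unstructured
  promoters carry the highest remodeler occupancy.  A matched input track
  contains noise only.
* **Sequences.**  Promoter sequences over [-500, +50) are scrubbed of all
  default motifs (both strands), then elements are planted at
  per-architecture rates (open: Reb1 0.6, Rsc3 0.6, TATA 0.1, poly(A)
  count ~ Poisson(2); closed: Reb1/Rsc3 0.1, TATA 0.7, poly(A) ~
  Poisson(0.3)); each sequence is re-scanned and regenerated on collision,
  so the recorded motif content is exact by construction.
* **Expression.**  Three replicates per genotype with a shared
  per-replicate array gain (removed by control scaling), probe noise SD
  0.15 log2; coding and ncRNA genes are planted 2-fold down in the single
  mutant (tRNAs unaffected), and 15 coding genes are "restored" in the
  double mutant to 20% of the single-mutant effect.

The ground truth records, besides the raw planted parameters, the
*infinite-fragment-limit* value of every geometry metric: the closed-form
expected window profiles (Gaussian and smoothed-uniform component masses
are available analytically, and the genome-mean density is exactly total
fragments / genome size) are pushed through the same estimators the
pipeline uses.  Recovery tests therefore separate estimator bias from
sampling noise.

What a green test does *not* establish: the generator has no
sequence-dependent nucleosome energetics (motifs and architecture are
planted independently), no replication or transcription dynamics, no
MNase digestion bias or read-level error model, iid (not autocorrelated)
ChIP noise, and literal fragment vacuum between gene architectures where
real genomes have neighboring chromatin.  The flanking rule in NDR
detection exists partly because of that last artifact, and performance
numbers on real data will differ.

# Known limitations

* Per-gene NDR calls at 200 fragments/gene miss ~3–8% of true open
  promoters; cohort-level statements are correspondingly more reliable
  than per-gene ones.
* The +1 locator needs >= 4 valid windows for the spline and declines to
  answer (flagged NA) when the zone has no qualifying interior maximum.
* Divergent tandem promoters sharing an NDR receive no special handling.
* The circular-shift null treats each chromosome's track as exchangeable
  under rotation; strong large-scale trends would violate that.
* `WindowMatrix` TSVs carry no mask distinct from NA scores: masked and
  no-data cells are both NA after a round trip.

# A short tour

```{r eval = FALSE}
dir <- tempfile()
truth <- generateCohort(syntheticConfig(seed = 1), dir)
res <- runPipeline(dir, file.path(dir, "out"), seed = 1)
truthReport(truth,
            architecture = res$architecture, clusters = res$clusters,
            chipCalls = res$chipCalls, screen = res$screen)
```

The acceptance criteria in `tests/testthat/test-acceptance.R` run exactly
this kind of cohort and assert the recovery bands discussed above;
`scripts/acceptance.R` regenerates the cohort at an arbitrary seed and
prints the same recovery report.
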