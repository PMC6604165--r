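---
title: "Single-nucleosome histone modification peak calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-nucleosome histone modification peak calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpeak)
```

## The problem

Conventional histone-modification ChIP-Seq produces peaks spanning hundreds
to thousands of base pairs, because formaldehyde crosslinking smears signal
well beyond the nucleosome actually carrying the mark. Histone
modifications, however, live on individual nucleosomes (~147 bp of DNA).
`nucpeak` resolves ChIP-Seq enrichment to single nucleosomes by changing the
coordinate system of the test: instead of scanning the genome for enriched
windows, it takes genuine nucleosome positions mapped by *native* MNase-Seq
(no crosslinking) as fixed units and asks, for each nucleosome and each
mark, whether the ChIP fragments assigned to that nucleosome are enriched
over background.

Because every mark is tested against the *same* nucleosome map, per-mark
calls join exactly per nucleosome, which is what makes multivalent states
(several marks on one nucleosome) and per-gene "histone codes" countable
quantities rather than overlap heuristics.

## Coordinate model

All coordinates are 0-based half-open (BED convention); DANPOS-style
1-based tables are converted on read. The nucleosome map is sorted and
overlap-trimmed at construction: where two calls overlap, both are cut at
the midpoint of the overlap, so the map partitions the covered bases. A
fragment belongs to the nucleosome whose interval contains its midpoint
`floor((start + end) / 2)`. Midpoint containment was chosen over any-overlap
because it is unambiguous (each fragment has exactly one midpoint, each
midpoint lies in at most one interval of a partition) and is the standard
convention for nucleosome-centric counting. The lookup is a per-chromosome
binary search, verified in the test suite against an exhaustive all-pairs
scan.

## The peak-calling model

For nucleosome $i$ and one mark, let $k_i$ be the ChIP fragment count and
$m_i$ the input count scaled by the library-depth ratio
$N_{\mathrm{chip}} / N_{\mathrm{input}}$. The pipeline applies, in order:

1. **Candidate gate.** $k_i - m_i \ge$ `min_excess` (default 4, inclusive).
   The comparator is depth-scaled input, consistent with the ChIP-vs-input
   test downstream.
2. **Shape filter** (below) on the within-nucleosome midpoint distribution.
3. **Double Poisson test.** Two one-sided upper-tail tests,
   $P(X \ge k_i)$ for $X \sim \mathrm{Poisson}(\lambda)$, against
   * $\lambda_{\mathrm{local}}$: the ChIP midpoint count in a
     `local_window_bp` window (default 10 kb) centered on the dyad,
     excluding the nucleosome's own interval, rescaled to the nucleosome
     width and floored at the genome-wide rate
     $N_{\mathrm{chip}} w / G$ (effective genome size $G$, default
     2.7 Gb); windows truncated at chromosome ends renormalize their
     denominator;
   * $\lambda_{\mathrm{input}} = \max(m_i, N_{\mathrm{chip}} w / G)$, the
     floor preventing zero-mean degeneracy.
4. **Fold gates.** $(k_i + c)/(\lambda_{\mathrm{local}} + c) \ge 4$ and
   $(k_i + c)/(m_i + c) \ge 4$ with pseudocount $c = 0.5$ (guards division
   by zero; any fixed small $c$ behaves identically at calling counts).
5. **FDR gates.** Benjamini–Hochberg adjustment applied per mark,
   genome-wide, *separately* to the local-test and input-test p-value
   families (two families, matching the two backgrounds); both adjusted
   values must be $\le 0.01$. Shape-rejected candidates never enter the
   families — they are removed before testing, so they do not dilute the
   adjustment.

A peak is accepted only if all six gates pass ($P \le 0.01$, fold $\ge 4$,
FDR $\le 0.01$, each for both comparisons); the two tests are combined by
conjunction. Every rejection records the first failed gate, so the full
decision trail is inspectable in the output.

## Crosslinking-artifact shape filter

Crosslinking can deposit fragment pileups that pass any enrichment test but
are not nucleosomal marks: *oblique* peaks (mass shifted off the dyad) and
*U-shaped* peaks (mass at both edges, dip at the dyad). Genuine nucleosomal
fragments concentrate their midpoints around the dyad. The filter bins the
ChIP midpoints inside the nucleosome into `shape_n_bins` (default 21, odd
so a central bin exists; boundary midpoints go right, last bin closed) and
computes two statistics:

* **asymmetry** — the center-of-mass offset from the central bin in units
  of the half-width, in $[-1, 1]$; $|a| >$ `shape_a_max` (default 0.5,
  i.e. the center of mass beyond halfway to the edge) is called oblique;
* **dip ratio** — mean coverage of the central third of bins over the mean
  of the flanking thirds; $d <$ `shape_d_min` (default 0.5, central
  coverage less than half the flanks) is called U-shaped. Zero flank
  coverage yields an `Inf` sentinel: a dyad-peaked profile is never
  filtered.

These are the simplest statistics that operationalize the two artifact
classes; the thresholds are validated by planted-artifact recovery in the
test suite, where artifacts are planted at 0.4 nucleosome-widths off the
dyad — far beyond both thresholds by construction. Profiles with fewer than
`shape_min_reads` (10) fragments are not evaluable and pass through
(`low_coverage_pass`): sparse candidates should be judged by the
statistical tests, not by noisy shape estimates. Shape is evaluated on ChIP
midpoints only; input profiles are far too sparse per nucleosome.

## Multivalent states and TSS codes

Accepted per-mark calls are joined on nucleosome id. A nucleosome's
category is its mark set in canonical order joined with "+", with the
field's aliases `T` = H3K4me3/H3K9ac/H3K27ac, `D` = H3K4me3/H3K9ac,
`A` = H3K4me3. Occupancy is summarized genome-wide (denominator: all
nucleosomes in the map) and within ±2 kb of any TSS (denominator:
nucleosomes whose dyad lies in some TSS window — a within-window relative
occupancy; the dyad, not interval overlap, decides proximity because it is
a point and unambiguous).

A gene's histone code is the string of per-nucleosome categories (with an
explicit `unmarked` symbol) for nucleosomes whose dyads fall within ±2 kb
of the TSS, ordered 5′→3′ in the direction of transcription; on the minus
strand genomic order is reversed so "downstream" always means downstream of
transcription. A dyad exactly at the TSS counts as downstream
(deterministic, and the TSS nucleosome travels with the transcribed side).
The ±2 kb default matches the occupancy analyses; it is a parameter, since
wider promoter neighborhoods are sometimes of interest.

For clustering, codes are featurized as a fixed-width one-hot matrix: the
15 nucleosomes nearest the TSS on each side, each slot one-hot over the
category alphabet, genes with fewer nucleosomes padded with `absent`.
One-hot slots were chosen over signal intensities because the calls are
binary by design; `stats::kmeans` (fixed seed, multiple restarts, labels
renumbered by descending size) does the clustering, with k = 13 as the
default reporting granularity. Mark counts per gene
(upstream/downstream/total for `T`, `D`, `A`, and all marked slots,
`codes`) are related to expression by Spearman correlation — rank-based,
because RPKM is heavy-tailed and the planted relationships are monotone,
not linear.

## The simulator

`simulate_dataset()` generates the setting the method assumes, with full
ground truth:

* **Nucleosome array**: phased tiling, 200 bp spacing, 147 bp width —
  the canonical repeat length and wrap.
* **MNase library**: per nucleosome, `Poisson(mnase_depth = 20)` fragments
  with midpoints from a truncated normal around the dyad
  (`fuzziness_sd_bp = 20`); truncated-normal rather than uniform jitter
  mimics phased nucleosomal protection.
* **ChIP libraries** (one per mark): a uniform background process at
  `background_rate = 0.02` fragments/bp (a deeply sequenced library,
  ~60M fragments at genome scale) plus `Poisson(fold × rate × width)`
  dyad-jittered fragments at each truly marked nucleosome
  (`enrichment_fold = 20`).
* **Input**: pure background at `input_depth_factor = 4` times the ChIP
  background rate. One deep input shared across all marks is standard
  practice, and it matters quantitatively here: at desk scale, 10% of
  nucleosomes marked at 20-fold means signal is a large fraction of the
  ChIP library, so the depth-ratio scaling raises the expected scaled
  input count per nucleosome; with a *shallow* input the Poisson noise on
  those few counts sits right at the fold-change gate and rejects a
  substantial share of genuine 20-fold signals. Deep input leaves the
  scaled mean unchanged but shrinks its variance, which is exactly what a
  well-designed experiment does.
* **Artifacts**: planted on never-marked nucleosomes, midpoints at
  dyad ± 0.4 × width (sd 5 bp) — oblique one-sided, U-shaped an equal
  mixture of both sides — so the planted shapes exceed the filter
  thresholds by construction and filter recovery is a deterministic check.
* **Genes and expression** (when `n_genes > 0`): TSSs on nucleosome dyads
  with non-overlapping windows, random strands; each gene plants a run of
  `T` nucleosomes downstream (0–6) and `A` upstream (0–3);
  `RPKM = 10 × (downstream T count) + lognormal noise`, a monotone planted
  relationship for the correlation stage.

The default configuration — one 200 kb chromosome, 1,000 nucleosomes, 100
marked (multivalent categories drawn over the five canonical marks), 30
artifacts, 20-fold enrichment — is the reference condition the validation
suite runs end to end. All randomness flows from one seed; a fixed seed
gives byte-identical output files.

What the simulator does **not** emulate: MNase sequence preference, GC
bias, duplicate reads, copy-number variation, fuzzy or overlapping
nucleosomes, chromatin-domain structure, and broad-domain marks spanning
many nucleosomes. Passing the recovery tests therefore demonstrates that
the statistical machinery is implemented correctly and calibrated under
its own model, not that real HepG2-scale data would yield any particular
recovery; on real data the local-background window and the shape
thresholds carry the burden the simulator's clean background does not
exercise.

## Numerical and degenerate-input choices

* Overlapping map calls: trimmed at the overlap midpoint; calls emptied by
  trimming are dropped with a warning.
* Dyads displaced outside a trimmed interval are reset to its midpoint.
* `P(X ≥ k)` is computed as the Poisson survival function at `k − 1`
  (`stats::ppois`, stable in the far tail); `P(X ≥ 0) = 1` exactly.
* Zero-λ degeneracy is impossible: both λ's are floored at the genome-wide
  rate.
* Fragments on chromosomes absent from the map are skipped with a warning
  (partial references are common), not an error.
* Empty candidate sets, empty peak files, and genes on missing chromosomes
  all produce well-formed empty outputs rather than errors.
* Validation problem sizes: 1,000-nucleosome recovery runs, 10,000-draw
  null calibration, 4,000-nucleosome TSS runs — sizes at which every
  brute-force oracle is still exhaustively computable, which is what makes
  the oracle comparisons meaningful.

## Known limitations

* The Poisson model ignores overdispersion; biological replicates are not
  modeled (no negative-binomial option).
* Broad domains (H3K9me3/H3K27me3 spreading over many nucleosomes) are
  called nucleosome-by-nucleosome; the local-background window then
  contains signal, making calls inside large domains conservative.
* The candidate gate compares against depth-scaled input using library
  totals; when enriched regions are a large fraction of the library this
  overstates the input expectation (the simulator section quantifies the
  consequence and the experimental remedy).
* One TSS per gene (the 5′-most transcript start); alternative promoters
  are not separated.
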