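---
title: "depbias: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{depbias: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depbias)
```

This vignette is the package's account of its science: what each stage
computes, which conventions were chosen where the method left room, and
what the synthetic generators do and do not emulate.

## Screen quantification

Amplicon reads follow the stacking-barcode layout
`[stagger][barcode][anchor][protospacer][...]`: a variable-length random
prefix staggers the sequencing cycles across samples, the barcode
identifies the sample, and the anchor is the constant vector sequence
immediately 5' of the protospacer. `demultiplex()` assigns a read to a
sample when the barcode matches exactly at offset `stagger_len` *and* the
anchor follows it; sheets in which two samples' patterns could claim the
same read are rejected at load time, which makes assignment unique and
order-independent. The anchor is part of the ambiguity check deliberately:
without it, any two samples with different stagger lengths are formally
compatible with some read.

`count_guides()` increments exactly one guide per read iff the substring
immediately after the anchor equals a library protospacer exactly — no
mismatch, no indel, qualities ignored (they cannot change an exact string
comparison). Everything else is booked as unassigned, so per sample
`assigned + unassigned` always equals the demultiplexed read count. When a
library mixes protospacer lengths (18–23 nt accepted), longer protospacers
are tried first so a guide extending another's sequence wins the exact
match. Reverse-complement matching is off: the amplicon orientation is
fixed by the PCR design. Representation QC flags samples below 1000x
fold-representation (assigned reads per guide), the usual maintenance
floor for dropout screens.

## Essentiality and biased-dependency scoring

Samples are scaled to a common read total before any ratio is formed; the
default target is the mean raw column total, configurable to a constant
such as 1e6 — the choice only shifts all abundances jointly and cancels in
the fold change. Per guide,

$$\mathrm{lfc}_i = \log_2\frac{\mathrm{final}_i + c}{\mathrm{initial}_i + c}, \qquad c = 1,$$

and the gene-level ES is the arithmetic mean of its guides' values. Two
conventions here were genuinely open:

* **Pseudocount placement.** The screen formula as usually printed
  ("final + 1 / initial") is typographically ambiguous, and a bare
  denominator can be zero. The package applies the pseudocount to both
  numerator and denominator: equal abundances give exactly 0, zero/zero
  gives 0, and the estimator stays finite everywhere.
  `pseudo_numerator_only = TRUE` reproduces the literal reading for
  comparison; it requires strictly positive initial abundances.
* **Sign of the biased ES.** `biased_es = mean(ES, comparison group) -
  mean(ES, focal group)`, so a dependency confined to the focal group
  (very negative ES there) ranks at the top with a large positive value.
  The statistic is exactly antisymmetric under swapping the groups.

Ranking ties are broken lexicographically by gene symbol — stable and
reproducible. Non-targeting guides aggregate under the sentinel
pseudo-gene `NON_TARGETING`; positive-control genes keep their real
symbols but are tagged `positive_control`. Both are excluded from the
biased-ES ranking by default (they are calibration controls, not
candidate hits) and reported alongside; `exclude_controls = FALSE`
retains them, since whether the original analysis ranked them is not
documented.

One property of the estimator worth knowing: because every column is
rescaled to a common total, strong dropout of a subset of guides slightly
inflates the apparent abundance of everything else in that sample. With
the default composition (20 positive-control guides at a $2^{-3}$ effect
among 2525) the shift on neutral guides is about +0.01 log2 units —
negligible — but it grows in tiny toy libraries where the depleted
fraction is large, and the test suite accounts for it.

## Interactome enrichment and intersection

Unique-peptide fold enrichment is `case / max(control, 1)` under the
default `floor_one` policy: proteins undetected in the control — the
expected situation for a true interactor — keep a finite ratio, and
proteins absent from both conditions are dropped. The exact treatment of
zero denominators in the original analysis is not documented, so the
policy is explicit and configurable (`exclude` drops control-absent rows
instead). Threshold comparisons are inclusive (`>= 5`-fold for "at least
5-fold"). Set intersection harmonizes identifiers case-insensitively with
an optional alias map, because immunoprecipitation and proximity-labeling
datasets often use different capitalization or synonyms for the same
protein; inclusion–exclusion holds exactly on the harmonized sets.

## Loops and peaks

All coordinates are 0-based half-open (BED convention) and pass through
I/O verbatim — no re-basing. Two intervals overlap iff they share a
chromosome and at least 1 bp (`max(starts) < min(ends)`); abutting
intervals do not overlap. A test loop is *shared* iff a single reference
loop overlaps it anchor-for-anchor (left with left and right with right);
matching different reference loops on the two sides does not count. The
classification partitions the test set (`shared + gained = n`), and
reference loops matched by no test loop are reported as `control_only`.
An optional `slop` pads anchors before the overlap test; the default is
0 because the designation rule says only "overlapped".

Loop length is the anchor-midpoint to anchor-midpoint distance. The
alternative (anchor-start distance) is available via `method = "start"`;
midpoint distance is the default because it is robust to anchor width and
matches how bin-resolution loop calls are usually summarized. The median
is the standard order statistic (mean of the middle two for even n).

Peak-set Venn overlap counts, per side, the peaks overlapping at least one
peak on the other side; the two directions can differ when one peak spans
several, which is why both are reported rather than a single "overlap"
number.

The BED/BEDPE parsers are hand-written on purpose: the package needs
verbatim 0-based round-trips, BEDPE support and parse errors that name the
offending line, none of which the generic importers provide. `track`,
`browser` and `#` lines are skipped; BEDPE rows with anchors on different
chromosomes violate the loop invariant and are rejected.

## Assay statistics

Competition-proliferation series are normalized to the day-3 baseline
(the earliest reliable flow-cytometry readout after infection), so the
baseline maps to exactly 1.0; an optional co-tracked control series
divides out shared culture effects day by day. Drug sensitization is the
day-matched treated/vehicle ratio, below 1 indicating drug-specific
depletion. DNA-fiber restart efficiency is the per-fork IdU/CldU tract
ratio, which cancels fork-speed differences between conditions; fibers
with a non-positive CldU tract are excluded with a warning, and fibers
with a zero IdU tract (no restart) are kept as ratio 0 by default — a
biological outcome, not a measurement failure — with
`include_zero_restart = FALSE` to drop them, since the original scoring
of such fibers is not documented. The two-condition comparison is a
two-tailed Mann–Whitney rank-sum test: exact when both arms have at most
20 fibers and no ties, the normal approximation with tie correction
otherwise (fiber experiments score 150+ fibers per arm, where the
approximation is accurate).

## Synthetic generators

The generators define the study conditions under which the pipeline is
validated; all randomness flows from one explicit seed and regeneration is
byte-identical.

* **Screen** (`screen_sim_config()`): 2405 targeting guides over 381 genes
  (119 genes get 7 guides, 262 get 6 — mean 6.3, matching a design of "at
  least five to six" per gene), 100 non-targeting guides, 20
  positive-control guides over 6 pan-essential genes; 6 cell lines (2 AML,
  4 other), one initial and one final sample each; 1000x per-guide
  representation. Counts are negative binomial with dispersion 0.05 — a
  tight, plasmid-pool-like spread appropriate for a well-maintained
  screen — with expected final counts equal to the initial expectation
  times $2^{\mathrm{effect}}$. Planted effects: -3 (pan-essential
  controls, all lines), -2 in the AML lines only for 20 randomly chosen
  genes. FASTQ mode assembles reads in the stacking-barcode layout with an
  optional per-base substitution rate (default 0: exact-match counting is
  the contract under test).
* **Peptides** (`simulate_peptides()`): two experiments of 1500 and 1000
  proteins with 395 and 60 planted interactors, 4 of them (VPRBP, SMC3,
  SMC1A, MCM4) planted in both. Background proteins model consistently
  detected nonspecific binders: per-protein abundance
  lognormal(meanlog 2.5, sdlog 0.5) (median ~12 unique peptides) with
  independent Poisson case/control counts, chosen at design time so the
  5-fold rule's background false-positive rate is a fraction of a percent.
  Planted interactors are guaranteed `case >= fold * max(control, 1)`
  (fold 8 by default, with upward noise), so they always clear a 5-fold
  threshold; the enriched-set sizes therefore sit slightly above the
  planted counts by the background false-positive margin, and the
  dual-experiment intersection is recovered exactly because a background
  protein would need to be a false positive in both experiments at once.
* **Loops** (`simulate_loops()`): a 23-chromosome, 130-Mb-per-chromosome
  genome binned at 10 kb (anchors are one bin, placement needs a
  several-Gb binned genome to stay collision-free at full scale).
  Reference loops: 10,662 with lognormal lengths, median 225 kb,
  sdlog 0.6. Test loops: 8,000 shared (reference anchors jittered by less
  than half a bin, preserving overlap) plus 3,871 gained placed disjoint
  from every reference anchor bin, for 11,871 total; the gained-length
  median is solved analytically from the lognormal quantile relation so
  the mixed test set hits the 310 kb target. Because lengths snap to the
  10-kb grid, the realized reference median lands on a grid value
  (220–230 kb around the 225 kb target); the test median, further from a
  grid midpoint, lands within about 1%.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: sequencing quality profiles and indels;
chimeric/recombined amplicons; guide-level efficacy variation and
off-target effects; copy-number artifacts in screens; correlated protein
abundances and shared contaminant structure across proteomics runs;
Hi-C matrix-level noise, resolution-dependent loop-calling uncertainty,
or anchor-width variation. The pipeline's contracts (exact counting,
set algebra, overlap semantics, estimator arithmetic) are exercised
fully; biological realism of the inputs is not claimed.

## Problem sizes and numerical choices

The test suite runs the screen generators at full library scale
(2525 guides x 12 samples) for the calibration and recovery checks
(10 seeds each), brute-force oracles on pools of up to 1000 reads and up
to 500 loops, the loop generator at full scale (10,662 + 11,871 loops)
for the median checks, and 1000 replicates of n = 150/arm for the
Mann–Whitney null calibration. Normalization requires every column total
to be positive and reproduces targets to a 1e-9 relative tolerance;
ES values are finite for every gene with at least one guide by
construction of the symmetric pseudocount. Degenerate inputs error
early and by name: zero-total samples, empty libraries and loop sets,
missing baseline days, non-positive CldU tracts, ambiguous sample
sheets, trans-chromosomal loop rows.

## Known limitations

* No replicate-aware variance model or p-values for screen hits: the
  design has one initial and one final pool per line, and genes are
  ranked by effect size only.
* The enrichment rule is a hard threshold on a peptide-count ratio; no
  FDR control is attempted (peptide-level identification confidence is
  upstream scope).
* Loop classification is purely positional; it does not use loop
  strength, and the `control_only` designation of a reference loop can
  occasionally be absorbed by a jittered shared loop of an adjacent
  reference loop (the shared/gained labels themselves are unaffected).
* The CLI covers the pipeline stages one at a time; orchestration across
  stages is left to the caller (or the R API).
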