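---
title: "Analysing cell-SELEX sequencing rounds with selexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing cell-SELEX sequencing rounds with selexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexr)
```

## The setting

A SELEX experiment iterates rounds of selection on a random
oligonucleotide library: members that survive a round (by binding the
target, being internalized by cells, resisting nuclease treatment) are
amplified and carried into the next. Deep sequencing of each round's pool
turns the analysis into a sequence-counting problem. selexr implements the
full downstream path — read filtering, variable-region extraction,
clustering, enrichment statistics, blot-band quantification and
cross-selection comparison — plus a generative simulator of the rounds
themselves, so that every analysis stage can be validated against planted
truth rather than only against real (and unrepeatable) selections.

The library design this package defaults to is a 40-nt random region (N40,
equimolar base composition) between the fixed flanks
5'-`TCGGGCGAGTCGTCTG` and `CCGCATCGTCCTCCCTA`-3', sequenced single-ended;
all defaults are overridable through `library_design()`.

## Read filtering and variable-region extraction

`filter_and_extract()` accepts a read only if

1. it is at least `min_read_length` (default 70) nt long;
2. the left constant flank occurs in it, and the right constant flank
   occurs to the right of the left one (within `max_flank_mismatch`
   mismatches each, default 0 — the strictest reading, since sequencer
   adapters are printed exactly and tolerance is a data-quality decision
   best made explicitly); and
3. the extracted variable region between the flanks is `vr_min`–`vr_max`
   (default 38–42) nt.

The rules are applied in that order and the first failing rule is the
recorded rejection reason, which makes the filter report a deterministic
partition: `passed + rejected reasons = total`, always. When the forward
orientation fails and `search_reverse_complement` is enabled, the reverse
complement of the read is searched and accepted reads are re-oriented; a
flank occurrence is chosen as the best (fewest mismatches, then leftmost)
hit, which resolves multiple hits deterministically. Coordinates in all
outputs are 1-based inclusive, the R/Bioconductor convention.

Degenerate inputs are values, not errors: an empty input file produces an
empty filter result with a warning at the pipeline level, and reads failing
any rule are counted, never dropped silently.

## Clustering by mismatch radius

Unique variable regions are pooled across all rounds (selection operates on
sequences, not on rounds) and visited in decreasing order of total read
count, with exact count ties broken lexicographically so results never
depend on input order. A visited sequence becomes a new cluster centroid
exactly when its distance to every previously chosen centroid exceeds the
radius (default 4 mismatches; "within 4" is read inclusively, so distance
4 blocks a centroid). All remaining sequences join their nearest centroid.
A sequence equidistant from two or more nearest centroids is *ambiguous*
and belongs to no cluster — these are reported with the tied cluster ids.
By default no cap is placed on member distance; setting
`max_assignment_distance` moves sequences beyond the cap into the
ambiguous set flagged `"too_far"`.

Distances are Hamming (mismatch counts) for equal-length pairs — the
natural metric for a fixed-length variable region — and Levenshtein edit
distance when the admitted 38–42-nt length range makes positional
comparison undefined. The implementation computes Hamming distance matrices
by one-hot encoding and matrix multiplication; the test suite checks the
whole procedure against an independent loop-based transcription of the
clustering rules on hundreds of randomized pools, and against hand-traced
cases.

## Enrichment and trajectories

Pool diversity collapse is summarized per round as

$$\%\,\mathrm{enrichment} = \left(1 - \frac{\text{unique sequences}}{\text{total reads}}\right)\times 100,$$

0 for an all-distinct pool and approaching 100 as few sequences dominate.
(The formula admits a second parse — subtracting the percentage from 1 —
which lands outside [0, 100] and is therefore rejected.) A round with zero
reads has no defined enrichment and errors; a round absent from a
trajectory is reported as missing rather than zero.

`abundance_trajectory()` reports, per cluster and round, the
cluster-inclusive share (centroid plus members) and the centroid-exact
share (the centroid sequence alone). Published per-round percentages of
named clones do not always say which of the two they are, so both are
always computed; cluster-inclusive is the headline because sequencing
errors scatter a clone's reads into satellites within the radius.
Cluster-inclusive shares, plus the ambiguous (and any uncapped) rows,
partition each round: they sum to 100 within floating-point tolerance
(1e-9 in the tests).

`mutation_profile()` counts, at each centroid position, the member
sequences differing there; members whose length differs from the
centroid's are excluded from the positional profile (indel placement is
alignment-dependent) but stay in all abundance tallies, and their number is
attached as an attribute. `motif_conservation()` splits the profile mass by
a motif span — a conserved motif is exactly one with zero in-span
mismatches, the pattern expected when selection pressure acts on a
structural motif while tolerating variation elsewhere.

## Band quantification

Northern-blot densitometry is summarized by three ratios, each in arbitrary
units and therefore scale-invariant:
`band_ratio = (aptamer - background) / (U6 - background)` with per-band
backgrounds; `relative_enrichment = aptamer ratio / library ratio` (fold
binding versus the unselected pool); and the internalized fraction
`100 × ratio(RNase-treated) / ratio(untreated)` — RNA inside the cell
survives the RNase, surface-bound RNA does not. A non-positive net loading
control is an error (the lane is uninterpretable); a non-positive net
aptamer band is physically "no detectable band" and is clamped to a zero
ratio with a warning at the table level (`quantify_lanes()`), while the
low-level `band_ratio()` reports it as a negative value for transparency.

## Cross-selection comparison

`global_align()` is a Needleman–Wunsch global aligner with simple default
scores (match 1, mismatch 0, gap -1) chosen for interpretability: the
score is then (matches − gap columns). Among equally optimal alignments
the one with the most matched columns is selected (a secondary dynamic
program), which makes `percent_identity()` symmetric in its arguments;
remaining ties break deterministically diagonal-first. Percent identity
divides matched columns by the alignment length (default) or by the
shorter sequence. Identity values for variable regions from different
selections are qualitative — different aligner parameterisations shift
them by a few points — which is why the aligner's parameters are exposed
rather than fixed.

## The selection simulator

`run_selection()` generates per-round reads with the statistical structure
the analysis assumes:

* **Library**: `n_library` distinct founder VRs drawn uniformly
  (equimolar bases), uniform starting fractions.
* **Selection**: one multiplicative coefficient per founder,
  $f_i' = s_i f_i / \sum_j s_j f_j$. A single coefficient deliberately
  folds binding, internalization, nuclease survival and amplification
  into one number: these factors are not separately identifiable from
  round-level count data, and one factor suffices to reproduce
  early-takeover dynamics.
* **Sequencing**: a multinomial draw of `depth_per_round` reads, each
  assembled as flank + VR + flank, with independent per-base substitution
  errors (uniform over the three alternatives). Indel (homopolymer) error
  is deliberately not modeled so that the planted truth stays exactly
  recoverable under Hamming distance. An optional protected motif span
  receives no errors, emulating a conserved motif.

Defaults are the study conditions the package is designed around:
1000 founders, 7 rounds, 10,000 reads per round, per-base error 1e-4, and
three sticky founders with coefficients 9700/1250/500 against a background
of 1. Those coefficients were chosen once so that the expected round-1
shares are roughly 78 %, 10 % and 4 %: a regime in which the top clone
exceeds 63 % of round 1 and pool enrichment exceeds 88 % in round 1 and
99 % from round 2 on — the dynamics reported for real cell-SELEX
selections dominated by sticky sequences. With uniform founder fractions
the implied per-round advantage is large, which is exactly the point: a
sticky sequence enriched from ~1/1000 to ~3/4 of the pool in one round.

Sticky founders are kept pairwise more than twice the cluster radius apart
(minimum separation 9 for radius 4), so planted families are recoverable
as distinct clusters by construction; for random 40-mers this is almost
surely true anyway and is enforced deterministically under the seed.

What the simulator does **not** emulate: PCR amplification bias as a
separate process (unidentifiable from `s` at this resolution), Ion-Torrent
homopolymer indels, chimeric reads, round-to-round changes in stringency
(they are folded into the single coefficient), and cross-contamination.
Passing tests on simulated data therefore demonstrate correctness of the
analysis under a clean substitution-error model — not robustness to every
artefact of a real sequencing run.

## Reproducibility and problem sizes

Every stochastic function is driven by the seed in `selex_sim_config()`;
`run_selection()` resets the RNG from it, so a config reproduces its
simulation exactly, and the pipeline is deterministic given its input —
re-running writes byte-identical tables. The test suite validates the
clustering against a brute-force oracle on pools of up to 50 unique
sequences (hundreds of randomized pools), and the end-to-end benchmark
uses the planted single-founder scenario (s = 10 from a 1 % starting
fraction, 10,000 reads per round, 7 rounds), checking the recovered
trajectory against the closed-form update within three multinomial
standard errors per round. These sizes were chosen to exercise every code
path at full statistical resolution while keeping the whole suite quick to
run on a laptop.

## Known limitations

* Clustering materialises the full unique-by-unique distance matrix;
  pools beyond a few tens of thousands of uniques need chunking that the
  package does not currently provide.
* Mixed-length pools fall back to `utils::adist` for cross-length pairs,
  which is markedly slower than the vectorized Hamming path.
* The per-round enrichment statistic conflates sequencing error with
  true diversity: every miscalled base mints a new "unique" sequence, so
  enrichment saturates below 100 at a level set by the error rate.
* Percent identity between variable regions depends on alignment
  parameters; treat cross-selection identity values as comparative, not
  absolute.
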