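---
title: "Modelling and measuring CRISPR spacer acquisition with adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring CRISPR spacer acquisition with adaptscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

## The system being modelled

Type I-F CRISPR-Cas systems store short invader-derived sequences (spacers)
between repeats in CRISPR arrays. New spacers are cut from protospacers --
target sequences flanked at their 3' end by a GG protospacer-adjacent motif
(PAM) -- and integrated at the leader end of an array, newest first.
Acquisition proceeds by three routes:

* **naive** acquisition from an element never seen before, slow and roughly
  PAM-density-shaped with hotspots at transcriptionally active and AT-rich
  regions;
* **primed** acquisition, triggered when a pre-existing spacer matches a
  target whose PAM has escaped by mutation (e.g. TG instead of GG). The
  surveillance complex forms an R-loop at this priming protospacer (PPS),
  recruits the Cas1:Cas2-3 adaptation machinery to the displaced
  (non-primed) strand, and 3'-5' translocation concentrates the first new
  capture close to, and 5' of, the PPS on that strand;
* **targeted** (interference-driven) acquisition: a newly acquired spacer
  with a consensus PAM is itself an interference-proficient target, and
  targeting it stimulates the next capture in the same geometry. This
  positive feedback loop dominates array expansion.

`adaptscan` implements both halves of the experimental logic: an analysis
pipeline from merged amplicon reads of expanded arrays to protospacer maps,
PAM-error calls and acquisition-order statistics; and a generative
simulator of the model above that emits reads *plus* the ground truth, so
the pipeline can be validated by parameter recovery rather than by eye.

## Coordinate and orientation conventions

All coordinates are 0-based, half-open, in plus-strand space; reports are
free to re-emit 1-based inclusive. On circular replicons an interval may
run past the end (`end > L`), meaning it wraps the origin; negative
coordinates are never used. A protospacer's strand is the strand whose
5'->3' sequence equals the spacer. The PAM is the 2 nt immediately 3' of
the protospacer on that strand. `N` bases never match any motif.

Signed travel distances between two protospacers use midpoints as anchors
(the 3' end would privilege one strand; midpoints do not, and the choice
is configurable in spirit -- the distance function takes any anchor).
Distances take the shortest arc on circular replicons; the sign is
positive when the destination lies 5' of the origin *on the destination's
strand*. Exact antipodes (arc exactly L/2) are undefined and excluded.

## The capture-error taxonomy

The canonical PAM window is the dinucleotide immediately 3' of a mapped
protospacer. The slip classifier searches for GG at window offsets
-3..+3; negative offsets overlap the protospacer's 3' end, so a -1 slip
incorporates a G as the spacer's last base. The call is the smallest |s|
containing GG, ties resolved toward positive s because plus slips produce
correctly measured spacers and are the better-behaved reading. No GG in
the radius is "other". Minus slips draw spacer length from a long-biased
distribution (33-36 nt uniform) while canonical and plus slips use the
standard 32/33 split -- the qualitative coupling between minus slips and
long spacers, expressed as a simple distribution because no law for it is
established.

Flipping inserts the captured duplex in the reverse orientation, leaving
the complement of the PAM (CC) near the mapped protospacer's 5' end. The
analysis flags a flip candidate when a CC *starts* at offsets -3..+1
relative to the 5' boundary, and excludes candidates from slip statistics
-- flips and slips are otherwise not separable, and the conservative CC
rule (not NC/CN) keeps the slip spectrum uncontaminated at the price of
excluding a background fraction of unflipped spacers whose 5' context
happens to contain CC (roughly a quarter on a GC-balanced reference; the
exclusion is independent of the 3' context, so slip estimates stay
unbiased).

## The generative model

Per cell, with probability `naive_rate` a naive chain starts, or with
`priming_rate` a primed chain starts at the configured seed site. The
first event is drawn naively (uniform over GG anchors, optionally
reweighted by a hotspot profile) or by the seeded kernel; every subsequent
event is seeded by the most recent interference-proficient event -- a
canonical-PAM, unflipped capture -- which is the single rule that produces
both the PS+1 concentration 5' of the PPS and the strand alternation of
later orders. Flipped or slipped captures face a defective target (a
CC-type motif or a mispositioned GG), so they do not seed; the chain falls
back to the previous proficient seed. Chain length beyond the first event
is truncated-geometric (`feedback_mean`, default 1.5, capped at 8). Each
event integrates into CRISPR1/2/3 with weights 0.70/0.28/0.02.

The seeded kernel picks one of four quadrants -- (displaced vs target
strand) x (5' vs 3', evaluated on the new protospacer's strand) -- with
weights 0.625/0.10/0.15/0.125, then walks successive GG anchors away from
the seed in that direction, capturing at each encountered anchor with a
Bernoulli probability tuned so the mean travel is about
`translocation_mean` nt (default 150 nt; a geometric hop kernel -- the
mechanism constrains the direction, not the kernel, so it is exposed as
configuration). The walk is confined to the half-arc on circular
replicons; on linear replicons running off the end resamples the quadrant.

Two capture-level biases are modelled. First, anchors whose PAM-proximal
protospacer base is A or T are preferred (`p_at_start_bias`, default 2x),
which reproduces the preference for AGG/TGG contexts and, inside G-runs
(GGG, GGGG), the preference for the 5'-most GG -- using a later GG would
leave a G as the protospacer's terminal base. Second, capture errors:
slip offsets are drawn from `slip_dist` (defaults: +/-1 at 3%, +/-2 at
0.7%, +/-3 at 0.3%, leaving 92% canonical, matching the observed 90-93%
GG-PAM fraction), and flips with probability 0.002 given |slip| <= 1 and
0.05 given |slip| >= 2 (flips are rare overall, well under 1%, and larger
slips exacerbate them).

**Re-anchoring at ambiguous contexts.** When the drawn slip offset is not
identifiable from the resulting sequence context -- e.g. a +1 slip whose
context contains a closer GG, which the windowed classifier must read as
a smaller offset -- the simulator resamples the capture site (same
quadrant and kernel) until the classifier applied to the event's own
context returns exactly the drawn offset. Physically this says the
machinery re-anchors where G-dense contexts make the registration
degenerate; practically it makes the truth log well defined, so that
"recover the configured slip spectrum" is a meaningful round-trip test
rather than a deconvolution problem. Without this rule the recovered
spectrum is the configured one convolved with the classifier's
smallest-|s| preference, exactly as in real data.

Chromosomal captures occur with `chrom_event_rate` per cell. With no
chromosomal seed site they are naive draws over the chromosome (optionally
hotspot-weighted). A seed site on the chromosome models self-priming -- a
plasmid-derived spacer with partial chromosomal similarity driving primed
acquisition of self-targeting spacers -- and then drives 70% of
chromosomal captures, the remainder staying naive and dispersed; the
mixture puts a priming-shaped cluster on top of a sparse background, which
is what hotspot detection is designed to find. A chromosomal capture with
a canonical PAM is terminal for its cell (self-targeting is lethal; only
escape-PAM captures can be followed by further plasmid events, modelled
with probability 0.5).

Amplicons are emitted per (cell, locus) with at least one new spacer:
barcode, leader tail, repeat+spacer units newest-first, then the two
pre-existing spacers (the second doubling as the 3' primer tag). Constant
quality, optional uniform substitution noise, no PCR bias or chimeras.

## What the simulator does and does not emulate

It emulates: barcoded leader-anchored amplicons of expanded arrays across
three loci; the naive/primed/targeted route structure and its positional
statistics; slip/flip/length error coupling; locus weights; read-count
weighting via exact dereplication; chromosomal self-priming. It does not
emulate: PCR amplification bias, chimeras, quality-score structure,
paired-end merging (reads are born merged; the published merge and
barcode-pass fractions are recomputed as arithmetic, not re-simulated),
indel sequencing errors, or the composition of real plasmid sequence
(references are random DNA, so composition-dependent effects are present
only through the planted biases). Passing tests therefore certify the
pipeline's correctness and the model's internal consistency on data of
this structure -- not that real libraries are free of the artefacts
listed above.

## Numerical and design choices

* **Scale.** The synthetic plasmid is 5,000 nt and the chromosome
  60,000 nt (both circular) -- large enough for hundreds of GG anchors per
  strand and for window/step geometry to be non-degenerate, small enough
  that the full simulate-sequence-analyse loop on 10,000 cells runs in
  about two minutes. Default simulations use 1,500-10,000 cells depending
  on the statistic's variance.
* **Extraction.** The amplicon design fixes the repeat, so arrays are
  extracted by repeat anchoring with Hamming tolerance 3 (substitutions
  only, greedy left-most on overlaps) instead of de-novo repeat discovery;
  spacer length bounds are [20, 45] nt. Dereplication is exact identity
  and length on full reads, before extraction, and read counts propagate
  as weights. Barcode matching is exact at both ends, after orientation
  correction.
* **Mapping.** Exact matching on both strands, circular-aware via doubled
  sequence. An optional Hamming-k rescue exists for the self-priming use
  case; rescued hits are flagged and never enter PAM statistics. Spacers
  mapping to more than one location are excluded from positional analyses;
  spacers hitting both plasmid and chromosome are tallied as ambiguous.
* **Tables.** Percentages are rounded half away from zero to 2 decimals
  against a single grand total (the target-class total when present; the
  published locus counts sum to one less than the printed grand total, and
  the printed percentages follow the grand total).
* **Tracks.** Density tracks use a sliding window (150 nt for
  plasmid-scale, 3,000 nt for chromosome-scale views) advanced in 10 nt
  steps everywhere; the chromosome step is stated and the same step is
  adopted for the plasmid for consistency. Windows wrap on circular
  replicons and the window count is `ceiling(L / step)`.
* **Hotspots.** Baseline = median over windows with nonzero value (a
  plain median is degenerate on sparse chromosome tracks); hotspots are
  runs of >= 3 consecutive windows at >= 5x baseline, merged across the
  origin on circular tracks. The thresholds are pragmatic defaults, since
  hotspot calling in the source analyses is visual.
* **Rarefaction** subsamples the read-level multiset without replacement
  (so full depth reproduces the true unique count with zero spread); the
  test oracle is the exact hypergeometric expectation.
* **Replicate QC** flags a sample when one S+1 spacer carries more than
  30% (strict) of its read-weighted arrays -- the signature of a
  population founded by an already-adapted clone. The threshold is a
  package default; no published value exists.
* **Order statistics.** PS-numbering survives unmapped intermediate
  spacers (k is a property of the array, not of mappability). Heatmaps
  and fractions weight by dereplicated read count; unweighted diagnostics
  are a one-line variation the tables support.

## Validation strategy

The test suite drives every stage from independent oracles: rotation and
doubled-sequence string oracles for circular arithmetic; a sliding-window
Hamming search against the Biostrings-backed matcher; an exhaustive sweep
of all 4^7 protospacer-tail x flank contexts (plus padding variants)
against a brute-force windowed GG search for the slip classifier; exact
closed forms for rarefaction and density recounts; and Monte-Carlo
parameter recovery -- simulate under known parameters, run the full
pipeline, and require the recovered slip spectrum, GG fraction, length
split, locus weights and PS+1 quadrant split to sit within three binomial
standard errors of their configured values. For the quadrant statistic
the recovery conditions on arrays whose S+1 is the cell's first
acquisition, identified through the read-to-cell map the simulator emits:
because each integration chooses a locus independently, roughly 30% of
CRISPR1 S+1 spacers belong to cells whose first event went elsewhere, and
the unconditioned array-level share is correspondingly diluted (the same
dilution affects any real experiment, which is why the first-acquisition
statistic is defined on the earliest event, not on any array's S+1).

One directional signature is asserted rather than measured against a
number: PS+1 to PS+2 travel distances are predominantly positive (5'),
while PPS to PS+2 distances are mixed in sign -- the fingerprint that
later captures are seeded by the previous protospacer, not by the PPS.
Under the default quadrant weights the two-hop composition still leaves a
mild positive excess in PPS to PS+2 (about 0.55-0.60 positive), so the
test asserts the sign-fraction *ordering* and the presence of both signs
in force, not a strict minority.

## Known limitations

* Flip-rate recovery is partial by construction: flips combined with
  slips of +2 or more leave no CC within the detection window, escape the
  flip flag and surface as rare "other"/mis-slipped calls (well under
  0.1% at default rates). The analysis mirrors the published exclusion
  rule rather than estimating the latent flip rate.
* The classifier's smallest-|s| preference means real slip spectra are
  convolved with context; the simulator's re-anchoring rule removes this
  on synthetic data but nothing can remove it from real data.
* Circular geometry excludes exact antipodes from side splits; on a
  5,000 nt plasmid this is a measure-zero set but it is logged.
* The published per-mechanism absolute rates are unknown beyond the
  >= 500x priming:naive ratio; the default rates honour that ratio, not
  measured values, and absolute event counts in simulations are therefore
  arbitrary up to that constraint.
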