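---
title: "Probe scoring, selection and hybridization QC: models and design choices"
author: "ProbeSieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe scoring, selection and hybridization QC: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProbeSieve)
```

# The problem and the model

A custom expression array needs exactly one trustworthy 60-mer per coding
sequence. Candidates fail for reasons a designer's thermodynamics does not
capture: they cross-hybridize with paralogous transcripts, fold on
themselves on the array surface, sit too far from the 3′ end for
oligo-dT-primed labeling to reach, or straddle an intron that was never
really there. ProbeSieve scores each candidate on five criteria whose sum
is a penalty (0 is a perfect probe), selects a per-CDS panel in two
rounds, re-validates probes whenever the annotation changes, and finally
lets a test hybridization decide among the survivors.

The package works in a single coordinate frame: gene models are converted
to coding orientation once, at read time (minus-strand genes are mirrored
with `pos' = contigLength - pos + 1`), and every downstream rule is
phrased in CDS coordinates or in distance from the CDS 3′ end
(`d = cds_length - cds_start + 1`). Probes are stored with CDS-relative
starts; genomic footprints are derived on demand. This removes strand
logic from all scoring code at the cost of one mirror transform, which is
exercised by a round-trip test (write annotation, re-read, compare) and
by rebuilding spliced CDS through an independent reverse-complement path.

## Cross-hybridization (CHI)

CHI is the maximum percent identity between a probe and any non-target
CDS. Hits can be ingested from the standard 12-column tabular alignment
format, or computed internally by a word-seeded ungapped search: exact
7-mer seeds, ungapped extension at +2/−3 with an X-drop of 20 score
units, keeping the full X-drop extent trimmed to its outermost matching
bases. A hit must be at least 20 nt long and its best 20-nt sub-window
must reach 70% identity; identity is matches over the extended hit
length. The 70%-over-20-nt window is the search's sensitivity contract:
the word size, rewards and X-drop are fixed so that any qualifying window
containing an exact 7-mer whose match span reaches 20 nt is provably
found (the seed lies inside the window; no dip within a qualifying window
can exceed the X-drop; extension grows through contiguous matches past
the window edges). The only possible misses are windows with no exact
7-mer run — the intrinsic insensitivity of any word-seeded search — and
windows whose matches span less than the minimum hit length. The
acceptance suite compares the search against a brute-force sliding-window
aligner on 1,000 seeded trials under exactly this accounting and requires
zero false positives, zero unexplained misses, and ≥ 99% agreement.

Two consequences of this permissive rule are worth knowing. First,
e-value significance is deliberately not modeled: the window rule *is*
the contract, so the search has a chance-hit noise floor that grows with
the CDS-set size — against a few hundred kilobases of unrelated CDS,
nearly every 60-mer shares some ~70% window somewhere, which lands in the
61–84% scoring band (score 1), not in the disqualifying ≥ 85% band.
Second, CHI uses the best single hit per subject, not an aggregate over
multiple hits; with 60-mer probes, multi-hit tiling has no room to change
the maximum materially.

## Hairpin self-folding

`hairpinDeltaG()` evaluates every single hairpin — a contiguous
Watson–Crick stem of at least 3 bp closed by a loop of at least 3 nt —
and returns the minimum of (stem nearest-neighbor stack terms) + (loop
length penalty), using the unified DNA nearest-neighbor ΔG°37 stack
table and tabulated hairpin-loop penalties (linear interpolation between
tabulated lengths, Jacobson–Stockmayer extrapolation beyond 30 nt).
Multiloops, bulges and internal mismatches are out of scope: for a 60-mer
the dominant self-structure is a single hairpin, and the −8 kcal/mol
decision boundary sits far from where those refinements matter. Sequences
admitting no hairpin return `Inf` (any value > 0 means "does not fold").
The model is exhaustively enumerable, so the acceptance suite demands
exact agreement with an independent triple-loop enumeration on 200 random
30-mers.

## Intron classes and the adjacency window

Class 3 means the probe's genomic footprint overlaps an intron interval
`(x, y)` exclusive of its endpoints; for probes designed on the spliced
CDS this is precisely "spans the exon–exon junction". Class 2 means the
probe starts within `adjacencyWindow` nt downstream of some intron's
`y`. The window width is not fixed by the procedure's description — the
motivation is that intron 3′ boundaries vary little but are predicted
imprecisely — so it is exposed as a parameter with a default of 10 nt:
about the scale of 3′-boundary wobble, wide enough to catch a probe whose
first bases would become intronic under a small boundary shift, narrow
enough not to blank out whole exon starts.

## Selection rounds

Round 1: final score < 4 (strict), start not within the 3′-terminal
100 nt (strict at 100: a probe at distance 100 is excluded, 101 is
admitted), keep the 4 closest to the 3′ end, ties broken by probe id so
panels are total-ordered and reruns byte-identical. Round 2 (only for
CDS with fewer than 4 round-1 probes): final score ≤ 8 (read as
inclusive), CHI ≤ 85 (the text's "over 85%" excluded), distance ≤ 1500
nt, class-3 probes only when every overlapped intron is EST-confirmed. A
CDS ending with fewer than 2 panel probes is flagged probe-deficient.
Two readings were genuinely open here. The 100-nt 3′ exclusion is *not*
re-applied in round 2, because the round-2 rule set enumerates its own
exclusions and does not list it; the effect is that a 3′-proximal probe
excluded in round 1 can return in round 2 on a probe-starved CDS, which
is arguably the intent of a rescue round. And EST confirmation lifts the
class-3 admission bar but does not reclassify a class-2 probe; the
adjacency penalty of 1 is retained even for confirmed introns.

## Re-annotation rescoring

After a re-annotation, a probe keeps sequence-match score 0 only if its
sequence occurs exactly in its target's updated CDS; otherwise it scores
20, a value chosen so that no combination of the other criteria can keep
it under any admission cut. Probes whose target vanished are orphaned
(also 20) and reported. The score is implemented as a fifth addend of the
final score rather than a separate kill flag — arithmetically equivalent,
but it keeps the additivity invariant testable.

## The experimental cascade

All filters are *computed* flags over the same normalized data, not
sequential eliminations, so their order is immaterial and each rejection
carries every reason it earned.

* **Normalization** (pluggable; the true normalization of the original
  platform lives outside the main text, so this is a package design
  choice): `log2(max(fg - bg, 1))`, median-centered per array × channel;
  technical replicate spots collapse to their median. Arrays with fewer
  than 10 spots in a channel are refused.
* **Signal-to-noise**: SSR = (fg − bg)/bg_sd and SBR = fg/bg, standard
  definitions of the two cited ratios; a probe fails when SSR < 10 *and*
  SBR < 2 in all samples or all but one, a "sample" being one
  hybridization (array × sample channel). Undefined ratios (zero
  denominators) report `Inf` with a warning — an undefined ratio can
  never fail a threshold.
* **Reproducibility**: CV = sd/mean (n−1 denominator) over biological
  replicates of one condition, computed on *linear-scale* normalized
  intensities — CVs of log values are not scale-free, and the 0.75
  threshold is meaningful only on the linear scale. Strict inequality:
  CV = 0.75 exactly is retained. Expert supervision is modeled as an
  auditable rescue file (probe id + mandatory justification), never as an
  interactive step.
* **Representative intensity**: M_probe (median reference-channel value
  per probe) must lie inside [Q1, Q3] of its CDS siblings' M_probe
  values, quartiles by linear interpolation (R type 7), boundaries
  inclusive, single-probe CDS exempt. Per array, members outside
  M_array ± 1.5 × CI on *every* array fail, CI being the
  normal-approximation 95% half-width `1.96 × sd/sqrt(n)` (a t-based
  alternative is exposed via `ciMethod`). "± 1.5 CI" is read as 1.5 ×
  half-width. With 4 probes per CDS these two filters have sharp
  structural behavior worth stating plainly: interpolated quartiles of 4
  distinct values always exclude the minimum and maximum, so the IQR
  filter rejects ~half the probes of every CDS (this is the mechanism
  behind that criterion's dominant rejection share on real data); and the
  largest attainable deviation among n = 4 members is 1.5 × sd versus a
  threshold of 1.47 × sd, so the M_array filter can only catch outliers
  whose three siblings are nearly equal — which is exactly the planted
  geometry the generator uses.
* **Election**: per CDS, the qualified probe closest to the 3′ end (ties
  by id). Deficient CDS get the rejected probe ranked by fewest failed
  filters, then smallest final score, then smallest distance — unless an
  expert override names one. Bypass-listed CDS (mitochondrial-style) are
  elected on in silico standing alone. Zero-probe CDS are listed, never
  fatal.

# The synthetic fixture generator

`simulateFixture()` emulates the pipeline's whole input surface: contigs
with genes on both strands, exon/intron structures (intron rate 0.5 —
about half the CDS intron-containing, as in the fungal genome that
motivated the procedure — with 1–3 introns of 60–200 nt), EST
confirmations (rate 0.3), four candidate probes per gene at 101–500 nt
from the 3′ end, and a common-reference two-channel design of 5
conditions × 4 biological replicates × 4 replicate spots. Intensities are
multiplicative log-normal: signal noise sd 0.15 log2 units puts the clean
per-condition CV near 0.10, inside the 0.05–0.2 band typical of this
platform class; background is log-normal around 100 with sd 0.1 and
reported bg_sd = bg/2.

Every defect is planted so that detection follows from arithmetic, not
luck, because the acceptance fixture must recover each planted set
*exactly* under any seed:

* `HIGH_CHI`: a 40-nt window of the probe is copied into a decoy CDS with
  mismatches at fixed interior offsets (default identity 90%), and the 10
  decoy bases flanking each side are forced to mismatch the probe, so the
  ungapped extension stops exactly at the window and the reported CHI is
  deterministically 90.
* `HAIRPIN`: a GC-rich 12-bp inverted repeat with a 4-nt loop inside the
  probe footprint; ~11 GC-heavy stacks put ΔG far below −8.
* `FAR_5P` / `INTRON_OVERLAP`: placement (distance > 1000 nt; spanning a
  junction) — class and position scores follow by definition.
* `LOW_SNR` is planted per *CDS*, not per probe: every spot of every
  probe of the CDS reads fg = 1.5 × bg with bg_sd = bg/2, i.e. SSR = 1
  and SBR = 1.5 on every array — an unexpressed gene. Planting low signal
  on a single probe would make it an intensity outlier against its
  siblings and be caught by the wrong filter; planting the whole CDS
  keeps siblings concordant, which is also the biologically realistic
  failure mode.
* `HIGH_CV`: in two of the five conditions the probe's replicate signals
  follow the fixed pattern {0.2, 0.5, 1, 4} (CV ≈ 1.25 against the 0.75
  threshold, robust to the multiplicative noise on top); other conditions
  stay clean, so the mean level — and hence the intensity filters — are
  untouched.
* `INTENSITY_OUTLIER`: a constant 2^5 sample-channel offset on all
  arrays. The margin analysis: with 4 members the outlier's deviation is
  1.5 × sd against a 1.47 × sd threshold, and the shortfall probability
  is second-order in (noise sd / offset) — at offset 5 log2 units and
  effective noise ~0.1 it is negligible on all 20 arrays. The offset is
  applied to the sample channel only, so the reference-channel M_probe
  statistics stay clean.

The generator pre-screens non-planted probe positions the way a designer
would (resampling until no hairpin ≤ −8 and CHI below a ceiling). The
ceiling (`screenChiMax`) defaults to 60 — the perfect-score band — which
is satisfiable on small fixtures; at the 200-gene scale the chance-hit
noise floor of the 70%/20-nt rule sits above 60, so large fixtures meant
for the hybridization filters use 84 (anything below the ≥ 85
disqualification band). What the generator does *not* emulate: realistic
sequence composition (GC skew, repeats, gene families — so real CHI
distributions will be heavier-tailed than simulated ones), dye bias and
spatial artifacts (so the default normalization looks better here than
on real scans), and probe-specific affinity differences beyond the
planted offsets. Passing tests therefore demonstrate that each rule
implements its definition and that each filter detects its intended
failure mode — not that the thresholds are optimal for any particular
real platform.

# Numerical choices

* Quantiles: linear interpolation (type 7), pinned for reproducibility;
  boundary inclusive (reject strictly outside [Q1, Q3]).
* CI: normal approximation by default; `ciMethod = "t"` for the Student
  version (note that with n = 4 the t-based threshold exceeds the
  attainable deviation, so that setting effectively disables the filter —
  the reason normal approximation is the default).
* Ties everywhere break by probe id after the scientific key, making
  every selection a total order; identical configurations produce
  byte-identical output files.
* Hairpin energies: shared constant table exposed via
  `hairpinEnergyParams()` so independent reimplementations (and the test
  oracle) use identical numbers; loop penalties interpolate linearly
  between tabulated lengths.
* Seeds: a fixture's master seed determines everything; the three
  generator stages draw from seed, seed+1, seed+2 so each stage is
  independently reproducible.
* Degenerate inputs: zero-exon genes, exons out of order, overlapping
  exons, missing contigs, malformed alignment rows, arrays with < 10
  spots, CV on < 2 replicates, non-positive mean intensities and
  rescue/override entries without justification are all hard errors;
  probe-deficient CDS never are.

# Problem sizes

The test suite runs its deep checks at sizes chosen to exercise the
asymptotics the rules depend on while staying desk-scale: boundary sweeps
on toy score cards (< 1 s), 1,000 probe/subject search trials against the
brute-force aligner, 200 random 30-mers against the hairpin enumeration,
and a 200-gene, 4-probes-per-gene, 5 × 4-replicate hybridization fixture
(128,000 spots across both channels) for planted-defect recovery and
election. End-to-end
determinism is checked on a 15-gene fixture by byte-comparing two
pipeline runs.

# Known limitations

* The internal search is ungapped; externally computed (possibly gapped)
  hits are consumed as-is. For 60-mer cross-hybridization the ungapped
  stretches dominate, but indel-mediated similarity is invisible to the
  internal path.
* CHI carries no significance model, so its 61–84 band fills up with
  chance windows as the CDS set grows (see above); the ≥ 85 band, which
  drives exclusions, is far above the noise floor at any realistic CDS
  count.
* The hairpin model scores single hairpins only and ignores
  probe–surface effects; it ranks self-structure risk, it does not
  predict melting curves.
* The M_array filter's power collapses for CDS with few probes (n = 3
  caps the attainable deviation below any usable threshold); it is
  effectively a 4-probe-panel instrument, which is how it is used here.
* One gene model per CDS: transcript isoforms are out of scope.
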