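# ProbeSieve

Selecting one reliable 60-mer probe per coding sequence (CDS) is the step
that decides whether a custom gene-expression microarray measures biology
or noise. Probe-design services emit many candidates per CDS, but their
physics is computed for probes in solution, gene-structure predictions are
wrong often enough that probes can straddle mispredicted introns, and
genome re-annotations silently invalidate probes after the fact.
ProbeSieve implements a complete screening pipeline for this situation,
aimed at groups building custom arrays for newly sequenced (typically
fungal or other intron-rich) genomes: an in silico scoring and two-round
selection stage that is robust to intron misprediction and re-annotation,
followed by an experimental quality-control cascade over test-array
hybridizations that elects a single final probe per CDS.

## The scoring model

Each candidate probe receives five criterion scores; their sum is the
final score (lower is better):

| criterion | measure | 0 | 1 | 4 | 20 |
|---|---|---|---|---|---|
| cross-hybridization | CHI, % identity to any non-target CDS | ≤ 60% | 61–84% | ≥ 85% | — |
| self-folding | hairpin ΔG (kcal/mol, 37 °C) | > −8 | ≤ −8 | — | — |
| position in CDS | nt from the CDS 3′ end | 1–500 | 501–1000 | > 1000 | — |
| intron relation | class 1 / 2 / 3 (see below) | class 1 | class 2 | class 3 | — |
| sequence match | after genome re-annotation | perfect | — | — | mismatch |

CHI is the maximum percent identity between the probe and any non-target
CDS, computed either from external 12-column tabular alignment hits or by
an internal word-seeded ungapped search (word size 7, match +2, mismatch
−3, X-drop 20) tuned to detect a minimal identity of 70% over 20
contiguous bases. Hairpin ΔG is the minimum free energy over all
single-hairpin structures (Watson–Crick stems ≥ 3 bp, loops ≥ 3 nt),
evaluated with unified DNA nearest-neighbor stack parameters plus a
hairpin-loop length penalty. The intron classes are positional: class 3
probes overlap a predicted intron (they span the exon–exon junction, so a
wrong prediction corrupts their sequence); class 2 probes start within 10
nt downstream of a predicted intron 3′ end, the least certain boundary;
class 1 probes are clear of both.

Selection round 1 admits probes with final score < 4 that do not start in
the 3′-terminal 100 nt, keeping the four closest to the 3′ end. Round 2
tops panels up to four with probes scoring ≤ 8, at most 1500 nt from the
3′ end, with CHI ≤ 85%; intron-overlapping probes are recoverable only
when every overlapped intron is EST-confirmed. After a re-annotation,
probes whose target CDS changed under them receive a sequence-match score
of 20 and fall out of all subsequent selections.

The experimental stage consumes spot-level two-channel intensities from a
common-reference design (conditions × biological replicates vs a pooled
reference). Probes fail on: (1) signal-to-noise, SSR = (fg − bg)/bg_sd
< 10 and SBR = fg/bg < 2 in all samples or all but one; (2)
reproducibility, per-condition CV > 0.75 in any condition (with an
auditable expert rescue list); (3) representative intensity, M_probe
outside the interquartile range of its CDS siblings (reference channel),
or intensity outside M_array ± 1.5 CI on every array (sample channel).
Per CDS, the qualified probe closest to the 3′ end is elected;
probe-deficient CDS get a supervised rescue from the rejected set;
bypass-listed (e.g. mitochondrial) CDS are elected on in silico standing
alone.

## Worked example

Everything is testable without array data: the fixture generator builds a
deterministic annotated genome, candidate probes and hybridization
intensities with planted defects recorded as ground truth.

```r
library(ProbeSieve)

spec <- fixtureSpec(seed = 42, nGenes = 12,
                    plantedDefects = c(HIGH_CHI = 1, HAIRPIN = 1, FAR_5P = 1,
                                       INTRON_OVERLAP = 1, LOW_SNR = 1,
                                       HIGH_CV = 1, INTENSITY_OUTLIER = 1))
fix <- simulateFixture(spec, "demo")

sc <- scoreProbes(fix$probes$probes, fix$genome$models,
                  genome = fix$genome$genome)
table(final_score = sc$final_score)
#> final_score
#>  0  1  4
#> 44  1  3
```

48 probes: 44 score 0, the planted hairpin probe scores 1
(ΔG ≤ −8 → fold score 1), and three probes score 4 — the planted
cross-hybridizer (CHI 90%), the probe placed 1450 nt from the 3′ end, and
the intron-overlapping probe (class 3):

```r
as.data.frame(sc[sc$final_score >= 4,
                 c("probe_id", "chi_percent", "distance_3p",
                   "intron_class", "final_score")])
#>   probe_id chi_percent distance_3p intron_class final_score
#> 1  g001_p1        90.0         148            1           4
#> 2  g003_p4         0.0        1450            1           4
#> 3  g004_p3        59.3         218            3           4
```

The QC cascade recovers exactly the planted intensity defects and elects
one probe per CDS; the CDS whose probes were all planted unexpressed
(LOW_SNR) is probe-deficient and receives a supervised rescue:

```r
qc  <- probeQc(fix$intensities$spots, fix$probes$probes)
rep <- finalizeSelection(qc, sc)
reportSummary(rep)
#>                metric rejected qualified
#> 1            SSR, SBR        4        44
#> 2                  CV        1        47
#> 3             M_probe       24        24
#> 4             M_array        1        47
#> 5        all criteria       26        22
#> 6 probe-deficient CDS        1        11
```

(The interquartile criterion is deliberately harsh — with four probes per
CDS it rejects the extremes of every CDS, here 24/48; that mirrors its
dominant share of rejections on real arrays.)

The same flow runs end to end from files via `runPipeline()` or the thin
CLI wrapper `inst/scripts/probesieve.R` (subcommands `simulate`, `score`,
`select`, `rescore`, `qc`, `elect`, `report`, `run`), writing score
cards, panels, verdicts, elections and a manifest echoing every threshold
used.

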