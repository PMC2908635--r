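## Small in-code builders shared across test files.

toyModel <- function(starts, ends, strand = "+", contigLen = max(ends) + 50L,
                     id = "g1", contig = "chr1",
                     est = logical(max(length(starts) - 1L, 0L))) {
  GeneModel(id, contig, strand, contigLen,
            IRanges::IRanges(start = starts, end = ends), est)
}

## score-card rows for selection tests
mkScores <- function(final, dist, chi = 0, class = 1L, est_ok = TRUE,
                     cds = "g1", ids = NULL) {
  n <- max(length(final), length(dist), length(chi), length(class),
           length(est_ok), length(ids))
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(n))
  S4Vectors::DataFrame(
    probe_id = ids, cds_id = cds,
    final_score = rep_len(as.integer(final), n),
    distance_3p = rep_len(as.integer(dist), n),
    chi_percent = rep_len(chi, n),
    intron_class = rep_len(as.integer(class), n),
    est_ok = rep_len(est_ok, n))
}

## replicate values with an exactly prescribed coefficient of variation:
## {1, 1+u, 1+2u} with u = cv / (1 - cv) has mean 1 + u and sd u + u^2/(1-?);
## derivation: sd of {1, 1+u, 1+2u} is u, mean is 1 + u, so CV = u/(1+u)
## and u = cv/(1-cv) realizes cv exactly (0.75 -> {1, 4, 7}).
replicatesWithCv <- function(cv) {
  u <- cv / (1 - cv)
  c(1, 1 + u, 1 + 2 * u)
}

## spot table builder: one array, one channel, nSpot probes
mkSpots <- function(array_id, channel, probe_ids, fg, bg = 100,
                    bg_sd = 50, condition = "C1", spot_index = 1L) {
  data.frame(array_id = array_id, condition = condition, channel = channel,
             probe_id = probe_ids, spot_index = spot_index,
             fg = fg, bg = bg, bg_sd = bg_sd, control_flag = 0L,
             stringsAsFactors = FALSE)
}

## cached small fixtures (built once per test run)
.fixtureCache <- new.env()
smallFixture <- function() {
  if (is.null(.fixtureCache$small)) {
    spec <- fixtureSpec(seed = 401, nGenes = 12,
                        plantedDefects = c(HIGH_CHI = 1, HAIRPIN = 1,
                                           FAR_5P = 1, INTRON_OVERLAP = 1,
                                           LOW_SNR = 1, HIGH_CV = 1,
                                           INTENSITY_OUTLIER = 1))
    .fixtureCache$small <- simulateFixture(spec)
    .fixtureCache$smallSpec <- spec
  }
  .fixtureCache$small
}
smallFixtureSpec <- function() { smallFixture(); .fixtureCache$smallSpec }
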