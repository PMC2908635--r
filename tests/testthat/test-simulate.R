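test_that("fixture output is byte-identical under a fixed seed", {
  spec <- fixtureSpec(seed = 77, nGenes = 6, plantedDefects = c(HAIRPIN = 1))
  d1 <- tempfile(); d2 <- tempfile()
  simulateFixture(spec, d1)
  simulateFixture(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("zero intron rate yields single-exon genes, all probes class 1", {
  spec <- fixtureSpec(seed = 78, nGenes = 6, intronRate = 0,
                      plantedDefects = c(LOW_SNR = 1))
  g <- simulateGenome(spec)
  expect_true(all(g$geneTruth$n_introns == 0L))
  p <- simulateProbes(spec, g)
  pd <- probeData(p$probes)
  cls <- vapply(seq_len(nrow(pd)), function(i)
    as.integer(classifyIntronRelation(g$models[[pd$cds_id[i]]],
                                      pd$cds_start[i], 60L)), integer(1))
  expect_true(all(cls == 1L))
})

test_that("probes match their CDS and planted defects are real", {
  fix <- smallFixture()
  expect_true(validateProbes(fix$probes$probes, fix$genome$models,
                             fix$genome$genome))
  tr <- fix$probes$truth
  pd <- probeData(fix$probes$probes)
  ## intron-overlap plants classify as class 3 by the package's own rule
  for (pid in tr$probe_id[tr$defect == "INTRON_OVERLAP"]) {
    i <- match(pid, pd$probe_id)
    expect_equal(as.integer(classifyIntronRelation(
      fix$genome$models[[pd$cds_id[i]]], pd$cds_start[i], 60L)), 3L)
  }
  ## hairpin plants fold below the disqualification energy
  for (pid in tr$probe_id[tr$defect == "HAIRPIN"]) {
    i <- match(pid, pd$probe_id)
    expect_lte(hairpinDeltaG(as.character(pd$sequence[[i]])), -8)
  }
})

test_that("zero signal noise gives CV 0 for clean probes", {
  ## a defect-free fixture: with no signal noise every replicate array
  ## carries identical normalized values, so each probe's CV is exactly 0
  spec <- fixtureSpec(seed = 79, nGenes = 6, intronRate = 0,
                      noise = list(signal_sd = 0))
  fx <- simulateFixture(spec)
  qc <- probeQc(fx$intensities$spots, fx$probes$probes)
  v <- as.data.frame(qc)
  expect_true(all(v$max_cv < 1e-10))
})

test_that("simulated intensities match the fixtureSpec design dimensions", {
  fix <- smallFixture()
  spec <- smallFixtureSpec()
  sp <- fix$intensities$spots
  expect_equal(length(unique(sp$condition)), spec$nConditions)
  expect_equal(length(unique(sp$array_id)),
               spec$nConditions * spec$nBioReplicates)
  expect_setequal(unique(sp$channel), c("sample", "reference"))
  expect_equal(max(sp$spot_index), spec$nTechReplicates)
  expect_equal(nrow(sp),
               length(fix$probes$probes) * spec$nConditions *
                 spec$nBioReplicates * 2L * spec$nTechReplicates)
})
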