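test_that("criterion score bands match their printed boundaries", {
  ## CHI: 0 at <= 60, 1 in (60, 85), 4 at >= 85
  expect_equal(scoreChi(c(0, 60, 60.5, 72, 84.9, 85, 100)),
               c(0L, 0L, 1L, 1L, 1L, 4L, 4L))
  expect_error(scoreChi(101), "within")
  ## self-folding: boundary -8 belongs to the penalized side
  expect_equal(scoreFold(c(-7.9, -8, -20, Inf)), c(0L, 1L, 1L, 0L))
  ## position: 500 belongs to the better bin
  expect_equal(scorePosition(c(1, 300, 500, 501, 800, 1000, 1001, 1200)),
               c(0L, 0L, 0L, 1L, 1L, 1L, 4L, 4L))
  expect_error(scorePosition(0), ">= 1")
  ## intron class
  expect_equal(scoreIntronClass(c(1L, 2L, 3L)), c(0L, 1L, 4L))
  expect_error(scoreIntronClass(4L), "class")
})

test_that("criterion scores are monotone in their inputs", {
  chis <- seq(0, 100, by = 0.5)
  expect_true(all(diff(scoreChi(chis)) >= 0))
  dists <- 1:2000
  expect_true(all(diff(scorePosition(dists)) >= 0))
  dgs <- seq(-30, 5, by = 0.1)
  expect_true(all(diff(scoreFold(dgs)) <= 0))  # lower dG never lowers score
})

test_that("intron classification separates overlap, adjacency and clear", {
  gm <- toyModel(c(1, 201, 501), c(100, 400, 800), contigLen = 900)
  ## CDS layout: exon1 1..100 (cds 1-100), exon2 201..400 (cds 101-300),
  ## exon3 501..800 (cds 301-600); introns x/y = 100/201 and 400/501
  ## wholly inside exon2, far from both junction zones -> class 1
  expect_equal(as.integer(classifyIntronRelation(gm, 130, 60)), 1L)
  ## spans the first junction (covers cds 100 and 101) -> class 3
  cl3 <- classifyIntronRelation(gm, 71, 60)
  expect_equal(as.integer(cl3), 3L)
  expect_equal(attr(cl3, "overlapped"), 1L)
  ## starts exactly at y (first base of exon2, cds 101) -> class 2
  expect_equal(as.integer(classifyIntronRelation(gm, 101, 60)), 2L)
  ## starts at y + 9 (still inside the default 10-nt zone) -> class 2
  expect_equal(as.integer(classifyIntronRelation(gm, 110, 60)), 2L)
  ## starts at y + 10 -> class 1
  expect_equal(as.integer(classifyIntronRelation(gm, 111, 60)), 1L)
  ## window width is configurable
  expect_equal(as.integer(classifyIntronRelation(gm, 110, 60,
                                                 adjacencyWindow = 5L)), 1L)
  ## single-exon gene is always class 1
  expect_equal(as.integer(classifyIntronRelation(toyModel(1, 900), 100, 60)),
               1L)
})

test_that("final score is the sum of the five criterion scores", {
  expect_equal(totalScore(list(chi_score = 0, fold_score = 0, pos_score = 0,
                               intron_score = 0, match_score = 0)), 0L)
  expect_equal(totalScore(list(chi_score = 1, fold_score = 1, pos_score = 1,
                               intron_score = 1, match_score = 0)), 4L)
  expect_equal(totalScore(list(chi_score = 0, fold_score = 0, pos_score = 0,
                               intron_score = 0, match_score = 20)), 20L)
})

test_that("scoreProbes assembles a consistent score card", {
  fix <- smallFixture()
  sc <- scoreProbes(fix$probes$probes, fix$genome$models,
                    genome = fix$genome$genome)
  expect_equal(nrow(sc), length(fix$probes$probes))
  ## additivity holds row by row
  expect_equal(sc$final_score,
               sc$chi_score + sc$fold_score + sc$pos_score +
                 sc$intron_score + sc$match_score)
  ## per-criterion values live in their Table-1 bands
  expect_true(all(sc$chi_score %in% c(0L, 1L, 4L)))
  expect_true(all(sc$fold_score %in% c(0L, 1L)))
  expect_true(all(sc$pos_score %in% c(0L, 1L, 4L)))
  expect_true(all(sc$intron_score %in% c(0L, 1L, 4L)))
  expect_true(all(sc$match_score == 0L))
  ## planted in silico defects score as constructed
  m <- merge(as.data.frame(sc), fix$probes$truth,
             by = c("probe_id", "cds_id"))
  expect_true(all(m$chi_percent[m$defect == "HIGH_CHI"] >= 85))
  expect_true(all(m$delta_g[m$defect == "HAIRPIN"] <= -8))
  expect_true(all(m$pos_score[m$defect == "FAR_5P"] == 4L))
  expect_true(all(m$intron_class[m$defect == "INTRON_OVERLAP"] == 3L))
  expect_true(all(m$final_score[m$defect == "CLEAN"] == 0L))
})
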