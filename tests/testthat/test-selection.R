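test_that("round 1 admits scores below 4 outside the 3'-terminal 100 nt", {
  s <- mkScores(final = 0:5, dist = c(150, 200, 250, 300, 350, 400))
  expect_setequal(selectRound1(s), c("p01", "p02", "p03", "p04"))
  ## more than four admissible: keep the four closest to the 3' end
  s2 <- mkScores(final = rep(0, 6), dist = c(150, 200, 250, 300, 350, 400))
  expect_equal(selectRound1(s2), c("p01", "p02", "p03", "p04"))
  ## 3'-proximity exclusion is strict at 100
  s3 <- mkScores(final = c(0, 0, 0), dist = c(90, 100, 101))
  expect_equal(selectRound1(s3), "p03")
  ## distance ties break lexicographically by probe id
  s4 <- mkScores(final = rep(0, 5), dist = c(200, 200, 200, 200, 200))
  expect_equal(selectRound1(s4), c("p01", "p02", "p03", "p04"))
})

test_that("round 2 recovers up to score 8 within CHI and distance bounds", {
  r1 <- character(0)
  base <- mkScores(final = c(6, 6, 6), dist = c(1200, 1200, 1200),
                   chi = c(80, 86, 80), class = c(1L, 1L, 1L))
  got <- selectRound2(base, r1)
  expect_setequal(got, c("p01", "p03"))          # CHI 86 excluded
  far <- mkScores(final = 6, dist = 1600, chi = 70)
  expect_equal(length(selectRound2(far, r1)), 0L)  # beyond 1500 nt
  high <- mkScores(final = 9, dist = 1200, chi = 70)
  expect_equal(length(selectRound2(high, r1)), 0L) # score 9 > 8
  edge <- mkScores(final = 8, dist = 1500, chi = 85)
  expect_equal(selectRound2(edge, r1), "p01")      # all bounds inclusive
})

test_that("class-3 probes are recovered only with full EST confirmation", {
  r1 <- character(0)
  est <- mkScores(final = c(6, 6), dist = c(1100, 1200), chi = 70,
                  class = 3L, est_ok = c(TRUE, FALSE))
  expect_equal(selectRound2(est, r1), "p01")
})

test_that("round 2 refuses a CDS whose panel is already full", {
  s <- mkScores(final = rep(0, 5), dist = 150 + 50 * (0:4))
  r1 <- selectRound1(s)
  expect_length(r1, 4L)
  expect_error(selectRound2(s, r1), "fewer than")
})

test_that("panels assemble, stay disjoint, and flag deficient CDS", {
  s <- rbind(
    mkScores(final = c(0, 1, 5, 6), dist = c(150, 250, 350, 450),
             cds = "gA", ids = paste0("a", 1:4)),
    mkScores(final = c(9, 9, 9, 20), dist = c(150, 250, 350, 450),
             cds = "gB", ids = paste0("b", 1:4)),
    mkScores(final = c(0, 0), dist = c(90, 50),
             cds = "gC", ids = paste0("c", 1:2)))
  p <- selectPanels(s)
  pa <- p[p$cds_id == "gA", ]
  expect_setequal(unlist(pa$round1), c("a1", "a2"))
  expect_setequal(unlist(pa$round2), c("a3", "a4"))
  expect_false(pa$deficient)
  pb <- p[p$cds_id == "gB", ]
  expect_length(unlist(pb$panel), 0L)
  expect_true(pb$deficient)
  pc <- p[p$cds_id == "gC", ]      # both probes 3'-excluded in round 1 but
  expect_true(all(unlist(pc$round2) %in% c("c1", "c2")))  # recovered in 2
  ## no probe appears in both rounds
  expect_length(intersect(unlist(p$round1), unlist(p$round2)), 0L)
})

test_that("panel selection is deterministic", {
  s <- mkScores(final = rep(0, 6), dist = c(200, 200, 150, 150, 400, 400))
  expect_identical(selectRound1(s), selectRound1(s[sample(6), ]))
})

test_that("re-annotation rescoring assigns 20 to mismatched probes", {
  set.seed(61)
  cdsSeq <- randDna(600)
  probes <- ProbeSet(c("p1", "p2"), c("gA", "gA"), c(101L, 301L),
                     c(substr(cdsSeq, 101, 160), substr(cdsSeq, 301, 360)))
  models <- GeneModelSet(list(toyModel(1, 600, id = "gA")))
  scores <- scoreProbes(probes, models,
                        genome = NULL,
                        chi = S4Vectors::DataFrame(
                          probe_id = c("p1", "p2"),
                          chi_percent = c(0, 0),
                          best_subject = NA_character_))
  ## re-annotation: one substitution inside p2's footprint
  newSeq <- cdsSeq
  substr(newSeq, 330, 330) <- setdiff(.B, substr(newSeq, 330, 330))[1L]
  newCds <- Biostrings::DNAStringSet(c(gA = newSeq))
  res <- rescoreAfterReannotation(probes, newCds, scores)
  expect_equal(res$scores$match_score[res$scores$probe_id == "p1"], 0L)
  expect_equal(res$scores$match_score[res$scores$probe_id == "p2"], 20L)
  expect_gte(res$scores$final_score[res$scores$probe_id == "p2"], 20L)
  expect_length(res$deficientCds, 0L)   # p1 survives

  ## target CDS removed entirely: probes orphaned, CDS reported
  gone <- Biostrings::DNAStringSet(c(gB = randDna(500)))
  res2 <- rescoreAfterReannotation(probes, gone, scores)
  expect_setequal(res2$orphaned, c("p1", "p2"))
  expect_equal(res2$deficientCds, "gA")
})
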