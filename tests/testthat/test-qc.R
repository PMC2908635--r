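test_that("normalization centers per array-channel and clamps at 1", {
  ids <- sprintf("p%02d", 1:12)
  ## identical spots -> all centered norms equal (zero)
  sp <- mkSpots("a1", "sample", ids, fg = 500)
  n1 <- normalizeSpots(sp)
  expect_true(all(n1$norm == 0))
  ## doubling every foreground-minus-background leaves centered norms
  ## unchanged (shift invariance of median-centering in log space)
  sp2 <- mkSpots("a1", "sample", ids, fg = 100 + (1:12) * 50)
  sp3 <- sp2; sp3$fg <- 100 + (sp2$fg - 100) * 2
  expect_equal(normalizeSpots(sp2)$norm, normalizeSpots(sp3)$norm)
  ## fg below bg clamps before the log
  spNeg <- mkSpots("a1", "sample", ids, fg = c(10, rep(500, 11)))
  expect_true(is.finite(normalizeSpots(spNeg)$norm[1L]))
  ## degenerate arrays are refused
  expect_error(normalizeSpots(mkSpots("tiny", "sample", ids[1:3],
                                      fg = 200)), "fewer than")
})

test_that("SSR and SBR follow their definitions, Inf on zero denominators", {
  r <- computeSsrSbr(1000, 100, 50)
  expect_equal(r$ssr, 18)
  expect_equal(r$sbr, 10)
  expect_equal(computeSsrSbr(100, 100, 50)$ssr, 0)
  r2 <- computeSsrSbr(150, 100, 100)
  expect_equal(r2$ssr, 0.5)
  expect_equal(r2$sbr, 1.5)
  expect_warning(r3 <- computeSsrSbr(100, 100, 0), "Inf")
  expect_true(is.infinite(r3$ssr))
})

test_that("the SNR rule discards on n and n-1 failures, keeps n-2", {
  mk <- function(nFail, nAll = 20L) {
    data.frame(probe_id = "p", array_id = sprintf("a%02d", seq_len(nAll)),
               ssr = c(rep(1, nFail), rep(50, nAll - nFail)),
               sbr = c(rep(1.5, nFail), rep(9, nAll - nFail)))
  }
  expect_true(snrFilter(mk(20))$SNR_FAIL)
  expect_true(snrFilter(mk(19))$SNR_FAIL)
  expect_false(snrFilter(mk(18))$SNR_FAIL)
  ## failing one threshold but not the other never counts
  one <- data.frame(probe_id = "p", array_id = sprintf("a%d", 1:20),
                    ssr = rep(1, 20), sbr = rep(5, 20))
  expect_false(snrFilter(one)$SNR_FAIL)
})

test_that("CV is sd/mean on linear intensities, scale-free", {
  expect_equal(computeCv(c(5, 5, 5, 5)), 0)
  expect_equal(computeCv(c(1, 2, 3, 4)), 0.5164, tolerance = 1e-4)
  v <- c(2, 3, 9, 4)
  expect_equal(computeCv(v * 1000), computeCv(v))
  expect_error(computeCv(3), "at least 2")
  expect_error(computeCv(c(-5, 3)), "mean")
})

test_that("the reproducibility filter is strict at 0.75 and honors rescues", {
  cvs <- data.frame(probe_id = c("a", "a", "b", "c"),
                    condition = c("C1", "C2", "C1", "C1"),
                    cv = c(0.10, 0.80, 0.75, 0.80))
  v <- cvFilter(cvs)
  expect_equal(v$CV_FAIL[v$probe_id == "a"], TRUE)   # any condition
  expect_equal(v$CV_FAIL[v$probe_id == "b"], FALSE)  # 0.75 exactly retained
  rescue <- data.frame(probe_id = "c",
                       justification = "known condition-specific expression")
  v2 <- cvFilter(cvs, rescue)
  expect_false(v2$CV_FAIL[v2$probe_id == "c"])
  expect_true(v2$RESCUED[v2$probe_id == "c"])
  expect_true(v2$CV_FAIL[v2$probe_id == "a"])        # not on the list
  bad <- data.frame(probe_id = "c", justification = "  ")
  expect_error(cvFilter(cvs, bad), "justification")
})

test_that("M_probe is judged against interpolated CDS quartiles", {
  mp <- data.frame(probe_id = c("a", "b", "c", "d"), cds_id = "g",
                   m_probe = c(1, 2, 3, 10))
  v <- mprobeFilter(mp)
  expect_equal(v$q1[1L], 1.75)
  expect_equal(v$q3[1L], 4.75)
  expect_equal(v$MPROBE_FAIL[order(v$probe_id)], c(TRUE, FALSE, FALSE, TRUE))
  ## all-equal members: boundary inclusive, none rejected
  eq <- data.frame(probe_id = letters[1:4], cds_id = "g", m_probe = 5)
  expect_false(any(mprobeFilter(eq)$MPROBE_FAIL))
  ## two distinct members: both outside the interpolated quartiles
  two <- data.frame(probe_id = c("a", "b"), cds_id = "g", m_probe = c(1, 2))
  expect_true(all(mprobeFilter(two)$MPROBE_FAIL))
  ## single-probe CDS exempt
  one <- data.frame(probe_id = "a", cds_id = "g", m_probe = 7)
  expect_false(mprobeFilter(one)$MPROBE_FAIL)
})

test_that("M_array failure must be universal across arrays", {
  mk <- function(outlierOn) {
    rows <- list()
    for (a in 1:3) {
      val <- c(0, 0, 0, if (a %in% outlierOn) 10 else 0)
      rows[[a]] <- data.frame(probe_id = c("w", "x", "y", "z"),
                              cds_id = "g", array_id = paste0("a", a),
                              value = val)
    }
    do.call(rbind, rows)
  }
  allOut <- marrayFilter(mk(1:3))
  expect_true(allOut$MARRAY_FAIL[allOut$probe_id == "z"])
  expect_false(any(allOut$MARRAY_FAIL[allOut$probe_id != "z"]))
  ## weakening a single array flips the verdict to retained
  oneIn <- marrayFilter(mk(1:2))
  expect_false(any(oneIn$MARRAY_FAIL))
  ## symmetric two-member CDS keeps both
  sym <- data.frame(probe_id = rep(c("a", "b"), 2), cds_id = "g",
                    array_id = rep(c("a1", "a2"), each = 2),
                    value = c(1, 3, 1, 3))
  expect_false(any(marrayFilter(sym)$MARRAY_FAIL))
})

test_that("verdict flags are independent and partition every probe", {
  fix <- smallFixture()
  qc <- probeQc(fix$intensities$spots, fix$probes$probes)
  v <- as.data.frame(qc)
  expect_equal(nrow(v), length(fix$probes$probes))
  ## every probe has exactly one terminal standing
  expect_equal(sum(v$qualified) + sum(!v$qualified), nrow(v))
  ## n_fail recounts the flags
  expect_equal(v$n_fail, as.integer(v$SNR_FAIL) + as.integer(v$CV_FAIL) +
                 as.integer(v$MPROBE_FAIL) + as.integer(v$MARRAY_FAIL))
  ## flags equal their stand-alone filter runs (order independence)
  tr <- fix$intensities$truth
  planted <- function(d) sort(tr$probe_id[tr$defect == d])
  expect_identical(sort(v$probe_id[v$SNR_FAIL]), planted("LOW_SNR"))
  expect_identical(sort(v$probe_id[v$CV_FAIL]), planted("HIGH_CV"))
  expect_identical(sort(v$probe_id[v$MARRAY_FAIL]),
                   planted("INTENSITY_OUTLIER"))
})

test_that("election prefers the 3'-proximal qualified probe, then rescues", {
  scores <- rbind(
    mkScores(final = c(0, 0), dist = c(450, 120), cds = "gA",
             ids = c("a1", "a2")),
    mkScores(final = c(2, 5), dist = c(200, 300), cds = "gB",
             ids = c("b1", "b2")),
    mkScores(final = c(0, 0), dist = c(150, 250), cds = "gM",
             ids = c("m1", "m2")))
  qc <- S4Vectors::DataFrame(
    probe_id = c("a1", "a2", "b1", "b2", "m1", "m2"),
    cds_id = c("gA", "gA", "gB", "gB", "gM", "gM"),
    SNR_FAIL = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    CV_FAIL = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    RESCUED = FALSE,
    MPROBE_FAIL = FALSE,
    MARRAY_FAIL = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  qc$n_fail <- as.integer(qc$SNR_FAIL) + as.integer(qc$CV_FAIL) +
    as.integer(qc$MPROBE_FAIL) + as.integer(qc$MARRAY_FAIL)
  qc$qualified <- qc$n_fail == 0L
  rep <- finalizeSelection(qc, scores, bypassCds = "gM")
  el <- as.data.frame(elections(rep))
  ## gA: both qualified, the 3'-closest (a2 at 120) wins
  expect_equal(el$probe_id[el$cds_id == "gA"], "a2")
  expect_equal(el$status[el$cds_id == "gA"], "qualified")
  ## gB: none qualified; b2 fails fewer filters than b1 -> rescued
  expect_equal(el$probe_id[el$cds_id == "gB"], "b2")
  expect_equal(el$status[el$cds_id == "gB"], "rescued")
  expect_equal(deficientCds(rep), "gB")
  ## gM: bypassed, elected on in silico standing (closest to 3')
  expect_equal(el$probe_id[el$cds_id == "gM"], "m1")
  expect_equal(el$status[el$cds_id == "gM"], "bypass")
})

test_that("expert overrides name the rescue and demand a justification", {
  scores <- mkScores(final = c(0, 0), dist = c(150, 250), cds = "gB",
                     ids = c("b1", "b2"))
  qc <- S4Vectors::DataFrame(
    probe_id = c("b1", "b2"), cds_id = "gB",
    SNR_FAIL = TRUE, CV_FAIL = FALSE, RESCUED = FALSE,
    MPROBE_FAIL = FALSE, MARRAY_FAIL = FALSE,
    n_fail = 1L, qualified = FALSE)
  ov <- data.frame(cds_id = "gB", probe_id = "b2",
                   justification = "validated by qPCR")
  rep <- finalizeSelection(qc, scores, overrides = ov)
  el <- as.data.frame(elections(rep))
  expect_equal(el$probe_id, "b2")
  expect_equal(el$status, "rescued")
  bad <- data.frame(cds_id = "gB", probe_id = "b2", justification = "")
  expect_error(finalizeSelection(qc, scores, overrides = bad),
               "justification")
})
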