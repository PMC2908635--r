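test_that("an exact embedded copy is found at 100% identity", {
  set.seed(31)
  probe <- randDna(60)
  subject <- paste0(randDna(120), probe, randDna(80))
  h <- seedExtendSearch(probe, c(sub = subject))
  expect_gte(nrow(h), 1L)
  top <- h[1L, ]
  expect_equal(top$percent_identity, 100)
  expect_equal(top$alignment_length, 60L)
  expect_equal(top$s_start, 121L)
})

test_that("a 14/20 window with an exact 7-mer run is reported", {
  set.seed(32)
  probe <- randDna(60)
  ## 6 mismatches confined to the first half leave the 13-nt tail intact,
  ## so a 7-mer seed exists and the window carries exactly 14/20 matches
  w <- strsplit(substr(probe, 21, 40), "")[[1L]]
  for (i in c(2, 4, 6, 8, 10, 12)) w[i] <- setdiff(.B, w[i])[1L]
  subject <- paste0(randDna(100), paste(w, collapse = ""), randDna(100))
  h <- seedExtendSearch(probe, c(sub = subject))
  expect_gte(nrow(h), 1L)
  expect_true(any(h$alignment_length >= 20L))
})

test_that("degenerate inputs follow the contract", {
  expect_equal(nrow(seedExtendSearch(randDna(30), character(0))), 0L)
  expect_error(seedExtendSearch("ACGTNNNACGT", c(s = randDna(50))),
               "non-ACGT")
  expect_error(seedExtendSearch(randDna(30), c(s = randDna(50)),
                                wordSize = 3), "wordSize")
})

test_that("CHI is the maximum non-target identity, zero without hits", {
  hits <- S4Vectors::DataFrame(
    probe_id = "p1",
    subject_cds_id = c("self", "a", "b", "c"),
    percent_identity = c(100, 61, 85, 90),
    is_target = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(chiOfProbe("p1", hits)$chi_percent, 90)
  none <- chiOfProbe("p2", hits[0L, ])
  expect_equal(none$chi_percent, 0)
  expect_true(is.na(none$best_subject))
})

test_that("adding a non-target subject never decreases CHI", {
  set.seed(33)
  probes <- ProbeSet("p1", "gX", 1L, randDna(60))
  pseq <- as.character(probeData(probes)$sequence[[1L]])
  subjects <- Biostrings::DNAStringSet(
    stats::setNames(replicate(5, randDna(800)), paste0("s", 1:5)))
  chi0 <- computeChi(probes, subjects)$chi_percent
  ## append a subject carrying a strong copy of the probe
  extra <- Biostrings::DNAStringSet(c(subjects,
    Biostrings::DNAStringSet(c(planted = paste0(randDna(50), pseq,
                                                randDna(50))))))
  chi1 <- computeChi(probes, extra)$chi_percent
  expect_gte(chi1, chi0)
  expect_equal(chi1, 100)
})

test_that("internal search agrees with the sliding-window oracle", {
  ## scaled-down spot check; the full 1000-trial comparison runs in the
  ## acceptance suite
  set.seed(34)
  for (t in 1:40) {
    probe <- randDna(60)
    subject <- randDna(600)
    if (t %% 2 == 0) {
      k <- sample(0:5, 1)
      w <- strsplit(substr(probe, 21, 40), "")[[1L]]
      if (k > 0) {
        at <- sample(20, k)
        for (i in at) w[i] <- sample(setdiff(.B, w[i]), 1)
      }
      at0 <- sample(500, 1)
      substr(subject, at0, at0 + 19) <- paste(w, collapse = "")
    }
    bf <- bruteForceWindows(probe, subject)
    se <- nrow(seedExtendSearch(probe, c(s = subject))) > 0
    expect_false(se && !bf$hit)          # never a false positive
    if (bf$findable) expect_true(se)     # seeded windows are always found
  }
})
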