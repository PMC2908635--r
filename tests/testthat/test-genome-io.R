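test_that("gene models derive intron x/y per the coding-strand convention", {
  gm <- toyModel(c(1, 201), c(100, 300), contigLen = 400)
  expect_equal(cdsLength(gm), 200L)
  iv <- introns(gm)
  expect_equal(iv$x, 100L)
  expect_equal(iv$y, 201L)
  single <- toyModel(1, 900, contigLen = 1000)
  expect_equal(nrow(introns(single)), 0L)
  expect_equal(cdsLength(single), 900L)
})

test_that("GeneModel validity rejects malformed exon structures", {
  expect_error(toyModel(c(1, 90), c(100, 200)), "non-empty intron")
  expect_error(toyModel(c(201, 1), c(300, 100)), "transcription order")
  expect_error(GeneModel("g", "c", "+", 50L, IRanges::IRanges(1, 100)),
               "past the end")
})

test_that("GFF3 reading mirrors minus-strand genes into coding orientation", {
  set.seed(20)
  contig <- Biostrings::DNAStringSet(c(chr1 = randDna(400)))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t300\t.\t-\t.\tID=gm1",
               "chr1\ttoy\texon\t1\t100\t.\t-\t.\tID=gm1.e1;Parent=gm1",
               "chr1\ttoy\texon\t201\t300\t.\t-\t.\tID=gm1.e2;Parent=gm1"),
             gff)
  models <- readGeneModels(gff, contig)
  m <- models[["gm1"]]
  ## mirrored coordinates: contig [201,300] -> coding [101,200], etc.
  expect_equal(IRanges::start(exons(m)), c(101L, 301L))
  expect_equal(IRanges::end(exons(m)), c(200L, 400L))
  expect_equal(introns(m)$x, 200L)
  expect_equal(introns(m)$y, 301L)
  ## spliced CDS equals the independent revcomp reconstruction
  got <- as.character(splicedCds(models, contig)[["gm1"]])
  want <- splicedByRevcomp(as.character(contig[[1]]),
                           c(1, 201), c(100, 300), "-")
  expect_equal(got, want)
})

test_that("reader errors name the offender for broken annotation", {
  contig <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrMISSING\ttoy\texon\t1\t90\t.\t+\t.\tID=g.e1;Parent=g"),
             bad)
  expect_error(readGeneModels(bad, contig), "chrMISSING")
  ooo <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t201\t300\t.\t+\t.\tID=g.e2;Parent=g",
               "chr1\ttoy\texon\t1\t100\t.\t+\t.\tID=g.e1;Parent=g"),
             ooo)
  expect_error(readGeneModels(ooo, contig), "out of order")
})

test_that("gene models round-trip through the annotation writer/reader", {
  fix <- smallFixture()
  models <- fix$genome$models
  out <- tempfile(fileext = ".gff3")
  writeGeneModels(models, out)
  back <- readGeneModels(out, fix$genome$genome)
  expect_setequal(names(back), names(models))
  for (id in names(models)) {
    expect_equal(IRanges::start(exons(back[[id]])),
                 IRanges::start(exons(models[[id]])), info = id)
    expect_equal(IRanges::end(exons(back[[id]])),
                 IRanges::end(exons(models[[id]])), info = id)
    expect_equal(back[[id]]@strand, models[[id]]@strand, info = id)
  }
})

test_that("distance from the 3' end follows d = L - start + 1", {
  expect_equal(distanceFrom3Prime(1000, 1000), 1L)
  expect_equal(distanceFrom3Prime(701, 1000), 300L)
  expect_equal(distanceFrom3Prime(1, 500), 500L)
  expect_error(distanceFrom3Prime(0, 500), "outside")
  expect_error(distanceFrom3Prime(501, 500), "outside")
})

test_that("probes re-map to their CDS by exact string search", {
  fix <- smallFixture()
  cds <- splicedCds(fix$genome$models, fix$genome$genome)
  pd <- probeData(fix$probes$probes)
  for (i in seq_len(nrow(pd))) {
    found <- Biostrings::matchPattern(pd$sequence[[i]],
                                      cds[[pd$cds_id[i]]])
    expect_true(pd$cds_start[i] %in% BiocGenerics::start(found))
  }
})

test_that("alignment-hit ingestion parses, flags targets, rejects bad rows", {
  tmp <- tempfile()
  rows <- c(paste(c("p1", "gA", "100.0", "60", "0", "0", "1", "60", "1",
                    "60", "1e-30", "120"), collapse = "\t"),
            paste(c("p1", "gB", "72.0", "25", "7", "0", "10", "34", "5",
                    "29", "1e-3", "30"), collapse = "\t"))
  writeLines(rows, tmp)
  hits <- readAlignmentHits(tmp, targetMap = c(p1 = "gA"))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$is_target, c(TRUE, FALSE))
  chi <- chiOfProbe("p1", hits)
  expect_equal(chi$chi_percent, 72)
  expect_equal(chi$best_subject, "gB")

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(readAlignmentHits(empty)), 0L)

  bad <- tempfile()
  writeLines(c(rows, "p2\tgC\tnot_a_number"), bad)
  expect_error(readAlignmentHits(bad), "line 3")
})
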