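## Deterministic synthetic fixtures.
##
## Generates a toy annotated genome, candidate probes and two-channel
## hybridization intensities whose defects are planted by construction, so
## every scoring rule and QC filter can be checked against ground truth
## without any real array data.  The experimental design mirrors a
## common-reference indirect design: several conditions, each with a fixed
## number of biological replicate arrays, hybridized against a pooled
## reference on the second channel.
##
## Defect types and the construction that guarantees their detection:
##   HIGH_CHI          a 40-nt window of the probe is copied, with
##                     mismatches giving the chosen identity, into a decoy
##                     CDS; the decoy flanks are forced to mismatch so the
##                     ungapped extension stops exactly at the window and
##                     the reported identity is deterministic.
##   HAIRPIN           a GC-rich 12-bp inverted repeat with a 4-nt loop is
##                     embedded inside the probe footprint.
##   FAR_5P            the probe is placed > 1000 nt from the CDS 3' end.
##   INTRON_OVERLAP    the probe spans an exon-exon junction.
##   LOW_SNR           planted per CDS (an unexpressed gene): every spot of
##                     every probe of the CDS gets fg = 1.5 * bg with
##                     bg_sd = bg / 2, failing SSR < 10 & SBR < 2 on every
##                     array deterministically.
##   HIGH_CV           in two conditions the probe's replicate signals are
##                     scaled by the pattern {0.2, 0.5, 1, 4} (CV about
##                     1.25 against a 0.75 threshold).
##   INTENSITY_OUTLIER the probe's sample-channel signal is offset by
##                     2^5 against its CDS siblings on every array.

#' Specification of a synthetic fixture
#'
#' The seed fully determines all outputs (genome, probes, intensities and
#' ground truth); sub-stages draw from \code{seed}, \code{seed + 1} and
#' \code{seed + 2} so each stage is independently reproducible.
#'
#' @param seed integer master seed.
#' @param nGenes number of genes carrying probes (a decoy CDS is appended
#'   when HIGH_CHI defects are planted).
#' @param intronRate probability that a gene has introns (1-3 when it
#'   does); the default mirrors a fungal genome where about half the CDS
#'   are intron-containing.
#' @param estConfirmRate probability that an intron is EST-confirmed.
#' @param probesPerGene candidate probes per CDS (default 4, the panel
#'   size).
#' @param plantedDefects named integer vector of planted counts for
#'   \code{HIGH_CHI}, \code{HAIRPIN}, \code{FAR_5P}, \code{INTRON_OVERLAP}
#'   (one probe per listed gene), \code{LOW_SNR} (whole CDS) and
#'   \code{HIGH_CV}, \code{INTENSITY_OUTLIER} (one probe per listed gene).
#'   \code{NULL} scales the default mix to \code{nGenes}.
#' @param nConditions,nBioReplicates,nTechReplicates experimental design
#'   (defaults 5 conditions x 4 biological replicates, 4 replicate spots).
#' @param noise list of noise parameters: \code{signal_sd} and
#'   \code{bg_sd} (log2 sd of the multiplicative signal and background
#'   noise), \code{bg_level} (mean background), \code{bg_sd_ratio}
#'   (reported bg_sd as a fraction of bg), \code{cond_sd} (log2 sd of
#'   per-condition expression changes), \code{expr_log2_range}
#'   (expression over background, log2).  The defaults put the clean
#'   per-condition CV near 0.1, inside the 0.05-0.2 band typical of a
#'   two-channel platform.
#' @param plantedChiIdentity window identity for HIGH_CHI plants
#'   (default 0.9).
#' @param screenClean when TRUE (default), candidate positions for
#'   non-planted probes are resampled until the probe is in silico clean
#'   (no hairpin at or below -8 kcal/mol, CHI at or below
#'   \code{screenChiMax}), emulating a designer that pre-screens its
#'   candidates.
#' @param screenChiMax CHI ceiling for the cleanliness screen (default 60,
#'   the perfect-score band).  The word-seeded search has a chance-hit
#'   noise floor that grows with the CDS-set size: against a few hundred
#'   kb of random CDS almost every 60-mer shares some 70\%-ish window, so
#'   requiring CHI at or below 60 is only satisfiable on small fixtures.
#'   Large fixtures built to exercise the hybridization filters should
#'   raise this to 84 (anything below the 85 disqualification band).
#' @return an object of class \code{FixtureSpec} (a validated list).
#' @export
fixtureSpec <- function(seed, nGenes = 200L, intronRate = 0.5,
                        estConfirmRate = 0.3, probesPerGene = 4L,
                        plantedDefects = NULL, nConditions = 5L,
                        nBioReplicates = 4L, nTechReplicates = 4L,
                        noise = list(), plantedChiIdentity = 0.9,
                        screenClean = TRUE, screenChiMax = 60) {
  defNoise <- list(signal_sd = 0.15, bg_sd = 0.1, bg_level = 100,
                   bg_sd_ratio = 0.5, cond_sd = 0.4,
                   expr_log2_range = c(3, 6))
  unknown <- setdiff(names(noise), names(defNoise))
  if (length(unknown))
    stop("unknown noise parameter(s): ", paste(unknown, collapse = ", "))
  noise <- utils::modifyList(defNoise, noise)
  if (is.null(plantedDefects)) {
    frac <- c(HIGH_CHI = 0.04, HAIRPIN = 0.04, FAR_5P = 0.04,
              INTRON_OVERLAP = 0.04, LOW_SNR = 0.025, HIGH_CV = 0.06,
              INTENSITY_OUTLIER = 0.05)
    plantedDefects <- vapply(frac, function(f) as.integer(floor(f * nGenes)),
                             integer(1))
  }
  known <- c("HIGH_CHI", "HAIRPIN", "FAR_5P", "INTRON_OVERLAP", "LOW_SNR",
             "HIGH_CV", "INTENSITY_OUTLIER")
  bad <- setdiff(names(plantedDefects), known)
  if (length(bad))
    stop("unknown defect type(s): ", paste(bad, collapse = ", "))
  planted <- stats::setNames(integer(length(known)), known)
  planted[names(plantedDefects)] <- as.integer(plantedDefects)
  if (sum(planted) > nGenes)
    stop("more planted defects than genes")
  structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                 intronRate = intronRate, estConfirmRate = estConfirmRate,
                 probesPerGene = as.integer(probesPerGene),
                 plantedDefects = planted,
                 nConditions = as.integer(nConditions),
                 nBioReplicates = as.integer(nBioReplicates),
                 nTechReplicates = as.integer(nTechReplicates),
                 noise = noise, plantedChiIdentity = plantedChiIdentity,
                 screenClean = isTRUE(screenClean),
                 screenChiMax = screenChiMax),
            class = "FixtureSpec")
}

.randDna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

## Deterministic per-gene defect assignment: contiguous blocks in the
## order of the defect table, remaining genes clean.
.assignDefects <- function(spec) {
  counts <- spec$plantedDefects
  lab <- rep("CLEAN", spec$nGenes)
  at <- 1L
  for (d in names(counts)) {
    k <- counts[[d]]
    if (k > 0L) {
      lab[at:(at + k - 1L)] <- d
      at <- at + k
    }
  }
  lab
}

#' Simulate an annotated genome with planted sequence features
#'
#' Generates contigs carrying genes on both strands (with spacers), exon /
#' intron structures, EST confirmation flags, and the sequence-level
#' defect plants (cross-homology windows in a decoy CDS, embedded
#' hairpins).  The annotation is written to GFF3 + FASTA and read back
#' through \code{\link{readGeneModels}}, so the returned models are
#' guaranteed consistent with the files on disk.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir optional output directory for \code{genome.fa},
#'   \code{annotation.gff3}, \code{est_confirmations.tsv} and
#'   \code{genome_truth.tsv} (a temporary directory is used otherwise).
#' @return a list: \code{genome} (\code{DNAStringSet}), \code{models}
#'   (\linkS4class{GeneModelSet}, EST flags applied), \code{est} (the
#'   confirmation table), \code{plants} (per-gene plant bookkeeping),
#'   \code{paths}.
#' @export
simulateGenome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  if (is.null(dir)) dir <- tempfile("fixture")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  defect <- .assignDefects(spec)
  ng <- spec$nGenes

  genes <- vector("list", ng)
  for (g in seq_len(ng)) {
    L <- if (defect[g] == "FAR_5P") sample(1700:2200, 1L)
         else sample(700:1500, 1L)
    needIntron <- defect[g] == "INTRON_OVERLAP"
    hasIntron <- needIntron || stats::runif(1) < spec$intronRate
    junctions <- integer(0)
    if (hasIntron) {
      k <- sample(1:3, 1L)
      ## junction CDS positions, >= 150 nt apart and away from the ends
      cand <- seq(150L, L - 150L, by = 10L)
      if (length(cand) >= k) {
        repeat {
          j <- sort(sample(cand, k))
          if (k == 1L || min(diff(j)) >= 150L) break
        }
        junctions <- j
      }
    }
    genes[[g]] <- list(
      id = sprintf("g%03d", g), L = L, junctions = junctions,
      intronLens = if (length(junctions))
        sample(60:200, length(junctions), replace = TRUE) else integer(0),
      est = stats::runif(length(junctions)) < spec$estConfirmRate,
      cds = .randDna(L), defect = defect[g])
  }

  ## choose positions now for probes whose plant alters sequence elsewhere
  plants <- list()
  for (g in seq_len(ng)) {
    ge <- genes[[g]]
    if (ge$defect %in% c("HIGH_CHI", "HAIRPIN")) {
      pos <- .sampleCleanStart(ge, dMin = 101L, dMax = 500L, n = 1L)
      if (ge$defect == "HAIRPIN") {
        stem <- paste(sample(c("G", "C", "G", "C", "A", "T"), 12L,
                             replace = TRUE, prob = c(3, 3, 3, 3, 1, 1)),
                      collapse = "")
        motif <- paste0(stem, .randDna(4L), .revcompChr(stem))
        at <- pos + 16L
        substr(genes[[g]]$cds, at, at + nchar(motif) - 1L) <- motif
      }
      plants[[ge$id]] <- list(defect = ge$defect, cds_start = pos)
    } else if (ge$defect == "INTRON_OVERLAP") {
      j <- ge$junctions[sample(length(ge$junctions), 1L)]
      plants[[ge$id]] <- list(defect = ge$defect, cds_start = j - 29L)
    } else if (ge$defect == "FAR_5P") {
      pos <- .sampleCleanStart(ge, dMin = 1100L, dMax = 1500L, n = 1L)
      plants[[ge$id]] <- list(defect = ge$defect, cds_start = pos)
    }
  }

  ## decoy CDS receiving the cross-homology windows
  nChi <- sum(defect == "HIGH_CHI")
  decoy <- NULL
  if (nChi > 0L) {
    win <- 40L; flank <- 10L
    slot <- win + 2L * flank + 20L
    decoySeq <- .randDna(100L + nChi * slot)
    chiGenes <- which(defect == "HIGH_CHI")
    for (k in seq_len(nChi)) {
      ge <- genes[[chiGenes[k]]]
      pos <- plants[[ge$id]]$cds_start
      probeSeq <- substr(ge$cds, pos, pos + 59L)
      insert <- .plantWindow(probeSeq, win = win, flank = flank,
                             identity = spec$plantedChiIdentity)
      at <- 50L + (k - 1L) * slot
      substr(decoySeq, at, at + nchar(insert) - 1L) <- insert
      plants[[ge$id]]$decoy_at <- at
    }
    decoy <- list(id = "decoy01", L = nchar(decoySeq),
                  junctions = integer(0), intronLens = integer(0),
                  est = logical(0), cds = decoySeq, defect = "DECOY")
  }
  allGenes <- c(genes, if (!is.null(decoy)) list(decoy))

  ## assemble contigs: 5 genes per contig, alternating strands
  contigs <- character(0)
  gff <- list(); estRows <- list()
  perContig <- 5L
  for (g in seq_along(allGenes)) {
    ge <- allGenes[[g]]
    ci <- (g - 1L) %/% perContig + 1L
    cname <- sprintf("ctg%02d", ci)
    if (length(contigs) < ci) contigs[ci] <- .randDna(150L)
    strand <- if (g %% 2L == 0L) "-" else "+"
    ## genomic fragment in coding orientation
    exonSeqs <- .splitAtJunctions(ge$cds, ge$junctions)
    frag <- exonSeqs[1L]
    exStartRel <- 1L; exRel <- matrix(0L, nrow = length(exonSeqs), ncol = 2L)
    exRel[1L, ] <- c(1L, nchar(exonSeqs[1L]))
    if (length(ge$junctions)) {
      for (k in seq_along(ge$junctions)) {
        frag <- paste0(frag, .randDna(ge$intronLens[k]), exonSeqs[k + 1L])
        s <- nchar(frag) - nchar(exonSeqs[k + 1L]) + 1L
        exRel[k + 1L, ] <- c(s, nchar(frag))
      }
    }
    Fr <- nchar(frag)
    offset <- nchar(contigs[ci])
    if (strand == "+") {
      contigs[ci] <- paste0(contigs[ci], frag)
      exAbs <- exRel + offset
    } else {
      contigs[ci] <- paste0(contigs[ci], .revcompChr(frag))
      exAbs <- cbind(offset + Fr - exRel[, 2L] + 1L,
                     offset + Fr - exRel[, 1L] + 1L)
    }
    contigs[ci] <- paste0(contigs[ci], .randDna(300L))
    ord <- order(exAbs[, 1L])
    gff[[g]] <- data.frame(contig = cname, start = exAbs[ord, 1L],
                           end = exAbs[ord, 2L], strand = strand,
                           id = ge$id, stringsAsFactors = FALSE)
    if (length(ge$junctions))
      estRows[[length(estRows) + 1L]] <- data.frame(
        cds_id = ge$id, intron_index = seq_along(ge$junctions),
        est_confirmed = ge$est, stringsAsFactors = FALSE)
  }
  names(contigs) <- sprintf("ctg%02d", seq_along(contigs))

  genomePath <- file.path(dir, "genome.fa")
  gffPath <- file.path(dir, "annotation.gff3")
  estPath <- file.path(dir, "est_confirmations.tsv")
  genome <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(genome, genomePath)
  gffTab <- do.call(rbind, gff)
  .writeGffTable(gffTab, gffPath)
  est <- if (length(estRows)) do.call(rbind, estRows) else
    data.frame(cds_id = character(), intron_index = integer(),
               est_confirmed = logical())
  .writeTsv(est, estPath)
  models <- readGeneModels(gffPath, genome)
  models <- applyEstConfirmations(models, est)
  truth <- data.frame(
    cds_id = vapply(allGenes, `[[`, character(1), "id"),
    defect = vapply(allGenes, `[[`, character(1), "defect"),
    cds_length = vapply(allGenes, `[[`, integer(1), "L"),
    n_introns = vapply(allGenes, function(x) length(x$junctions),
                       integer(1)),
    stringsAsFactors = FALSE)
  .writeTsv(truth, file.path(dir, "genome_truth.tsv"))
  list(genome = genome, models = models, est = est, plants = plants,
       geneTruth = truth, spec = spec,
       paths = list(genome = genomePath, gff = gffPath, est = estPath))
}

## split a CDS string at junction positions (junction = last base of the
## upstream exon)
.splitAtJunctions <- function(cds, junctions) {
  bounds <- c(0L, junctions, nchar(cds))
  vapply(seq_len(length(bounds) - 1L), function(k)
    substr(cds, bounds[k] + 1L, bounds[k + 1L]), character(1))
}

.revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## degrade a probe's central window to the requested identity and wrap it
## in flanks that mismatch the probe base-for-base, pinning the extension
.plantWindow <- function(probeSeq, win, flank, identity) {
  off <- (60L - win) %/% 2L                 # window = probe[off+1 .. off+win]
  wseq <- strsplit(substr(probeSeq, off + 1L, off + win), "")[[1L]]
  nMm <- max(1L, round((1 - identity) * win))
  at <- round(seq(5L, win - 5L, length.out = nMm))
  for (i in at) wseq[i] <- sample(setdiff(.BASES, wseq[i]), 1L)
  left <- strsplit(substr(probeSeq, off - flank + 1L, off), "")[[1L]]
  right <- strsplit(substr(probeSeq, off + win + 1L,
                           off + win + flank), "")[[1L]]
  anti <- function(b) vapply(b, function(x) sample(setdiff(.BASES, x), 1L),
                             character(1))
  paste(c(anti(left), wseq, anti(right)), collapse = "")
}

## sample a class-1, junction-free probe start at 3' distance in
## [dMin, dMax]; positions are CDS coordinates of the 5'-most base
.sampleCleanStart <- function(ge, dMin, dMax, n, probeLen = 60L,
                              avoid = integer(0), minSepAvoid = 60L,
                              minSepPicked = 20L) {
  L <- ge$L
  dHi <- min(dMax, L)
  starts <- (L - dHi + 1L):(L - dMin + 1L)
  starts <- starts[starts >= 1L & starts + probeLen - 1L <= L]
  if (length(ge$junctions)) {
    ok <- vapply(starts, function(s) {
      e <- s + probeLen - 1L
      ex <- findInterval(s - 1L, c(0L, ge$junctions))
      exEnd <- findInterval(e - 1L, c(0L, ge$junctions))
      if (ex != exEnd) return(FALSE)
      ## class-2 zone: first 10 bases of any non-first exon
      if (ex > 1L && s - (ge$junctions[ex - 1L] + 1L) < 10L) return(FALSE)
      TRUE
    }, logical(1))
    starts <- starts[ok]
  }
  ## keep a wide berth around planted positions (their motifs must not
  ## leak into other probes); picked clean probes may overlap each other
  for (a in avoid) starts <- starts[abs(starts - a) >= minSepAvoid]
  picked <- integer(0)
  while (length(picked) < n && length(starts)) {
    s <- sample(starts, 1L)
    starts <- starts[abs(starts - s) >= minSepPicked]
    picked <- c(picked, s)
  }
  if (length(picked) < n)
    stop("gene ", ge$id, ": could not place ", n, " probes")
  picked
}

## minimal hand-rolled GFF3 writer for the simulator (rtracklayer's writer
## is exercised by writeGeneModels; this one keeps the fixture files
## byte-stable and trivially diffable)
.writeGffTable <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (id in unique(tab$id)) {
    s <- tab[tab$id == id, , drop = FALSE]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       s$contig[1L], min(s$start), max(s$end),
                       s$strand[1L], id), con)
    for (k in seq_len(nrow(s)))
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         s$contig[k], s$start[k], s$end[k], s$strand[k],
                         id, k, id), con)
  }
  invisible(path)
}

#' Simulate candidate probes with planted score defects
#'
#' Places \code{probesPerGene} 60-mers per gene: planted positions (from
#' \code{\link{simulateGenome}}) are honored, remaining slots are clean
#' class-1 probes at 101-500 nt from the 3' end, optionally screened so
#' their in silico final score is 0.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param genomeFix result of \code{\link{simulateGenome}}.
#' @param dir optional output directory (\code{probes.tsv},
#'   \code{probe_truth.tsv}).
#' @return list: \code{probes} (\linkS4class{ProbeSet}), \code{truth}
#'   (probe_id, cds_id, defect), \code{paths}.
#' @export
simulateProbes <- function(spec, genomeFix, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed + 1L)
  if (is.null(dir)) dir <- dirname(genomeFix$paths$genome)
  cds <- splicedCds(genomeFix$models, genomeFix$genome)
  geneTruth <- genomeFix$geneTruth
  plants <- genomeFix$plants
  idx <- if (spec$screenClean)
    .subjectIndex(stats::setNames(as.character(cds), names(cds)), 7L)
  else NULL

  rows <- list(); truth <- list()
  for (gi in seq_len(nrow(geneTruth))) {
    id <- geneTruth$cds_id[gi]
    def <- geneTruth$defect[gi]
    if (def == "DECOY") next
    L <- geneTruth$cds_length[gi]
    seqStr <- as.character(cds[[id]])
    ge <- list(id = id, L = L,
               junctions = .junctionsOf(genomeFix$models[[id]]))
    plantPos <- if (!is.null(plants[[id]])) plants[[id]]$cds_start else NULL
    probeDefect <- if (def %in% c("HIGH_CHI", "HAIRPIN", "FAR_5P",
                                  "INTRON_OVERLAP")) def else NA
    nClean <- spec$probesPerGene - length(plantPos)
    cleanPos <- .placeScreened(ge, seqStr, id, nClean, idx, spec,
                               avoid = if (is.null(plantPos)) integer(0)
                                       else plantPos)
    pos <- c(plantPos, cleanPos)
    ord <- order(-pos)                       # ascending 3' distance
    pos <- pos[ord]
    lab <- c(if (!is.null(plantPos)) probeDefect,
             rep(if (def %in% c("LOW_SNR", "HIGH_CV",
                                "INTENSITY_OUTLIER")) def else "CLEAN",
                 nClean))[ord]
    ## intensity-level defects hit a single probe (the 3'-most clean one),
    ## except LOW_SNR which marks the whole CDS
    if (def %in% c("HIGH_CV", "INTENSITY_OUTLIER")) {
      lab[] <- "CLEAN"
      lab[1L] <- def
    }
    for (k in seq_along(pos)) {
      pid <- sprintf("%s_p%d", id, k)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, cds_id = id, cds_start = pos[k],
        sequence = substr(seqStr, pos[k], pos[k] + 59L),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        probe_id = pid, cds_id = id, defect = lab[k],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  probes <- ProbeSet(tab$probe_id, tab$cds_id, tab$cds_start, tab$sequence)
  truthTab <- do.call(rbind, truth)
  pPath <- file.path(dir, "probes.tsv")
  tPath <- file.path(dir, "probe_truth.tsv")
  writeProbeTable(probes, pPath)
  .writeTsv(truthTab, tPath)
  list(probes = probes, truth = truthTab,
       paths = list(probes = pPath, truth = tPath))
}

.junctionsOf <- function(model) {
  w <- IRanges::width(exons(model))
  if (length(w) < 2L) integer(0) else cumsum(w)[-length(w)]
}

## sample clean starts, optionally rejecting candidates that are not
## in silico clean (hairpin or chance cross-homology)
.placeScreened <- function(ge, seqStr, id, n, idx, spec, avoid,
                           maxTries = 200L) {
  out <- integer(0)
  if (n == 0L) return(out)
  for (k in seq_len(n)) {
    for (try in seq_len(maxTries)) {
      s <- .sampleCleanStart(ge, 101L, 500L, 1L, avoid = avoid)
      if (length(out) && min(abs(s - out)) < 20L) next
      pseq <- substr(seqStr, s, s + 59L)
      if (!is.null(idx)) {
        if (hairpinDeltaG(pseq) <= -8) next
        h <- .seedExtendOne(.encodeDna(pseq), idx, 7L, 2L, 3L, 20L, 70, 20L)
        h <- h[h$subject_cds_id != id, , drop = FALSE]
        if (nrow(h) && max(h$percent_identity) > spec$screenChiMax) next
      }
      out <- c(out, s)
      break
    }
    if (length(out) < k)
      stop("gene ", id, ": no clean position found after ", maxTries,
           " tries")
  }
  out
}

#' Simulate two-channel hybridization intensities with planted QC defects
#'
#' Every probe gets a latent expression level; spot foregrounds are the
#' background plus the latent level under multiplicative log-normal noise.
#' Planted LOW_SNR CDS read at 1.5 x background; HIGH_CV probes follow a
#' dispersed replicate pattern in two conditions; INTENSITY_OUTLIER probes
#' are offset from their CDS siblings on every array.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param genomeFix result of \code{\link{simulateGenome}}.
#' @param probesFix result of \code{\link{simulateProbes}}.
#' @param dir optional output directory (\code{intensities.tsv},
#'   \code{intensity_truth.tsv}).
#' @return list: \code{spots} (data frame), \code{truth} (probe_id,
#'   defect for intensity-level plants), \code{paths}.
#' @export
simulateIntensities <- function(spec, genomeFix, probesFix, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed + 2L)
  if (is.null(dir)) dir <- dirname(genomeFix$paths$genome)
  nz <- spec$noise
  pd <- probeData(probesFix$probes)
  truth <- probesFix$truth
  geneIds <- unique(pd$cds_id)
  ng <- length(geneIds)

  expr <- nz$bg_level *
    2^stats::runif(ng, nz$expr_log2_range[1L], nz$expr_log2_range[2L])
  names(expr) <- geneIds
  condMult <- matrix(2^stats::rnorm(ng * spec$nConditions, 0, nz$cond_sd),
                     nrow = ng,
                     dimnames = list(geneIds, NULL))
  refLatent <- rowMeans(expr * condMult)

  conds <- sprintf("C%d", seq_len(spec$nConditions))
  reps <- seq_len(spec$nBioReplicates)
  grid <- expand.grid(spot = seq_len(spec$nTechReplicates),
                      probe = seq_len(nrow(pd)),
                      channel = c("sample", "reference"),
                      rep = reps, cond = seq_along(conds),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  probeIds <- pd$probe_id[grid$probe]
  cdsIds <- pd$cds_id[grid$probe]
  latent <- ifelse(grid$channel == "sample",
                   expr[cdsIds] *
                     condMult[cbind(match(cdsIds, geneIds), grid$cond)],
                   refLatent[cdsIds])

  defMap <- stats::setNames(truth$defect, truth$probe_id)
  pDef <- unname(defMap[probeIds])

  ## HIGH_CV: dispersed replicate pattern in the last two conditions
  cvPattern <- c(0.2, 0.5, 1, 4)[grid$rep]
  cvConds <- utils::tail(seq_along(conds), 2L)
  isCv <- pDef == "HIGH_CV" & grid$channel == "sample" &
    grid$cond %in% cvConds
  mult <- ifelse(isCv, cvPattern, 1)
  ## INTENSITY_OUTLIER: constant 2^5 offset on the sample channel
  isOut <- pDef == "INTENSITY_OUTLIER" & grid$channel == "sample"
  mult <- mult * ifelse(isOut, 2^5, 1)

  bg <- nz$bg_level * 2^stats::rnorm(n, 0, nz$bg_sd)
  signal <- latent * mult * 2^stats::rnorm(n, 0, nz$signal_sd)
  fg <- bg + signal
  ## LOW_SNR: unexpressed CDS, foreground pinned to 1.5 x background
  isLow <- pDef == "LOW_SNR"
  fg[isLow] <- 1.5 * bg[isLow]

  spots <- data.frame(
    array_id = sprintf("%s_r%d", conds[grid$cond], grid$rep),
    condition = conds[grid$cond],
    channel = grid$channel,
    probe_id = probeIds,
    spot_index = grid$spot,
    fg = fg, bg = bg, bg_sd = nz$bg_sd_ratio * bg,
    control_flag = 0L,
    stringsAsFactors = FALSE)
  iTruth <- truth[truth$defect %in% c("LOW_SNR", "HIGH_CV",
                                      "INTENSITY_OUTLIER"), , drop = FALSE]
  sPath <- file.path(dir, "intensities.tsv")
  tPath <- file.path(dir, "intensity_truth.tsv")
  .writeTsv(spots, sPath)
  .writeTsv(iTruth, tPath)
  list(spots = spots, truth = iTruth,
       paths = list(spots = sPath, truth = tPath))
}

#' Generate a complete fixture (genome, probes, intensities)
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir optional output directory shared by all three stages.
#' @return list with elements \code{genome} (see
#'   \code{\link{simulateGenome}}), \code{probes}
#'   (\code{\link{simulateProbes}}) and \code{intensities}
#'   (\code{\link{simulateIntensities}}).
#' @export
simulateFixture <- function(spec, dir = NULL) {
  if (is.null(dir)) dir <- tempfile("fixture")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- simulateGenome(spec, dir)
  p <- simulateProbes(spec, g, dir)
  i <- simulateIntensities(spec, g, p, dir)
  list(genome = g, probes = p, intensities = i, dir = dir)
}
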