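## Cross-hybridization identity (CHI).
##
## A probe's CHI is the maximum percent identity it shares with any
## non-target CDS.  Hits can be ingested from an external 12-column tabular
## alignment file, or computed internally by a word-seeded ungapped
## seed-and-extend search tuned to detect a minimal identity of 70% over 20
## contiguous bases (word size 7, match +2, mismatch -3, fixed X-drop).

.BASES <- c("A", "C", "G", "T")

## Encode an ACGT string as integers 0..3; error on anything else.
.encodeDna <- function(x) {
  v <- match(strsplit(toupper(as.character(x)), "")[[1L]], .BASES) - 1L
  if (anyNA(v)) stop("sequence contains non-ACGT characters")
  v
}

## Rolling word codes (base-4) for word size w; positions 1..(n-w+1).
## Encodings >= 4 (sentinels) poison every window they touch.
.wordCodes <- function(codes, w) {
  n <- length(codes)
  if (n < w) return(integer(0))
  acc <- numeric(n - w + 1L)
  bad <- logical(n - w + 1L)
  for (k in 0L:(w - 1L)) {
    seg <- codes[(1L + k):(n - w + 1L + k)]
    acc <- acc * 4 + ifelse(seg > 3L, 0, seg)
    bad <- bad | seg > 3L
  }
  acc[bad] <- -1
  acc
}

#' Word-seeded ungapped probe-vs-CDS search
#'
#' Finds ungapped local alignments between a probe and a set of subject CDS
#' sequences.  Alignments are seeded by exact \code{wordSize}-mers and
#' extended in both directions under an X-drop rule
#' (\code{+matchReward} per match, \code{-mismatchPenalty} per mismatch;
#' extension stops when the running score falls more than \code{xDrop} below
#' its maximum, and the alignment ends at the score maxima).  Extended hits
#' shorter than \code{minWindow} nt, or whose best \code{minWindow}-nt
#' sub-window has identity below \code{minWindowIdentity} percent, are
#' discarded.  The defaults realize the sensitivity target of a minimal
#' identity of 70\% over 20 contiguous bases.
#'
#' @param probe a single probe sequence (character or \code{DNAString}).
#' @param subjects named \code{DNAStringSet} (or named character vector) of
#'   CDS sequences.
#' @param wordSize exact-match seed length (>= 4).
#' @param matchReward,mismatchPenalty ungapped extension scores.
#' @param minWindow,minWindowIdentity sensitivity window (nt, percent).
#' @param xDrop extension drop-off in score units.
#' @return a \code{DataFrame} with one row per hit: \code{subject_cds_id},
#'   \code{percent_identity} (matches / alignment length over the extended
#'   hit), \code{alignment_length}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end}.
#' @examples
#' seedExtendSearch("ACGTACGTACGTACGTACGTACGT",
#'                  c(s1 = "TTTTACGTACGTACGTACGTACGTACGTTTTT"))
#' @export
seedExtendSearch <- function(probe, subjects, wordSize = 7L,
                             matchReward = 2L, mismatchPenalty = 3L,
                             minWindow = 20L, minWindowIdentity = 70,
                             xDrop = 20L) {
  if (wordSize < 4L) stop("wordSize must be >= 4")
  p <- .encodeDna(probe)
  if (length(p) < wordSize) stop("probe shorter than wordSize")
  empty <- S4Vectors::DataFrame(
    subject_cds_id = character(), percent_identity = numeric(),
    alignment_length = integer(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer())
  if (length(subjects) == 0L) return(empty)
  nms <- names(subjects)
  subjects <- stats::setNames(as.character(subjects), nms)
  if (is.null(names(subjects)) || any(!nzchar(names(subjects))))
    stop("subjects must be named")
  idx <- .subjectIndex(subjects, wordSize)
  hits <- .seedExtendOne(p, idx, wordSize, matchReward, mismatchPenalty,
                         minWindow, minWindowIdentity, xDrop)
  if (nrow(hits) == 0L) return(empty)
  hits
}

## Concatenate subjects with sentinel runs long enough that the X-drop can
## never bridge them, and index every word position.
.subjectIndex <- function(subjects, wordSize, xDrop = 20L,
                          mismatchPenalty = 3L) {
  sep <- ceiling(xDrop / mismatchPenalty) + wordSize + 2L
  codesList <- lapply(subjects, .encodeDna)
  lens <- lengths(codesList)
  n <- length(codesList)
  offsets <- cumsum(c(0L, head(lens + sep, -1L)))
  total <- offsets[n] + lens[n]
  S <- rep.int(9L, total + sep)
  for (i in seq_len(n))
    S[(offsets[i] + 1L):(offsets[i] + lens[i])] <- codesList[[i]]
  W <- as.integer(.wordCodes(S, wordSize))
  list(S = S, W = W, offsets = offsets, lens = lens,
       names = names(subjects))
}

## One probe against an indexed subject set; the extension engine lives in
## compiled code (src/seed_extend.cpp), this wrapper maps concatenated
## coordinates back to per-subject ones.
.seedExtendOne <- function(p, idx, wordSize, matchReward, mismatchPenalty,
                           minWindow, minWindowIdentity, xDrop) {
  raw <- .seedExtendCore(as.integer(p), idx$S, idx$W,
                         as.integer(wordSize), as.integer(matchReward),
                         as.integer(mismatchPenalty), as.integer(minWindow),
                         as.numeric(minWindowIdentity), as.integer(xDrop))
  if (length(raw$q_start) == 0L)
    return(S4Vectors::DataFrame(
      subject_cds_id = character(), percent_identity = numeric(),
      alignment_length = integer(), q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer()))
  subj <- findInterval(raw$s_abs, idx$offsets + 1L)
  sLocal <- raw$s_abs - idx$offsets[subj]
  tab <- unique(data.frame(
    subject_cds_id = idx$names[subj],
    percent_identity = 100 * raw$matches / raw$length,
    alignment_length = raw$length,
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = sLocal, s_end = sLocal + raw$length - 1L,
    stringsAsFactors = FALSE))
  S4Vectors::DataFrame(tab[order(-tab$percent_identity,
                                 tab$subject_cds_id, tab$s_start), ,
                           drop = FALSE])
}

#' Read probe-vs-CDS hits from 12-column tabular alignment output
#'
#' Parses the standard 12-column tabular format (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, q.start,
#' q.end, s.start, s.end, e-value, bit score).  Hits whose subject is the
#' probe's own target CDS are flagged \code{is_target} and are excluded
#' from CHI.
#'
#' @param path path to the tabular file (no header, tab-separated).
#' @param targetMap named character vector mapping \code{probe_id} to its
#'   target \code{cds_id} (e.g. from a \linkS4class{ProbeSet}).
#' @return a \code{DataFrame} of hits with an \code{is_target} column.
#' @export
readAlignmentHits <- function(path, targetMap = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(S4Vectors::DataFrame(
      probe_id = character(), subject_cds_id = character(),
      percent_identity = numeric(), alignment_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      q_start = integer(), q_end = integer(), s_start = integer(),
      s_end = integer(), evalue = numeric(), bit_score = numeric(),
      is_target = logical()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("malformed alignment row at line ", which(nf != 12L)[1L],
         ": expected 12 tab-separated columns, got ", nf[nf != 12L][1L])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  colnames(tab) <- c("probe_id", "subject_cds_id", "percent_identity",
                     "alignment_length", "mismatches", "gap_opens",
                     "q_start", "q_end", "s_start", "s_end", "evalue",
                     "bit_score")
  numCols <- colnames(tab)[-(1:2)]
  for (cn in numCols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stop("malformed alignment row at line ",
           which(is.na(v))[1L], ": non-numeric '", cn, "'")
    tab[[cn]] <- v
  }
  for (cn in c("alignment_length", "mismatches", "gap_opens", "q_start",
               "q_end", "s_start", "s_end"))
    tab[[cn]] <- as.integer(tab[[cn]])
  if (any(tab$alignment_length < 1L))
    stop("alignment_length must be >= 1")
  if (any(tab$percent_identity < 0 | tab$percent_identity > 100))
    stop("percent_identity must be within [0, 100]")
  tab$is_target <- if (is.null(targetMap)) FALSE else
    !is.na(targetMap[tab$probe_id]) &
      targetMap[tab$probe_id] == tab$subject_cds_id
  S4Vectors::DataFrame(tab)
}

#' CHI of one probe from a collection of hits
#'
#' CHI is the maximum percent identity over the probe's non-target hits;
#' 0 when the probe has no non-target hit.
#'
#' @param probe_id the probe.
#' @param hits a hit \code{DataFrame} (rows for this probe) with columns
#'   \code{percent_identity} and \code{is_target}.
#' @return a one-row \code{DataFrame}: \code{probe_id}, \code{chi_percent},
#'   \code{best_subject} (\code{NA} when no non-target hit exists).
#' @export
chiOfProbe <- function(probe_id, hits) {
  h <- hits[!hits$is_target, , drop = FALSE]
  if ("probe_id" %in% colnames(h))
    h <- h[h$probe_id == probe_id, , drop = FALSE]
  if (nrow(h) == 0L)
    return(S4Vectors::DataFrame(probe_id = probe_id, chi_percent = 0,
                                best_subject = NA_character_))
  k <- which.max(h$percent_identity)
  S4Vectors::DataFrame(probe_id = probe_id,
                       chi_percent = h$percent_identity[k],
                       best_subject = h$subject_cds_id[k])
}

#' Cross-hybridization identity for a probe set
#'
#' Computes per-probe CHI either from externally supplied alignment hits
#' (\code{hits}) or by running the internal seed-and-extend search of each
#' probe against the whole CDS set.  Hits to a probe's own target CDS are
#' never counted.
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @param cdsSeqs named \code{DNAStringSet} of all CDS (required unless
#'   \code{hits} is given).
#' @param hits optional hit \code{DataFrame} from
#'   \code{\link{readAlignmentHits}}.
#' @param ... passed to \code{\link{seedExtendSearch}}.
#' @return \code{DataFrame} with \code{probe_id}, \code{chi_percent},
#'   \code{best_subject}, one row per probe.
#' @export
computeChi <- function(probes, cdsSeqs = NULL, hits = NULL, ...) {
  pd <- probeData(probes)
  targetMap <- stats::setNames(pd$cds_id, pd$probe_id)
  if (is.null(hits)) {
    if (is.null(cdsSeqs))
      stop("either 'cdsSeqs' or 'hits' must be supplied")
    subjects <- stats::setNames(as.character(cdsSeqs), names(cdsSeqs))
    dots <- list(...)
    wordSize <- if (is.null(dots$wordSize)) 7L else dots$wordSize
    idx <- .subjectIndex(subjects, wordSize)
    rows <- lapply(seq_len(nrow(pd)), function(i) {
      h <- .seedExtendOne(.encodeDna(pd$sequence[[i]]), idx,
                          wordSize = wordSize,
                          matchReward = if (is.null(dots$matchReward)) 2L else dots$matchReward,
                          mismatchPenalty = if (is.null(dots$mismatchPenalty)) 3L else dots$mismatchPenalty,
                          minWindow = if (is.null(dots$minWindow)) 20L else dots$minWindow,
                          minWindowIdentity = if (is.null(dots$minWindowIdentity)) 70 else dots$minWindowIdentity,
                          xDrop = if (is.null(dots$xDrop)) 20L else dots$xDrop)
      h <- h[h$subject_cds_id != pd$cds_id[i], , drop = FALSE]
      if (nrow(h) == 0L)
        return(data.frame(probe_id = pd$probe_id[i], chi_percent = 0,
                          best_subject = NA_character_,
                          stringsAsFactors = FALSE))
      k <- which.max(h$percent_identity)
      data.frame(probe_id = pd$probe_id[i],
                 chi_percent = h$percent_identity[k],
                 best_subject = h$subject_cds_id[k],
                 stringsAsFactors = FALSE)
    })
    return(S4Vectors::DataFrame(do.call(rbind, rows)))
  }
  hits$is_target <- !is.na(targetMap[hits$probe_id]) &
    targetMap[hits$probe_id] == hits$subject_cds_id
  res <- lapply(pd$probe_id, function(id) chiOfProbe(id, hits))
  do.call(rbind, res)
}
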