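## In silico criterion scores.
##
## Each probe receives five scores whose sum is its final score:
##   CHI           0 (<= 60%), 1 (60-85%), 4 (>= 85%)
##   self-folding  0 (dG > -8 kcal/mol), 1 (dG <= -8)
##   position      0 (1-500 nt from 3' end), 1 (501-1000), 4 (> 1000)
##   intron class  0 (class 1), 1 (class 2), 4 (class 3)
##   seq. match    0 (perfect match after re-annotation), 20 (mismatch)

#' Criterion score for cross-hybridization identity
#'
#' @param chi_percent numeric vector of CHI values (percent, 0-100).
#' @return integer scores: 0 when CHI <= 60, 1 when 60 < CHI < 85,
#'   4 when CHI >= 85.
#' @examples
#' scoreChi(c(60, 72, 90))  # 0 1 4
#' @export
scoreChi <- function(chi_percent) {
  if (any(chi_percent < 0 | chi_percent > 100))
    stop("CHI must be within [0, 100]")
  ifelse(chi_percent >= 85, 4L, ifelse(chi_percent > 60, 1L, 0L))
}

#' Criterion score for hairpin self-folding
#'
#' @param delta_g numeric vector, hairpin free energy in kcal/mol.
#' @return integer scores: 0 when dG > -8, 1 when dG <= -8.
#' @examples
#' scoreFold(c(-7.9, -8, -20))  # 0 1 1
#' @export
scoreFold <- function(delta_g) {
  ifelse(delta_g <= -8, 1L, 0L)
}

#' Criterion score for probe position in the CDS
#'
#' Distances are counted from the CDS 3' end (labeling starts at the polyA
#' tail and attenuates 3' to 5', so 3'-proximal probes score best).  The
#' 500 boundary belongs to the better bin.
#'
#' @param distance_3p integer vector of distances (nt, >= 1).
#' @return integer scores: 0 for 1-500, 1 for 501-1000, 4 for > 1000.
#' @examples
#' scorePosition(c(300, 800, 1200))  # 0 1 4
#' @export
scorePosition <- function(distance_3p) {
  if (any(distance_3p < 1)) stop("distance_3p must be >= 1")
  ifelse(distance_3p > 1000, 4L, ifelse(distance_3p > 500, 1L, 0L))
}

#' Intron score from the positional class
#' @param intron_class integer vector in \{1, 2, 3\}.
#' @return integer scores 0, 1, 4 for classes 1, 2, 3.
#' @export
scoreIntronClass <- function(intron_class) {
  if (any(!intron_class %in% 1:3)) stop("intron class must be 1, 2 or 3")
  c(0L, 1L, 4L)[intron_class]
}

#' Classify a probe's position relative to predicted introns
#'
#' Class 3: the probe's genomic footprint overlaps an intron interval
#' \code{(x, y)} (exclusive of x and y) -- for probes designed on the
#' spliced CDS this means the probe spans the exon-exon junction, so a
#' wrong intron prediction corrupts its sequence.  Class 2: the probe does
#' not overlap an intron but its 5'-most base lies within
#' \code{adjacencyWindow} nt downstream of some intron's \code{y}; intron
#' 3' boundaries are the least certain part of a prediction, so these
#' probes are penalized mildly.  Class 1: everything else.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param cds_start 1-based CDS position of the probe's 5'-most base.
#' @param probe_length probe length in nt.
#' @param adjacencyWindow width (nt) of the class-2 zone downstream of an
#'   intron 3' end; default 10.
#' @return integer class 1, 2 or 3, with attribute \code{overlapped}:
#'   indices of the introns the footprint overlaps (empty unless class 3).
#' @export
classifyIntronRelation <- function(model, cds_start, probe_length = 60L,
                                   adjacencyWindow = 10L) {
  span <- .probeSpan(model, cds_start, probe_length)
  iv <- introns(model)
  if (nrow(iv) == 0L)
    return(structure(1L, overlapped = integer()))
  overlapped <- which(iv$x + 1L <= span[["end"]] &
                      iv$y - 1L >= span[["start"]])
  if (length(overlapped))
    return(structure(3L, overlapped = overlapped))
  gStart <- span[["start"]]
  adjacent <- any(gStart >= iv$y & gStart < iv$y + adjacencyWindow)
  structure(if (adjacent) 2L else 1L, overlapped = integer())
}

#' Final score of a score card
#'
#' @param card a list or one-row data frame with \code{chi_score},
#'   \code{fold_score}, \code{pos_score}, \code{intron_score},
#'   \code{match_score}.
#' @return integer sum of the five criterion scores.
#' @export
totalScore <- function(card) {
  as.integer(card$chi_score + card$fold_score + card$pos_score +
             card$intron_score + card$match_score)
}

#' Score a probe set against its gene models
#'
#' Computes all per-criterion scores and the final score for every probe:
#' CHI (internal search against the whole CDS set, or externally supplied
#' hits), hairpin free energy, distance from the CDS 3' end, and intron
#' class.  The sequence-match score is 0 here (it only changes after
#' re-annotation, see \code{\link{rescoreAfterReannotation}}).
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @param models a \linkS4class{GeneModelSet} covering every target CDS.
#' @param genome genome \code{DNAStringSet} or FASTA path (needed to build
#'   the CDS set for the internal CHI search when \code{chi} and
#'   \code{hits} are absent).
#' @param chi optional precomputed CHI \code{DataFrame} from
#'   \code{\link{computeChi}}.
#' @param hits optional external alignment hits (see
#'   \code{\link{readAlignmentHits}}).
#' @param adjacencyWindow class-2 zone width, see
#'   \code{\link{classifyIntronRelation}}.
#' @return a score-card \code{DataFrame}, one row per probe: identifiers,
#'   \code{distance_3p}, \code{chi_percent}, \code{delta_g},
#'   \code{intron_class}, \code{est_ok} (TRUE when every overlapped intron
#'   is EST-confirmed), the five criterion scores, and \code{final_score}.
#' @export
scoreProbes <- function(probes, models, genome = NULL, chi = NULL,
                        hits = NULL, adjacencyWindow = 10L) {
  pd <- probeData(probes)
  missing <- setdiff(unique(pd$cds_id), names(models))
  if (length(missing))
    stop("no gene model for CDS: ", paste(missing, collapse = ", "))
  if (is.null(chi)) {
    cdsSeqs <- NULL
    if (is.null(hits)) {
      if (is.null(genome))
        stop("need 'genome' (or 'chi'/'hits') to compute CHI")
      cdsSeqs <- splicedCds(models, genome)
    }
    chi <- computeChi(probes, cdsSeqs = cdsSeqs, hits = hits)
  }
  chiMap <- stats::setNames(chi$chi_percent, chi$probe_id)
  n <- nrow(pd)
  lens <- Biostrings::width(pd$sequence)
  dist3 <- integer(n); iclass <- integer(n); estOk <- logical(n)
  dg <- numeric(n)
  for (i in seq_len(n)) {
    m <- models[[pd$cds_id[i]]]
    dist3[i] <- distanceFrom3Prime(pd$cds_start[i], cdsLength(m))
    cl <- classifyIntronRelation(m, pd$cds_start[i], lens[i],
                                 adjacencyWindow)
    iclass[i] <- as.integer(cl)
    ov <- attr(cl, "overlapped")
    estOk[i] <- length(ov) == 0L || all(introns(m)$est_confirmed[ov])
    dg[i] <- hairpinDeltaG(pd$sequence[[i]])
  }
  chiPct <- unname(chiMap[pd$probe_id])
  if (anyNA(chiPct))
    stop("missing CHI value for probe(s): ",
         paste(pd$probe_id[is.na(chiPct)], collapse = ", "))
  card <- S4Vectors::DataFrame(
    probe_id = pd$probe_id, cds_id = pd$cds_id,
    cds_start = pd$cds_start, length = lens,
    distance_3p = dist3,
    chi_percent = chiPct, chi_score = scoreChi(chiPct),
    delta_g = dg, fold_score = scoreFold(dg),
    pos_score = scorePosition(dist3),
    intron_class = iclass, intron_score = scoreIntronClass(iclass),
    est_ok = estOk,
    match_score = 0L)
  card$final_score <- totalScore(card)
  card
}
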