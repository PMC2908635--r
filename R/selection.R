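## Two-round per-CDS probe selection and re-annotation rescoring.

#' First-round selection for one CDS
#'
#' Admits probes with a final score below 4 whose 5'-most base does not
#' start within the last 100 nt of the CDS (distance from the 3' end must
#' exceed \code{minDistance}).  When more than \code{maxPanel} probes
#' qualify, the four closest to the 3' end are kept; ties are broken by
#' probe id.
#'
#' @param scores score-card rows (\code{DataFrame} or data frame) of the
#'   probes of one CDS; needs \code{probe_id}, \code{final_score},
#'   \code{distance_3p}.
#' @param scoreCut admission bound, exclusive (default 4: "below 4").
#' @param minDistance 3'-proximity exclusion, exclusive (default 100 nt).
#' @param maxPanel panel size (default 4).
#' @return character vector of admitted probe ids, ordered by ascending
#'   distance from the 3' end.
#' @export
selectRound1 <- function(scores, scoreCut = 4L, minDistance = 100L,
                         maxPanel = 4L) {
  ok <- scores$final_score < scoreCut & scores$distance_3p > minDistance
  adm <- scores[ok, , drop = FALSE]
  ord <- order(adm$distance_3p, adm$probe_id)
  ids <- adm$probe_id[ord]
  utils::head(ids, maxPanel)
}

#' Second-round selection for one CDS
#'
#' Called only when round 1 produced fewer than \code{maxPanel} probes.
#' Admits additional probes with final scores up to 8 (inclusive),
#' excluding probes with a CHI over 85\% and probes starting upstream of
#' the 3'-terminal 1500 nt.  Intron-overlapping (class 3) probes are
#' recoverable only when every intron they overlap is EST-confirmed.
#' The panel is topped up to \code{maxPanel} by ascending distance from
#' the 3' end.
#'
#' @param scores score-card rows of one CDS (must include
#'   \code{chi_percent}, \code{intron_class}, \code{est_ok}).
#' @param round1 character vector of round-1 probe ids.
#' @param scoreCut inclusive score bound (default 8).
#' @param chiCut exclusive CHI bound (default 85: "over 85\%" excluded).
#' @param maxDistance inclusive distance bound (default 1500 nt).
#' @param maxPanel panel size (default 4).
#' @return character vector of additionally admitted probe ids (ascending
#'   distance).
#' @export
selectRound2 <- function(scores, round1, scoreCut = 8L, chiCut = 85,
                         maxDistance = 1500L, maxPanel = 4L) {
  if (length(round1) >= maxPanel)
    stop("second-round selection applies only to CDS with fewer than ",
         maxPanel, " first-round probes")
  cand <- scores[!scores$probe_id %in% round1, , drop = FALSE]
  ok <- cand$final_score <= scoreCut &
    cand$chi_percent <= chiCut &
    cand$distance_3p <= maxDistance &
    (cand$intron_class != 3L | cand$est_ok)
  cand <- cand[ok, , drop = FALSE]
  ord <- order(cand$distance_3p, cand$probe_id)
  utils::head(cand$probe_id[ord], maxPanel - length(round1))
}

#' Run both selection rounds over all CDS
#'
#' @param scores a full score card from \code{\link{scoreProbes}}.
#' @param maxPanel,scoreCut,minDistance round-1 parameters.
#' @param round2ScoreCut,round2ChiCut,round2MaxDistance round-2 parameters.
#' @param deficientBelow a CDS is probe-deficient when its panel ends up
#'   with fewer than this many probes (default 2: no, or only one, probe
#'   after round 2 triggers new design).
#' @return \code{DataFrame} with one row per CDS: \code{cds_id},
#'   \code{round1} and \code{round2} (\code{CharacterList} columns of probe
#'   ids), \code{panel} (their union, ascending distance), and
#'   \code{deficient}.
#' @export
selectPanels <- function(scores, maxPanel = 4L, scoreCut = 4L,
                         minDistance = 100L, round2ScoreCut = 8L,
                         round2ChiCut = 85, round2MaxDistance = 1500L,
                         deficientBelow = 2L) {
  sc <- as.data.frame(scores[, c("probe_id", "cds_id", "final_score",
                                 "distance_3p", "chi_percent",
                                 "intron_class", "est_ok")])
  byCds <- split(sc, sc$cds_id)
  rows <- lapply(byCds, function(s) {
    r1 <- selectRound1(s, scoreCut, minDistance, maxPanel)
    r2 <- character()
    if (length(r1) < maxPanel)
      r2 <- selectRound2(s, r1, round2ScoreCut, round2ChiCut,
                         round2MaxDistance, maxPanel)
    panel <- c(r1, r2)
    dmap <- stats::setNames(s$distance_3p, s$probe_id)
    panel <- panel[order(dmap[panel], panel)]
    list(r1 = r1, r2 = r2, panel = panel)
  })
  S4Vectors::DataFrame(
    cds_id = names(byCds),
    round1 = IRanges::CharacterList(lapply(rows, `[[`, "r1")),
    round2 = IRanges::CharacterList(lapply(rows, `[[`, "r2")),
    panel = IRanges::CharacterList(lapply(rows, `[[`, "panel")),
    deficient = vapply(rows, function(r) length(r$panel), integer(1)) <
      deficientBelow)
}

#' Re-validate probes against a re-annotated CDS set
#'
#' After a genome re-annotation, every probe is checked for an exact
#' sequence match within its target's updated CDS.  Probes that still
#' match keep a sequence-match score of 0; probes whose target CDS changed
#' under them receive a score of 20, which guarantees they fall out of any
#' subsequent selection.  Probes whose target CDS no longer exists are
#' orphaned (also score 20) and their CDS reported.
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @param newCds \code{DNAStringSet} (or FASTA path) of the updated CDS set.
#' @param scores the current score card from \code{\link{scoreProbes}}.
#' @return a list: \code{scores} (updated score card with recomputed
#'   \code{match_score}/\code{final_score} and an \code{orphaned} column),
#'   \code{orphaned} (probe ids), and \code{deficientCds} (target CDS ids
#'   left without a single surviving probe).
#' @export
rescoreAfterReannotation <- function(probes, newCds, scores) {
  if (is.character(newCds)) newCds <- Biostrings::readDNAStringSet(newCds)
  pd <- probeData(probes)
  idx <- match(scores$probe_id, pd$probe_id)
  if (anyNA(idx))
    stop("score card contains probes absent from the probe set: ",
         paste(scores$probe_id[is.na(idx)], collapse = ", "))
  n <- nrow(scores)
  match0 <- integer(n); orphan <- logical(n)
  for (i in seq_len(n)) {
    target <- pd$cds_id[idx[i]]
    if (!target %in% names(newCds)) {
      orphan[i] <- TRUE
      match0[i] <- 20L
      next
    }
    hit <- Biostrings::matchPattern(pd$sequence[[idx[i]]],
                                    newCds[[target]], fixed = TRUE)
    match0[i] <- if (length(hit) > 0L) 0L else 20L
  }
  scores$match_score <- match0
  scores$orphaned <- orphan
  scores$final_score <- totalScore(scores)
  surviving <- scores$cds_id[scores$match_score == 0L]
  S4Vectors::metadata(scores)$reannotated <- TRUE
  list(scores = scores,
       orphaned = scores$probe_id[orphan],
       deficientCds = sort(setdiff(unique(scores$cds_id), surviving)))
}
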