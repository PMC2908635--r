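## Experimental probe quality control.
##
## Spot-level two-channel intensities are normalized, collapsed over
## technical replicates, and pushed through three criteria:
##   (1) signal-to-noise: SSR = (fg - bg) / bg_sd and SBR = fg / bg; a
##       probe failing SSR < 10 AND SBR < 2 in all samples, or all but
##       one, is discarded;
##   (2) reproducibility: per-condition CV of the normalized signal over
##       biological replicates; CV > 0.75 in any condition rejects the
##       probe unless an expert rescue entry retains it;
##   (3) representative intensity: M_probe (median reference-channel
##       signal) must lie within the interquartile range of its CDS
##       siblings, and the per-array signal must fall inside
##       M_array +/- 1.5 CI on at least one array.
## Flags are computed independently, never as sequential eliminations.

#' Read / write a spot-level intensity table
#'
#' Tab-separated with columns \code{array_id}, \code{condition},
#' \code{channel} (\code{sample} or \code{reference}), \code{probe_id},
#' \code{spot_index}, \code{fg}, \code{bg}, \code{bg_sd},
#' \code{control_flag}.
#'
#' @param path file path.
#' @return a data frame of spots.
#' @export
readIntensityTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("array_id", "condition", "channel", "probe_id", "spot_index",
            "fg", "bg", "bg_sd")
  if (!all(need %in% colnames(tab)))
    stop("intensity table needs columns: ", paste(need, collapse = ", "))
  if (!all(tab$channel %in% c("sample", "reference")))
    stop("channel must be 'sample' or 'reference'")
  if (any(tab$fg < 0 | tab$bg < 0 | tab$bg_sd < 0))
    stop("intensities and background statistics must be non-negative")
  tab
}

#' @rdname readIntensityTable
#' @param spots a spot data frame.
#' @export
writeIntensityTable <- function(spots, path) .writeTsv(spots, path)

#' Normalize spot intensities
#'
#' Default method: background-subtract (clamped at 1), log2, then
#' median-center within each array-by-channel group.  The result is
#' written into a \code{norm} column.  Alternative methods can be plugged
#' in as a function \code{f(fg, bg)} returning pre-centering values.
#'
#' @param spots spot data frame (see \code{\link{readIntensityTable}}).
#' @param method \code{"bgLog2Median"} or a function \code{f(fg, bg)}.
#' @param minSpots an array-channel group with fewer spots than this is a
#'   degenerate normalization target and raises an error (default 10).
#' @return \code{spots} with a filled \code{norm} column (log2 scale).
#' @export
normalizeSpots <- function(spots, method = "bgLog2Median",
                           minSpots = 10L) {
  raw <- if (is.function(method)) method(spots$fg, spots$bg)
         else log2(pmax(spots$fg - spots$bg, 1))
  grp <- paste(spots$array_id, spots$channel, sep = "\r")
  cnt <- table(grp)
  if (any(cnt < minSpots))
    stop("array '", sub("\r.*", "", names(cnt)[cnt < minSpots][1L]),
         "' has fewer than ", minSpots,
         " spots in a channel; refusing to normalize")
  med <- tapply(raw, grp, stats::median)
  spots$norm <- raw - unname(med[grp])
  spots
}

#' Signal-to-noise metrics of a spot
#'
#' SSR (signal-to-standard-deviation ratio) is the background-subtracted
#' foreground over the background standard deviation; SBR
#' (signal-to-background ratio) is foreground over background.
#'
#' @param fg,bg,bg_sd numeric vectors.
#' @return a data frame with columns \code{ssr} and \code{sbr}.  Zero
#'   denominators yield \code{Inf} with a warning (an undefined ratio can
#'   never fail a threshold).
#' @examples
#' computeSsrSbr(1000, 100, 50)  # ssr 18, sbr 10
#' @export
computeSsrSbr <- function(fg, bg, bg_sd) {
  ssr <- ifelse(bg_sd > 0, (fg - bg) / bg_sd, Inf)
  if (any(bg_sd == 0))
    warning("bg_sd = 0: SSR undefined, reported as Inf")
  sbr <- ifelse(bg > 0, fg / bg, Inf)
  if (any(bg == 0))
    warning("bg = 0: SBR undefined, reported as Inf")
  data.frame(ssr = ssr, sbr = sbr)
}

#' Signal-to-noise verdict per probe
#'
#' A probe is discarded when it fails both thresholds (SSR below
#' \code{ssrCut} and SBR below \code{sbrCut}) in all samples or in all
#' samples but one; a sample is one hybridization (array, sample channel).
#'
#' @param snr data frame with one row per probe-sample pair: columns
#'   \code{probe_id}, \code{array_id}, \code{ssr}, \code{sbr}.
#' @param ssrCut,sbrCut thresholds (defaults 10 and 2).
#' @return data frame: \code{probe_id}, \code{n_samples},
#'   \code{n_fail_samples}, \code{SNR_FAIL}.
#' @export
snrFilter <- function(snr, ssrCut = 10, sbrCut = 2) {
  fail <- snr$ssr < ssrCut & snr$sbr < sbrCut
  nFail <- tapply(fail, snr$probe_id, sum)
  nAll <- tapply(fail, snr$probe_id, length)
  data.frame(probe_id = names(nFail),
             n_samples = as.integer(nAll),
             n_fail_samples = as.integer(nFail),
             SNR_FAIL = as.integer(nFail) >= as.integer(nAll) - 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coefficient of variation of replicate intensities
#'
#' Sample standard deviation (n - 1 denominator) over the mean, computed on
#' linear-scale normalized intensities.
#'
#' @param values numeric vector of at least 2 replicate intensities.
#' @return the CV.
#' @examples
#' computeCv(c(1, 2, 3, 4))  # 0.5164
#' @export
computeCv <- function(values) {
  if (length(values) < 2L) stop("CV needs at least 2 replicates")
  m <- mean(values)
  if (m <= 0) stop("mean intensity <= 0: normalization contract violated")
  stats::sd(values) / m
}

#' Reproducibility verdict per probe
#'
#' Flags \code{CV_FAIL} when the CV exceeds \code{cvCut} in at least one
#' condition; probes on the expert rescue list are retained and flagged
#' \code{RESCUED} instead (modeling supervised retention of biologically
#' heterogeneous genes).  Every rescue entry must carry a justification.
#'
#' @param cvs data frame with columns \code{probe_id}, \code{condition},
#'   \code{cv}.
#' @param rescue optional data frame with columns \code{probe_id},
#'   \code{justification}.
#' @param cvCut threshold (default 0.75, strict inequality).
#' @return data frame: \code{probe_id}, \code{max_cv}, \code{CV_FAIL},
#'   \code{RESCUED}, \code{rescue_justification}.
#' @export
cvFilter <- function(cvs, rescue = NULL, cvCut = 0.75) {
  if (!is.null(rescue)) {
    if (!all(c("probe_id", "justification") %in% colnames(rescue)))
      stop("rescue list needs columns 'probe_id' and 'justification'")
    bad <- is.na(rescue$justification) | !nzchar(trimws(rescue$justification))
    if (any(bad))
      stop("rescue entry without justification: ",
           paste(rescue$probe_id[bad], collapse = ", "))
  }
  maxCv <- tapply(cvs$cv, cvs$probe_id, max)
  over <- unname(maxCv) > cvCut
  ids <- names(maxCv)
  rescued <- over & ids %in% rescue$probe_id
  just <- rep(NA_character_, length(ids))
  if (any(rescued))
    just[rescued] <- rescue$justification[match(ids[rescued],
                                                rescue$probe_id)]
  data.frame(probe_id = ids, max_cv = unname(maxCv),
             CV_FAIL = over & !rescued, RESCUED = rescued,
             rescue_justification = just,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Representative-intensity verdict: M_probe vs the CDS interquartile range
#'
#' M_probe is each probe's median reference-channel normalized intensity;
#' probes strictly outside the interquartile range (linear-interpolation
#' quantiles) of their CDS siblings' M_probe values are rejected.
#' Single-probe CDS are exempt.
#'
#' @param mprobe data frame with columns \code{probe_id}, \code{cds_id},
#'   \code{m_probe}.
#' @return data frame: \code{probe_id}, \code{cds_id}, \code{m_probe},
#'   \code{q1}, \code{q3}, \code{MPROBE_FAIL}.
#' @examples
#' mprobeFilter(data.frame(probe_id = letters[1:4], cds_id = "g",
#'                         m_probe = c(1, 2, 3, 10)))
#' @export
mprobeFilter <- function(mprobe) {
  out <- lapply(split(mprobe, mprobe$cds_id), function(s) {
    if (nrow(s) < 2L) {
      s$q1 <- s$q3 <- s$m_probe
      s$MPROBE_FAIL <- FALSE
      return(s)
    }
    q <- stats::quantile(s$m_probe, c(0.25, 0.75), type = 7, names = FALSE)
    s$q1 <- q[1L]; s$q3 <- q[2L]
    s$MPROBE_FAIL <- s$m_probe < q[1L] | s$m_probe > q[2L]
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Representative-intensity verdict: per-array signal vs M_array +/- 1.5 CI
#'
#' For every array, M_array is the mean sample-channel intensity of the
#' probes of a CDS and CI its 95\% confidence half-width.  A probe is
#' discarded only if its intensity falls outside
#' M_array \eqn{\pm} \code{ciFactor} * CI on \emph{every} array: failure
#' must be universal, a single in-range array retains the probe.
#' CDS with fewer than 2 probes are exempt.
#'
#' @param intensities data frame with columns \code{probe_id},
#'   \code{cds_id}, \code{array_id}, \code{value} (normalized
#'   sample-channel intensity, one row per probe-array).
#' @param ciFactor multiplier on the CI half-width (default 1.5).
#' @param ciMethod \code{"normal"} (1.96 * sd / sqrt(n)) or \code{"t"}
#'   (Student quantile, small-n alternative).
#' @return data frame: \code{probe_id}, \code{cds_id}, \code{n_arrays},
#'   \code{n_out_arrays}, \code{MARRAY_FAIL}.
#' @export
marrayFilter <- function(intensities, ciFactor = 1.5,
                         ciMethod = c("normal", "t")) {
  ciMethod <- match.arg(ciMethod)
  out <- lapply(split(intensities, intensities$cds_id), function(s) {
    ids <- unique(s$probe_id)
    if (length(ids) < 2L)
      return(data.frame(probe_id = ids, cds_id = s$cds_id[1L],
                        n_arrays = length(unique(s$array_id)),
                        n_out_arrays = 0L, MARRAY_FAIL = FALSE,
                        stringsAsFactors = FALSE))
    nOut <- stats::setNames(integer(length(ids)), ids)
    arrays <- split(s, s$array_id)
    for (a in arrays) {
      mu <- mean(a$value)
      sdv <- stats::sd(a$value)
      nm <- nrow(a)
      z <- if (ciMethod == "normal") 1.96 else stats::qt(0.975, nm - 1L)
      hw <- z * sdv / sqrt(nm)
      outside <- abs(a$value - mu) > ciFactor * hw
      nOut[a$probe_id[outside]] <- nOut[a$probe_id[outside]] + 1L
    }
    nArr <- length(arrays)
    data.frame(probe_id = ids, cds_id = s$cds_id[1L], n_arrays = nArr,
               n_out_arrays = as.integer(nOut[ids]),
               MARRAY_FAIL = as.integer(nOut[ids]) == nArr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Collapse technical replicate spots: one value per probe x array x
## channel (median), keeping condition and median ssr/sbr.
.collapseSpots <- function(spots) {
  key <- paste(spots$probe_id, spots$array_id, spots$channel, sep = "\r")
  first <- !duplicated(key)
  agg <- data.frame(
    probe_id = spots$probe_id[first],
    array_id = spots$array_id[first],
    channel = spots$channel[first],
    condition = spots$condition[first],
    norm = as.numeric(tapply(spots$norm, key, stats::median)[key[first]]),
    ssr = as.numeric(tapply(spots$ssr, key, stats::median)[key[first]]),
    sbr = as.numeric(tapply(spots$sbr, key, stats::median)[key[first]]),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg
}

#' Run the full experimental QC cascade
#'
#' Normalizes spots, collapses technical replicates, applies the three
#' experimental criteria, and combines the flags into one verdict per
#' probe.  Flags are computed independently of each other, so the filter
#' order is immaterial.
#'
#' @param spots spot-level intensity data frame (see
#'   \code{\link{readIntensityTable}}).
#' @param probes a \linkS4class{ProbeSet} (maps probes to their CDS); only
#'   probes present here are assessed.
#' @param rescue optional CV rescue list (see \code{\link{cvFilter}}).
#' @param ssrCut,sbrCut,cvCut,ciFactor,ciMethod filter parameters.
#' @param normMethod passed to \code{\link{normalizeSpots}}.
#' @return a verdict \code{DataFrame}, one row per probe: metrics, the
#'   four flags, \code{n_fail} (number of failed criteria) and
#'   \code{qualified}.
#' @export
probeQc <- function(spots, probes, rescue = NULL, ssrCut = 10, sbrCut = 2,
                    cvCut = 0.75, ciFactor = 1.5,
                    ciMethod = c("normal", "t"),
                    normMethod = "bgLog2Median") {
  ciMethod <- match.arg(ciMethod)
  pd <- probeData(probes)
  spots <- spots[spots$probe_id %in% pd$probe_id, , drop = FALSE]
  if (!nrow(spots)) stop("no spots left for the probes under assessment")
  spots <- normalizeSpots(spots, method = normMethod)
  sn <- computeSsrSbr(spots$fg, spots$bg, spots$bg_sd)
  spots$ssr <- sn$ssr; spots$sbr <- sn$sbr
  agg <- .collapseSpots(spots)
  cdsMap <- stats::setNames(pd$cds_id, pd$probe_id)

  samp <- agg[agg$channel == "sample", , drop = FALSE]
  refc <- agg[agg$channel == "reference", , drop = FALSE]

  snrV <- snrFilter(samp[, c("probe_id", "array_id", "ssr", "sbr")],
                    ssrCut, sbrCut)

  cvKey <- paste(samp$probe_id, samp$condition, sep = "\r")
  lin <- 2^samp$norm
  cvTab <- data.frame(
    probe_id = sub("\r.*", "", names(tapply(lin, cvKey, length))),
    condition = sub(".*\r", "", names(tapply(lin, cvKey, length))),
    cv = as.numeric(tapply(lin, cvKey, computeCv)),
    stringsAsFactors = FALSE)
  cvV <- cvFilter(cvTab, rescue, cvCut)

  mp <- data.frame(
    probe_id = names(tapply(refc$norm, refc$probe_id, stats::median)),
    m_probe = as.numeric(tapply(refc$norm, refc$probe_id, stats::median)),
    stringsAsFactors = FALSE)
  mp$cds_id <- unname(cdsMap[mp$probe_id])
  mpV <- mprobeFilter(mp)

  maTab <- data.frame(probe_id = samp$probe_id,
                      cds_id = unname(cdsMap[samp$probe_id]),
                      array_id = samp$array_id, value = samp$norm,
                      stringsAsFactors = FALSE)
  maV <- marrayFilter(maTab, ciFactor, ciMethod)

  ids <- sort(unique(agg$probe_id))
  v <- S4Vectors::DataFrame(
    probe_id = ids,
    cds_id = unname(cdsMap[ids]),
    n_fail_samples = snrV$n_fail_samples[match(ids, snrV$probe_id)],
    SNR_FAIL = snrV$SNR_FAIL[match(ids, snrV$probe_id)],
    max_cv = cvV$max_cv[match(ids, cvV$probe_id)],
    CV_FAIL = cvV$CV_FAIL[match(ids, cvV$probe_id)],
    RESCUED = cvV$RESCUED[match(ids, cvV$probe_id)],
    m_probe = mpV$m_probe[match(ids, mpV$probe_id)],
    MPROBE_FAIL = mpV$MPROBE_FAIL[match(ids, mpV$probe_id)],
    MARRAY_FAIL = maV$MARRAY_FAIL[match(ids, maV$probe_id)])
  for (fl in c("SNR_FAIL", "CV_FAIL", "RESCUED", "MPROBE_FAIL",
               "MARRAY_FAIL"))
    v[[fl]][is.na(v[[fl]])] <- FALSE
  v$n_fail <- as.integer(v$SNR_FAIL) + as.integer(v$CV_FAIL) +
    as.integer(v$MPROBE_FAIL) + as.integer(v$MARRAY_FAIL)
  v$qualified <- v$n_fail == 0L
  v
}

#' Elect one final probe per CDS
#'
#' For every CDS with at least one qualified probe, the qualified probe
#' closest to the CDS 3' end is elected (ties by probe id).  Probe-deficient
#' CDS (no qualified probe) receive one probe from the rejected set:
#' either the expert-override probe, or the rejected probe ranked first by
#' fewest failed filters, then smallest final score, then smallest
#' distance from the 3' end; these elections are marked rescued.  CDS on
#' the bypass list (e.g. mitochondrial probes that undergo only the
#' computational screening) are elected on in silico standing alone:
#' their panel head (smallest distance) wins regardless of QC.
#'
#' @param qc verdict \code{DataFrame} from \code{\link{probeQc}} (or
#'   \code{NULL} when every CDS is bypassed).
#' @param scores score card from \code{\link{scoreProbes}} (supplies
#'   \code{final_score} and \code{distance_3p}).
#' @param allCds optional character vector of every CDS that should appear
#'   in the report (defaults to the CDS present in \code{scores}).
#' @param bypassCds character vector of CDS ids exempt from experimental
#'   criteria.
#' @param overrides optional data frame \code{cds_id}, \code{probe_id},
#'   \code{justification}: expert-named elections for deficient CDS.
#' @return a \linkS4class{SelectionReport}.
#' @export
finalizeSelection <- function(qc, scores, allCds = NULL,
                              bypassCds = character(), overrides = NULL) {
  sc <- as.data.frame(scores[, c("probe_id", "cds_id", "final_score",
                                 "distance_3p")])
  if (is.null(allCds)) allCds <- sort(unique(sc$cds_id))
  if (!is.null(overrides)) {
    if (!all(c("cds_id", "probe_id", "justification") %in%
             colnames(overrides)))
      stop("overrides need columns cds_id, probe_id, justification")
    bad <- is.na(overrides$justification) |
      !nzchar(trimws(overrides$justification))
    if (any(bad))
      stop("override without justification: ",
           paste(overrides$cds_id[bad], collapse = ", "))
  }
  qcDf <- if (is.null(qc)) NULL else as.data.frame(qc)
  rows <- lapply(allCds, function(cds) {
    s <- sc[sc$cds_id == cds, , drop = FALSE]
    if (nrow(s) == 0L)
      return(data.frame(cds_id = cds, probe_id = NA_character_,
                        status = "none", reason = "no probes",
                        stringsAsFactors = FALSE))
    if (cds %in% bypassCds || is.null(qcDf)) {
      k <- order(s$distance_3p, s$probe_id)[1L]
      return(data.frame(cds_id = cds, probe_id = s$probe_id[k],
                        status = "bypass",
                        reason = "computational screening only",
                        stringsAsFactors = FALSE))
    }
    q <- qcDf[match(s$probe_id, qcDf$probe_id), , drop = FALSE]
    q$n_fail[is.na(q$n_fail)] <- 4L   # probe never measured: worst rank
    qual <- s[!is.na(q$qualified) & q$qualified, , drop = FALSE]
    if (nrow(qual)) {
      k <- order(qual$distance_3p, qual$probe_id)[1L]
      return(data.frame(cds_id = cds, probe_id = qual$probe_id[k],
                        status = "qualified",
                        reason = "closest qualified probe to 3' end",
                        stringsAsFactors = FALSE))
    }
    ov <- if (is.null(overrides)) NULL else
      overrides[overrides$cds_id == cds, , drop = FALSE]
    if (!is.null(ov) && nrow(ov)) {
      if (!ov$probe_id[1L] %in% s$probe_id)
        stop("override probe '", ov$probe_id[1L],
             "' does not target CDS '", cds, "'")
      return(data.frame(cds_id = cds, probe_id = ov$probe_id[1L],
                        status = "rescued",
                        reason = paste0("expert override: ",
                                        ov$justification[1L]),
                        stringsAsFactors = FALSE))
    }
    k <- order(q$n_fail, s$final_score, s$distance_3p, s$probe_id)[1L]
    data.frame(cds_id = cds, probe_id = s$probe_id[k], status = "rescued",
               reason = sprintf("least-failing rejected probe (%d filters)",
                                q$n_fail[k]),
               stringsAsFactors = FALSE)
  })
  el <- S4Vectors::DataFrame(do.call(rbind, rows))
  new("SelectionReport",
      verdicts = if (is.null(qc)) S4Vectors::DataFrame() else qc,
      elections = el,
      deficient = el$cds_id[el$status == "rescued"])
}

#' Summary counts in the layout of an experimental-scoring table
#'
#' One row per criterion with rejected / qualified probe counts, plus the
#' overall election outcome.
#'
#' @param report a \linkS4class{SelectionReport}.
#' @return a data frame of counts.
#' @export
reportSummary <- function(report) {
  v <- verdicts(report)
  el <- elections(report)
  if (nrow(v) == 0L)
    return(data.frame(metric = "election",
                      rejected = sum(el$status == "none"),
                      qualified = sum(el$status != "none")))
  metrics <- c(`SSR, SBR` = "SNR_FAIL", CV = "CV_FAIL",
               `M_probe` = "MPROBE_FAIL", `M_array` = "MARRAY_FAIL")
  tab <- data.frame(
    metric = names(metrics),
    rejected = vapply(metrics, function(f) sum(v[[f]]), integer(1)),
    qualified = vapply(metrics, function(f) sum(!v[[f]]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  rbind(tab,
        data.frame(metric = "all criteria",
                   rejected = sum(!v$qualified),
                   qualified = sum(v$qualified)),
        data.frame(metric = "probe-deficient CDS",
                   rejected = length(deficientCds(report)),
                   qualified = sum(el$status == "qualified")))
}
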