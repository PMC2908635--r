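## End-to-end orchestration: score -> select rounds -> [rescore] -> QC ->
## elect -> report, with a resolved-config manifest per run.

.CONFIG_DEFAULTS <- list(
  genome = NULL, gff3 = NULL, est = NULL, probes = NULL, hits = NULL,
  intensities = NULL, new_cds = NULL, rescue_cv = NULL, overrides = NULL,
  bypass_cds = NULL, out_dir = NULL,
  score_cut = 4L, round2_score_cut = 8L, round2_chi_cut = 85,
  chi_band_low = 60, chi_band_high = 85, delta_g_cut = -8,
  pos_bin1 = 500L, pos_bin2 = 1000L,
  min_distance = 100L, round2_max_distance = 1500L, max_panel = 4L,
  adjacency_window = 10L,
  ssr_cut = 10, sbr_cut = 2, cv_cut = 0.75, ci_factor = 1.5,
  ci_method = "normal", quantile_type = 7L,
  run_qc = TRUE, seed = 1L)

#' Assemble / read a pipeline run configuration
#'
#' A run configuration holds all input paths and every threshold of the
#' procedure, pre-filled with the published defaults (first-round score
#' cut 4, second-round cut 8, CHI bands 60/85, hairpin cut -8 kcal/mol,
#' position bins 500/1000, 3'-exclusions 100/1500 nt, SSR 10, SBR 2,
#' CV 0.75, CI factor 1.5).  Unknown keys are rejected so typos cannot
#' silently disable a filter.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class \code{RunConfig}.
#' @export
runConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over, keep.null = TRUE)
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param path a YAML file of config keys.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full probe-selection pipeline
#'
#' Executes, in order: in silico scoring, the two selection rounds,
#' optional re-annotation rescoring (when \code{new_cds} is configured),
#' optional experimental QC (when \code{intensities} is configured), the
#' final per-CDS election and the summary report.  Each stage writes its
#' table before the next begins; a manifest echoing the resolved
#' configuration is written alongside.  Probe-deficient CDS are reported,
#' never fatal.  With QC disabled every CDS is elected on in silico
#' standing alone (panel head closest to the 3' end), the treatment the
#' computational-screening-only (e.g. mitochondrial) probes receive.
#'
#' @param config a \code{\link{runConfig}} (or path to a YAML config).
#' @return invisibly, a list with \code{scores}, \code{panels},
#'   \code{qc}, \code{report} and \code{outputs} (paths of everything
#'   written).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!inherits(config, "RunConfig")) config <- do.call(runConfig, config)
  for (key in c("genome", "gff3", "probes", "out_dir"))
    if (is.null(config[[key]]))
      stop("config key '", key, "' is required")
  outDir <- config$out_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- config
  class(manifest) <- NULL
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

  genome <- .asGenome(config$genome)
  models <- readGeneModels(config$gff3, genome)
  if (!is.null(config$est))
    models <- readEstConfirmations(config$est, models)
  probes <- readProbeTable(config$probes)
  pd <- probeData(probes)
  missing <- setdiff(unique(pd$cds_id), names(models))
  if (length(missing))
    stop("probes reference CDS without gene models: ",
         paste(missing, collapse = ", "))

  hits <- if (!is.null(config$hits))
    readAlignmentHits(config$hits,
                      stats::setNames(pd$cds_id, pd$probe_id)) else NULL
  scores <- scoreProbes(probes, models, genome = genome, hits = hits,
                        adjacencyWindow = config$adjacency_window)
  .writeTsv(scores, file.path(outDir, "scorecards.tsv"))

  panels <- selectPanels(scores, maxPanel = config$max_panel,
                         scoreCut = config$score_cut,
                         minDistance = config$min_distance,
                         round2ScoreCut = config$round2_score_cut,
                         round2ChiCut = config$round2_chi_cut,
                         round2MaxDistance = config$round2_max_distance)
  panelTab <- data.frame(
    cds_id = panels$cds_id,
    round1 = vapply(panels$round1, paste, character(1), collapse = ","),
    round2 = vapply(panels$round2, paste, character(1), collapse = ","),
    deficient = panels$deficient, stringsAsFactors = FALSE)
  .writeTsv(panelTab, file.path(outDir, "panels.tsv"))

  if (!is.null(config$new_cds)) {
    res <- rescoreAfterReannotation(probes, config$new_cds, scores)
    scores <- res$scores
    .writeTsv(scores, file.path(outDir, "scorecards_reannotated.tsv"))
    .writeTsv(data.frame(cds_id = res$deficientCds),
              file.path(outDir, "reannotation_deficient.tsv"))
    scores <- scores[scores$match_score == 0L, , drop = FALSE]
  }

  panelIds <- unique(unlist(panels$panel))
  panelScores <- scores[scores$probe_id %in% panelIds, , drop = FALSE]

  qc <- NULL
  bypass <- character()
  if (!is.null(config$bypass_cds))
    bypass <- utils::read.delim(config$bypass_cds,
                                stringsAsFactors = FALSE)$cds_id
  if (isTRUE(config$run_qc) && !is.null(config$intensities)) {
    spots <- readIntensityTable(config$intensities)
    rescue <- if (!is.null(config$rescue_cv))
      utils::read.delim(config$rescue_cv, stringsAsFactors = FALSE)
      else NULL
    qc <- probeQc(spots, probes[pd$probe_id %in% panelScores$probe_id],
                  rescue = rescue, ssrCut = config$ssr_cut,
                  sbrCut = config$sbr_cut, cvCut = config$cv_cut,
                  ciFactor = config$ci_factor, ciMethod = config$ci_method)
    .writeTsv(qc, file.path(outDir, "qc_verdicts.tsv"))
  }

  overrides <- if (!is.null(config$overrides))
    utils::read.delim(config$overrides, stringsAsFactors = FALSE)
    else NULL
  report <- finalizeSelection(qc, panelScores,
                              allCds = sort(names(models)),
                              bypassCds = bypass, overrides = overrides)
  .writeTsv(elections(report), file.path(outDir, "elections.tsv"))
  .writeTsv(data.frame(cds_id = deficientCds(report)),
            file.path(outDir, "deficient_cds.tsv"))
  .writeTsv(reportSummary(report), file.path(outDir, "summary.tsv"))

  invisible(list(scores = scores, panels = panels, qc = qc,
                 report = report,
                 outputs = file.path(outDir,
                   c("manifest.yaml", "scorecards.tsv", "panels.tsv",
                     if (!is.null(config$new_cds))
                       c("scorecards_reannotated.tsv",
                         "reannotation_deficient.tsv"),
                     if (!is.null(qc)) "qc_verdicts.tsv",
                     "elections.tsv", "deficient_cds.tsv",
                     "summary.tsv"))))
}
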