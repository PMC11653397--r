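## Orchestration: run the whole pipeline (suspects -> screen -> quantify
## -> EF -> statistics) on real or simulated inputs, writing plain-text
## outputs plus a run manifest.

#' Write a run manifest
#'
#' Records command, seed, package version, configuration snapshot, input
#' checksums and a timestamp to `manifest.json` in the output directory,
#' before any results are written.
#'
#' @param out_dir Output directory.
#' @param command Command label.
#' @param seed Integer seed in force.
#' @param config Configuration list snapshot.
#' @param inputs Character vector of input file paths (checksummed).
#' @return Manifest list, invisibly.
#' @export
writeManifest <- function(out_dir, command, seed, config = list(),
                          inputs = character()) {
  checksums <- if (length(inputs))
    vapply(inputs, function(f) as.character(tools::md5sum(f)),
           character(1)) else NULL
  manifest <- list(command = command, seed = seed,
                   version = as.character(utils::packageVersion("pcbscreen")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, input_md5 = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Run the full pipeline on a simulated study
#'
#' Executes suspect enumeration, study simulation, the semitargeted
#' screen, GC quantification, EF computation and the statistics stage,
#' optionally writing all outputs (CSV/JSON + manifest) to a directory.
#' All randomness flows from `seed`; a rerun with the same seed and
#' config reproduces every output.
#'
#' @param config A [studyConfig()] list.
#' @param seed Integer seed.
#' @param out_dir Optional output directory (created if needed).
#' @return list: `suspects`, `study`, `screen` (detections/audit/report),
#'   `quant` (concentrations, limits, molar summary), `ef`, `stats`
#'   (ANOVA + similarity matrix).
#' @export
runAll <- function(config = studyConfig(), seed = 1L, out_dir = NULL) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeManifest(out_dir, "run-all", seed,
                  config = config[setdiff(names(config), "species")])
  }
  suspects <- enumerateSuspects()
  study <- generateStudy(config, seed)
  scr <- screenStudy(study$peaks, study$meta, suspects)

  gc <- generateGcTables(config, seed)
  rrf <- computeRRF(gc$standards)
  known <- gc$analyte_groups$analyte[gc$analyte_groups$has_standard]
  limits <- blankLimits(gc$blanks$method, gc$blanks$tissue)
  conc_known <- quantifyAreas(
    gc$areas[gc$areas$analyte %in% c(known, "PFOS_IS"), , drop = FALSE],
    rrf, gc$is_amount, gc$meta, gc$recoveries, gc$surrogate_map)
  unknown_tab <- gc$analyte_groups[!gc$analyte_groups$has_standard, ,
                                   drop = FALSE]
  conc_unknown <- do.call(rbind, lapply(seq_len(nrow(unknown_tab)),
                                        function(i) {
    estimateUnknown(
      gc$areas[gc$areas$analyte %in%
                 c(unknown_tab$analyte[i], "PFOS_IS"), , drop = FALSE],
      rrf, unknown_tab$group[i], gc$is_amount, gc$meta, gc$recoveries,
      gc$surrogate_map)
  }))
  conc <- rbind(conc_known, conc_unknown)

  masses <- vapply(conc$analyte, function(a) {
    f <- switch(gc$analyte_groups$group[match(a, gc$analyte_groups$analyte)],
                parent = "C12H5Cl5", monoOH = "C12H5Cl5O",
                diOH = "C12H5Cl5O2")
    monoisotopicMass(formula_parse(f))
  }, numeric(1))
  molar <- molarSummary(conc, stats::setNames(masses, conc$analyte))

  ef <- efSummary(gc$atropisomers)

  grp_of <- function(sid) {
    i <- match(sid, gc$meta$sample_id)
    paste(gc$meta$sex[i], gc$meta$genotype[i], sep = "_")
  }
  oh <- conc[conc$analyte != "PCB95", , drop = FALSE]
  sum_oh <- tapply(oh$concentration, oh$sample_id, sum)
  anova_df <- data.frame(sample_id = names(sum_oh),
                         sum_oh = as.numeric(sum_oh),
                         stringsAsFactors = FALSE)
  i <- match(anova_df$sample_id, gc$meta$sample_id)
  anova_df$sex <- gc$meta$sex[i]
  anova_df$genotype <- gc$meta$genotype[i]
  aov_res <- twoWayAnovaBonferroni(anova_df, "sum_oh")

  prof <- tapply(oh$concentration,
                 list(grp_of(oh$sample_id), oh$analyte), mean)
  sim <- similarityMatrix(prof)

  res <- list(suspects = suspects, study = study, screen = scr,
              quant = list(concentrations = conc, limits = limits,
                           molar = molar, rrf = rrf),
              ef = ef, stats = list(anova = aov_res, similarity = sim))
  if (!is.null(out_dir)) {
    writeSuspects(suspects, file.path(out_dir, "suspects.csv"))
    utils::write.csv(scr$detections, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(scr$audit, file.path(out_dir, "audit.csv"),
                     row.names = FALSE)
    utils::write.csv(scr$report, file.path(out_dir, "screen_report.csv"),
                     row.names = FALSE)
    utils::write.csv(conc, file.path(out_dir, "concentrations.csv"),
                     row.names = FALSE)
    utils::write.csv(limits, file.path(out_dir, "limits.csv"),
                     row.names = FALSE)
    utils::write.csv(ef$samples, file.path(out_dir, "ef.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sim),
                     file.path(out_dir, "similarity.csv"))
    jsonlite::write_json(
      list(anova = aov_res$anova, pairwise = aov_res$pairwise,
           retained_classes =
             sort(unique(scr$report$class_id[scr$report$retained &
                                               !is.na(scr$report$class_id)]))),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  res
}
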