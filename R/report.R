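# Unified evaluation report: contour metrics, CT-number differences, DVH
# statistics and gamma pass rates in one deterministic bundle of CSV tables
# plus a JSON manifest.

#' Run the full sCT evaluation report
#'
#' Orchestrates the evaluation stack over a reference/test pair: contour
#' agreement ([contourMetrics()]), per-structure CT-number differences
#' ([huDifference()]), DVH statistics on the target ([doseStats()]) and
#' gamma pass rates ([gammaSummary()]). Inputs may optionally be cropped to
#' a common FOV first. Output is deterministic: rerunning an identical
#' configuration reproduces byte-identical files.
#'
#' @param refCT,testCT [ImageVolume-class] reference and test (sCT) volumes.
#' @param refStructures,testStructures [StructureSet-class] contour sets.
#' @param refDose,testDose [DoseGrid-class] dose grids.
#' @param gtv name of the target structure for DVH statistics (must exist in
#'   `refStructures`).
#' @param criteria list of [GammaCriteria-class] (default the clinical
#'   3%/3mm, 2%/2mm, 1%/2mm triple).
#' @param fov optional [FOVSpec-class] applied to every input first.
#' @param outDir output directory (created if needed).
#' @param seed seed recorded in the manifest (the evaluation itself is
#'   deterministic).
#' @param quiet suppress per-stage messages.
#' @return Invisibly, `list(contours, hu, dose, gamma, manifest)`.
#' @export
runReport <- function(refCT, testCT, refStructures, testStructures,
                      refDose, testDose, gtv, criteria = clinicalGammaCriteria(),
                      fov = NULL, outDir, seed = 0L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("report stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(fov)) {
    say("cropping inputs to FOV")
    refCT <- cropToFOV(refCT, fov); testCT <- cropToFOV(testCT, fov)
    refStructures <- cropToFOV(refStructures, fov)
    testStructures <- cropToFOV(testStructures, fov)
    refDose <- cropToFOV(refDose, fov); testDose <- cropToFOV(testDose, fov)
  }
  if (!gtv %in% names(refStructures@masks))
    stop("target structure '", gtv, "' not found")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  say("contour metrics")
  contours <- stage("contours", contourMetrics(refStructures, testStructures))
  nFail <- sum(!contours$dsc_pass | !contours$mda_pass)
  if (nFail > 0)
    warning(nFail, " structure(s) outside DSC > 0.8 / MDA < 2 mm tolerances")
  say("CT-number differences")
  hu <- stage("hu", huDifference(refCT, testCT, refStructures))
  say("DVH statistics")
  dvh <- stage("dose", doseStats(refDose, testDose, refStructures[[gtv]]))
  say(sprintf("gamma analysis (%d criteria)", length(criteria)))
  gam <- stage("gamma", gammaSummary(refDose, testDose, criteria))

  utils::write.csv(contours, file.path(outDir, "contour_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(hu, file.path(outDir, "hu_differences.csv"),
                   row.names = FALSE)
  utils::write.csv(dvh, file.path(outDir, "dose_stats.csv"), row.names = FALSE)
  utils::write.csv(gam, file.path(outDir, "gamma_summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = seed, gtv = gtv,
    criteria = lapply(criteria, function(cr)
      list(dose_percent = cr@dosePercent, dta_mm = cr@dtaMm,
           threshold_percent = cr@lowDoseThresholdPercent)),
    grid = as.integer(gridDim(refCT)), spacing = spacing(refCT),
    package = "sctgan",
    version = as.character(utils::packageVersion("sctgan")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(contours = contours, hu = hu, dose = dvh, gamma = gam,
                 manifest = manifest))
}
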