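# End-to-end case orchestration: mask -> mesh, contours -> mesh, landmark
# registration into the specimen frame, measurement, report row.

#' Read a case configuration (YAML or JSON)
#'
#' Fields: `case_id`; paths `mri_mask`, `contour_stack`, `landmarks_mri`,
#' `landmarks_specimen`, optional `specimen_mesh`; `grid_spacing` (mm,
#' default 0.5); `registration` (`"rigid"` or `"similarity"`); optional
#' `n_slides`, `output_dir`. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return a named list.
#' @export
readCaseConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("specimen_mesh", "mri_mask", "contour_stack", "landmarks_mri",
              "landmarks_specimen")) {
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  cfg
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  log(sprintf("stage %-12s done in %.2f s", name,
              proc.time()[["elapsed"]] - t0))
  res
}

.defaultConfig <- function(config) {
  defaults <- list(grid_spacing = 0.5, registration = "rigid")
  for (n in names(defaults))
    if (is.null(config[[n]])) config[[n]] <- defaults[[n]]
  if (is.null(config$case_id)) config$case_id <- "case"
  config
}

#' Run one fusion case
#'
#' Executes the full workflow: load the MRI mask and iso-surface it,
#' reconstruct the histopathological tumor from the contour stack, fit the
#' landmark transform (MRI frame to specimen frame) and apply it to the MRI
#' body, then measure both bodies in the specimen frame and derive the
#' report row. Every stage is logged with its parameters; when
#' `config$output_dir` is set the co-registered STL set, the transform JSON
#' and the per-case log are written there.
#'
#' @param config named list (see [readCaseConfig()]) or a config file path.
#' @return list with elements `report` (one-case
#'   \linkS4class{FusionReport}), `transform`
#'   (\linkS4class{RigidTransform}), `fre_mm`, and the meshes `histoMesh`,
#'   `mriMesh` (registered), `specimenMesh` (or `NULL`).
#' @export
runCase <- function(config) {
  if (is.character(config)) config <- readCaseConfig(config)
  config <- .defaultConfig(config)
  lines <- character(0)
  log <- function(msg) {
    lines <<- c(lines, msg)
    message(sprintf("[%s] %s", config$case_id, msg))
  }
  log(sprintf("grid_spacing=%g mm, registration=%s", config$grid_spacing,
              config$registration))
  for (f in c("mri_mask", "contour_stack", "landmarks_mri",
              "landmarks_specimen")) {
    if (is.null(config[[f]]))
      stop(sprintf("[stage inputs] config is missing '%s'", f), call. = FALSE)
    if (is.character(config[[f]]) && !file.exists(config[[f]]))
      stop(sprintf("[stage inputs] missing file for '%s': %s", f,
                   config[[f]]), call. = FALSE)
    if (is.character(config[[f]]))
      log(sprintf("input %s: %s (md5 %s)", f, config[[f]],
                  unname(tools::md5sum(config[[f]]))))
  }

  asObj <- function(x, reader) if (is.character(x)) reader(x) else x
  mask <- .stage("load_mask", log,
                 asObj(config$mri_mask, loadLabelVolume))
  stack <- .stage("load_contours", log,
                  asObj(config$contour_stack, readContourStack))
  lmM <- .stage("load_landmarks", log,
                asObj(config$landmarks_mri, readLandmarks))
  lmS <- asObj(config$landmarks_specimen, readLandmarks)
  specimen <- if (!is.null(config$specimen_mesh))
    .stage("load_specimen", log, asObj(config$specimen_mesh, loadMesh))

  mriMesh <- .stage("meshify", log, maskToMesh(mask))
  histoMesh <- .stage("reconstruct", log,
                      interpolateSurface(stack,
                                         spacing = config$grid_spacing))
  transform <- .stage("register", log,
    fitLandmarkTransform(lmM, lmS,
                         allowScale = identical(config$registration,
                                                "similarity")))
  fre <- fiducialRegistrationError(lmM, lmS, transform)
  log(sprintf("fiducial registration error: %.4f mm", fre))
  mriMesh <- .stage("superimpose", log, applyTransform(mriMesh, transform))

  cases <- list(list(histo = histoMesh, mri = mriMesh,
                     nSlides = if (!is.null(config$n_slides))
                       config$n_slides else length(stack@slices)))
  names(cases) <- config$case_id
  report <- .stage("measure", log, buildReport(cases))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    saveMesh(mriMesh, out("tumor_mri_registered.stl"))
    saveMesh(histoMesh, out("tumor_histo.stl"))
    if (!is.null(specimen)) saveMesh(specimen, out("specimen.stl"))
    writeTransform(transform, out("transform.json"))
    writeReport(report, out("report.csv"))
    writeLines(lines, out(paste0(config$case_id, ".log")))
  }
  list(report = report, transform = transform, fre_mm = fre,
       histoMesh = histoMesh, mriMesh = mriMesh, specimenMesh = specimen)
}

#' Run a cohort of fusion cases
#'
#' Runs [runCase()] for each configuration; a failing case is reported (with
#' its stage-tagged error) and the remaining cases continue. Rows are
#' concatenated and summarized with [summarizeCohort()].
#'
#' @param configs list of case configurations (lists or file paths).
#' @return a \linkS4class{FusionReport}; failed cases are attached as the
#'   `failures` attribute (named character vector of error messages).
#' @export
runCohort <- function(configs) {
  if (length(configs) < 1) stop("need at least one case configuration")
  results <- list()
  failures <- character(0)
  for (i in seq_along(configs)) {
    res <- tryCatch(runCase(configs[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      id <- if (is.list(configs[[i]]) && !is.null(configs[[i]]$case_id))
        configs[[i]]$case_id else as.character(i)
      failures[id] <- conditionMessage(res)
      message(sprintf("case '%s' FAILED: %s", id, conditionMessage(res)))
    } else {
      results <- c(results, list(res))
    }
  }
  if (!length(results)) stop("all cases failed")
  rows <- do.call(rbind, lapply(results, function(r) reportRows(r$report)))
  rep <- new("FusionReport", rows = rows, summary = summarizeCohort(rows))
  attr(rep, "failures") <- failures
  rep
}

#' Write a phantom case to a directory of standard files
#'
#' Produces the on-disk form a real case would arrive in: `specimen.stl`,
#' `tumor_truth.stl`, `mri_mask.nii.gz`, `contours.json`,
#' `landmarks_mri.json`, `landmarks_specimen.json`, `truth.json`, plus a
#' ready-to-run `case.yaml` configuration.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantomCase <- function(case, dir) {
  stopifnot(is(case, "PhantomCase"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(dir, f)
  saveMesh(case@specimenMesh, out("specimen.stl"))
  saveMesh(case@tumorMesh, out("tumor_truth.stl"))
  saveLabelVolume(case@mriMask, out("mri_mask.nii.gz"))
  writeContourStack(case@contourStack, out("contours.json"))
  writeLandmarks(case@landmarksMRI, out("landmarks_mri.json"))
  writeLandmarks(case@landmarksSpecimen, out("landmarks_specimen.json"))
  tr <- case@truth
  jsonlite::write_json(
    list(seed = tr$seed, volume_cm3 = tr$volume_cm3,
         histo_volume_cm3 = tr$histo_volume_cm3,
         extents_cm = as.list(tr$extents_cm),
         diameter_cm = tr$diameter_cm, shrinkage = tr$shrinkage,
         transform = list(
           rotation = apply(tr$transform@rotation, 1, as.numeric,
                            simplify = FALSE),
           translation = as.numeric(tr$transform@translation),
           scale = tr$transform@scale)),
    out("truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(case_id = sprintf("phantom_%d", tr$seed),
                        specimen_mesh = "specimen.stl",
                        mri_mask = "mri_mask.nii.gz",
                        contour_stack = "contours.json",
                        landmarks_mri = "landmarks_mri.json",
                        landmarks_specimen = "landmarks_specimen.json",
                        grid_spacing = 0.5,
                        registration = "rigid"),
                   out("case.yaml"))
  invisible(dir)
}
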