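#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 5.161 -> 5.2 at one
#' decimal and 0.25 -> 0.3), as used for every reported volume, length and
#' percentage. This is deliberately not R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Histopathological-to-MRI volume ratio, percent
#'
#' `100 * histo / mri`, rounded half-up to one decimal. Values above 100
#' mean the histopathological model measured larger than the MRI model.
#'
#' @param histoVolume,mriVolume volumes in cm^3; `mriVolume` must be > 0.
#' @return percentage, one decimal.
#' @export
volumeRatioPercent <- function(histoVolume, mriVolume) {
  if (any(mriVolume <= 0)) stop("mriVolume must be positive")
  roundHalfUp(100 * histoVolume / mriVolume, 1)
}

#' MRI minus histopathological volume
#'
#' @param mriVolume,histoVolume volumes in cm^3.
#' @return difference in cm^3, rounded half-up to one decimal (may be
#'   negative).
#' @export
volumeDifference <- function(mriVolume, histoVolume) {
  roundHalfUp(mriVolume - histoVolume, 1)
}

#' Percent change of a directional dimension
#'
#' `100 * (mri - histo) / mri`, rounded half-up to one decimal.
#'
#' @param mriDim,histoDim lengths in cm; `mriDim` must be > 0.
#' @return percentage, one decimal.
#' @export
dimensionPercentChange <- function(mriDim, histoDim) {
  if (any(mriDim <= 0)) stop("mriDim must be positive")
  roundHalfUp(100 * (mriDim - histoDim) / mriDim, 1)
}

#' MRI minus histopathological dimension
#'
#' @param mriDim,histoDim lengths in cm.
#' @return difference in cm, rounded half-up to one decimal.
#' @export
dimensionDifference <- function(mriDim, histoDim) {
  roundHalfUp(mriDim - histoDim, 1)
}

.medianHalfUp <- function(x) roundHalfUp(stats::median(x), 1)
.meanHalfUp <- function(x) roundHalfUp(mean(x), 1)

#' Cohort summary (median and average) of the volume columns
#'
#' Median (middle order statistic, mean of the middle two for even n) and
#' arithmetic mean of the MRI volume, histopathological volume, volume
#' difference and ratio columns, each rounded half-up to one decimal. The
#' summary is computed from the column values as reported (i.e. at their
#' printed precision), and is permutation-invariant.
#'
#' @param rows data.frame with columns `mri_volume_cm3`, `histo_volume_cm3`,
#'   `volume_difference_cm3`, `volume_ratio_pct` (e.g. the rows of a
#'   \linkS4class{FusionReport}).
#' @return data.frame with rows `median` and `average`.
#' @export
summarizeCohort <- function(rows) {
  cols <- c("mri_volume_cm3", "histo_volume_cm3", "volume_difference_cm3",
            "volume_ratio_pct")
  miss <- setdiff(cols, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rows) < 1) stop("need at least one case row")
  out <- rbind(
    vapply(rows[cols], .medianHalfUp, 0),
    vapply(rows[cols], .meanHalfUp, 0))
  out <- as.data.frame(out)
  rownames(out) <- c("median", "average")
  out
}

#' Derive the comparison columns from tabulated measurements
#'
#' The table-ingestion path: given per-case measurements at their printed
#' precision (volumes in cm^3, optional per-axis dimensions in cm), derives
#' difference, ratio and percent-change columns and the cohort summary
#' without any mesh input.
#'
#' @param tab data.frame with columns `case_id`, `mri_volume_cm3`,
#'   `histo_volume_cm3` and optionally `mri_ap_cm`, `histo_ap_cm`,
#'   `mri_cc_cm`, `histo_cc_cm`, `mri_lr_cm`, `histo_lr_cm`, `n_slides`.
#' @return a \linkS4class{FusionReport}.
#' @export
reportFromTable <- function(tab) {
  need <- c("case_id", "mri_volume_cm3", "histo_volume_cm3")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rows <- data.frame(case_id = tab$case_id,
                     mri_volume_cm3 = tab$mri_volume_cm3,
                     histo_volume_cm3 = tab$histo_volume_cm3)
  rows$volume_difference_cm3 <- volumeDifference(rows$mri_volume_cm3,
                                                 rows$histo_volume_cm3)
  rows$volume_ratio_pct <- volumeRatioPercent(rows$histo_volume_cm3,
                                              rows$mri_volume_cm3)
  for (ax in c("ap", "cc", "lr")) {
    m <- tab[[paste0("mri_", ax, "_cm")]]
    h <- tab[[paste0("histo_", ax, "_cm")]]
    if (is.null(m) || is.null(h)) next
    rows[[paste0("mri_", ax, "_cm")]] <- m
    rows[[paste0("histo_", ax, "_cm")]] <- h
    rows[[paste0(ax, "_difference_cm")]] <- dimensionDifference(m, h)
    rows[[paste0(ax, "_pct_change")]] <- dimensionPercentChange(m, h)
  }
  if (!is.null(tab$n_slides)) rows$n_slides <- tab$n_slides
  new("FusionReport", rows = rows, summary = summarizeCohort(rows))
}

#' Build the fusion report from per-case meshes
#'
#' The mesh path: measures each case's registered MRI and histopathological
#' tumor bodies with the geometry primitives (volume, AP/CC/LR extents,
#' greatest MRI surface diameter), derives the comparison columns from the
#' full-precision measurements, rounds for reporting (volumes two decimals,
#' lengths and percentages one), and appends the cohort summary.
#'
#' Both bodies are measured in the specimen frame, i.e. after registration
#' of the MRI model.
#'
#' @param cases named list; each element is a list with elements `histo` and
#'   `mri` (\linkS4class{TriangleMesh}, both already in the specimen frame)
#'   and optionally `nSlides`.
#' @return a \linkS4class{FusionReport}.
#' @export
buildReport <- function(cases) {
  if (length(cases) < 1) stop("need at least one case")
  ids <- names(cases)
  if (is.null(ids)) ids <- as.character(seq_along(cases))
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    row <- tryCatch(.measureCase(cs$histo, cs$mri),
                    error = function(e)
                      stop("case '", ids[i], "': ", conditionMessage(e),
                           call. = FALSE))
    row$case_id <- ids[i]
    row$n_slides <- if (!is.null(cs$nSlides)) cs$nSlides else NA_integer_
    row
  })
  rows <- do.call(rbind, lapply(rows, as.data.frame))
  front <- c("case_id", "mri_volume_cm3", "histo_volume_cm3",
             "volume_difference_cm3", "volume_ratio_pct")
  rows <- rows[, c(front, setdiff(names(rows), front))]
  new("FusionReport", rows = rows, summary = summarizeCohort(rows))
}

.measureCase <- function(histo, mri) {
  stopifnot(is(histo, "TriangleMesh"), is(mri, "TriangleMesh"))
  vm <- meshVolume(mri)
  vh <- meshVolume(histo)
  out <- list(
    mri_volume_cm3 = roundHalfUp(vm, 2),
    histo_volume_cm3 = roundHalfUp(vh, 2),
    volume_difference_cm3 = volumeDifference(vm, vh),
    volume_ratio_pct = volumeRatioPercent(vh, vm))
  for (ax in c("ap", "cc", "lr")) {
    AX <- toupper(ax)
    m <- directionalExtent(mri, AX)
    h <- directionalExtent(histo, AX)
    out[[paste0("mri_", ax, "_cm")]] <- roundHalfUp(m, 1)
    out[[paste0("histo_", ax, "_cm")]] <- roundHalfUp(h, 1)
    out[[paste0(ax, "_difference_cm")]] <- dimensionDifference(m, h)
    out[[paste0(ax, "_pct_change")]] <- dimensionPercentChange(m, h)
  }
  out$mri_max_diameter_cm <- roundHalfUp(maxDiameter(mri), 1)
  out
}

setMethod("show", "FusionReport", function(object) {
  cat(sprintf("FusionReport: %d case(s)\n", nrow(object@rows)))
  print(object@rows, row.names = FALSE)
  cat("summary (volume columns):\n")
  print(object@summary)
})

#' @rdname FusionReport-class
#' @param report a \linkS4class{FusionReport}.
#' @export
reportRows <- function(report) {
  stopifnot(is(report, "FusionReport"))
  report@rows
}

#' @rdname FusionReport-class
#' @export
reportSummary <- function(report) {
  stopifnot(is(report, "FusionReport"))
  report@summary
}

#' Write a fusion report to CSV or JSON
#'
#' CSV output holds one row per case with the stable column names of the
#' report, followed by `median` / `average` summary rows for the volume
#' columns. JSON output carries `rows` and `summary` objects.
#'
#' @param report a \linkS4class{FusionReport}.
#' @param path output path.
#' @param fmt `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, fmt = c("auto", "csv", "json")) {
  stopifnot(is(report, "FusionReport"))
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (fmt == "json") {
    jsonlite::write_json(list(rows = report@rows,
                              summary = cbind(statistic =
                                                rownames(report@summary),
                                              report@summary)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- report@rows
    sm <- report@summary
    pad <- rows[0, , drop = FALSE]
    for (r in rownames(sm)) {
      line <- as.list(rep(NA, ncol(rows)))
      names(line) <- names(rows)
      line$case_id <- r
      for (cn in colnames(sm)) line[[cn]] <- sm[r, cn]
      pad <- rbind(pad, as.data.frame(line))
    }
    utils::write.csv(rbind(rows, pad), path, row.names = FALSE, na = "")
  }
  invisible(path)
}
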