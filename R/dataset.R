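#' Observation datasets
#'
#' An observation dataset holds per-tissue time series of percent of
#' administered dose, with both nominal (scan-start) and offset
#' (scan-midpoint) times.  Imaging acquisitions have a non-negligible
#' duration, so each measurement is assigned to the middle of its
#' acquisition window via [apply_scan_offset()].
#'
#' @param data data.frame with columns `tissue`, `time_min` (nominal scan
#'   start) and `pct_dose`.
#' @param dose Administered dose on the same scale as `pct_dose` (100 for
#'   percent).
#' @param decay_corrected Whether the values are decay-corrected amounts
#'   (the kinetic domain); the bundled data are.
#' @return An object of class `pbpk_dataset`: the data frame gains columns
#'   `nominal_min` and `time_min` (initially equal) plus metadata
#'   attributes.
#' @export
observation_dataset <- function(data, dose = 100, decay_corrected = TRUE) {
  need <- c("tissue", "time_min", "pct_dose")
  if (!all(need %in% names(data))) {
    stop("observations need columns: ", paste(need, collapse = ", "))
  }
  if (any(data$pct_dose < 0)) stop("negative observation values")
  if (any(data$time_min < 0)) stop("negative observation times")
  bad <- setdiff(unique(data$tissue),
                 c(observable_tissues(), "gallbladder"))
  if (length(bad)) stop("unknown tissue(s): ", paste(bad, collapse = ", "))
  df <- data.frame(tissue = data$tissue, nominal_min = data$time_min,
                   time_min = data$time_min, pct_dose = data$pct_dose,
                   stringsAsFactors = FALSE)
  df <- df[order(df$tissue, df$nominal_min), ]
  if (any(duplicated(df[, c("tissue", "nominal_min")]))) {
    stop("duplicated time point within a tissue")
  }
  structure(df, dose = dose, decay_corrected = decay_corrected,
            lag_min = 0, class = c("pbpk_dataset", "data.frame"))
}

#' Apply the scan-midpoint time offset
#'
#' Shifts every observation time by half the typical acquisition duration
#' (default 10 min), so that each measurement is attributed to the middle
#' of its scan window.  The offset can only be applied once; a second
#' application is an error.
#'
#' @param dataset A `pbpk_dataset`.
#' @param lag_min Scan-midpoint lag in minutes (>= 0).
#' @return The dataset with `time_min = nominal_min + lag_min`.
#' @export
apply_scan_offset <- function(dataset, lag_min = 10) {
  stopifnot(inherits(dataset, "pbpk_dataset"), lag_min >= 0)
  if (attr(dataset, "lag_min") != 0) {
    stop("scan offset already applied (lag ", attr(dataset, "lag_min"),
         " min); single application enforced")
  }
  dataset$time_min <- dataset$nominal_min + lag_min
  attr(dataset, "lag_min") <- lag_min
  dataset
}

#' @export
print.pbpk_dataset <- function(x, ...) {
  cat(sprintf("<pbpk_dataset> %d observations, %d tissues, lag %g min\n",
              nrow(x), length(unique(x$tissue)), attr(x, "lag_min")))
  NextMethod()
}

#' Read observations from CSV
#'
#' Long format `tissue, time_min, pct_dose`, as written by
#' [write_dataset()].
#'
#' @param file CSV path.
#' @inheritParams observation_dataset
#' @return A `pbpk_dataset`.
#' @export
read_observations <- function(file, dose = 100, decay_corrected = TRUE) {
  observation_dataset(utils::read.csv(file, stringsAsFactors = FALSE),
                      dose = dose, decay_corrected = decay_corrected)
}

#' Write a dataset to CSV (nominal times)
#' @param dataset A `pbpk_dataset`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_dataset <- function(dataset, file) {
  utils::write.csv(data.frame(tissue = dataset$tissue,
                              time_min = dataset$nominal_min,
                              pct_dose = dataset$pct_dose),
                   file, row.names = FALSE)
  invisible(file)
}
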