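#' Study dataset container
#'
#' Bundles the four tables of a study — patient covariates, time-stamped
#' labs, dose events, and plasma concentration observations — after
#' validation and unit normalization (internal units mg, mL, min).
#'
#' @param covariates Tibble: `patient_id`, `sex` ("male"/"female"), `age`
#'   (y), `weight` (kg), `height` (cm), `race` (White/Asian/Black/Other).
#' @param labs Tibble: `patient_id`, `time` (min), `hct` (fraction),
#'   `scr` (mg/dL).
#' @param doses Tibble: `patient_id`, `start`, `duration` (min),
#'   `amount` (mg).
#' @param observations Tibble: `patient_id`, `time` (min), `conc`
#'   (mg/mL).
#' @return A list of the four tibbles, class `mtx_dataset`.
#' @export
mtx_dataset <- function(covariates, labs, doses, observations) {
  covariates <- tibble::as_tibble(covariates)
  labs <- tibble::as_tibble(labs)
  doses <- tibble::as_tibble(doses)
  observations <- tibble::as_tibble(observations)

  problems <- character()
  need_cols <- function(tb, cols, what) {
    miss <- setdiff(cols, names(tb))
    if (length(miss)) {
      problems <<- c(problems, paste0(what, " missing columns: ",
                                      paste(miss, collapse = ", ")))
    }
  }
  need_cols(covariates, c("patient_id", "sex", "age", "weight", "height",
                          "race"), "covariates")
  need_cols(labs, c("patient_id", "time", "hct", "scr"), "labs")
  need_cols(doses, c("patient_id", "start", "duration", "amount"), "doses")
  need_cols(observations, c("patient_id", "time", "conc"), "observations")
  if (length(problems)) stop(paste(problems, collapse = "\n"), call. = FALSE)

  ids <- covariates$patient_id
  if (anyDuplicated(ids)) {
    problems <- c(problems, "duplicated patient_id in covariates")
  }
  check_ref <- function(tb, what) {
    bad <- !tb$patient_id %in% ids
    if (any(bad)) {
      problems <<- c(problems, paste0(
        what, " rows with unknown patient_id: ",
        paste(utils::head(which(bad), 5), collapse = ", "),
        " (ids: ", paste(utils::head(unique(tb$patient_id[bad]), 5),
                         collapse = ", "), ")"))
    }
  }
  check_ref(labs, "labs"); check_ref(doses, "doses")
  check_ref(observations, "observations")
  if (any(labs$time < 0) || any(doses$start < 0) ||
      any(observations$time < 0)) {
    problems <- c(problems, "negative times present")
  }
  miss_labs <- setdiff(ids, labs$patient_id)
  if (length(miss_labs)) {
    problems <- c(problems, paste0("patients without any lab panel: ",
                                   paste(utils::head(miss_labs, 5),
                                         collapse = ", ")))
  }
  if (length(problems)) stop(paste(problems, collapse = "\n"), call. = FALSE)

  out <- list(covariates = covariates, labs = labs, doses = doses,
              observations = observations)
  class(out) <- "mtx_dataset"
  out
}

#' @export
print.mtx_dataset <- function(x, ...) {
  cat("<mtx_dataset> ", nrow(x$covariates), " patients, ",
      nrow(x$doses), " infusions, ", nrow(x$observations),
      " observations\n", sep = "")
  invisible(x)
}

obs_unit_map <- c(umol_per_L = "umol/L", ug_per_ml = "ug/mL",
                  mg_per_ml = "mg/mL")

#' Read a study dataset from a directory of CSV files
#'
#' Expects `covariates.csv` (patient_id, sex, age_y, weight_kg, height_cm,
#' race), `labs.csv` (patient_id, time_min, hct, scr_mgdl), `doses.csv`
#' (patient_id, start_min, duration_min, amount_mg) and
#' `observations.csv` (patient_id, time_min, conc, conc_unit with
#' conc_unit one of umol_per_L, ug_per_ml, mg_per_ml).  Concentrations
#' are converted to the internal mg/mL; all validation failures are
#' collected and reported together.
#'
#' @param path Directory containing the four CSV files.
#' @param config Model configuration (molar mass for unit conversion).
#' @return An [mtx_dataset()].
#' @export
read_dataset <- function(path, config = load_config()) {
  f <- function(name) {
    fp <- file.path(path, name)
    if (!file.exists(fp)) stop("missing file: ", fp, call. = FALSE)
    readr::read_csv(fp, show_col_types = FALSE, progress = FALSE)
  }
  cov <- f("covariates.csv")
  labs <- f("labs.csv")
  doses <- f("doses.csv")
  obs <- f("observations.csv")

  cov <- dplyr::rename(cov, age = "age_y", weight = "weight_kg",
                       height = "height_cm")
  labs <- dplyr::rename(labs, time = "time_min", scr = "scr_mgdl")
  doses <- dplyr::rename(doses, start = "start_min",
                         duration = "duration_min", amount = "amount_mg")
  if (!"conc_unit" %in% names(obs)) {
    stop("observations.csv needs a conc_unit column", call. = FALSE)
  }
  bad_unit <- !obs$conc_unit %in% names(obs_unit_map)
  if (any(bad_unit)) {
    stop("unknown conc_unit in observations.csv rows ",
         paste(utils::head(which(bad_unit), 5), collapse = ", "), ": ",
         paste(unique(obs$conc_unit[bad_unit]), collapse = ", "),
         call. = FALSE)
  }
  conc <- vapply(seq_len(nrow(obs)), function(i) {
    convert_concentration(obs$conc[i], obs_unit_map[[obs$conc_unit[i]]],
                          "mg/mL", config)
  }, numeric(1))
  obs <- tibble::tibble(patient_id = obs$patient_id,
                        time = obs$time_min, conc = conc)
  mtx_dataset(cov, labs, doses, obs)
}

#' Write a study dataset to a directory of CSV files
#'
#' Inverse of [read_dataset()]; observation concentrations are written in
#' mg/mL with an explicit `conc_unit` column, so a write/read round trip
#' is lossless.
#'
#' @param dataset An [mtx_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- function(tb, name) {
    readr::write_csv(tb, file.path(path, name), progress = FALSE)
  }
  w(dplyr::rename(dataset$covariates, age_y = "age", weight_kg = "weight",
                  height_cm = "height"), "covariates.csv")
  w(dplyr::rename(dataset$labs, time_min = "time", scr_mgdl = "scr"),
    "labs.csv")
  w(dplyr::rename(dataset$doses, start_min = "start",
                  duration_min = "duration", amount_mg = "amount"),
    "doses.csv")
  w(dplyr::mutate(dplyr::rename(dataset$observations, time_min = "time"),
                  conc_unit = "mg_per_ml"), "observations.csv")
  invisible(path)
}
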