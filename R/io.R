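#' Pipeline configuration
#'
#' Thresholds and seeds shared across the pipeline stages. The cleaning
#' threshold (4.5 minutes) drops respondents with unrealistically short
#' completion times; the first-quartile threshold (7 minutes) defines the
#' "slower" scale group in the model.
#'
#' @param clean_threshold_minutes speeder exclusion cut (minutes).
#' @param q1_threshold_minutes completion-time first-quartile threshold.
#' @param seed master seed.
#' @param optimizer list passed to [fit_smnl()]'s `control`.
#' @return list of class `bws_pipeline_config`.
#' @export
pipeline_config <- function(clean_threshold_minutes = 4.5,
                            q1_threshold_minutes = 7,
                            seed = 1L, optimizer = list()) {
  if (clean_threshold_minutes <= 0 || q1_threshold_minutes <= 0) {
    stop("thresholds must be positive")
  }
  if (clean_threshold_minutes >= q1_threshold_minutes) {
    stop("cleaning threshold must be below the first-quartile threshold")
  }
  structure(list(clean_threshold_minutes = clean_threshold_minutes,
                 q1_threshold_minutes = q1_threshold_minutes,
                 seed = as.integer(seed), optimizer = optimizer),
            class = "bws_pipeline_config")
}

#' Drop speeders from a dataset
#'
#' Respondent-level (all-or-nothing) exclusion of everyone whose completion
#' time is below the threshold; all 32 observations of an excluded
#' respondent are removed together. Mirrors the study practice of dropping
#' completions under 4.5 minutes.
#'
#' @param dataset a `bws_dataset`.
#' @param threshold_minutes exclusion cut; respondents strictly below it are
#'   dropped (0 drops nobody).
#' @return list with `dataset` (cleaned `bws_dataset`) and `report` (list
#'   with `excluded_ids`, `n_excluded`, `n_before`, `n_after`, `threshold`).
#' @export
clean_dataset <- function(dataset, threshold_minutes = 4.5) {
  stopifnot(inherits(dataset, "bws_dataset"))
  prof <- dataset$profiles
  drop <- prof$respondent_id[prof$completion_minutes < threshold_minutes]
  keep_obs <- !(dataset$observations$respondent_id %in% drop)
  cleaned <- new_dataset(dataset$observations[keep_obs, , drop = FALSE],
                         prof[!(prof$respondent_id %in% drop), , drop = FALSE],
                         dataset$plan, dataset$instrument)
  rownames(cleaned$observations) <- NULL
  list(dataset = cleaned,
       report = list(excluded_ids = drop, n_excluded = length(drop),
                     n_before = nrow(prof),
                     n_after = nrow(prof) - length(drop),
                     threshold = threshold_minutes))
}

#' Read / write a choice dataset (CSV pair)
#'
#' Long-format observations and respondent profiles as two UTF-8 CSV files
#' (comma separator, dot decimal, header row). Write-read round-trips are
#' lossless. Observation columns: `respondent_id`, `block`, `task_id`,
#' `stage`, `domain`, `level`, `display_position`, `available_flag`,
#' `chosen_flag`; profile columns: `respondent_id`, `age_35_plus`,
#' `understood`, `completion_minutes`, `block`, `display_order`.
#'
#' @param dataset a `bws_dataset`.
#' @param obs_path observations CSV path.
#' @param profiles_path profiles CSV path.
#' @param design_path optional design CSV path (written with
#'   [write_design()]).
#' @return `write_choice_data()` returns `obs_path` invisibly;
#'   `read_choice_data()` returns a `bws_dataset`.
#' @export
write_choice_data <- function(dataset, obs_path, profiles_path,
                              design_path = NULL) {
  stopifnot(inherits(dataset, "bws_dataset"))
  utils::write.csv(dataset$observations, obs_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$profiles, profiles_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(design_path)) write_design(dataset$plan, design_path)
  invisible(obs_path)
}

#' @rdname write_choice_data
#' @param instrument a `bws_instrument` the files refer to.
#' @export
read_choice_data <- function(obs_path, profiles_path, design_path = NULL,
                             instrument = ascot_carer_instrument()) {
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "block", "task_id", "stage", "domain", "level",
            "display_position", "available_flag", "chosen_flag")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("observations file lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(obs$stage %in% stage_names()))
  if (length(bad)) {
    stop("invalid stage value '", obs$stage[bad[1]], "' at data line ",
         bad[1] + 1L, " of ", obs_path)
  }
  bad <- which(!(obs$level %in% 1:4))
  if (length(bad)) {
    stop("level out of range at data line ", bad[1] + 1L, " of ", obs_path)
  }
  prof <- utils::read.csv(profiles_path, stringsAsFactors = FALSE)
  needp <- c("respondent_id", "age_35_plus", "understood",
             "completion_minutes", "block")
  missp <- setdiff(needp, names(prof))
  if (length(missp)) {
    stop("profiles file lacks column(s): ", paste(missp, collapse = ", "))
  }
  plan <- if (!is.null(design_path)) read_design(design_path)
  new_dataset(obs, prof, plan, instrument)
}
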