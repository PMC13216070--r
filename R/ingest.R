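#' Ingest the four survey tables and validate them against the data model
#'
#' The survey data model has four levels: studies (study type, period),
#' locations (coordinates, settlement type, the four continuous covariates),
#' households (monitored days, observed frequency, education, AME) and recall
#' events (duration, consumption flag, quantity). This function validates the
#' level invariants, translates the legacy `-1` missing code (and empty cells)
#' to `NA`, rejects records violating hard invariants (logged in the report)
#' and returns a validated `wm_survey` object.
#'
#' Hard rules enforced here:
#' * study type in 1..3, period in 1..2;
#' * `hdi` in \[0,1\], `hpd >= 0`, three settlement levels;
#' * `mdays` in \[1, 365\]; an observed frequency requires `mdays >= 2`;
#' * `consumed` in 0/1; a positive quantity on a non-consumption recall is
#'   invalid; duplicated recall ids are rejected (all copies) and logged;
#' * recalls must reference an existing household, households a location,
#'   locations nothing (studies are referenced from households).
#'
#' @param studies,locations,households,recalls data.frames; see the package
#'   vignette for the column dictionary.
#' @return object of class `wm_survey`: list of the four cleaned tables plus
#'   `report` (counts, exclusions, flags) suitable for `jsonlite::toJSON`.
#' @export
ingest_survey <- function(studies, locations, households, recalls) {
  # "" is always missing; the legacy numeric code -1 only on the columns
  # where it is a documented missing marker (never on coordinates or
  # covariates, where -1 is a legal value)
  na_str <- function(x) {
    if (is.character(x)) x[x == ""] <- NA
    x
  }
  na_m1 <- function(x) {
    if (is.character(x)) x[x == "-1"] <- NA
    if (is.numeric(x)) x[!is.na(x) & x == -1] <- NA
    x
  }
  studies[]    <- lapply(studies, na_str)
  locations[]  <- lapply(locations, na_str)
  households[] <- lapply(households, na_str)
  recalls[]    <- lapply(recalls, na_str)
  for (col in c("frequency", "ame", "education"))
    if (col %in% names(households))
      households[[col]] <- na_m1(households[[col]])
  for (col in c("quantity_kg", "ame"))
    if (col %in% names(recalls)) recalls[[col]] <- na_m1(recalls[[col]])

  report <- list(
    counts = list(studies = nrow(studies), locations = nrow(locations),
                  households = nrow(households), recalls = nrow(recalls)),
    exclusions = list(), flags = list()
  )
  drop_log <- function(tab, bad, why) {
    if (any(bad)) report$exclusions[[why]] <<- sum(bad)
    tab[!bad, , drop = FALSE]
  }

  stopifnot(all(c("study_id", "study_type", "period") %in% names(studies)))
  if (!all(studies$study_type %in% 1:3)) stop("study_type must be in 1..3")
  if (!all(studies$period %in% 1:2)) stop("period must be in 1..2")

  stopifnot(all(c("location_id", "lon", "lat", "location_type",
                  "hpd", "rem", "hdi", "fci") %in% names(locations)))
  locations$location_type <- factor(locations$location_type,
                                    levels = c("village", "town", "city"))
  if (anyNA(locations$location_type)) stop("location_type has unknown levels")
  ok <- is.na(locations$hdi) | (locations$hdi >= 0 & locations$hdi <= 1)
  if (!all(ok)) stop("hdi must lie in [0, 1]")
  if (any(locations$hpd < 0, na.rm = TRUE)) stop("hpd must be >= 0")

  stopifnot(all(c("household_id", "location_id", "mdays", "frequency",
                  "education", "ame") %in% names(households)))
  households <- drop_log(households,
                         !households$location_id %in% locations$location_id,
                         "household_unknown_location")
  bad <- households$mdays < 1 | households$mdays > 365
  households <- drop_log(households, bad, "household_mdays_out_of_range")
  bad <- !is.na(households$frequency) &
    (households$frequency < 0 | households$frequency > 1)
  households <- drop_log(households, bad, "household_frequency_out_of_range")
  bad <- !is.na(households$frequency) & households$mdays < 2
  households <- drop_log(households, bad, "household_frequency_needs_mdays2")
  households$education <- factor(
    households$education,
    levels = c("primary-or-none", "secondary-or-higher", "unknown"))
  households$education[is.na(households$education)] <- "unknown"
  if (any(households$ame <= 0, na.rm = TRUE)) stop("ame must be > 0")

  stopifnot(all(c("recall_id", "household_id", "days", "consumed",
                  "quantity_kg", "ame") %in% names(recalls)))
  dup <- recalls$recall_id %in% recalls$recall_id[duplicated(recalls$recall_id)]
  recalls <- drop_log(recalls, dup, "recall_duplicate_id")
  recalls <- drop_log(recalls,
                      !recalls$household_id %in% households$household_id,
                      "recall_unknown_household")
  recalls <- drop_log(recalls, recalls$days < 1, "recall_days_lt_1")
  recalls <- drop_log(recalls, !recalls$consumed %in% c(0, 1),
                      "recall_consumed_not_binary")
  bad <- !is.na(recalls$quantity_kg) & recalls$consumed == 0 &
    recalls$quantity_kg > 0
  recalls <- drop_log(recalls, bad, "recall_quantity_without_consumption")
  if (any(recalls$quantity_kg < 0, na.rm = TRUE))
    stop("quantity_kg must be >= 0")

  report$counts_clean <- list(households = nrow(households),
                              recalls = nrow(recalls))
  report$flags$missing_ame_households <- sum(is.na(households$ame))
  report$flags$missing_frequency_households <- sum(is.na(households$frequency))
  report$flags$missing_quantity_recalls <-
    sum(recalls$consumed == 1 & is.na(recalls$quantity_kg))

  structure(list(studies = studies, locations = locations,
                 households = households, recalls = recalls,
                 report = report),
            class = "wm_survey")
}

#' Read the four survey CSV tables from a directory
#'
#' Expects `studies.csv`, `locations.csv`, `households.csv`, `recalls.csv`
#' (UTF-8; missing values as empty cells or `-1`) and runs [ingest_survey()].
#'
#' @param dir directory holding the four CSV files.
#' @return a `wm_survey` object.
#' @export
read_survey <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  ingest_survey(rd("studies.csv"), rd("locations.csv"),
                rd("households.csv"), rd("recalls.csv"))
}

#' Write a validated survey and its ingestion report to a directory
#'
#' Emits the four cleaned CSV tables plus `ingestion_report.json`.
#'
#' @param survey a `wm_survey` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "wm_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("studies", "locations", "households", "recalls"))
    utils::write.csv(survey[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(survey$report,
                       file.path(dir, "ingestion_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.wm_survey <- function(x, ...) {
  cat("<wm_survey>", x$report$counts$studies, "studies,",
      x$report$counts$locations, "locations,",
      nrow(x$households), "households,", nrow(x$recalls), "recalls\n")
  ex <- x$report$exclusions
  if (length(ex))
    cat("exclusions:", paste(names(ex), unlist(ex), sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}
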