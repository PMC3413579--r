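## Delimited-file readers/writers for the two person-level tables.
##
## deaths.csv : death_id, age_years, sex, remoteness, cause_icd10,
##              reported_indigenous
## linked.csv : record_id, death_id, source, indigenous_flag,
##              mother_indigenous_flag, father_indigenous_flag,
##              admit_date, discharge_date, facility, transferred_from,
##              transferred_to
##
## Status flags are written as "1"/"0"/"" and held in memory as
## "yes"/"no"/"missing". Dates are ISO-8601.

DEATH_COLS <- c("death_id", "age_years", "sex", "remoteness",
                "cause_icd10", "reported_indigenous")
LINKED_COLS <- c("record_id", "death_id", "source", "indigenous_flag",
                 "mother_indigenous_flag", "father_indigenous_flag",
                 "admit_date", "discharge_date", "facility",
                 "transferred_from", "transferred_to")

stop_rows <- function(msgs) {
  if (length(msgs))
    stop(paste0("invalid input:\n", paste0("  ", msgs, collapse = "\n")),
         call. = FALSE)
}

read_delim_table <- function(path, sep, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, colClasses = "character",
                        check.names = FALSE, na.strings = NULL,
                        strip.white = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Construct a validated table of death records
#'
#' One row per registered death. Used both by [read_deaths()] and by code
#' building cohorts programmatically.
#'
#' @param death_id opaque unique key.
#' @param age_years completed years at death, integer in \[0, 130\].
#' @param sex `"male"` or `"female"`.
#' @param remoteness one of the five ARIA+ categories or `"Unknown"`.
#' @param cause_icd10 underlying-cause ICD-10 code (letter + 2 digits,
#'   optional decimal).
#' @param reported_indigenous tri-state status as reported on the death
#'   registration (`"yes"`, `"no"`, `"missing"`; file codes accepted).
#' @return a `data.frame` of class `death_records`.
#' @export
death_records <- function(death_id, age_years, sex, remoteness,
                          cause_icd10, reported_indigenous) {
  df <- data.frame(
    death_id = as.character(death_id),
    age_years = suppressWarnings(as.integer(age_years)),
    sex = as.character(sex),
    remoteness = as.character(remoteness),
    cause_icd10 = toupper(as.character(cause_icd10)),
    reported_indigenous = as_tristate(reported_indigenous),
    stringsAsFactors = FALSE
  )
  msgs <- character()
  bad <- function(i, what) sprintf("row %d: %s", i, what)
  idx <- which(is.na(df$age_years) | df$age_years < 0 | df$age_years > 130)
  msgs <- c(msgs, vapply(idx, bad, "", what = "age_years outside [0, 130]"))
  idx <- which(!df$sex %in% SEXES)
  msgs <- c(msgs, vapply(idx, bad, "", what = "sex must be male/female"))
  idx <- which(!df$remoteness %in% REMOTENESS)
  msgs <- c(msgs, vapply(idx, bad, "", what = "unknown remoteness category"))
  idx <- which(!grepl(ICD10_RE, df$cause_icd10))
  msgs <- c(msgs, vapply(idx, bad, "", what = "malformed ICD-10 cause code"))
  idx <- which(is.na(df$reported_indigenous))
  msgs <- c(msgs, vapply(idx, bad, "", what = "unreadable status flag"))
  stop_rows(msgs)
  if (anyDuplicated(df$death_id))
    stop("duplicate death_id: ",
         paste(unique(df$death_id[duplicated(df$death_id)]), collapse = ", "),
         call. = FALSE)
  class(df) <- c("death_records", "data.frame")
  df
}

#' Read a death-registration table from a delimited file
#'
#' @param path file path; must have a header row naming the required
#'   columns (`death_id, age_years, sex, remoteness, cause_icd10,
#'   reported_indigenous`).
#' @param sep field delimiter; comma by default, tab accepted.
#' @return a validated `death_records` data frame, one row per input row.
#' @export
read_deaths <- function(path, sep = ",") {
  df <- read_delim_table(path, sep, DEATH_COLS)
  if (nrow(df) == 0L)
    return(death_records(character(), integer(), character(), character(),
                         character(), character()))
  do.call(death_records, as.list(df[DEATH_COLS]))
}

#' @rdname read_deaths
#' @param deaths a `death_records` data frame to write.
#' @export
write_deaths <- function(deaths, path, sep = ",") {
  out <- as.data.frame(deaths)[DEATH_COLS]
  out$reported_indigenous <- tristate_to_file(out$reported_indigenous)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Construct a validated table of linked administrative records
#'
#' One row per linked record. Hospital (`APD`) rows carry episode dates and
#' optional transfer/facility codes; all other sources must leave those
#' fields empty. Infant birth rows (`PDC_infant`, `RBDM_infant`) carry the
#' mother's (and for RBDM the father's) status flag used by the inheritance
#' rule.
#'
#' @param record_id opaque unique key.
#' @param death_id key of the death the record was linked to (may reference
#'   deaths absent from the deaths table: unlinked residue).
#' @param source one of `APD, EDDC, PDC_mother, PDC_infant, RBDM_mother,
#'   RBDM_infant`.
#' @param indigenous_flag,mother_indigenous_flag,father_indigenous_flag
#'   tri-state status flags.
#' @param admit_date,discharge_date ISO-8601 episode dates (APD only).
#' @param facility,transferred_from,transferred_to facility codes
#'   (APD only), empty string when absent.
#' @return a `data.frame` of class `linked_records`.
#' @export
linked_records <- function(record_id, death_id, source,
                           indigenous_flag,
                           mother_indigenous_flag = "",
                           father_indigenous_flag = "",
                           admit_date = "", discharge_date = "",
                           facility = "", transferred_from = "",
                           transferred_to = "") {
  n <- length(record_id)
  rep_n <- function(x) {
    x <- as.character(x)
    if (length(x) == 1L && n != 1L) rep(x, n) else x
  }
  df <- data.frame(
    record_id = as.character(record_id),
    death_id = rep_n(death_id),
    source = rep_n(source),
    indigenous_flag = as_tristate(rep_n(indigenous_flag)),
    mother_indigenous_flag = as_tristate(rep_n(mother_indigenous_flag)),
    father_indigenous_flag = as_tristate(rep_n(father_indigenous_flag)),
    admit_date = rep_n(admit_date),
    discharge_date = rep_n(discharge_date),
    facility = rep_n(facility),
    transferred_from = rep_n(transferred_from),
    transferred_to = rep_n(transferred_to),
    stringsAsFactors = FALSE
  )
  for (col in c("facility", "transferred_from", "transferred_to"))
    df[[col]][is.na(df[[col]])] <- ""

  msgs <- character()
  bad <- function(i, what) sprintf("row %d: %s", i, what)
  idx <- which(!df$source %in% LINK_SOURCES)
  msgs <- c(msgs, vapply(idx, function(i)
    bad(i, paste0("unknown source code '", df$source[i], "'")), ""))
  ok_src <- df$source %in% LINK_SOURCES

  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  adm <- parse_date(df$admit_date)
  dis <- parse_date(df$discharge_date)
  is_apd <- ok_src & df$source == "APD"
  idx <- which(is_apd & (is.na(adm) | is.na(dis)))
  msgs <- c(msgs, vapply(idx, bad, "",
                         what = "APD row requires valid admit and discharge dates"))
  idx <- which(is_apd & !is.na(adm) & !is.na(dis) & adm > dis)
  msgs <- c(msgs, vapply(idx, bad, "", what = "admit_date after discharge_date"))
  non_apd <- ok_src & df$source != "APD"
  has_episode_fields <- trimws(df$admit_date) != "" |
    trimws(df$discharge_date) != "" | df$facility != "" |
    df$transferred_from != "" | df$transferred_to != ""
  idx <- which(non_apd & has_episode_fields)
  msgs <- c(msgs, vapply(idx, bad, "",
                         what = "episode/transfer fields permitted on APD rows only"))
  idx <- which(is.na(df$indigenous_flag))
  msgs <- c(msgs, vapply(idx, bad, "", what = "unreadable status flag"))
  stop_rows(msgs)
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id", call. = FALSE)

  df$admit_date <- adm
  df$discharge_date <- dis
  class(df) <- c("linked_records", "data.frame")
  df
}

#' Read a linked-records table from a delimited file
#'
#' @inheritParams read_deaths
#' @return a validated `linked_records` data frame.
#' @export
read_linked_records <- function(path, sep = ",") {
  df <- read_delim_table(path, sep, LINKED_COLS)
  if (nrow(df) == 0L) {
    out <- linked_records(character(), character(), character(), character())
    return(out)
  }
  do.call(linked_records, as.list(df[LINKED_COLS]))
}

#' @rdname read_linked_records
#' @param records a `linked_records` data frame to write.
#' @export
write_linked_records <- function(records, path, sep = ",") {
  out <- as.data.frame(records)[LINKED_COLS]
  for (col in c("indigenous_flag", "mother_indigenous_flag",
                "father_indigenous_flag"))
    out[[col]] <- tristate_to_file(out[[col]])
  for (col in c("admit_date", "discharge_date")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", format(v, "%Y-%m-%d"))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
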