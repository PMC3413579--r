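## Deriving "units of information" from raw linked records.
##
## A unit is one independent evidence item about a person's status: one
## birth registration, one perinatal record, one ED attendance, or one
## hospital *stay*. A stay may span several admitted-patient episodes
## connected by same-day discharge/admission or explicit transfer pointers;
## those episodes carry only one independent report between them, so they
## collapse to a single unit.

# collapse tri-state flags for one stay: any yes wins; otherwise no if any
# non-missing flag; otherwise missing
collapse_status <- function(flags) {
  if (any(flags == "yes")) "yes"
  else if (any(flags != "missing")) "no"
  else "missing"
}

#' Collapse admitted-patient episodes into hospital stays
#'
#' Episodes for one person are sorted by admission date and merged into a
#' stay when the next episode starts on (or before) the running discharge
#' date plus `gap_days`, or when an explicit transfer pointer connects the
#' two episodes (`transferred_to` of the earlier names the facility of the
#' later, or `transferred_from` of the later names the earlier facility).
#' A stay reports status `yes` if any constituent episode flags yes, `no`
#' if all non-missing flags are no, and `missing` if every flag is missing.
#'
#' @param episodes a `linked_records` data frame (or plain data frame with
#'   the same columns) of APD rows belonging to one person.
#' @param gap_days non-negative integer: maximum admit-to-previous-discharge
#'   gap still merged as one stay (default 0 = same-day only).
#' @return data frame of stays: `death_id`, `source = "APD_stay"`,
#'   `reports_indigenous`, `n_source_records`, `admit_date`,
#'   `discharge_date`.
#' @export
collapse_apd_stays <- function(episodes, gap_days = 0) {
  cols <- c("death_id", "source", "reports_indigenous", "n_source_records",
            "admit_date", "discharge_date")
  if (is.null(episodes) || nrow(episodes) == 0L) {
    out <- data.frame(death_id = character(), source = character(),
                      reports_indigenous = character(),
                      n_source_records = integer(),
                      admit_date = as.Date(character()),
                      discharge_date = as.Date(character()))
    return(out[cols])
  }
  if (length(unique(episodes$death_id)) != 1L)
    stop("collapse_apd_stays expects episodes for a single person",
         call. = FALSE)
  if (any(episodes$source != "APD"))
    stop("collapse_apd_stays expects APD rows only", call. = FALSE)
  st <- collapse_apd_stays_all(episodes, gap_days = gap_days)
  as.data.frame(st)[cols]
}

# vectorised stay collapsing across many persons (data.table backend)
collapse_apd_stays_all <- function(episodes, gap_days = 0) {
  stopifnot(gap_days >= 0)
  ep <- data.table::as.data.table(as.data.frame(episodes))
  data.table::setorder(ep, death_id, admit_date, discharge_date, record_id)
  ep[, prev_disc_cmax :=
       data.table::shift(cummax(as.integer(discharge_date))),
     by = death_id]
  ep[, prev_fac := data.table::shift(facility), by = death_id]
  ep[, prev_to := data.table::shift(transferred_to), by = death_id]
  date_adj <- !is.na(ep$prev_disc_cmax) &
    as.integer(ep$admit_date) <= ep$prev_disc_cmax + gap_days
  xfer <- (!is.na(ep$prev_to) & ep$prev_to != "" & ep$prev_to == ep$facility) |
    (ep$transferred_from != "" & !is.na(ep$prev_fac) &
       ep$transferred_from == ep$prev_fac)
  # first episode of each person has NA shifts, hence starts a new stay
  ep[, new_stay := !(date_adj | xfer)]
  ep[, stay_id := cumsum(new_stay)]
  st <- ep[, .(
    death_id = death_id[1L],
    source = "APD_stay",
    reports_indigenous = collapse_status(indigenous_flag),
    n_source_records = .N,
    admit_date = min(admit_date),
    discharge_date = max(discharge_date)
  ), by = stay_id]
  st[, stay_id := NULL]
  st[]
}

#' Apply parent-to-infant status inheritance to birth records
#'
#' On perinatal records for an infant, the infant is recorded as a member
#' of the group whenever the mother is so recorded; on birth registrations,
#' whenever the mother or the father is. Otherwise the record's own flag
#' stands.
#'
#' @param source record source (`PDC_infant` or `RBDM_infant`; vectorised).
#' @param own the record's own tri-state flag.
#' @param mother,father parental tri-state flags (`father` used only for
#'   `RBDM_infant`).
#' @return tri-state character vector.
#' @export
apply_infant_inheritance <- function(source, own, mother,
                                     father = "missing") {
  n <- max(length(source), length(own))
  source <- rep_len(source, n); own <- rep_len(own, n)
  mother <- rep_len(mother, n); father <- rep_len(father, n)
  if (any(!source %in% c("PDC_infant", "RBDM_infant")))
    stop("inheritance applies to PDC_infant/RBDM_infant records only",
         call. = FALSE)
  out <- own
  out[source == "PDC_infant" & mother == "yes"] <- "yes"
  out[source == "RBDM_infant" & (mother == "yes" | father == "yes")] <- "yes"
  out
}

# effective per-record flag after inheritance, any source (vectorised)
effective_flag <- function(records) {
  flag <- records$indigenous_flag
  i <- records$source == "PDC_infant"
  if (any(i))
    flag[i] <- apply_infant_inheritance(records$source[i],
                                        flag[i],
                                        records$mother_indigenous_flag[i])
  i <- records$source == "RBDM_infant"
  if (any(i))
    flag[i] <- apply_infant_inheritance(records$source[i],
                                        flag[i],
                                        records$mother_indigenous_flag[i],
                                        records$father_indigenous_flag[i])
  flag
}

# map raw sources to unit sources
unit_source_of <- function(source) {
  c(APD = "APD_stay", EDDC = "EDDC", PDC_mother = "PDC", PDC_infant = "PDC",
    RBDM_mother = "RBDM_birth", RBDM_infant = "RBDM_birth")[source]
}

#' Derive units of information for one death
#'
#' APD episodes are collapsed into hospital stays ([collapse_apd_stays()]);
#' every other linked record becomes one unit after infant inheritance
#' ([apply_infant_inheritance()]). The death registration itself is *not*
#' emitted as a unit: the weight-of-evidence rules count linked evidence
#' only, with the death record handled separately by the classifiers.
#'
#' @param death_id the person's key.
#' @param records `linked_records` rows for that person.
#' @param gap_days passed to [collapse_apd_stays()].
#' @return data frame of units: `death_id`, `source` (one of
#'   `APD_stay, EDDC, PDC, RBDM_birth`), `reports_indigenous`,
#'   `n_source_records`; ordered by source then date.
#' @export
derive_units <- function(death_id, records, gap_days = 0) {
  if (!is.null(records) && nrow(records) > 0 &&
      any(records$death_id != death_id))
    stop("records must all reference the given death_id", call. = FALSE)
  u <- derive_units_all(records, gap_days = gap_days)
  as.data.frame(u)
}

# vectorised unit derivation for a whole linked table
derive_units_all <- function(records, gap_days = 0) {
  empty <- data.table::data.table(
    death_id = character(), source = character(),
    reports_indigenous = character(), n_source_records = integer())
  if (is.null(records) || nrow(records) == 0L) return(empty)
  rec <- data.table::as.data.table(as.data.frame(records))
  apd <- rec[source == "APD"]
  other <- rec[source != "APD"]
  parts <- list()
  if (nrow(apd))
    parts$stays <- collapse_apd_stays_all(apd, gap_days = gap_days)[
      , .(death_id, source, reports_indigenous, n_source_records,
          admit_date)]
  if (nrow(other)) {
    other[, reports_indigenous := effective_flag(other)]
    parts$single <- other[, .(death_id, source = unit_source_of(source),
                              reports_indigenous, n_source_records = 1L,
                              admit_date = as.Date(NA))]
  }
  u <- data.table::rbindlist(parts, use.names = TRUE)
  u[, source := factor(source, levels = UNIT_SOURCES)]
  data.table::setorder(u, death_id, source, admit_date, na.last = TRUE)
  u[, source := as.character(source)]
  u[, admit_date := NULL]
  u[]
}
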