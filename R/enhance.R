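## Per-death classification under the three reporting methods.
##
## Baseline ("as reported"): the death registration's own flag.
## Method 1 ("at least one report"): any linked unit reporting yes.
## Method 2 (weight-of-evidence algorithm): with n countable linked units
## of which k report yes,
##   n >= 3       -> enhanced when k >= 2
##   n in {1, 2}  -> enhanced when k >= 1
##   n == 0       -> never enhanced
## and in every method a death already reported is accepted as reported.
## Units with a missing flag carry no information and are excluded from n
## by default (count_missing_units restores them).

#' Configuration for the enhancement pipeline
#'
#' @param count_missing_units should units whose status flag is missing
#'   count towards the algorithm's unit totals? Default `FALSE`: a missing
#'   field carries no information.
#' @param method1_on_raw_records evaluate "at least one report" on raw
#'   linked records instead of derived units. The two differ only when
#'   flags conflict within one hospital stay (a stay reports yes if any
#'   episode does, so the unit route is already equivalent for `yes`);
#'   exposed for sensitivity checks.
#' @param gap_days admit-to-discharge gap merged as one hospital stay.
#' @return a list of class `enhance_config`.
#' @export
enhance_config <- function(count_missing_units = FALSE,
                           method1_on_raw_records = FALSE,
                           gap_days = 0) {
  structure(list(count_missing_units = isTRUE(count_missing_units),
                 method1_on_raw_records = isTRUE(method1_on_raw_records),
                 gap_days = gap_days),
            class = "enhance_config")
}

#' Classify a death as reported on the death registration
#'
#' @param reported_indigenous tri-state flag(s) from the death record; a
#'   `death_records` data frame is also accepted.
#' @return logical: `TRUE` iff the flag is `"yes"`. Missing is not a
#'   report.
#' @export
classify_as_reported <- function(reported_indigenous) {
  if (is.data.frame(reported_indigenous))
    reported_indigenous <- reported_indigenous$reported_indigenous
  reported_indigenous == "yes"
}

# unit tallies for one death's units
unit_tally <- function(units, count_missing_units = FALSE) {
  flags <- if (is.null(units) || nrow(units) == 0L) character()
           else units$reports_indigenous
  k <- sum(flags == "yes")
  n <- if (count_missing_units) length(flags) else sum(flags != "missing")
  c(n = n, k = k)
}

#' "At least one report" classifier
#'
#' @param reported_indigenous the death record's tri-state flag.
#' @param units units of information for this death ([derive_units()]).
#' @return logical: reported on the death record, or any unit reports yes.
#' @export
classify_at_least_one <- function(reported_indigenous, units) {
  classify_as_reported(reported_indigenous) ||
    unit_tally(units)[["k"]] >= 1L
}

#' Weight-of-evidence algorithm classifier
#'
#' @inheritParams classify_at_least_one
#' @param count_missing_units see [enhance_config()].
#' @return logical per the n/k thresholds described above.
#' @export
classify_algorithm <- function(reported_indigenous, units,
                               count_missing_units = FALSE) {
  t <- unit_tally(units, count_missing_units)
  classify_as_reported(reported_indigenous) ||
    algorithm_rule(t[["n"]], t[["k"]])
}

# the bare n/k rule (vectorised; used by classifiers and oracles alike)
algorithm_rule <- function(n, k) {
  (n >= 3L & k >= 2L) | (n >= 1L & n <= 2L & k >= 1L)
}

#' Proportion-threshold classifier variant
#'
#' Enhancement requiring that at least a fixed fraction of countable units
#' report yes (e.g. 50%, 75% or 90%) — a stricter weight of evidence than
#' the count-based algorithm.
#'
#' @inheritParams classify_algorithm
#' @param threshold fraction in (0, 1].
#' @return logical: reported, or `n >= 1` and `k/n >= threshold`.
#' @export
classify_proportion <- function(reported_indigenous, units, threshold,
                                count_missing_units = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  t <- unit_tally(units, count_missing_units)
  classify_as_reported(reported_indigenous) ||
    (t[["n"]] >= 1L && t[["k"]] / t[["n"]] >= threshold)
}

#' Classify every death in a dataset under all reporting methods
#'
#' Derives units of information from the linked records and applies the
#' three classifiers to each death. Linked records referencing a death
#' absent from the deaths table (unlinked residue) are dropped with a
#' warning. Deaths with no linked records are classified by the death
#' record alone.
#'
#' @param deaths a `death_records` data frame.
#' @param linked a `linked_records` data frame.
#' @param config an [enhance_config()].
#' @param proportion_threshold optional fraction in (0, 1]; when given, an
#'   extra logical column `proportion` is added.
#' @return data frame of class `enhancement_results`: `death_id`,
#'   `as_reported`, `algorithm`, `at_least_one`, `n_units`, `n_units_yes`
#'   (and `proportion` when requested), one row per death in input order.
#' @export
enhance_dataset <- function(deaths, linked, config = enhance_config(),
                            proportion_threshold = NULL) {
  stopifnot(inherits(config, "enhance_config"))
  orphan <- !linked$death_id %in% deaths$death_id
  if (any(orphan)) {
    warning(sum(orphan), " linked record(s) reference unknown death_id; ",
            "ignored as unlinked residue", call. = FALSE)
    linked <- linked[!orphan, , drop = FALSE]
  }

  units <- derive_units_all(linked, gap_days = config$gap_days)
  tal <- if (nrow(units)) {
    units <- data.table::as.data.table(units)
    units[, .(
      n_units = if (config$count_missing_units) .N
                else sum(reports_indigenous != "missing"),
      n_units_yes = sum(reports_indigenous == "yes")
    ), by = death_id]
  } else {
    data.table::data.table(death_id = character(), n_units = integer(),
                           n_units_yes = integer())
  }

  res <- data.table::data.table(death_id = deaths$death_id)
  res <- tal[res, on = "death_id"]
  res[is.na(n_units), `:=`(n_units = 0L, n_units_yes = 0L)]
  res[, as_reported := classify_as_reported(deaths$reported_indigenous)]

  if (config$method1_on_raw_records && nrow(linked)) {
    raw <- data.table::as.data.table(as.data.frame(linked))
    raw[, indigenous_flag := effective_flag(raw)]
    raw_yes <- raw[, .(any_yes = any(indigenous_flag == "yes")),
                   by = death_id]
    res <- raw_yes[res, on = "death_id"]
    res[is.na(any_yes), any_yes := FALSE]
    res[, at_least_one := as_reported | any_yes]
    res[, any_yes := NULL]
  } else {
    res[, at_least_one := as_reported | n_units_yes >= 1L]
  }
  res[, algorithm := as_reported | algorithm_rule(n_units, n_units_yes)]

  if (!is.null(proportion_threshold)) {
    if (!is.numeric(proportion_threshold) || proportion_threshold <= 0 ||
        proportion_threshold > 1)
      stop("proportion_threshold must be in (0, 1]", call. = FALSE)
    res[, proportion := as_reported |
          (n_units >= 1L & n_units_yes / pmax(n_units, 1L) >=
             proportion_threshold)]
  }

  cols <- c("death_id", "as_reported", "algorithm", "at_least_one",
            "n_units", "n_units_yes",
            if (!is.null(proportion_threshold)) "proportion")
  out <- as.data.frame(res[match(deaths$death_id, res$death_id), ..cols])
  rownames(out) <- NULL
  class(out) <- c("enhancement_results", "data.frame")
  out
}

#' Aggregate counts of deaths under each reporting method
#'
#' @param results an `enhancement_results` data frame.
#' @return named integer vector with elements `as_reported`, `algorithm`,
#'   `at_least_one` (and `proportion` when present).
#' @export
method_counts <- function(results) {
  cols <- intersect(c("as_reported", "algorithm", "at_least_one",
                      "proportion"), names(results))
  vapply(results[cols], sum, 0L)
}

#' @rdname enhance_dataset
#' @param results an `enhancement_results` data frame to write.
#' @param path,sep output file and delimiter.
#' @export
write_enhancement_results <- function(results, path, sep = ",") {
  out <- as.data.frame(results)
  for (col in intersect(c("as_reported", "algorithm", "at_least_one",
                          "proportion"), names(out)))
    out[[col]] <- as.integer(out[[col]])
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
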