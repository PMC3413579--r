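## Category vocabularies and ICD-10 range logic shared by all stages.

#' Vocabulary constants
#'
#' Fixed category sets used throughout the package.
#'
#' @name vocab
#' @keywords internal
NULL

TRISTATE <- c("yes", "no", "missing")
SEXES <- c("male", "female")
REMOTENESS <- c("MajorCities", "InnerRegional", "OuterRegional",
                "Remote", "VeryRemote", "Unknown")
LINK_SOURCES <- c("APD", "EDDC", "PDC_mother", "PDC_infant",
                  "RBDM_mother", "RBDM_infant")
UNIT_SOURCES <- c("APD_stay", "EDDC", "PDC", "RBDM_birth")

#' Convert file encodings to tri-state status values
#'
#' Files encode the status flag as `"1"` (yes), `"0"` (no) and the empty
#' string or `NA` (missing). In memory the package uses the strings
#' `"yes"`, `"no"`, `"missing"`; those strings are also accepted on input.
#'
#' @param x character vector of raw values.
#' @return character vector with values in `yes`, `no`, `missing`;
#'   unrecognised values become `NA` (callers treat that as a validation
#'   error).
#' @export
as_tristate <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[is.na(x) | trimws(x) == ""] <- "missing"
  v <- trimws(tolower(x))
  out[v %in% c("1", "yes", "y", "true")] <- "yes"
  out[v %in% c("0", "no", "n", "false")] <- "no"
  out[v %in% c("missing", "na", "unknown", "9")] <- "missing"
  out
}

tristate_to_file <- function(x) {
  c(yes = "1", no = "0", missing = "")[x]
}

## ---- ICD-10 cause groups -------------------------------------------------

ICD10_RE <- "^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$"

#' Define an ICD-10 cause-of-death group
#'
#' A cause group is a named set of inclusive ICD-10 code ranges. Membership
#' is decided on the 3-character code (letter plus two digits); codes with a
#' decimal extension inherit their 3-character parent's classification.
#'
#' @param name group label.
#' @param ranges list of length-2 character vectors, each an inclusive
#'   `(start, end)` pair of 3-character ICD-10 codes, e.g.
#'   `list(c("I00", "I99"))`. Ranges may span letters ("V01"--"Y98").
#' @return an object of class `cause_group`.
#' @export
#' @examples
#' cvd <- cause_group("cardiovascular", list(c("I00", "I99")))
#' icd10_in_range("I21.4", cvd)
cause_group <- function(name, ranges) {
  stopifnot(is.character(name), length(name) == 1L, is.list(ranges))
  ranges <- lapply(ranges, function(r) {
    r <- toupper(as.character(r))
    if (length(r) != 2L || !all(grepl("^[A-Z][0-9]{2}$", r)))
      stop("each range must be two 3-character ICD-10 codes", call. = FALSE)
    if (icd10_key(r[1]) > icd10_key(r[2]))
      stop("range start exceeds range end: ", r[1], "-", r[2], call. = FALSE)
    r
  })
  structure(list(name = name, ranges = ranges), class = "cause_group")
}

#' @export
print.cause_group <- function(x, ...) {
  spans <- vapply(x$ranges, function(r) paste(r, collapse = "-"), "")
  cat("<cause_group> ", x$name, ": ", paste(spans, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Built-in cause-of-death groups
#'
#' The three cause groups used in the mortality tables: cancer (C00--C97),
#' cardiovascular diseases (I00--I99) and external causes (V01--Y98).
#' The lower bound of the external group is V01, not V00.
#'
#' @return named list of [cause_group()] objects.
#' @export
default_cause_groups <- function() {
  list(
    cancer         = cause_group("cancer", list(c("C00", "C97"))),
    cardiovascular = cause_group("cardiovascular", list(c("I00", "I99"))),
    external       = cause_group("external", list(c("V01", "Y98")))
  )
}

# integer sort key for a 3-character code: letter index * 100 + number
icd10_key <- function(code3) {
  (match(substr(code3, 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(code3, 2, 3))
}

#' Test ICD-10 codes for cause-group membership
#'
#' @param code character vector of ICD-10 codes (letter, two digits,
#'   optional decimal extension, e.g. `"I21.4"`).
#' @param group a [cause_group()].
#' @return logical vector.
#' @export
icd10_in_range <- function(code, group) {
  stopifnot(inherits(group, "cause_group"))
  code <- toupper(as.character(code))
  bad <- !grepl(ICD10_RE, code)
  if (any(bad))
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  key <- icd10_key(substr(code, 1, 3))
  out <- rep(FALSE, length(code))
  for (r in group$ranges)
    out <- out | (key >= icd10_key(r[1]) & key <= icd10_key(r[2]))
  out
}

#' Assign each code to the first matching cause group
#'
#' @param code character vector of ICD-10 codes.
#' @param groups named list of [cause_group()]s; defaults to
#'   [default_cause_groups()].
#' @param other label for codes matching no group.
#' @return character vector of group names.
#' @export
icd10_group_of <- function(code, groups = default_cause_groups(),
                           other = "other") {
  out <- rep(other, length(code))
  for (nm in rev(names(groups)))
    out[icd10_in_range(code, groups[[nm]])] <- nm
  out
}
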