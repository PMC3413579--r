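# fixture builders used across test files

fix_deaths <- function(n = 3, reported = "no", age = 60) {
  death_records(
    death_id = sprintf("D%03d", seq_len(n)),
    age_years = rep_len(age, n),
    sex = rep_len(c("male", "female"), n),
    remoteness = rep_len("MajorCities", n),
    cause_icd10 = rep_len("I21", n),
    reported_indigenous = rep_len(reported, n)
  )
}

# one APD episode row
apd_episode <- function(record_id, death_id, admit, discharge,
                        flag = "no", facility = "",
                        transferred_from = "", transferred_to = "") {
  linked_records(record_id = record_id, death_id = death_id,
                 source = "APD", indigenous_flag = flag,
                 admit_date = admit, discharge_date = discharge,
                 facility = facility, transferred_from = transferred_from,
                 transferred_to = transferred_to)
}

# a non-APD linked record
simple_record <- function(record_id, death_id, source, flag = "no",
                          mother = "", father = "") {
  linked_records(record_id = record_id, death_id = death_id,
                 source = source, indigenous_flag = flag,
                 mother_indigenous_flag = mother,
                 father_indigenous_flag = father)
}

rbind_records <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("linked_records", "data.frame")
  out
}

# build a units data frame directly (for classifier tests)
make_units <- function(flags, source = "EDDC") {
  data.frame(death_id = rep("D001", length(flags)),
             source = rep_len(source, length(flags)),
             reports_indigenous = flags,
             n_source_records = rep(1L, length(flags)),
             stringsAsFactors = FALSE)
}

# units with k yes out of n countable
units_nk <- function(n, k) make_units(rep(c("yes", "no"), c(k, n - k)))

noiseless_config <- function(...) {
  generator_config(report_fp_rate = c(death = 0, APD = 0, EDDC = 0,
                                      PDC = 0, RBDM = 0),
                   false_link_rate = 0, missed_link_rate = 0, ...)
}
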