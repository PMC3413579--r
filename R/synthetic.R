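## Synthetic linked-cohort generator.
##
## Emulates the statistical structure the enhancement analysis assumes:
## a cohort of registered deaths with a (latent) true group status;
## per-dataset probabilities that a true member's record actually reports
## membership (death registration 0.76, admitted-patient 0.88, perinatal
## 0.68 — external validation figures; ED and birth-registration quality
## is unmeasured and the 0.80 defaults are labelled placeholders);
## age/cause/remoteness-dependent counts of linked hospital stays (stays
## expand into transfer-linked episode rows so stay collapsing can be
## validated); and record-linkage errors at the reported rates (5/1000
## missed links, 4/1000 false links).

#' Configuration for the synthetic cohort generator
#'
#' Every probability the generator uses, with the study-like scenario as
#' the default. `report_sensitivity[s]` is the probability that a record
#' of source `s` for a *true member* flags yes; `report_fp_rate[s]` the
#' probability that a *non-member's* record flags yes; `missing_rate[s]`
#' the probability that a non-yes flag is recorded as missing (so the
#' yes-probability is exactly the sensitivity regardless of missingness).
#'
#' @param n_deaths cohort size.
#' @param prevalence_true_indigenous probability a death is a true member
#'   of the group of interest.
#' @param report_sensitivity named vector over
#'   `death, APD, EDDC, PDC, RBDM`.
#' @param report_fp_rate named vector, same names; default all 0.
#' @param missing_rate named vector, same names.
#' @param stay_intensity mean linked hospital stays for a middle-aged
#'   death before age/cause/remoteness multipliers.
#' @param episodes_extra_mean mean number of extra transfer-linked
#'   episodes per stay (Poisson), so mean episodes per stay is
#'   `1 + episodes_extra_mean`.
#' @param ed_intensity mean linked ED attendances before multipliers.
#' @param birth_record_probability probability an infant death (age 0) has
#'   a linked perinatal record (the birth-registration probability is
#'   taken as `0.95 *` this).
#' @param mother_record_probability probability a female death aged 15-44
#'   has a linked perinatal/birth-registration record of her own.
#' @param false_link_rate probability a linked record is attached to the
#'   wrong death.
#' @param missed_link_rate probability a true linked record is missed.
#' @param seed root seed; stage streams are derived from it.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_deaths = 2000,
                             prevalence_true_indigenous = 0.02,
                             report_sensitivity = c(death = 0.76,
                                                    APD = 0.88,
                                                    EDDC = 0.80,
                                                    PDC = 0.68,
                                                    RBDM = 0.80),
                             report_fp_rate = c(death = 0, APD = 0,
                                                EDDC = 0, PDC = 0,
                                                RBDM = 0),
                             missing_rate = c(death = 0.01, APD = 0.01,
                                              EDDC = 0.05, PDC = 0.01,
                                              RBDM = 0.01),
                             stay_intensity = 1.2,
                             episodes_extra_mean = 0.15,
                             ed_intensity = 0.8,
                             birth_record_probability = 0.9,
                             mother_record_probability = 0.1,
                             false_link_rate = 0.004,
                             missed_link_rate = 0.005,
                             seed = 1L) {
  srcs <- c("death", "APD", "EDDC", "PDC", "RBDM")
  fill <- function(x, default) {
    out <- default
    out[names(x)] <- x
    out[srcs]
  }
  cfg <- list(
    n_deaths = as.integer(n_deaths),
    prevalence_true_indigenous = prevalence_true_indigenous,
    report_sensitivity = fill(report_sensitivity,
                              c(death = 0.76, APD = 0.88, EDDC = 0.80,
                                PDC = 0.68, RBDM = 0.80)),
    report_fp_rate = fill(report_fp_rate,
                          c(death = 0, APD = 0, EDDC = 0, PDC = 0,
                            RBDM = 0)),
    missing_rate = fill(missing_rate,
                        c(death = 0.01, APD = 0.01, EDDC = 0.05,
                          PDC = 0.01, RBDM = 0.01)),
    stay_intensity = stay_intensity,
    episodes_extra_mean = episodes_extra_mean,
    ed_intensity = ed_intensity,
    birth_record_probability = birth_record_probability,
    mother_record_probability = mother_record_probability,
    false_link_rate = false_link_rate,
    missed_link_rate = missed_link_rate,
    seed = as.integer(seed)
  )
  probs <- c(cfg$prevalence_true_indigenous, cfg$report_sensitivity,
             cfg$report_fp_rate, cfg$missing_rate,
             cfg$birth_record_probability, cfg$mother_record_probability,
             cfg$false_link_rate, cfg$missed_link_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_deaths < 0 || cfg$stay_intensity < 0 ||
      cfg$episodes_extra_mean < 0 || cfg$ed_intensity < 0)
    stop("counts and intensities must be non-negative", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

#' Read a generator configuration from a YAML file
#'
#' The YAML schema mirrors the arguments of [generator_config()]; absent
#' keys take the defaults.
#'
#' @param path YAML file path.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(generator_config)))
  for (nm in c("report_sensitivity", "report_fp_rate", "missing_rate"))
    if (nm %in% keep) raw[[nm]] <- unlist(raw[[nm]])
  do.call(generator_config, raw[keep])
}

## multipliers shaping record intensity; chronic causes and older ages
## generate more hospital contact, remote areas less
CAUSE_STAY_MULT <- c(cancer = 1.6, cardiovascular = 1.3, external = 0.5,
                     other = 1.0)
REMOTE_STAY_MULT <- c(MajorCities = 1.15, InnerRegional = 1.05,
                      OuterRegional = 0.95, Remote = 0.8,
                      VeryRemote = 0.65, Unknown = 1.0)
age_stay_mult <- function(age) 0.25 + 1.75 * pmin(age, 85) / 85

## demographic profiles per true status: members die younger, live in
## remoter areas, and have relatively more external-cause deaths
REMOTE_PROB <- list(
  member = c(0.30, 0.33, 0.24, 0.08, 0.04, 0.01),
  nonmember = c(0.70, 0.17, 0.09, 0.015, 0.005, 0.015)
)
CAUSE_PROB <- list(
  member = c(cancer = 0.20, cardiovascular = 0.30, external = 0.10,
             other = 0.40),
  nonmember = c(cancer = 0.28, cardiovascular = 0.33, external = 0.06,
                other = 0.33)
)

# tri-state flag draws: P(yes) = s for members / f for non-members;
# the remaining mass splits missing : no as m : (1 - m)
draw_flags <- function(member, s, f, m) {
  n <- length(member)
  p_yes <- ifelse(member, s, f)
  yes <- stats::runif(n) < p_yes
  miss <- !yes & stats::runif(n) < m
  ifelse(yes, "yes", ifelse(miss, "missing", "no"))
}

sample_age <- function(member, n) {
  age <- integer(n)
  infant <- stats::runif(n) < ifelse(member, 0.05, 0.005)
  mu <- ifelse(member, 60, 79)
  sdv <- ifelse(member, 20, 13)
  a <- round(stats::rnorm(n, mu, sdv))
  age <- pmin(pmax(a, 1L), 105L)
  age[infant] <- 0L
  as.integer(age)
}

sample_cause_code <- function(group, n) {
  code <- character(n)
  idx <- group == "cancer"
  code[idx] <- sprintf("C%02d", sample(0:96, sum(idx), replace = TRUE))
  idx <- group == "cardiovascular"
  code[idx] <- sprintf("I%02d", sample(0:99, sum(idx), replace = TRUE))
  idx <- group == "external"
  if (any(idx)) {
    key <- sample(icd10_key("V01"):icd10_key("Y98"), sum(idx),
                  replace = TRUE)
    code[idx] <- sprintf("%s%02d", LETTERS[key %/% 100 + 1], key %% 100)
  }
  idx <- group == "other"
  if (any(idx))
    code[idx] <- sample(c("J18", "J44", "E11", "E14", "G30", "K70",
                          "F03", "N18", "A41", "R99"),
                        sum(idx), replace = TRUE)
  code
}

#' Generate a synthetic linked cohort
#'
#' Draws the death cohort, its linked administrative records (hospital
#' stays expanded into date-adjacent, transfer-linked episode rows; ED
#' attendances; perinatal and birth-registration records for infant
#' deaths and for mothers), then injects linkage errors. Reproducible:
#' the same configuration (including seed) yields byte-identical output
#' files.
#'
#' @param config a [generator_config()].
#' @param out_dir optional directory; when given, writes `deaths.csv`,
#'   `linked.csv`, `truth.csv` (and `linkage_errors.csv` when any error
#'   was injected).
#' @return (invisibly when writing) a list with elements `deaths`
#'   (`death_records`), `linked` (`linked_records`), `truth` (data frame
#'   `death_id, true_indigenous`), and `linkage_errors` (log of injected
#'   perturbations).
#' @export
generate_cohort <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_deaths
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  ## -- stage 1: the death cohort ------------------------------------------
  set.seed(stage_seeds[1])
  member <- stats::runif(n) < config$prevalence_true_indigenous
  age <- sample_age(member, n)
  sex <- sample(SEXES, n, replace = TRUE)
  remoteness <- character(n)
  cause_grp <- character(n)
  for (st in c(TRUE, FALSE)) {
    idx <- member == st
    who <- if (st) "member" else "nonmember"
    remoteness[idx] <- sample(REMOTENESS, sum(idx), replace = TRUE,
                              prob = REMOTE_PROB[[who]])
    cause_grp[idx] <- sample(names(CAUSE_PROB[[who]]), sum(idx),
                             replace = TRUE, prob = CAUSE_PROB[[who]])
  }
  cause <- sample_cause_code(cause_grp, n)
  reported <- draw_flags(member, config$report_sensitivity["death"],
                         config$report_fp_rate["death"],
                         config$missing_rate["death"])
  death_id <- sprintf("D%06d", seq_len(n))
  deaths <- death_records(death_id, age, sex, remoteness, cause, reported)
  truth <- data.frame(death_id = death_id, true_indigenous = member,
                      stringsAsFactors = FALSE)

  ## -- stage 2: linked records --------------------------------------------
  set.seed(stage_seeds[2])
  s <- config$report_sensitivity; f <- config$report_fp_rate
  m <- config$missing_rate

  # hospital stays -> transfer-linked episodes
  mean_stays <- config$stay_intensity * age_stay_mult(age) *
    CAUSE_STAY_MULT[cause_grp] * REMOTE_STAY_MULT[remoteness]
  n_stays <- stats::rpois(n, mean_stays)
  stay_death <- rep(seq_len(n), n_stays)
  n_stay_tot <- length(stay_death)
  apd <- NULL
  if (n_stay_tot > 0) {
    # at most 3 episodes of <= 12 days each, and stays of one person
    # spaced >= 80 days apart: distinct stays can never touch by date,
    # so the generated stay structure is exactly recoverable
    n_ep <- 1L + pmin(stats::rpois(n_stay_tot, config$episodes_extra_mean),
                      2L)
    stay_idx <- sequence(n_stays)  # index of the stay within its person
    admit0 <- as.Date("2001-01-01") + (stay_idx - 1L) * 80L +
      sample.int(15L, n_stay_tot, replace = TRUE) - 1L
    ep_stay <- rep(seq_len(n_stay_tot), n_ep)
    ep_len <- sample.int(12L, length(ep_stay), replace = TRUE)
    dt <- data.table::data.table(stay = ep_stay, len = ep_len)
    dt[, ep_in_stay := seq_len(.N), by = stay]
    dt[, disc_off := cumsum(len), by = stay]
    dt[, adm_off := disc_off - len]
    dt[, death := stay_death[stay]]
    dt[, admit := admit0[stay] + adm_off]
    dt[, discharge := admit0[stay] + disc_off]
    dt[, facility := sprintf("F%03d", sample.int(40L, .N, replace = TRUE))]
    # transfer pointers chain episodes within a stay
    dt[, transferred_to :=
         c(utils::head(data.table::shift(facility, type = "lead"), -1), ""),
       by = stay]
    dt[, transferred_from := data.table::shift(facility, fill = ""),
       by = stay]
    dt[is.na(transferred_to), transferred_to := ""]
    dt[, flag := draw_flags(member[death], s["APD"], f["APD"], m["APD"])]
    apd <- dt
  }

  # emergency department attendances
  mean_ed <- config$ed_intensity * (0.7 + 0.6 * pmin(age, 85) / 85)
  n_ed <- stats::rpois(n, mean_ed)
  ed_death <- rep(seq_len(n), n_ed)
  ed_flag <- draw_flags(member[ed_death], s["EDDC"], f["EDDC"], m["EDDC"])

  # birth records: infants inherit from parents (parents share the
  # infant's true status), mothers of reproductive age carry their own
  infant <- which(age == 0)
  pdc_inf <- infant[stats::runif(length(infant)) <
                      config$birth_record_probability]
  rbdm_inf <- infant[stats::runif(length(infant)) <
                       0.95 * config$birth_record_probability]
  mothers <- which(sex == "female" & age >= 15 & age <= 44)
  pdc_mot <- mothers[stats::runif(length(mothers)) <
                       config$mother_record_probability]
  rbdm_mot <- mothers[stats::runif(length(mothers)) <
                        config$mother_record_probability]

  birth <- data.frame(
    death = c(pdc_inf, rbdm_inf, pdc_mot, rbdm_mot),
    source = rep(c("PDC_infant", "RBDM_infant", "PDC_mother",
                   "RBDM_mother"),
                 c(length(pdc_inf), length(rbdm_inf), length(pdc_mot),
                   length(rbdm_mot))),
    stringsAsFactors = FALSE)
  src_key <- c(PDC_infant = "PDC", RBDM_infant = "RBDM",
               PDC_mother = "PDC", RBDM_mother = "RBDM")[birth$source]
  birth$flag <- draw_flags(member[birth$death], s[src_key], f[src_key],
                           m[src_key])
  is_inf <- birth$source %in% c("PDC_infant", "RBDM_infant")
  birth$mother_flag <- rep("", nrow(birth))
  birth$father_flag <- rep("", nrow(birth))
  if (any(is_inf)) {
    birth$mother_flag[is_inf] <-
      draw_flags(member[birth$death[is_inf]], s[src_key[is_inf]],
                 f[src_key[is_inf]], m[src_key[is_inf]])
    is_rb <- birth$source == "RBDM_infant"
    birth$father_flag[is_rb] <-
      draw_flags(member[birth$death[is_rb]], s["RBDM"], f["RBDM"],
                 m["RBDM"])
  }

  linked_death <- c(if (!is.null(apd)) apd$death, ed_death, birth$death)
  n_lnk <- length(linked_death)
  blank <- function(x) if (is.null(x)) character() else x
  linked_raw <- data.frame(
    record_id = sprintf("R%07d", seq_len(n_lnk)),
    death_id = death_id[linked_death],
    source = c(rep("APD", if (is.null(apd)) 0 else nrow(apd)),
               rep("EDDC", length(ed_death)), birth$source),
    indigenous_flag = c(blank(apd$flag), ed_flag, birth$flag),
    mother_indigenous_flag = c(rep("", if (is.null(apd)) 0 else nrow(apd)),
                               rep("", length(ed_death)),
                               birth$mother_flag),
    father_indigenous_flag = c(rep("", if (is.null(apd)) 0 else nrow(apd)),
                               rep("", length(ed_death)),
                               birth$father_flag),
    admit_date = c(if (is.null(apd)) character() else
                     format(apd$admit, "%Y-%m-%d"),
                   rep("", length(ed_death) + nrow(birth))),
    discharge_date = c(if (is.null(apd)) character() else
                         format(apd$discharge, "%Y-%m-%d"),
                       rep("", length(ed_death) + nrow(birth))),
    facility = c(blank(apd$facility), rep("", length(ed_death) +
                                            nrow(birth))),
    transferred_from = c(blank(apd$transferred_from),
                         rep("", length(ed_death) + nrow(birth))),
    transferred_to = c(blank(apd$transferred_to),
                       rep("", length(ed_death) + nrow(birth))),
    stringsAsFactors = FALSE)

  ## -- stage 3: linkage errors --------------------------------------------
  err <- inject_linkage_errors(linked_raw, death_id,
                               missed_link_rate = config$missed_link_rate,
                               false_link_rate = config$false_link_rate,
                               seed = stage_seeds[3])
  linked <- do.call(linked_records, as.list(err$records))
  out <- list(deaths = deaths, linked = linked, truth = truth,
              linkage_errors = err$log)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_deaths(deaths, file.path(out_dir, "deaths.csv"))
    write_linked_records(linked, file.path(out_dir, "linked.csv"))
    tr <- truth
    tr$true_indigenous <- as.integer(tr$true_indigenous)
    utils::write.table(tr, file.path(out_dir, "truth.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    if (nrow(err$log))
      utils::write.table(err$log, file.path(out_dir, "linkage_errors.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Inject linkage errors into a linked-records table
#'
#' Each record is independently dropped (missed link) with
#' `missed_link_rate`; each surviving record is reassigned to a uniformly
#' chosen *other* death (false link) with `false_link_rate`.
#'
#' @param records data frame of linked records (raw character form or a
#'   `linked_records` object).
#' @param death_ids pool of death keys a false link may point to.
#' @param missed_link_rate,false_link_rate probabilities in \[0, 1\].
#' @param seed optional seed for this stage's stream.
#' @return list with `records` (perturbed table) and `log` (data frame
#'   `record_id, action, original_death_id, new_death_id`).
#' @export
inject_linkage_errors <- function(records, death_ids,
                                  missed_link_rate = 0.005,
                                  false_link_rate = 0.004,
                                  seed = NULL) {
  stopifnot(missed_link_rate >= 0, missed_link_rate <= 1,
            false_link_rate >= 0, false_link_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  log_empty <- data.frame(record_id = character(), action = character(),
                          original_death_id = character(),
                          new_death_id = character(),
                          stringsAsFactors = FALSE)
  if (n == 0L) return(list(records = records, log = log_empty))
  drop <- stats::runif(n) < missed_link_rate
  relink <- !drop & stats::runif(n) < false_link_rate
  new_target <- rep(NA_character_, n)
  if (any(relink) && length(death_ids) > 1L) {
    for (i in which(relink)) {
      pool <- death_ids[death_ids != records$death_id[i]]
      new_target[i] <- pool[sample.int(length(pool), 1L)]
    }
  } else relink[] <- FALSE
  log <- rbind(
    if (any(drop)) data.frame(record_id = records$record_id[drop],
                              action = "missed_link",
                              original_death_id = records$death_id[drop],
                              new_death_id = NA_character_,
                              stringsAsFactors = FALSE),
    if (any(relink)) data.frame(record_id = records$record_id[relink],
                                action = "false_link",
                                original_death_id = records$death_id[relink],
                                new_death_id = new_target[relink],
                                stringsAsFactors = FALSE))
  if (is.null(log)) log <- log_empty
  out <- records
  out$death_id[relink] <- new_target[relink]
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, log = log)
}
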