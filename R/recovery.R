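## End-to-end parameter recovery: simulated enhancement counts versus
## closed-form expectations computed from the generator's own parameters
## and the realized unit structure.
##
## For a true member with death-record sensitivity s0 and countable units
## whose yes-probabilities are p_j,
##   P(at least one) = 1 - (1 - s0) * prod_j (1 - p_j)
## and the algorithm probability is s0 + (1 - s0) * P(pass), with P(pass)
## the probability that the tri-state unit outcomes (yes / countable-no /
## missing) satisfy the n/k thresholds — computed exactly by a small
## dynamic programme over units. Valid only in the noiseless-linkage,
## zero-false-positive scenario, which the function enforces.

# P(units pass the weight-of-evidence rule), exact DP.
# py = per-unit P(yes), pm = per-unit P(missing); countable-no = rest.
# state: (k capped at 2, c capped at 2), pass iff k>=2 or (k==1 & c<=1).
algorithm_pass_prob <- function(py, pm) {
  P <- matrix(0, 3, 3)
  P[1, 1] <- 1
  for (j in seq_along(py)) {
    pn <- 1 - py[j] - pm[j]
    Q <- matrix(0, 3, 3)
    for (k in 1:3) for (c in 1:3) {
      if (P[k, c] == 0) next
      Q[min(k + 1, 3), c] <- Q[min(k + 1, 3), c] + P[k, c] * py[j]
      Q[k, min(c + 1, 3)] <- Q[k, min(c + 1, 3)] + P[k, c] * pn
      Q[k, c] <- Q[k, c] + P[k, c] * pm[j]
    }
    P <- Q
  }
  sum(P[3, ]) + P[2, 1] + P[2, 2]
}

# per-unit (p_yes, p_missing) from the generator parameters and the
# realized unit structure of one true member's linked records
unit_probs_for_death <- function(rec, cfg) {
  s <- cfg$report_sensitivity; m <- cfg$missing_rate
  py <- numeric(0); pm <- numeric(0)
  apd <- rec[rec$source == "APD", , drop = FALSE]
  if (nrow(apd)) {
    st <- collapse_apd_stays_all(apd)
    n_ep <- st$n_source_records
    py <- c(py, 1 - (1 - s["APD"])^n_ep)
    pm <- c(pm, (m["APD"] * (1 - s["APD"]))^n_ep)
  }
  add <- function(p_yes, p_miss, times) {
    py <<- c(py, rep(p_yes, times)); pm <<- c(pm, rep(p_miss, times))
  }
  add(s["EDDC"], m["EDDC"] * (1 - s["EDDC"]),
      sum(rec$source == "EDDC"))
  add(s["PDC"], m["PDC"] * (1 - s["PDC"]),
      sum(rec$source == "PDC_mother"))
  # infant units: own flag OR inherited parent flags, parents sharing the
  # infant's true status — yes-probability compounds across the reports
  add(1 - (1 - s["PDC"])^2, m["PDC"] * (1 - s["PDC"])^2,
      sum(rec$source == "PDC_infant"))
  add(s["RBDM"], m["RBDM"] * (1 - s["RBDM"]),
      sum(rec$source == "RBDM_mother"))
  add(1 - (1 - s["RBDM"])^3, m["RBDM"] * (1 - s["RBDM"])^3,
      sum(rec$source == "RBDM_infant"))
  list(py = unname(py), pm = unname(pm))
}

#' Validate the pipeline end-to-end against closed-form expectations
#'
#' Repeatedly generates a cohort, runs unit derivation and enhancement,
#' and compares each method's simulated count of classified deaths with
#' its analytic expectation given the generator parameters and the
#' realized linked-record structure. Requires the noiseless scenario:
#' zero false-positive report rates and zero linkage-error rates (an
#' error otherwise), so every classified death is a true member and the
#' closed forms are exact.
#'
#' @param config a [generator_config()] with `report_fp_rate` all zero and
#'   both linkage-error rates zero.
#' @param n_reps number of replicate cohorts.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @return data frame, one row per method: total `simulated` and
#'   `expected` counts over all replicates, the Monte-Carlo `se`, the
#'   standardised difference `z`, and `within_3se`.
#' @export
recovery_check <- function(config = generator_config(), n_reps = 50,
                           seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (any(config$report_fp_rate > 0) || config$false_link_rate > 0 ||
      config$missed_link_rate > 0)
    stop("recovery_check requires zero false-positive and linkage-error ",
         "rates", call. = FALSE)
  s0 <- config$report_sensitivity[["death"]]
  sim <- c(as_reported = 0, algorithm = 0, at_least_one = 0)
  expd <- sim; vars <- sim

  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seed + i
    cohort <- generate_cohort(cfg)
    res <- enhance_dataset(cohort$deaths, cohort$linked)
    sim <- sim + method_counts(res)[names(sim)]

    members <- cohort$truth$death_id[cohort$truth$true_indigenous]
    rec_all <- as.data.frame(cohort$linked)
    rec_split <- split(rec_all[rec_all$death_id %in% members, ],
                       factor(rec_all$death_id[rec_all$death_id %in%
                                                 members],
                              levels = members))
    for (d in members) {
      up <- unit_probs_for_death(rec_split[[d]], cfg)
      p_as <- s0
      p_alo <- 1 - (1 - s0) * prod(1 - up$py)
      p_alg <- s0 + (1 - s0) * algorithm_pass_prob(up$py, up$pm)
      p <- c(as_reported = p_as, algorithm = p_alg, at_least_one = p_alo)
      expd <- expd + p
      vars <- vars + p * (1 - p)
    }
  }
  se <- sqrt(vars)
  z <- ifelse(se > 0, (sim - expd) / se, 0)
  data.frame(method = names(sim), simulated = unname(sim),
             expected = unname(expd), se = unname(se), z = unname(z),
             within_3se = unname(abs(z) <= 3), row.names = NULL,
             stringsAsFactors = FALSE)
}
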