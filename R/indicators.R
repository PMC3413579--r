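## Mortality indicators on a classified dataset: stratified counts with
## percent increases, median age at death, and indirectly standardised
## mortality ratios (SMR, scaled x100) with exact gamma confidence
## intervals.

#' Round half away from zero
#'
#' Printed mortality tables round 0.05 upwards (in magnitude), unlike
#' base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent increase of an enhanced count over the baseline
#'
#' @param baseline count under "as reported"; must be positive.
#' @param enhanced count under an enhancement method.
#' @param digits decimal places (1 matches the printed tables); `NULL`
#'   for the unrounded value.
#' @return `100 * (enhanced - baseline) / baseline`, rounded half away
#'   from zero.
#' @export
#' @examples
#' percent_increase(580, 780) # 34.5
#' percent_increase(580, 908) # 56.6
percent_increase <- function(baseline, enhanced, digits = 1) {
  if (any(baseline <= 0))
    stop("percent increase undefined for baseline <= 0", call. = FALSE)
  x <- 100 * (enhanced - baseline) / baseline
  if (is.null(digits)) x else round_half_out(x, digits)
}

#' Implied baseline reporting level
#'
#' Taking an enhanced count as the estimate of the true number of deaths,
#' the baseline count expressed as a percentage of it estimates the level
#' of reporting on the unenhanced death data.
#'
#' @inheritParams percent_increase
#' @return `100 * baseline / enhanced`, rounded half away from zero.
#' @export
#' @examples
#' reporting_level(580, 780) # 74.4
reporting_level <- function(baseline, enhanced, digits = 1) {
  if (any(enhanced <= 0))
    stop("reporting level undefined for enhanced <= 0", call. = FALSE)
  x <- 100 * baseline / enhanced
  if (is.null(digits)) x else round_half_out(x, digits)
}

#' Median age at death
#'
#' Middle order statistic; for even counts the mean of the two middle
#' values. An empty stratum yields `NA`, never zero.
#'
#' @param ages numeric ages (completed years; fractional accepted).
#' @param digits decimal places for the printed value.
#' @return median age, or `NA_real_` for an empty stratum.
#' @export
median_age <- function(ages, digits = 1) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0L) return(NA_real_)
  round_half_out(stats::median(ages), digits)
}

## ---- age bands -----------------------------------------------------------

#' Assign ages to age bands
#'
#' Two band schemes are used: `"counts"` is the demographic-table layout
#' (0, 1-4, then five-year bands to 85+); `"five_year"` is the uniform
#' standardisation layout (0-4, 5-9, ..., 85+).
#'
#' @param age numeric vector of ages in years.
#' @param scheme `"counts"` or `"five_year"`.
#' @return factor with bands in ascending order.
#' @export
age_band <- function(age, scheme = c("counts", "five_year")) {
  scheme <- match.arg(scheme)
  breaks5 <- c(seq(0, 85, by = 5), Inf)
  labs5 <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
  if (scheme == "five_year")
    return(cut(age, breaks = breaks5, labels = labs5, right = FALSE))
  breaks <- c(0, 1, seq(5, 85, by = 5), Inf)
  labs <- c("0", "1-4", labs5[-1])
  cut(age, breaks = breaks, labels = labs, right = FALSE)
}

#' @rdname age_band
#' @param scheme band scheme.
#' @return character vector of band labels in ascending order.
#' @export
age_band_levels <- function(scheme = c("counts", "five_year")) {
  levels(age_band(0, match.arg(scheme)))
}

## ---- standardisation tables ----------------------------------------------

#' Read a standard rate or population table
#'
#' Both tables are delimited files keyed by `sex` and `age_band`
#' (five-year bands `0-4` ... `85+`): `rates.csv` has a `rate` column
#' (deaths per person-year), `population.csv` a `count` column.
#'
#' @param path file path.
#' @param value `"rate"` or `"count"` — the expected value column.
#' @param sep delimiter.
#' @return data frame with columns `sex`, `age_band`, and the value column.
#' @export
read_strata_table <- function(path, value = c("rate", "count"), sep = ",") {
  value <- match.arg(value)
  df <- read_delim_table(path, sep, c("sex", "age_band", value))
  df[[value]] <- as.numeric(df[[value]])
  if (any(is.na(df[[value]])) || any(df[[value]] < 0))
    stop("non-numeric or negative ", value, " in ", path, call. = FALSE)
  if (any(!df$sex %in% SEXES))
    stop("sex must be male/female in ", path, call. = FALSE)
  keep <- c("sex", "age_band", value,
            if ("cause" %in% names(df)) "cause")
  df[keep]
}

#' Expected deaths under indirect standardisation
#'
#' Applies standard (reference-population) death rates to the study
#' population by sex and five-year age band and sums:
#' \eqn{E = \sum_s rate_s \times population_s}.
#'
#' @param rates data frame `sex, age_band, rate`.
#' @param population data frame `sex, age_band, count`.
#' @return the expected number of deaths (scalar).
#' @export
expected_deaths <- function(rates, population) {
  kr <- paste(rates$sex, rates$age_band)
  kp <- paste(population$sex, population$age_band)
  miss <- union(setdiff(kr, kp), setdiff(kp, kr))
  if (length(miss))
    stop("rate/population strata mismatch: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(kr) || anyDuplicated(kp))
    stop("duplicate (sex, age_band) strata", call. = FALSE)
  sum(rates$rate * population$count[match(kr, kp)])
}

#' Standardised mortality ratio with exact gamma confidence interval
#'
#' The SMR is the observed count over the expected count, scaled by 100.
#' Exact limits treat the observed count as Poisson: with `d` observed and
#' expectation `E`, the lower limit is the `alpha/2` quantile of a
#' Gamma(shape = d, scale = 1) divided by `E` (zero when `d = 0`) and the
#' upper limit the `1 - alpha/2` quantile of Gamma(shape = d + 1) divided
#' by `E` — equivalently half the chi-square quantiles at `2d` and
#' `2(d + 1)` degrees of freedom.
#'
#' @param observed non-negative integer count.
#' @param expected positive expected count.
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @param scale 100 for the conventional printed scale; 1 for a plain
#'   ratio.
#' @param stratum optional label carried through to the result.
#' @return data frame of class `smr_result`: `stratum`, `observed`,
#'   `expected`, `smr`, `ci_low`, `ci_high`, `alpha`.
#' @export
smr_with_ci <- function(observed, expected, alpha = 0.05, scale = 100,
                        stratum = NA_character_) {
  if (any(expected <= 0))
    stop("expected deaths must be positive", call. = FALSE)
  if (any(observed < 0) || any(observed != floor(observed)))
    stop("observed must be a non-negative integer count", call. = FALSE)
  n <- max(length(observed), length(expected))
  observed <- rep_len(observed, n); expected <- rep_len(expected, n)
  stratum <- rep_len(stratum, n)
  lo <- ifelse(observed == 0, 0,
               stats::qgamma(alpha / 2, shape = observed) / expected)
  hi <- stats::qgamma(1 - alpha / 2, shape = observed + 1) / expected
  out <- data.frame(stratum = stratum, observed = observed,
                    expected = expected,
                    smr = scale * observed / expected,
                    ci_low = scale * lo, ci_high = scale * hi,
                    alpha = alpha, stringsAsFactors = FALSE)
  class(out) <- c("smr_result", "data.frame")
  out
}

## ---- report tables -------------------------------------------------------

count_by <- function(deaths, results, key) {
  methods <- c("as_reported", "algorithm", "at_least_one")
  ag <- stats::aggregate(results[methods], by = list(stratum = key), FUN = sum)
  ag
}

table1_block <- function(deaths, results, key, levels, axis) {
  key <- as.character(key)
  rows <- lapply(levels, function(lv) {
    sel <- key == lv
    b <- sum(results$as_reported[sel])
    a <- sum(results$algorithm[sel])
    o <- sum(results$at_least_one[sel])
    data.frame(axis = axis, stratum = lv, as_reported = b, algorithm = a,
               algorithm_increase = if (b > 0) percent_increase(b, a) else NA,
               at_least_one = o,
               at_least_one_increase = if (b > 0) percent_increase(b, o)
                                       else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the three report tables for a classified dataset
#'
#' Reproduces the structure of the standard mortality report:
#' \describe{
#'   \item{`counts`}{deaths under each reporting method with percent
#'     increases, stratified by age band, sex, geographic remoteness and
#'     cause-of-death group, plus a Total row. Deaths with Unknown
#'     remoteness are kept in totals but not shown as a remoteness
#'     stratum.}
#'   \item{`median_age`}{median age at death by cause group, remoteness
#'     and overall, for each method, by sex and combined.}
#'   \item{`smr`}{indirectly standardised mortality ratios (x100) with
#'     exact gamma intervals by cause group and overall, for each method,
#'     by sex and combined — only when `rates` and `population` are
#'     supplied.}
#' }
#'
#' @param deaths a `death_records` data frame.
#' @param results the matching `enhancement_results`.
#' @param rates,population optional standardisation tables (see
#'   [read_strata_table()]); sex-specific rates are applied to the
#'   sex-specific population.
#' @param cause_groups named list of [cause_group()]s.
#' @param alpha significance level for the SMR intervals.
#' @return list with elements `counts`, `median_age`, and (if
#'   standardisation inputs given) `smr`.
#' @export
build_tables <- function(deaths, results, rates = NULL, population = NULL,
                         cause_groups = default_cause_groups(),
                         alpha = 0.05) {
  stopifnot(identical(deaths$death_id, results$death_id))
  methods <- c("as_reported", "algorithm", "at_least_one")
  band <- as.character(age_band(deaths$age_years, "counts"))
  cg <- icd10_group_of(deaths$cause_icd10, cause_groups)

  counts <- rbind(
    table1_block(deaths, results, band, age_band_levels("counts"), "age"),
    table1_block(deaths, results, deaths$sex, SEXES, "sex"),
    table1_block(deaths, results, deaths$remoteness,
                 setdiff(REMOTENESS, "Unknown"), "remoteness"),
    table1_block(deaths, results, cg, names(cause_groups), "cause"),
    table1_block(deaths, results, rep("Total", nrow(deaths)), "Total",
                 "total")
  )

  med_block <- function(key, levels, axis) {
    grid <- expand.grid(stratum = levels, method = methods,
                        stringsAsFactors = FALSE)
    grid$axis <- axis
    for (s in c("male", "female", "total")) {
      grid[[s]] <- mapply(function(lv, m) {
        sel <- key == lv & results[[m]] &
          (s == "total" | deaths$sex == s)
        median_age(deaths$age_years[sel])
      }, grid$stratum, grid$method)
    }
    grid[c("axis", "stratum", "method", "male", "female", "total")]
  }
  med <- rbind(
    med_block(cg, names(cause_groups), "cause"),
    med_block(deaths$remoteness, setdiff(REMOTENESS, "Unknown"),
              "remoteness"),
    med_block(rep("Total", nrow(deaths)), "Total", "total")
  )

  out <- list(counts = counts, median_age = med)

  if (!is.null(rates) && !is.null(population)) {
    # cause-specific standard rates via an optional `cause` column; with
    # all-cause rates only, SMRs are computed for the Total cause row
    has_cause <- "cause" %in% names(rates)
    rates_for <- function(cs) {
      if (!has_cause) return(rates)
      rates[rates$cause == cs, setdiff(names(rates), "cause")]
    }
    smr_rows <- list()
    causes <- if (has_cause) intersect(c(names(cause_groups), "Total"),
                                       unique(rates$cause))
              else "Total"
    for (cs in causes) for (m in methods) {
      in_cause <- if (cs == "Total") rep(TRUE, nrow(deaths)) else cg == cs
      for (s in c("male", "female", "total")) {
        sexes <- if (s == "total") SEXES else s
        rt <- rates_for(cs)
        exp_d <- expected_deaths(rt[rt$sex %in% sexes, ],
                                 population[population$sex %in% sexes, ])
        obs <- sum(results[[m]] & in_cause & deaths$sex %in% sexes)
        r <- smr_with_ci(obs, exp_d, alpha = alpha,
                         stratum = paste(cs, m, s, sep = "/"))
        r$cause <- cs; r$method <- m; r$sex <- s
        smr_rows[[length(smr_rows) + 1L]] <- r
      }
    }
    out$smr <- do.call(rbind, smr_rows)
  }
  out
}
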