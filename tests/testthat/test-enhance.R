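# brute-force oracle transcribing the rule text directly
oracle_algorithm <- function(reported, n, k) {
  if (reported == "yes") return(TRUE)
  if (n >= 3) return(k >= 2)
  if (n >= 1) return(k >= 1)
  FALSE
}

test_that("as-reported accepts only an explicit yes", {
  expect_true(classify_as_reported("yes"))
  expect_false(classify_as_reported("no"))
  expect_false(classify_as_reported("missing"))
})

test_that("at-least-one triggers on any reporting unit", {
  expect_true(classify_at_least_one("no", units_nk(5, 1)))
  expect_false(classify_at_least_one("no", units_nk(0, 0)))
  expect_true(classify_at_least_one("yes", units_nk(0, 0)))
  expect_false(classify_at_least_one("no", make_units(rep("missing", 4))))
})

test_that("algorithm thresholds match the stated cases", {
  expect_false(classify_algorithm("no", units_nk(3, 1)))
  expect_true(classify_algorithm("no", units_nk(2, 1)))
  expect_true(classify_algorithm("no", units_nk(5, 2)))
  expect_false(classify_algorithm("no", units_nk(0, 0)))
  expect_true(classify_algorithm("yes", units_nk(0, 0)))
  # missing units carry no information unless explicitly counted
  u <- make_units(c("yes", "missing", "missing"))
  expect_true(classify_algorithm("no", u))   # n = 1, k = 1
  expect_false(classify_algorithm("no", u, count_missing_units = TRUE))
})

test_that("algorithm equals the exhaustive truth-table oracle for n <= 10", {
  for (rep_status in c("yes", "no", "missing"))
    for (n in 0:10) for (k in 0:n) {
      expect_identical(
        classify_algorithm(rep_status, units_nk(n, k)),
        oracle_algorithm(rep_status, n, k),
        label = sprintf("reported=%s n=%d k=%d", rep_status, n, k))
    }
})

test_that("proportion variant respects its threshold and is monotone in it", {
  expect_true(classify_proportion("no", units_nk(4, 2), 0.5))
  expect_false(classify_proportion("no", units_nk(4, 2), 0.75))
  expect_error(classify_proportion("no", units_nk(4, 2), 0), "threshold")
  expect_error(classify_proportion("no", units_nk(4, 2), 1.2), "threshold")
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(0:8, 1); k <- if (n) sample(0:n, 1) else 0
    u <- units_nk(n, k)
    thr <- sort(runif(5, 0.05, 1))
    res <- vapply(thr, function(t) classify_proportion("no", u, t), TRUE)
    expect_true(all(diff(as.integer(res)) <= 0))  # non-increasing
  }
})

test_that("adding a yes unit never flips any classifier to FALSE", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(0:7, 1); k <- if (n) sample(0:n, 1) else 0
    u <- units_nk(n, k)
    u2 <- rbind(u, make_units("yes"))
    for (f in list(classify_at_least_one,
                   function(r, u) classify_algorithm(r, u),
                   function(r, u) classify_proportion(r, u, 0.5))) {
      if (f("no", u)) expect_true(f("no", u2))
    }
  }
})

test_that("enhance_dataset matches per-death application of the classifiers", {
  deaths <- death_records(
    death_id = sprintf("D%03d", 1:10),
    age_years = c(0, 5, 30, 45, 60, 70, 75, 80, 85, 90),
    sex = rep(c("male", "female"), 5),
    remoteness = rep("InnerRegional", 10),
    cause_icd10 = rep(c("C50", "I21"), 5),
    reported_indigenous = c("yes", rep("no", 6), "missing", "no", "no"))
  # hand-built linked evidence with known unit structure
  linked <- rbind_records(
    # D002: one ED yes -> n=1 k=1: both methods
    simple_record("R01", "D002", "EDDC", "yes"),
    # D003: 3 units, 1 yes -> at-least-one only
    simple_record("R02", "D003", "EDDC", "yes"),
    simple_record("R03", "D003", "EDDC", "no"),
    simple_record("R04", "D003", "PDC_mother", "no"),
    # D004: 3 units, 2 yes -> both
    simple_record("R05", "D004", "EDDC", "yes"),
    simple_record("R06", "D004", "EDDC", "yes"),
    simple_record("R07", "D004", "RBDM_mother", "no"),
    # D005: two episodes one stay, flag yes inside -> n=1 k=1
    apd_episode("R08", "D005", "2007-01-01", "2007-01-04", flag = "no",
                facility = "A", transferred_to = "B"),
    apd_episode("R09", "D005", "2007-01-04", "2007-01-09", flag = "yes",
                facility = "B"),
    # D006: all-no evidence
    simple_record("R10", "D006", "EDDC", "no"),
    # D008: reported missing, one yes unit -> both
    simple_record("R11", "D008", "EDDC", "yes"),
    # D009: missing-flag unit only -> nothing
    simple_record("R12", "D009", "EDDC", "missing"))
  res <- enhance_dataset(deaths, linked)
  expect_s3_class(res, "enhancement_results")
  expect_equal(res$death_id, deaths$death_id)

  # oracle: apply the three classifiers independently per death
  for (i in seq_len(nrow(deaths))) {
    u <- derive_units(deaths$death_id[i],
                      linked[linked$death_id == deaths$death_id[i], ])
    r <- deaths$reported_indigenous[i]
    expect_identical(res$as_reported[i], classify_as_reported(r))
    expect_identical(res$at_least_one[i], classify_at_least_one(r, u))
    expect_identical(res$algorithm[i], classify_algorithm(r, u))
  }
  expect_equal(unname(method_counts(res)),
               c(1L, 5L, 6L))  # as_reported, algorithm, at_least_one
  expect_equal(res$n_units[res$death_id == "D005"], 1L)
  expect_equal(res$n_units[res$death_id == "D009"], 0L)
})

test_that("classifier ordering and idempotence hold on the fixture", {
  deaths <- fix_deaths(6, reported = c("yes", "no", "no", "no", "missing",
                                       "no"))
  linked <- rbind_records(
    simple_record("R1", "D002", "EDDC", "yes"),
    simple_record("R2", "D004", "EDDC", "yes"),
    simple_record("R3", "D004", "EDDC", "no"),
    simple_record("R4", "D004", "PDC_mother", "no"))
  res <- enhance_dataset(deaths, linked)
  cnt <- method_counts(res)
  expect_lte(cnt[["as_reported"]], cnt[["algorithm"]])
  expect_lte(cnt[["algorithm"]], cnt[["at_least_one"]])
  expect_true(all(!res$as_reported | res$algorithm))
  expect_true(all(!res$algorithm | res$at_least_one))

  # idempotence: feeding enhanced status back as the reported flag and
  # re-running changes nothing
  d2 <- deaths
  d2$reported_indigenous <- ifelse(res$algorithm, "yes", "no")
  res2 <- enhance_dataset(d2, linked)
  expect_equal(res2$algorithm, res$algorithm)
})

test_that("degenerate datasets give equal or zero counts", {
  deaths <- fix_deaths(4, reported = "yes")
  res <- enhance_dataset(deaths, linked_records(character(), character(),
                                                character(), character()))
  expect_equal(unname(method_counts(res)), c(4L, 4L, 4L))

  deaths2 <- fix_deaths(4, reported = "no")
  linked2 <- simple_record("R1", "D001", "EDDC", "no")
  expect_equal(unname(method_counts(enhance_dataset(deaths2, linked2))),
               c(0L, 0L, 0L))
})

test_that("unlinked residue is dropped with a warning", {
  deaths <- fix_deaths(2)
  linked <- simple_record(c("R1", "R2"), c("D001", "D999"), "EDDC", "yes")
  expect_warning(res <- enhance_dataset(deaths, linked),
                 "unknown death_id")
  expect_true(res$at_least_one[1])
  expect_equal(sum(res$n_units), 1L)
})

test_that("proportion column and raw-record method 1 switches work", {
  deaths <- fix_deaths(2)
  linked <- rbind_records(
    simple_record("R1", "D001", "EDDC", "yes"),
    simple_record("R2", "D001", "EDDC", "no"),
    simple_record("R3", "D001", "EDDC", "no"),
    simple_record("R4", "D001", "EDDC", "no"))
  res <- enhance_dataset(deaths, linked, proportion_threshold = 0.5)
  expect_false(res$proportion[1])  # 1/4 < 0.5
  expect_true(res$at_least_one[1])

  res2 <- enhance_dataset(deaths, linked,
                          enhance_config(method1_on_raw_records = TRUE))
  expect_equal(res2$at_least_one, res$at_least_one)
})
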