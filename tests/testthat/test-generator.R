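test_that("identical configs and seeds reproduce identical tables", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  expect_identical(as.data.frame(a$labs), as.data.frame(b$labs))
  expect_identical(as.data.frame(a$patients), as.data.frame(b$patients))
  expect_identical(as.data.frame(a$ground_truth), as.data.frame(b$ground_truth))
  c <- tiny_cohort(seed = 12)
  expect_false(identical(as.data.frame(a$labs), as.data.frame(c$labs)))
})

test_that("trajectory deterministic limits are exact", {
  days <- seq(0, 900, by = 30)
  flat <- simulate_trajectory(days, baseline = 80, slope = 0)
  expect_equal(flat$egfr, rep(80, length(days)))
  two <- simulate_trajectory(days, baseline = 80, slope = 0,
                             episode_day = 450, rapid_slope = -10)
  expect_equal(two$egfr, piecewise_series(days, 80, 0, -10, 450))
  expect_error(simulate_trajectory(c(5, 1), 80, 0), "sorted")
})

test_that("measurement noise has the stated zero-mean Gaussian structure", {
  set.seed(42)
  days <- seq_len(10000)
  tr <- simulate_trajectory(days, baseline = 80, slope = 0, noise_sd = 3)
  resid <- tr$egfr - tr$noise_free
  expect_lt(abs(mean(resid)), 3 * 3 / sqrt(10000))
  expect_equal(sd(resid), 3, tolerance = 0.1)
  expect_true(all(tr$egfr >= 1))
})

test_that("dialysis censors every later observation", {
  co <- generate_cohort(generator_config(
    n_patients = 80, n_tests = 4, baseline_egfr_mean = 30,
    baseline_egfr_sd = 5, rd_fraction = 0.8, dialysis_egfr_threshold = 20,
    seed = 3))
  dial <- co$ground_truth[!is.na(co$ground_truth$dialysis_date), ]
  expect_gt(nrow(dial), 0)
  for (i in seq_len(nrow(dial))) {
    rows <- co$labs[co$labs$patient_id == dial$patient_id[i], ]
    expect_true(all(rows$date <= dial$dialysis_date[i]))
  }
  expect_identical(co$patients$dialysis_date[match(dial$patient_id,
                                                   co$patients$patient_id)],
                   dial$dialysis_date)
})

test_that("ground-truth structure follows the configuration", {
  none <- generate_cohort(generator_config(n_patients = 40, n_tests = 4,
                                           rd_fraction = 0, seed = 5))
  expect_false(any(none$ground_truth$rd_planted))

  gone <- generate_cohort(generator_config(
    n_patients = 20, n_tests = 4, seed = 5,
    informative_tests = "LAB001",
    missing_rate_per_test = c(LAB002 = 1)))
  expect_false("LAB002" %in% gone$labs$test_code)
  expect_true("LAB001" %in% gone$labs$test_code)

  planted <- lapply(1:20, function(s)
    generate_cohort(generator_config(n_patients = 500, n_tests = 4,
                                     rd_fraction = 0.3,
                                     seed = s))$ground_truth$rd_planted)
  expect_equal(mean(unlist(planted)), 0.3, tolerance = 0.05 / 0.3)

  withep <- tiny_cohort(seed = 8, rd_fraction = 1)
  ep <- withep$ground_truth$episode_start
  expect_true(all(ep > withep$config$study_start & ep < withep$config$study_end))
})

test_that("eGFR and creatinine rows are mutually consistent", {
  co <- tiny_cohort(seed = 21)
  labs <- as.data.frame(co$labs)
  eg <- labs[labs$test_code == "eGFR", c("patient_id", "date", "value")]
  cre <- labs[labs$test_code == "Cre", c("patient_id", "date", "value")]
  both <- merge(eg, cre, by = c("patient_id", "date"),
                suffixes = c("_egfr", "_cre"))
  expect_gt(nrow(both), 100)
  pat <- co$patients[match(both$patient_id, co$patients$patient_id), ]
  age <- as.numeric(both$date - pat$birth_date) / 365.25
  expect_equal(egfr_from_creatinine(both$value_cre, age, pat$sex),
               both$value_egfr, tolerance = 1e-9)
})

test_that("noise tests carry no signal about the planted episodes", {
  co <- generate_cohort(generator_config(n_patients = 150, n_tests = 5,
                                         informative_tests = "LAB001",
                                         seed = 31))
  labs <- as.data.frame(co$labs)
  noise_mean <- tapply(labs$value[labs$test_code == "LAB003"],
                       labs$patient_id[labs$test_code == "LAB003"], mean)
  gt <- co$ground_truth$rd_planted[match(names(noise_mean),
                                         co$ground_truth$patient_id)]
  obs <- abs(cor(noise_mean, gt))
  set.seed(1)
  null <- replicate(400, abs(cor(noise_mean, sample(gt))))
  expect_gt(mean(null >= obs), 0.01)

  # while the informative test does separate the groups
  inf_mean <- tapply(labs$value[labs$test_code == "LAB001"],
                     labs$patient_id[labs$test_code == "LAB001"], mean)
  gt2 <- co$ground_truth$rd_planted[match(names(inf_mean),
                                          co$ground_truth$patient_id)]
  expect_lt(wilcox.test(inf_mean[gt2], inf_mean[!gt2])$p.value, 1e-4)
})
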