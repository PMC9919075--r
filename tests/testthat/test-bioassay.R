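test_that("inhibition rate reproduces its defining identities", {
  expect_equal(inhibition_rate(0.8, 0.1, 0.9, 0.2), 0)    # Asa-Asc = Aea-Aec
  expect_equal(inhibition_rate(0.3, 0.3, 0.9, 0.2), 100)  # Asa = Asc
  # sample interference can push the rate negative; it is not clamped
  expect_equal(inhibition_rate(1.25, 0.2, 0.9, 0.2), -50)
  expect_error(inhibition_rate(0.5, 0.1, 0.2, 0.2), "Aea")
  expect_error(inhibition_rate(Inf, 0.1, 0.9, 0.2), "finite")
})

test_that("inhibition rate is invariant to a common absorbance offset", {
  set.seed(3)
  for (i in 1:20) {
    q <- runif(4, 0.1, 1.5)
    if (q[3] - q[4] <= 0) q[3] <- q[4] + runif(1, 0.1, 1)
    shift <- runif(1, -0.5, 0.5)
    expect_equal(inhibition_rate(q[1], q[2], q[3], q[4]),
                 inhibition_rate(q[1] + shift, q[2] + shift,
                                 q[3] + shift, q[4] + shift),
                 tolerance = 1e-9)
  }
})

test_that("noiseless 4PL data is recovered to high relative accuracy", {
  conc <- c(12.5, 25, 50, 100, 200, 400, 800)
  d <- gen_dose_response(100, 1, 0, 100, conc, noise_sd = 0, replicates = 1)
  fit <- fit_four_pl(d$concentration, d$inhibition)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 100, tolerance = 1e-4)
  # all four parameters, across the plausible hill range
  for (h in c(0.5, 1, 2, 4)) {
    d <- gen_dose_response(60, h, 5, 95, conc, noise_sd = 0, replicates = 1)
    f <- fit_four_pl(d$concentration, d$inhibition)
    expect_true(f$converged)
    expect_equal(f$ic50, 60, tolerance = 1e-3)
    expect_equal(f$hill, h, tolerance = 1e-3)
    expect_equal(f$bottom, 5, tolerance = 1e-2)
    expect_equal(f$top, 95, tolerance = 1e-2)
  }
})

test_that("degenerate dose-response inputs are flagged, not fit", {
  conc <- c(10, 20, 40, 80)
  flat <- fit_four_pl(conc, rep(50, 4))
  expect_false(flat$converged)
  low <- fit_four_pl(conc, c(-5, 2, 4, 8))   # nothing above 10% inhibition
  expect_false(low$converged)
  expect_error(fit_four_pl(c(10, 10, 20, 20), c(1, 2, 3, 4)), "distinct")
})

test_that("replicate IC50 summaries mirror the published mean +/- sd style", {
  fits <- lapply(c(60, 65, 70), function(v) {
    structure(list(ic50 = v, converged = TRUE), class = "four_pl_fit")
  })
  s <- summarize_ic50(fits)
  expect_equal(s$mean, 65)
  expect_equal(s$sd, 5)
  single <- summarize_ic50(fits[1])
  expect_equal(single$mean, 60)
  expect_true(is.na(single$sd))
  dead <- summarize_ic50(list(structure(list(converged = FALSE),
                                        class = "four_pl_fit")))
  expect_true(is.na(dead$mean))
  expect_match(dead$reason, "no converged")
})

test_that("the MIC is read off the dilution plate correctly", {
  # growth pattern clear down to 0.20 mg/mL, growth below
  plate <- gen_mic_plate(0.20)
  r <- read_mic(plate)
  expect_equal(r$mic, 0.20)
  expect_equal(r$censored, "none")

  all_growth <- gen_mic_plate(10)
  ra <- read_mic(all_growth)
  expect_true(is.na(ra$mic))
  expect_equal(ra$censored, "above")
  expect_equal(ra$label, ">3.12")

  all_clear <- gen_mic_plate(0.0125)
  rc <- read_mic(all_clear)
  expect_equal(rc$mic, 0.0125)
  expect_equal(rc$censored, "below")
})

test_that("MIC reading round-trips every series position and random plates", {
  for (m in mic_dilution_series) {
    expect_equal(read_mic(gen_mic_plate(m))$mic, m)
  }
  set.seed(14)
  for (i in 1:50) {
    m <- sample(mic_dilution_series, 1)
    expect_equal(read_mic(gen_mic_plate(m))$mic, m)
  }
})

test_that("plate errors are rejected with informative messages", {
  plate <- gen_mic_plate(0.20)
  plate$growth[2] <- TRUE     # growth at 1.56 above a clear 0.78 well
  expect_error(read_mic(plate), "non-monotone")
  bad_ctl <- gen_mic_plate(0.20)
  bad_ctl$controls$positive <- FALSE
  expect_error(read_mic(bad_ctl), "control")
})

test_that("zone summaries use the n-1 sd and two-decimal label", {
  z <- zone_summary(c(9.0, 9.8, 10.0))
  expect_equal(z$mean, 9.6)
  expect_equal(z$sd, sd(c(9.0, 9.8, 10.0)))
  expect_equal(z$label, sprintf("%.2f ± %.2f", 9.6, z$sd))
  expect_equal(zone_summary(c(8, 8, 8))$sd, 0)
  expect_equal(zone_summary(c(9.78 - 0.72, 9.78, 9.78 + 0.72))$label,
               "9.78 ± 0.72")
})

test_that("activity tables carry direction metadata and missing masks", {
  ids <- sprintf("S%d", 1:10)
  zones <- setNames(seq(7, 16), ids)
  ic50 <- setNames(c(258.93, 160.67, 394.17, 180.73, 596.93, NA, NA,
                     1193.00, 250.10, 261.23), ids)
  act <- build_activity_table(list(
    zone_ecoli = list(values = zones, direction = "higher_is_active"),
    ic50_amylase = list(values = ic50[!is.na(ic50)],
                        direction = "lower_is_active")))
  expect_equal(dim(act$values), c(10L, 2L))
  expect_equal(sum(is.na(act$values[, "ic50_amylase"])), 2L)
  expect_true(all(is.na(act$values[c("S6", "S7"), "ic50_amylase"])))

  empty <- build_activity_table(list())
  expect_equal(dim(empty$values), c(0L, 0L))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(act, path)
  back <- read_activity_table(path)
  expect_equal(back$values, act$values)
  expect_equal(back$direction, act$direction)

  expect_error(build_activity_table(list(
    e = list(values = c(S1 = 1, S1 = 2), direction = "higher_is_active"))),
    "conflicting")
  expect_error(build_activity_table(list(
    e = list(values = c(S1 = 1), direction = "sideways"))), "direction")
})

test_that("the shipped ten-extract endpoint panel loads as expected", {
  panel <- read_activity_table(
    system.file("extdata", "extract_activity_endpoints.tsv",
                package = "speceffect"))
  expect_equal(dim(panel$values), c(10L, 8L))
  expect_equal(sum(panel$direction == "higher_is_active"), 6L)
  expect_equal(sum(panel$direction == "lower_is_active"), 2L)
  # the amylase IC50 could not be determined for the two sugar-rich extracts
  expect_true(all(is.na(panel$values[c("S6", "S7"), "ic50_amylase"])))
  expect_equal(sum(is.na(panel$values)), 2L)

  seqs <- build_characteristic_sequences(panel)
  expect_length(seqs$ic50_amylase$values, 8)
  expect_setequal(seqs$ic50_amylase$dropped, c("S6", "S7"))
  # the most potent glucosidase inhibitor leads the reciprocal sequence
  expect_equal(names(which.max(seqs$ic50_glucosidase$values)), "S10")
})
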