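censored_set <- function() {
  tibble::tibble(
    medium = "water",
    value = c(1, 2, NA, 3, NA),
    detected = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    lod_low = c(NA, NA, 0.5, NA, 0.5),
    lod_high = c(NA, NA, 0.5, NA, 0.5)
  )
}

test_that("fully detected samples give the same mean under every policy", {
  s <- tibble::tibble(
    medium = "water", value = c(1, 2, 3), detected = TRUE,
    lod_low = 0.1, lod_high = 0.1
  )
  for (p in c("exclude", "lod_over_sqrt2", "half_lod_split", "zero")) {
    out <- summarize_concentrations(s, p)
    expect_equal(out$mean, 2.0)
    expect_equal(out$pct_above_lod, 100)
    expect_true(out$mean_defined)
  }
})

test_that("censoring substitutions follow the stated policies", {
  s <- censored_set()
  # exclude: detects only
  expect_equal(summarize_concentrations(s, "exclude")$mean, 2)
  # zero substitution
  expect_equal(summarize_concentrations(s, "zero")$mean, 6 / 5)
  # LOD/sqrt(2)
  expect_equal(
    summarize_concentrations(s, "lod_over_sqrt2")$mean,
    (6 + 2 * 0.5 / sqrt(2)) / 5
  )
  one <- tibble::tibble(
    medium = "breastmilk", value = NA_real_, detected = FALSE,
    lod_low = 6.18e-7, lod_high = 6.18e-7
  )
  expect_equal(
    summarize_concentrations(one, "lod_over_sqrt2")$mean,
    4.370e-7,
    tolerance = 1e-4
  )
  # half/half split: first half (input order) gets the LOD, rest LOD/2
  two <- tibble::tibble(
    medium = "water", value = c(NA, NA), detected = FALSE,
    lod_low = 0.05, lod_high = 0.05
  )
  expect_equal(summarize_concentrations(two, "half_lod_split")$mean, 0.0375)
  # odd censored count: the extra sample gets the full LOD
  three <- dplyr::bind_rows(two, two[1, ])
  expect_equal(
    summarize_concentrations(three, "half_lod_split")$mean,
    mean(c(0.05, 0.05, 0.025))
  )
})

test_that("LOD ranges substitute at their midpoint", {
  s <- tibble::tibble(
    medium = "dairy", value = NA_real_, detected = FALSE,
    lod_low = 3e-4, lod_high = 4e-4
  )
  expect_equal(
    summarize_concentrations(s, "lod_over_sqrt2")$mean,
    3.5e-4 / sqrt(2)
  )
})

test_that("all-censored input under exclude flags the mean undefined", {
  s <- tibble::tibble(
    medium = "water", value = NA_real_, detected = FALSE,
    lod_low = 0.1, lod_high = 0.1
  )
  out <- summarize_concentrations(s, "exclude")
  expect_false(out$mean_defined)
  expect_true(is.na(out$mean))
  expect_equal(out$pct_above_lod, 0)
})

test_that("substitution policies are ordered: zero <= LOD/sqrt2 <= all-LOD", {
  for (seed in 1:5) {
    s <- simulate_concentration_samples(
      n = 60, censoring_fraction = 0.3, seed = seed
    )
    m_zero <- summarize_concentrations(s, "zero")$mean
    m_sqrt2 <- summarize_concentrations(s, "lod_over_sqrt2")$mean
    m_split <- summarize_concentrations(s, "half_lod_split")$mean
    # all-LOD upper bound: every censored sample at the full LOD
    s_hi <- s
    s_hi$value[!s_hi$detected] <- s_hi$lod_low[!s_hi$detected]
    s_hi$detected <- TRUE
    m_hi <- summarize_concentrations(s_hi, "exclude")$mean
    expect_lte(m_zero, m_sqrt2)
    expect_lte(m_sqrt2, m_hi)
    expect_lte(m_split, m_hi)
    expect_gte(m_split, m_zero)
  }
})

test_that("input guards reject mixed media and valueless detects", {
  s <- censored_set()
  expect_error(
    summarize_concentrations(dplyr::mutate(s, medium = c("water", "soil", "water", "water", "water"))),
    "single medium"
  )
  bad <- s
  bad$value[1] <- NA
  expect_error(summarize_concentrations(bad), "detected samples")
  nolod <- s
  nolod$lod_low <- NA
  nolod$lod_high <- NA
  expect_error(summarize_concentrations(nolod, "lod_over_sqrt2"), "usable LOD")
})

test_that("metabolite sums behave as proxy concentrations", {
  expect_equal(
    metabolite_sum_proxy(tibble::tibble(name = "a", mean = 0), "breastmilk")$mean,
    0
  )
  out <- metabolite_sum_proxy(
    tibble::tibble(name = c("m1", "m2"), mean = c(2e-4, 5e-4)), "breastmilk"
  )
  expect_equal(out$mean, 7e-4)
  expect_match(out$source, "m1 \\+ m2")
  expect_error(metabolite_sum_proxy(tibble::tibble(name = character(), mean = numeric()), "x"), "at least one")
  # three components reproducing the packaged breastmilk mean stay consistent
  comp <- tibble::tibble(name = c("MEHP", "MEOHP", "MEHHP"), mean = c(5.0e-4, 1.2e-4, 8.7e-5))
  expect_equal(
    metabolite_sum_proxy(comp, "breastmilk")$mean,
    load_fixture("dehp")$mean[load_fixture("dehp")$medium == "breastmilk"]
  )
})

test_that("packaged concentration tables match their published summary statistics", {
  dehp <- load_fixture("dehp")
  expect_equal(nrow(dehp), 10)
  expect_setequal(dehp$medium, media_roster()$medium)
  key_dehp <- tibble::tribble(
    ~medium, ~mean, ~median, ~sd, ~n,
    "dust", 9.73e-2, 7.31e-2, 1.11e-1, 11L,
    "soil", 9.39e-3, 8.63e-3, 2.19e-3, 6L,
    "water", 2.56e-6, NA_real_, NA_real_, 15L,
    "breastmilk", 7.07e-4, 1.91e-4, 8.87e-4, 21L,
    "dairy", 1.26e-4, 6.97e-5, 1.25e-4, 11L,
    "meat", 1.01e-4, 7.00e-6, 3.18e-4, 13L,
    "fish", 3.14e-5, 3.96e-5, 2.60e-5, 5L,
    "vegetables", 5.09e-6, 1.85e-6, 8.70e-6, 5L,
    "fruit", 5.09e-6, 1.85e-6, 8.70e-6, 5L,
    "grains", 6.16e-5, 5.06e-5, 4.25e-5, 7L
  )
  got <- dehp[match(key_dehp$medium, dehp$medium), c("medium", "mean", "median", "sd", "n")]
  expect_equal(as.data.frame(got), as.data.frame(key_dehp))

  mn <- load_fixture("manganese")
  expect_equal(mn$mean[mn$medium == "water"], 6.35e-5)
  expect_equal(mn$mean[mn$medium == "grains"], 7.34e-3)
  expect_equal(mn$mean[mn$medium == "soil"], 3.41e-1)
  expect_equal(mn$mean[mn$medium == "dust"], 2.22e-1)
  expect_equal(mn$mean[mn$medium == "breastmilk"], 2.71e-6)
  expect_equal(mn$n[mn$medium == "meat"], 1725L)

  pre <- load_fixture("endosulfan_pre")
  expect_equal(nrow(pre), 6)
  expect_setequal(pre$medium, c("dairy", "meat", "fish", "vegetables", "fruit", "grains"))
  expect_equal(pre$mean[pre$medium == "vegetables"], 3.80e-5)
  expect_equal(pre$mean[pre$medium == "grains"], 2.00e-6)

  post <- load_fixture("endosulfan_post")
  expect_equal(nrow(post), 2)
  expect_setequal(post$medium, c("vegetables", "fruit"))
  expect_equal(post$mean[post$medium == "vegetables"], 2.53e-5)
  expect_equal(post$mean[post$medium == "fruit"], 2.26e-5)

  expect_error(load_fixture("caffeine"))
})

test_that("the sample generator is reproducible and censors the stated fraction", {
  a <- simulate_concentration_samples(100, censoring_fraction = 0.25, seed = 99)
  b <- simulate_concentration_samples(100, censoring_fraction = 0.25, seed = 99)
  expect_identical(a, b)
  expect_equal(sum(!a$detected), 25)
  expect_true(all(is.na(a$value[!a$detected])))
  expect_true(all(a$value[a$detected] > a$lod_low[!a$detected][1]))
  expect_error(simulate_concentration_samples(10, censoring_fraction = 1.5), "censoring_fraction")

  # fully censored set has no defined mean under exclusion
  full <- simulate_concentration_samples(20, censoring_fraction = 1, seed = 4)
  expect_false(summarize_concentrations(full, "exclude")$mean_defined)
})

test_that("uncensored simulated means recover the closed-form lognormal mean", {
  mu <- log(1e-3)
  sigma <- 0.8
  s <- simulate_concentration_samples(
    n = 10000, censoring_fraction = 0,
    meanlog = mu, sdlog = sigma, seed = 21
  )
  out <- summarize_concentrations(s, "exclude")
  true_mean <- exp(mu + sigma^2 / 2)
  se <- stats::sd(s$value) / sqrt(nrow(s))
  expect_lt(abs(out$mean - true_mean), 3 * se)
  expect_equal(attr(s, "true_mean"), true_mean)
})

test_that("synthetic exposure factors keep structure and respond to seed", {
  f1 <- simulate_exposure_factors(seed = 5)
  f2 <- simulate_exposure_factors(seed = 5)
  f3 <- simulate_exposure_factors(seed = 6)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  base <- default_exposure_factors()
  # structural zeros survive the jitter
  zero_base <- base$intake_rate == 0
  expect_true(all(f1$intake_rate[zero_base] == 0))
  expect_true(all(f1$intake_rate[!zero_base] > 0))
  expect_equal(f1$exposure_frequency, base$exposure_frequency)
  expect_equal(f1$averaging_time, base$averaging_time)
})

test_that("bundled factors cover the full grid with the newborn soil/dust zero rule", {
  fac <- default_exposure_factors()
  expect_equal(nrow(fac), 110)
  expect_false(any(duplicated(fac[, c("medium", "age_group")])))
  newborn <- fac[fac$age_group == "birth_to_1mo" & fac$medium %in% c("soil", "dust"), ]
  expect_equal(newborn$intake_rate, c(0, 0))
  expect_true(all(fac$body_weight > 0))
  expect_true(all(fac$averaging_time > 0))
  # chronic scenario: AT = ED x 365
  expect_equal(fac$averaging_time, fac$exposure_duration * 365)
  # round-trips through the factor CSV interface
  path <- tempfile(fileext = ".csv")
  readr::write_csv(fac, path)
  expect_equal(as.data.frame(read_exposure_factors(path)), as.data.frame(fac))
})
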