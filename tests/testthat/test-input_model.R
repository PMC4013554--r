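test_that("build_trend interpolates and extrapolates linearly", {
  pts <- data.frame(year = c(1992, 2002), prevalence = c(0.20, 0.30))
  tr <- build_trend(pts, 1992:2012)
  # frozen from an independent two-point line evaluation
  expect_equal(tr$value[tr$year == 1997],
               line_eval(1992, 0.20, 2002, 0.30, 1997))  # 0.25
  expect_equal(tr$value[tr$year == 2012],
               line_eval(1992, 0.20, 2002, 0.30, 2012))  # 0.40
  expect_equal(tr$value[tr$year == 1997], 0.25)
  expect_equal(tr$value[tr$year == 2012], 0.40)
})

test_that("a single survey point yields a constant series", {
  tr <- build_trend(data.frame(year = 1992, prevalence = 0.20), 1992:2012)
  expect_true(all(tr$value == 0.20))
})

test_that("extrapolated values are clamped to [0, 1]", {
  pts <- data.frame(year = c(1992, 2002), prevalence = c(0.90, 0.99))
  tr <- build_trend(pts, 1992:2022)
  expect_equal(tr$value[tr$year == 2022], 1.00)  # not 1.08
  expect_true(all(tr$value >= 0 & tr$value <= 1))
})

test_that("extrapolation uses the overall first-to-last slope with 3 points", {
  # uneven spacing: segments have different slopes
  pts <- data.frame(year = c(1992, 1997, 2005),
                    prevalence = c(0.20, 0.22, 0.345))
  tr <- build_trend(pts, 1992:2022)
  overall <- (0.345 - 0.20) / (2005 - 1992)
  expect_equal(tr$value[tr$year == 2010], 0.345 + 5 * overall)
  # interior years follow the local segment, not the overall slope
  expect_equal(tr$value[tr$year == 1994],
               line_eval(1992, 0.20, 1997, 0.22, 1994))
})

test_that("build_trend reproduces survey points and stays in range (property)", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    yrs <- sort(sample(1992:2012, n))
    pv <- runif(n)
    tr <- build_trend(data.frame(year = yrs, prevalence = pv), 1985:2040)
    expect_equal(tr$value[match(yrs, tr$year)], pv, tolerance = 1e-12)
    expect_true(all(tr$value >= 0 & tr$value <= 1))
  }
})

test_that("build_trend rejects empty and duplicated inputs", {
  expect_error(build_trend(data.frame(year = integer(), prevalence = numeric()),
                           1992:2000))
  expect_error(build_trend(data.frame(year = c(1992, 1992),
                                      prevalence = c(0.1, 0.2)), 1992:2000),
               "duplicate")
})

test_that("apply_cap caps, leaves small values alone, and is idempotent", {
  tr <- build_trend(data.frame(year = c(1992, 2002),
                               prevalence = c(0.40, 0.70)), 1992:2012)
  capped <- apply_cap(tr, 0.60)
  expect_true(all(capped$value <= 0.60))
  expect_equal(apply_cap(capped, 0.60), capped)
  # published cap examples: 0.62 under the female cap, 0.345 under the male
  s <- data.frame(year = 1:2, value = c(0.62, 0.345))
  expect_equal(apply_cap(s, 0.60)$value[1], 0.60)
  expect_equal(apply_cap(s, 0.35)$value[2], 0.345)
  z <- data.frame(year = 1:3, value = 0)
  expect_equal(apply_cap(z, 0.35)$value, c(0, 0, 0))
})

test_that("capped series is pointwise below uncapped, equal before binding", {
  pts <- data.frame(year = c(1992, 2005), prevalence = c(0.30, 0.588))
  tr <- build_trend(pts, 1992:2022)
  capped <- apply_cap(tr, 0.60)
  expect_true(all(capped$value <= tr$value))
  bind <- which(tr$value > 0.60)[1]
  expect_equal(capped$value[seq_len(bind - 1)], tr$value[seq_len(bind - 1)])
})

test_that("validate_inputs passes a clean bundle and names violations", {
  b <- default_bundle()
  rep <- validate_inputs(b$hazards, b$baseline, b$population, b$surveys,
                         b$config)
  expect_equal(nrow(rep), 0)

  # negative incidence for one stratum is reported with stratum and field
  bad <- b
  bad$hazards$rates$incidence[1] <- -1
  rep <- validate_inputs(bad$hazards, b$baseline, b$population, b$surveys,
                         b$config)
  expect_equal(nrow(rep), 1)
  expect_match(rep$message, "incidence")
  expect_equal(rep$where, "male:25-34")

  # a missing population year is reported as a coverage gap
  bad <- b
  bad$population <- b$population[b$population$year != 2000, ]
  rep <- validate_inputs(b$hazards, b$baseline, bad$population, b$surveys,
                         b$config)
  expect_equal(nrow(rep), 12)
  expect_true(all(grepl("^2000 ", rep$where)))
})

test_that("model_config enforces its invariants", {
  expect_error(model_config(start_year = 2000, end_year = 1999))
  expect_error(model_config(extremes_factor = 1.2))
  expect_error(model_config(cap_male = 0))
  cfg <- model_config()
  expect_equal(cfg$extremes_factor, 0.20)
  expect_equal(cfg$cap_male, 0.35)
  expect_equal(cfg$cap_female, 0.60)
})

test_that("input bundles round-trip through the CSV + config interface", {
  b <- default_bundle(seed = 3L)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$baseline$prevalence, b$baseline$prevalence)
  expect_equal(b2$population$population, b$population$population)
  expect_equal(b2$surveys$prevalence, b$surveys$prevalence)
  expect_equal(b2$hazards$rates, b$hazards$rates)
  expect_equal(b2$hazards$rr, b$hazards$rr)
  expect_equal(b2$config$start_year, b$config$start_year)
  expect_equal(run_model(b2$config, b2)$prevalence,
               run_model(b$config, b)$prevalence)
})
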