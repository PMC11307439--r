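test_that("the shipped model has the published structure", {
  m <- published_vat_model()
  expect_equal(m$constant, 249)
  expect_length(m$basis_functions, 7L)
  degrees <- vapply(m$basis_functions, function(bf) length(bf$factors),
                    integer(1))
  expect_identical(max(degrees), 2L)
  expect_setequal(m$predictors, c("sex", "wc", "hc", "bmi"))
})

test_that("basis-function contributions match hand evaluation", {
  m <- published_vat_model()
  bf <- m$basis_functions
  fem <- subject_record(sex = "female", wc = 120, hc = 100, height = 170,
                        weight = 26 * 1.7^2)
  expect_equal(evaluate_basis(bf[[1]], fem), -79.9)                 # BF1
  expect_equal(evaluate_basis(bf[[2]], fem), 0)                     # WC 120
  rec <- subject_record(sex = "male", wc = 100, hc = 100, height = 170,
                        weight = 26 * 1.7^2)
  expect_equal(evaluate_basis(bf[[7]], rec), 0.459 * 11 * 2.4,
               tolerance = 1e-12)                                   # 12.1176
  expect_error(evaluate_basis(bf[[2]], data.frame(sex = "male")),
               "missing predictor 'wc'")
})

test_that("predictions reproduce hand-evaluated examples", {
  m <- published_vat_model()
  coh <- fixture_cohort3()
  expect_equal(predict_vat(m, coh[1, ]), 249)        # all hinges vanish
  expect_equal(predict_vat(m, coh[2, ]), 58.9756, tolerance = 1e-10)
  expect_equal(predict_vat(m, coh[3, ]), 233.34, tolerance = 1e-10)
  expect_equal(predict_vat(m, coh), c(249, 58.9756, 233.34),
               tolerance = 1e-10)
})

test_that("predictions equal the flat oracle expression on random inputs", {
  m <- published_vat_model()
  d <- random_records(10000, seed = 42)
  expect_equal(predict_vat(m, d, check_range = FALSE), flat_vat_oracle(d),
               tolerance = 1e-12)
})

test_that("the prediction surface is continuous and piecewise linear", {
  m <- published_vat_model()
  base <- list(sex = "female", hc = 100, height = 170)
  at <- function(wc, bmi_v, hc = 100, sex = "female") {
    predict_vat(m, data.frame(sex = sex, wc = wc, hc = hc,
                              bmi = bmi_v), check_range = FALSE)
  }
  eps <- 1e-8
  # continuity at every knot
  for (k in c(25.9, 28.4, 29)) {
    expect_equal(at(100, k - eps), at(100, k + eps), tolerance = 1e-5)
  }
  expect_equal(at(111 - eps, 26), at(111 + eps, 26), tolerance = 1e-5)
  expect_equal(at(100, 26, hc = 106 - eps), at(100, 26, hc = 106 + eps),
               tolerance = 1e-5)
  # second differences vanish away from knots
  for (b0 in c(20, 27, 31)) {
    d2 <- at(100, b0 + 0.2) - 2 * at(100, b0 + 0.1) + at(100, b0)
    expect_equal(d2, 0, tolerance = 1e-9)
  }
})

test_that("female-male offset is exactly -79.9 once BMI is at least 29", {
  m <- published_vat_model()
  grid <- expand.grid(wc = c(80, 105, 120), hc = c(90, 110),
                      bmi = c(29, 33, 40))
  f <- predict_vat(m, data.frame(sex = "female", grid), check_range = FALSE)
  g <- predict_vat(m, data.frame(sex = "male", grid), check_range = FALSE)
  expect_equal(f - g, rep(-79.9, nrow(grid)), tolerance = 1e-12)
})

test_that("explicit bmi column is honoured, computed bmi wins conflicts", {
  m <- published_vat_model()
  # bmi supplied without height/weight
  expect_equal(predict_vat(m, data.frame(sex = "male", wc = 111, hc = 106,
                                         bmi = 25.9)), 249)
  # conflicting explicit bmi loses, with a warning
  rec <- data.frame(sex = "male", wc = 111, hc = 106, height = 175,
                    weight = 25.9 * 1.75^2, bmi = 40)
  expect_warning(p <- predict_vat(m, rec), "bmi differs")
  expect_equal(p, 249)
})

test_that("batch prediction preserves order and reports skipped rows", {
  m <- published_vat_model()
  coh <- fixture_cohort3()
  expect_equal(as.numeric(predict_vat_batch(m, coh)),
               c(249, 58.9756, 233.34), tolerance = 1e-10)
  # missing hc in row 2 is skipped with a reason
  coh2 <- coh
  coh2$hc[2] <- NA
  out <- predict_vat_batch(m, coh2, on_invalid = "skip")
  expect_equal(as.numeric(out), c(249, 233.34), tolerance = 1e-10)
  expect_identical(attr(out, "skipped")$row, 2L)
  expect_match(attr(out, "skipped")$reason, "hc absent")
  expect_error(predict_vat_batch(m, coh2), "hc")
  # empty cohort with skip policy
  out0 <- predict_vat_batch(m, coh[0, ], on_invalid = "skip")
  expect_length(out0, 0L)
  expect_identical(nrow(attr(out0, "skipped")), 0L)
  # all rows invalid
  coh3 <- coh; coh3$wc <- NA
  expect_error(predict_vat_batch(m, coh3, on_invalid = "skip"),
               "no valid rows")
})

test_that("implausible predictions raise a range warning", {
  m <- published_vat_model()
  expect_warning(predict_vat(m, data.frame(sex = "female", wc = 60,
                                           hc = 170, bmi = 16)),
                 "plausible")
})

test_that("model JSON serialization round-trips", {
  m <- published_vat_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_mars_model(m, path)
  back <- read_mars_model(path)
  expect_equal(back$constant, m$constant)
  d <- random_records(500, seed = 7)
  expect_equal(predict_vat(back, d, check_range = FALSE),
               predict_vat(m, d, check_range = FALSE), tolerance = 1e-12)
})

test_that("basis-function invariants are enforced at construction", {
  expect_error(basis_function(1, list()), "degree")
  expect_error(basis_function(1, list(hinge("wc", 100, "above"),
                                      hinge("wc", 90, "below"))),
               "twice")
  expect_error(basis_function(1, list(hinge("wc", 100, "above"),
                                      hinge("bmi", 25, "below"),
                                      hinge("hc", 100, "above"))),
               "degree")
})
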