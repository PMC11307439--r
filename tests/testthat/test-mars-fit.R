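# Brute-force single-step knot oracle: RSS-argmin over all candidate
# interior knots, each evaluated by an explicit least-squares fit of
# {1, max(0, x - k), max(0, k - x)}.
brute_first_knot <- function(x, y) {
  cands <- sort(unique(x))
  cands <- cands[-c(1L, length(cands))]
  rss <- vapply(cands, function(k) {
    B <- cbind(1, pmax(x - k, 0), pmax(k - x, 0))
    sum(qr.resid(qr(B), y)^2)
  }, numeric(1))
  cands[which.min(rss)]
}

first_knot <- function(model) {
  f <- model$basis_functions[[1]]$factors[[1]]
  f$knot
}

test_that("forward pass places the first hinge pair at the RSS-optimal knot", {
  # noiseless hinge: the knot is identified exactly, at a data value
  x <- seq(0, 10, by = 0.1)
  y <- 3 * pmax(0, x - 5)
  cand <- forward_pass(data.frame(x = x), y,
                       mars_control(max_basis_functions = 2))
  expect_equal(first_knot(cand), 5.0)
  expect_true(first_knot(cand) %in% x)

  # equality with the exhaustive oracle on small random problems
  for (seed in 1:8) {
    withr::with_seed(seed, {
      x <- runif(40)
      y <- sin(3 * x) + rnorm(40, 0, 0.1)
    })
    cand <- forward_pass(data.frame(x = x), y,
                         mars_control(max_basis_functions = 2))
    expect_equal(first_knot(cand), brute_first_knot(x, y),
                 info = paste("seed", seed))
  }
})

test_that("degenerate responses give a constant-only model", {
  x <- data.frame(x = runif(30))
  fit <- fit_mars(x, rep(4.2, 30))
  expect_length(fit$model$basis_functions, 0L)
  expect_equal(fit$model$constant, 4.2)
  expect_identical(nrow(variable_importance(fit)), 0L)
})

test_that("a line is reproduced by a few hinge terms", {
  withr::local_seed(3)
  x <- data.frame(x = runif(200))
  y <- x$x
  cand <- forward_pass(x, y)
  expect_lte(length(cand$basis_functions), 4L)
  pred <- predict_vat(cand, x, check_range = FALSE)
  expect_gte(1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.999)
})

test_that("gcv_score matches its closed form and orders nested models", {
  withr::local_seed(11)
  n <- 150
  y <- rnorm(n)
  x <- data.frame(x = runif(n))
  const <- mars_model(mean(y), list(), predictors = "x")
  mse <- mean((y - mean(y))^2)
  expect_equal(gcv_score(const, x, y, penalty = 3),
               mse / (1 - 1 / n)^2, tolerance = 1e-12)
  # with penalty 0, GCV ordering of nested models equals MSE/(1-p/n)^2
  m1 <- mars_model(0, list(basis_function(1, list(hinge("x", 0.5, "above")))),
                   predictors = "x")
  g1 <- gcv_score(m1, x, y, penalty = 0)
  B <- cbind(1, pmax(x$x - 0.5, 0))
  rss1 <- sum(qr.resid(qr(B), y)^2)
  expect_equal(g1, (rss1 / n) / (1 - 2 / n)^2, tolerance = 1e-12)
  # infinite sentinel when effective parameters reach n
  tiny_y <- rnorm(4)
  tiny_x <- data.frame(x = runif(4))
  expect_identical(gcv_score(m1, tiny_x, tiny_y, penalty = 3), Inf)
})

test_that("a useless term increases GCV on pure noise", {
  worse <- 0L
  n <- 200
  for (seed in 1:100) {
    y <- withr::with_seed(seed, rnorm(n))
    x <- data.frame(x = withr::with_seed(seed + 5000, runif(n)))
    const <- mars_model(mean(y), list(), predictors = "x")
    with_term <- mars_model(0, list(
      basis_function(1, list(hinge("x", 0.5, "above")))), predictors = "x")
    if (gcv_score(with_term, x, y, 3) > gcv_score(const, x, y, 3)) {
      worse <- worse + 1L
    }
  }
  expect_gte(worse, 95L)
})

test_that("backward pruning keeps a true term and drops noise terms", {
  kept_true <- 0L; dropped4 <- 0L
  for (seed in 1:50) {
    n <- 500
    dat <- withr::with_seed(seed, {
      x <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n), x3 = runif(n),
                      x4 = runif(n), x5 = runif(n), x6 = runif(n))
      list(x = x, y = 3 * pmax(0, x$x1 - 5) + rnorm(n, 0, 0.1))
    })
    cand_terms <- c(
      list(basis_function(3, list(hinge("x1", 5, "above")))),
      lapply(paste0("x", 2:6), function(v)
        basis_function(1, list(hinge(v, 0.5, "above"))))
    )
    cand <- mars_model(0, cand_terms, predictors = names(dat$x))
    attr(cand, "trace") <- NULL
    fit <- backward_prune(cand, dat$x, dat$y)
    vars <- unique(unlist(lapply(fit$model$basis_functions, function(bf)
      vapply(bf$factors, function(f) f$variable, character(1)))))
    if ("x1" %in% vars) kept_true <- kept_true + 1L
    if (length(setdiff(vars, "x1")) <= 1L) dropped4 <- dropped4 + 1L
  }
  expect_gte(kept_true, 45L)   # >= 90% of 50 seeds
  expect_gte(dropped4, 45L)
})

test_that("pruning a constant-only candidate returns it unchanged", {
  withr::local_seed(2)
  x <- data.frame(x = runif(30))
  y <- rnorm(30)
  cand <- mars_model(mean(y), list(), predictors = "x")
  fit <- backward_prune(cand, x, y)
  expect_length(fit$model$basis_functions, 0L)
})

test_that("forward pass monotonically decreases training RSS", {
  d <- generate_fit_dataset(400, seed = 5)
  cand <- forward_pass(d$x, d$y, mars_control(min_span = 10))
  rss <- attr(cand, "trace")$rss
  expect_true(all(diff(rss) <= 1e-8 * rss[1]))
})

test_that("fitting is deterministic", {
  d <- generate_fit_dataset(300, seed = 8)
  f1 <- fit_mars(d$x, d$y, mars_control(min_span = 10))
  f2 <- fit_mars(d$x, d$y, mars_control(min_span = 10))
  expect_identical(f1$model, f2$model)
  expect_identical(f1$gcv, f2$gcv)
})

test_that("noiseless model-generated data is recovered cleanly", {
  p <- default_profile()
  p$vat_noise_sd <- 0
  d <- generate_fit_dataset(800, seed = 21, p)
  fit <- fit_mars(d$x, d$y, mars_control(min_span = 20))
  expect_gte(fit$rsq, 0.99)
  vars <- unique(unlist(lapply(fit$model$basis_functions, function(bf)
    vapply(bf$factors, function(f) f$variable, character(1)))))
  expect_true(all(vars %in% c("wc", "hc", "bmi", "sex")))
})

test_that("importance is 100 for the only variable of a one-variable model", {
  withr::local_seed(13)
  n <- 300
  x <- data.frame(wc = runif(n, 60, 130), age = runif(n, 20, 50))
  y <- 2 * pmax(0, x$wc - 100) + rnorm(n, 0, 0.5)
  fit <- fit_mars(x, y, mars_control(min_span = 10))
  imp <- variable_importance(fit)
  expect_identical(imp$variable[1], "wc")
  expect_equal(imp$importance[1], 100)
  expect_true(all(imp$importance[imp$variable != "wc"] < 10))
})

test_that("cross-validation separates signal from noise", {
  # noiseless two-hinge signal: near-perfect out-of-fold R^2
  withr::local_seed(4)
  n <- 1000
  x <- data.frame(x = runif(n, 0, 10))
  y <- 3 * pmax(0, x$x - 5) - 2 * pmax(0, x$x - 8)
  cv <- kfold_cv(x, y, mars_control(min_span = 10), k = 10, seed = 1)
  expect_gte(cv$rsq, 0.99)

  # pure noise: pooled out-of-fold R^2 stays near or below zero
  rsqs <- vapply(1:25, function(seed) {
    n <- 100
    dat <- withr::with_seed(seed, {
      list(x = data.frame(a = runif(n), b = runif(n), c = runif(n)),
           y = rnorm(n))
    })
    kfold_cv(dat$x, dat$y, mars_control(min_span = 5), k = 10,
             seed = seed)$rsq
  }, numeric(1))
  expect_lte(stats::quantile(rsqs, 0.95), 0.05)

  # same seed gives the same folds
  cv2 <- kfold_cv(x, y, mars_control(min_span = 10), k = 10, seed = 1)
  expect_identical(cv$oof, cv2$oof)
  expect_error(kfold_cv(x, y, k = 1), "at least 2")
  expect_error(kfold_cv(x[1:10, , drop = FALSE], y[1:10], k = 10), "2k")
})
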