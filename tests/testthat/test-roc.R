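test_that("AUC matches brute-force pair counting on hand examples", {
  r <- roc_auc(c(3, 5, 1, 2, 4), c(1, 1, 0, 0, 0))
  expect_equal(r$auc, 5 / 6, tolerance = 1e-15)
  # perfectly separated
  r2 <- roc_auc(c(10, 11, 1, 2), c(1, 1, 0, 0))
  expect_equal(r2$auc, 1)
  expect_equal(r2$se, 0)
  # ties count one half
  r3 <- roc_auc(c(2, 2), c(1, 0))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("AUC equals brute force on random instances including ties", {
  for (seed in 1:60) {
    dat <- withr::with_seed(seed, {
      n <- sample(4:200, 1)
      scores <- sample(round(rnorm(n), sample(0:2, 1)))
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      list(scores = scores, labels = labels)
    })
    expect_equal(roc_auc(dat$scores, dat$labels)$auc,
                 brute_auc(dat$scores, dat$labels), tolerance = 1e-12)
  }
})

test_that("the ROC curve is a valid monotone step function", {
  withr::local_seed(8)
  sc <- rnorm(80)
  lb <- rbinom(80, 1, 0.5)
  cv <- roc_auc(sc, lb)$curve
  expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
})

test_that("ROC results are invariant under strictly increasing transforms", {
  withr::local_seed(12)
  sc <- rnorm(100)
  lb <- rbinom(100, 1, 0.5)
  a <- roc_auc(sc, lb)
  b <- roc_auc(exp(sc), lb)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  ct <- select_cutoff(sc, lb)
  ct2 <- select_cutoff(exp(sc), lb)
  expect_equal(ct2$cutoff, exp(ct$cutoff), tolerance = 1e-12)
  expect_equal(ct2$youden_j, ct$youden_j, tolerance = 1e-12)
})

test_that("null AUC stays within three standard errors of one half", {
  withr::local_seed(77)
  sc <- rnorm(2000)
  lb <- rbinom(2000, 1, 0.5)
  r <- roc_auc(sc, lb)
  expect_lt(abs(r$auc - 0.5), 3 * r$se)
})

test_that("DeLong components agree with pROC and a brute-force oracle", {
  library(pROC)
  withr::local_seed(9)
  n <- 120
  lb <- rbinom(n, 1, 0.5)
  sa <- rnorm(n) + lb
  sb <- rnorm(n) + 0.5 * lb
  r <- roc_auc(sa, lb)
  pr <- pROC::roc(lb, sa, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$se^2, pROC::var(pr, method = "delong"), tolerance = 1e-10)
  dl <- delong_test(sa, sb, lb)
  pt <- pROC::roc.test(pROC::roc(lb, sa, quiet = TRUE, direction = "<"),
                       pROC::roc(lb, sb, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p, pt$p.value, tolerance = 1e-10)

  # six-subject hand-sized example against the explicit-loop oracle
  sa6 <- c(0.9, 0.2, 0.8, 0.4, 0.7, 0.1)
  sb6 <- c(0.6, 0.3, 0.5, 0.8, 0.9, 0.2)
  lb6 <- c(1, 0, 1, 0, 1, 0)
  got <- delong_test(sa6, sb6, lb6)
  want <- brute_delong(sa6, sb6, lb6)
  expect_equal(got$auc_a, want$auc_a, tolerance = 1e-12)
  expect_equal(got$auc_b, want$auc_b, tolerance = 1e-12)
  expect_equal(got$z, want$z, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("identical markers give z = 0 and p = 1", {
  withr::local_seed(5)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.5)
  d <- delong_test(sc, sc, lb)
  expect_identical(d$z, 0)
  expect_identical(d$p, 1)
  expect_error(delong_test(sc, sc[-1], lb), "equal length")
})

test_that("DeLong variance is close to the bootstrap variance", {
  withr::local_seed(14)
  n <- 300
  lb <- rbinom(n, 1, 0.5)
  sc <- rnorm(n) + 0.8 * lb
  r <- roc_auc(sc, lb)
  boots <- vapply(1:2000, function(i) {
    idx <- sample.int(n, replace = TRUE)
    while (length(unique(lb[idx])) < 2) idx <- sample.int(n, replace = TRUE)
    roc_auc(sc[idx], lb[idx])$auc
  }, numeric(1))
  expect_lt(abs(r$se^2 - stats::var(boots)) / stats::var(boots), 0.10)
})

test_that("operating points and cutoff selection follow the conventions", {
  sc <- c(3, 5, 1, 2, 4); lb <- c(1, 1, 0, 0, 0)
  op <- operating_point(sc, lb, 3)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 2 / 3)
  expect_equal(operating_point(sc, lb, 0),
               list(sensitivity = 1, specificity = 0))
  expect_equal(operating_point(sc, lb, 99),
               list(sensitivity = 0, specificity = 1))

  ct <- select_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(ct$cutoff, 3)
  expect_equal(ct$sensitivity, 1)
  expect_equal(ct$specificity, 1)
  # all scores identical: J = 0 at the single candidate
  ct2 <- select_cutoff(rep(2, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(ct2$youden_j, 0)
})

test_that("compare_indices ranks the generating model highest", {
  wins <- 0L
  for (seed in 1:50) {
    coh <- generate_cohort(250, seed = 3000 + seed)
    tab <- compare_indices(coh, stratify_by_sex = FALSE)
    best <- tab$marker[which.max(tab$auc)]
    top <- max(tab$auc[tab$marker != "new_model"])
    if (best == "new_model" && tab$auc[tab$marker == "new_model"] > top) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 45L)  # >= 90% of 50 seeds
})

test_that("compare_indices handles reference rows and degenerate strata", {
  coh <- generate_cohort(300, seed = 4)
  tab <- compare_indices(coh, markers = list(
    new_model = predict_vat(published_vat_model(), coh, check_range = FALSE),
    twin = predict_vat(published_vat_model(), coh, check_range = FALSE)),
    reference = "new_model")
  expect_true(all(tab$p_vs_reference[tab$marker == "twin"] == 1))
  expect_true(all(is.na(tab$p_vs_reference[tab$marker == "new_model"])))

  # permuted outcomes: AUCs near 0.5
  coh2 <- coh
  coh2$ct_vat <- withr::with_seed(1, sample(coh2$ct_vat))
  tab2 <- compare_indices(coh2, stratify_by_sex = FALSE)
  expect_true(all(abs(tab2$auc - 0.5) < 3 * tab2$se + 0.02))

  # a stratum with one outcome class is skipped with a warning
  coh3 <- as.data.frame(coh)
  coh3$ct_vat[coh3$sex == "male"] <- 500
  expect_warning(tab3 <- compare_indices(coh3), "male")
  expect_true(all(tab3$stratum == "female"))
})
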