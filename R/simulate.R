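# Synthetic cohort generator: gender-stratified Gaussian copula with
# moment-calibrated truncated-normal marginals, and "measured" VAT
# simulated as the published model's prediction plus Gaussian noise.

.SIM_VARS <- c("age", "height", "wc", "hc", "bmi", "sbp", "dbp",
               "glucose", "tg", "hdl", "c_peptide")

.sim_corr_default <- function() {
  v <- .SIM_VARS
  R <- matrix(0.10, length(v), length(v), dimnames = list(v, v))
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("wc", "bmi", 0.85)
  set_r("wc", "hc", 0.80)
  set_r("bmi", "hc", 0.80)
  set_r("wc", "tg", 0.35)
  set_r("wc", "glucose", 0.30)
  set_r("wc", "hdl", -0.30)
  set_r("tg", "hdl", -0.40)
  set_r("age", "wc", 0.20)
  set_r("c_peptide", "bmi", 0.40)
  diag(R) <- 1
  .nearest_psd_corr(R)
}

.nearest_psd_corr <- function(R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  stats::cov2cor(R2)
}

#' Synthetic cohort profile
#'
#' Gender-stratified means and SDs for the continuous variables, a
#' shared correlation matrix, truncation bounds, the female fraction,
#' the VAT noise SD, and a dysmetabolism dial shifting waist,
#' triglycerides, glucose and blood pressure upward and HDL-C downward
#' (in SD units).
#'
#' @param male,female Named lists with numeric vectors `mean` and `sd`
#'   over the variables `age, height, wc, hc, bmi, sbp, dbp, glucose,
#'   tg, hdl, c_peptide`.
#' @param corr Correlation matrix over those variables (symmetric, unit
#'   diagonal, positive semi-definite).
#' @param bounds Named list of `c(lower, upper)` truncation bounds.
#' @param sex_fraction_female Proportion of women in \[0, 1\].
#' @param vat_noise_sd SD (cm^2) of the Gaussian noise added to the
#'   model prediction to form measured VAT.
#' @param dysmetabolism_shift Dial, in SD units (default 0).
#' @return A `synthetic_profile` object.
#' @seealso [default_profile()], [generate_cohort()]
#' @export
synthetic_profile <- function(male, female, corr = .sim_corr_default(),
                              bounds = NULL, sex_fraction_female = 0.5,
                              vat_noise_sd = 41, dysmetabolism_shift = 0) {
  for (sx in list(male, female)) {
    stopifnot(is.list(sx),
              all(.SIM_VARS %in% names(sx$mean)),
              all(.SIM_VARS %in% names(sx$sd)),
              all(sx$sd[.SIM_VARS] > 0))
  }
  stopifnot(is.matrix(corr), identical(dim(corr), c(length(.SIM_VARS),
                                                    length(.SIM_VARS))))
  if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8) {
    stop("corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("corr is not positive semi-definite", call. = FALSE)
  }
  dimnames(corr) <- list(.SIM_VARS, .SIM_VARS)
  bounds <- bounds %||% list(
    age = c(20, 50), height = c(140, 210), wc = c(55, 160),
    hc = c(70, 180), bmi = c(15, 60), sbp = c(80, 220), dbp = c(40, 130),
    glucose = c(60, 125), tg = c(30, 600), hdl = c(20, 120),
    c_peptide = c(0.2, 8)
  )
  stopifnot(all(.SIM_VARS %in% names(bounds)),
            sex_fraction_female >= 0, sex_fraction_female <= 1,
            vat_noise_sd >= 0)
  structure(list(male = male, female = female,
                 corr = .nearest_psd_corr(corr), bounds = bounds,
                 sex_fraction_female = sex_fraction_female,
                 vat_noise_sd = vat_noise_sd,
                 dysmetabolism_shift = dysmetabolism_shift),
            class = "synthetic_profile")
}

#' Default synthetic profile (study-group conditions)
#'
#' Gender-stratified means and SDs matching the study group's
#' descriptive statistics (male n = 77 / female n = 108 stratification,
#' 58.4% women), VAT noise SD 41 cm^2.  Height and fasting C-peptide
#' are not reported in the descriptives and use typical adult values
#' (see the methods vignette).
#'
#' @return A `synthetic_profile`.
#' @examples
#' p <- default_profile()
#' p$male$mean[["wc"]]   # 93.6
#' p$vat_noise_sd        # 41
#' @export
default_profile <- function() {
  male <- list(
    mean = c(age = 39.6, height = 173, wc = 93.6, hc = 103.4, bmi = 26.5,
             sbp = 122.3, dbp = 80, glucose = 88.6, tg = 131.8, hdl = 45.4,
             c_peptide = 2.1),
    sd = c(age = 7.3, height = 7, wc = 10.9, hc = 7.6, bmi = 4.2,
           sbp = 15.5, dbp = 9.4, glucose = 10.7, tg = 70.5, hdl = 10.9,
           c_peptide = 0.8)
  )
  female <- list(
    mean = c(age = 37.3, height = 160, wc = 86.6, hc = 104.5, bmi = 27,
             sbp = 111.6, dbp = 79.9, glucose = 90.4, tg = 101.4,
             hdl = 55.3, c_peptide = 2.0),
    sd = c(age = 8.3, height = 7, wc = 15.5, hc = 13.3, bmi = 6.5,
           sbp = 12, dbp = 9, glucose = 11.8, tg = 62.3, hdl = 13.5,
           c_peptide = 0.8)
  )
  synthetic_profile(male, female, sex_fraction_female = 0.584,
                    vat_noise_sd = 41)
}

# Truncated-normal moments on [a, b] for underlying (mu, sigma).
.tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z < 1e-12) return(list(mean = NA_real_, sd = NA_real_, Z = Z))
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)), Z = Z)
}

# Solve for the underlying (mu, sigma) whose truncation to [a, b]
# has the target mean and SD, so truncation does not bias the
# generator's marginal moments.
.calibrate_tnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mom <- .tnorm_moments(par[1L], exp(par[2L]), a, b)
    if (!is.finite(mom$mean)) return(1e10)
    ((mom$mean - target_mean) / target_sd)^2 +
      ((mom$sd - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

.draw_stratum <- function(ns, stratum, profile) {
  shift <- profile$dysmetabolism_shift
  means <- stratum$mean[.SIM_VARS]
  sds <- stratum$sd[.SIM_VARS]
  up <- c("wc", "tg", "glucose", "sbp", "dbp")
  means[up] <- means[up] + shift * sds[up]
  means[["hdl"]] <- means[["hdl"]] - shift * sds[["hdl"]]

  k <- length(.SIM_VARS)
  L <- chol(profile$corr)
  z <- matrix(stats::rnorm(ns * k), ns, k) %*% L
  u <- stats::pnorm(z)
  out <- matrix(NA_real_, ns, k, dimnames = list(NULL, .SIM_VARS))
  for (j in seq_len(k)) {
    v <- .SIM_VARS[j]
    ab <- profile$bounds[[v]]
    par <- .calibrate_tnorm(means[[v]], sds[[v]], ab[1L], ab[2L])
    pa <- stats::pnorm((ab[1L] - par[["mu"]]) / par[["sigma"]])
    pb <- stats::pnorm((ab[2L] - par[["mu"]]) / par[["sigma"]])
    out[, j] <- par[["mu"]] + par[["sigma"]] *
      stats::qnorm(pa + u[, j] * (pb - pa))
  }
  out
}

#' Generate a synthetic cohort
#'
#' Sex is drawn from the profile's female fraction; the continuous
#' variables come from a per-sex Gaussian copula with the profile's
#' correlation matrix and truncated-normal marginals calibrated so the
#' truncated distributions reproduce the profile means and SDs.  Weight
#' is derived from BMI and height, and measured VAT is simulated as the
#' published model's prediction plus `Normal(0, vat_noise_sd)`, floored
#' at 1 cm^2.  Fully reproducible from `seed`.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed.
#' @param profile A [synthetic_profile()]; defaults to the study-group
#'   conditions.
#' @return A validated `vat_cohort` data frame of `n` subjects.
#' @examples
#' coh <- generate_cohort(50, seed = 1)
#' @export
generate_cohort <- function(n, seed, profile = default_profile()) {
  stopifnot(inherits(profile, "synthetic_profile"), n >= 1)
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    female <- stats::runif(n) < profile$sex_fraction_female
    vals <- matrix(NA_real_, n, length(.SIM_VARS),
                   dimnames = list(NULL, .SIM_VARS))
    if (any(!female)) {
      vals[!female, ] <- .draw_stratum(sum(!female), profile$male, profile)
    }
    if (any(female)) {
      vals[female, ] <- .draw_stratum(sum(female), profile$female, profile)
    }
    df <- as.data.frame(vals)
    df$sex <- ifelse(female, "female", "male")
    df$weight <- df$bmi * (df$height / 100)^2
    df$subject_id <- sprintf("S%05d", seq_len(n))
    df$bp_treated <- FALSE
    pred <- predict_vat(published_vat_model(), df, check_range = FALSE)
    df$ct_vat <- pmax(1, pred + stats::rnorm(n, 0, profile$vat_noise_sd))
    cols <- intersect(.COHORT_FIELDS, names(df))
    validate_cohort(df[cols], label = sprintf("synthetic(n=%d, seed=%d)",
                                              n, as.integer(seed)))
  })
}

#' Generate a predictor table and response for MARS fitting
#'
#' Emits exactly the nine candidate predictors (age, sex, WC, HC, BMI,
#' glucose, C-peptide, triglycerides, HDL-C) and the simulated measured
#' VAT response, formatted for [fit_mars()].
#'
#' @inheritParams generate_cohort
#' @return A list with `x` (data frame of 9 predictors, fixed column
#'   order) and `y` (numeric response, cm^2).
#' @export
generate_fit_dataset <- function(n, seed, profile = default_profile()) {
  coh <- generate_cohort(n, seed, profile)
  x <- data.frame(age = coh$age, sex = coh$sex, wc = coh$wc, hc = coh$hc,
                  bmi = bmi(coh$height, coh$weight), glucose = coh$glucose,
                  c_peptide = coh$c_peptide, tg = coh$tg, hdl = coh$hdl,
                  stringsAsFactors = FALSE)
  list(x = x, y = coh$ct_vat)
}
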