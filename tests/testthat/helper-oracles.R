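# Shared fixtures and independent oracles.  Oracles are coded flat, from
# the printed formulas, and never call the implementation paths they
# check.

# Random but physiologically valid subject records.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    height <- runif(n, 145, 200)
    bmi_v <- runif(n, 16, 45)
    data.frame(
      subject_id = sprintf("R%04d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = runif(n, 20, 50),
      height = height,
      weight = bmi_v * (height / 100)^2,
      wc = runif(n, 60, 140),
      hc = runif(n, 80, 150),
      sbp = runif(n, 90, 180),
      dbp = runif(n, 55, 110),
      glucose = runif(n, 65, 124),
      tg = runif(n, 40, 400),
      hdl = runif(n, 25, 100),
      c_peptide = runif(n, 0.5, 5),
      stringsAsFactors = FALSE
    )
  })
}

# Flat one-line rendering of the published prediction model.
flat_vat_oracle <- function(d) {
  fem <- as.numeric(d$sex == "female")
  b <- d$weight / (d$height / 100)^2
  249 - 79.9 * fem - 4.4 * pmax(0, 111 - d$wc) - 5.14 * pmax(0, d$hc - 106) -
    29.5 * pmax(0, 25.9 - b) + 13 * pmax(0, b - 25.9) +
    7.18 * fem * pmax(0, 29 - b) +
    0.459 * pmax(0, 111 - d$wc) * pmax(0, 28.4 - b)
}

# One-line adiposity-index oracles (lipids converted inline).
oracle_indices <- function(d) {
  b <- d$weight / (d$height / 100)^2
  tgm <- d$tg / 88.57
  hdlm <- d$hdl / 38.67
  male <- d$sex == "male"
  list(
    vai = ifelse(male,
                 d$wc / (39.68 + 1.88 * b) * (tgm / 1.03) * (1.31 / hdlm),
                 d$wc / (36.58 + 1.89 * b) * (tgm / 0.81) * (1.52 / hdlm)),
    lap = ifelse(male, (d$wc - 65) * tgm, (d$wc - 58) * tgm),
    absi = (d$wc / 100) / (b^(2 / 3) * sqrt(d$height / 100)),
    bri = 364.2 - 365.5 * sqrt(1 - (d$wc / (2 * pi))^2 / (0.5 * d$height)^2),
    mets_ir = log(2 * d$glucose + d$tg) * b / log(d$hdl),
    mets_vf = 4.466 +
      0.011 * log(log(2 * d$glucose + d$tg) * b / log(d$hdl))^3 +
      3.239 * log(d$wc / d$height)^3 + 0.319 * as.numeric(male) +
      0.594 * log(d$age),
    whr = d$wc / d$hc,
    whtr = d$wc / d$height,
    bmi = b
  )
}

# Brute-force AUC: concordant-pair fraction with ties counted 1/2.
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  cmp <- outer(cases, controls, FUN = function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force DeLong machinery via explicit per-observation loops.
brute_delong <- function(sa, sb, labels) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  place <- function(s) {
    cases <- s[labels == 1]; controls <- s[labels == 0]
    m <- length(cases); n <- length(controls)
    v10 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
    v01 <- vapply(controls, function(y) mean(psi(cases, y)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
  }
  pa <- place(sa); pb <- place(sb)
  va <- var(pa$v10) / pa$m + var(pa$v01) / pa$n
  vb <- var(pb$v10) / pb$m + var(pb$v01) / pb$n
  cab <- cov(pa$v10, pb$v10) / pa$m + cov(pa$v01, pb$v01) / pa$n
  z <- (pa$auc - pb$auc) / sqrt(va + vb - 2 * cab)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

# A tiny hand-checkable three-subject cohort used across files.
fixture_cohort3 <- function() {
  rbind(
    subject_record(sex = "male", age = 40, height = 175,
                   weight = 25.9 * 1.75^2, wc = 111, hc = 106,
                   subject_id = "A"),
    subject_record(sex = "female", age = 35, height = 170,
                   weight = 22 * 1.70^2, wc = 80, hc = 100,
                   subject_id = "B"),
    subject_record(sex = "male", age = 45, height = 170,
                   weight = 30 * 1.70^2, wc = 100, hc = 110,
                   subject_id = "C")
  )
}
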