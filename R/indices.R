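# Comparator adiposity indices.  Storage units are cm / kg / mg/dl; VAI
# and LAP convert lipids to mmol/l internally, ABSI and BRI work in
# meters.  All functions are vectorised over the rows of `data` and, by
# default, raise on domain violations; `strict = FALSE` converts
# violating rows to NA (used by adiposity_indices()).

.idx_get <- function(data, fields, index) {
  missing <- fields[!fields %in% names(data)]
  if (length(missing)) {
    stop(index, " needs missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

.idx_domain <- function(bad, msg, strict, values) {
  bad <- !is.na(bad) & bad
  if (any(bad)) {
    if (strict) stop(msg, call. = FALSE)
    values[bad] <- NA_real_
  }
  values
}

#' Visceral adiposity index (VAI)
#'
#' Sex-specific index of visceral adipose function from WC, BMI,
#' triglycerides and HDL-C (lipids in mmol/l):
#' males `WC/(39.68 + 1.88 BMI) * (TG/1.03) * (1.31/HDL)`,
#' females `WC/(36.58 + 1.89 BMI) * (TG/0.81) * (1.52/HDL)`.
#'
#' @param data Subject record or cohort data frame (canonical units:
#'   cm, kg, mg/dl).
#' @param strict Raise on domain violations (`TRUE`) or return NA for
#'   the violating rows (`FALSE`).
#' @return Numeric index values (dimensionless).
#' @export
vai <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("sex", "wc", "tg", "hdl"), "VAI")
  bad <- (!is.na(data$tg) & data$tg <= 0) |
    (!is.na(data$hdl) & data$hdl <= 0)
  if (strict && any(bad)) {
    stop("VAI requires strictly positive triglycerides and HDL-C",
         call. = FALSE)
  }
  tgv <- replace(data$tg, bad, NA_real_)
  hdlv <- replace(data$hdl, bad, NA_real_)
  tg <- mgdl_to_mmoll(tgv, "triglyceride")
  hdl <- mgdl_to_mmoll(hdlv, "cholesterol")
  b <- data$bmi
  male <- data$sex == "male"
  ifelse(male,
         data$wc / (39.68 + 1.88 * b) * (tg / 1.03) * (1.31 / hdl),
         data$wc / (36.58 + 1.89 * b) * (tg / 0.81) * (1.52 / hdl))
}

#' Lipid accumulation product (LAP)
#'
#' `(WC - 65) * TG` in males, `(WC - 58) * TG` in females, TG in mmol/l.
#' A waist below the sex constant yields a negative value, which is
#' retained (not truncated).
#'
#' @inheritParams vai
#' @return Numeric index values (cm x mmol/l).
#' @export
lap <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("sex", "wc", "tg"), "LAP")
  tg <- mgdl_to_mmoll(data$tg, "triglyceride")
  ifelse(data$sex == "male", (data$wc - 65) * tg, (data$wc - 58) * tg)
}

#' A body shape index (ABSI)
#'
#' `WC / (BMI^(2/3) * height^(1/2))` with WC and height both in meters,
#' the original definition (magnitude ~0.08).
#'
#' @inheritParams vai
#' @return Numeric index values.
#' @export
absi <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("wc", "height"), "ABSI")
  (data$wc / 100) / (data$bmi^(2 / 3) * sqrt(data$height / 100))
}

#' Body roundness index (BRI)
#'
#' `364.2 - 365.5 * sqrt(1 - (WC/(2*pi))^2 / (0.5*height)^2)`, WC and
#' height in the same length unit (the index is scale-invariant).
#' Requires `WC/pi < height` (the eccentricity argument must stay
#' non-negative).
#'
#' @inheritParams vai
#' @return Numeric index values.
#' @export
bri <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("wc", "height"), "BRI")
  arg <- 1 - (data$wc / (2 * pi))^2 / (0.5 * data$height)^2
  v <- 364.2 - 365.5 * sqrt(pmax(arg, 0))
  .idx_domain(arg < 0, "BRI undefined: WC/pi must be below height",
              strict, v)
}

#' Metabolic score for insulin resistance (METS-IR)
#'
#' `ln(2 * glucose + TG) * BMI / ln(HDL)`, all analytes in mg/dl.
#'
#' @inheritParams vai
#' @return Numeric index values.
#' @export
mets_ir <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("glucose", "tg", "hdl"), "METS-IR")
  v <- log(2 * data$glucose + data$tg) * data$bmi / log(data$hdl)
  .idx_domain(data$hdl <= 1 | (2 * data$glucose + data$tg) <= 0,
              "METS-IR requires HDL-C > 1 mg/dl and 2*glucose + TG > 0",
              strict, v)
}

#' Metabolic score for visceral fat (METS-VF)
#'
#' `4.466 + 0.011 ln(METS-IR)^3 + 3.239 ln(WHtR)^3 + 0.319 [male] +
#' 0.594 ln(age)`.
#'
#' @inheritParams vai
#' @return Numeric index values.
#' @export
mets_vf <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("sex", "age", "wc", "height", "glucose", "tg", "hdl"),
           "METS-VF")
  mir <- mets_ir(data, strict = strict)
  whtr_v <- data$wc / data$height
  sex_bin <- as.numeric(data$sex == "male")
  4.466 + 0.011 * log(mir)^3 + 3.239 * log(whtr_v)^3 + 0.319 * sex_bin +
    0.594 * log(data$age)
}

#' Waist-to-hip ratio
#' @inheritParams vai
#' @return Numeric `wc / hc`.
#' @export
whr <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("wc", "hc"), "WHR")
  data$wc / data$hc
}

#' Waist-to-height ratio
#' @inheritParams vai
#' @return Numeric `wc / height` (same units).
#' @export
whtr <- function(data, strict = TRUE) {
  data <- .model_frame(data)
  .idx_get(data, c("wc", "height"), "WHtR")
  data$wc / data$height
}

.INDEX_REQUIREMENTS <- list(
  vai = c("sex", "wc", "bmi", "tg", "hdl"),
  lap = c("sex", "wc", "tg"),
  absi = c("wc", "height", "bmi"),
  bri = c("wc", "height"),
  mets_ir = c("glucose", "tg", "hdl", "bmi"),
  mets_vf = c("sex", "age", "wc", "height", "glucose", "tg", "hdl", "bmi"),
  whr = c("wc", "hc"),
  whtr = c("wc", "height"),
  bmi = c("bmi")
)

#' Compute all adiposity indices for a cohort
#'
#' One column per index (VAI, LAP, ABSI, BRI, METS-IR, METS-VF, WHR,
#' WHtR, BMI), row order preserved.  An index whose inputs are missing or
#' out of domain for a row is reported absent (NA) with a reason in the
#' `"absence"` attribute rather than raising.
#'
#' @param data Cohort data frame.
#' @return Data frame of index values with attribute `"absence"` (row,
#'   index, reason).
#' @export
adiposity_indices <- function(data) {
  data <- .model_frame(data)
  n <- nrow(data)
  fns <- list(vai = vai, lap = lap, absi = absi, bri = bri,
              mets_ir = mets_ir, mets_vf = mets_vf, whr = whr, whtr = whtr,
              bmi = function(d, strict) d$bmi)
  out <- data.frame(row.names = seq_len(n))
  absence <- list()
  for (nm in names(fns)) {
    req <- .INDEX_REQUIREMENTS[[nm]]
    have <- req[req %in% names(data)]
    if (length(have) < length(req)) {
      out[[nm]] <- rep(NA_real_, n)
      absence[[length(absence) + 1L]] <- data.frame(
        row = seq_len(n), index = nm,
        reason = paste("missing field:",
                       paste(setdiff(req, have), collapse = ", ")),
        stringsAsFactors = FALSE)
      next
    }
    vals <- fns[[nm]](data, strict = FALSE)
    out[[nm]] <- vals
    miss <- which(is.na(vals))
    if (length(miss)) {
      absence[[length(absence) + 1L]] <- data.frame(
        row = miss, index = nm,
        reason = "missing or out-of-domain input", stringsAsFactors = FALSE)
    }
  }
  attr(out, "absence") <- if (length(absence)) do.call(rbind, absence) else
    data.frame(row = integer(0), index = character(0),
               reason = character(0))
  out
}
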