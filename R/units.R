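# mg/dl per mmol/l; conventional molar-mass based constants.
.TG_MGDL_PER_MMOLL <- 88.57
.CHOL_MGDL_PER_MMOLL <- 38.67

.lipid_divisor <- function(analyte, divisor = NULL) {
  if (!is.null(divisor)) {
    stopifnot(is.numeric(divisor), length(divisor) == 1L, divisor > 0)
    return(divisor)
  }
  switch(analyte,
    triglyceride = .TG_MGDL_PER_MMOLL,
    cholesterol  = .CHOL_MGDL_PER_MMOLL,
    stop("unknown analyte: ", analyte, call. = FALSE)
  )
}

#' Convert a lipid concentration from mg/dl to mmol/l
#'
#' Triglycerides divide by 88.57, cholesterol fractions (HDL-C, LDL-C)
#' by 38.67.  The constants can be overridden via `divisor` for labs that
#' use rounded factors.
#'
#' @param value Concentration in mg/dl (vectorised), non-negative.
#' @param analyte `"triglyceride"` or `"cholesterol"`.
#' @param divisor Optional numeric override of the conversion constant
#'   (mg/dl per mmol/l).
#' @return Concentration in mmol/l.
#' @seealso [mmoll_to_mgdl()]
#' @examples
#' mgdl_to_mmoll(88.57, "triglyceride")  # 1
#' mgdl_to_mmoll(38.67, "cholesterol")   # 1
#' @export
mgdl_to_mmoll <- function(value, analyte = c("triglyceride", "cholesterol"),
                          divisor = NULL) {
  analyte <- match.arg(analyte)
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("negative concentration supplied to mgdl_to_mmoll()", call. = FALSE)
  }
  value / .lipid_divisor(analyte, divisor)
}

#' Convert a lipid concentration from mmol/l to mg/dl
#'
#' Exact inverse of [mgdl_to_mmoll()].
#'
#' @inheritParams mgdl_to_mmoll
#' @param value Concentration in mmol/l (vectorised), non-negative.
#' @return Concentration in mg/dl.
#' @export
mmoll_to_mgdl <- function(value, analyte = c("triglyceride", "cholesterol"),
                          divisor = NULL) {
  analyte <- match.arg(analyte)
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("negative concentration supplied to mmoll_to_mgdl()", call. = FALSE)
  }
  value * .lipid_divisor(analyte, divisor)
}

#' Body mass index
#'
#' @param height Standing height in cm.
#' @param weight Body weight in kg.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(175, 81.2)
#' @export
bmi <- function(height, weight) {
  if (missing(height) || missing(weight)) {
    stop("bmi() needs both height and weight", call. = FALSE)
  }
  stopifnot(is.numeric(height), is.numeric(weight))
  weight / (height / 100)^2
}
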