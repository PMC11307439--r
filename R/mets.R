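# NCEP ATP III metabolic-syndrome classification.

#' ATP III criteria thresholds
#'
#' Defaults follow the revised NCEP ATP III definition: waist above
#' 102 cm (men) / 88 cm (women), triglycerides at least 150 mg/dl,
#' HDL-C below 40 / 50 mg/dl, blood pressure at least 130/85 mmHg or
#' treated, fasting glucose at least 100 mg/dl; syndrome positive at 3
#' or more criteria.  The original 110 mg/dl glucose cut is available
#' via `glucose_cut = 110`.
#'
#' @param wc_cut_male,wc_cut_female Waist cuts (cm), compared strictly
#'   (`>`).
#' @param tg_cut Triglyceride cut (mg/dl, `>=`).
#' @param hdl_cut_male,hdl_cut_female HDL-C cuts (mg/dl, below = `<`).
#' @param sbp_cut,dbp_cut Blood-pressure cuts (mmHg, `>=`).
#' @param glucose_cut Fasting glucose cut (mg/dl, `>=`).
#' @param required_count Criteria needed for a positive call (1-5).
#' @return A `mets_criteria` list.
#' @export
mets_criteria <- function(wc_cut_male = 102, wc_cut_female = 88,
                          tg_cut = 150, hdl_cut_male = 40,
                          hdl_cut_female = 50, sbp_cut = 130, dbp_cut = 85,
                          glucose_cut = 100, required_count = 3L) {
  cuts <- c(wc_cut_male, wc_cut_female, tg_cut, hdl_cut_male,
            hdl_cut_female, sbp_cut, dbp_cut, glucose_cut)
  stopifnot(all(cuts > 0), required_count >= 1L, required_count <= 5L)
  structure(list(wc_cut_male = wc_cut_male, wc_cut_female = wc_cut_female,
                 tg_cut = tg_cut, hdl_cut_male = hdl_cut_male,
                 hdl_cut_female = hdl_cut_female, sbp_cut = sbp_cut,
                 dbp_cut = dbp_cut, glucose_cut = glucose_cut,
                 required_count = as.integer(required_count)),
            class = "mets_criteria")
}

#' Classify metabolic syndrome (NCEP ATP III)
#'
#' Evaluates the five ATP III component criteria per subject: abdominal
#' obesity (sex-specific waist cut, strict `>`), raised triglycerides,
#' low HDL-C (sex-specific), raised blood pressure (systolic or
#' diastolic, or antihypertensive treatment), and raised fasting
#' glucose.  Positive when at least `required_count` criteria are met.
#'
#' @param data Subject record or cohort data frame (needs sex, wc, tg,
#'   hdl, sbp, dbp, glucose; optional `bp_treated`).
#' @param criteria A [mets_criteria()] object.
#' @return Data frame with logical columns `abdominal`, `triglyceride`,
#'   `hdl`, `blood_pressure`, `glucose`, integer `met_count`, and logical
#'   `positive`; one row per subject, order preserved.
#' @examples
#' classify_mets(subject_record(sex = "female", wc = 90, tg = 160,
#'                              hdl = 45, sbp = 120, dbp = 80,
#'                              glucose = 95))
#' @export
classify_mets <- function(data, criteria = mets_criteria()) {
  stopifnot(inherits(criteria, "mets_criteria"))
  if (!is.data.frame(data)) data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$sex <- .normalize_sex(data$sex)
  need <- c("sex", "wc", "tg", "hdl", "sbp", "dbp", "glucose")
  have <- need[need %in% names(data)]
  miss_col <- setdiff(need, have)
  na_fields <- unique(c(miss_col, have[vapply(have, function(f)
    anyNA(data[[f]]), logical(1))]))
  if (length(na_fields)) {
    stop("classify_mets() missing required field(s): ",
         paste(sort(na_fields), collapse = ", "), call. = FALSE)
  }
  treated <- if ("bp_treated" %in% names(data)) {
    tr <- as.logical(data$bp_treated)
    tr[is.na(tr)] <- FALSE
    tr
  } else rep(FALSE, nrow(data))

  male <- data$sex == "male"
  abdominal <- data$wc > ifelse(male, criteria$wc_cut_male,
                                criteria$wc_cut_female)
  triglyceride <- data$tg >= criteria$tg_cut
  hdl_low <- data$hdl < ifelse(male, criteria$hdl_cut_male,
                               criteria$hdl_cut_female)
  blood_pressure <- data$sbp >= criteria$sbp_cut |
    data$dbp >= criteria$dbp_cut | treated
  glucose <- data$glucose >= criteria$glucose_cut
  met_count <- abdominal + triglyceride + hdl_low + blood_pressure + glucose
  data.frame(
    abdominal = abdominal, triglyceride = triglyceride, hdl = hdl_low,
    blood_pressure = blood_pressure, glucose = glucose,
    met_count = as.integer(met_count),
    positive = met_count >= criteria$required_count
  )
}
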