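# Canonical cohort schema.  All storage in cm / kg / mmHg / mg/dl / ng/ml /
# cm^2; index formulas convert internally where they need mmol/l or m.

.COHORT_REQUIRED <- c("sex", "age", "height", "weight", "wc", "hc")
.COHORT_NUMERIC <- c(
  "age", "height", "weight", "wc", "hc", "bmi", "sbp", "dbp", "glucose",
  "tg", "hdl", "ldl", "c_peptide", "ct_vat", "ct_sat"
)
.COHORT_POSITIVE <- setdiff(.COHORT_NUMERIC, "age")
.COHORT_FIELDS <- c("subject_id", "sex", .COHORT_NUMERIC, "bp_treated")

.normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  s[s == ""] <- NA_character_
  s
}

#' Build a one-row subject record
#'
#' Convenience constructor for interactive use and examples; all
#' measurements use the package's canonical units (cm, kg, mmHg, mg/dl,
#' ng/ml, cm^2).
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param height,weight Height (cm) and weight (kg).
#' @param wc,hc Waist and hip circumference (cm).
#' @param sbp,dbp Systolic/diastolic blood pressure (mmHg).
#' @param glucose Fasting plasma glucose (mg/dl).
#' @param tg,hdl,ldl Triglycerides, HDL-C, LDL-C (mg/dl).
#' @param c_peptide Fasting C-peptide (ng/ml).
#' @param bp_treated Logical; on antihypertensive treatment.
#' @param ct_vat,ct_sat Measured visceral / subcutaneous adipose tissue
#'   area at L3 (cm^2).
#' @param subject_id Identifier, unique within a cohort.
#' @return A one-row data frame in the cohort schema.
#' @examples
#' subject_record(sex = "male", age = 40, height = 175, weight = 81.2,
#'                wc = 93.6, hc = 103.4)
#' @export
subject_record <- function(sex, age = NA_real_, height = NA_real_,
                           weight = NA_real_, wc = NA_real_, hc = NA_real_,
                           sbp = NA_real_, dbp = NA_real_,
                           glucose = NA_real_, tg = NA_real_,
                           hdl = NA_real_, ldl = NA_real_,
                           c_peptide = NA_real_, bp_treated = FALSE,
                           ct_vat = NA_real_, ct_sat = NA_real_,
                           subject_id = "S1") {
  data.frame(
    subject_id = subject_id, sex = .normalize_sex(sex), age = age,
    height = height, weight = weight, wc = wc, hc = hc, sbp = sbp,
    dbp = dbp, glucose = glucose, tg = tg, hdl = hdl, ldl = ldl,
    c_peptide = c_peptide, bp_treated = bp_treated, ct_vat = ct_vat,
    ct_sat = ct_sat, stringsAsFactors = FALSE
  )
}

#' Validate a cohort data frame
#'
#' Checks the invariants of the subject data model: sex is `male`/`female`,
#' physical measurements strictly positive when present, age within
#' \[18, 120\], derived BMI finite and positive, `subject_id` unique.
#' All violations are collected and reported together, indexed by row and
#' field.
#'
#' @param data A data frame in the cohort schema.
#' @param label Provenance tag stored on the returned cohort.
#' @return The validated data (classed `vat_cohort`), invisibly usable as
#'   a plain data frame.
#' @export
validate_cohort <- function(data, label = "cohort") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  problems <- character(0)
  note <- function(row, field, msg) {
    problems[[length(problems) + 1L]] <<- sprintf("row %d / %s: %s", row, field, msg)
  }

  if (!"subject_id" %in% names(data)) {
    data$subject_id <- if (nrow(data)) sprintf("S%d", seq_len(nrow(data))) else character(0)
  }
  missing_req <- setdiff(.COHORT_REQUIRED, names(data))
  if (length(missing_req)) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  for (f in intersect(.COHORT_NUMERIC, names(data))) {
    if (!is.numeric(data[[f]])) {
      coerced <- suppressWarnings(as.numeric(as.character(data[[f]])))
      bad <- which(!is.na(data[[f]]) & as.character(data[[f]]) != "" & is.na(coerced))
      for (r in bad) note(r, f, sprintf("non-numeric value '%s'", data[[f]][r]))
      data[[f]] <- coerced
    }
  }

  data$sex <- .normalize_sex(data$sex)
  for (r in which(!is.na(data$sex) & !data$sex %in% c("male", "female"))) {
    note(r, "sex", sprintf("must be 'male' or 'female', got '%s'", data$sex[r]))
  }
  for (r in which(is.na(data$sex))) note(r, "sex", "missing")

  for (f in intersect(.COHORT_POSITIVE, names(data))) {
    for (r in which(!is.na(data[[f]]) & data[[f]] <= 0)) {
      note(r, f, sprintf("must be strictly positive, got %g", data[[f]][r]))
    }
  }
  for (r in which(!is.na(data$age) & (data$age < 18 | data$age > 120))) {
    note(r, "age", sprintf("must lie in [18, 120], got %g", data$age[r]))
  }

  ok_hw <- !is.na(data$height) & !is.na(data$weight) &
    data$height > 0 & data$weight > 0
  bmi_derived <- ifelse(ok_hw, data$weight / (data$height / 100)^2, NA_real_)
  for (r in which(ok_hw & !is.finite(bmi_derived))) {
    note(r, "bmi", "derived BMI is not finite")
  }

  dup <- data$subject_id[duplicated(data$subject_id)]
  if (length(dup)) {
    problems[[length(problems) + 1L]] <-
      sprintf("duplicated subject_id: %s", paste(unique(dup), collapse = ", "))
  }
  if (length(problems)) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  if ("bp_treated" %in% names(data)) {
    data$bp_treated <- as.logical(data$bp_treated)
    data$bp_treated[is.na(data$bp_treated)] <- FALSE
  }
  structure(data, class = c("vat_cohort", "data.frame"), label = label)
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated, header-first cohort table, applies an
#' optional column-name mapping (canonical name -> source column), and
#' validates every row against the subject-record invariants.  Columns
#' outside the canonical schema are dropped; absent optional fields stay
#' absent (NA).
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical
#'   field names to source column names, e.g.
#'   `c(wc = "waist_circumference_cm")`.
#' @param label Provenance tag.
#' @return A validated `vat_cohort` data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, column_map = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column_map refers to absent source column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_req <- setdiff(.COHORT_REQUIRED, names(raw))
  if (length(missing_req)) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(.COHORT_FIELDS, names(raw))
  validate_cohort(raw[keep], label = label)
}

#' Write a cohort to CSV
#'
#' Round-trips losslessly with [read_cohort()]: text fields bit-equal,
#' numerics to full double precision, absent optional values emitted as
#' empty cells.
#'
#' @param cohort A (validated) cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- as.data.frame(cohort, stringsAsFactors = FALSE)
  keep <- intersect(.COHORT_FIELDS, names(out))
  out <- out[keep]
  for (f in intersect(.COHORT_NUMERIC, names(out))) {
    v <- out[[f]]
    s <- rep(NA_character_, length(v))
    s[!is.na(v)] <- sprintf("%.17g", v[!is.na(v)])  # lossless double text
    out[[f]] <- s
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @export
print.vat_cohort <- function(x, ...) {
  cat(sprintf("<vat_cohort '%s': %d subjects (%d female, %d male)>\n",
              attr(x, "label") %||% "cohort", nrow(x),
              sum(x$sex == "female", na.rm = TRUE),
              sum(x$sex == "male", na.rm = TRUE)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BMI used for prediction and indices: computed from height/weight when
# both present (a conflicting explicit bmi column loses, with a warning
# beyond 0.1 kg/m^2); an explicit bmi column is honoured otherwise.
.resolve_bmi <- function(data) {
  has_hw <- !is.null(data[["height"]]) && !is.null(data[["weight"]])
  explicit <- data[["bmi"]]
  if (has_hw) {
    computed <- bmi(data[["height"]], data[["weight"]])
    if (!is.null(explicit)) {
      both <- !is.na(computed) & !is.na(explicit)
      if (any(both & abs(computed - explicit) > 0.1)) {
        warning("explicit bmi differs from height/weight-derived bmi by ",
                "> 0.1 kg/m^2 in ", sum(both & abs(computed - explicit) > 0.1),
                " row(s); computed value used", call. = FALSE)
      }
      computed[is.na(computed)] <- explicit[is.na(computed)]
    }
    return(computed)
  }
  if (!is.null(explicit)) return(explicit)
  rep(NA_real_, max(1L, nrow(data)))
}
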