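# MARS model representation: a constant plus coefficient-weighted
# products of hinge factors max(0, +/-(x - knot)) and categorical
# indicator factors.  Degree is capped at 2 (first-order interactions).

#' Hinge factor
#'
#' One piecewise-linear factor of a MARS basis function:
#' `max(0, x - knot)` (`direction = "above"`) or `max(0, knot - x)`
#' (`direction = "below"`).
#'
#' @param variable Canonical predictor name.
#' @param knot Knot location, in the variable's units.
#' @param direction `"above"` or `"below"`.
#' @return A `hinge` factor object.
#' @export
hinge <- function(variable, knot, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.character(variable), length(variable) == 1L,
            is.numeric(knot), length(knot) == 1L, is.finite(knot))
  structure(list(kind = "hinge", variable = variable, knot = knot,
                 direction = direction),
            class = c("hinge", "mars_factor"))
}

#' Indicator factor
#'
#' A 0/1 factor that is 1 when a categorical predictor takes `level`.
#'
#' @param variable Categorical predictor name.
#' @param level Category value switching the factor on.
#' @return An `indicator` factor object.
#' @export
indicator <- function(variable, level) {
  stopifnot(is.character(variable), length(variable) == 1L,
            length(level) == 1L)
  structure(list(kind = "indicator", variable = variable,
                 level = as.character(level)),
            class = c("indicator", "mars_factor"))
}

#' Basis function
#'
#' A coefficient times a product of one or two factors.  A variable may
#' appear in at most one factor of a basis function.
#'
#' @param coefficient Coefficient, in response units per product of
#'   factor units.
#' @param factors A list of [hinge()] / [indicator()] factors (length 1
#'   or 2).
#' @return A `basis_function` object.
#' @export
basis_function <- function(coefficient, factors) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient), is.list(factors))
  if (length(factors) < 1L || length(factors) > 2L) {
    stop("a basis function has degree 1 or 2 (use the model constant for ",
         "degree 0)", call. = FALSE)
  }
  vars <- vapply(factors, function(f) f$variable, character(1))
  if (anyDuplicated(vars)) {
    stop("a variable may not appear twice in one basis function",
         call. = FALSE)
  }
  structure(list(coefficient = coefficient, factors = factors),
            class = "basis_function")
}

#' MARS model container
#'
#' @param constant Model constant, in response units.
#' @param basis_functions Ordered list of [basis_function()] terms.
#' @param response_name Name of the response, for reporting.
#' @param predictors Optional character vector of predictor names; derived
#'   from the terms when omitted.
#' @return A `mars_model` object, usable with [predict_vat()] /
#'   `predict()`.
#' @export
mars_model <- function(constant, basis_functions = list(),
                       response_name = "ct_vat", predictors = NULL) {
  stopifnot(is.numeric(constant), length(constant) == 1L,
            is.finite(constant), is.list(basis_functions))
  for (bf in basis_functions) stopifnot(inherits(bf, "basis_function"))
  used <- unique(unlist(lapply(basis_functions, function(bf)
    vapply(bf$factors, function(f) f$variable, character(1)))))
  structure(
    list(constant = constant, basis_functions = basis_functions,
         response_name = response_name,
         predictors = predictors %||% used),
    class = "mars_model"
  )
}

.factor_values <- function(f, data) {
  x <- data[[f$variable]]
  if (is.null(x)) {
    stop("missing predictor '", f$variable, "' in data", call. = FALSE)
  }
  if (f$kind == "hinge") {
    if (!is.numeric(x)) stop("predictor '", f$variable, "' must be numeric",
                             call. = FALSE)
    if (f$direction == "above") pmax(0, x - f$knot) else pmax(0, f$knot - x)
  } else {
    as.numeric(as.character(x) == f$level)
  }
}

#' Evaluate one basis function on subject data
#'
#' Returns the contribution of a single basis function, i.e. its
#' coefficient times the product of its factor values; any inactive hinge
#' or indicator makes the contribution zero.
#'
#' @param bf A [basis_function()].
#' @param data A subject record (one-row data frame / named list) or a
#'   whole cohort; vectorised over rows.
#' @return Numeric contribution(s) in response units.
#' @examples
#' bf1 <- published_vat_model()$basis_functions[[1]]
#' evaluate_basis(bf1, subject_record(sex = "female"))  # -79.9
#' @export
evaluate_basis <- function(bf, data) {
  stopifnot(inherits(bf, "basis_function"))
  .basis_values(bf, .model_frame(data))
}

.basis_values <- function(bf, data) {
  vals <- lapply(bf$factors, .factor_values, data = data)
  bf$coefficient * Reduce(`*`, vals)
}

# Normalizes sex + resolves bmi for model evaluation.
.model_frame <- function(data) {
  if (!is.data.frame(data)) data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!is.null(data[["sex"]])) data$sex <- .normalize_sex(data$sex)
  data$bmi <- .resolve_bmi(data)
  data
}

#' Predict visceral adipose tissue area
#'
#' Evaluates a MARS model (by default the published one, see
#' [published_vat_model()]) on one record or a cohort: the constant plus
#' the sum of all basis-function contributions.  BMI is derived from
#' height and weight when available, otherwise an explicit `bmi` column
#' is honoured.
#'
#' @param model A `mars_model`.
#' @param data A subject record or cohort data frame.
#' @param check_range Warn when a prediction falls outside the
#'   physiologically plausible \[0, 700\] cm^2.
#' @return Predicted VAT area(s) in cm^2.
#' @examples
#' rec <- subject_record(sex = "male", wc = 111, hc = 106,
#'                       height = 175, weight = 25.9 * 1.75^2)
#' predict_vat(published_vat_model(), rec)  # 249, all basis functions zero
#' @export
predict_vat <- function(model = published_vat_model(), data,
                        check_range = TRUE) {
  stopifnot(inherits(model, "mars_model"))
  data <- .model_frame(data)
  for (v in model$predictors) {
    if (is.null(data[[v]])) {
      stop("missing predictor '", v, "' in data", call. = FALSE)
    }
  }
  pred <- rep(model$constant, nrow(data))
  for (bf in model$basis_functions) pred <- pred + .basis_values(bf, data)
  if (anyNA(pred)) {
    bad <- unique(unlist(lapply(model$predictors, function(v)
      if (anyNA(data[[v]])) v)))
    stop("missing predictor value(s) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (check_range && any(pred < 0 | pred > 700)) {
    warning(sum(pred < 0 | pred > 700), " prediction(s) outside the ",
            "plausible 0-700 cm^2 range", call. = FALSE)
  }
  pred
}

#' @export
predict.mars_model <- function(object, newdata, ...) {
  predict_vat(object, newdata, ...)
}

#' Predict VAT for a cohort with per-row error policy
#'
#' Order-preserving batch prediction.  With `on_invalid = "skip"`, rows
#' whose predictors are missing are skipped and reported (attribute
#' `"skipped"`: row index and reason) instead of failing the batch.
#'
#' @inheritParams predict_vat
#' @param cohort Cohort data frame.
#' @param on_invalid `"error"` (default) or `"skip"`.
#' @return Numeric predictions for the retained rows, with attribute
#'   `"skipped"` (a data frame of `row`, `reason`) when skipping.
#' @export
predict_vat_batch <- function(model = published_vat_model(), cohort,
                              on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  data <- .model_frame(cohort)
  if (on_invalid == "error" || nrow(data) == 0L) {
    out <- if (nrow(data) == 0L) numeric(0) else predict_vat(model, data)
    attr(out, "skipped") <- data.frame(row = integer(0),
                                       reason = character(0))
    return(out)
  }
  reasons <- rep(NA_character_, nrow(data))
  for (v in model$predictors) {
    miss <- if (is.null(data[[v]])) rep(TRUE, nrow(data)) else is.na(data[[v]])
    reasons[miss & is.na(reasons)] <- paste0(v, " absent")
  }
  keep <- is.na(reasons)
  if (!any(keep)) stop("no valid rows to predict", call. = FALSE)
  out <- predict_vat(model, data[keep, , drop = FALSE])
  attr(out, "skipped") <- data.frame(row = which(!keep),
                                     reason = reasons[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' The published VAT prediction model
#'
#' The final sex-specific MARS model: constant 249 cm^2 and seven basis
#' functions over female sex, waist circumference (cm), hip circumference
#' (cm) and BMI (kg/m^2), with knots at WC 111, HC 106, BMI 25.9 / 28.4 /
#' 29.  It is loaded from the JSON fixture shipped with the package (see
#' [read_mars_model()]).
#'
#' @return A `mars_model` with 7 basis functions.
#' @examples
#' m <- published_vat_model()
#' m$constant                      # 249
#' length(m$basis_functions)       # 7
#' @export
published_vat_model <- function() {
  path <- system.file("extdata", "vat_mars_model.json", package = "vatmars",
                      mustWork = TRUE)
  read_mars_model(path)
}

#' Serialize / deserialize a MARS model as JSON
#'
#' The document stores the constant, the response name, and one entry per
#' basis function with its coefficient and factor list
#' (`{variable, kind, knot, direction}` or `{variable, kind, level}`).
#'
#' @param model A `mars_model`.
#' @param path JSON file path.
#' @return `write_mars_model()` returns `path` invisibly;
#'   `read_mars_model()` returns the `mars_model`.
#' @export
write_mars_model <- function(model, path) {
  stopifnot(inherits(model, "mars_model"))
  doc <- list(
    response = model$response_name,
    constant = model$constant,
    basis_functions = lapply(model$basis_functions, function(bf) {
      list(coefficient = bf$coefficient,
           factors = lapply(bf$factors, function(f) unclass(f)))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mars_model
#' @export
read_mars_model <- function(path) {
  doc <- jsonlite::read_json(path)
  bfs <- lapply(doc$basis_functions, function(b) {
    factors <- lapply(b$factors, function(f) {
      if (f$kind == "hinge") hinge(f$variable, as.numeric(f$knot), f$direction)
      else indicator(f$variable, f$level)
    })
    basis_function(as.numeric(b$coefficient), factors)
  })
  mars_model(as.numeric(doc$constant), bfs,
             response_name = doc$response %||% "ct_vat")
}

.describe_factor <- function(f) {
  if (f$kind == "hinge") {
    if (f$direction == "above") sprintf("max(0, %s - %g)", f$variable, f$knot)
    else sprintf("max(0, %g - %s)", f$knot, f$variable)
  } else {
    sprintf("[%s = %s]", f$variable, f$level)
  }
}

.describe_term <- function(factors) {
  paste(vapply(factors, .describe_factor, character(1)), collapse = " * ")
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("MARS model for %s (%d basis functions)\n", x$response_name,
              length(x$basis_functions)))
  cat(sprintf("  %10.4g  (constant)\n", x$constant))
  for (bf in x$basis_functions) {
    cat(sprintf("  %+10.4g  * %s\n", bf$coefficient,
                .describe_term(bf$factors)))
  }
  invisible(x)
}
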