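# ROC analysis with DeLong placement variance and paired-AUC tests.
# The AUC is the Mann-Whitney placement estimator (ties count 1/2);
# standard errors come from the per-observation placement components of
# DeLong, DeLong & Clarke-Pearson (1988), computed via midranks.

.check_labels <- function(scores, labels) {
  stopifnot(is.numeric(scores))
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels) || !all(is.finite(scores))) {
    stop("scores and labels must be complete and finite", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1, logical, or two-level factor)",
         call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  as.integer(labels)
}

# Midrank-based placement components: V10 (cases), V01 (controls).
.placements <- function(scores, labels) {
  cases <- scores[labels == 1L]
  controls <- scores[labels == 0L]
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_cases <- rank(cases, ties.method = "average")
  r_controls <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m
  list(v10 = v10, v01 = v01, m = m, n = n,
       auc = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n))
}

#' ROC curve and AUC with DeLong standard error
#'
#' @param scores Numeric marker values; higher scores indicate the
#'   positive class.
#' @param labels Binary outcomes (0/1, logical, or two-level factor with
#'   the positive class second).
#' @return A `vat_roc` object: `auc`, `se`, placement components
#'   (`case_placements`, `control_placements`), class counts, and the
#'   ROC step `curve` (`fpr`, `tpr`), starting at (0,0) and ending at
#'   (1,1).
#' @examples
#' r <- roc_auc(c(3, 5, 1, 2, 4), c(1, 1, 0, 0, 0))
#' r$auc  # 5/6
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_labels(scores, labels)
  pl <- .placements(scores, labels)
  s10 <- if (pl$m > 1L) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1L) stats::var(pl$v01) else 0
  se <- sqrt(s10 / pl$m + s01 / pl$n)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  curve <- data.frame(fpr = c(0, fp / pl$n), tpr = c(0, tp / pl$m))
  structure(list(auc = pl$auc, se = se,
                 case_placements = pl$v10, control_placements = pl$v01,
                 n_cases = pl$m, n_controls = pl$n, curve = curve),
            class = "vat_roc")
}

#' @export
print.vat_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (DeLong SE %.4f), %d cases / %d controls\n",
              x$auc, x$se, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
plot.vat_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using
#' the covariance of their placement components:
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`, two-sided normal
#' p-value.  Identical markers give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Marker values on the same subjects.
#' @inheritParams roc_auc
#' @return A `delong_comparison` object: `auc_a`, `auc_b`, `var_a`,
#'   `var_b`, `covariance`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must have equal length (same subjects)",
         call. = FALSE)
  }
  labels <- .check_labels(scores_a, labels)
  .check_labels(scores_b, labels)
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  m <- pa$m; n <- pa$n
  var_a <- (if (m > 1L) stats::var(pa$v10) else 0) / m +
    (if (n > 1L) stats::var(pa$v01) else 0) / n
  var_b <- (if (m > 1L) stats::var(pb$v10) else 0) / m +
    (if (n > 1L) stats::var(pb$v01) else 0) / n
  covab <- (if (m > 1L) stats::cov(pa$v10, pb$v10) else 0) / m +
    (if (n > 1L) stats::cov(pa$v01, pb$v01) else 0) / n
  d <- pa$auc - pb$auc
  v <- var_a + var_b - 2 * covab
  if (v <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      stop("degenerate variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_a = var_a,
                 var_b = var_b, covariance = covab, z = z, p = p),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Sensitivity and specificity at a cutoff
#'
#' Positive call when `score >= cutoff`.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold, in score units.
#' @return List with `sensitivity` and `specificity`.
#' @export
operating_point <- function(scores, labels, cutoff) {
  labels <- .check_labels(scores, labels)
  pos <- scores >= cutoff
  list(sensitivity = sum(pos & labels == 1L) / sum(labels == 1L),
       specificity = sum(!pos & labels == 0L) / sum(labels == 0L))
}

#' Cutoff with balanced and high sensitivity/specificity
#'
#' Among the observed score values, maximizes Youden's
#' `J = sensitivity + specificity - 1`; ties are broken by the smaller
#' `|sensitivity - specificity|`, then by the smaller cutoff.
#'
#' @inheritParams roc_auc
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- .check_labels(scores, labels)
  cand <- sort(unique(scores))
  best <- NULL
  for (ct in cand) {
    op <- operating_point(scores, labels, ct)
    j <- op$sensitivity + op$specificity - 1
    bal <- abs(op$sensitivity - op$specificity)
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && bal < best$balance - 1e-12)) {
      best <- list(cutoff = ct, sensitivity = op$sensitivity,
                   specificity = op$specificity, youden_j = j,
                   balance = bal)
    }
  }
  best$balance <- NULL
  best
}

.MARKER_BUILDERS <- list(
  new_model = function(data) predict_vat(published_vat_model(), data,
                                         check_range = FALSE),
  bmi = function(data) .model_frame(data)$bmi,
  wc = function(data) data$wc,
  mets_vf = function(data) mets_vf(data, strict = FALSE),
  vai = function(data) vai(data, strict = FALSE),
  whr = function(data) whr(data, strict = FALSE),
  absi = function(data) absi(data, strict = FALSE),
  lap = function(data) lap(data, strict = FALSE),
  bri = function(data) bri(data, strict = FALSE)
)

#' Compare the model with the adiposity indices by ROC
#'
#' Computes, per sex stratum (or overall), the AUC and DeLong SE of each
#' marker for the increased-VAT outcome `ct_vat > threshold`, plus the
#' DeLong paired p-value of each marker against the reference marker.
#' Strata where only one outcome class is present are skipped with a
#' warning.
#'
#' @param cohort Cohort data frame with measured `ct_vat`.
#' @param threshold Increased-VAT cutoff in cm^2 (130 by default).
#' @param markers Character vector naming markers to evaluate (subset of
#'   `new_model`, `bmi`, `wc`, `mets_vf`, `vai`, `whr`, `absi`, `lap`,
#'   `bri`), or a named list of numeric score vectors.
#' @param reference Name of the reference marker for the pairwise tests.
#' @param stratify_by_sex Analyse male/female strata separately.
#' @return Data frame: `stratum`, `marker`, `auc`, `se`, `p_vs_reference`
#'   (NA for the reference itself).
#' @export
compare_indices <- function(cohort, threshold = 130,
                            markers = names(.MARKER_BUILDERS),
                            reference = "new_model",
                            stratify_by_sex = TRUE) {
  data <- .model_frame(cohort)
  if (is.null(data$ct_vat) || anyNA(data$ct_vat)) {
    stop("compare_indices() requires measured ct_vat for every record",
         call. = FALSE)
  }
  stopifnot(threshold > 0)
  if (is.character(markers)) {
    unknown <- setdiff(markers, names(.MARKER_BUILDERS))
    if (length(unknown)) stop("unknown marker(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    scores <- lapply(.MARKER_BUILDERS[markers], function(f) f(data))
  } else {
    stopifnot(is.list(markers), !is.null(names(markers)))
    scores <- markers
  }
  if (!reference %in% names(scores)) {
    stop("reference marker '", reference, "' not among markers",
         call. = FALSE)
  }
  outcome <- as.integer(data$ct_vat > threshold)
  strata <- if (stratify_by_sex) split(seq_len(nrow(data)), data$sex) else
    list(all = seq_len(nrow(data)))
  rows <- list()
  for (st in names(strata)) {
    idx <- strata[[st]]
    if (length(unique(outcome[idx])) < 2L) {
      warning("stratum '", st, "' has a single outcome class; skipped",
              call. = FALSE)
      next
    }
    for (mk in names(scores)) {
      sc <- scores[[mk]][idx]
      ok <- !is.na(sc)
      r <- roc_auc(sc[ok], outcome[idx][ok])
      p <- if (mk == reference) NA_real_ else {
        ok2 <- ok & !is.na(scores[[reference]][idx])
        delong_test(scores[[reference]][idx][ok2], scores[[mk]][idx][ok2],
                    outcome[idx][ok2])$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, marker = mk, auc = r$auc, se = r$se,
        p_vs_reference = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
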