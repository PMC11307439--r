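# MARS fitting engine: greedy forward selection of hinge pairs (and
# categorical indicators) with first-order interactions, followed by
# backward deletion under generalized cross-validation (GCV).
#
# Terms are represented as factor lists (as in basis_function()); the
# intercept is the empty factor list.  Candidate knots are observed data
# values, thinned by `min_span` and excluding the extremes of the
# parent-active range.

#' Fitting configuration
#'
#' @param max_basis_functions Forward-pass budget for non-constant terms
#'   (a hinge pair counts as two).
#' @param max_degree Maximum number of factors per term: 1 (additive) or
#'   2 (first-order interactions).
#' @param gcv_penalty Cost per non-constant term in the GCV
#'   effective-parameter count; 3 is the conventional value when
#'   interactions are allowed.
#' @param min_span Minimum number of observations between candidate
#'   knots; 1 admits every interior data value.
#' @param forward_tolerance Smallest relative residual-sum-of-squares
#'   improvement for the forward pass to continue.
#' @param seed Integer seed for seeded sub-procedures (fold assignment).
#' @return A `mars_control` list.
#' @export
mars_control <- function(max_basis_functions = 20L, max_degree = 2L,
                         gcv_penalty = 3, min_span = 1L,
                         forward_tolerance = 1e-4, seed = 0L) {
  stopifnot(max_basis_functions >= 1L, max_degree %in% c(1L, 2L),
            gcv_penalty >= 0, min_span >= 1L, forward_tolerance >= 0)
  structure(list(max_basis_functions = as.integer(max_basis_functions),
                 max_degree = as.integer(max_degree),
                 gcv_penalty = gcv_penalty,
                 min_span = as.integer(min_span),
                 forward_tolerance = forward_tolerance,
                 seed = as.integer(seed)),
            class = "mars_control")
}

.term_vars <- function(tf) vapply(tf, function(f) f$variable, character(1))

.term_column <- function(tf, data) {
  if (!length(tf)) return(rep(1, nrow(data)))
  Reduce(`*`, lapply(tf, .factor_values, data = data))
}

.design_matrix <- function(terms, data) {
  vapply(terms, .term_column, numeric(nrow(data)), data = data)
}

.check_xy <- function(x, y) {
  stopifnot(is.data.frame(x), is.numeric(y))
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (anyNA(x) || anyNA(y)) {
    stop("missing values in predictors or response are not allowed",
         call. = FALSE)
  }
  if (!all(is.finite(y))) stop("non-finite response values", call. = FALSE)
  invisible(TRUE)
}

.candidate_knots <- function(x_active, min_span) {
  xs <- sort(x_active)
  n <- length(xs)
  if (n < 2L * min_span + 1L) return(numeric(0))
  unique(xs[seq(1L + min_span, n - min_span, by = min_span)])
}

#' Forward pass of the MARS algorithm
#'
#' Greedily grows a model from the constant: at each step the (parent
#' term x hinge pair at a candidate knot) or (parent term x categorical
#' indicator) with the largest residual-sum-of-squares reduction is
#' added, honouring `max_degree`, no variable reuse within a term, and
#' `min_span`.  Hinge pairs enter jointly; a rank-deficient member is
#' dropped with a log entry.  Stops at the basis-function budget or when
#' the relative RSS improvement falls below `forward_tolerance`.
#'
#' @param x Predictor data frame (numeric columns enter as hinges,
#'   character/factor columns as indicators; reference level = first
#'   alphabetically).
#' @param y Numeric response.
#' @param control A [mars_control()].
#' @return An (intentionally overfit) `mars_model` candidate with
#'   least-squares coefficients, carrying a `"trace"` attribute and a
#'   `"terms"` attribute used by [backward_prune()].
#' @export
forward_pass <- function(x, y, control = mars_control()) {
  .check_xy(x, y)
  n <- length(y)
  if (n < 10L) stop("forward_pass() needs at least 10 observations",
                    call. = FALSE)
  vars <- names(x)
  is_cat <- vapply(x, function(col) is.character(col) || is.factor(col),
                   logical(1))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (v in vars[is_cat]) x[[v]] <- as.character(x[[v]])
  cat_levels <- lapply(x[vars[is_cat]], function(col) sort(unique(col)))

  terms <- list(list())                 # intercept
  B <- matrix(1, n, 1)
  trace <- list()
  log_row <- function(action, term, rss) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = "forward", step = length(trace) + 1L, action = action,
      term = term, rss = rss, gcv = NA_real_, stringsAsFactors = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  repeat {
    n_bf <- length(terms) - 1L
    if (n_bf >= control$max_basis_functions) break
    allow_pair <- (control$max_basis_functions - n_bf) >= 2L
    qrB <- qr(B)
    r <- qr.resid(qrB, y)
    rss <- sum(r^2)
    if (rss <= 1e-12 * (sst + 1)) break
    Q <- qr.Q(qrB)

    best <- list(red = 0)
    consider <- function(red, cols, factors_new, desc) {
      if (is.finite(red) && red > best$red) {
        best <<- list(red = red, cols = cols, factors = factors_new,
                      desc = desc)
      }
    }
    resid_cols <- function(H) H - Q %*% crossprod(Q, H)

    for (ti in seq_along(terms)) {
      parent <- terms[[ti]]
      if (length(parent) >= control$max_degree) next
      pcol <- B[, ti]
      active <- pcol != 0
      if (sum(active) < 3L) next
      pvars <- .term_vars(parent)
      for (v in setdiff(vars, pvars)) {
        if (is_cat[[v]]) {
          lev <- cat_levels[[v]]
          for (lv in lev[-1L]) {
            h <- pcol * (x[[v]] == lv)
            cn <- sum(h^2)
            if (cn == 0) next
            rh <- resid_cols(matrix(h, ncol = 1))
            a <- sum(rh^2)
            if (a <= 1e-10 * cn) next
            b <- sum(rh * r)
            consider(b^2 / a, matrix(h, ncol = 1),
                     list(c(parent, list(indicator(v, lv)))),
                     sprintf("%s[%s = %s]",
                             if (length(parent)) paste0(.describe_term(parent), " * ") else "",
                             v, lv))
          }
        } else {
          knots <- .candidate_knots(x[[v]][active], control$min_span)
          if (!length(knots)) next
          xv <- x[[v]]
          D <- outer(xv, knots, "-")
          H1 <- pcol * pmax(D, 0)      # above-knot hinges (pmax keeps dim
          H2 <- pcol * pmax(-D, 0)     # of its first argument)
          cn1 <- colSums(H1^2); cn2 <- colSums(H2^2)
          R1 <- resid_cols(H1); R2 <- resid_cols(H2)
          a11 <- colSums(R1^2); a22 <- colSums(R2^2)
          a12 <- colSums(R1 * R2)
          b1 <- drop(crossprod(R1, r)); b2 <- drop(crossprod(R2, r))
          ok1 <- cn1 > 0 & a11 > 1e-10 * cn1
          ok2 <- cn2 > 0 & a22 > 1e-10 * cn2
          det <- a11 * a22 - a12^2
          okp <- allow_pair & ok1 & ok2 & det > 1e-10 * a11 * a22
          red_pair <- ifelse(okp,
                             (a22 * b1^2 - 2 * a12 * b1 * b2 + a11 * b2^2) / det,
                             -Inf)
          red_ab <- ifelse(ok1, b1^2 / a11, -Inf)
          red_be <- ifelse(ok2, b2^2 / a22, -Inf)
          for (ki in seq_along(knots)) {
            k <- knots[ki]
            ha <- hinge(v, k, "above"); hb <- hinge(v, k, "below")
            pre <- if (length(parent)) paste0(.describe_term(parent), " * ") else ""
            if (red_pair[ki] >= red_ab[ki] && red_pair[ki] >= red_be[ki]) {
              consider(red_pair[ki], cbind(H1[, ki], H2[, ki]),
                       list(c(parent, list(ha)), c(parent, list(hb))),
                       sprintf("%shinge pair %s @ %g", pre, v, k))
            } else if (red_ab[ki] >= red_be[ki]) {
              consider(red_ab[ki], H1[, ki, drop = FALSE],
                       list(c(parent, list(ha))),
                       sprintf("%smax(0, %s - %g)", pre, v, k))
            } else {
              consider(red_be[ki], H2[, ki, drop = FALSE],
                       list(c(parent, list(hb))),
                       sprintf("%smax(0, %g - %s)", pre, k, v))
            }
          }
        }
      }
    }

    if (best$red <= 0 || best$red < control$forward_tolerance * rss) break
    terms <- c(terms, best$factors)
    B <- cbind(B, best$cols)
    log_row("add", best$desc, rss - best$red)
  }

  qrB <- qr(B)
  coefs <- qr.coef(qrB, y)
  coefs[is.na(coefs)] <- 0
  bfs <- vector("list", length(terms) - 1L)
  for (i in seq_along(bfs)) {
    bfs[[i]] <- basis_function(coefs[i + 1L], terms[[i + 1L]])
  }
  model <- mars_model(coefs[1L], bfs, predictors = vars)
  attr(model, "terms") <- terms
  attr(model, "trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(phase = character(0), step = integer(0),
               action = character(0), term = character(0), rss = numeric(0),
               gcv = numeric(0))
  model
}

.refit <- function(B, y) {
  qrB <- qr(B)
  co <- qr.coef(qrB, y)
  rank_ok <- !anyNA(co)
  co[is.na(co)] <- 0
  list(coef = co, rss = sum(qr.resid(qrB, y)^2), rank_ok = rank_ok)
}

.gcv_value <- function(rss, n, n_terms, penalty) {
  c_eff <- n_terms + penalty * (n_terms - 1L)
  if (c_eff >= n) return(Inf)
  (rss / n) / (1 - c_eff / n)^2
}

#' Generalized cross-validation score of a MARS model
#'
#' Refits the model's terms on `(x, y)` by least squares and returns
#' `MSE / (1 - C(M)/n)^2` with effective parameters
#' `C(M) = M + penalty * (M - 1)`, `M` counting terms including the
#' constant.  Returns `Inf` when `C(M) >= n`.
#'
#' @inheritParams forward_pass
#' @param model A `mars_model`.
#' @param penalty GCV cost per non-constant term.
#' @return The GCV score (response-squared units).
#' @export
gcv_score <- function(model, x, y, penalty = 3) {
  stopifnot(inherits(model, "mars_model"))
  .check_xy(x, y)
  terms <- c(list(list()), lapply(model$basis_functions, `[[`, "factors"))
  B <- .design_matrix(terms, x)
  fit <- .refit(B, y)
  .gcv_value(fit$rss, length(y), length(terms), penalty)
}

#' Backward pruning by GCV
#'
#' Starting from a forward-pass candidate, iteratively deletes the
#' non-constant term whose removal gives the lowest GCV, refitting the
#' coefficients by least squares at every step, and returns the
#' GCV-minimal model over the whole deletion sequence.
#'
#' @inheritParams forward_pass
#' @param candidate A `mars_model` (typically from [forward_pass()]).
#' @return A `mars_fit` object: `model`, `gcv`, `rsq` (training),
#'   `importance` (see [variable_importance()]) and `trace`.
#' @export
backward_prune <- function(candidate, x, y, control = mars_control()) {
  stopifnot(inherits(candidate, "mars_model"))
  .check_xy(x, y)
  n <- length(y)
  terms <- c(list(list()), lapply(candidate$basis_functions, `[[`, "factors"))
  B <- .design_matrix(terms, x)
  penalty <- control$gcv_penalty
  sst <- sum((y - mean(y))^2)

  state_gcv <- function(idx) {
    fit <- .refit(B[, idx, drop = FALSE], y)
    list(gcv = .gcv_value(fit$rss, n, length(idx), penalty),
         rss = fit$rss, coef = fit$coef)
  }

  current <- seq_along(terms)
  full <- state_gcv(current)
  best <- list(idx = current, gcv = full$gcv, rss = full$rss,
               coef = full$coef)
  deletions <- list()
  trace <- list(data.frame(phase = "backward", step = 0L,
                           action = "start", term = sprintf("%d terms", length(current) - 1L),
                           rss = full$rss, gcv = full$gcv,
                           stringsAsFactors = FALSE))
  gcv_now <- full$gcv
  while (length(current) > 1L) {
    cand_gcv <- vapply(seq_along(current)[-1L], function(ci) {
      state_gcv(current[-ci])$gcv
    }, numeric(1))
    ci <- which.min(cand_gcv) + 1L       # first minimum wins ties
    removed <- current[ci]
    new <- state_gcv(current[-ci])
    deletions[[length(deletions) + 1L]] <- list(
      term = removed, gcv_before = gcv_now, gcv_after = new$gcv)
    current <- current[-ci]
    trace[[length(trace) + 1L]] <- data.frame(
      phase = "backward", step = length(deletions), action = "remove",
      term = .describe_term(terms[[removed]]), rss = new$rss, gcv = new$gcv,
      stringsAsFactors = FALSE)
    if (new$gcv < best$gcv) {
      best <- list(idx = current, gcv = new$gcv, rss = new$rss,
                   coef = new$coef)
    }
    gcv_now <- new$gcv
  }

  final_terms <- terms[best$idx]
  bfs <- vector("list", length(final_terms) - 1L)
  for (i in seq_along(bfs)) {
    bfs[[i]] <- basis_function(best$coef[i + 1L], final_terms[[i + 1L]])
  }
  model <- mars_model(best$coef[1L], bfs, predictors = names(x))

  importance <- .importance_from_deletions(terms, deletions, best$idx)
  structure(list(
    model = model,
    gcv = best$gcv,
    rsq = if (sst > 0) 1 - best$rss / sst else 1,
    importance = importance,
    trace = do.call(rbind, c(list(attr(candidate, "trace")), trace)),
    control = control, n = n
  ), class = "mars_fit")
}

# Importance: walking the deletion sequence, the GCV increase caused by
# removing a term of the final model is credited to each variable in
# that term; totals are normalized so the top variable scores 100.
.importance_from_deletions <- function(terms, deletions, final_idx) {
  final_set <- setdiff(final_idx, 1L)
  scores <- numeric(0)
  for (d in deletions) {
    if (!d$term %in% final_set) next
    delta <- d$gcv_after - d$gcv_before
    if (!is.finite(delta) || delta <= 0) next
    for (v in unique(.term_vars(terms[[d$term]]))) {
      scores[v] <- (if (v %in% names(scores)) scores[[v]] else 0) + delta
    }
  }
  model_vars <- unique(unlist(lapply(terms[final_set], .term_vars)))
  for (v in setdiff(model_vars, names(scores))) scores[v] <- 0
  if (!length(scores)) {
    return(data.frame(variable = character(0), importance = numeric(0)))
  }
  if (max(scores) > 0) scores <- 100 * scores / max(scores)
  out <- data.frame(variable = names(scores), importance = unname(scores),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$variable), , drop = FALSE]
}

#' Fit a MARS model
#'
#' Runs [forward_pass()] then [backward_prune()].  Deterministic for a
#' given `(x, y, control)`.
#'
#' @inheritParams forward_pass
#' @return A `mars_fit` object.
#' @examples
#' x <- data.frame(x = seq(0, 10, by = 0.1))
#' fit <- fit_mars(x, 3 * pmax(0, x$x - 5))
#' fit$model
#' @export
fit_mars <- function(x, y, control = mars_control()) {
  candidate <- forward_pass(x, y, control)
  backward_prune(candidate, x, y, control)
}

#' Variable importance of a fitted MARS model
#'
#' Importance is the total GCV reduction attributed to each variable
#' across the backward deletion sequence, normalized so the most
#' important variable scores 100; ties are broken alphabetically.  Only
#' variables present in the final model appear.
#'
#' @param fit A `mars_fit` from [fit_mars()] / [backward_prune()].
#' @return A data frame with columns `variable` and `importance`, sorted
#'   by decreasing importance.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "mars_fit"))
  fit$importance
}

#' k-fold cross-validation of the MARS fit
#'
#' Folds are formed by seeded shuffling followed by contiguous splitting;
#' each fold's model is trained on its complement and evaluated
#' out-of-fold.
#'
#' @inheritParams forward_pass
#' @param k Number of folds (>= 2; `n >= 2k` required).
#' @param seed Integer seed for the fold shuffle (defaults to
#'   `control$seed`).
#' @return A list with `folds` (per-fold n, R-squared, RMSE),
#'   `rsq` and `rmse` (pooled out-of-fold), and `oof` (out-of-fold
#'   predictions in input order).
#' @export
kfold_cv <- function(x, y, control = mars_control(), k = 10L,
                     seed = control$seed) {
  .check_xy(x, y)
  n <- length(y)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < 2L * k) stop("need n >= 2k observations", call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- diff(round(seq(0, n, length.out = k + 1L)))
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(k), times = sizes)  # contiguous split of the shuffled order
  oof <- rep(NA_real_, n)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_id == f
    fit <- fit_mars(x[!test, , drop = FALSE], y[!test], control)
    oof[test] <- predict_vat(fit$model, x[test, , drop = FALSE],
                             check_range = FALSE)
    sse <- sum((y[test] - oof[test])^2)
    sst <- sum((y[test] - mean(y[test]))^2)
    folds[[f]] <- data.frame(fold = f, n = sum(test),
                             rsq = if (sst > 0) 1 - sse / sst else NA_real_,
                             rmse = sqrt(sse / sum(test)))
  }
  sse <- sum((y - oof)^2)
  sst <- sum((y - mean(y))^2)
  list(folds = do.call(rbind, folds),
       rsq = if (sst > 0) 1 - sse / sst else NA_real_,
       rmse = sqrt(sse / n),
       oof = oof)
}

#' @export
print.mars_fit <- function(x, ...) {
  cat(sprintf("MARS fit: %d basis functions, training R^2 = %.4f, GCV = %.4g\n",
              length(x$model$basis_functions), x$rsq, x$gcv))
  print(x$model)
  if (nrow(x$importance)) {
    cat("Variable importance:\n")
    print(x$importance, row.names = FALSE)
  }
  invisible(x)
}
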