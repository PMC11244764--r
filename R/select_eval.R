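#' Backward variable elimination by AIC
#'
#' Starting from all candidate variables, repeatedly drops the variable
#' (whole one-hot column group) whose removal most decreases the AIC, and
#' stops when no removal decreases it. Pure backward elimination: dropped
#' variables never re-enter (a stepwise-with-re-entry variant is available
#' via \code{allow_reentry = TRUE}).
#'
#' @param table Training \code{\link{cohort_table}}.
#' @param candidates Character vector of candidate variables (default: all
#'   schema variables).
#' @param allow_reentry Also consider re-adding previously dropped
#'   variables at each step (default FALSE).
#' @return Object of class \code{selection_trace}: list with \code{trace}
#'   (data.frame: step, action, variable, aic_before, aic_after),
#'   \code{selected} (final variable set), \code{fit} (final
#'   \code{vic_fit}) and \code{candidates}.
#' @export
backwardAIC <- function(table, candidates = NULL, allow_reentry = FALSE) {
  sch <- cohortSchema(table)
  all_vars <- variable_names(sch)
  if (is.null(candidates)) candidates <- all_vars
  unknown <- setdiff(candidates, all_vars)
  if (length(unknown))
    stop("unknown candidate variables: ", paste(unknown, collapse = ", "))
  if (!length(candidates)) stop("no candidate variables")
  current <- candidates
  fit <- fitOptimal(table, current)
  aic_cur <- modelAIC(fit)
  steps <- list(); step_i <- 0L
  repeat {
    moves <- lapply(current, function(v) {
      rest <- setdiff(current, v)
      if (!length(rest)) return(NULL)
      f <- fitOptimal(table, rest)
      list(action = "drop", variable = v, fit = f, aic = modelAIC(f))
    })
    if (allow_reentry) {
      for (v in setdiff(candidates, current)) {
        f <- fitOptimal(table, c(current, v))
        moves[[length(moves) + 1L]] <-
          list(action = "add", variable = v, fit = f, aic = modelAIC(f))
      }
    }
    moves <- Filter(Negate(is.null), moves)
    if (!length(moves)) break
    aics <- vapply(moves, `[[`, 0, "aic")
    best <- moves[[which.min(aics)]]
    if (best$aic >= aic_cur) break
    step_i <- step_i + 1L
    steps[[step_i]] <- data.frame(step = step_i, action = best$action,
                                  variable = best$variable,
                                  aic_before = aic_cur,
                                  aic_after = best$aic,
                                  stringsAsFactors = FALSE)
    current <- if (best$action == "drop") setdiff(current, best$variable)
               else c(current, best$variable)
    fit <- best$fit
    aic_cur <- best$aic
  }
  trace <- if (step_i) do.call(rbind, steps)
           else data.frame(step = integer(0), action = character(0),
                           variable = character(0), aic_before = numeric(0),
                           aic_after = numeric(0))
  structure(list(trace = trace, selected = current, fit = fit,
                 candidates = candidates),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", length(x$candidates), " candidates -> ",
      length(x$selected), " selected (", nrow(x$trace),
      " steps); final AIC ", sprintf("%.2f", modelAIC(x$fit)), "\n",
      sep = "")
  if (nrow(x$trace)) print(format(x$trace, digits = 6), row.names = FALSE)
  invisible(x)
}

#' Importance-prescreened backward selection
#'
#' The importance-assisted model-building route: variables whose pooled
#' overall importance is not significant (95% prediction interval not
#' entirely above zero) are excluded up front, and backward AIC elimination
#' runs on the survivors. The final model is therefore always a subset of
#' the significant set — which is how a robustly non-significant sensitive
#' variable (e.g. race) is kept out of the model.
#'
#' @param table Training \code{\link{cohort_table}}.
#' @param pooled A \code{\link{poolAll}} result covering all candidates.
#' @param candidates Candidate variables (default: all schema variables).
#' @return A \code{selection_trace} (see \code{\link{backwardAIC}}) with an
#'   extra element \code{prescreen_excluded}.
#' @export
assistedSelection <- function(table, pooled, candidates = NULL) {
  sch <- cohortSchema(table)
  if (is.null(candidates)) candidates <- variable_names(sch)
  missing_v <- setdiff(candidates, pooled$variable)
  if (length(missing_v))
    stop("pooled importance does not cover: ",
         paste(missing_v, collapse = ", "))
  sig <- pooled$variable[pooled$significant]
  survivors <- intersect(candidates, sig)
  if (!length(survivors))
    stop("no candidate variable has significant overall importance; ",
         "inspect the pooled prediction intervals before model building")
  out <- backwardAIC(table, survivors)
  out$prescreen_excluded <- setdiff(candidates, survivors)
  out
}

#' AUC with a bootstrap confidence interval
#'
#' The area under the ROC curve computed from the Mann-Whitney rank
#' statistic (midranks, hence tie-corrected), with a percentile bootstrap
#' CI over test rows.
#'
#' @param scores Predicted probabilities (or any monotone scores).
#' @param y Binary 0/1 outcomes; both classes must be present.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @return List with \code{auc}, \code{ci} (length-2 vector), \code{n}.
#' @export
aucWithCI <- function(scores, y, n_boot = 2000L, seed = 1L, conf = 0.95) {
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  auc1 <- function(s, yy) {
    r <- rank(s)
    n1 <- sum(yy == 1); n0 <- sum(yy == 0)
    (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  set.seed(seed)
  n <- length(y)
  boots <- numeric(0)
  if (n_boot > 0L) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) return(NA_real_)
      auc1(scores[idx], y[idx])
    }, 0)
    boots <- boots[!is.na(boots)]
  }
  alpha <- (1 - conf) / 2
  ci <- if (length(boots)) unname(stats::quantile(boots, c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  list(auc = auc1(scores, y), ci = ci, n = n)
}

roc_points <- function(scores, y) {
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) mean(scores[y == 1] >= t), 0)
  spec <- vapply(th, function(t) mean(scores[y == 0] < t), 0)
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Corner-optimal ROC threshold
#'
#' The operating threshold nearest the upper-left corner of the ROC curve:
#' over candidate thresholds (the unique scores), minimises
#' sqrt((1 - sensitivity)^2 + (1 - specificity)^2), breaking ties toward
#' higher specificity (then the higher threshold). Classification is
#' positive at score >= threshold.
#'
#' @param scores Predicted probabilities.
#' @param y Binary 0/1 outcomes; both classes must be present.
#' @return The selected threshold (scalar).
#' @export
cornerThreshold <- function(scores, y) {
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  pts <- roc_points(scores, y)
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  cand <- which(d <= min(d) + 1e-12)
  cand <- cand[pts$specificity[cand] >= max(pts$specificity[cand]) - 1e-12]
  pts$threshold[max(cand)]
}

metric_ratios <- function(scores, y, threshold) {
  pos <- scores >= threshold
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = safe(tp + tn, tp + tn + fp + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    npv = safe(tn, tn + fn),
    ppv = safe(tp, tp + fp))
}

#' Classification metrics at a threshold, with bootstrap CIs
#'
#' Confusion-table metrics (accuracy, sensitivity, specificity, NPV, PPV)
#' for positive classification at score >= threshold, each with a
#' percentile-bootstrap confidence interval over test rows. A metric whose
#' denominator is zero is reported as \code{NA} with no interval.
#'
#' @param scores Predicted probabilities.
#' @param y Binary 0/1 outcomes.
#' @param threshold Probability threshold in [0, 1].
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @return Data.frame of class \code{eval_report}: metric, estimate,
#'   ci_lower, ci_upper; attribute \code{n_test}.
#' @export
classificationReport <- function(scores, y, threshold, n_boot = 2000L,
                                 seed = 1L, conf = 0.95) {
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must be in [0, 1]")
  est <- metric_ratios(scores, y, threshold)
  set.seed(seed)
  n <- length(y)
  bm <- matrix(NA_real_, n_boot, length(est),
               dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bm[b, ] <- metric_ratios(scores[idx], y[idx], threshold)
  }
  alpha <- (1 - conf) / 2
  ci <- apply(bm, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA_real_, NA_real_))
    unname(stats::quantile(col, c(alpha, 1 - alpha)))
  })
  out <- data.frame(metric = names(est), estimate = unname(est),
                    ci_lower = ifelse(is.na(est), NA_real_, ci[1L, ]),
                    ci_upper = ifelse(is.na(est), NA_real_, ci[2L, ]),
                    stringsAsFactors = FALSE)
  attr(out, "n_test") <- n
  attr(out, "threshold") <- threshold
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Predict survival probabilities from a fitted model
#'
#' @param fit A \code{vic_fit}.
#' @param table A \code{\link{cohort_table}} sharing the fit's schema.
#' @return Numeric vector of predicted probabilities.
#' @export
predictRisk <- function(fit, table) {
  stopifnot(inherits(fit, "vic_fit"))
  enc <- encodeDesign(table)
  keep <- unlist(enc$groups[fit$variables], use.names = FALSE)
  X <- enc$X[, keep, drop = FALSE]
  stats::plogis(fit$beta[1L] + drop(X %*% fit$beta[-1L]))
}
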