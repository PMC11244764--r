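clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Mean negative log-likelihood of a logistic model
#'
#' The working loss of the whole pipeline: the mean (not summed) Bernoulli
#' negative log-likelihood, so that the near-optimality tolerance (excess
#' loss ratio < 5%) is free of sample size. Fitted probabilities are clipped
#' to [1e-12, 1 - 1e-12] to keep the loss finite under near-separation.
#'
#' @param beta Coefficient vector, intercept first (length p + 1).
#' @param design n x p design matrix (no intercept column).
#' @param y Binary 0/1 outcome vector of length n.
#' @return Nonnegative scalar loss.
#' @examples
#' X <- matrix(rnorm(20), 10, 2)
#' logisticLoss(c(0, 0, 0), X, rbinom(10, 1, 0.5))  # = log(2)
#' @export
logisticLoss <- function(beta, design, y) {
  if (!length(y) || !nrow(design)) stop("empty data")
  if (length(beta) != ncol(design) + 1L)
    stop("beta must have length ncol(design) + 1 (intercept first)")
  p <- clip_prob(stats::plogis(beta[1L] + drop(design %*% beta[-1L])))
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# loss from a precomputed linear predictor
eta_loss <- function(eta, y) {
  p <- clip_prob(stats::plogis(eta))
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

#' Fit the optimal logistic regression on a cohort
#'
#' Maximum-likelihood fit of all schema variables by iteratively reweighted
#' least squares (via \code{stats::glm.fit}, convergence tolerance 1e-10),
#' returning the coefficient vector, the inverse observed information as the
#' coefficient covariance, and the training loss — the centre and scale of
#' the nearly-optimal model ensemble.
#'
#' @param table A \code{\link{cohort_table}} with both outcome classes
#'   present.
#' @param variables Optional character vector restricting the predictors
#'   used (defaults to all schema variables).
#' @return An object of class \code{vic_fit}: list with \code{beta}
#'   (named, intercept first), \code{Sigma} (coefficient covariance),
#'   \code{train_loss} (mean negative log-likelihood), \code{n_train},
#'   \code{groups} (variable -> design-column indices), \code{variables},
#'   and the training \code{design}/\code{y} used.
#' @export
fitOptimal <- function(table, variables = NULL) {
  enc <- encodeDesign(table)
  if (!is.null(variables)) {
    unknown <- setdiff(variables, names(enc$groups))
    if (length(unknown))
      stop("unknown variables: ", paste(unknown, collapse = ", "))
    keep <- unlist(enc$groups[variables], use.names = FALSE)
    enc$X <- enc$X[, keep, drop = FALSE]
    enc$groups <- local({
      g <- list(); off <- 0L
      for (v in variables) {
        g[[v]] <- off + seq_along(enc$groups[[v]]); off <- off + length(enc$groups[[v]])
      }
      g
    })
  }
  X <- enc$X; y <- enc$y
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present to fit")
  X1 <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X1)
  if (qrX$rank < ncol(X1)) {
    bad <- colnames(X1)[qrX$pivot[(qrX$rank + 1L):ncol(X1)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(X1, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  if (!fit$converged)
    stop("IRLS did not converge in 100 iterations (possible separation); ",
         "final deviance ", format(fit$deviance))
  beta <- fit$coefficients
  w <- fit$fitted.values * (1 - fit$fitted.values)
  Sigma <- chol2inv(chol(crossprod(X1, X1 * w)))
  dimnames(Sigma) <- list(names(beta), names(beta))
  structure(list(beta = beta, Sigma = Sigma,
                 train_loss = eta_loss(drop(X1 %*% beta), y),
                 n_train = length(y), groups = enc$groups,
                 variables = names(enc$groups),
                 design = X, y = y),
            class = "vic_fit")
}

#' @export
print.vic_fit <- function(x, ...) {
  cat("<vic_fit> logistic model: ", length(x$variables), " variables (",
      length(x$beta) - 1L, " columns + intercept), n = ", x$n_train,
      ", training loss ", sprintf("%.4f", x$train_loss),
      ", AIC ", sprintf("%.1f", modelAIC(x)), "\n", sep = "")
  invisible(x)
}

#' Akaike information criterion of a fitted model
#'
#' AIC = 2k + 2 n L, with k the number of estimated coefficients (including
#' the intercept) and L the mean training negative log-likelihood, so it
#' agrees with \code{stats::AIC} on the same fit.
#'
#' @param fit A \code{vic_fit}.
#' @return Numeric AIC.
#' @export
modelAIC <- function(fit) {
  stopifnot(inherits(fit, "vic_fit"))
  2 * length(fit$beta) + 2 * fit$n_train * fit$train_loss
}

#' Wald summary of a fitted logistic model
#'
#' Per-coefficient odds ratios with 95% confidence intervals, and
#' per-variable p-values from the Wald chi-square test of the variable's
#' whole column group (df = number of columns, i.e. L - 1 for an L-level
#' categorical), ranked in ascending p — the conventional regression view
#' of variable importance. A likelihood-ratio alternative for the group
#' test is available via \code{test = "lrt"} (refits without the group).
#'
#' @param fit A \code{vic_fit}.
#' @param test Group test: \code{"wald"} (default) or \code{"lrt"}.
#' @return List of class \code{wald_summary} with data.frames
#'   \code{coefficients} (term, estimate, se, or, ci_lower, ci_upper, p) and
#'   \code{variables} (variable, df, statistic, p), the latter sorted by p.
#' @export
waldSummary <- function(fit, test = c("wald", "lrt")) {
  stopifnot(inherits(fit, "vic_fit"))
  test <- match.arg(test)
  se <- sqrt(diag(fit$Sigma))
  z <- stats::qnorm(0.975)
  co <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                   se = unname(se),
                   or = exp(unname(fit$beta)),
                   ci_lower = exp(unname(fit$beta) - z * se),
                   ci_upper = exp(unname(fit$beta) + z * se),
                   p = 2 * stats::pnorm(-abs(unname(fit$beta) / se)),
                   stringsAsFactors = FALSE)
  rows <- lapply(names(fit$groups), function(v) {
    idx <- fit$groups[[v]] + 1L  # shift past intercept
    if (test == "wald") {
      b <- fit$beta[idx]
      stat <- drop(t(b) %*% solve(fit$Sigma[idx, idx, drop = FALSE], b))
    } else {
      drop_cols <- fit$groups[[v]]
      Xr <- fit$design[, -drop_cols, drop = FALSE]
      sub <- stats::glm.fit(cbind(1, Xr), fit$y, family = stats::binomial(),
                            control = stats::glm.control(epsilon = 1e-10,
                                                         maxit = 100L))
      stat <- sub$deviance - 2 * fit$n_train * fit$train_loss
    }
    data.frame(variable = v, df = length(idx), statistic = stat,
               p = stats::pchisq(stat, df = length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  vars <- do.call(rbind, rows)
  vars <- vars[order(vars$p, vars$variable), , drop = FALSE]
  rownames(vars) <- NULL
  structure(list(coefficients = co, variables = vars, test = test),
            class = "wald_summary")
}

#' @export
print.wald_summary <- function(x, ...) {
  cat("<wald_summary> per-variable ", toupper(x$test),
      " tests (ascending p):\n", sep = "")
  print(format(x$variables, digits = 3), row.names = FALSE)
  invisible(x)
}
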