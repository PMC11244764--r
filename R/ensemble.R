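#' Configuration for the nearly-optimal model ensemble
#'
#' @param M Target ensemble size (number of eligible models; default 250).
#' @param loss_tolerance Excess-loss ratio bound: a candidate is eligible
#'   when its training loss is below (1 + loss_tolerance) times the optimal
#'   loss (default 0.05, i.e. "< 5% above the minimum").
#' @param u1,u2 Lower/upper bound of the uniform covariance-scaling draw;
#'   leave \code{NULL} to tune with \code{\link{tuneScalingBounds}}.
#' @param eligibility_target Interval the tuned eligibility proportion must
#'   fall in (default c(0.70, 0.80)).
#' @param seed Sampling seed.
#' @param max_attempts Cap on candidate draws before giving up
#'   (default 50 * M).
#' @return A list of class \code{ensemble_config}.
#' @export
ensembleConfig <- function(M = 250L, loss_tolerance = 0.05,
                           u1 = NULL, u2 = NULL,
                           eligibility_target = c(0.70, 0.80),
                           seed = 1L, max_attempts = 50L * M) {
  if (M < 3L) stop("ensemble size M must be at least 3")
  if (!(loss_tolerance > 0 && loss_tolerance < 1))
    stop("'loss_tolerance' must be in (0, 1)")
  if (!is.null(u1) && !is.null(u2) && !(u1 > 0 && u1 <= u2))
    stop("need 0 < u1 <= u2")
  structure(list(M = as.integer(M), loss_tolerance = loss_tolerance,
                 u1 = u1, u2 = u2, eligibility_target = eligibility_target,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "ensemble_config")
}

# Cholesky factor of the coefficient covariance, with a clear failure mode
sigma_chol <- function(fit) {
  tryCatch(chol(fit$Sigma), error = function(e)
    stop("Cholesky factorisation of the coefficient covariance failed (",
         conditionMessage(e),
         "); consider adding a small diagonal jitter to Sigma", call. = FALSE))
}

# one candidate given a precomputed Cholesky factor; uses the current RNG
draw_one <- function(fit, R, u1, u2, loss_tolerance) {
  m <- stats::runif(1L, u1, u2)
  beta <- fit$beta + sqrt(m) * drop(crossprod(R, stats::rnorm(length(fit$beta))))
  loss <- eta_loss(beta[1L] + drop(fit$design %*% beta[-1L]), fit$y)
  ratio <- loss / fit$train_loss
  list(beta = beta, m = m, loss = loss, loss_ratio = ratio,
       eligible = ratio < 1 + loss_tolerance)
}

#' Draw a single nearly-optimal candidate model
#'
#' A candidate is sampled as beta ~ MVN(beta_hat, m * Sigma_hat) with the
#' scaling m drawn uniformly on [u1, u2]; its training loss and eligibility
#' (excess-loss ratio below the tolerance) are recorded.
#'
#' @param fit A \code{\link{fitOptimal}} result.
#' @param u1,u2 Scaling bounds, 0 < u1 <= u2.
#' @param loss_tolerance Eligibility bound on the excess-loss ratio.
#' @return A list with \code{beta}, \code{m}, \code{loss},
#'   \code{loss_ratio}, \code{eligible}.
#' @export
drawCandidate <- function(fit, u1, u2, loss_tolerance = 0.05) {
  stopifnot(inherits(fit, "vic_fit"), u1 > 0, u1 <= u2)
  draw_one(fit, sigma_chol(fit), u1, u2, loss_tolerance)
}

#' Tune the covariance-scaling bounds
#'
#' Searches a geometric grid of (u1, u2) pairs, estimating each pair's
#' eligibility proportion from \code{pilot_size} candidate draws, and keeps
#' the pair whose proportion is closest to the middle of the target band
#' (0.75 by default). Because the proportion is monotone non-increasing in
#' the overall scale of (u1, u2), a pair outside the band is refined by
#' bisection on that scale (at the fixed u2/u1 ratio) until the pilot
#' proportion falls inside the band; if bisection cannot land in the band
#' the full diagnostic table is reported in the failure.
#'
#' @param fit A \code{\link{fitOptimal}} result.
#' @param pilot_size Draws per grid point (>= 100; default 200).
#' @param loss_tolerance Eligibility bound (default 0.05).
#' @param eligibility_target Acceptance band for the proportion
#'   (default c(0.70, 0.80)).
#' @param seed Pilot-sampling seed.
#' @return A list with \code{u1}, \code{u2}, the pilot \code{proportion},
#'   and the full \code{grid} searched.
#' @export
tuneScalingBounds <- function(fit, pilot_size = 200L, loss_tolerance = 0.05,
                              eligibility_target = c(0.70, 0.80),
                              seed = 1L) {
  stopifnot(inherits(fit, "vic_fit"))
  if (pilot_size < 100L) stop("'pilot_size' must be at least 100")
  R <- sigma_chol(fit)
  target_mid <- mean(eligibility_target)
  in_band <- function(p) p >= eligibility_target[1L] &&
                         p <= eligibility_target[2L]
  set.seed(seed)
  prop_at <- function(u1, u2) {
    mean(vapply(seq_len(pilot_size), function(j)
      draw_one(fit, R, u1, u2, loss_tolerance)$eligible, TRUE))
  }
  grid <- expand.grid(u1 = 2^seq(-6, 3), mult = c(2, 4, 8))
  grid$u2 <- grid$u1 * grid$mult
  grid$proportion <- mapply(prop_at, grid$u1, grid$u2)
  best <- grid[which.min(abs(grid$proportion - target_mid)), ]
  u1 <- best$u1; u2 <- best$u2; prop <- best$proportion
  if (!in_band(prop)) {
    # proportion is monotone non-increasing in the overall scale, so
    # bisect on the scale at the chosen u2/u1 ratio
    ratio <- u2 / u1
    lo <- u1 / 8; hi <- u1 * 8  # prop(lo) high, prop(hi) low
    for (i in 1:30) {
      mid <- sqrt(lo * hi)
      p <- prop_at(mid, mid * ratio)
      grid <- rbind(grid, data.frame(u1 = mid, mult = ratio,
                                     u2 = mid * ratio, proportion = p))
      if (in_band(p)) { u1 <- mid; u2 <- mid * ratio; prop <- p; break }
      if (p > target_mid) lo <- mid else hi <- mid
    }
  }
  if (!in_band(prop)) {
    stop("no (u1, u2) reached an eligibility proportion in [",
         eligibility_target[1L], ", ", eligibility_target[2L],
         "]; searched:\n",
         paste(utils::capture.output(print(
           grid[c("u1", "u2", "proportion")])), collapse = "\n"))
  }
  list(u1 = u1, u2 = u2, proportion = prop,
       grid = grid[c("u1", "u2", "proportion")])
}

#' Build the ensemble of nearly-optimal models
#'
#' Rejection-samples candidates around the optimal fit until exactly M
#' eligible members are collected (or \code{max_attempts} is exhausted).
#' The full ensemble is a pure function of the training data, the
#' configuration and the seed.
#'
#' @param fit A \code{\link{fitOptimal}} result.
#' @param config An \code{\link{ensembleConfig}}; its \code{u1}/\code{u2}
#'   must be set (tuned or user-supplied).
#' @return Object of class \code{model_ensemble}: list with \code{optimal}
#'   (the fit), \code{beta} (M x (p+1) member coefficient matrix),
#'   \code{m}, \code{loss}, \code{loss_ratio} (per-member vectors),
#'   \code{attempts}, and the \code{config}.
#' @export
buildEnsemble <- function(fit, config) {
  stopifnot(inherits(fit, "vic_fit"), inherits(config, "ensemble_config"))
  if (is.null(config$u1) || is.null(config$u2))
    stop("config has no scaling bounds; run tuneScalingBounds first")
  R <- sigma_chol(fit)
  M <- config$M
  beta <- matrix(NA_real_, M, length(fit$beta),
                 dimnames = list(NULL, names(fit$beta)))
  mvec <- loss <- ratio <- numeric(M)
  got <- 0L; attempts <- 0L
  set.seed(config$seed)
  while (got < M) {
    if (attempts >= config$max_attempts)
      stop("max_attempts (", config$max_attempts, ") exhausted with only ",
           got, "/", M, " eligible members (eligibility rate ",
           sprintf("%.2f", got / attempts), ")")
    cand <- draw_one(fit, R, config$u1, config$u2, config$loss_tolerance)
    attempts <- attempts + 1L
    if (cand$eligible) {
      got <- got + 1L
      beta[got, ] <- cand$beta
      mvec[got] <- cand$m; loss[got] <- cand$loss
      ratio[got] <- cand$loss_ratio
    }
  }
  structure(list(optimal = fit, beta = beta, m = mvec, loss = loss,
                 loss_ratio = ratio, attempts = attempts, config = config),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble> ", nrow(x$beta), " nearly-optimal models (",
      x$attempts, " draws, eligibility ",
      sprintf("%.2f", nrow(x$beta) / x$attempts), "); scaling in [",
      format(x$config$u1), ", ", format(x$config$u2),
      "]; max excess-loss ratio ",
      sprintf("%.4f", max(x$loss_ratio)), "\n", sep = "")
  invisible(x)
}

#' Export ensemble members as a data.frame
#'
#' One row per member: scaling draw, loss, loss ratio, coefficients —
#' the audit/serialisation format (write with \code{write.csv}).
#'
#' @param ensemble A \code{model_ensemble}.
#' @return A data.frame.
#' @export
ensembleAsDataFrame <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  data.frame(model_id = seq_len(nrow(ensemble$beta)),
             m = ensemble$m, loss = ensemble$loss,
             loss_ratio = ensemble$loss_ratio,
             ensemble$beta, check.names = FALSE,
             stringsAsFactors = FALSE)
}
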