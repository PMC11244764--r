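#' Coalition value function (exact, by full enumeration)
#'
#' The value of a coalition S of variables for a logistic model is the mean
#' loss when the design columns of every variable NOT in S are replaced,
#' per evaluation, by values from background rows (marginal/interventional
#' imputation), averaged over all explanation row x background row pairs.
#' All one-hot columns of a categorical variable are replaced together.
#' This exact version enumerates every pair and is the building block of
#' the small-problem Shapley oracle.
#'
#' @param beta Model coefficients, intercept first.
#' @param S Character vector of variable names in the coalition (may be
#'   empty).
#' @param explanation n_e x p design matrix of explanation rows.
#' @param y Outcomes of the explanation rows.
#' @param background n_b x p design matrix of background rows.
#' @param groups Named list mapping variables to design-column indices.
#' @return Scalar mean loss under the masking.
#' @export
coalitionValue <- function(beta, S, explanation, y, background, groups) {
  if (!nrow(explanation)) stop("empty explanation set")
  unknown <- setdiff(S, names(groups))
  if (length(unknown))
    stop("unknown variables in coalition: ", paste(unknown, collapse = ", "))
  ne <- nrow(explanation); nb <- nrow(background)
  ie <- rep(seq_len(ne), each = nb); ib <- rep(seq_len(nb), ne)
  Xm <- background[ib, , drop = FALSE]
  keep <- unlist(groups[S], use.names = FALSE)
  if (length(keep))
    Xm[, keep] <- explanation[ie, keep, drop = FALSE]
  eta_loss(beta[1L] + drop(Xm %*% beta[-1L]), y[ie])
}

#' Exact Shapley values by coalition enumeration (small-problem oracle)
#'
#' Computes each variable's exact Shapley value
#' sum over S of w(S) [v(S) - v(S + j)] with the standard combinatorial
#' weights and v the exact \code{\link{coalitionValue}} (loss scale;
#' positive value = including the variable reduces loss). Enumerates all
#' 2^d coalitions, so it is restricted to d <= 6 variables and serves as
#' the reference the permutation-sampling estimator is validated against.
#'
#' @inheritParams coalitionValue
#' @return Named numeric vector of exact per-variable values, plus
#'   attributes \code{v_full} and \code{v_null}.
#' @export
exactShapleyOracle <- function(beta, explanation, y, background, groups) {
  d <- length(groups)
  if (d > 6L) stop("exact enumeration is limited to d <= 6 variables")
  vars <- names(groups)
  # v over all subsets, indexed by bitmask + 1
  v <- numeric(2^d)
  for (mask in 0:(2^d - 1L)) {
    S <- vars[bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L]
    v[mask + 1L] <- coalitionValue(beta, S, explanation, y, background,
                                   groups)
  }
  phi <- stats::setNames(numeric(d), vars)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^d - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
      w <- factorial(s) * factorial(d - s - 1L) / factorial(d)
      # loss reduction from adding j to S
      phi[j] <- phi[j] + w * (v[mask + 1L] - v[mask + bit + 1L])
    }
  }
  attr(phi, "v_full") <- v[2^d]
  attr(phi, "v_null") <- v[1L]
  phi
}

#' Permutation-sampling Shapley (SAGE-style) importance of one model
#'
#' Estimates each variable's global importance to a logistic model as its
#' Shapley value under the coalition loss game: for each sampled
#' permutation of the d variables, a mini-batch of (explanation row,
#' background row) pairs is drawn, the permutation is walked adding
#' variables one at a time, and each variable's incremental loss reduction
#' is recorded. The estimate is the mean of a variable's increments over
#' walks (positive = inclusion reduces loss) and its standard error is the
#' CLT sd over independent sampling units. By default permutations are
#' antithetic (each sampled order is paired with its reverse on the same
#' batch), which reduces variance; the independent unit is then the pair
#' average. Per-walk telescoping is exact, so the estimates sum exactly to
#' the sampled estimate of v(empty) - v(full).
#'
#' @param beta Model coefficients, intercept first.
#' @param explanation n_e x p design matrix of explanation rows.
#' @param y Outcomes of the explanation rows.
#' @param groups Named list mapping variables to design-column indices.
#' @param n_permutations Total permutation walks (default 200; must be even
#'   when antithetic).
#' @param background_size Rows sampled from the explanation set as the
#'   background pool (default 100); ignored when \code{background} is given.
#' @param background Optional explicit background design matrix (same
#'   columns as \code{explanation}); defaults to a random subset of the
#'   explanation rows.
#' @param batch_size Explanation/background pairs per walk (default 10).
#' @param antithetic Pair each order with its reverse (default TRUE).
#' @param seed Optional sampling seed.
#' @return A data.frame of class \code{importance_record} with columns
#'   \code{variable}, \code{estimate}, \code{se}, \code{n_walks}; attributes
#'   \code{v_full} and \code{v_null} hold the matching sampled endpoint
#'   values.
#' @export
sageValues <- function(beta, explanation, y, groups,
                       n_permutations = 200L, background_size = 100L,
                       batch_size = 10L, antithetic = TRUE, seed = NULL,
                       background = NULL) {
  if (n_permutations < 2L) stop("'n_permutations' must be at least 2")
  if (background_size < 1L) stop("'background_size' must be at least 1")
  if (!nrow(explanation)) stop("empty explanation set")
  if (antithetic && n_permutations %% 2L != 0L)
    stop("'n_permutations' must be even with antithetic sampling")
  if (!is.null(seed)) set.seed(seed)
  d <- length(groups); vars <- names(groups)
  ne <- nrow(explanation)
  Xpool <- if (!is.null(background)) background
           else explanation[sample(seq_len(ne),
                                   min(background_size, ne)), ,
                            drop = FALSE]
  npool <- nrow(Xpool)
  b0 <- beta[1L]; bv <- beta[-1L]
  n_units <- if (antithetic) n_permutations %/% 2L else n_permutations
  deltas <- matrix(0, n_units, d, dimnames = list(NULL, vars))
  v_null_acc <- v_full_acc <- 0

  walk <- function(contrib, eta0, yb, ord) {
    eta <- eta0
    loss_prev <- eta_loss(eta, yb)
    dd <- numeric(d)
    for (k in ord) {
      eta <- eta + contrib[, k]
      loss_new <- eta_loss(eta, yb)
      dd[k] <- loss_prev - loss_new
      loss_prev <- loss_new
    }
    list(delta = dd, v_null = eta_loss(eta0, yb), v_full = loss_prev)
  }

  for (u in seq_len(n_units)) {
    ie <- sample(seq_len(ne), batch_size, replace = TRUE)
    ib <- sample(seq_len(npool), batch_size, replace = TRUE)
    Xe <- explanation[ie, , drop = FALSE]
    Xb <- Xpool[ib, , drop = FALSE]
    yb <- y[ie]
    # per-variable linear-predictor increments for this batch
    contrib <- vapply(groups, function(cols)
      drop((Xe[, cols, drop = FALSE] - Xb[, cols, drop = FALSE]) %*%
             bv[cols]),
      numeric(batch_size))
    if (batch_size == 1L) contrib <- matrix(contrib, nrow = 1L)
    eta0 <- b0 + drop(Xb %*% bv)
    ord <- sample.int(d)
    w1 <- walk(contrib, eta0, yb, ord)
    if (antithetic) {
      w2 <- walk(contrib, eta0, yb, rev(ord))
      deltas[u, ] <- (w1$delta + w2$delta) / 2
    } else {
      deltas[u, ] <- w1$delta
    }
    v_null_acc <- v_null_acc + w1$v_null
    v_full_acc <- v_full_acc + w1$v_full
  }
  est <- colMeans(deltas)
  se <- apply(deltas, 2L, stats::sd) / sqrt(n_units)
  out <- data.frame(variable = vars, estimate = unname(est),
                    se = unname(se), n_walks = n_permutations,
                    stringsAsFactors = FALSE)
  attr(out, "v_null") <- v_null_acc / n_units
  attr(out, "v_full") <- v_full_acc / n_units
  class(out) <- c("importance_record", "data.frame")
  out
}

#' Shapley importance for every member of an ensemble
#'
#' Runs \code{\link{sageValues}} for each nearly-optimal model on shared
#' explanation data, producing the stacked per-model importance table that
#' \code{\link{poolAll}} consumes. Per-model seeds are derived as
#' \code{seed + model_id} so the table is reproducible and members are
#' independent streams.
#'
#' @param ensemble A \code{\link{buildEnsemble}} result.
#' @param explanation n_e x p design matrix of explanation rows (defaults
#'   to the training design of the optimal fit).
#' @param y Outcomes of the explanation rows.
#' @param ... Passed to \code{\link{sageValues}}.
#' @param seed Base seed for per-model streams.
#' @return A data.frame with columns \code{model_id}, \code{variable},
#'   \code{estimate}, \code{se}, \code{n_walks}.
#' @export
ensembleImportance <- function(ensemble, explanation = NULL, y = NULL,
                               ..., seed = 1L) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  fit <- ensemble$optimal
  if (is.null(explanation)) { explanation <- fit$design; y <- fit$y }
  M <- nrow(ensemble$beta)
  out <- vector("list", M)
  for (mi in seq_len(M)) {
    rec <- sageValues(ensemble$beta[mi, ], explanation, y, fit$groups,
                      ..., seed = seed + mi)
    out[[mi]] <- cbind(model_id = mi, as.data.frame(rec))
  }
  do.call(rbind, out)
}
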