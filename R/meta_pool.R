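#' Pool one variable's per-model Shapley estimates
#'
#' Random-effects meta-analysis of a variable's importance across the M
#' ensemble members, with the DerSimonian-Laird between-model variance:
#' with fixed-effect weights w = 1/se^2, Q = sum w (s - s_FE)^2,
#' C = sum(w) - sum(w^2)/sum(w), tau2 = max(0, (Q - (M-1))/C). Random-
#' effects weights are 1/(se^2 + tau2); the pooled mean and its standard
#' error follow, and the 95% prediction interval — the interval expected to
#' contain the importance of a new model drawn from the same near-optimal
#' ensemble — is pooled_mean +/- t(M-2, 0.975) * sqrt(tau2 + se_pooled^2)
#' (the standard Higgins-Thompson construction). A variable's overall
#' importance is flagged significant when the interval lies entirely above
#' zero. When every standard error is zero, heterogeneity is carried by
#' tau2 alone (the unweighted sample variance). An isolated zero standard
#' error — a Monte-Carlo artifact of a model whose sampled increments for
#' the variable were all identical — is floored at the smallest positive
#' standard error observed for that variable, keeping the inverse-variance
#' weights finite.
#'
#' @param estimates Numeric vector of per-model importance estimates
#'   (length M >= 3).
#' @param ses Matching nonnegative standard errors.
#' @param variable Optional variable name carried into the result.
#' @return One-row data.frame: \code{variable}, \code{pooled_mean},
#'   \code{tau2}, \code{se_pooled}, \code{pi_lower}, \code{pi_upper},
#'   \code{significant}, \code{M_used}.
#' @examples
#' poolVariable(c(1, 2, 3), rep(1, 3))  # tau2 = 0, mean 2, se 1/sqrt(3)
#' @export
poolVariable <- function(estimates, ses, variable = NA_character_) {
  M <- length(estimates)
  if (M < 3L) stop("meta-analysis needs at least 3 models (got ", M, ")")
  if (length(ses) != M) stop("'estimates' and 'ses' lengths differ")
  if (any(!is.finite(estimates)) || any(!is.finite(ses)) || any(ses < 0))
    stop("estimates must be finite and standard errors finite and >= 0")
  if (all(ses == 0)) {
    tau2 <- stats::var(estimates)
    mu <- mean(estimates)
    se_pooled <- sqrt(tau2 / M)
  } else {
    ses <- pmax(ses, min(ses[ses > 0]))  # floor MC-degenerate zero SEs
    w <- 1 / ses^2
    s_fe <- sum(w * estimates) / sum(w)
    Q <- sum(w * (estimates - s_fe)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (M - 1)) / C)
    ws <- 1 / (ses^2 + tau2)
    mu <- sum(ws * estimates) / sum(ws)
    se_pooled <- sqrt(1 / sum(ws))
  }
  half <- stats::qt(0.975, df = M - 2) * sqrt(tau2 + se_pooled^2)
  data.frame(variable = variable, pooled_mean = mu, tau2 = tau2,
             se_pooled = se_pooled,
             pi_lower = mu - half, pi_upper = mu + half,
             significant = (mu - half) > 0, M_used = M,
             stringsAsFactors = FALSE)
}

#' Pool the full per-model importance table
#'
#' Applies \code{\link{poolVariable}} to every variable of a stacked
#' importance table (as produced by \code{\link{ensembleImportance}}) and
#' returns variables sorted by decreasing overall importance (ties broken
#' alphabetically). Every variable must have a record for every model.
#'
#' @param records Data.frame with columns \code{model_id}, \code{variable},
#'   \code{estimate}, \code{se}.
#' @return Data.frame of class \code{pooled_importance}, one row per
#'   variable.
#' @export
poolAll <- function(records) {
  need <- c("model_id", "variable", "estimate", "se")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  tab <- table(records$variable, records$model_id)
  if (any(tab != 1L)) {
    gaps <- which(tab != 1L, arr.ind = TRUE)
    stop("missing or duplicated (variable, model) cells, e.g. variable '",
         rownames(tab)[gaps[1L, 1L]], "' / model ",
         colnames(tab)[gaps[1L, 2L]])
  }
  rows <- lapply(split(records, records$variable), function(df)
    poolVariable(df$estimate, df$se, variable = df$variable[1L]))
  out <- do.call(rbind, rows)
  out <- out[order(-out$pooled_mean, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pooled_importance", "data.frame")
  out
}

#' @export
print.pooled_importance <- function(x, ...) {
  cat("<pooled_importance> ", nrow(x), " variables, ",
      sum(x$significant), " with 95% prediction interval above zero\n",
      sep = "")
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot-ready table of pooled importance
#'
#' @param pooled A \code{\link{poolAll}} result.
#' @return Data.frame with \code{variable}, \code{mean}, \code{pi_lower},
#'   \code{pi_upper}, \code{significant} and a \code{color_class}
#'   (\code{"significant"}/\code{"not significant"}), in pooled order.
#' @export
importancePlotData <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_importance"), nrow(pooled) > 0)
  data.frame(variable = pooled$variable, mean = pooled$pooled_mean,
             pi_lower = pooled$pi_lower, pi_upper = pooled$pi_upper,
             significant = pooled$significant,
             color_class = ifelse(pooled$significant, "significant",
                                  "not significant"),
             stringsAsFactors = FALSE)
}

#' Bar-and-whisker plot of overall variable importance
#'
#' Variables ordered by overall importance; bars show the pooled mean,
#' whiskers the 95% prediction interval, and significant variables (PI
#' entirely above zero) are coloured and starred.
#'
#' @param pooled A \code{\link{poolAll}} result.
#' @return A ggplot object.
#' @export
plotImportance <- function(pooled) {
  df <- importancePlotData(pooled)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  df$label <- ifelse(df$significant, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = variable,
                                   fill = color_class)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = pi_lower, xmax = pi_upper),
                            height = 0.25, linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(x = pi_upper, label = label),
                       hjust = -0.6, size = 4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(significant = "#2166ac",
                                          `not significant` = "grey65"),
                               name = NULL) +
    ggplot2::labs(x = "Overall importance (mean loss reduction)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
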