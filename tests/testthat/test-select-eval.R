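test_that("the rank AUC matches enumeration, pROC, and the null", {
  # 4-point worked example: 3 of 4 case-control pairs correctly ordered
  expect_equal(aucWithCI(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0),
                         n_boot = 0)$auc, 0.75)
  # perfect separation
  expect_equal(aucWithCI(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                         n_boot = 0)$auc, 1)
  # tie-free random data: equals pROC / trapezoidal area exactly
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  ref <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(aucWithCI(s, y, n_boot = 0)$auc, as.numeric(ref),
               tolerance = 1e-12)
  # independent scores: AUC ~ 0.5
  set.seed(4)
  y0 <- rbinom(1e4, 1, 0.3); s0 <- runif(1e4)
  res <- aucWithCI(s0, y0, n_boot = 200, seed = 1)
  expect_lt(abs(res$auc - 0.5), 3 * sqrt(1 / (12 * sum(y0 == 1))))
  expect_true(res$ci[1] <= res$auc && res$auc <= res$ci[2])
  expect_error(aucWithCI(s0, rep(1, 1e4), n_boot = 0), "both")
})

test_that("the corner threshold matches brute-force search", {
  brute <- function(s, y) {
    th <- sort(unique(s))
    d <- vapply(th, function(t) {
      sens <- mean(s[y == 1] >= t); spec <- mean(s[y == 0] < t)
      sqrt((1 - sens)^2 + (1 - spec)^2)
    }, 0)
    spec_at <- vapply(th, function(t) mean(s[y == 0] < t), 0)
    k <- which(d <= min(d) + 1e-12)
    k <- k[spec_at[k] >= max(spec_at[k]) - 1e-12]
    th[max(k)]
  }
  # 6-point toy with one misclassification structure
  s6 <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1)
  y6 <- c(1, 1, 0, 1, 0, 0)
  expect_equal(cornerThreshold(s6, y6), brute(s6, y6))
  # random toys
  set.seed(6)
  for (i in 1:20) {
    s <- round(runif(40), 2)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(cornerThreshold(s, y), brute(s, y))
  }
  # perfect separation: a zero-distance threshold between the classes
  sp <- c(0.9, 0.8, 0.2, 0.1); yp <- c(1, 1, 0, 0)
  tp <- cornerThreshold(sp, yp)
  expect_true(tp > 0.2 && tp <= 0.8)
  # degenerate: all scores equal
  expect_equal(cornerThreshold(rep(0.4, 10), rep(c(0, 1), 5)), 0.4)
})

test_that("classification metrics match hand arithmetic and boundary contracts", {
  # TP 40, FN 10, TN 80, FP 20
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.2, 80), rep(0.8, 20))
  y <- c(rep(1, 50), rep(0, 100))
  rep1 <- classificationReport(scores, y, 0.5, n_boot = 100, seed = 2)
  est <- setNames(rep1$estimate, rep1$metric)
  expect_equal(unname(est["accuracy"]), 0.8)
  expect_equal(unname(est["sensitivity"]), 0.8)
  expect_equal(unname(est["specificity"]), 0.8)
  expect_equal(unname(est["ppv"]), 2 / 3)
  expect_equal(unname(est["npv"]), 8 / 9)
  expect_true(all(rep1$ci_lower <= rep1$estimate &
                  rep1$estimate <= rep1$ci_upper))

  # threshold 0: everything positive
  r0 <- classificationReport(scores, y, 0, n_boot = 0, seed = 1)
  e0 <- setNames(r0$estimate, r0$metric)
  expect_equal(unname(e0["sensitivity"]), 1)
  expect_equal(unname(e0["specificity"]), 0)
  expect_true(is.na(e0["npv"]))  # no negatives called

  # threshold 1: only score-1 rows positive (closed on the left)
  s1 <- c(1, 1, 0.99, 0.5); y1 <- c(1, 0, 1, 0)
  r1 <- classificationReport(s1, y1, 1, n_boot = 0, seed = 1)
  e1 <- setNames(r1$estimate, r1$metric)
  expect_equal(unname(e1["sensitivity"]), 0.5)
  expect_equal(unname(e1["specificity"]), 0.5)
  expect_error(classificationReport(s1, y1, 1.5, n_boot = 0), "threshold")
})

test_that("backward AIC drops noise, keeps signal, and never revisits", {
  sch <- cohort_schema(list(variable_spec("strong", "binary"),
                            variable_spec("noise", "binary"),
                            variable_spec("grp", "categorical",
                                          levels = c("A", "B", "C"))),
                       "y")
  set.seed(18)
  n <- 2000
  df <- data.frame(strong = rbinom(n, 1, 0.5),
                   noise = rbinom(n, 1, 0.5),
                   grp = sample(c("A", "B", "C"), n, replace = TRUE))
  eta <- -0.5 + 1.5 * df$strong + 0.8 * (df$grp == "B")
  df$y <- rbinom(n, 1, plogis(eta))
  tab <- cohort_table(df, sch)
  tr <- backwardAIC(tab)
  expect_true("strong" %in% tr$selected)
  expect_false("noise" %in% tr$selected)
  expect_true("grp" %in% tr$selected)  # dropped/kept as a whole block only
  if (nrow(tr$trace)) {
    expect_true(all(tr$trace$aic_after <= tr$trace$aic_before))
    expect_false(any(duplicated(tr$trace$variable)))
  }
  full_aic <- modelAIC(fitOptimal(tab))
  expect_lte(modelAIC(tr$fit), full_aic)

  # agreement with MASS::stepAIC on the same data
  skip_if_not_installed("MASS")
  df$grp <- factor(df$grp)
  ref <- MASS::stepAIC(glm(y ~ strong + noise + grp, binomial, df),
                       direction = "backward", trace = 0)
  ref_vars <- attr(terms(ref), "term.labels")
  expect_setequal(tr$selected, ref_vars)
})

test_that("assisted selection prescreens to the significant set", {
  co <- generateCohort(tiny_binary_spec(), 1500, seed = 9)
  # pooled table marking only 'a' and 'b' significant
  pooled <- poolAll(data.frame(
    model_id = rep(1:5, 3),
    variable = rep(c("a", "b", "c"), each = 5),
    estimate = rep(c(0.5, 0.3, 0.0), each = 5) + rnorm(15, sd = 0.005),
    se = 0.01))
  sel <- assistedSelection(co, pooled)
  expect_true(all(sel$selected %in% c("a", "b")))
  expect_true("c" %in% sel$prescreen_excluded)

  # all significant -> identical to plain backward AIC
  pooled_all <- poolAll(data.frame(
    model_id = rep(1:5, 3),
    variable = rep(c("a", "b", "c"), each = 5),
    estimate = rep(0.4, 15) + rnorm(15, sd = 0.005), se = 0.01))
  expect_setequal(assistedSelection(co, pooled_all)$selected,
                  backwardAIC(co)$selected)

  # none significant -> explicit failure
  pooled_none <- poolAll(data.frame(
    model_id = rep(1:5, 3),
    variable = rep(c("a", "b", "c"), each = 5),
    estimate = rnorm(15, 0, 0.2), se = 0.5))
  if (!any(pooled_none$significant))
    expect_error(assistedSelection(co, pooled_none), "no candidate")
})
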