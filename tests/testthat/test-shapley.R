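test_that("coalition values hit their boundary cases", {
  toy <- shapley_toy()
  # S = all variables: the model's plain loss on the explanation rows
  v_all <- coalitionValue(toy$beta, c("a", "b", "c"), toy$X, toy$y,
                          toy$bg, toy$groups)
  expect_equal(v_all, logisticLoss(toy$beta, toy$X, toy$y))
  # S = empty on an intercept-only model: masking is a no-op
  b0 <- c(0.4, 0, 0, 0)
  expect_equal(coalitionValue(b0, character(0), toy$X, toy$y, toy$bg,
                              toy$groups),
               logisticLoss(b0, toy$X, toy$y))
  # 2-variable toy with a 2-row background matches full enumeration by hand
  Xe <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(NULL, c("p", "q")))
  bg <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(NULL, c("p", "q")))
  ye <- c(1L, 0L)
  beta <- c(0.1, 0.8, -0.5)
  v_hand <- mean(vapply(1:2, function(e) {
    mean(vapply(1:2, function(b) {
      x <- bg[b, ]; x["p"] <- Xe[e, "p"]  # S = {p}
      eta <- beta[1] + sum(x * beta[-1])
      p <- plogis(eta)
      -(ye[e] * log(p) + (1 - ye[e]) * log(1 - p))
    }, 0))
  }, 0))
  expect_equal(coalitionValue(beta, "p", Xe, ye, bg,
                              list(p = 1L, q = 2L)),
               v_hand)
  expect_error(coalitionValue(beta, "zz", Xe, ye, bg,
                              list(p = 1L, q = 2L)), "unknown")
})

test_that("the exact oracle satisfies the Shapley axioms on constructed games", {
  # d = 1: value = v({1}) - v(empty)
  X1 <- matrix(c(0, 1, 1, 0), 4, 1, dimnames = list(NULL, "a"))
  y1 <- c(0L, 1L, 1L, 0L)
  beta1 <- c(-0.2, 1.1)
  g1 <- list(a = 1L)
  phi1 <- exactShapleyOracle(beta1, X1, y1, X1, g1)
  expect_equal(unname(phi1["a"]),
               coalitionValue(beta1, character(0), X1, y1, X1, g1) -
               coalitionValue(beta1, "a", X1, y1, X1, g1))

  # symmetry: an exchangeable pair receives identical values
  Xs <- as.matrix(expand.grid(a = 0:1, b = 0:1))
  ys <- c(0L, 1L, 1L, 0L)  # symmetric in (a, b)
  betas <- c(-0.3, 0.7, 0.7)
  phis <- exactShapleyOracle(betas, Xs, ys, Xs, list(a = 1L, b = 2L))
  expect_equal(unname(phis["a"]), unname(phis["b"]), tolerance = 1e-12)

  expect_error(exactShapleyOracle(rep(0, 8), matrix(0, 2, 7), c(0L, 1L),
                                  matrix(0, 2, 7),
                                  as.list(setNames(1:7, paste0("v", 1:7)))),
               "d <= 6")
})

test_that("permutation sampling is efficient and converges to the exact oracle", {
  toy <- shapley_toy()
  rec <- sageValues(toy$beta, toy$X, toy$y, toy$groups,
                    n_permutations = 2000, batch_size = 4, seed = 11,
                    background = toy$bg)
  # efficiency: estimates telescope exactly to v(empty) - v(full) as
  # sampled on the same walks
  expect_equal(sum(rec$estimate),
               attr(rec, "v_null") - attr(rec, "v_full"),
               tolerance = 1e-9)
  # agreement with 2^3-coalition enumeration over the same background,
  # within 3 SEs
  oracle <- exactShapleyOracle(toy$beta, toy$X, toy$y, toy$bg, toy$groups)
  for (v in rec$variable) {
    i <- match(v, rec$variable)
    expect_lt(abs(rec$estimate[i] - oracle[v]), 3 * rec$se[i] + 1e-6)
  }
})

test_that("a zero-coefficient variable has exactly zero importance", {
  toy <- shapley_toy()
  beta <- toy$beta
  beta[1 + toy$groups$b] <- 0
  rec <- sageValues(beta, toy$X, toy$y, toy$groups,
                    n_permutations = 200, background_size = 4,
                    batch_size = 2, seed = 5)
  # marginal masking of a zero-coefficient column never changes the loss
  expect_equal(rec$estimate[rec$variable == "b"], 0)
  expect_equal(rec$se[rec$variable == "b"], 0)
})

test_that("Monte-Carlo error shrinks with the permutation budget", {
  toy <- shapley_toy()
  oracle <- exactShapleyOracle(toy$beta, toy$X, toy$y, toy$bg, toy$groups)
  err <- function(n_perm, seed) {
    rec <- sageValues(toy$beta, toy$X, toy$y, toy$groups,
                      n_permutations = n_perm, batch_size = 2,
                      seed = seed, background = toy$bg)
    mean(abs(rec$estimate - oracle[rec$variable]))
  }
  # average over a few seeds to probe the rate, not one lucky draw
  e_small <- mean(vapply(1:5, function(s) err(100, s), 0))
  e_large <- mean(vapply(1:5, function(s) err(1600, s), 0))
  expect_lt(e_large, e_small)
  # reported SE also shrinks at roughly the root-n rate (x4 budget ~ /2)
  se_small <- mean(sageValues(toy$beta, toy$X, toy$y, toy$groups, 400,
                              batch_size = 2, seed = 9,
                              background = toy$bg)$se)
  se_large <- mean(sageValues(toy$beta, toy$X, toy$y, toy$groups, 1600,
                              batch_size = 2, seed = 9,
                              background = toy$bg)$se)
  expect_equal(se_large / se_small, 0.5, tolerance = 0.2)
})

test_that("grouped importance is invariant to the categorical reference level", {
  # same 3-level model written against reference A and reference B
  lv <- c("A", "B", "C")
  set.seed(21)
  gval <- sample(lv, 40, replace = TRUE)
  z <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  enc <- function(ref) {
    others <- setdiff(lv, ref)
    X <- cbind(vapply(others, function(l) as.numeric(gval == l),
                      numeric(40)), z = z)
    colnames(X) <- c(paste0("g=", others), "z")
    X
  }
  a <- 0.3; bB <- 0.8; bC <- -0.5; bz <- 0.6
  beta_refA <- c(a, bB, bC, bz)
  beta_refB <- c(a + bB, -bB, bC - bB, bz)  # identical model, reference B
  groups <- list(g = 1:2, z = 3L)
  XA <- enc("A"); XB <- enc("B")
  phiA <- exactShapleyOracle(beta_refA, XA, y, XA[1:8, ], groups)
  phiB <- exactShapleyOracle(beta_refB, XB, y, XB[1:8, ], groups)
  expect_equal(unname(phiA["g"]), unname(phiB["g"]), tolerance = 1e-10)
  expect_equal(unname(phiA["z"]), unname(phiB["z"]), tolerance = 1e-10)
})

test_that("ensemble importance tables are reproducible and complete", {
  co <- generateCohort(tiny_binary_spec(), 600, seed = 2)
  fit <- fitOptimal(co)
  ens <- buildEnsemble(fit, ensembleConfig(M = 5, u1 = 0.5, u2 = 4,
                                           seed = 3))
  r1 <- ensembleImportance(ens, n_permutations = 20, batch_size = 4,
                           background_size = 50, seed = 8)
  r2 <- ensembleImportance(ens, n_permutations = 20, batch_size = 4,
                           background_size = 50, seed = 8)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5L * 3L)
  expect_true(all(table(r1$variable, r1$model_id) == 1L))
})
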