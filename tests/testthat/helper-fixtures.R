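# Small in-code fixtures shared across test files.

# three-binary-predictor schema with a known outcome model
tiny_binary_spec <- function(gamma = c(a = 1.2, b = -0.8, c = 0),
                             intercept = -0.5, seed = 1L) {
  sch <- cohort_schema(list(variable_spec("a", "binary"),
                            variable_spec("b", "binary"),
                            variable_spec("c", "binary")),
                       outcome = "y")
  syntheticSpec(sch,
                marginals = list(a = 0.5, b = 0.4, c = 0.3),
                coefficients = gamma, intercept = intercept, seed = seed)
}

# mixed-kind schema: binary + 3-level categorical + continuous
mixed_spec <- function(gamma = c(x = 0.9, "g=B" = 0.6, "g=C" = -0.4,
                                 z = 0.5),
                       intercept = -0.3, seed = 1L) {
  sch <- cohort_schema(list(variable_spec("x", "binary"),
                            variable_spec("g", "categorical",
                                          levels = c("A", "B", "C")),
                            variable_spec("z", "continuous")),
                       outcome = "y")
  syntheticSpec(sch,
                marginals = list(x = 0.5, g = c(0.5, 0.3, 0.2),
                                 z = c(0, 0.5)),
                coefficients = gamma, intercept = intercept, seed = seed)
}

# a random schema for property tests: k_b binaries, k_c continuous,
# categoricals with the given level counts
random_schema <- function(k_b, k_c, cat_levels) {
  vars <- c(
    lapply(seq_len(k_b), function(i) variable_spec(paste0("b", i), "binary")),
    lapply(seq_len(k_c), function(i)
      variable_spec(paste0("x", i), "continuous")),
    lapply(seq_along(cat_levels), function(i)
      variable_spec(paste0("g", i), "categorical",
                    levels = paste0("L", seq_len(cat_levels[i])))))
  cohort_schema(vars, "y")
}

# deterministic d = 3 toy for Shapley tests: discrete explanation rows,
# a 4-row background, and a fixed logistic model
shapley_toy <- function() {
  X <- matrix(c(0, 1, 0, 1, 1, 0,
                1, 1, 0, 0, 1, 0,
                0.5, -1, 2, 0, 1, -0.5), 6, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  list(X = X,
       y = c(1L, 0L, 1L, 0L, 1L, 0L),
       bg = X[c(1L, 2L, 4L, 6L), , drop = FALSE],
       beta = c(0.2, 0.9, -0.7, 0.5),
       groups = list(a = 1L, b = 2L, c = 3L))
}
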