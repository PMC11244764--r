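test_that("design encoding drops the reference level and maps columns to variables", {
  sch <- ohcaSyntheticSpec()$schema
  expect_equal(nEncodedColumns(sch), 24L)
  co <- generateCohort(ohcaSyntheticSpec(), 50, seed = 3)
  enc <- encodeDesign(co)
  expect_equal(ncol(enc$X), 24L)
  expect_equal(length(enc$groups$race), 3L)  # 4 levels -> 3 indicators
  expect_equal(length(enc$groups$time_of_day), 2L)
  expect_setequal(unlist(enc$groups), seq_len(24L))

  # all-binary schema: identity-like map
  spec3 <- tiny_binary_spec()
  enc3 <- encodeDesign(generateCohort(spec3, 20, seed = 1))
  expect_equal(ncol(enc3$X), 3L)
  expect_equal(enc3$groups, list(a = 1L, b = 2L, c = 3L))

  # single 4-level categorical: 3 columns, all mapped to it
  sch1 <- cohort_schema(list(variable_spec("g", "categorical",
                                           levels = c("p", "q", "r", "s"))),
                        "y")
  tab <- cohort_table(data.frame(g = c("p", "q", "r", "s", "q"),
                                 y = c(0, 1, 0, 1, 0)), sch1)
  enc1 <- encodeDesign(tab)
  expect_equal(ncol(enc1$X), 3L)
  expect_equal(enc1$groups, list(g = 1:3))
  expect_equal(unname(enc1$X[2, ]), c(1, 0, 0))  # treatment coding vs "p"
})

test_that("encoded column count matches the closed form on random schemas", {
  set.seed(42)
  for (i in 1:20) {
    k_b <- sample(0:4, 1); k_c <- sample(0:3, 1)
    n_cat <- sample(0:3, 1)
    lv <- if (n_cat) sample(2:5, n_cat, replace = TRUE) else integer(0)
    if (k_b + k_c + n_cat == 0) k_b <- 1
    sch <- random_schema(k_b, k_c, lv)
    expected <- k_b + k_c + sum(lv - 1L)
    expect_equal(nEncodedColumns(sch), expected)
    # build one row of data and check the actual matrix width agrees
    df <- data.frame(y = 0L)
    for (v in sch$variables)
      df[[v$name]] <- switch(v$kind, binary = 1L, continuous = 0.5,
                             categorical = v$levels[1L])
    expect_equal(ncol(encodeDesign(cohort_table(df, sch))$X), expected)
  }
})

test_that("undeclared categorical levels are rejected with the row index", {
  sch <- cohort_schema(list(variable_spec("g", "categorical",
                                          levels = c("A", "B"))), "y")
  df <- data.frame(g = c("A", "B", "Z"), y = c(0, 1, 0))
  expect_error(cohort_table(df, sch), "undeclared level 'Z' at row 3")
})

test_that("schema construction enforces its invariants", {
  expect_error(variable_spec("g", "categorical", levels = "only"), ">= 2")
  expect_error(cohort_schema(list(variable_spec("a", "binary"),
                                  variable_spec("a", "binary")), "y"),
               "duplicate")
  expect_error(cohort_schema(list(variable_spec("a", "binary")), "a"),
               "clashes")
  sch <- cohort_schema(list(variable_spec("a", "binary")), "y")
  expect_error(cohort_table(data.frame(a = c(1, NA), y = c(0, 1)), sch),
               "missing values")
})

test_that("splitting partitions the cohort at the printed sizes", {
  co <- generateCohort(ohcaSyntheticSpec(), 7490, seed = 1)
  sp <- splitCohort(co, 0.6, seed = 11)
  expect_equal(nrow(sp$train), 4494L)
  expect_equal(nrow(sp$test), 2996L)

  # exhaustive + disjoint, across sizes and fractions
  spec <- tiny_binary_spec()
  for (case in list(c(101, 0.5), c(37, 0.33), c(200, 0.9))) {
    coh <- generateCohort(spec, case[1], seed = 2)
    s <- splitCohort(coh, case[2], seed = 5)
    expect_equal(nrow(s$train), floor(case[2] * case[1] + 0.5))
    expect_equal(nrow(s$train) + nrow(s$test), as.integer(case[1]))
  }

  # fraction 1 -> empty test set; determinism under a fixed seed
  coh <- generateCohort(spec, 100, seed = 2)
  expect_equal(nrow(splitCohort(coh, 1, seed = 1)$test), 0L)
  s1 <- splitCohort(coh, 0.5, seed = 7)
  s2 <- splitCohort(coh, 0.5, seed = 7)
  expect_identical(as.data.frame(s1$train), as.data.frame(s2$train))
  expect_error(splitCohort(coh, 1.2, seed = 1), "train_fraction")
})

test_that("subsampling draws without replacement, reproducibly", {
  co <- generateCohort(tiny_binary_spec(), 400, seed = 3)
  sub <- subsampleCohort(co, 150, seed = 9)
  expect_equal(nrow(sub), 150L)
  expect_identical(as.data.frame(subsampleCohort(co, 150, seed = 9)),
                   as.data.frame(sub))
  # m = n is a permutation of the input
  perm <- subsampleCohort(co, 400, seed = 1)
  expect_identical(dim(perm), dim(co))
  expect_equal(sort(perm$a * 4 + perm$b * 2 + perm$c),
               sort(co$a * 4 + co$b * 2 + co$c))
  # two seeds almost surely differ
  expect_false(identical(as.data.frame(subsampleCohort(co, 150, seed = 1)),
                         as.data.frame(subsampleCohort(co, 150, seed = 2))))
  expect_error(subsampleCohort(co, 401, seed = 1), "401")
})

test_that("CSV + YAML round trip reproduces the cohort exactly", {
  co <- generateCohort(ohcaSyntheticSpec(), 80, seed = 12)
  csv <- tempfile(fileext = ".csv"); yml <- tempfile(fileext = ".yaml")
  writeCohortCSV(co, csv, yml)
  back <- readCohortCSV(csv, yml)
  expect_identical(as.data.frame(back), as.data.frame(co))
  sch2 <- cohortSchema(back)
  expect_equal(variable_spec_names <- names(sch2$variables),
               names(cohortSchema(co)$variables))
  expect_equal(sch2$variables$race$levels,
               cohortSchema(co)$variables$race$levels)
  unlink(c(csv, yml))
})
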