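#' Declare a cohort variable
#'
#' A variable is one of three kinds: \code{binary} (coded 0/1),
#' \code{categorical} (a declared, ordered set of level labels; the first
#' level is the dummy-coding reference) or \code{continuous}.
#'
#' @param name Variable name (unique within a schema).
#' @param kind One of \code{"binary"}, \code{"categorical"},
#'   \code{"continuous"}.
#' @param levels For categorical variables, an ordered character vector of
#'   at least two distinct level labels; the first is the reference level.
#' @param unit Optional free-text unit (e.g. \code{"minutes"}).
#' @return An object of class \code{variable_spec}.
#' @examples
#' variable_spec("race", "categorical",
#'               levels = c("Chinese", "Indian", "Malay", "Others"))
#' @export
variable_spec <- function(name, kind = c("binary", "categorical", "continuous"),
                          levels = NULL, unit = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L || anyDuplicated(levels))
      stop("categorical variable '", name,
           "' needs >= 2 distinct declared levels")
    levels <- as.character(levels)
  } else if (!is.null(levels)) {
    stop("'levels' is only meaningful for categorical variables")
  }
  structure(list(name = name, kind = kind, levels = levels, unit = unit),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec> ", x$name, " (", x$kind, ")", sep = "")
  if (!is.null(x$levels)) cat(": ", paste(x$levels, collapse = " | "), sep = "")
  if (!is.null(x$unit)) cat(" [", x$unit, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Assemble a cohort schema
#'
#' @param variables A list of \code{\link{variable_spec}} objects (order is
#'   preserved and determines design-matrix column order).
#' @param outcome Name of the binary outcome column; must not clash with a
#'   predictor name.
#' @return An object of class \code{cohort_schema}.
#' @seealso [nEncodedColumns()] for the implied design-matrix width.
#' @export
cohort_schema <- function(variables, outcome) {
  if (!length(variables) || !all(vapply(variables, inherits, TRUE, "variable_spec")))
    stop("'variables' must be a non-empty list of variable_spec objects")
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (!is.character(outcome) || length(outcome) != 1L || !nzchar(outcome))
    stop("'outcome' must be a single non-empty string")
  if (outcome %in% nms)
    stop("outcome name '", outcome, "' clashes with a predictor name")
  names(variables) <- nms
  structure(list(variables = variables, outcome = outcome),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  kinds <- vapply(x$variables, `[[`, "", "kind")
  cat("<cohort_schema> ", length(x$variables), " variables (",
      sum(kinds == "binary"), " binary, ",
      sum(kinds == "categorical"), " categorical, ",
      sum(kinds == "continuous"), " continuous) -> ",
      nEncodedColumns(x), " design columns; outcome '", x$outcome, "'\n",
      sep = "")
  invisible(x)
}

#' Number of design-matrix columns implied by a schema
#'
#' Binary and continuous variables contribute one column each; a categorical
#' variable with L declared levels contributes L - 1 indicator columns
#' (reference level dropped). The intercept is not counted.
#'
#' @param schema A \code{cohort_schema}.
#' @return Integer column count.
#' @export
nEncodedColumns <- function(schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  sum(vapply(schema$variables, function(v)
    if (v$kind == "categorical") length(v$levels) - 1L else 1L, 1L))
}

variable_names <- function(schema) names(schema$variables)

#' Bind data to a schema as a validated cohort table
#'
#' Validates that every declared variable and the outcome are present, that
#' there are no missing values (analyses assume complete cases), that binary
#' columns and the outcome are coded 0/1, continuous values are finite, and
#' categorical values fall within their declared levels.
#'
#' @param data A data.frame holding one column per declared variable plus the
#'   outcome column (0/1).
#' @param schema A \code{cohort_schema}.
#' @return A \code{cohort_table}: the data.frame (columns reordered to match
#'   the schema) carrying the schema as an attribute.
#' @export
cohort_table <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  need <- c(variable_names(schema), schema$outcome)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data[need], stringsAsFactors = FALSE)
  if (anyNA(data)) {
    bad <- which(!stats::complete.cases(data))
    stop("missing values are not allowed (complete-case analysis); ",
         "first offending row: ", bad[1L])
  }
  y <- data[[schema$outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome '", schema$outcome, "' must be coded 0/1")
  data[[schema$outcome]] <- as.integer(y)
  for (v in schema$variables) {
    col <- data[[v$name]]
    if (v$kind == "binary") {
      if (!all(col %in% c(0, 1)))
        stop("binary variable '", v$name, "' must be coded 0/1; ",
             "first offending row: ", which(!col %in% c(0, 1))[1L])
      data[[v$name]] <- as.integer(col)
    } else if (v$kind == "continuous") {
      if (!is.numeric(col) || any(!is.finite(col)))
        stop("continuous variable '", v$name, "' has non-finite values")
      data[[v$name]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      bad <- which(!col %in% v$levels)
      if (length(bad))
        stop("categorical variable '", v$name, "' has undeclared level '",
             col[bad[1L]], "' at row ", bad[1L])
      data[[v$name]] <- col
    }
  }
  structure(data, schema = schema,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  sch <- cohortSchema(x)
  y <- x[[sch$outcome]]
  cat("<cohort_table> ", nrow(x), " subjects, ",
      length(sch$variables), " variables; outcome prevalence ",
      sprintf("%.1f%%", 100 * mean(y)), "\n", sep = "")
  invisible(x)
}

#' @rdname cohort_table
#' @param table A \code{cohort_table}.
#' @export
cohortSchema <- function(table) {
  sch <- attr(table, "schema")
  if (is.null(sch)) stop("not a cohort_table: no schema attached")
  sch
}

#' @rdname cohort_table
#' @export
outcomeVector <- function(table) {
  as.integer(table[[cohortSchema(table)$outcome]])
}

#' Encode a cohort table as a numeric design matrix
#'
#' Binary and continuous variables map to one column each; a categorical
#' variable with L levels maps to L - 1 treatment-coded indicators against
#' its first declared level. No intercept column is added (models handle the
#' intercept separately). Every column is assigned to exactly one source
#' variable via the returned group map, which is how grouped (variable-level)
#' Shapley values and Wald tests treat one-hot blocks atomically.
#'
#' @param table A \code{cohort_table}.
#' @return A list with elements \code{X} (n x p numeric matrix), \code{y}
#'   (integer outcome vector), \code{groups} (named list: variable ->
#'   integer column indices of \code{X}) and \code{column_variable}
#'   (character vector, length p: source variable of each column).
#' @export
encodeDesign <- function(table) {
  sch <- cohortSchema(table)
  n <- nrow(table)
  cols <- list(); colnms <- character(0); colvar <- character(0)
  for (v in sch$variables) {
    val <- table[[v$name]]
    if (v$kind == "categorical") {
      for (lev in v$levels[-1L]) {
        cols[[length(cols) + 1L]] <- as.numeric(val == lev)
        colnms <- c(colnms, paste0(v$name, "=", lev))
        colvar <- c(colvar, v$name)
      }
    } else {
      cols[[length(cols) + 1L]] <- as.numeric(val)
      colnms <- c(colnms, v$name)
      colvar <- c(colvar, v$name)
    }
  }
  X <- matrix(unlist(cols, use.names = FALSE), nrow = n,
              dimnames = list(NULL, colnms))
  groups <- lapply(variable_names(sch), function(nm) which(colvar == nm))
  names(groups) <- variable_names(sch)
  list(X = X, y = outcomeVector(table), groups = groups,
       column_variable = colvar)
}

subset_rows <- function(table, idx) {
  sch <- cohortSchema(table)
  out <- as.data.frame(table, stringsAsFactors = FALSE)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, schema = sch, class = c("cohort_table", "data.frame"))
}

#' Split a cohort into training and test sets
#'
#' A simple random (by default unstratified) partition. The training size is
#' \code{fraction * n} rounded half away from zero, so a 60/40 split of 7490
#' subjects gives 4494/2996.
#'
#' @param table A \code{cohort_table}.
#' @param train_fraction Proportion in (0, 1] assigned to training.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param stratify_outcome If \code{TRUE}, split within each outcome class
#'   (off by default).
#' @return A list with \code{train} and \code{test} cohort tables.
#' @export
splitCohort <- function(table, train_fraction, seed,
                        stratify_outcome = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  if (!(train_fraction > 0 && train_fraction <= 1))
    stop("'train_fraction' must be in (0, 1]")
  n <- nrow(table)
  if (n < 2L && train_fraction < 1)
    stop("cannot split fewer than 2 rows into non-empty parts")
  set.seed(seed)
  take <- function(idx, frac) {
    k <- floor(frac * length(idx) + 0.5)  # round half away from zero
    sort(sample(idx, k))
  }
  if (stratify_outcome) {
    y <- outcomeVector(table)
    tr <- sort(c(take(which(y == 1L), train_fraction),
                 take(which(y == 0L), train_fraction)))
  } else {
    tr <- take(seq_len(n), train_fraction)
  }
  list(train = subset_rows(table, tr),
       test = subset_rows(table, setdiff(seq_len(n), tr)))
}

#' Draw a random subsample of a cohort
#'
#' @param table A \code{cohort_table}.
#' @param m Number of rows to draw without replacement (\code{m <= n}).
#' @param seed Integer seed for reproducibility.
#' @return A \code{cohort_table} of \code{m} rows.
#' @export
subsampleCohort <- function(table, m, seed) {
  stopifnot(inherits(table, "cohort_table"))
  n <- nrow(table)
  if (m > n) stop("requested subsample of ", m, " rows from only ", n)
  set.seed(seed)
  subset_rows(table, sample(seq_len(n), m))
}

#' Read and write cohort tables as CSV plus a YAML schema
#'
#' The CSV carries one header row of variable names with the outcome coded
#' 0/1; continuous values are written with 17 significant digits so that a
#' write/read round trip reproduces the table exactly. The schema file is a
#' YAML document mapping each variable to its kind, levels and unit.
#'
#' @param table A \code{cohort_table}.
#' @param csv_path Path of the data CSV.
#' @param schema_path Path of the YAML schema.
#' @return \code{readCohortCSV} returns a \code{cohort_table};
#'   \code{writeCohortCSV} returns its paths invisibly.
#' @export
writeCohortCSV <- function(table, csv_path, schema_path) {
  sch <- cohortSchema(table)
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (v in sch$variables)
    if (v$kind == "continuous")
      out[[v$name]] <- sprintf("%.17g", out[[v$name]])
  utils::write.csv(out, csv_path, row.names = FALSE, quote = TRUE)
  writeSchemaYAML(sch, schema_path)
  invisible(c(csv = csv_path, schema = schema_path))
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(csv_path, schema_path) {
  sch <- readSchemaYAML(schema_path)
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (v in sch$variables)
    if (v$kind != "categorical") raw[[v$name]] <- as.numeric(raw[[v$name]])
  raw[[sch$outcome]] <- as.integer(raw[[sch$outcome]])
  cohort_table(raw, sch)
}

#' @rdname writeCohortCSV
#' @param schema A \code{cohort_schema}.
#' @export
writeSchemaYAML <- function(schema, schema_path) {
  vars <- lapply(schema$variables, function(v) {
    out <- list(kind = v$kind)
    if (!is.null(v$levels)) out$levels <- as.list(v$levels)
    if (!is.null(v$unit)) out$unit <- v$unit
    out
  })
  yaml::write_yaml(list(outcome = schema$outcome, variables = vars),
                   schema_path)
  invisible(schema_path)
}

#' @rdname writeCohortCSV
#' @export
readSchemaYAML <- function(schema_path) {
  doc <- yaml::read_yaml(schema_path)
  vars <- lapply(names(doc$variables), function(nm) {
    v <- doc$variables[[nm]]
    variable_spec(nm, v$kind,
                  levels = if (!is.null(v$levels)) unlist(v$levels),
                  unit = v$unit)
  })
  cohort_schema(vars, doc$outcome)
}
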