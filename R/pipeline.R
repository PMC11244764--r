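#' Configure a full analysis run
#'
#' Bundles every knob of the end-to-end workflow. Per-stage seeds are
#' derived from the master seed by a fixed counter scheme
#' (\code{master * 1000 + stage offset}), so replicates are independent but
#' fully reproducible; every derived seed is written to the run log.
#'
#' @param spec A \code{\link{syntheticSpec}} to simulate from, or
#'   \code{NULL} when \code{cohort} is given.
#' @param cohort An existing \code{\link{cohort_table}} (overrides
#'   \code{spec}).
#' @param n Cohort size to simulate (default 7490).
#' @param train_fraction Training proportion (default 0.6).
#' @param M Ensemble size (default 250).
#' @param loss_tolerance Excess-loss eligibility bound (default 0.05).
#' @param n_permutations,batch_size,background_size Shapley sampling
#'   budget per model (defaults 200 / 10 / 100).
#' @param explanation_min_n Training size at and above which only a random
#'   half of the training set is used as explanation data (default 3000);
#'   below it the full training set is used.
#' @param n_boot Bootstrap resamples for evaluation CIs (default 2000).
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts, or \code{NULL} to skip
#'   writing.
#' @return A list of class \code{run_config}.
#' @export
runConfig <- function(spec = NULL, cohort = NULL, n = 7490L,
                      train_fraction = 0.6, M = 250L,
                      loss_tolerance = 0.05, n_permutations = 200L,
                      batch_size = 10L, background_size = 100L,
                      explanation_min_n = 3000L, n_boot = 2000L,
                      seed = 1L, out_dir = NULL) {
  if (is.null(spec) && is.null(cohort))
    stop("provide a synthetic spec or a cohort table")
  structure(list(spec = spec, cohort = cohort, n = as.integer(n),
                 train_fraction = train_fraction, M = as.integer(M),
                 loss_tolerance = loss_tolerance,
                 n_permutations = as.integer(n_permutations),
                 batch_size = as.integer(batch_size),
                 background_size = as.integer(background_size),
                 explanation_min_n = as.integer(explanation_min_n),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage_seed <- function(master, offset) master * 1000L + offset

# explanation rule: half the training rows when training is large enough,
# otherwise the full training set
explanation_rows <- function(n_train, min_n, seed) {
  if (n_train >= min_n) {
    set.seed(seed)
    sort(sample.int(n_train, n_train %/% 2L))
  } else seq_len(n_train)
}

log_line <- function(log, ...) c(log, paste0(...))

#' Importance pipeline on a single training cohort
#'
#' Fit the optimal model, tune the scaling bounds, build the
#' nearly-optimal ensemble, estimate per-model Shapley importance on the
#' explanation data, and pool by random-effects meta-analysis.
#'
#' @param train Training \code{\link{cohort_table}}.
#' @param config A \code{\link{runConfig}}.
#' @param seed_base Base for the derived stage seeds (default the config
#'   master seed).
#' @return List with \code{fit}, \code{tuning}, \code{ensemble},
#'   \code{records}, \code{pooled}, \code{explanation_n}, \code{log}.
#' @export
runImportance <- function(train, config, seed_base = config$seed) {
  log <- character(0)
  fit <- fitOptimal(train)
  log <- log_line(log, "fit: n_train=", fit$n_train,
                  " columns=", length(fit$beta) - 1L,
                  " loss=", sprintf("%.6f", fit$train_loss))
  tun <- tuneScalingBounds(fit, pilot_size = 200L,
                           loss_tolerance = config$loss_tolerance,
                           seed = stage_seed(seed_base, 2L))
  log <- log_line(log, "tune: u1=", format(tun$u1), " u2=", format(tun$u2),
                  " eligibility=", sprintf("%.3f", tun$proportion),
                  " seed=", stage_seed(seed_base, 2L))
  ens <- buildEnsemble(fit, ensembleConfig(
    M = config$M, loss_tolerance = config$loss_tolerance,
    u1 = tun$u1, u2 = tun$u2, seed = stage_seed(seed_base, 3L)))
  log <- log_line(log, "ensemble: M=", config$M, " attempts=", ens$attempts,
                  " max_loss_ratio=", sprintf("%.4f", max(ens$loss_ratio)),
                  " seed=", stage_seed(seed_base, 3L))
  er <- explanation_rows(fit$n_train, config$explanation_min_n,
                         stage_seed(seed_base, 4L))
  records <- ensembleImportance(
    ens, explanation = fit$design[er, , drop = FALSE], y = fit$y[er],
    n_permutations = config$n_permutations,
    background_size = config$background_size,
    batch_size = config$batch_size,
    seed = stage_seed(seed_base, 5L))
  log <- log_line(log, "shapley: explanation_n=", length(er),
                  " permutations=", config$n_permutations,
                  " batch=", config$batch_size,
                  " background=", config$background_size,
                  " seed=", stage_seed(seed_base, 5L))
  pooled <- poolAll(records)
  log <- log_line(log, "pooled: significant=",
                  sum(pooled$significant), "/", nrow(pooled))
  list(fit = fit, tuning = tun, ensemble = ens, records = records,
       pooled = pooled, explanation_n = length(er), log = log)
}

#' Run the full main analysis
#'
#' The end-to-end workflow: simulate (or take) a cohort, split it, run the
#' importance pipeline on the training set, build a prediction model by
#' plain backward AIC and by importance-prescreened backward AIC, and
#' evaluate both on the test set (AUC, corner-optimal threshold,
#' classification metrics with bootstrap CIs). All numeric outputs are a
#' pure function of the configuration; artifacts (CSV tables, an SVG
#' importance figure, a plain-text run log) are written when
#' \code{out_dir} is set.
#'
#' @param config A \code{\link{runConfig}}.
#' @return List of class \code{vic_run}: \code{cohort_n}, \code{train},
#'   \code{test}, \code{importance} (see \code{\link{runImportance}}),
#'   \code{selection_backward}, \code{selection_assisted},
#'   \code{eval_backward}, \code{eval_assisted}, \code{log}.
#' @export
runMainAnalysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- log_line(character(0), "master_seed=", config$seed)
  cohort <- if (!is.null(config$cohort)) config$cohort
            else generateCohort(config$spec, config$n,
                                seed = stage_seed(config$seed, 0L))
  sp <- splitCohort(cohort, config$train_fraction,
                    seed = stage_seed(config$seed, 1L))
  log <- log_line(log, "split: n=", nrow(cohort),
                  " train=", nrow(sp$train), " test=", nrow(sp$test),
                  " fraction=", config$train_fraction,
                  " seed=", stage_seed(config$seed, 1L))
  imp <- runImportance(sp$train, config)
  log <- c(log, imp$log)

  sel_a <- backwardAIC(sp$train)
  log <- log_line(log, "backward: selected=", length(sel_a$selected),
                  " [", paste(sel_a$selected, collapse = ","), "]")
  sel_b <- assistedSelection(sp$train, imp$pooled)
  log <- log_line(log, "assisted: prescreen_excluded=",
                  length(sel_b$prescreen_excluded),
                  " selected=", length(sel_b$selected),
                  " [", paste(sel_b$selected, collapse = ","), "]")

  y_test <- outcomeVector(sp$test)
  eval_one <- function(sel, offset) {
    scores <- predictRisk(sel$fit, sp$test)
    auc <- aucWithCI(scores, y_test, n_boot = config$n_boot,
                     seed = stage_seed(config$seed, offset))
    th <- cornerThreshold(scores, y_test)
    rep <- classificationReport(scores, y_test, th,
                                n_boot = config$n_boot,
                                seed = stage_seed(config$seed, offset + 1L))
    list(auc = auc, threshold = th, report = rep, scores = scores)
  }
  ev_a <- eval_one(sel_a, 6L)
  ev_b <- eval_one(sel_b, 8L)
  log <- log_line(log, "eval: backward AUC=", sprintf("%.3f", ev_a$auc$auc),
                  " thr=", sprintf("%.3f", ev_a$threshold),
                  "; assisted AUC=", sprintf("%.3f", ev_b$auc$auc),
                  " thr=", sprintf("%.3f", ev_b$threshold))

  out <- structure(list(cohort_n = nrow(cohort), train = sp$train,
                        test = sp$test, importance = imp,
                        selection_backward = sel_a,
                        selection_assisted = sel_b,
                        eval_backward = ev_a, eval_assisted = ev_b,
                        log = log),
                   class = "vic_run")
  if (!is.null(config$out_dir)) write_run_artifacts(out, config)
  out
}

#' @export
print.vic_run <- function(x, ...) {
  cat("<vic_run> cohort n=", x$cohort_n, " (train ", nrow(x$train),
      " / test ", nrow(x$test), "); ",
      sum(x$importance$pooled$significant), "/",
      nrow(x$importance$pooled), " variables significant; backward AUC ",
      sprintf("%.3f", x$eval_backward$auc$auc), ", assisted AUC ",
      sprintf("%.3f", x$eval_assisted$auc$auc), "\n", sep = "")
  invisible(x)
}

write_run_artifacts <- function(run, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(as.data.frame(run$importance$pooled),
                   p("pooled_importance.csv"), row.names = FALSE)
  utils::write.csv(run$importance$records, p("importance_records.csv"),
                   row.names = FALSE)
  utils::write.csv(ensembleAsDataFrame(run$importance$ensemble),
                   p("ensemble_members.csv"), row.names = FALSE)
  for (nm in c("backward", "assisted")) {
    sel <- run[[paste0("selection_", nm)]]
    ev <- run[[paste0("eval_", nm)]]
    utils::write.csv(sel$trace, p(paste0("selection_", nm, ".csv")),
                     row.names = FALSE)
    ws <- waldSummary(sel$fit)
    utils::write.csv(ws$coefficients, p(paste0("model_", nm, "_terms.csv")),
                     row.names = FALSE)
    df <- as.data.frame(ev$report)
    df <- rbind(df, data.frame(metric = c("auc", "threshold"),
                               estimate = c(ev$auc$auc, ev$threshold),
                               ci_lower = c(ev$auc$ci[1L], NA),
                               ci_upper = c(ev$auc$ci[2L], NA)))
    utils::write.csv(df, p(paste0("eval_", nm, ".csv")), row.names = FALSE)
  }
  grDevices::svg(p("importance.svg"), width = 7, height = 6)
  print(plotImportance(run$importance$pooled))
  grDevices::dev.off()
  writeLines(run$log, p("run_log.txt"))
  invisible(config$out_dir)
}

#' Subsample stability experiments
#'
#' For each requested subsample size and replicate, draws a random
#' subsample of the cohort, reruns the importance pipeline on it (using
#' the full subsample for fitting, ensemble generation and explanation,
#' as appropriate for limited sample sizes), and tabulates which variables
#' remain significant across runs.
#'
#' @param config A \code{\link{runConfig}} (its spec/cohort defines the
#'   full cohort).
#' @param sizes Integer vector of subsample sizes (default c(2500, 500)).
#' @param replicates Replicates per size, recycled against \code{sizes}
#'   (default c(1, 3)).
#' @return List with \code{runs} (list of per-run \code{pooled} tables,
#'   named size_replicate), \code{stability} (variables x runs logical
#'   matrix of significance flags) and \code{log}.
#' @export
runSubsampleExperiments <- function(config, sizes = c(2500L, 500L),
                                    replicates = c(1L, 3L)) {
  stopifnot(inherits(config, "run_config"))
  replicates <- rep_len(replicates, length(sizes))
  cohort <- if (!is.null(config$cohort)) config$cohort
            else generateCohort(config$spec, config$n,
                                seed = stage_seed(config$seed, 0L))
  if (any(sizes > nrow(cohort)))
    stop("subsample sizes exceed the cohort size (", nrow(cohort), ")")
  log <- character(0)
  runs <- list()
  for (si in seq_along(sizes)) {
    for (r in seq_len(replicates[si])) {
      seed_base <- config$seed + 100L * si + r
      sub <- subsampleCohort(cohort, sizes[si],
                             seed = stage_seed(seed_base, 1L))
      imp <- runImportance(sub, config, seed_base = seed_base)
      nm <- paste0("n", sizes[si], "_r", r)
      runs[[nm]] <- imp$pooled
      log <- c(log, paste0("[", nm, "] seed_base=", seed_base),
               imp$log)
    }
  }
  vars <- sort(runs[[1L]]$variable)
  stability <- vapply(runs, function(pl)
    pl$significant[match(vars, pl$variable)], logical(length(vars)))
  rownames(stability) <- vars
  list(runs = runs, stability = stability, log = log)
}
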