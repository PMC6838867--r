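#' Default run configuration
#'
#' Assembles the single configuration object driving [run_pipeline()] and
#' the command-line interface. Serializes to/from JSON.
#'
#' @param manifest path to a cohort manifest (mutually exclusive with
#'   `simulate`).
#' @param simulate named list of [synthetic_cohort_config()] arguments; a
#'   synthetic cohort is generated when no manifest is given.
#' @param alpha t-test filter threshold.
#' @param C SVM soft-margin cost.
#' @param selection_mode `"paper"` or `"nested"`.
#' @param n_perm label permutations (0 skips the permutation test).
#' @param kmeans_restarts k-means restarts.
#' @param seed seed for permutations / clustering / simulation.
#' @param fisher Fisher z-transform edges on load.
#' @param var_equal pooled (TRUE) or Welch filter t-test.
#' @param out_dir output directory for artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, simulate = list(), alpha = 0.05,
                       C = 1, selection_mode = "paper", n_perm = 1000,
                       kmeans_restarts = 50, seed = 1L, fisher = FALSE,
                       var_equal = TRUE, out_dir = "rehabdist_out") {
  stopifnot(selection_mode %in% c("paper", "nested"),
            alpha > 0, alpha < 1, C > 0, n_perm >= 0)
  structure(list(manifest = manifest, simulate = simulate, alpha = alpha,
                 C = C, selection_mode = selection_mode, n_perm = n_perm,
                 kmeans_restarts = kmeans_restarts, seed = as.integer(seed),
                 fisher = isTRUE(fisher), var_equal = isTRUE(var_equal),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with any subset of the configuration fields.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  do.call(run_config, x[intersect(names(x), known)])
}

.log <- function(...) message("[rehabdist] ", ...)

#' Run the full evaluation pipeline
#'
#' Executes, in order: cohort assembly (load from a manifest or simulate),
#' feature selection + SVM training on first sessions, LOOCV
#' classification, second-session testing, the label-permutation test,
#' the 2-means clustering check, the LOOCV distance protocol over all
#' sessions, paired intra-group statistics on first-vs-second-session
#' distances and clinical scores, and normalized trajectory export.
#' Machine-readable results are written under `config$out_dir` (JSON
#' report plus tab-separated tables); progress is logged to stderr.
#'
#' @param config a `run_config` (or a path to its JSON form).
#' @return the report, invisibly: a list mirroring `report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log("resolved config: ",
       jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"))

  if (!is.null(config$manifest)) {
    .log("loading cohort from ", config$manifest)
    cohort <- load_cohort(config$manifest, fisher = config$fisher)
  } else {
    .log("simulating synthetic cohort")
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- simulate_cohort(do.call(synthetic_cohort_config, sim_args))
  }
  man <- cohort$manifest
  fs <- first_session_data(cohort)

  .log("training discriminant model (alpha = ", config$alpha,
       ", C = ", config$C, ")")
  model <- fit_discriminant(fs$X, fs$y, alpha = config$alpha, C = config$C,
                            var_equal = config$var_equal)
  write_model(model_bundle(model$sig, model$hyperplane,
                           cohort$region_labels, seed = config$seed),
              file.path(config$out_dir, "model.json"))

  .log("LOOCV classification (", config$selection_mode, " mode)")
  cv <- loocv_classify(fs$X, fs$y, alpha = config$alpha, C = config$C,
                       selection_mode = config$selection_mode,
                       var_equal = config$var_equal)
  .write_tsv(cv$predictions, file.path(config$out_dir, "loocv_predictions.tsv"))

  has_s2 <- any(man$session_index == 2L)
  acc2 <- if (has_s2) {
    sel <- man$session_index == 2L
    second_session_test(model, cohort$edges[sel, , drop = FALSE])
  } else NA_real_

  perm <- NULL
  if (config$n_perm > 0) {
    .log("permutation test (", config$n_perm, " permutations)")
    perm <- permutation_test(fs$X, fs$y, n_perm = config$n_perm,
                             alpha = config$alpha, C = config$C,
                             seed = config$seed,
                             selection_mode = config$selection_mode,
                             var_equal = config$var_equal)
  }

  .log("2-means clustering check")
  km <- kmeans_validation(extract_features(fs$X, model$sig), fs$y,
                          restarts = config$kmeans_restarts,
                          seed = config$seed)

  .log("LOOCV distance protocol over all sessions")
  dist_rec <- loocv_distance_protocol(cohort, alpha = config$alpha,
                                      C = config$C,
                                      selection_mode = config$selection_mode,
                                      var_equal = config$var_equal)
  .write_tsv(dist_rec, file.path(config$out_dir, "distance_records.tsv"))

  stats_list <- .paired_stats(dist_rec, man)
  traj <- distance_trajectories(dist_rec, man, min_sessions = 3)
  if (!is.null(traj) && nrow(traj))
    .write_tsv(traj, file.path(config$out_dir, "trajectories.tsv"))

  report <- list(
    config = unclass(config),
    software = paste0("rehabdist ",
                      as.character(utils::packageVersion("rehabdist"))),
    n_controls = sum(man$group == -1L),
    n_patients = length(unique(man$subject_id[man$group == 1L])),
    n_edges = ncol(cohort$edges),
    n_significant = length(model$sig$positions),
    discover = length(model$sig$positions) / model$sig$n_edges,
    loocv = cv$metrics[c("TP", "FP", "FN", "TN", "accuracy", "precision",
                         "sensitivity", "specificity")],
    second_session_accuracy = acc2,
    permutation = if (!is.null(perm))
      list(observed = perm$observed, p = perm$p, n_perm = perm$n_perm),
    clustering = list(accuracy = km$accuracy, n_errors = km$n_errors),
    distance_summary = .distance_summary(dist_rec),
    intra_group = stats_list)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  .log("report written to ", file.path(config$out_dir, "report.json"))
  invisible(report)
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)

.distance_summary <- function(dist_rec) {
  hc <- dist_rec$distance[dist_rec$group == -1L]
  p1 <- dist_rec$distance[dist_rec$group == 1L & dist_rec$session_index == 1L]
  p2 <- dist_rec$distance[dist_rec$group == 1L & dist_rec$session_index == 2L]
  f <- function(x) if (length(x))
    list(mean = mean(x), sd = stats::sd(x), n = length(x)) else NULL
  list(hc = f(hc), patients_before = f(p1), patients_after = f(p2))
}

# paired session-1 vs session-2 tests on distance and every score column
.paired_stats <- function(dist_rec, man) {
  pats <- unique(man$subject_id[man$group == 1L])
  with_s2 <- pats[vapply(pats, function(s)
    any(man$subject_id == s & man$session_index == 2L), logical(1))]
  if (length(with_s2) < 3L) return(NULL)
  d1 <- dist_rec$distance[match(paste(with_s2, 1L),
                                paste(dist_rec$subject_id,
                                      dist_rec$session_index))]
  d2 <- dist_rec$distance[match(paste(with_s2, 2L),
                                paste(dist_rec$subject_id,
                                      dist_rec$session_index))]
  out <- list(distance = unclass(intra_group_tests(d1, d2, with_s2)))
  for (sc in grep("^score_", names(man), value = TRUE)) {
    s1 <- man[[sc]][match(paste(with_s2, 1L),
                          paste(man$subject_id, man$session_index))]
    s2 <- man[[sc]][match(paste(with_s2, 2L),
                          paste(man$subject_id, man$session_index))]
    if (all(is.finite(s1)) && all(is.finite(s2)))
      out[[sc]] <- unclass(intra_group_tests(s1, s2, with_s2))
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the `rehabdist` subcommands (`simulate`, `build-network`,
#' `select-features`, `train`, `loocv`, `permtest`, `cluster`,
#' `distance`, `stats`, `report`, `run-all`) over the package functions.
#' Invoked by the installed `cli/rehabdist.R` script; callable directly
#' for testing. Logs to stderr; writes machine-readable results to files
#' only. Any stage error exits nonzero (when not interactive) naming the
#' stage.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in the script).
#' @return exit status, invisibly (0 on success).
#' @export
rehabdist_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rehabdist <command> [options]",
    "commands: simulate build-network select-features train loocv",
    "          permtest cluster distance stats report run-all", sep = "\n")
  if (length(args) == 0L || args[1L] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1L]; rest <- args[-1L]
  status <- tryCatch({
    switch(cmd,
      "simulate" = .cli_simulate(rest),
      "build-network" = .cli_build_network(rest),
      "select-features" = .cli_select_features(rest),
      "train" = .cli_train(rest),
      "loocv" = .cli_loocv(rest),
      "permtest" = .cli_permtest(rest),
      "cluster" = .cli_cluster(rest),
      "distance" = .cli_distance(rest),
      "stats" = .cli_stats(rest),
      "report" = ,
      "run-all" = .cli_run_all(rest),
      stop("unknown command '", cmd, "'\n", usage))
    0L
  }, error = function(e) {
    message("[rehabdist] error in stage '", cmd, "': ",
            conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_opts <- function(args, spec) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command-line interface needs the 'optparse' package")
  opts <- lapply(spec, function(s)
    optparse::make_option(s$flag, type = s$type, default = s$default,
                          action = if (identical(s$type, "logical"))
                            "store_true" else "store",
                          help = s$help))
  optparse::parse_args(optparse::OptionParser(option_list = opts),
                       args = args)
}

.cli_simulate <- function(args) {
  o <- .cli_opts(args, list(
    list(flag = "--config", type = "character", default = NULL,
         help = "JSON with synthetic_cohort_config fields"),
    list(flag = "--seed", type = "integer", default = 1L, help = "seed"),
    list(flag = "--out", type = "character", default = "cohort",
         help = "output directory")))
  sim <- if (!is.null(o$config))
    jsonlite::read_json(o$config, simplifyVector = TRUE) else list()
  if (is.null(sim$seed)) sim$seed <- o$seed
  cohort <- simulate_cohort(do.call(synthetic_cohort_config, sim))
  p <- write_cohort(cohort, o$out)
  .log("cohort written; manifest at ", p)
}

.cli_build_network <- function(args) {
  o <- .cli_opts(args, list(
    list(flag = "--timeseries", type = "character", default = NULL,
         help = "ROI time-series table"),
    list(flag = "--out", type = "character", default = "network.csv",
         help = "output connectivity matrix"),
    list(flag = "--fisher-z", type = "logical", default = FALSE,
         help = "Fisher z-transform")))
  net <- pearson_connectivity(read_timeseries_csv(o$timeseries))
  if (isTRUE(o$`fisher-z`)) net <- fisher_z(net)
  write_network_csv(net, o$out)
  .log("network written to ", o$out)
}

.cli_cohort_opts <- function(args, extra = list()) {
  .cli_opts(args, c(list(
    list(flag = "--manifest", type = "character", default = NULL,
         help = "cohort manifest"),
    list(flag = "--alpha", type = "double", default = 0.05,
         help = "filter threshold"),
    list(flag = "--C", type = "double", default = 1, help = "SVM cost"),
    list(flag = "--nested", type = "logical", default = FALSE,
         help = "nested feature selection"),
    list(flag = "--welch", type = "logical", default = FALSE,
         help = "Welch filter t-test"),
    list(flag = "--fisher-z", type = "logical", default = FALSE,
         help = "Fisher z edges"),
    list(flag = "--out", type = "character", default = NULL,
         help = "output file")), extra))
}

.cli_load <- function(o) {
  if (is.null(o$manifest)) stop("--manifest is required")
  load_cohort(o$manifest, fisher = isTRUE(o$`fisher-z`))
}

.cli_mode <- function(o) if (isTRUE(o$nested)) "nested" else "paper"

.cli_select_features <- function(args) {
  o <- .cli_cohort_opts(args)
  cohort <- .cli_load(o)
  fs <- first_session_data(cohort)
  sig <- ttest_filter(fs$X[fs$y == -1, , drop = FALSE],
                      fs$X[fs$y == 1, , drop = FALSE],
                      alpha = o$alpha, var_equal = !isTRUE(o$welch))
  out <- if (is.null(o$out)) "sig_set.json" else o$out
  jsonlite::write_json(
    list(positions = sig$positions, pairs = sig$pairs, t = sig$t, p = sig$p,
         alpha = sig$alpha, n_edges = sig$n_edges),
    out, auto_unbox = TRUE, digits = NA)
  .log(length(sig$positions), " significant edges written to ", out)
}

.cli_train <- function(args) {
  o <- .cli_cohort_opts(args, list(
    list(flag = "--model", type = "character", default = "model.json",
         help = "output model bundle")))
  cohort <- .cli_load(o)
  fs <- first_session_data(cohort)
  m <- fit_discriminant(fs$X, fs$y, alpha = o$alpha, C = o$C,
                        var_equal = !isTRUE(o$welch))
  write_model(model_bundle(m$sig, m$hyperplane, cohort$region_labels),
              o$model)
  .log("model written to ", o$model)
}

.cli_loocv <- function(args) {
  o <- .cli_cohort_opts(args)
  cohort <- .cli_load(o)
  fs <- first_session_data(cohort)
  cv <- loocv_classify(fs$X, fs$y, alpha = o$alpha, C = o$C,
                       selection_mode = .cli_mode(o),
                       var_equal = !isTRUE(o$welch))
  out <- if (is.null(o$out)) "loocv.json" else o$out
  jsonlite::write_json(cv$metrics[c("TP", "FP", "FN", "TN", "accuracy",
                                    "precision", "sensitivity",
                                    "specificity")],
                       out, auto_unbox = TRUE, digits = NA)
  .log("LOOCV accuracy ", format(cv$metrics$accuracy), "; written to ", out)
}

.cli_permtest <- function(args) {
  o <- .cli_cohort_opts(args, list(
    list(flag = "--n-perm", type = "integer", default = 1000L,
         help = "number of permutations"),
    list(flag = "--seed", type = "integer", default = 1L, help = "seed")))
  cohort <- .cli_load(o)
  fs <- first_session_data(cohort)
  pt <- permutation_test(fs$X, fs$y, n_perm = o$`n-perm`, alpha = o$alpha,
                         C = o$C, seed = o$seed,
                         selection_mode = .cli_mode(o),
                         var_equal = !isTRUE(o$welch))
  out <- if (is.null(o$out)) "permtest.json" else o$out
  jsonlite::write_json(list(observed = pt$observed, p = pt$p,
                            n_perm = pt$n_perm, seed = pt$seed),
                       out, auto_unbox = TRUE, digits = NA)
  .log("permutation p = ", format(pt$p), "; written to ", out)
}

.cli_cluster <- function(args) {
  o <- .cli_cohort_opts(args, list(
    list(flag = "--restarts", type = "integer", default = 50L,
         help = "k-means restarts"),
    list(flag = "--seed", type = "integer", default = 1L, help = "seed")))
  cohort <- .cli_load(o)
  fs <- first_session_data(cohort)
  sig <- ttest_filter(fs$X[fs$y == -1, , drop = FALSE],
                      fs$X[fs$y == 1, , drop = FALSE],
                      alpha = o$alpha, var_equal = !isTRUE(o$welch))
  km <- kmeans_validation(extract_features(fs$X, sig), fs$y,
                          restarts = o$restarts, seed = o$seed)
  out <- if (is.null(o$out)) "cluster.json" else o$out
  jsonlite::write_json(list(accuracy = km$accuracy, n_errors = km$n_errors,
                            restarts = km$restarts, seed = km$seed),
                       out, auto_unbox = TRUE, digits = NA)
  .log("clustering accuracy ", format(km$accuracy), "; written to ", out)
}

.cli_distance <- function(args) {
  o <- .cli_cohort_opts(args, list(
    list(flag = "--model", type = "character", default = NULL,
         help = "model bundle JSON (single-network mode)"),
    list(flag = "--network", type = "character", default = NULL,
         help = "connectivity matrix to score (single-network mode)")))
  if (!is.null(o$model) && !is.null(o$network)) {
    bundle <- read_model(o$model)
    net <- read_network_csv(o$network)
    d <- signed_distance(extract_features(net, bundle$sig),
                         bundle$hyperplane)
    if (is.null(o$out)) cat(format(d, digits = 15), "\n")
    else jsonlite::write_json(list(distance = d), o$out,
                              auto_unbox = TRUE, digits = NA)
    .log("signed distance ", format(d))
    return(invisible(NULL))
  }
  cohort <- .cli_load(o)
  rec <- loocv_distance_protocol(cohort, alpha = o$alpha, C = o$C,
                                 selection_mode = .cli_mode(o),
                                 var_equal = !isTRUE(o$welch))
  out <- if (is.null(o$out)) "distance_records.tsv" else o$out
  .write_tsv(rec, out)
  .log(nrow(rec), " distance records written to ", out)
}

.cli_stats <- function(args) {
  o <- .cli_cohort_opts(args, list(
    list(flag = "--distances", type = "character", default = NULL,
         help = "distance_records.tsv from the distance command")))
  if (is.null(o$distances)) stop("--distances is required")
  if (is.null(o$manifest)) stop("--manifest is required")
  rec <- utils::read.table(o$distances, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  man <- read_manifest(o$manifest)
  st <- .paired_stats(rec, man)
  out <- if (is.null(o$out)) "stats.json" else o$out
  jsonlite::write_json(st, out, auto_unbox = TRUE, digits = NA, na = "null")
  .log("intra-group statistics written to ", out)
}

.cli_run_all <- function(args) {
  o <- .cli_opts(args, list(
    list(flag = "--config", type = "character", default = NULL,
         help = "run_config JSON"),
    list(flag = "--seed", type = "integer", default = NULL, help = "seed"),
    list(flag = "--out", type = "character", default = NULL,
         help = "output directory")))
  cfg <- if (!is.null(o$config)) read_run_config(o$config) else run_config()
  if (!is.null(o$seed)) cfg$seed <- as.integer(o$seed)
  if (!is.null(o$out)) cfg$out_dir <- o$out
  run_pipeline(cfg)
}
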