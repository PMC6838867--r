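#' Configuration for a synthetic connectome cohort
#'
#' Defines the study conditions the simulator emulates: a control group
#' and a patient group of functional-connectivity matrices whose edges are
#' correlation-like values, a fixed random subset of edges carrying a
#' group mean shift in patients (a group-level lesion signature), patient
#' follow-up sessions whose affected edges drift back toward the control
#' mean as recovery proceeds, and a clinical score that increases with
#' that recovery.
#'
#' Defaults follow the cohort this method was developed on: 22 healthy
#' controls and 18 patients, 82 regions (a Brodmann-scale parcellation,
#' 3321 edges), 7% of edges affected, a 1.5 pooled-SD edge shift, and a
#' two-session schedule in which half of the patient-specific offset is
#' removed at the second scan two weeks later. Five of the patients
#' receive two further sessions, emulating the longitudinal sub-study.
#'
#' @param n_controls,n_patients group sizes.
#' @param k number of regions.
#' @param affected_fraction fraction f of the k(k-1)/2 edges carrying the
#'   patient shift.
#' @param effect_size edge shift delta in units of the edge noise SD
#'   (approximately the pooled between-subject SD).
#' @param edge_sd between-subject SD of the latent edge value.
#' @param baseline_mean,baseline_sd distribution of per-edge latent
#'   baseline means (shared by both groups at unaffected edges).
#' @param drift recovery schedule lambda_s per session for ordinary
#'   patients: fraction of the session-1 offset removed at session s
#'   (lambda = 0 none, 1 full recovery to the control mean). Must start
#'   at 0.
#' @param n_long number of patients with the longer `long_drift` schedule.
#' @param long_drift recovery schedule for the `n_long` longitudinal
#'   patients.
#' @param weeks,long_weeks weeks since inclusion per session.
#' @param score_baseline_mean,score_baseline_sd,score_gain,score_noise_sd
#'   clinical score model s = s0 + gain * lambda_s + noise.
#' @param seed single RNG seed from which all randomness flows.
#' @return a list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_controls = 22, n_patients = 18, k = 82,
                                    affected_fraction = 0.07,
                                    effect_size = 1.5,
                                    edge_sd = 0.15,
                                    baseline_mean = 0.15, baseline_sd = 0.25,
                                    drift = c(0, 0.5),
                                    n_long = 5,
                                    long_drift = c(0, 0.5, 0.75, 0.9),
                                    weeks = c(0, 2),
                                    long_weeks = c(0, 2, 6, 14),
                                    score_baseline_mean = 32.6,
                                    score_baseline_sd = 8.4,
                                    score_gain = 9,
                                    score_noise_sd = 1,
                                    seed = 1L) {
  cfg <- list(n_controls = n_controls, n_patients = n_patients, k = k,
              affected_fraction = affected_fraction,
              effect_size = effect_size, edge_sd = edge_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              drift = drift, n_long = n_long, long_drift = long_drift,
              weeks = weeks, long_weeks = long_weeks,
              score_baseline_mean = score_baseline_mean,
              score_baseline_sd = score_baseline_sd,
              score_gain = score_gain, score_noise_sd = score_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname synthetic_cohort_config
#' @param cfg a config to validate.
#' @export
validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_controls < 2 || n_patients < 2) stop("need >= 2 subjects per group")
    if (k < 3) stop("'k' must be >= 3")
    if (affected_fraction < 0 || affected_fraction > 1)
      stop("'affected_fraction' must be in [0, 1]")
    if (floor(affected_fraction * n_edges(k)) < 1)
      stop("affected_fraction * k(k-1)/2 < 1: no affected edges")
    if (edge_sd <= 0) stop("'edge_sd' must be > 0")
    if (drift[1L] != 0) stop("drift schedule must start at 0 (session 1)")
    if (is.unsorted(drift) || is.unsorted(long_drift))
      stop("drift schedules must be non-decreasing (recovery scenario)")
    if (any(drift < 0 | drift > 1) || any(long_drift < 0 | long_drift > 1))
      stop("drift values must lie in [0, 1]")
    if (n_long > n_patients) stop("'n_long' exceeds 'n_patients'")
    if (length(weeks) != length(drift) ||
        length(long_weeks) != length(long_drift))
      stop("weeks and drift schedules must have equal lengths")
  })
  invisible(cfg)
}

#' Simulate a synthetic longitudinal connectome cohort
#'
#' Draws, per session, a latent Gaussian value for every upper-triangle
#' edge and squashes it through tanh so edges respect (-1, 1) without hard
#' clipping artifacts. Controls are scanned once. Patients carry a fixed
#' signed offset of `effect_size * edge_sd` at the affected edges at
#' session 1; at a later session with recovery fraction lambda the offset
#' is scaled by (1 - lambda), so lambda = 1 puts affected edges back on
#' the control mean. The clinical score increases linearly in lambda.
#' All randomness flows from `cfg$seed`; the same seed reproduces the
#' cohort exactly.
#'
#' @param cfg a `synthetic_cohort_config` (or arguments forwarded to one).
#' @param ... used to build a config when `cfg` is missing.
#' @return a list of class `synthetic_cohort`:
#'   \describe{
#'     \item{manifest}{session records (subject_id, group, group_label,
#'       session_index, weeks, score_motor, lambda)}
#'     \item{edges}{sessions x k(k-1)/2 matrix of tanh-squashed edge
#'       values, rows aligned with the manifest}
#'     \item{affected}{flat positions of the planted affected edges}
#'     \item{region_labels, config}{bookkeeping}
#'   }
#' @export
simulate_cohort <- function(cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- synthetic_cohort_config(...)
  if (!inherits(cfg, "synthetic_cohort_config"))
    stop("'cfg' must be a synthetic_cohort_config")
  validate_cohort_config(cfg)
  set.seed(cfg$seed)
  E <- n_edges(cfg$k)
  n_aff <- floor(cfg$affected_fraction * E)
  mu <- stats::rnorm(E, cfg$baseline_mean, cfg$baseline_sd)
  affected <- sort(sample.int(E, n_aff))
  signs <- sample(c(-1, 1), n_aff, replace = TRUE)
  offset <- numeric(E)
  offset[affected] <- signs * cfg$effect_size * cfg$edge_sd

  subjects <- list()
  ctrl_ids <- sprintf("HC%02d", seq_len(cfg$n_controls))
  pat_ids <- sprintf("SCI%02d", seq_len(cfg$n_patients))
  long_set <- if (cfg$n_long > 0)
    pat_ids[seq.int(cfg$n_patients - cfg$n_long + 1L, cfg$n_patients)]
  else character()

  rows <- list(); man <- list(); ri <- 0L
  add_session <- function(sid, grp, s_idx, wk, lambda, s0) {
    ri <<- ri + 1L
    shift <- if (grp == 1L) (1 - lambda) * offset else 0
    z <- mu + shift + stats::rnorm(E, 0, cfg$edge_sd)
    rows[[ri]] <<- tanh(z)
    score <- if (grp == 1L)
      s0 + cfg$score_gain * lambda + stats::rnorm(1, 0, cfg$score_noise_sd)
    else NA_real_
    man[[ri]] <<- data.frame(
      subject_id = sid, group = grp,
      group_label = if (grp == 1L) "patient" else "control",
      session_index = s_idx, weeks = wk, lambda = lambda,
      score_motor = score, stringsAsFactors = FALSE)
  }
  for (sid in ctrl_ids) add_session(sid, -1L, 1L, 0, 0, NA_real_)
  for (sid in pat_ids) {
    s0 <- stats::rnorm(1, cfg$score_baseline_mean, cfg$score_baseline_sd)
    lam <- if (sid %in% long_set) cfg$long_drift else cfg$drift
    wks <- if (sid %in% long_set) cfg$long_weeks else cfg$weeks
    for (s in seq_along(lam)) add_session(sid, 1L, s, wks[s], lam[s], s0)
  }
  manifest <- do.call(rbind, man)
  edges <- do.call(rbind, rows)
  rownames(edges) <- paste(manifest$subject_id, manifest$session_index,
                           sep = "_s")
  structure(list(manifest = manifest, edges = edges,
                 affected = affected,
                 region_labels = as.character(seq_len(cfg$k)),
                 config = cfg),
            class = "synthetic_cohort")
}

#' First-session training data of a cohort
#'
#' @param cohort a `synthetic_cohort` or `rehab_cohort`.
#' @return list with `X` (first-session edge matrix, controls and
#'   patients), `y` (labels +1/-1), `subject_id`.
#' @export
first_session_data <- function(cohort) {
  man <- cohort$manifest
  sel <- man$session_index == 1L
  list(X = cohort$edges[sel, , drop = FALSE],
       y = man$group[sel],
       subject_id = man$subject_id[sel])
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  man <- x$manifest
  cat("synthetic_cohort: ", sum(man$group == -1L), " controls, ",
      length(unique(man$subject_id[man$group == 1L])), " patients, ",
      x$config$k, " regions, ", length(x$affected), " affected edges, ",
      nrow(man), " sessions (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in the cohort-io formats
#'
#' Emits one labeled connectivity-matrix CSV per session plus a manifest,
#' exactly the files [load_cohort()] reads — the simulator and the reader
#' round-trip through the same on-disk contract.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$data_path <- paste0(rownames(cohort$edges), ".csv")
  for (r in seq_len(nrow(man))) {
    net <- devectorize_edges(cohort$edges[r, ], cohort$region_labels)
    write_network_csv(net, file.path(dir, man$data_path[r]))
  }
  out <- man
  names(out)[names(out) == "score_motor"] <- "score_motor"
  path <- file.path(dir, "manifest.csv")
  write_manifest(out, path)
  invisible(path)
}

#' Simulate ROI time series realizing a target correlation matrix
#'
#' Secondary, slower generator path: draws T multivariate-Gaussian
#' timepoints whose population correlation is the target, so the sample
#' correlation converges to the target as T grows. A target that is not
#' positive semi-definite is repaired to the nearest correlation matrix
#' first.
#'
#' @param target k x k target correlation matrix (symmetric, unit
#'   diagonal).
#' @param n_timepoints number of timepoints T (>= 3).
#' @param seed RNG seed.
#' @return an `roi_timeseries`.
#' @export
simulate_timeseries <- function(target, n_timepoints = 240, seed = 1L) {
  target <- as.matrix(target)
  k <- nrow(target)
  if (ncol(target) != k) stop("'target' must be square")
  if (max(abs(target - t(target))) > 1e-8) stop("'target' must be symmetric")
  if (max(abs(diag(target) - 1)) > 1e-8) stop("'target' must have unit diagonal")
  if (n_timepoints < 3) stop("need at least 3 timepoints")
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    rep <- try(as.matrix(Matrix::nearPD(target, corr = TRUE)$mat),
               silent = TRUE)
    if (inherits(rep, "try-error"))
      stop("target correlation matrix is not PSD and nearest-PD repair failed")
    target <- rep
  }
  set.seed(seed)
  ts <- MASS::mvrnorm(n_timepoints, mu = rep(0, k), Sigma = target)
  roi_timeseries(ts, region_labels = as.character(seq_len(k)))
}
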