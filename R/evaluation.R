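#' Classification metrics from a confusion table
#'
#' Patients are the positive class (+1). TP = patients classified as
#' patients, FP = controls classified as patients, FN = patients
#' classified as controls, TN = controls classified as controls;
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param truth,pred vectors in \{+1, -1\}.
#' @return list of class `confusion_metrics` with the four counts and
#'   four proportions.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(-1L, 1L)), all(pred %in% c(-1L, 1L)))
  TP <- sum(truth == 1L & pred == 1L)
  FP <- sum(truth == -1L & pred == 1L)
  FN <- sum(truth == 1L & pred == -1L)
  TN <- sum(truth == -1L & pred == -1L)
  n <- TP + FP + FN + TN
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN, n = n,
    accuracy = (TP + TN) / n,
    precision = if (TP + FP > 0) TP / (TP + FP) else NaN,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NaN,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NaN),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "confusion_metrics (n = %d): TP %d FP %d FN %d TN %d\n  accuracy %.4f  precision %.4f  sensitivity %.4f  specificity %.4f\n",
    x$n, x$TP, x$FP, x$FN, x$TN,
    x$accuracy, x$precision, x$sensitivity, x$specificity))
  invisible(x)
}

#' Fit the full discriminant model on labeled first-session data
#'
#' Runs the t-test filter then trains the linear SVM on the retained
#' edges — the model used for second-session testing and for scoring new
#' sessions outside a cross-validation fold.
#'
#' @param X sessions x edges matrix of first-session edge vectors.
#' @param y labels in \{+1, -1\}.
#' @param alpha filter threshold; @param C SVM cost;
#' @param var_equal pooled (TRUE) or Welch t-test.
#' @return list of class `rehab_model` with `sig` and `hyperplane`.
#' @export
fit_discriminant <- function(X, y, alpha = 0.05, C = 1, var_equal = TRUE) {
  X <- .as_edge_matrix(X)
  sig <- ttest_filter(X[y == -1, , drop = FALSE], X[y == 1, , drop = FALSE],
                      alpha = alpha, var_equal = var_equal)
  hp <- train_linear_svm(extract_features(X, sig), y, C = C)
  structure(list(sig = sig, hyperplane = hp, alpha = alpha, C = C),
            class = "rehab_model")
}

# internal LOOCV engine over an edge matrix; returns per-fold predictions
# and decisions. on_empty: behavior when a fold's (or the shared)
# significant set is empty — "error", or "majority" (predict the training
# majority class, used inside the permutation null where an empty set can
# occur by chance).
.loocv_predict <- function(X, y, alpha, C, selection_mode, var_equal,
                           on_empty = "error") {
  n <- nrow(X)
  sig_all <- NULL
  Xsel <- NULL
  if (selection_mode == "paper") {
    sig_all <- suppressWarnings(
      ttest_filter(X[y == -1, , drop = FALSE], X[y == 1, , drop = FALSE],
                   alpha = alpha, var_equal = var_equal))
    if (length(sig_all$positions) == 0L && on_empty != "majority")
      stop("empty significant set in LOOCV; refusing to train on zero ",
           "features")
    Xsel <- X[, sig_all$positions, drop = FALSE]
  }
  pred <- integer(n); dec <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop("LOOCV fold ", i, " lost an entire class")
    if (selection_mode == "paper") {
      if (ncol(Xsel) == 0L) {
        maj <- if (sum(ytr == 1L) >= sum(ytr == -1L)) 1L else -1L
        pred[i] <- maj; dec[i] <- NA_real_
        next
      }
      Xtr <- Xsel[-i, , drop = FALSE]
      xte <- Xsel[i, ]
    } else {
      Xfold <- X[-i, , drop = FALSE]
      sig <- suppressWarnings(
        ttest_filter(Xfold[ytr == -1, , drop = FALSE],
                     Xfold[ytr == 1, , drop = FALSE],
                     alpha = alpha, var_equal = var_equal))
      if (length(sig$positions) == 0L) {
        if (on_empty == "majority") {
          maj <- if (sum(ytr == 1L) >= sum(ytr == -1L)) 1L else -1L
          pred[i] <- maj; dec[i] <- NA_real_
          next
        }
        stop("empty significant set in LOOCV; refusing to train on zero ",
             "features")
      }
      Xtr <- Xfold[, sig$positions, drop = FALSE]
      xte <- X[i, sig$positions]
    }
    hp <- train_linear_svm(Xtr, ytr, C = C)
    h <- decision_value(xte, hp)
    pred[i] <- if (h > 0) 1L else -1L
    dec[i] <- h
  }
  list(pred = pred, decision = dec, sig = sig_all)
}

#' Leave-one-out cross-validated classification of a cohort
#'
#' Each first-session sample is predicted exactly once by an SVM trained
#' on all the others. Two feature-selection protocols are available:
#' `"paper"` fits the t-test filter once on the full labeled first-session
#' data (the protocol the headline accuracies use — note that the filter
#' then sees every label, including the held-out one, so the estimate is
#' optimistic), and `"nested"` refits the filter inside each fold on the
#' training samples only, the statistically sound protocol.
#'
#' @param x a cohort (`synthetic_cohort`/`rehab_cohort`) or a sessions x
#'   edges matrix of first-session edge vectors.
#' @param labels labels in \{+1, -1\}; taken from the cohort when `x` is
#'   one.
#' @param alpha filter threshold; @param C SVM cost.
#' @param selection_mode `"paper"` (default) or `"nested"`.
#' @param var_equal pooled (TRUE) or Welch filter t-test.
#' @return list of class `loocv_result`: `metrics` (a
#'   `confusion_metrics`), `predictions` (data frame with truth,
#'   prediction and decision value per left-out sample), `sig` (the
#'   shared significant set in paper mode), `selection_mode`, `alpha`,
#'   `C`.
#' @export
loocv_classify <- function(x, labels = NULL, alpha = 0.05, C = 1,
                           selection_mode = c("paper", "nested"),
                           var_equal = TRUE) {
  selection_mode <- match.arg(selection_mode)
  if (inherits(x, c("synthetic_cohort", "rehab_cohort"))) {
    fs <- first_session_data(x)
    X <- fs$X; labels <- fs$y; ids <- fs$subject_id
  } else {
    X <- .as_edge_matrix(x); ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  y <- as.integer(labels)
  if (min(sum(y == 1L), sum(y == -1L)) < 2L)
    stop("need at least 2 samples per class for LOOCV")
  res <- .loocv_predict(X, y, alpha, C, selection_mode, var_equal)
  structure(list(
    metrics = confusion_metrics(y, res$pred),
    predictions = data.frame(subject_id = ids, truth = y, pred = res$pred,
                             decision = res$decision,
                             stringsAsFactors = FALSE),
    sig = res$sig, selection_mode = selection_mode,
    alpha = alpha, C = C), class = "loocv_result")
}

#' Classification accuracy on second-session patient data
#'
#' Feeds follow-up (session 2) networks into a trained classifier. Only
#' patients have a second session in this design, so every true label is
#' +1 and the accuracy equals the sensitivity on these sessions; a drop
#' relative to session 1 is expected under recovery, since follow-up
#' feature vectors move toward the controls.
#'
#' @param model a `rehab_model` from [fit_discriminant()], or a cohort
#'   (`synthetic_cohort`/`rehab_cohort`), in which case the model is fit
#'   on its first sessions.
#' @param second_edges sessions x edges matrix of second-session edge
#'   vectors; taken from the cohort when `model` is one.
#' @param alpha,C,var_equal model settings used when fitting from a
#'   cohort.
#' @return fraction of second-session vectors predicted +1.
#' @export
second_session_test <- function(model, second_edges = NULL, alpha = 0.05,
                                C = 1, var_equal = TRUE) {
  if (inherits(model, c("synthetic_cohort", "rehab_cohort"))) {
    cohort <- model
    fs <- first_session_data(cohort)
    sel <- cohort$manifest$session_index == 2L
    second_edges <- cohort$edges[sel, , drop = FALSE]
    model <- fit_discriminant(fs$X, fs$y, alpha = alpha, C = C,
                              var_equal = var_equal)
  }
  stopifnot(inherits(model, "rehab_model"))
  second_edges <- .as_edge_matrix(second_edges)
  if (nrow(second_edges) == 0L) stop("no second-session data supplied")
  pred <- predict_label(extract_features(second_edges, model$sig),
                        model$hyperplane)
  mean(pred == 1L)
}

#' Label-permutation significance of the LOOCV accuracy
#'
#' Re-runs the full pipeline (t-test filter, refit per permutation by
#' default, then LOOCV) on randomly permuted labels and reports the
#' empirical p-value p = (1 + #\{permuted accuracy >= observed\}) /
#' (n_perm + 1), which can never be 0 and reports at minimum 1/(n_perm+1)
#' ("< 0.001" at 1,000 permutations).
#'
#' @inheritParams loocv_classify
#' @param n_perm number of label permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param refit_filter refit the t-test filter on the permuted labels
#'   (default TRUE; keeping the original filter would leak true-label
#'   structure into the null).
#' @return list of class `permutation_result`: `observed`, `permuted`
#'   (length `n_perm`), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, labels = NULL, n_perm = 1000, alpha = 0.05,
                             C = 1, seed = 1L,
                             selection_mode = c("paper", "nested"),
                             var_equal = TRUE, refit_filter = TRUE) {
  selection_mode <- match.arg(selection_mode)
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (inherits(x, c("synthetic_cohort", "rehab_cohort"))) {
    fs <- first_session_data(x)
    X <- fs$X; labels <- fs$y
  } else X <- .as_edge_matrix(x)
  y <- as.integer(labels)
  obs <- mean(.loocv_predict(X, y, alpha, C, selection_mode,
                             var_equal)$pred == y)
  Xf <- NULL
  if (!refit_filter) {
    sig_fixed <- ttest_filter(X[y == -1, , drop = FALSE],
                              X[y == 1, , drop = FALSE],
                              alpha = alpha, var_equal = var_equal)
    Xf <- suppressWarnings(extract_features(X, sig_fixed))
  }
  set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yb <- sample(y)
    acc <- if (refit_filter) {
      r <- suppressWarnings(
        .loocv_predict(X, yb, alpha, C, selection_mode, var_equal,
                       on_empty = "majority"))
      mean(r$pred == yb)
    } else {
      r <- .loocv_predict(Xf, yb, alpha = 1, C = C,
                          selection_mode = "paper", var_equal = var_equal,
                          on_empty = "majority")
      mean(r$pred == yb)
    }
    perm[b] <- acc
  }
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  structure(list(observed = obs, permuted = perm, p = p,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  plab <- if (x$p <= 1 / (x$n_perm + 1) + 1e-12)
    paste0("< ", format(1 / x$n_perm)) else format(x$p, digits = 3)
  cat(sprintf("permutation_result: observed accuracy %.4f, p %s (%d permutations)\n",
              x$observed, plab, x$n_perm))
  invisible(x)
}

#' Two-means clustering check of the selected feature space
#'
#' Clusters the selected feature vectors without labels (k-means,
#' squared-Euclidean, `restarts` random initializations from a seeded
#' RNG, best within-cluster sum of squares kept, inertia ties broken by
#' the lowest restart index) and reports how well the unsupervised
#' partition matches the patient/control split: the accuracy is the best
#' matched fraction over the two cluster-to-class assignments, and the
#' error count is n (1 - accuracy).
#'
#' @param features samples x features matrix (significant-edge vectors).
#' @param labels true labels in \{+1, -1\}.
#' @param k number of clusters (2).
#' @param restarts random initializations (default 50).
#' @param seed RNG seed.
#' @return list of class `kmeans_validation`: `accuracy`, `n_errors`,
#'   `cluster` assignments, `inertia`, `restart` (winning index).
#' @export
kmeans_validation <- function(features, labels, k = 2, restarts = 50,
                              seed = 1L) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (k != 2) stop("the clustering check is defined for k = 2")
  if (nrow(X) < k) stop("more clusters than samples")
  set.seed(seed)
  best <- NULL; best_w <- Inf; best_r <- NA_integer_
  for (r in seq_len(restarts)) {
    km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 1))
    if (km$tot.withinss < best_w - 1e-12) {
      best <- km; best_w <- km$tot.withinss; best_r <- r
    }
  }
  cl <- best$cluster
  acc1 <- mean((cl == 1L) == (y == 1L))
  acc <- max(acc1, 1 - acc1)
  structure(list(accuracy = acc,
                 n_errors = as.integer(round(length(y) * (1 - acc))),
                 cluster = cl, inertia = best_w, restart = best_r,
                 restarts = restarts, seed = seed),
            class = "kmeans_validation")
}

#' LOOCV signed-distance protocol over all sessions
#'
#' For every subject, a model is trained with that subject held out of
#' the first-session training data (filter per `selection_mode`, then the
#' SVM), and all of the held-out subject's sessions — the single control
#' scan, or every patient follow-up — are scored by that fold's signed
#' distance. Each session of each subject thus receives exactly one d,
#' from a model never trained on that subject.
#'
#' @param cohort a `synthetic_cohort` or `rehab_cohort` whose manifest
#'   covers all sessions.
#' @inheritParams loocv_classify
#' @return data frame of distance records: `subject_id`, `group`,
#'   `session_index`, `weeks`, `distance`, `decision`, `fold`.
#' @export
loocv_distance_protocol <- function(cohort, alpha = 0.05, C = 1,
                                    selection_mode = c("paper", "nested"),
                                    var_equal = TRUE) {
  selection_mode <- match.arg(selection_mode)
  man <- cohort$manifest
  X <- cohort$edges
  subs <- unique(man$subject_id)
  has_s1 <- vapply(subs, function(s)
    any(man$subject_id == s & man$session_index == 1L), logical(1))
  if (!all(has_s1))
    stop("subject(s) missing session 1: ",
         paste(subs[!has_s1], collapse = ", "))
  first <- man$session_index == 1L
  sig_all <- NULL
  if (selection_mode == "paper") {
    y1 <- man$group[first]
    X1 <- X[first, , drop = FALSE]
    sig_all <- ttest_filter(X1[y1 == -1, , drop = FALSE],
                            X1[y1 == 1, , drop = FALSE],
                            alpha = alpha, var_equal = var_equal)
  }
  out <- vector("list", length(subs))
  for (si in seq_along(subs)) {
    s <- subs[si]
    tr <- first & man$subject_id != s
    ytr <- man$group[tr]
    if (length(unique(ytr)) < 2L)
      stop("fold for subject ", s, " lost an entire class")
    Xtr <- X[tr, , drop = FALSE]
    sig <- if (selection_mode == "paper") sig_all
           else ttest_filter(Xtr[ytr == -1, , drop = FALSE],
                             Xtr[ytr == 1, , drop = FALSE],
                             alpha = alpha, var_equal = var_equal)
    hp <- train_linear_svm(extract_features(Xtr, sig), ytr, C = C)
    rows <- which(man$subject_id == s)
    feats <- extract_features(X[rows, , drop = FALSE], sig)
    d <- signed_distance(feats, hp)
    h <- decision_value(feats, hp)
    out[[si]] <- data.frame(
      subject_id = s, group = man$group[rows],
      session_index = man$session_index[rows],
      weeks = if ("weeks" %in% names(man)) man$weeks[rows] else NA_real_,
      distance = d, decision = h, fold = s, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# smaller signed-rank sum, the Wilcoxon statistic convention used in the
# clinical tables (0 when all differences share one sign); zero
# differences are dropped before ranking
.wilcoxon_min_sum <- function(diff) {
  d <- diff[diff != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero: Wilcoxon signed-rank undefined")
  r <- rank(abs(d))
  min(sum(r[d > 0]), sum(r[d < 0]))
}

#' Paired first-vs-second-session statistics for the patient group
#'
#' The intra-group analysis of the recovery signal: for a paired variable
#' (signed distance, or a clinical score) measured at sessions 1 and 2 of
#' the same patients, reports Shapiro normality per session, the
#' two-sided paired t-test on first minus second, the Wilcoxon
#' signed-rank test on the same pairs (statistic = smaller signed-rank
#' sum; zero differences dropped; exact p for n <= 25 without ties), and
#' per-session mean ± sample SD.
#'
#' @param first,second numeric vectors, same subjects in the same order.
#' @param subject_id optional ids carried through for reporting.
#' @return list of class `group_stats`: `n`, `mean`, `sd`, `shapiro_p`
#'   (each length 2, sessions 1 and 2), `t`, `t_p`, `mean_difference`
#'   (first minus second), `wilcoxon`, `wilcoxon_p`.
#' @export
intra_group_tests <- function(first, second, subject_id = NULL) {
  first <- as.numeric(first); second <- as.numeric(second)
  if (length(first) != length(second))
    stop("paired tests need the same subjects in both sessions")
  n <- length(first)
  if (n < 3L) stop("need at least 3 paired subjects")
  diff <- first - second
  if (stats::sd(diff) == 0) {
    # constant differences: the t statistic degenerates; nonzero constant
    # shifts are (sign) infinitely significant
    tt <- list(statistic = if (mean(diff) == 0) 0 else sign(mean(diff)) * Inf,
               p.value = if (mean(diff) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(first, second, paired = TRUE)
  }
  wstat <- .wilcoxon_min_sum(diff)
  wp <- suppressWarnings(
    stats::wilcox.test(first, second, paired = TRUE,
                       exact = (n <= 25))$p.value)
  structure(list(
    n = n,
    subject_id = subject_id,
    mean = c(session1 = mean(first), session2 = mean(second)),
    sd = c(session1 = stats::sd(first), session2 = stats::sd(second)),
    shapiro_p = c(session1 = stats::shapiro.test(first)$p.value,
                  session2 = stats::shapiro.test(second)$p.value),
    t = unname(tt$statistic), t_p = tt$p.value,
    mean_difference = mean(diff),
    wilcoxon = wstat, wilcoxon_p = wp),
    class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf(
    paste0("group_stats (n = %d, first minus second)\n",
           "  session 1: %.3f +/- %.3f   session 2: %.3f +/- %.3f\n",
           "  paired t = %.3f, p = %.4g;  Wilcoxon stat = %g, p = %.4g\n",
           "  Shapiro p: %.3f / %.3f\n"),
    x$n, x$mean[1], x$sd[1], x$mean[2], x$sd[2],
    x$t, x$t_p, x$wilcoxon, x$wilcoxon_p,
    x$shapiro_p[1], x$shapiro_p[2]))
  invisible(x)
}

#' Normalized longitudinal trajectories of distance and scores
#'
#' For each subject with at least `min_sessions` sessions, standardizes
#' the signed distances within subject with a sign flip (so an increase
#' means improvement) and each clinical score without flipping, putting
#' both modalities on a common zero-mean unit-variance scale for
#' trajectory comparison.
#'
#' @param distance_records data frame from [loocv_distance_protocol()].
#' @param manifest cohort manifest carrying `score_*` columns.
#' @param min_sessions minimum sessions for a trajectory (default 3).
#' @param sd_type passed to [normalize_trajectory()].
#' @return tidy data frame: `subject_id`, `session_index`, `weeks`,
#'   `distance`, `distance_norm`, and one `<score>_norm` column per
#'   score.
#' @export
distance_trajectories <- function(distance_records, manifest,
                                  min_sessions = 3, sd_type = "sample") {
  score_cols <- grep("^score_", names(manifest), value = TRUE)
  subs <- unique(distance_records$subject_id)
  out <- list()
  for (s in subs) {
    dr <- distance_records[distance_records$subject_id == s, , drop = FALSE]
    dr <- dr[order(dr$session_index), , drop = FALSE]
    if (nrow(dr) < min_sessions) next
    row <- data.frame(subject_id = s, session_index = dr$session_index,
                      weeks = dr$weeks, distance = dr$distance,
                      distance_norm = normalize_trajectory(
                        dr$distance, "distance", sd_type),
                      stringsAsFactors = FALSE)
    for (sc in score_cols) {
      v <- manifest[[sc]][match(paste(s, dr$session_index),
                                paste(manifest$subject_id,
                                      manifest$session_index))]
      row[[paste0(sc, "_norm")]] <-
        if (all(is.finite(v))) normalize_trajectory(v, "score", sd_type)
        else NA_real_
    }
    out[[s]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
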