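#' Mass-univariate two-sample t-test edge filter
#'
#' Screens every edge with a two-tailed two-sample t-test between the
#' control and patient groups and retains edges with p below `alpha`,
#' uncorrected for multiple comparisons — the deliberate choice of this
#' method, which aims to keep as many potentially discriminative
#' connections as possible rather than a corrected subset. Retained edge
#' positions form the significant set used to build feature vectors.
#'
#' @param controls numeric matrix (subjects x edges) of control edge
#'   vectors, or a list of equal-length numeric vectors.
#' @param patients same, for patients.
#' @param alpha significance threshold (default 0.05).
#' @param var_equal pooled-variance t-test when TRUE (default); Welch
#'   otherwise.
#' @return An object of class `significant_set`: list with integer
#'   `positions` (strictly increasing flat edge positions), `pairs`
#'   ((i, j) node pairs when the edge count is triangular), `t` and `p`
#'   for retained edges, `alpha`, `var_equal`, `n_edges`.
#' @details Edges with zero pooled variance have an undefined t statistic
#'   and are skipped with a warning rather than treated as infinitely
#'   significant. Both groups must have at least 2 samples. The filter is
#'   fully deterministic.
#' @export
ttest_filter <- function(controls, patients, alpha = 0.05, var_equal = TRUE) {
  Xc <- .as_edge_matrix(controls)
  Xp <- .as_edge_matrix(patients)
  if (ncol(Xc) != ncol(Xp))
    stop("control and patient edge vectors have different lengths")
  if (nrow(Xc) < 2L || nrow(Xp) < 2L)
    stop("each group needs at least 2 samples for the t-test filter")
  if (!(alpha > 0 && alpha <= 1)) stop("'alpha' must be in (0, 1]")
  st <- .edge_tstats(Xc, Xp, var_equal = var_equal)
  undef <- !is.finite(st$t)
  if (any(undef))
    warning(sum(undef), " edge(s) with zero variance in both groups ",
            "skipped (t undefined)")
  keep <- which(!undef & st$p < alpha)
  E <- ncol(Xc)
  pairs <- NULL
  ktry <- try(nodes_from_edges(E), silent = TRUE)
  if (!inherits(ktry, "try-error")) pairs <- edge_index(ktry)[keep, , drop = FALSE]
  structure(
    list(positions = as.integer(keep), pairs = pairs,
         t = st$t[keep], p = st$p[keep],
         alpha = alpha, var_equal = var_equal, n_edges = E),
    class = "significant_set")
}

# vectorized two-sample t over edge columns; returns t and two-sided p
.edge_tstats <- function(Xc, Xp, var_equal = TRUE) {
  n1 <- nrow(Xc); n2 <- nrow(Xp)
  m1 <- colMeans(Xc); m2 <- colMeans(Xp)
  v1 <- colSums(sweep(Xc, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(Xp, 2L, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se            # patient minus control
  t[se == 0] <- NaN
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p)
}

.as_edge_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' @export
print.significant_set <- function(x, ...) {
  cat("significant_set: ", length(x$positions), " of ", x$n_edges,
      " edges at alpha = ", x$alpha,
      if (!x$var_equal) " (Welch)", "\n", sep = "")
  invisible(x)
}

#' Extract the significant-edge feature vector of a session
#'
#' Pulls the edge values at the significant-set positions out of one
#' network (or flat edge vector), producing the feature vector v used for
#' SVM training and distance scoring. The same positions are applied
#' unchanged to follow-up sessions, so longitudinal vectors live in the
#' same feature space as the training data.
#'
#' @param x a `connectivity_network`, or a flat edge vector of length
#'   matching `sig$n_edges`, or a matrix of edge vectors (rows = sessions).
#' @param sig a `significant_set`.
#' @return numeric feature vector of length `length(sig$positions)` (or a
#'   matrix with that many columns when `x` is a matrix). An empty
#'   significant set yields a length-0 vector with a warning.
#' @export
extract_features <- function(x, sig) {
  stopifnot(inherits(sig, "significant_set"))
  if (length(sig$positions) == 0L)
    warning("significant set is empty; returning a length-0 feature vector")
  if (inherits(x, "connectivity_network")) x <- vectorize_edges(x)
  if (is.matrix(x)) {
    if (ncol(x) != sig$n_edges)
      stop("edge matrix has ", ncol(x), " columns; significant set was ",
           "built on ", sig$n_edges, " edges (region mismatch)")
    return(x[, sig$positions, drop = FALSE])
  }
  if (length(x) != sig$n_edges)
    stop("edge vector has length ", length(x), "; significant set was ",
         "built on ", sig$n_edges, " edges (region mismatch)")
  unname(x[sig$positions])
}

#' Train the soft-margin linear SVM separating patients from controls
#'
#' Solves the primal problem min_(w,b) 1/2 ||w||^2 + C sum_i xi_i subject
#' to y_i (w'v_i + b) >= 1 - xi_i, xi_i >= 0, with patients labeled +1 and
#' healthy controls -1, via the exact dual solver in \pkg{e1071} (libsvm)
#' with a tight tolerance. The returned hyperplane is oriented so the
#' decision value h(v) = w'v + b is positive on the patient side.
#'
#' @param features numeric matrix (samples x features) of significant-edge
#'   feature vectors.
#' @param labels vector in \{+1, -1\} (+1 = patient); both classes required.
#' @param C soft-margin cost, > 0 (default 1, the setting all headline
#'   results use).
#' @param tolerance dual optimizer termination tolerance.
#' @return An object of class `rehab_hyperplane`: list with `w` (weight
#'   vector), `b` (bias), `C`, `xi` (training slacks max(0, 1 - y h)),
#'   `objective` (primal objective at the solution), `n_support`, and
#'   `labels` convention.
#' @export
train_linear_svm <- function(features, labels, C = 1, tolerance = 1e-8) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  if (nrow(X) != length(y)) stop("features and labels disagree in length")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 (patient) or -1 (control)")
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; cannot fit a separating ",
         "hyperplane")
  if (!(is.numeric(C) && length(C) == 1L && C > 0)) stop("'C' must be > 0")
  if (ncol(X) == 0L)
    stop("empty feature set: the significant set has no edges; refusing ",
         "to train on zero features")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance, fitted = FALSE,
                    na.action = stats::na.fail)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients its decision value toward the class it saw first
  # (fit$labels[1]); flip so that h > 0 always means +1 (patient)
  if (fit$levels[fit$labels[1L]] == "-1") {
    w <- -w; b <- -b
  }
  h <- drop(X %*% w) + b
  xi <- pmax(0, 1 - y * h)
  structure(
    list(w = unname(w), b = unname(b), C = C,
         xi = xi, objective = 0.5 * sum(w^2) + C * sum(xi),
         n_support = nrow(fit$SV),
         labels = c(patient = 1, control = -1)),
    class = "rehab_hyperplane")
}

#' @export
print.rehab_hyperplane <- function(x, ...) {
  cat("rehab_hyperplane: ", length(x$w), " features, C = ", x$C,
      ", ||w|| = ", format(sqrt(sum(x$w^2)), digits = 4),
      ", ", x$n_support, " support vectors\n", sep = "")
  invisible(x)
}

#' Decision value h(v) = w'v + b
#' @param v feature vector or matrix (rows = samples).
#' @param hyperplane a `rehab_hyperplane`.
#' @return numeric decision value(s).
#' @export
decision_value <- function(v, hyperplane) {
  stopifnot(inherits(hyperplane, "rehab_hyperplane"))
  w <- hyperplane$w
  if (is.matrix(v)) {
    if (ncol(v) != length(w))
      stop("feature dimension ", ncol(v), " does not match model (",
           length(w), ")")
    return(drop(v %*% w) + hyperplane$b)
  }
  if (length(v) != length(w))
    stop("feature dimension ", length(v), " does not match model (",
         length(w), ")")
  sum(w * v) + hyperplane$b
}

#' Predict the class label of feature vectors
#'
#' y = sgn(w'v + b); a decision value of exactly 0 is resolved to -1
#' (control), a documented boundary convention for a measure-zero event.
#'
#' @inheritParams decision_value
#' @return integer vector in \{+1, -1\}.
#' @export
predict_label <- function(v, hyperplane) {
  h <- decision_value(v, hyperplane)
  ifelse(h > 0, 1L, -1L)
}

#' Signed L2 distance to the separating hyperplane
#'
#' d = (w'v + b) / ||w||_2, the method's outcome measure. Positive d means
#' the sample lies on the patient side of the hyperplane; a decrease over
#' sessions means the session's connectivity pattern has moved toward the
#' healthy controls — the recovery signal.
#'
#' @inheritParams decision_value
#' @return numeric signed distance(s), in feature-space units.
#' @export
signed_distance <- function(v, hyperplane) {
  nw <- sqrt(sum(hyperplane$w^2))
  if (nw == 0) stop("zero weight vector: distance undefined")
  decision_value(v, hyperplane) / nw
}

#' Primal soft-margin SVM objective at a candidate (w, b)
#'
#' Evaluates 1/2 ||w||^2 + C sum_i max(0, 1 - y_i (w'x_i + b)). Used to
#' compare solutions from different solvers.
#'
#' @param w weight vector; @param b bias; @param X sample matrix;
#' @param y labels in \{+1, -1\}; @param C cost.
#' @return the primal objective value.
#' @export
svm_primal_objective <- function(w, b, X, y, C) {
  h <- drop(as.matrix(X) %*% w) + b
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * h))
}

#' Normalize a per-session trajectory for cross-modality comparison
#'
#' Standardizes a within-subject series of session values to zero mean and
#' unit variance. Distances are additionally sign-flipped
#' (d* = -(d - mean(d)) / sd(d)) so that an increase in normalized
#' distance means an improvement, aligning with clinical scores, which are
#' standardized without flipping (s* = (s - mean(s)) / sd(s)).
#'
#' @param values numeric vector of per-session values (>= 2 sessions,
#'   nonconstant).
#' @param kind `"distance"` (flipped) or `"score"` (not flipped).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n denominator).
#' @return normalized numeric vector with mean 0.
#' @export
normalize_trajectory <- function(values, kind = c("distance", "score"),
                                 sd_type = c("sample", "population")) {
  kind <- match.arg(kind)
  sd_type <- match.arg(sd_type)
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need at least 2 sessions to normalize")
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0)
    stop("constant trajectory: standard deviation is zero")
  z <- (x - mean(x)) / s
  if (kind == "distance") -z else z
}
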