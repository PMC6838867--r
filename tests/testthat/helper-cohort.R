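# Shared fixtures: all built in code, seeded.

# small, fast synthetic cohort for unit tests (20 nodes -> 190 edges)
small_cohort <- function(seed = 1, ...) {
  args <- list(n_controls = 8, n_patients = 6, k = 20,
               affected_fraction = 0.1, effect_size = 2,
               n_long = 2, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_cohort(do.call(synthetic_cohort_config, args))
}

# two well-separated Gaussian blobs in `p` dimensions
blob_data <- function(n_per = 10, p = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per) - sep / 2,
             matrix(rnorm(n_per * p), n_per) + sep / 2)
  list(X = X, y = rep(c(-1, 1), each = n_per))
}

# Independent oracle for the soft-margin linear SVM: solves the dual
#   min 1/2 a' Q a - 1'a   s.t. y'a = 0, 0 <= a <= C,   Q = (y y') * (X X')
# with kernlab's generic interior-point QP solver, then recovers (w, b).
# Entirely separate code path from the libsvm fit under test.
svm_qp_oracle <- function(X, y, C) {
  stopifnot(requireNamespace("kernlab", quietly = TRUE))
  X <- as.matrix(X); y <- as.numeric(y); n <- nrow(X)
  Q <- (y %*% t(y)) * (X %*% t(X))
  # Q has rank <= ncol(X); a small ridge keeps the interior-point
  # iterations non-singular without moving the solution at 1e-6
  Q <- Q + diag(1e-8, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q,
                       A = matrix(y, nrow = 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = 9, maxiter = 200)
  a <- kernlab::primal(sol)
  w <- drop(t(X) %*% (a * y))
  # bias by exact 1-D minimization of the primal over b given w: the
  # hinge sum is piecewise linear in b, so the minimum sits at a kink
  # b = y_i - w'x_i (y_i in {-1, 1})
  h <- drop(X %*% w)
  cand <- y - h
  hinge <- vapply(cand, function(b) sum(pmax(0, 1 - y * (h + b))), numeric(1))
  b <- cand[which.min(hinge)]
  list(w = w, b = b, alpha = a)
}

# textbook Pearson correlation, written out from first principles
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
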