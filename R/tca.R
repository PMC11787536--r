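# Canonical polyadic (CP / PARAFAC) decomposition of a 3-way tensor by
# alternating least squares. Written from first principles: the model is
#   X[n, t, k] ~ sum_r lambda_r * A[n, r] * B[t, r] * C[k, r]
# with unit-norm factor columns and nonnegative component scales lambda.

# Column-wise Khatri-Rao product; rows of `slow` vary slowest.
khatri_rao <- function(slow, fast) {
  ks <- nrow(slow)
  kf <- nrow(fast)
  slow[rep(seq_len(ks), each = kf), , drop = FALSE] *
    fast[rep(seq_len(kf), times = ks), , drop = FALSE]
}

# Solve M %*% G = RHS' for the factor update, with a tiny ridge fallback
# when the Gram matrix is numerically singular.
solve_gram <- function(gram, rhs) {
  out <- tryCatch(t(solve(gram, t(rhs))), error = function(e) NULL)
  if (is.null(out)) {
    out <- t(solve(gram + diag(1e-10 * (1 + mean(diag(gram))), nrow(gram)),
                   t(rhs)))
  }
  out
}

#' Fit a CP decomposition by alternating least squares
#'
#' Factors are initialized from standard normals and updated cyclically by
#' exact least squares; the fit with the lowest normalized reconstruction
#' error over `n_restarts` restarts is returned. The returned model is gauge-
#' fixed: neuron and temporal columns have unit Euclidean norm, the trial
#' columns carry unit norm as well, all scale is absorbed into
#' `lambda >= 0`, sign flips make each temporal column's absolute peak and
#' each neuron column's absolute peak positive (compensated in the trial
#' factor), and components are ordered by decreasing `lambda`.
#'
#' @param tensor An `aligned_tensor` or a plain 3-way numeric array
#'   (neurons x time x trials).
#' @param rank Number of components (the headline analysis uses 5).
#' @param n_restarts Independent random restarts; the best fit is kept.
#' @param max_iter Maximum ALS sweeps per restart.
#' @param tol Stop when the relative change in reconstruction error between
#'   sweeps falls below this.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param trace_error Keep the per-sweep error trace of the winning restart
#'   in `$error_trace` (used for monotonicity checks).
#' @return A `tca_model`: list with `neuron_factor` (N x R), `temporal_factor`
#'   (T x R), `trial_factor` (K x R), `lambda`, `error` (normalized
#'   reconstruction error), `iterations`, `converged`, `rank`, `dims`,
#'   `seed` and optionally `error_trace`.
#' @export
fit_cp_als <- function(tensor, rank = 5L, n_restarts = 5L, max_iter = 500L,
                       tol = 1e-6, seed = 1L, trace_error = FALSE) {
  X <- if (inherits(tensor, "aligned_tensor")) tensor$data else tensor
  if (!is.array(X) || length(dim(X)) != 3L) {
    stop("`tensor` must be a 3-way array or aligned_tensor", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("tensor contains non-finite values",
                               call. = FALSE)
  if (rank < 1L) stop("`rank` must be >= 1", call. = FALSE)
  d <- dim(X)
  if (rank > min(d)) {
    warning(sprintf("rank %d exceeds the smallest tensor dimension %d",
                    rank, min(d)))
  }
  # mode unfoldings, computed once
  X1 <- matrix(X, d[1L], d[2L] * d[3L])                        # N x (T K)
  X2 <- matrix(aperm(X, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])  # T x (N K)
  X3 <- matrix(aperm(X, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])  # K x (N T)
  xnorm2 <- sum(X^2)
  xnorm <- sqrt(xnorm2)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, r), {
      lapply(d, function(n) matrix(stats::rnorm(n * rank), n, rank))
    })
    A <- init[[1L]]; B <- init[[2L]]; C <- init[[3L]]
    err_prev <- Inf
    errs <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      A <- solve_gram(crossprod(C) * crossprod(B), X1 %*% khatri_rao(C, B))
      B <- solve_gram(crossprod(C) * crossprod(A), X2 %*% khatri_rao(C, A))
      C <- solve_gram(crossprod(B) * crossprod(A), X3 %*% khatri_rao(B, A))
      # error without forming the reconstruction:
      # ||X - Xhat||^2 = ||X||^2 - 2<X, Xhat> + ||Xhat||^2
      cross <- sum((X3 %*% khatri_rao(B, A)) * C)
      hat2 <- sum(crossprod(A) * crossprod(B) * crossprod(C))
      err <- sqrt(max(0, xnorm2 - 2 * cross + hat2)) / xnorm
      errs <- c(errs, err)
      if (is.finite(err_prev) && abs(err_prev - err) < tol) {
        converged <- TRUE
        err_prev <- err
        break
      }
      err_prev <- err
    }
    if (is.null(best) || err_prev < best$error) {
      best <- list(A = A, B = B, C = C, error = err_prev, iterations = it,
                   converged = converged, errs = errs, restart = r)
    }
  }
  model <- gauge_fix(best$A, best$B, best$C)
  model$error <- best$error
  model$iterations <- best$iterations
  model$converged <- best$converged
  model$rank <- as.integer(rank)
  model$dims <- d
  model$seed <- as.integer(seed)
  if (trace_error) model$error_trace <- best$errs
  structure(model, class = "tca_model")
}

# Normalize columns, absorb scale into lambda, fix signs deterministically,
# order by decreasing lambda.
gauge_fix <- function(A, B, C) {
  norm2 <- function(m) sqrt(colSums(m^2))
  na <- norm2(A); nb <- norm2(B); nc <- norm2(C)
  na[na == 0] <- 1; nb[nb == 0] <- 1; nc[nc == 0] <- 1
  A <- sweep(A, 2L, na, "/")
  B <- sweep(B, 2L, nb, "/")
  C <- sweep(C, 2L, nc, "/")
  lambda <- na * nb * nc
  for (r in seq_len(ncol(A))) {
    sb <- sign(B[which.max(abs(B[, r])), r])
    if (sb < 0) { B[, r] <- -B[, r]; C[, r] <- -C[, r] }
    sa <- sign(A[which.max(abs(A[, r])), r])
    if (sa < 0) { A[, r] <- -A[, r]; C[, r] <- -C[, r] }
  }
  ord <- order(lambda, decreasing = TRUE)
  list(neuron_factor = A[, ord, drop = FALSE],
       temporal_factor = B[, ord, drop = FALSE],
       trial_factor = C[, ord, drop = FALSE],
       lambda = lambda[ord])
}

#' Reconstruct the dense tensor implied by a CP model
#'
#' @param model A `tca_model`.
#' @return 3-way array of the model's dimensions.
#' @export
cp_reconstruct <- function(model) {
  d <- model$dims
  A <- sweep(model$neuron_factor, 2L, model$lambda, "*")
  M <- A %*% t(khatri_rao(model$trial_factor, model$temporal_factor))
  array(M, d)
}

#' Normalized reconstruction error of a CP model on a tensor
#'
#' `||X - Xhat||_F / ||X||_F`. For the best model returned by
#' [fit_cp_als()] on the data it was fit to this lies in `[0, 1]` (the ALS
#' solution is never worse than the zero model); for an arbitrary
#' model/tensor combination it can exceed 1.
#'
#' @param model A `tca_model`.
#' @param tensor An `aligned_tensor` or 3-way array of matching shape.
#' @return Scalar normalized error.
#' @export
reconstruction_error <- function(model, tensor) {
  X <- if (inherits(tensor, "aligned_tensor")) tensor$data else tensor
  if (!identical(dim(X), model$dims)) {
    stop("tensor shape does not match model dims", call. = FALSE)
  }
  xn <- sqrt(sum(X^2))
  if (xn == 0) stop("zero tensor has no normalized error", call. = FALSE)
  sqrt(sum((X - cp_reconstruct(model))^2)) / xn
}

#' Cross-fit similarity of two CP models
#'
#' Components are matched one-to-one by solving the assignment problem that
#' maximizes the product of the absolute cosine similarities of the neuron,
#' temporal and trial factor columns; the score is the mean of that product
#' over matched components. Invariant to component permutation and to
#' sign/scale gauge, equal to 1 for a model against itself.
#'
#' @param a,b `tca_model`s of equal rank fitted to same-shaped tensors.
#' @return Similarity score in `[0, 1]`.
#' @export
model_similarity <- function(a, b) {
  if (a$rank != b$rank) stop("models have different ranks", call. = FALSE)
  if (!identical(a$dims, b$dims)) stop("models have different tensor shapes",
                                       call. = FALSE)
  abscos <- function(m1, m2) {
    n1 <- sqrt(colSums(m1^2)); n2 <- sqrt(colSums(m2^2))
    abs(crossprod(m1, m2)) / outer(n1, n2)
  }
  S <- abscos(a$neuron_factor, b$neuron_factor) *
    abscos(a$temporal_factor, b$temporal_factor) *
    abscos(a$trial_factor, b$trial_factor)
  assign_ <- clue::solve_LSAP(S, maximum = TRUE)
  mean(S[cbind(seq_len(a$rank), as.integer(assign_))])
}

#' Fit an ensemble of CP decompositions
#'
#' Runs `n_iterations` independent fits with distinct seeds derived from a
#' master seed (the convention is 100 iterations, to average over
#' decomposition variability). Each ensemble member uses a single restart by
#' default since the ensemble itself samples initializations.
#'
#' @param tensor An `aligned_tensor` or 3-way array.
#' @param n_iterations Ensemble size (default 100).
#' @param rank,n_restarts,max_iter,tol As in [fit_cp_als()].
#' @param seed Master seed.
#' @return List of `tca_model`s of length `n_iterations`.
#' @export
run_tca_ensemble <- function(tensor, n_iterations = 100L, rank = 5L,
                             n_restarts = 1L, max_iter = 500L, tol = 1e-6,
                             seed = 1L) {
  lapply(seq_len(n_iterations), function(i) {
    tryCatch(
      fit_cp_als(tensor, rank = rank, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol,
                 seed = derive_seed(seed, 1000L + i)),
      error = function(e) {
        stop(sprintf("ensemble iteration %d failed: %s", i,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  })
}

#' Scale-weighted factor weights of a CP model
#'
#' The gauge-fixed factors are unit-norm; for magnitude comparisons the
#' component scale is redistributed evenly across the three modes, i.e. each
#' factor column is multiplied by `lambda^(1/3)` (the balanced gauge).
#'
#' @param model A `tca_model`.
#' @param mode `"neuron"`, `"temporal"` or `"trial"`.
#' @param scaled Multiply by `lambda^(1/3)`? Default `TRUE`.
#' @return Matrix of weights (rows follow the chosen mode).
#' @export
component_weights <- function(model, mode = c("neuron", "temporal", "trial"),
                              scaled = TRUE) {
  mode <- match.arg(mode)
  m <- switch(mode, neuron = model$neuron_factor,
              temporal = model$temporal_factor, trial = model$trial_factor)
  if (scaled) m <- sweep(m, 2L, model$lambda^(1 / 3), "*")
  m
}

#' @export
print.tca_model <- function(x, ...) {
  cat(sprintf(
    "<tca_model> rank %d on %s tensor; error %.4f after %d iterations (%s)\n",
    x$rank, paste(x$dims, collapse = " x "), x$error, x$iterations,
    if (isTRUE(x$converged)) "converged" else "max_iter reached"
  ))
  invisible(x)
}
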