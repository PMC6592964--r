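#' Reduce a unipolar reference model to full row rank
#'
#' A unipolar operator `T_r` is rank deficient by 1, so one row can be
#' discarded without losing information, yielding the block model
#' `v_r- = T_r- phi + eps_r-` with `T_r-` of full row rank `N_c - 1`.
#' With `drop = "auto"` the discarded row is the physical reference channel
#' for a recording reference (its row of `T_r` is identically zero), either
#' mastoid for linked mastoids, and the last channel otherwise (the
#' estimators built on the reduced model are invariant to the choice).
#'
#' @param op a [ur_operator()].
#' @param d optional [eeg_data()] or matrix referenced by `op`; its rows are
#'   reduced alongside the operator.
#' @param drop channel index to discard, or `"auto"`.
#' @return An object of class `ur_reduced_model`: `T_minus`
#'   (`(N_c-1) x N_c`), `t_r` (the dropped row), `dropped_index`,
#'   `v_minus` (reduced data or `NULL`), `n_channels`.
#' @export
reduce_model <- function(op, d = NULL, drop = "auto") {
  stopifnot(inherits(op, "ur_operator"))
  Tm <- op$matrix
  n <- nrow(Tm)
  if (identical(drop, "auto")) {
    drop_idx <- switch(op$weights$kind,
                       RR = op$weights$anchors[1],
                       LM = op$weights$anchors[1],
                       n)
  } else {
    drop_idx <- as.integer(drop)
    if (drop_idx < 1L || drop_idx > n) stop("drop index out of range")
  }
  T_minus <- Tm[-drop_idx, , drop = FALSE]
  if (mat_rank(T_minus) < n - 1L) {
    stop("discarding row ", drop_idx, " does not leave a full-row-rank ",
         "operator")
  }
  v_minus <- NULL
  if (!is.null(d)) {
    x <- as_data_matrix(d)
    if (nrow(x) != n) stop("data channel count does not match operator")
    if (inherits(d, "eeg_data") && identical(d$reference, "unknown")) {
      warning("data reference is 'unknown'; the reduced model assumes the ",
              "data were referenced by the supplied operator")
    }
    v_minus <- x[-drop_idx, , drop = FALSE]
  }
  structure(list(T_minus = T_minus, t_r = Tm[drop_idx, ],
                 dropped_index = drop_idx, v_minus = v_minus,
                 n_channels = n),
            class = "ur_reduced_model")
}

#' Average-reference-constrained best linear unbiased estimator
#'
#' Estimates the infinity-referenced potentials from the reduced unipolar
#' model under the zero-sum constraint `1' phi = 0` (the discrete surface
#' integral of the potential vanishing on a layered spherical conductor).
#' Two algebraically equivalent routes are implemented:
#'
#' * `"simplified"` — `phi_hat = T_AR T_r-^+ v_r-`, the closed form showing
#'   that the constrained BLUE is the average reference when the sensor
#'   noise is neglected;
#' * `"full"` — the general constrained-least-squares formula
#'   `phi_hat = (I - P^-1 1 1' / (1' P^-1 1)) P^-1 T_r-' (T_r- T_r-')^-1
#'   v_r-` with `P = T_r-' (T_r- T_r-')^-1 T_r- + 1 1'`, computed literally
#'   with numeric inverses.
#'
#' The output always has zero column sums (the constraint is enforced
#' exactly up to float roundoff).
#'
#' @param rm a [reduce_model()] result.
#' @param v reduced data (`(N_c-1) x N_t`); defaults to `rm$v_minus`.
#' @param method `"simplified"` or `"full"`.
#' @return `N_c x N_t` matrix of estimated potentials.
#' @export
blue_ar <- function(rm, v = NULL, method = c("simplified", "full")) {
  method <- match.arg(method)
  stopifnot(inherits(rm, "ur_reduced_model"))
  if (is.null(v)) v <- rm$v_minus
  if (is.null(v)) stop("no data: supply v or build the model with data")
  v <- as.matrix(v)
  n <- rm$n_channels
  if (nrow(v) != n - 1L) stop("reduced data must have N_c - 1 rows")
  Tm <- rm$T_minus
  if (method == "simplified") {
    T_ar <- diag(n) - matrix(1 / n, n, n)
    T_ar %*% (pinv(Tm) %*% v)
  } else {
    G <- Tm %*% t(Tm)
    Tp <- t(Tm) %*% solve(G)
    ones <- matrix(1, n, 1)
    P <- Tp %*% Tm + ones %*% t(ones)
    Pinv <- solve(P)
    proj <- diag(n) - (Pinv %*% ones %*% t(ones)) /
      as.numeric(t(ones) %*% Pinv %*% ones)
    proj %*% (Pinv %*% (Tp %*% v))
  }
}

#' Maximum-likelihood REST estimator on the reduced model
#'
#' Minimum-source-norm estimator of the infinity-referenced potentials from
#' the reduced unipolar model, using the lead field as the constraint:
#' `phi_hat = K_inf K_r-' (K_r- K_r-' + lambda T_r- T_r-')^-1 v_r-` with
#' `K_r- = T_r- K_inf` and `lambda = sigma^2 / alpha^2`.  At `lambda = 0`
#' the pure pseudoinverse path `phi_hat = K_inf K_r-^+ v_r-` is used, which
#' is the classical REST estimate computed from the reduced recording; note
#' `K_inf` retains the dropped channel's row, which is what makes this
#' formula an interpolator (see [interpolate_channels()]).
#'
#' The `"svd"` route re-derives the same estimate through the singular value
#' decomposition `K_inf = U S W'`: regressing on `L = T_r- U S` for the
#' rotated sources `beta = W' j` (whose minimum Euclidean norm equals the
#' minimum norm of `j` under an IID source prior), then mapping back with
#' `U S`.
#'
#' @param rm a [reduce_model()] result.
#' @param K infinity-referenced lead field, full row rank.
#' @param lam regularization ratio `sigma^2 / alpha^2`, >= 0.
#' @param v reduced data; defaults to `rm$v_minus`.
#' @param method `"direct"` or `"svd"` (two independently coded routes).
#' @return `N_c x N_t` matrix of estimated potentials.
#' @export
mle_rest <- function(rm, K, lam = 0, v = NULL,
                     method = c("direct", "svd")) {
  method <- match.arg(method)
  stopifnot(inherits(rm, "ur_reduced_model"))
  if (lam < 0) stop("lambda must be >= 0")
  if (is.null(v)) v <- rm$v_minus
  if (is.null(v)) stop("no data: supply v or build the model with data")
  v <- as.matrix(v)
  gain <- as_gain(K)
  n <- rm$n_channels
  if (nrow(gain) != n) stop("lead field rows do not match channel count")
  Tm <- rm$T_minus
  if (method == "direct") {
    Km <- Tm %*% gain
    if (lam == 0) {
      gain %*% (pinv(Km) %*% v)
    } else {
      G <- tcrossprod(Km) + lam * tcrossprod(Tm)
      ok <- tryCatch({ci <- chol(G); TRUE}, error = function(e) FALSE)
      if (!ok) stop("singular regularized Gram matrix: degenerate lead field")
      gain %*% crossprod(Km, solve(G, v))
    }
  } else {
    s <- svd(gain, nu = nrow(gain), nv = 0)
    US <- s$u %*% diag(s$d, nrow(gain))
    L <- Tm %*% US
    H <- tcrossprod(L) + lam * tcrossprod(Tm)
    beta <- if (lam == 0) {
      crossprod(L, pinv(H) %*% v)
    } else {
      crossprod(L, solve(H, v))
    }
    US %*% beta
  }
}

#' Bayesian MAP estimator of the potentials at infinity
#'
#' The general Gaussian maximum a posteriori solution of the reference
#' problem `x = T_o (phi + eps)`:
#' `phi_hat = Sigma T_o' (T_o Sigma T_o' + sigma^2 T_o T_o')^+ x`,
#' where `Sigma` is the prior covariance of the infinity-referenced
#' potentials and `T_o` any reference transform (unipolar or not).  Two
#' priors are provided:
#'
#' * `"iid_potentials"` — `Sigma = alpha^2 I`: ignoring volume conduction.
#'   With `sigma2 = 0` and unipolar-referenced data this reproduces the
#'   average reference whatever the embedded UR was.
#' * `"iid_sources"` — `Sigma = alpha^2 K K'`: IID equivalent sources
#'   propagated through the lead field.  With `sigma2 = 0` this is the
#'   classical REST estimate, and for `sigma2 > 0` it coincides with the
#'   [rrest_operator()] at `lambda = sigma2 / alpha2`.
#'
#' The `sigma2 = 0` limit is an explicit pseudoinverse path, not a
#' numerical limit.
#'
#' @param x [eeg_data()] or channels-by-samples matrix of referenced data.
#' @param T_o reference transform embedded in the data (matrix,
#'   [ur_operator()] or [ur_weights()]).
#' @param prior `"iid_potentials"` or `"iid_sources"`.
#' @param alpha2 prior variance (> 0); only the ratio `sigma2/alpha2`
#'   affects the estimate.
#' @param sigma2 sensor-noise variance (>= 0).
#' @param K infinity-referenced lead field, required for `"iid_sources"`.
#' @return `N_c x N_t` matrix of estimated potentials.
#' @export
map_estimate <- function(x, T_o, prior = c("iid_potentials", "iid_sources"),
                         alpha2 = 1, sigma2 = 0, K = NULL) {
  prior <- match.arg(prior)
  if (alpha2 <= 0) stop("alpha2 must be > 0")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  xm <- as_data_matrix(x)
  To <- as_operator_matrix(T_o)
  n <- nrow(To)
  if (nrow(xm) != n) stop("data channel count does not match transform")
  Sigma <- if (prior == "iid_potentials") {
    alpha2 * diag(n)
  } else {
    if (is.null(K)) stop("the iid_sources prior requires a lead field")
    gain <- as_gain(K)
    if (nrow(gain) != n) stop("lead field rows do not match transform")
    alpha2 * tcrossprod(gain)
  }
  M <- Sigma %*% t(To) %*% pinv(To %*% Sigma %*% t(To) +
                                  sigma2 * tcrossprod(To))
  M %*% xm
}
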