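# Build the n_obs x n_full transform mapping the full infinity-referenced
# potentials to the observed referenced data.  Two provenances:
#   * an observed-set UR (weights over the observed channels): rows of
#     (I - 1 f') applied after selecting the observed channels;
#   * a full-montage UR whose observed rows survived channel deletion
#     ("reduced form", e.g. the recording reference channel removed).
observed_transform <- function(reference, obs_idx, n_full) {
  w <- if (inherits(reference, "ur_weights")) reference$w else
    as.numeric(reference)
  n_obs <- length(obs_idx)
  if (length(w) == n_obs) {
    S <- diag(n_full)[obs_idx, , drop = FALSE]
    (diag(n_obs) - outer(rep(1, n_obs), w)) %*% S
  } else if (length(w) == n_full) {
    T_full <- diag(n_full) - outer(rep(1, n_full), w)
    T_full[obs_idx, , drop = FALSE]
  } else {
    stop("reference weights must cover the observed set (", n_obs,
         ") or the full montage (", n_full, "), got length ", length(w))
  }
}

#' Interpolate missing or rejected channels through the lead field
#'
#' Recovers channels absent from a recording by evaluating the (regularized)
#' REST estimator through lead-field rows that were not observed: the full
#' lead field has rows for every montage channel, so
#' `phi_hat = K_full K_obs' (K_obs K_obs' + lambda T_obs T_obs')^+ d_obs`
#' returns infinity-referenced estimates over the *full* montage, including
#' the missing channels.  Here `T_obs` is the transform relating the
#' observed data to the full infinity-referenced potentials and
#' `K_obs = T_obs K_full`.  This covers both the recording-reference channel
#' (whose referenced row is identically zero and is typically discarded)
#' and arbitrary rejected bad channels; several channels may be missing at
#' once.  Missing channels must exist in the lead field's montage — no
#' geometric extrapolation is attempted.
#'
#' With `missing` empty this degenerates to the plain rREST estimate of the
#' observed recording.
#'
#' @param d_obs [eeg_data()] or matrix over the observed channels.
#' @param K full infinity-referenced [leadfield()] covering observed and
#'   missing channels (needs a montage, or rownames on the gain matrix).
#' @param missing character labels (or integer indices) of the channels to
#'   reconstruct.
#' @param lam regularization ratio `sigma^2/alpha^2`, >= 0.
#' @param reference how `d_obs` relates to the full potentials: a
#'   [ur_weights()] over the observed set, or over the full montage when the
#'   observed rows are the remnant of a full-montage reference ("reduced
#'   form").  Defaults to the reference tag of `d_obs`.
#' @return [eeg_data()] over the full montage (montage order), reference
#'   tag `"infinity"`.
#' @export
interpolate_channels <- function(d_obs, K, missing, lam = 0,
                                 reference = NULL) {
  if (lam < 0) stop("lambda must be >= 0")
  gain <- as_gain(K)
  labels <- if (inherits(K, "ur_leadfield") && !is.null(K$montage)) {
    K$montage$labels
  } else {
    rownames(gain)
  }
  if (is.null(labels)) stop("the lead field must carry channel labels")
  n_full <- nrow(gain)
  if (is.numeric(missing)) {
    miss_idx <- as.integer(missing)
    if (any(miss_idx < 1L | miss_idx > n_full)) {
      stop("missing channel index out of range")
    }
  } else {
    miss_idx <- match(as.character(missing), labels)
    if (anyNA(miss_idx)) {
      stop("missing channel(s) absent from the lead field montage: ",
           paste(missing[is.na(miss_idx)], collapse = ", "))
    }
  }
  obs_idx <- setdiff(seq_len(n_full), miss_idx)
  if (length(obs_idx) < 2L) stop("need at least 2 observed channels")
  x <- as_data_matrix(d_obs)
  if (nrow(x) != length(obs_idx)) {
    stop("observed data has ", nrow(x), " rows but ", length(obs_idx),
         " channels remain after removing the missing set")
  }
  if (is.null(reference)) {
    tag <- if (inherits(d_obs, "eeg_data")) d_obs$reference else NULL
    if (!inherits(tag, "ur_weights")) {
      stop("supply `reference`: the observed data's relation to the full ",
           "potentials is needed")
    }
    reference <- tag
  }
  T_obs <- observed_transform(reference, obs_idx, n_full)
  K_obs <- T_obs %*% gain
  est <- if (lam == 0) {
    gain %*% (pinv(K_obs) %*% x)
  } else {
    gain %*% crossprod(K_obs,
                       pinv(tcrossprod(K_obs) + lam * tcrossprod(T_obs)) %*% x)
  }
  eeg_data(est, labels = labels, reference = "infinity")
}

#' Leave-one-channel-out interpolation score
#'
#' Validation harness for the interpolation function: each channel is
#' deleted in turn from a fully observed unipolar-referenced recording,
#' reconstructed by [interpolate_channels()] with the remaining channels,
#' and compared against a reference signal.  By default the reference is
#' the full-montage rREST estimate at the same `lambda` (on noise-free
#' model-consistent data the reconstruction reproduces it to numerical
#' precision); pass `phi_ref` (e.g. the simulated true potentials) to score
#' against ground truth instead.
#'
#' @param d [eeg_data()] over the full montage whose reference tag is a
#'   [ur_weights()] (or supply `reference`).
#' @param K full infinity-referenced lead field with channel labels.
#' @param lam regularization ratio, >= 0.
#' @param phi_ref optional `N_c x N_t` reference signal.
#' @param reference full-montage [ur_weights()] overriding the data tag.
#' @return Named vector of per-channel relative errors
#'   `||rec_i - ref_i|| / ||ref_i||`.
#' @export
loo_interpolation_score <- function(d, K, lam = 0, phi_ref = NULL,
                                    reference = NULL) {
  gain <- as_gain(K)
  n <- nrow(gain)
  if (n < 3L) stop("leave-one-out scoring needs at least 3 channels")
  x <- as_data_matrix(d)
  if (nrow(x) != n) stop("data channel count does not match lead field")
  if (is.null(reference)) {
    tag <- if (inherits(d, "eeg_data")) d$reference else NULL
    if (!inherits(tag, "ur_weights")) {
      stop("data must carry a unipolar reference tag (or pass `reference`)")
    }
    reference <- tag
  }
  labels <- if (inherits(K, "ur_leadfield") && !is.null(K$montage)) {
    K$montage$labels
  } else {
    rownames(gain)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  ref_sig <- if (is.null(phi_ref)) {
    rrest_operator(gain, ur_operator(reference)$matrix, lam) %*% x
  } else {
    as.matrix(phi_ref)
  }
  Kl <- leadfield(gain)
  rownames(Kl$gain) <- labels
  errs <- vapply(seq_len(n), function(i) {
    rec <- interpolate_channels(x[-i, , drop = FALSE], Kl, missing = i,
                                lam = lam, reference = reference)
    num <- sqrt(sum((rec$data[i, ] - ref_sig[i, ])^2))
    den <- sqrt(sum(ref_sig[i, ]^2))
    num / den
  }, numeric(1))
  names(errs) <- labels
  errs
}
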