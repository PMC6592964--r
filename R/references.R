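#' Unipolar reference weight vectors
#'
#' Every unipolar reference (UR) subtracts one common signal, a linear
#' combination `f_r' phi` of the infinity-referenced potentials, from all
#' channels.  The family is parameterized by the weight vector `f_r` with
#' `sum(f_r) = 1`:
#'
#' * `"RR"` — recording (physical) reference: an indicator vector at the
#'   reference electrode (e.g. Cz, Fz, Oz, FCz).
#' * `"LM"` — linked mastoids/earlobes: 0.5 at each of the two mastoid
#'   channels.
#' * `"AR"` — average reference: `1/N_c` everywhere.
#' * `"REST"` — reference electrode standardization technique: the
#'   lead-field-dependent vector of [rest_weights()].
#' * `"custom"` — any user weights whose sum is 1 (tolerance 1e-9, since
#'   vectors loaded from files carry rounding).
#'
#' @param kind one of `"RR"`, `"LM"`, `"AR"`, `"REST"`, `"custom"`.
#' @param montage a [montage()], or `NULL` if `n_channels` is given.
#' @param n_channels number of channels when no montage is supplied.
#' @param anchors channel labels (or indices): one for `"RR"`, two for
#'   `"LM"`.  For `"LM"` without anchors, the mastoid pair is auto-detected
#'   case-insensitively among (A1, A2), (M1, M2), (TP9, TP10).
#' @param leadfield infinity-referenced lead field, required for `"REST"`.
#' @param weights numeric vector for `"custom"`.
#' @return An object of class `ur_weights`: fields `w` (numeric weights),
#'   `kind`, `anchors` (indices), `labels`.
#' @export
#' @examples
#' ur_weights("AR", n_channels = 4)$w
#' ur_weights("RR", montage = montage_1020(), anchors = "Cz")
ur_weights <- function(kind = c("AR", "RR", "LM", "REST", "custom"),
                       montage = NULL, n_channels = NULL, anchors = NULL,
                       leadfield = NULL, weights = NULL) {
  kind <- match.arg(kind)
  labels <- NULL
  if (!is.null(montage)) {
    stopifnot(inherits(montage, "ur_montage"))
    labels <- montage$labels
    n <- montage$n_channels
  } else if (!is.null(n_channels)) {
    n <- as.integer(n_channels)
  } else if (!is.null(leadfield)) {
    n <- nrow(as_gain(leadfield))
  } else if (!is.null(weights)) {
    n <- length(weights)
  } else {
    stop("supply a montage, n_channels, a lead field or weights")
  }
  if (n < 2L) stop("a unipolar reference needs at least 2 channels")

  resolve <- function(a) {
    if (is.numeric(a)) {
      idx <- as.integer(a)
      if (any(idx < 1L | idx > n)) stop("anchor index out of range")
      return(idx)
    }
    if (is.null(labels)) stop("anchor labels require a montage")
    idx <- match(a, labels)
    if (anyNA(idx)) {
      stop("anchor label(s) not in montage: ",
           paste(a[is.na(idx)], collapse = ", "))
    }
    idx
  }

  anchor_idx <- NULL
  w <- switch(kind,
    AR = rep(1 / n, n),
    RR = {
      if (length(anchors) != 1L) stop("RR needs exactly one anchor channel")
      anchor_idx <- resolve(anchors)
      w <- numeric(n); w[anchor_idx] <- 1; w
    },
    LM = {
      if (is.null(anchors)) {
        if (is.null(labels)) stop("LM without anchors requires a montage")
        low <- tolower(labels)
        pair <- NULL
        for (cand in list(c("a1", "a2"), c("m1", "m2"), c("tp9", "tp10"))) {
          hit <- match(cand, low)
          if (!anyNA(hit)) { pair <- hit; break }
        }
        if (is.null(pair)) {
          stop("no mastoid pair (A1/A2, M1/M2, TP9/TP10) found; ",
               "supply anchors explicitly")
        }
        anchor_idx <- pair
      } else {
        if (length(anchors) != 2L) stop("LM needs exactly two anchor channels")
        anchor_idx <- resolve(anchors)
      }
      if (anchor_idx[1] == anchor_idx[2]) stop("LM anchors must differ")
      w <- numeric(n); w[anchor_idx] <- 0.5; w
    },
    REST = {
      if (is.null(leadfield)) stop("REST weights require a lead field")
      rest_weights(leadfield)$w
    },
    custom = {
      if (is.null(weights)) stop("custom kind requires weights")
      if (length(weights) != n) stop("weights length does not match channels")
      weights
    })
  if (abs(sum(w) - 1) > 1e-9) {
    stop("unipolar reference weights must sum to 1 (got ", sum(w), ")")
  }
  structure(list(w = as.numeric(w), kind = kind, anchors = anchor_idx,
                 labels = labels),
            class = "ur_weights")
}

#' REST weights from a lead field
#'
#' The unipolar weight vector of the reference electrode standardization
#' technique: `f_REST = K^+T K^+ 1 / (1' K^+T K^+ 1)` for a full-row-rank
#' infinity-referenced lead field `K`.  Among all weight vectors summing to
#' one, `f_REST` minimizes the variance `f' K K' f` of the reference signal
#' under IID equivalent sources, which is what distinguishes REST from the
#' average reference.  The weights are invariant to rescaling of `K`; when
#' `K` is the identity they reduce to the average-reference weights `1/N_c`.
#'
#' @param K infinity-referenced lead field (object or gain matrix), full
#'   row rank.
#' @return A [ur_weights()] of kind `"REST"`.
#' @export
rest_weights <- function(K) {
  gain <- as_gain(K)
  if (mat_rank(gain) < nrow(gain)) {
    stop("REST weights require a full-row-rank lead field")
  }
  Kp <- pinv(gain)
  u <- crossprod(Kp, Kp %*% rep(1, nrow(gain)))   # K^+T K^+ 1
  w <- as.numeric(u / sum(u))
  labels <- if (inherits(K, "ur_leadfield") && !is.null(K$montage)) {
    K$montage$labels
  } else {
    rownames(gain)
  }
  structure(list(w = w, kind = "REST", anchors = NULL, labels = labels),
            class = "ur_weights")
}

#' @export
print.ur_weights <- function(x, ...) {
  cat("<ur_weights> kind ", x$kind, ", ", length(x$w), " channels, sum = ",
      format(sum(x$w)), "\n", sep = "")
  invisible(x)
}

#' Unipolar reference operator
#'
#' Builds the rank-one reference transformation `T_r = I - 1 f_r'` from a
#' weight vector with `sum(f_r) = 1`.  Every such operator annihilates the
#' constant vector (`T_r 1 = 0`), is idempotent, and has rank `N_c - 1`.
#'
#' @param f a [ur_weights()] object or a numeric weight vector summing to 1
#'   (tolerance 1e-9).
#' @return An object of class `ur_operator` with fields `matrix` and
#'   `weights`.
#' @export
#' @examples
#' ur_operator(c(0.5, 0.5))$matrix
ur_operator <- function(f) {
  if (!inherits(f, "ur_weights")) {
    f <- ur_weights("custom", weights = as.numeric(f))
  }
  if (abs(sum(f$w) - 1) > 1e-9) {
    stop("weights must sum to 1 for a unipolar reference operator")
  }
  n <- length(f$w)
  Tm <- diag(n) - outer(rep(1, n), f$w)
  if (!is.null(f$labels)) dimnames(Tm) <- list(f$labels, f$labels)
  structure(list(matrix = Tm, weights = f), class = "ur_operator")
}

#' @export
print.ur_operator <- function(x, ...) {
  cat("<ur_operator> ", nrow(x$matrix), " x ", ncol(x$matrix),
      ", kind ", x$weights$kind, "\n", sep = "")
  invisible(x)
}

#' Multichannel EEG container
#'
#' Channels-by-samples potentials in microvolts, with an optional sampling
#' rate and a reference tag recording how the data relate to the
#' (unobservable) infinity-referenced potentials: `"infinity"` for model
#' data or estimator output, a [ur_weights()] after [apply_reference()],
#' or `"unknown"` for data of unrecorded provenance.
#'
#' @param data numeric `N_c x N_t` matrix.
#' @param srate sampling rate in Hz (optional).
#' @param labels channel labels (defaults to rownames).
#' @param reference `"infinity"`, `"unknown"`, or a [ur_weights()].
#' @return An object of class `eeg_data`.
#' @export
eeg_data <- function(data, srate = NULL, labels = NULL,
                     reference = "unknown") {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("non-finite values in EEG data")
  if (is.null(labels)) labels <- rownames(data)
  if (!is.null(labels)) {
    if (length(labels) != nrow(data)) {
      stop("labels length does not match channel count")
    }
    rownames(data) <- labels
  }
  if (inherits(reference, "ur_weights") &&
      length(reference$w) != nrow(data)) {
    stop("reference weights length does not match channel count")
  }
  structure(list(data = data, srate = srate, labels = labels,
                 reference = reference),
            class = "eeg_data")
}

#' @export
print.eeg_data <- function(x, ...) {
  tag <- if (is.character(x$reference)) x$reference
         else paste0("UR(", x$reference$kind, ")")
  cat("<eeg_data> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples, reference: ", tag,
      if (!is.null(x$srate)) paste0(", ", x$srate, " Hz") else "",
      "\n", sep = "")
  invisible(x)
}

as_data_matrix <- function(d) {
  if (inherits(d, "eeg_data")) d$data else as.matrix(d)
}

#' Apply a unipolar reference to EEG data
#'
#' Left-multiplies the data by the reference operator.  Because of the
#' no-memory property this fully replaces any unipolar reference already in
#' the data; if the current reference tag is `"unknown"` a warning reminds
#' the user that the guarantee requires the prior reference to have been a
#' UR (re-referencing non-UR data, e.g. bipolar derivations, corrupts it).
#'
#' @param d an [eeg_data()] object or a channels-by-samples matrix.
#' @param op a [ur_operator()] (or [ur_weights()]).
#' @return An [eeg_data()] whose reference tag is `op`'s weight vector.
#' @export
apply_reference <- function(d, op) {
  if (inherits(op, "ur_weights")) op <- ur_operator(op)
  stopifnot(inherits(op, "ur_operator"))
  x <- as_data_matrix(d)
  if (nrow(x) != nrow(op$matrix)) {
    stop("operator is ", nrow(op$matrix), " x ", ncol(op$matrix),
         " but data has ", nrow(x), " channels")
  }
  if (inherits(d, "eeg_data") && identical(d$reference, "unknown")) {
    warning("data reference is 'unknown'; re-referencing is only guaranteed ",
            "to be exact if the prior reference was unipolar")
  }
  out <- op$matrix %*% x
  srate <- if (inherits(d, "eeg_data")) d$srate else NULL
  labels <- if (inherits(d, "eeg_data")) d$labels else rownames(x)
  eeg_data(out, srate = srate, labels = labels, reference = op$weights)
}

#' No-memory deviation of a pair of unipolar references
#'
#' For any two unipolar operators, applying `op2` first and `op1` second
#' equals applying `op1` alone: `T_r1 T_r2 = T_r1` whenever
#' `f_r1' 1 = 1`.  Returns `max(abs(T1 - T1 %*% T2))`, which is at
#' machine precision (<= 1e-12) for valid URs.
#'
#' @param op1,op2 [ur_operator()] objects of equal size.
#' @return Scalar maximum absolute deviation.
#' @export
no_memory_deviation <- function(op1, op2) {
  T1 <- as_operator_matrix(op1)
  T2 <- as_operator_matrix(op2)
  if (!all(dim(T1) == dim(T2))) stop("operator dimensions differ")
  max(abs(T1 - T1 %*% T2))
}

#' Rank deficiency of a reference operator
#'
#' Returns `N_c - rank(T_r)` under the shared SVD cutoff; equal to 1 for
#' every unipolar reference.
#'
#' @param op a [ur_operator()] (or matrix).
#' @return Integer rank deficiency.
#' @export
rank_deficiency <- function(op) {
  Tm <- as_operator_matrix(op)
  nrow(Tm) - mat_rank(Tm)
}

#' Centering-property deviation of a reference operator
#'
#' The orthogonal projector onto the row space of any unipolar reference is
#' the average-reference (centering) operator: `T_r^+ T_r = T_AR`.  Returns
#' the maximum absolute deviation, <= 1e-10 for all URs.
#'
#' @param op a [ur_operator()] (or matrix).
#' @return Scalar maximum absolute deviation.
#' @export
centering_deviation <- function(op) {
  Tm <- as_operator_matrix(op)
  n <- nrow(Tm)
  T_ar <- diag(n) - matrix(1 / n, n, n)
  max(abs(pinv(Tm) %*% Tm - T_ar))
}
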