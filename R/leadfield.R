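#' Lead field container
#'
#' A lead field is an `N_c x N_s` gain matrix mapping dipolar source moments
#' to scalp potentials.  Gains produced by [spherical_leadfield()] are in
#' microvolts per nA.m.  The `reference_tag` records which reference the
#' gains are expressed in: `"infinity"` for the ideal infinity reference, or
#' a [ur_weights()] object after [reference_leadfield()].
#'
#' @param gain numeric `N_c x N_s` matrix.
#' @param montage optional [montage()] whose channel count must match
#'   `nrow(gain)`.
#' @param grid optional [source_grid()].
#' @param reference_tag `"infinity"` (default) or a [ur_weights()] object.
#' @return An object of class `ur_leadfield`.
#' @export
leadfield <- function(gain, montage = NULL, grid = NULL,
                      reference_tag = "infinity") {
  gain <- as.matrix(gain)
  if (!all(is.finite(gain))) stop("non-finite entries in lead field gain")
  if (!is.null(montage) && montage$n_channels != nrow(gain)) {
    stop("montage has ", montage$n_channels, " channels but gain has ",
         nrow(gain), " rows")
  }
  if (!is.null(montage)) rownames(gain) <- montage$labels
  structure(list(gain = gain, montage = montage, grid = grid,
                 reference_tag = reference_tag),
            class = "ur_leadfield")
}

#' @export
print.ur_leadfield <- function(x, ...) {
  tag <- if (is.character(x$reference_tag)) x$reference_tag
         else paste0("UR(", x$reference_tag$kind, ")")
  cat("<ur_leadfield> ", nrow(x$gain), " channels x ", ncol(x$gain),
      " source columns, reference: ", tag, "\n", sep = "")
  invisible(x)
}

#' Quasi-uniform spherical source grid
#'
#' Places `n_sources` points on a sphere of radius
#' `radius_fraction * brain_radius` using the deterministic Fibonacci-sphere
#' layout, emulating the distributed equivalent-source layer used by REST.
#' The same inputs always produce the same grid.
#'
#' @param n_sources number of source locations (>= 1).
#' @param radius_fraction fraction of the brain-shell radius, in (0, 1);
#'   sources must lie strictly inside the innermost shell.
#' @param brain_radius brain-shell radius in meters.
#' @param orientations `"radial"` (default; one dipole per location, oriented
#'   along the location vector), `"free"` (three orthogonal unit dipoles per
#'   location, tripling the gain columns), or an `n_sources x 3` matrix of
#'   unit orientation vectors.
#' @return An object of class `ur_source_grid` with fields `locations`
#'   (`n_sources x 3`, meters), `orientations`, `n_sources`.
#' @export
#' @examples
#' g <- source_grid(200)
#' range(sqrt(rowSums(g$locations^2)))
source_grid <- function(n_sources, radius_fraction = 0.8,
                        brain_radius = 0.087, orientations = "radial") {
  n_sources <- as.integer(n_sources)
  if (n_sources < 1L) stop("n_sources must be >= 1")
  if (!(radius_fraction > 0 && radius_fraction < 1)) {
    stop("radius_fraction must be in (0, 1): sources must be strictly ",
         "inside the brain shell")
  }
  i <- seq_len(n_sources) - 0.5
  z <- 1 - 2 * i / n_sources
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  s <- sqrt(pmax(0, 1 - z^2))
  loc <- radius_fraction * brain_radius * cbind(s * cos(phi), s * sin(phi), z)
  colnames(loc) <- c("x", "y", "z")
  if (is.matrix(orientations)) {
    orientations <- as.matrix(orientations)
    if (nrow(orientations) != n_sources || ncol(orientations) != 3L) {
      stop("orientation matrix must be n_sources x 3")
    }
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("orientation vectors must be unit norm")
  } else {
    orientations <- match.arg(orientations, c("radial", "free"))
  }
  structure(list(locations = loc, orientations = orientations,
                 n_sources = n_sources),
            class = "ur_source_grid")
}

# Harmonic transfer coefficients M_n for a concentric-shell conductor:
# the surface potential of degree n equals M_n times the bare (infinite
# medium, brain conductivity) dipole coefficient evaluated at the outer
# radius.  For equal conductivities M_n = (2n+1)/n exactly.  Radii are
# normalized by the outer radius; per-degree 2L-1 unknowns (A_j, B_j with
# B_1 belonging to the dipole's own singular term, fixed to 1) are solved
# from interface continuity of potential and radial current plus the
# insulating outer boundary.
shell_coeffs <- function(n_max, radii, cond) {
  L <- length(radii)
  stopifnot(length(cond) == L, all(diff(radii) > 0), all(cond > 0))
  rho <- radii / radii[L]
  M <- numeric(n_max)
  for (n in seq_len(n_max)) {
    if (L == 1L) {
      M[n] <- (2 * n + 1) / n
      next
    }
    nu <- 2L * L - 1L                       # A_1..A_L, B_2..B_L
    Amat <- matrix(0, nu, nu)
    rhs <- numeric(nu)
    iA <- seq_len(L)
    iB <- L + seq_len(L - 1L)               # B_2..B_L
    row <- 0L
    for (j in seq_len(L - 1L)) {
      r <- rho[j]
      # potential continuity at interface j
      row <- row + 1L
      Amat[row, iA[j]] <- r^n
      if (j > 1L) Amat[row, iB[j - 1L]] <- r^(-(n + 1))
      Amat[row, iA[j + 1L]] <- -r^n
      Amat[row, iB[j]] <- -r^(-(n + 1))
      if (j == 1L) rhs[row] <- -r^(-(n + 1))
      # radial current continuity
      row <- row + 1L
      Amat[row, iA[j]] <- cond[j] * n * r^(n - 1)
      if (j > 1L) Amat[row, iB[j - 1L]] <- -cond[j] * (n + 1) * r^(-(n + 2))
      Amat[row, iA[j + 1L]] <- -cond[j + 1L] * n * r^(n - 1)
      Amat[row, iB[j]] <- cond[j + 1L] * (n + 1) * r^(-(n + 2))
      if (j == 1L) rhs[row] <- cond[j] * (n + 1) * r^(-(n + 2))
    }
    # insulating scalp surface at rho = 1
    row <- row + 1L
    Amat[row, iA[L]] <- n
    Amat[row, iB[L - 1L]] <- -(n + 1)
    # row/column equilibration: the system mixes rho^n with rho^-(n+2),
    # which is hopelessly ill-conditioned at high degree without scaling
    rs <- 1 / apply(abs(Amat), 1, max)
    cs <- 1 / apply(abs(Amat) * rs, 2, max)
    sol <- cs * solve(Amat * rs * rep(cs, each = nu), rhs * rs)
    M[n] <- sol[iA[L]] + sol[iB[L - 1L]]
  }
  M
}

#' Spherical-head analytic lead field
#'
#' Computes the EEG forward model for dipoles inside a three-concentric-
#' sphere head (brain, skull, scalp) with an insulating exterior, by the
#' classical spherical-harmonic series.  Sensors are radially projected onto
#' the scalp sphere before evaluation; sources must lie strictly inside the
#' brain shell.  Default radii 0.087/0.092/0.100 m and conductivities
#' 0.33/0.0042/0.33 S/m are standard literature values.  The series for each
#' sensor-source pair is truncated when the relative contribution of a term
#' falls below `tol`, or errors if `max_terms` is reached first.
#'
#' Gains are expressed in microvolts per nA.m of dipole moment, referenced
#' at infinity.
#'
#' @param montage a [montage()].
#' @param grid a [source_grid()].
#' @param radii increasing shell radii in meters (brain, skull, scalp).
#' @param conductivities shell conductivities in S/m, same length as `radii`.
#' @param tol relative series truncation tolerance.
#' @param max_terms maximum number of series terms.
#' @return A [leadfield()] with `reference_tag = "infinity"`.  With
#'   `orientations = "free"` the gain has three columns (x, y, z moments)
#'   per source location, in source-major order.
#' @export
spherical_leadfield <- function(montage, grid,
                                radii = c(0.087, 0.092, 0.100),
                                conductivities = c(0.33, 0.0042, 0.33),
                                tol = 1e-10, max_terms = 200L) {
  stopifnot(inherits(montage, "ur_montage"), inherits(grid, "ur_source_grid"))
  R <- radii[length(radii)]
  sens <- montage$positions
  sens <- sens * (R / sqrt(rowSums(sens^2)))   # radial projection to scalp
  src <- grid$locations
  b <- sqrt(rowSums(src^2))
  if (any(b >= radii[1])) {
    stop("source location on or outside the brain shell (radius ",
         radii[1], " m)")
  }
  free <- identical(grid$orientations, "free")
  moments <- if (free) {
    list(cbind(1, 0, 0)[rep(1, nrow(src)), , drop = FALSE],
         cbind(0, 1, 0)[rep(1, nrow(src)), , drop = FALSE],
         cbind(0, 0, 1)[rep(1, nrow(src)), , drop = FALSE])
  } else if (is.matrix(grid$orientations)) {
    list(grid$orientations)
  } else {
    u <- src / ifelse(b > 0, b, 1)           # radial; center dipole -> +z
    u[b == 0, ] <- rep(c(0, 0, 1), each = sum(b == 0))
    list(u)
  }
  M <- shell_coeffs(max_terms, radii, conductivities)
  nc <- nrow(sens); ns <- nrow(src)
  rhat_e <- sens / R
  rhat_s <- src / ifelse(b > 0, b, 1)
  rhat_s[b == 0, ] <- rep(c(0, 0, 1), each = sum(b == 0))
  C <- rhat_e %*% t(rhat_s)                 # cos(angle), nc x ns
  C <- pmin(1, pmax(-1, C))
  S <- sqrt(pmax(0, 1 - C^2))
  x <- b / R                                # per-source radial fraction

  series_sum <- function(pr, pt) {
    # pr, pt: nc x ns matrices of radial / tangential moment components
    P_prev <- matrix(1, nc, ns)             # P_0
    P_cur <- C                              # P_1
    dP_prev <- matrix(0, nc, ns)            # P_0'
    dP_cur <- matrix(1, nc, ns)             # P_1'
    xp <- matrix(1, nc, ns)                 # x^(n-1), n = 1
    xrow <- matrix(rep(x, each = nc), nc, ns)
    acc <- matrix(0, nc, ns)
    for (n in seq_len(max_terms)) {
      term <- M[n] * xp * (n * pr * P_cur + pt * S * dP_cur)
      acc <- acc + term
      scale_ref <- max(abs(acc), .Machine$double.xmin)
      if (n >= 2L && max(abs(term)) < tol * scale_ref) {
        return(acc)
      }
      # advance recurrences to degree n+1
      P_next <- ((2 * n + 1) * C * P_cur - n * P_prev) / (n + 1)
      dP_next <- dP_prev + (2 * n + 1) * P_cur
      P_prev <- P_cur; P_cur <- P_next
      dP_prev <- dP_cur; dP_cur <- dP_next
      xp <- xp * xrow
    }
    stop("spherical-model series did not converge within ", max_terms,
         " terms (tol = ", tol, ")")
  }

  cols <- list()
  for (p3 in moments) {
    pr_s <- rowSums(p3 * rhat_s)            # per source: p . rhat_source
    A <- rhat_e %*% t(p3)                   # per pair:   p . rhat_electrode
    pr <- matrix(rep(pr_s, each = nc), nc, ns)
    pt <- (A - C * pr) / S
    pt[S < 1e-10] <- 0
    cols[[length(cols) + 1L]] <- series_sum(pr, pt)
  }
  if (free) {
    gain <- matrix(0, nc, 3L * ns)
    for (k in 1:3) gain[, seq(k, 3L * ns, by = 3L)] <- cols[[k]]
  } else {
    gain <- cols[[1L]]
  }
  # 1/(4 pi sigma_scalp R^2), potential in volts per A.m, then to uV per nA.m
  sigma_out <- conductivities[length(conductivities)]
  gain <- gain / (4 * pi * sigma_out * R^2) * 1e6 * 1e-9
  leadfield(gain, montage = montage, grid = grid)
}

#' Closed-form homogeneous-sphere surface potential
#'
#' Analytic (series-free) surface potential of a current dipole inside a
#' homogeneous conducting sphere with insulating exterior.  This is the
#' classical closed-form solution that the multi-shell series must approach
#' when all shell conductivities are equal; it is exposed mainly as an
#' independent check of [spherical_leadfield()].
#'
#' @param sensors `n x 3` sensor positions (projected radially onto the
#'   sphere of radius `R`).
#' @param sources `m x 3` dipole locations strictly inside the sphere.
#' @param moments `m x 3` dipole moment vectors (nA.m).
#' @param sigma conductivity in S/m.
#' @param R sphere radius in meters.
#' @return `n x m` matrix of potentials in microvolts.
#' @export
sphere_potential_homogeneous <- function(sensors, sources, moments,
                                         sigma = 0.33, R = 0.1) {
  sens <- as.matrix(sensors)
  sens <- sens * (R / sqrt(rowSums(sens^2)))
  src <- as.matrix(sources)
  p <- as.matrix(moments)
  n <- nrow(sens); m <- nrow(src)
  b <- sqrt(rowSums(src^2))
  if (any(b >= R)) stop("source outside the sphere")
  rhat_e <- sens / R
  rhat_s <- src / ifelse(b > 0, b, 1)
  rhat_s[b == 0, ] <- rep(c(0, 0, 1), each = sum(b == 0))
  C <- pmin(1, pmax(-1, rhat_e %*% t(rhat_s)))
  S <- sqrt(pmax(0, 1 - C^2))
  x <- matrix(rep(b / R, each = n), n, m)
  pr_s <- rowSums(p * rhat_s)
  pr <- matrix(rep(pr_s, each = n), n, m)
  A <- rhat_e %*% t(p)
  pt <- (A - C * pr) / S
  pt[S < 1e-10] <- 0
  d <- sqrt(pmax(0, 1 - 2 * x * C + x^2))
  small <- x < 1e-12
  xs <- x * S
  xs[small | S < 1e-10] <- 1              # guarded; those entries are overridden
  Fr <- (2 * x * (C - x) / d^3 + 1 / d - 1) / ifelse(small, 1, x)
  Fr[small] <- (3 * C)[small]             # central-dipole limit
  Ft <- 2 * S / d^3 + ((x - C) / d + C) / xs
  Ft[small] <- (3 * S)[small]
  Ft[S < 1e-10] <- 0                      # tangential direction undefined, pt = 0
  V <- pr * Fr + pt * Ft
  V / (4 * pi * sigma * R^2) * 1e6 * 1e-9
}

#' Re-reference a lead field to a unipolar reference
#'
#' Applies `T_r = I - 1 f_r'` to an infinity-referenced lead field:
#' `K_r = T_r K_inf`.  Every unipolar reference drops the rank by exactly
#' one: `rank(K_r) = rank(K_inf) - 1`.
#'
#' @param K a [leadfield()] (with `reference_tag = "infinity"`) or a plain
#'   gain matrix.
#' @param f a [ur_weights()] of length `nrow(K)`.
#' @return A [leadfield()] whose `reference_tag` is `f`.
#' @export
reference_leadfield <- function(K, f) {
  stopifnot(inherits(f, "ur_weights"))
  gain <- as_gain(K)
  if (length(f$w) != nrow(gain)) {
    stop("weight vector length ", length(f$w), " does not match ",
         nrow(gain), " lead field rows")
  }
  if (inherits(K, "ur_leadfield") && !identical(K$reference_tag, "infinity")) {
    stop("lead field is not referenced at infinity")
  }
  Tr <- diag(nrow(gain)) - outer(rep(1, nrow(gain)), f$w)
  out <- Tr %*% gain
  if (inherits(K, "ur_leadfield")) {
    leadfield(out, montage = K$montage, grid = K$grid, reference_tag = f)
  } else {
    leadfield(out, reference_tag = f)
  }
}

#' Deviation of the referenced-lead-field pseudoinverse identity
#'
#' For a full-row-rank infinity lead field and any unipolar reference, the
#' projector onto the row space of `K_r = T_r K_inf` equals the row-space
#' projector of `K_inf` minus the rank-one direction `K_inf^+ 1`:
#' `K_r^+ K_r = K_inf^+ K_inf - u u' / (u'u)` with `u = K_inf^+ 1`
#' (a rank-one pseudoinverse-modification identity; note `K_r u = T_r 1 = 0`).
#' Returns the maximum absolute deviation between the two sides, which is at
#' machine-precision level for well-conditioned lead fields.
#'
#' @param K infinity-referenced lead field (object or matrix), full row rank.
#' @param f a [ur_weights()].
#' @return Scalar maximum absolute deviation.
#' @export
kr_pinv_deviation <- function(K, f) {
  gain <- as_gain(K)
  if (mat_rank(gain) < nrow(gain)) stop("lead field is not full row rank")
  Kr <- as_gain(reference_leadfield(gain, f))
  lhs <- pinv(Kr) %*% Kr
  Kp <- pinv(gain)
  u <- Kp %*% rep(1, nrow(gain))
  rhs <- Kp %*% gain - (u %*% t(u)) / sum(u^2)
  max(abs(lhs - rhs))
}
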