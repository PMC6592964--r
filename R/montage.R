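#' Electrode montage
#'
#' An ordered set of channel labels with 3-D sensor positions (meters,
#' head-centered).  The montage fixes the channel ordering used by every
#' operator in the package: reference operators, lead fields and data
#' matrices are all indexed in montage order and never reordered silently.
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix with one row per channel and columns
#'   x, y, z in meters (x right, y anterior, z superior).
#' @return An object of class `ur_montage` with fields `labels`,
#'   `positions` and `n_channels`.
#' @export
#' @examples
#' m <- montage(c("Cz", "Fz"), rbind(c(0, 0, 0.09), c(0, 0.07, 0.05)))
#' m$n_channels
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (length(labels) < 2L) {
    stop("a montage needs at least 2 channels, got ", length(labels))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (nrow(positions) != length(labels) || ncol(positions) != 3L) {
    stop("positions must be a ", length(labels), " x 3 matrix")
  }
  if (!all(is.finite(positions))) stop("non-finite sensor position")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm <= 0)) {
    stop("zero-norm position for channel(s): ",
         paste(labels[nrm <= 0], collapse = ", "))
  }
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  structure(list(labels = labels, positions = positions,
                 n_channels = length(labels)),
            class = "ur_montage")
}

#' Read an electrode montage from an .sfp file
#'
#' Parses the plain-text `.sfp` dialect: one `label x y z` record per line,
#' whitespace-separated, with `#` starting a comment.  Positions are taken
#' as meters.
#'
#' @param path path to the montage file.
#' @return A [montage()] object with channels in file order.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  labels <- character(0)
  pos <- list()
  for (i in seq_along(raw)) {
    line <- sub("#.*$", "", raw[i])
    if (!nzchar(trimws(line))) next
    fields <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(fields) != 4L) {
      stop("line ", i, " of ", path, ": expected 'label x y z', got ",
           length(fields), " field(s)")
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(xyz)) {
      stop("line ", i, " of ", path, ": non-numeric coordinate in '",
           trimws(line), "'")
    }
    labels <- c(labels, fields[1])
    pos[[length(pos) + 1L]] <- xyz
  }
  if (length(labels) == 0L) stop("no channels found in ", path)
  if (anyDuplicated(labels)) {
    stop("duplicate channel label(s) in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  montage(labels, do.call(rbind, pos))
}

#' Standard 19-channel 10-20 montage
#'
#' The classic 19-electrode International 10-20 layout on a spherical scalp
#' of radius 0.1 m, with optional ear/mastoid channels A1, A2 for
#' linked-mastoids referencing.  Positions are the usual idealized spherical
#' 10-20 coordinates, adequate for spherical-model forward calculations.
#'
#' @param mastoids if `TRUE`, append A1 and A2 below the ears.
#' @return A [montage()] object.
#' @export
montage_1020 <- function(mastoids = FALSE) {
  deg <- pi / 180
  r <- 0.1
  ring <- function(incl, az) {                 # incl from vertex, az from +y (nasion), +az to the right
    c(r * sin(incl * deg) * sin(az * deg),
      r * sin(incl * deg) * cos(az * deg),
      r * cos(incl * deg))
  }
  pos <- rbind(
    Fp1 = ring(72, -18), Fp2 = ring(72, 18),
    F7  = ring(72, -54), F3  = c(-0.0345, 0.0674, 0.0653),
    Fz  = ring(36, 0),   F4  = c(0.0345, 0.0674, 0.0653),
    F8  = ring(72, 54),
    T7  = ring(72, -90), C3  = ring(36, -90), Cz = c(0, 0, r),
    C4  = ring(36, 90),  T8  = ring(72, 90),
    P7  = ring(72, -126), P3 = c(-0.0345, -0.0674, 0.0653),
    Pz  = ring(36, 180), P4  = c(0.0345, -0.0674, 0.0653),
    P8  = ring(72, 126),
    O1  = ring(72, -162), O2 = ring(72, 162))
  if (mastoids) {
    pos <- rbind(pos,
                 A1 = c(-0.080, -0.030, -0.045),
                 A2 = c(0.080, -0.030, -0.045))
  }
  montage(rownames(pos), pos)
}

#' @export
print.ur_montage <- function(x, ...) {
  cat("<ur_montage> ", x$n_channels, " channels: ",
      paste(utils::head(x$labels, 8), collapse = ", "),
      if (x$n_channels > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
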