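#' Read a labeled numeric matrix from delimited text
#'
#' The canonical interchange format of the package: one row per channel,
#' first column the channel label, remaining columns numeric samples,
#' tab-separated (configurable).  Parsing is strict: ragged rows and
#' non-numeric or missing cells raise errors naming the offending row and
#' column.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return Numeric matrix with channel labels as rownames.
#' @export
read_eeg_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("empty file: ", path)
  parts <- strsplit(raw, sep, fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != nfield[1])) {
    bad <- which(nfield != nfield[1])[1]
    stop("ragged row ", bad, " in ", path, ": expected ", nfield[1],
         " fields, got ", nfield[bad])
  }
  if (nfield[1] < 2L) stop("no numeric columns in ", path)
  labels <- vapply(parts, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(parts), nfield[1] - 1L)
  for (i in seq_along(parts)) {
    x <- suppressWarnings(as.numeric(parts[[i]][-1L]))
    if (anyNA(x)) {
      j <- which(is.na(x))[1]
      stop("non-numeric or missing value at row ", i, " ('", labels[i],
           "'), sample column ", j, " of ", path)
    }
    vals[i, ] <- x
  }
  rownames(vals) <- labels
  vals
}

#' Write a labeled numeric matrix as delimited text
#'
#' Inverse of [read_eeg_matrix()]: values are printed with 17 significant
#' digits so that a write/read round trip reproduces every double exactly.
#'
#' @param x numeric matrix with rownames (or supply `labels`).
#' @param path output path.
#' @param labels channel labels overriding rownames.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_eeg_matrix <- function(x, path, labels = NULL, sep = "\t") {
  x <- as_data_matrix(x)
  if (is.null(labels)) labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  body <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(paste(labels, body, sep = sep), path)
  invisible(path)
}

#' Write a lead field with sidecar metadata
#'
#' Stores the gain matrix via [write_eeg_matrix()] plus a `<path>.meta`
#' key=value text file recording the reference tag and, when available,
#' grid size and model parameters.
#'
#' @param K a [leadfield()].
#' @param path output path for the gain TSV.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(K, path) {
  stopifnot(inherits(K, "ur_leadfield"))
  write_eeg_matrix(K$gain, path,
                   labels = if (!is.null(K$montage)) K$montage$labels
                            else rownames(K$gain))
  tag <- K$reference_tag
  meta <- c(paste0("n_channels=", nrow(K$gain)),
            paste0("n_source_columns=", ncol(K$gain)))
  if (is.character(tag)) {
    meta <- c(meta, paste0("reference=", tag))
  } else {
    meta <- c(meta, "reference=ur",
              paste0("reference_kind=", tag$kind),
              paste0("reference_weights=",
                     paste(sprintf("%.17g", tag$w), collapse = ",")))
  }
  if (!is.null(K$grid)) {
    meta <- c(meta, paste0("n_sources=", K$grid$n_sources))
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a lead field written by [write_leadfield()]
#'
#' @param path path to the gain TSV (the `<path>.meta` sidecar is read when
#'   present).
#' @return A [leadfield()]; without a sidecar the reference tag defaults to
#'   `"infinity"`.
#' @export
read_leadfield <- function(path) {
  gain <- read_eeg_matrix(path)
  tag <- "infinity"
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    kv <- readLines(meta_path, warn = FALSE)
    kv <- kv[grepl("=", kv, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    meta <- stats::setNames(as.list(vals), keys)
    if (identical(meta$reference, "ur")) {
      w <- as.numeric(strsplit(meta$reference_weights, ",")[[1]])
      tag <- ur_weights("custom", weights = w)
      tag$kind <- if (!is.null(meta$reference_kind)) meta$reference_kind
                  else "custom"
    } else if (!is.null(meta$reference)) {
      tag <- meta$reference
    }
  }
  leadfield(gain, reference_tag = tag)
}

#' Batch check of the unipolar-reference properties
#'
#' Runs the full property suite on a seeded random lead field (and any
#' supplied lead field): weight normalization, the 4 x 4 no-memory sweep
#' over RR, LM, AR and REST, rank deficiency by one, projector centering,
#' and the equivalence of the composed and unipolar REST routes.  Intended
#' as a one-shot validation entry point (used by the command-line
#' `check-properties` command).
#'
#' @param n_channels number of channels (>= 2).
#' @param seed RNG seed for the random lead field.
#' @param K optional additional infinity-referenced lead field to test
#'   (e.g. a spherical one).
#' @param extra_weights optional named list of raw weight vectors to force
#'   into the no-memory sweep unvalidated (negative controls: a vector not
#'   summing to 1 must fail).
#' @return A list with `results` (named numeric deviations / rank checks),
#'   `tolerances`, and `pass` (logical).
#' @export
check_ur_properties <- function(n_channels = 19, seed = 1, K = NULL,
                                extra_weights = NULL) {
  n <- as.integer(n_channels)
  if (n < 2L) stop("n_channels must be >= 2")
  set.seed(as.integer(seed))
  Krand <- matrix(stats::rnorm(n * 10L * n), n, 10L * n)
  Ks <- list(random = Krand)
  if (!is.null(K)) Ks$supplied <- as_gain(K)

  make_family <- function(gain) {
    anchors <- c(1L, if (n >= 3L) 2L else 1L, min(3L, n))
    list(RR = ur_weights("RR", n_channels = n, anchors = anchors[1]),
         LM = ur_weights("LM", n_channels = n,
                         anchors = c(anchors[1], anchors[3])),
         AR = ur_weights("AR", n_channels = n),
         REST = rest_weights(gain))
  }

  res <- c()
  for (nm in names(Ks)) {
    gain <- Ks[[nm]]
    fam <- make_family(gain)
    ops <- lapply(fam, ur_operator)
    res[paste0(nm, ".weight_sum_dev")] <-
      max(vapply(fam, function(f) abs(sum(f$w) - 1), numeric(1)))
    mats <- lapply(ops, `[[`, "matrix")
    if (!is.null(extra_weights)) {
      for (en in names(extra_weights)) {
        w <- as.numeric(extra_weights[[en]])
        mats[[en]] <- diag(n) - outer(rep(1, n), w)
      }
    }
    nm_dev <- 0
    for (a in seq_along(mats)) {
      for (b in seq_along(mats)) {
        nm_dev <- max(nm_dev, max(abs(mats[[a]] - mats[[a]] %*% mats[[b]])))
      }
    }
    res[paste0(nm, ".no_memory_dev")] <- nm_dev
    res[paste0(nm, ".rank_deficiency_dev")] <-
      max(vapply(ops, function(o) abs(rank_deficiency(o) - 1L), numeric(1)))
    res[paste0(nm, ".centering_dev")] <-
      max(vapply(ops, centering_deviation, numeric(1)))
    T_uni <- rest_operator(gain, "unipolar")
    res[paste0(nm, ".rest_route_dev")] <-
      max(vapply(fam, function(f) {
        max(abs(rest_operator(gain, "composed", f) - T_uni))
      }, numeric(1)))
  }
  tol <- c(weight_sum_dev = 1e-12, no_memory_dev = 1e-12,
           rank_deficiency_dev = 0, centering_dev = 1e-10,
           rest_route_dev = 1e-9)
  ok <- vapply(names(res), function(k) {
    res[[k]] <= tol[[sub("^[^.]*\\.", "", k)]]
  }, logical(1))
  list(results = res, tolerances = tol, pass = all(ok), detail = ok)
}
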