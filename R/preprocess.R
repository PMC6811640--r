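# Correction arithmetic (flat field, background, autofluorescence),
# the cell-fluorescence summary, the per-cell bi-exponential fit, and
# quality filtering. The canonical correction order is: flat field,
# then background, then autofluorescence.

#' Flat-field correction
#'
#' Element-wise division of an image (or any numeric array) by a flat-field
#' image normalized to median one, removing inhomogeneous illumination.
#'
#' @param pixels Numeric array of raw pixel values.
#' @param flatfield Numeric array of the same shape, strictly positive.
#'
#' @return Corrected pixels (same shape).
#' @export
flatfield_correct <- function(pixels, flatfield) {
  if (!identical(dim(pixels), dim(flatfield)) &&
      length(pixels) != length(flatfield)) {
    stop("pixels and flatfield must have matching shapes")
  }
  if (any(flatfield <= 0)) {
    stop("flatfield must be strictly positive everywhere")
  }
  pixels / flatfield
}

#' Background subtraction
#'
#' Subtracts the mean pixel value of a cell-free region from a trace or
#' pixel array. Negative results are preserved: the measurement-noise model
#' has support for negative fluorescence.
#'
#' @param x Numeric trace values or pixel array.
#' @param background_level Scalar background level (camera units).
#'
#' @return `x - background_level`.
#' @export
background_subtract <- function(x, background_level) {
  stopifnot(is.numeric(background_level), length(background_level) == 1,
            is.finite(background_level))
  x - background_level
}

#' Cell fluorescence summary from in-mask pixels
#'
#' The fluorescence of a cell is the sum of the brightest 80% of the pixels
#' within its boundary (this truncation reduces sensitivity to small stage
#' movements). The pixel count is `ceiling(0.8 * n)`.
#'
#' @param pixels Numeric vector of pixel values inside the cell mask.
#' @param top_fraction Fraction of brightest pixels to keep (default 0.8).
#'
#' @return Scalar fluorescence value.
#' @export
#' @examples
#' cell_fluorescence(1:10)  # top 8 pixels: 3..10, sum 52
cell_fluorescence <- function(pixels, top_fraction = 0.8) {
  if (length(pixels) < 1) stop("empty pixel mask")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  k <- ceiling(top_fraction * length(pixels))
  sum(sort(pixels, decreasing = TRUE)[seq_len(k)])
}

#' Autofluorescence correction using wild-type cells
#'
#' Subtracts, at each time point, the mean fluorescence of bleached
#' wild-type (non-fluorescent) cells from every tagged cell. Both inputs
#' must already be flat-field and background corrected and share the same
#' time grid.
#'
#' @param traces Long-format data.frame (`cell_id`, `time_s`,
#'   `fluorescence`) of tagged cells.
#' @param wildtype_traces Same format, wild-type cells.
#'
#' @return `traces` with the per-time wild-type mean subtracted.
#' @export
autofluorescence_correct <- function(traces, wildtype_traces) {
  check_trace_frame(traces)
  check_trace_frame(wildtype_traces)
  grid <- sort(unique(traces$time_s))
  wt_grid <- sort(unique(wildtype_traces$time_s))
  if (length(grid) != length(wt_grid) ||
      any(abs(grid - wt_grid) > 1e-9)) {
    stop("wild-type traces do not share the sample time grid")
  }
  wt_mean <- tapply(wildtype_traces$fluorescence, wildtype_traces$time_s,
                    mean)
  idx <- match(as.character(traces$time_s), names(wt_mean))
  if (anyNA(idx)) stop("time grid mismatch between samples and wild type")
  out <- traces
  out$fluorescence <- traces$fluorescence - as.numeric(wt_mean[idx])
  out
}

# Residual sum of squares of the bi-exponential model on frame index i.
biexp_rss <- function(par, i, y) {
  pred <- par[1] + par[2] * par[4]^i + par[3] * par[5]^i
  sum((y - pred)^2)
}

#' Fit a bi-exponential bleaching curve to one trace
#'
#' Least-squares fit of `f_i = a0 + a1 * l1^i + a2 * l2^i` over the frame
#' index `i = 0, 1, ...`, with per-frame survival factors constrained to
#' `(0, 1]`. The two components are returned in canonical order
#' `l1 >= l2` (slow pool first) to break the relabeling symmetry.
#' Initialization comes from log-linear fits of the late and early thirds
#' of the trace, with random multi-starts on failure.
#'
#' @param values Fluorescence values ordered by frame.
#' @param n_starts Number of additional random restarts (default 3).
#'
#' @return A list of class `biexp_fit` with `a0`, `a1`, `a2`, `ell1`,
#'   `ell2`, `rss`, `converged`.
#' @export
fit_biexponential <- function(values, n_starts = 3) {
  y <- as.numeric(values)
  n <- length(y)
  if (n < 6) stop("need at least 6 time points to fit 5 parameters")
  i <- seq_len(n) - 1

  # Variable-projection initialization: for fixed survival factors the
  # model is linear in the amplitudes, so scan a coarse (l1, l2) grid,
  # solve the amplitudes by least squares, and start from the best pair.
  grid_l1 <- c(0.999, 0.99, 0.97, 0.94)
  grid_l2 <- c(0.92, 0.85, 0.75, 0.6, 0.4)
  best_start <- NULL
  best_rss <- Inf
  for (l1 in grid_l1) {
    for (l2 in grid_l2[grid_l2 < l1]) {
      X <- cbind(1, l1^i, l2^i)
      co <- tryCatch(stats::lm.fit(X, y)$coefficients,
                     error = function(e) NULL)
      if (is.null(co) || anyNA(co)) next
      rss0 <- sum((y - X %*% co)^2)
      if (rss0 < best_rss) {
        best_rss <- rss0
        best_start <- c(a0 = unname(co[1]), a1 = max(unname(co[2]), 1e-6),
                        a2 = max(unname(co[3]), 1e-6), ell1 = l1,
                        ell2 = l2)
      }
    }
  }
  start0 <- best_start

  lower <- c(-Inf, 0, 0, 1e-6, 1e-6)
  upper <- c(Inf, Inf, Inf, 1, 1)
  run_fit <- function(start) {
    df <- data.frame(i = i, y = y)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ a0 + a1 * ell1^i + a2 * ell2^i,
        data = df,
        start = as.list(start),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  fits <- list(run_fit(start0))
  for (s in seq_len(n_starts)) {
    jit <- start0 * exp(stats::rnorm(5, 0, 0.3))
    jit[1] <- start0[1] + stats::rnorm(1, 0, max(abs(start0[1]), 1) * 0.3)
    jit[4] <- min(max(jit[4], 1e-4), 1)
    jit[5] <- min(max(jit[5], 1e-4), 1)
    fits <- c(fits, list(run_fit(jit)))
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    return(structure(
      list(a0 = NA_real_, a1 = NA_real_, a2 = NA_real_,
           ell1 = NA_real_, ell2 = NA_real_, rss = NA_real_,
           converged = FALSE),
      class = "biexp_fit"))
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- stats::coef(fits[[which.min(rss)]])
  # canonical order: component 1 is the slower (larger survival factor)
  if (best["ell1"] < best["ell2"]) {
    best[c("a1", "a2")] <- best[c("a2", "a1")]
    best[c("ell1", "ell2")] <- best[c("ell2", "ell1")]
  }
  structure(
    list(a0 = unname(best["a0"]), a1 = unname(best["a1"]),
         a2 = unname(best["a2"]), ell1 = unname(best["ell1"]),
         ell2 = unname(best["ell2"]), rss = min(rss), converged = TRUE),
    class = "biexp_fit"
  )
}

#' Quality-filter traces for sudden artefactual drops
#'
#' Rejects a cell when any single-frame decrement exceeds `threshold` times
#' that cell's robust frame-to-frame scale (the median absolute successive
#' difference). This quantifies the qualitative criterion of discarding
#' cells with large systematic deviations such as a sudden drop in
#' fluorescence; the default multiple of 5 is a configurable stand-in, not
#' an experimentally derived constant.
#'
#' @param traces Long-format data.frame (`cell_id`, `time_s`,
#'   `fluorescence`).
#' @param threshold Rejection multiple (default 5); `Inf` disables.
#'
#' @return A list with `kept` (filtered data.frame) and `rejections`
#'   (data.frame: `cell_id`, `reason`, `max_drop`, `scale`).
#' @export
qc_filter <- function(traces, threshold = 5) {
  check_trace_frame(traces)
  ids <- unique(traces$cell_id)
  rej <- list()
  keep <- logical(length(ids))
  for (k in seq_along(ids)) {
    y <- traces$fluorescence[traces$cell_id == ids[k]]
    d <- diff(y)
    scale <- stats::median(abs(d))
    max_drop <- if (any(d < 0)) max(-d[d < 0]) else 0
    bad <- is.finite(threshold) && scale > 0 && max_drop > threshold * scale
    keep[k] <- !bad
    if (bad) {
      rej[[length(rej) + 1]] <- data.frame(
        cell_id = ids[k], reason = "sudden drop",
        max_drop = max_drop, scale = scale, stringsAsFactors = FALSE)
    }
  }
  rejections <- if (length(rej) > 0) do.call(rbind, rej) else
    data.frame(cell_id = character(), reason = character(),
               max_drop = numeric(), scale = numeric(),
               stringsAsFactors = FALSE)
  list(kept = traces[traces$cell_id %in% ids[keep], , drop = FALSE],
       rejections = rejections)
}
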