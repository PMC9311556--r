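# Empirical mode decomposition by iterative sifting.

#' Locate strict local extrema of a signal
#'
#' Extrema are detected as sign changes of the first difference. Runs of
#' equal values (plateaus) are collapsed to a single candidate extremum at
#' the plateau midpoint, so a flat top counts once and never produces
#' duplicate spline knots.
#'
#' @param x Numeric vector.
#' @return A list with integer index vectors `maxima` and `minima`.
#' @export
find_extrema <- function(x) {
  stopifnot(is.numeric(x))
  r <- rle(as.numeric(x))
  v <- r$values
  if (length(v) < 3L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  d <- sign(diff(v))
  # interior turning points of the collapsed series
  up_down <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  down_up <- which(d[-length(d)] < 0 & d[-1] > 0) + 1L
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- as.integer((starts + ends) %/% 2L)
  list(maxima = mid[up_down], minima = mid[down_up])
}

#' Count local extrema and zero crossings
#'
#' Counts strict local maxima and minima (plateaus collapsed to their
#' midpoint) and strict sign changes. Exact zeros are attached to the
#' preceding sign, so a signal touching zero without changing sign does not
#' register a crossing.
#'
#' @param x Numeric vector of length at least 3.
#' @return Named integer vector with elements `maxima`, `minima`,
#'   `zero_crossings`.
#' @export
count_extrema_crossings <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3L)
  ex <- find_extrema(x)
  s <- sign(x)
  s <- s[s != 0]       # dropping zeros == attaching them to the preceding sign
  zc <- if (length(s) < 2L) 0L else sum(s[-1L] != s[-length(s)])
  c(maxima = length(ex$maxima), minima = length(ex$minima),
    zero_crossings = as.integer(zc))
}

# TRUE when x satisfies the defining IMF count condition:
# |#maxima + #minima - #zero crossings| <= 1.
is_imf_candidate <- function(x) {
  k <- count_extrema_crossings(x)
  abs(k[["maxima"]] + k[["minima"]] - k[["zero_crossings"]]) <= 1L
}

# Classed condition raised when a candidate has too few extrema to envelope.
monotonic_residual_error <- function(call = sys.call(-1)) {
  structure(
    class = c("copemd_monotonic_residual", "error", "condition"),
    list(message = "signal has fewer than 2 maxima or 2 minima: monotonic residual",
         call = call)
  )
}

# Natural cubic spline through (idx, val) after mirroring the `n_mirror`
# extrema nearest each end across the signal boundaries, evaluated at 1..n.
spline_envelope <- function(idx, val, n, n_mirror = 2L) {
  m <- min(n_mirror, length(idx))
  left_x <- 2 - idx[seq_len(m)]
  left_y <- val[seq_len(m)]
  right_x <- 2 * n - idx[length(idx) - seq_len(m) + 1L]
  right_y <- val[length(idx) - seq_len(m) + 1L]
  xs <- c(left_x, idx, right_x)
  ys <- c(left_y, val, right_y)
  keep <- !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  o <- order(xs)
  stats::spline(xs[o], ys[o], method = "natural", xout = seq_len(n))$y
}

#' One sifting step
#'
#' Subtracts from the candidate the mean of its upper and lower envelopes.
#' Envelopes are natural cubic splines through the local maxima (upper) and
#' minima (lower), after mirroring the two extrema nearest each end across
#' the signal boundary to tame end effects.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @return Numeric vector of the same length: `x` minus the envelope mean.
#'   Signals a classed error (`copemd_monotonic_residual`) when too few
#'   extrema exist, which tells the decomposition loop to stop.
#' @export
sift_once <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
    stop(monotonic_residual_error())
  }
  n <- length(x)
  upper <- spline_envelope(ex$maxima, x[ex$maxima], n)
  lower <- spline_envelope(ex$minima, x[ex$minima], n)
  x - (upper + lower) / 2
}

#' Decompose a signal into intrinsic mode functions
#'
#' Plain (non-ensemble) EMD. Each mode is obtained by sifting the current
#' residual until a Cauchy-type criterion
#' \eqn{SD = \sum (h_{prev}-h_{cur})^2 / \sum h_{prev}^2 < sd\_tol}
#' is met and the candidate satisfies the IMF extrema/zero-crossing count
#' condition, with a hard iteration cap guaranteeing termination. The mode is
#' subtracted and extraction continues on the residual until `max_imfs` modes
#' exist or the residual has fewer than two extrema of either kind.
#'
#' The returned modes are ordered from highest to lowest frequency; the sum of
#' all modes plus the residual reconstructs the input to machine precision.
#'
#' @param x Numeric signal, length >= 16, finite, non-constant.
#' @param max_imfs Maximum number of modes to extract (pipeline default 8).
#' @param sd_tol Sifting stop threshold on the Cauchy criterion (default 0.2).
#' @param max_sifts Hard cap on sifting iterations per mode (default 100).
#' @return An object of class `imf_set`: list with `imfs` (length-n columns,
#'   one per mode; zero columns when nothing oscillatory exists), `residual`,
#'   `n_imfs`, `source_length`, and `n_sifts` (iterations spent per mode).
#' @export
emd_decompose <- function(x, max_imfs = 8L, sd_tol = 0.2, max_sifts = 100L) {
  stopifnot(is.numeric(x), max_imfs >= 1L)
  if (length(x) < 16L || any(!is.finite(x))) {
    stop("signal must be finite and have length >= 16")
  }
  if (max(x) == min(x)) stop("constant signal cannot be decomposed")
  n <- length(x)
  residual <- as.numeric(x)
  imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  n_sifts <- integer(0)

  for (k in seq_len(max_imfs)) {
    ex <- find_extrema(residual)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
    h <- residual
    iters <- 0L
    repeat {
      h_new <- tryCatch(sift_once(h),
                        copemd_monotonic_residual = function(e) NULL)
      if (is.null(h_new)) break
      iters <- iters + 1L
      sd_crit <- sum((h - h_new)^2) / sum(h^2)
      h <- h_new
      if (iters >= max_sifts) break
      if (sd_crit < sd_tol && is_imf_candidate(h)) break
    }
    if (iters == 0L) break
    imfs <- cbind(imfs, h)
    n_sifts <- c(n_sifts, iters)
    residual <- residual - h
  }

  colnames(imfs) <- if (ncol(imfs) > 0) paste0("imf", seq_len(ncol(imfs))) else NULL
  structure(
    list(imfs = imfs, residual = residual, n_imfs = ncol(imfs),
         source_length = n, n_sifts = n_sifts),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, source length %d\n",
              x$n_imfs, x$source_length))
  if (x$n_imfs > 0) {
    cat("  sift iterations per IMF:", paste(x$n_sifts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.imf_set <- function(x, ...) {
  m <- cbind(x$imfs, residual = x$residual)
  colnames(m) <- c(colnames(x$imfs), "residual")
  m
}

#' Write a decomposition as a delimited text matrix
#'
#' One column per IMF plus the residual, tab-separated with a header row,
#' for external inspection of a decomposition.
#'
#' @param x An `imf_set`.
#' @param path Output file path.
#' @export
write_imfs <- function(x, path) {
  stopifnot(inherits(x, "imf_set"))
  utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
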