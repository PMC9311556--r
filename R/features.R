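# Temporal and spectral sway descriptors, and per-subject feature assembly.

FEATURE_NAMES <- c("sigma_t", "beta_t", "kurt_t", "C_s", "beta_s", "kurt_s")
DIRECTIONS <- c("ML", "AP")

degenerate_error <- function(msg, call = sys.call(-1)) {
  structure(class = c("copemd_degenerate", "error", "condition"),
            list(message = msg, call = call))
}

#' Temporal descriptors of a sway signal
#'
#' Standard deviation, skewness and kurtosis with population (1/N)
#' normalisation and non-excess kurtosis (a Gaussian signal has kurtosis 3):
#' \deqn{\sigma_t = \sqrt{\tfrac1N \sum (x_i-\mu)^2},\quad
#'       \beta_t  = \tfrac1N \sum \left(\tfrac{x_i-\mu}{\sigma}\right)^3,\quad
#'       Kurt_t   = \tfrac1N \sum \left(\tfrac{x_i-\mu}{\sigma}\right)^4.}
#'
#' @param x Numeric vector, length >= 2, not constant.
#' @return Named numeric vector `c(sigma_t, beta_t, kurt_t)`.
#' @export
temporal_features <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)
  if (sigma == 0) stop(degenerate_error("constant signal: sigma_t is zero"))
  z <- (x - mu) / sigma
  c(sigma_t = sigma, beta_t = sum(z^3) / n, kurt_t = sum(z^4) / n)
}

#' One-sided amplitude spectrum
#'
#' Magnitude of the discrete Fourier transform of the mean-removed signal,
#' positive-frequency bins only, DC excluded. No window or detrend beyond
#' mean removal is applied.
#'
#' @param x Numeric signal, length >= 16.
#' @param sampling_rate Sampling rate in Hz.
#' @return Object of class `cop_spectrum`: list with `freq` (Hz, strictly
#'   increasing) and `amp` (non-negative amplitudes).
#' @export
amplitude_spectrum <- function(x, sampling_rate) {
  stopifnot(is.numeric(x), length(x) >= 16L, sampling_rate > 0)
  n <- length(x)
  xc <- x - mean(x)
  X <- stats::fft(xc)
  half <- n %/% 2L
  idx <- seq(2L, half + 1L)          # bins 1..half; DC (bin 0) excluded
  structure(
    list(freq = (idx - 1L) * sampling_rate / n, amp = Mod(X[idx]),
         sampling_rate = sampling_rate, n = n),
    class = "cop_spectrum"
  )
}

#' Spectral descriptors of an amplitude spectrum
#'
#' Amplitude-weighted moments of frequency: the spectral centroid (center of
#' mass of the spectrum), and the skewness and kurtosis of the spectral
#' energy distribution standardised by the spectral spread
#' \eqn{\sigma_s = \sqrt{\sum (w - C_s)^2 P(w) / \sum P(w)}}:
#' \deqn{C_s = \frac{\sum_w w P(w)}{\sum_w P(w)},\quad
#'       \beta_s = \frac{\sum_w ((w-C_s)/\sigma_s)^3 P(w)}{\sum_w P(w)},\quad
#'       Kurt_s = \frac{\sum_w ((w-C_s)/\sigma_s)^4 P(w)}{\sum_w P(w)}.}
#'
#' @param s A `cop_spectrum`, or a numeric vector of frequencies.
#' @param amp Amplitudes, when `s` is a plain frequency vector.
#' @return Named numeric vector `c(C_s, beta_s, kurt_s)`.
#' @export
spectral_features <- function(s, amp = NULL) {
  if (inherits(s, "cop_spectrum")) {
    w <- s$freq; p <- s$amp
  } else {
    w <- as.numeric(s); p <- as.numeric(amp)
  }
  stopifnot(length(w) == length(p), all(p >= 0))
  total <- sum(p)
  if (total <= 0) stop(degenerate_error("spectrum has zero total amplitude"))
  cs <- sum(w * p) / total
  sigma_s <- sqrt(sum((w - cs)^2 * p) / total)
  if (sigma_s == 0) {
    stop(degenerate_error("single-bin spectrum: spectral spread is zero"))
  }
  z <- (w - cs) / sigma_s
  c(C_s = cs, beta_s = sum(z^3 * p) / total, kurt_s = sum(z^4 * p) / total)
}

#' All six descriptors of one signal
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @return Named numeric vector of the three temporal followed by the three
#'   spectral descriptors.
#' @export
signal_features <- function(x, sampling_rate) {
  c(temporal_features(x), spectral_features(amplitude_spectrum(x, sampling_rate)))
}

#' Assemble the per-subject feature vector
#'
#' Features are computed per direction (ML, AP) from the raw signal and/or
#' from its first `max_imfs` intrinsic mode functions, each mode contributing
#' its own temporal and spectral block. Name layout is fixed:
#' `<direction>.<source>.<feature>` with directions in order ML, AP; sources
#' `raw` then `imf1..imf<max_imfs>` (as the mode requires); features
#' `sigma_t, beta_t, kurt_t, C_s, beta_s, kurt_s`. Raw mode yields 12 values,
#' EMD mode `6 * 2 * max_imfs` (96 by default), combined mode both. When a
#' signal yields fewer than `max_imfs` modes the missing blocks are
#' zero-filled with a warning so the layout never varies.
#'
#' @param rec A `stabilogram_recording`.
#' @param imfs Optional named list with elements `ML` and `AP`, each an
#'   `imf_set` for the corresponding direction; computed on the fly when
#'   omitted and the mode requires modes.
#' @param mode `"raw"`, `"emd"` or `"raw+emd"`.
#' @param max_imfs Number of mode blocks per direction (default 8).
#' @return Named numeric vector with attributes `subject_id` and `label`.
#' @export
build_feature_vector <- function(rec, imfs = NULL,
                                 mode = c("emd", "raw", "raw+emd"),
                                 max_imfs = 8L) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "stabilogram_recording"))
  use_raw <- mode %in% c("raw", "raw+emd")
  use_emd <- mode %in% c("emd", "raw+emd")
  rate <- rec$sampling_rate
  out <- numeric(0)

  for (dir in DIRECTIONS) {
    x <- if (dir == "ML") rec$ml else rec$ap
    if (use_raw) {
      f <- tryCatch(signal_features(x, rate), copemd_degenerate = function(e) {
        stop(degenerate_error(sprintf("block %s.raw: %s", dir, conditionMessage(e))))
      })
      names(f) <- paste(dir, "raw", FEATURE_NAMES, sep = ".")
      out <- c(out, f)
    }
    if (use_emd) {
      dec <- if (!is.null(imfs)) imfs[[dir]] else emd_decompose(x, max_imfs = max_imfs)
      stopifnot(inherits(dec, "imf_set"))
      if (dec$n_imfs < max_imfs) {
        warning(sprintf(
          "%s: only %d of %d IMFs available for direction %s; zero-filling missing blocks",
          rec$subject_id, dec$n_imfs, max_imfs, dir))
      }
      for (k in seq_len(max_imfs)) {
        f <- if (k <= dec$n_imfs) {
          tryCatch(signal_features(dec$imfs[, k], rate),
                   copemd_degenerate = function(e) {
                     stop(degenerate_error(sprintf("block %s.imf%d: %s",
                                                   dir, k, conditionMessage(e))))
                   })
        } else {
          stats::setNames(rep(0, 6L), FEATURE_NAMES)
        }
        names(f) <- paste(dir, paste0("imf", k), FEATURE_NAMES, sep = ".")
        out <- c(out, f)
      }
    }
  }
  attr(out, "subject_id") <- rec$subject_id
  attr(out, "label") <- rec$label
  out
}

#' Feature matrix for a cohort of recordings
#'
#' Runs [build_feature_vector()] over a list of recordings and stacks the
#' results, decomposing each direction once.
#'
#' @param recordings List of `stabilogram_recording` objects.
#' @param mode,max_imfs Passed to [build_feature_vector()].
#' @return A data.frame with columns `subject_id`, `label`, then one column
#'   per feature in the fixed layout.
#' @export
build_feature_matrix <- function(recordings, mode = c("emd", "raw", "raw+emd"),
                                 max_imfs = 8L) {
  mode <- match.arg(mode)
  rows <- lapply(recordings, function(rec) {
    imfs <- NULL
    if (mode %in% c("emd", "raw+emd")) {
      imfs <- list(ML = emd_decompose(rec$ml, max_imfs = max_imfs),
                   AP = emd_decompose(rec$ap, max_imfs = max_imfs))
    }
    build_feature_vector(rec, imfs = imfs, mode = mode, max_imfs = max_imfs)
  })
  vals <- do.call(rbind, rows)
  df <- data.frame(
    subject_id = vapply(recordings, function(r) r$subject_id, character(1)),
    label = vapply(recordings, function(r) as.character(r$label), character(1)),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  rownames(df) <- NULL
  df
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated, header row of feature names, one row per subject, with
#' `subject_id` and `label` leading columns. `read_feature_matrix()` inverts
#' [write_feature_matrix()] exactly.
#'
#' @param df Feature matrix data.frame.
#' @param path File path.
#' @export
write_feature_matrix <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
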