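# Synthetic two-direction COP cohorts with class-dependent spectral content.

#' Class-conditional sway parameters
#'
#' Each direction of a simulated recording is the sum of four components:
#' a slow postural drift (white noise through a second-order low-pass,
#' cutoff 0.5 Hz, rescaled to `drift_sd`), band-limited sway in 0.5-2 Hz
#' rescaled to `sway_sd`, an optional tremor tone with frequency drawn
#' uniformly from `tremor_band` (Hz) and amplitude `tremor_amp`, and white
#' measurement noise with standard deviation `noise_sd`. All amplitudes are
#' in millimetres. Healthy defaults carry no tremor; a parkinsonian tremor
#' band of 4-6 Hz with amplitude ~1 mm gives the disease class its distinct
#' spectral signature.
#'
#' @param drift_sd Drift component standard deviation (mm).
#' @param sway_sd Sway-band component standard deviation (mm).
#' @param tremor_amp Tremor tone amplitude (mm); 0 disables the tone.
#' @param tremor_band Length-2 frequency band (Hz) the tremor frequency is
#'   drawn from; must lie below the Nyquist frequency.
#' @param noise_sd Measurement noise standard deviation (mm).
#' @return A list of class `cop_class_params`.
#' @export
class_params <- function(drift_sd = 3, sway_sd = 1.5, tremor_amp = 0,
                         tremor_band = c(4, 6), noise_sd = 0.3) {
  stopifnot(drift_sd >= 0, sway_sd >= 0, tremor_amp >= 0, noise_sd >= 0,
            length(tremor_band) == 2L, tremor_band[1] <= tremor_band[2],
            all(tremor_band > 0))
  structure(list(drift_sd = drift_sd, sway_sd = sway_sd,
                 tremor_amp = tremor_amp, tremor_band = tremor_band,
                 noise_sd = noise_sd),
            class = "cop_class_params")
}

#' Cohort specification
#'
#' Defaults mirror a typical posturographic study design: 28 healthy subjects
#' and 32 Parkinson's patients, quiet standing for 60 s. The default sampling
#' rate is 100 Hz, which preserves all spectral content of interest (sway and
#' tremor both live well below 50 Hz) while keeping decomposition times in
#' seconds; force-plate rates such as 1000 Hz are available by argument.
#'
#' @param n_healthy,n_pd Subject counts per class.
#' @param duration Recording duration in seconds (default 60).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param healthy,pd `cop_class_params` for each class.
#' @param seed Master seed; per-subject seeds are derived from it with
#'   [derive_seed()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 28L, n_pd = 32L, duration = 60,
                        sampling_rate = 100,
                        healthy = class_params(),
                        pd = class_params(tremor_amp = 1),
                        seed = 1L) {
  stopifnot(n_healthy >= 0, n_pd >= 0, duration > 0, sampling_rate > 0,
            inherits(healthy, "cop_class_params"),
            inherits(pd, "cop_class_params"))
  for (p in list(healthy, pd)) {
    if (p$tremor_band[2] >= sampling_rate / 2) {
      stop("tremor band must lie below the Nyquist frequency")
    }
  }
  structure(list(n_healthy = as.integer(n_healthy), n_pd = as.integer(n_pd),
                 duration = duration, sampling_rate = sampling_rate,
                 healthy = healthy, pd = pd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# White noise shaped by a Butterworth filter, rescaled to a target sd.
shaped_noise <- function(n, filt, target_sd) {
  if (target_sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  y <- as.numeric(signal::filter(filt, w))
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s * target_sd
}

#' Simulate one COP recording
#'
#' Deterministic given `seed`. Both directions receive independent drift,
#' sway, noise, and (when `tremor_amp > 0`) tremor tones with independent
#' phases; the tremor frequency is drawn once per direction from
#' `tremor_band`.
#'
#' @param subject_id Identifier.
#' @param label `"Healthy"` or `"PD"` (label only tags the recording; the
#'   spectral content comes entirely from `params`).
#' @param params A `cop_class_params`.
#' @param duration Seconds.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return A `stabilogram_recording`.
#' @export
simulate_recording <- function(subject_id, label, params, duration = 60,
                               sampling_rate = 100, seed = 1L) {
  stopifnot(inherits(params, "cop_class_params"))
  n <- round(duration * sampling_rate)
  nyq <- sampling_rate / 2
  lp <- signal::butter(2, 0.5 / nyq, type = "low")
  bp <- signal::butter(2, c(0.5, 2) / nyq, type = "pass")
  t <- (seq_len(n) - 1L) / sampling_rate
  with_seed(seed, {
    chan <- lapply(1:2, function(d) {
      drift <- shaped_noise(n, lp, params$drift_sd)
      sway <- shaped_noise(n, bp, params$sway_sd)
      tremor <- if (params$tremor_amp > 0) {
        f <- stats::runif(1, params$tremor_band[1], params$tremor_band[2])
        phi <- stats::runif(1, 0, 2 * pi)
        params$tremor_amp * sin(2 * pi * f * t + phi)
      } else numeric(n)
      noise <- stats::rnorm(n, 0, params$noise_sd)
      drift + sway + tremor + noise
    })
    stabilogram_recording(subject_id, ml = chan[[1]], ap = chan[[2]],
                          sampling_rate = sampling_rate, label = label)
  })
}

#' Simulate a labelled cohort
#'
#' Generates `n_healthy + n_pd` recordings with per-subject seeds derived
#' from the master seed, plus a manifest. Regenerating from the same spec is
#' bit-identical.
#'
#' @param spec A `cohort_spec`.
#' @return A list of class `cop_cohort`: `recordings` (list), `manifest`
#'   (data.frame with subject_id, label, seed), and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_healthy + spec$n_pd
  labels <- c(rep("Healthy", spec$n_healthy), rep("PD", spec$n_pd))
  ids <- sprintf("S%03d", seq_len(n_total))
  seeds <- vapply(seq_len(n_total), function(i) derive_seed(spec$seed, i),
                  integer(1))
  recordings <- lapply(seq_len(n_total), function(i) {
    params <- if (labels[i] == "Healthy") spec$healthy else spec$pd
    simulate_recording(ids[i], labels[i], params, spec$duration,
                       spec$sampling_rate, seeds[i])
  })
  structure(
    list(recordings = recordings,
         manifest = data.frame(subject_id = ids, label = labels, seed = seeds,
                               stringsAsFactors = FALSE),
         spec = spec),
    class = "cop_cohort"
  )
}

#' @export
print.cop_cohort <- function(x, ...) {
  cat(sprintf("<cop_cohort> %d recordings (%d Healthy, %d PD), %.0f s at %g Hz\n",
              nrow(x$manifest), sum(x$manifest$label == "Healthy"),
              sum(x$manifest$label == "PD"), x$spec$duration,
              x$spec$sampling_rate))
  invisible(x)
}

#' Write / read a cohort as delimited text files
#'
#' One file per subject (via [write_recording()]) plus `manifest.tsv` listing
#' subject_id, label, per-subject seed and file name, with the master seed
#' recorded in a comment header.
#'
#' @param cohort A `cop_cohort`.
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cop_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(cohort$manifest$subject_id, ".tsv")
  for (i in seq_along(cohort$recordings)) {
    write_recording(cohort$recordings[[i]], file.path(dir, files[i]))
  }
  man <- cbind(cohort$manifest, file = files)
  con <- file(file.path(dir, "manifest.tsv"), "w")
  on.exit(close(con))
  writeLines(sprintf("# master_seed: %d", cohort$spec$seed), con)
  utils::write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop(sprintf("no manifest.tsv in %s", dir))
  man <- utils::read.table(man_path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(man)), function(i) {
    read_recording(file.path(dir, man$file[i]), subject_id = man$subject_id[i],
                   label = man$label[i])
  })
  list(recordings = recordings, manifest = man)
}
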