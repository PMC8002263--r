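#' Synthetic subject profiles
#'
#' Default tachogram profiles for the three source classes the pipeline is
#' exercised with. NSR-like subjects have slower heart rate with high,
#' strongly autocorrelated beat-to-beat variability; CHF-like subjects show
#' the clinical hallmark of heart failure — faster rate and severely reduced
#' variability; AF-like subjects are fast and erratic (high variability,
#' nearly uncorrelated). Only the first two moments and the lag-one
#' autocorrelation are modelled; no claim of deeper physiological realism.
#'
#' @param class `"NSR"`, `"CHF"` or `"AF"`.
#' @param mean_rr Mean RR interval (s).
#' @param sdnn Stationary standard deviation of the RR series (s).
#' @param ar_coefficient Lag-one autocorrelation in `[0, 1)`.
#' @param ectopic_rate Per-beat probability of a non-`"N"` annotation.
#' @param pause_rate Per-beat probability of a long (> 2 s) pause artefact.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(class = c("NSR", "CHF", "AF"),
                            mean_rr = NULL, sdnn = NULL,
                            ar_coefficient = NULL,
                            ectopic_rate = 0.01, pause_rate = 0.005) {
  class <- match.arg(class)
  def <- switch(class,
    NSR = list(mean_rr = 0.90, sdnn = 0.060, ar = 0.90),
    CHF = list(mean_rr = 0.65, sdnn = 0.015, ar = 0.30),
    AF  = list(mean_rr = 0.75, sdnn = 0.120, ar = 0.05))
  p <- list(class = class,
            mean_rr = mean_rr %||% def$mean_rr,
            sdnn = sdnn %||% def$sdnn,
            ar_coefficient = ar_coefficient %||% def$ar,
            ectopic_rate = ectopic_rate, pause_rate = pause_rate)
  if (p$mean_rr <= 0 || p$sdnn < 0 ||
      p$ar_coefficient < 0 || p$ar_coefficient >= 1 ||
      p$ectopic_rate < 0 || p$ectopic_rate > 1 ||
      p$pause_rate < 0 || p$pause_rate > 1)
    stop_invalid("invalid subject profile")
  structure(p, class = "subject_profile")
}

#' Simulate one beat-annotated RR series
#'
#' RR intervals follow a first-order autoregressive Gaussian process around
#' `mean_rr` with stationary standard deviation `sdnn` (innovation SD
#' `sdnn * sqrt(1 - ar^2)`), clipped below at 0.2 s. With probability
#' `ectopic_rate` a beat is annotated with an ectopic code (`"V"`); with
#' probability `pause_rate` an interval is replaced by a pause drawn
#' uniformly from (2, 3] s, so the cleaning filters always have work to do.
#' Fully determined by `seed`.
#'
#' @param profile A [subject_profile()].
#' @param n_beats Number of intervals to generate, `>= 1`.
#' @param seed Integer RNG seed.
#' @param subject_id Id for the resulting series.
#' @return An [rr_series()].
#' @examples
#' s <- generate_subject(subject_profile("CHF"), 500, seed = 7)
#' mean(s$intervals)
#' @export
generate_subject <- function(profile, n_beats, seed,
                             subject_id = paste0(profile$class, "-", seed)) {
  if (!inherits(profile, "subject_profile")) stop_invalid("invalid profile")
  if (n_beats < 1) stop_invalid("n_beats must be >= 1")
  n_beats <- as.integer(n_beats)
  with_seed(seed, {
    phi <- profile$ar_coefficient
    innov_sd <- profile$sdnn * sqrt(1 - phi^2)
    e <- stats::rnorm(n_beats, 0, innov_sd)
    x <- numeric(n_beats)
    # start from the stationary distribution so the series has no burn-in
    x[1] <- stats::rnorm(1, 0, profile$sdnn)
    for (t in seq_len(n_beats)[-1]) x[t] <- phi * x[t - 1] + e[t]
    rr <- pmax(profile$mean_rr + x, 0.2)
    pause <- stats::runif(n_beats) < profile$pause_rate
    rr[pause] <- 2 + stats::runif(sum(pause), 0, 1)  # (2, 3] s
    ann <- ifelse(stats::runif(n_beats) < profile$ectopic_rate, "V", "N")
    rr_series(subject_id, profile$class, rr, ann)
  })
}

#' Simulate a labelled RR cohort
#'
#' Generates `n_per_class` subjects for each requested class, with
#' per-subject seeds derived deterministically from `seed`. CHF-like
#' subjects carry the positive cohort label; NSR- and AF-like subjects are
#' the negative class, so the same binary pipeline covers both the two-class
#' and the CHF-vs-(NSR+AF) style experiment.
#'
#' @param n_per_class Subjects per class.
#' @param n_beats Beats per subject.
#' @param seed Master seed; every series is a pure function of it.
#' @param classes Character vector of source classes to include.
#' @param profiles Optional named list of [subject_profile()] overrides,
#'   keyed by class.
#' @return List of [rr_series()] objects with unique subject ids.
#' @examples
#' coh <- generate_cohort(n_per_class = 3, n_beats = 400, seed = 42)
#' vapply(coh, function(s) s$label, character(1))
#' @export
generate_cohort <- function(n_per_class = 10, n_beats = 1500, seed = 1,
                            classes = c("NSR", "CHF"), profiles = NULL) {
  if (n_per_class < 1 || n_beats < 1) stop_invalid("counts must be positive")
  cohort <- list()
  idx <- 0L
  for (cl in classes) {
    prof <- profiles[[cl]] %||% subject_profile(cl)
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("%s-%02d", cl, i)
      cohort[[idx]] <- generate_subject(prof, n_beats,
                                        seed = derive_seed(seed, idx),
                                        subject_id = id)
    }
  }
  cohort
}
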