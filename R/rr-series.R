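#' Beat-annotated RR-interval series
#'
#' The basic input unit of the pipeline: one subject's tachogram — the ordered
#' sequence of RR intervals (seconds between successive R peaks) — together
#' with the beat-type annotation of each interval's terminating beat
#' (`"N"` for a normal sinus beat, any other code for an abnormal/ectopic
#' beat) and the subject's cohort label.
#'
#' @param subject_id Non-empty string identifying the subject.
#' @param label Cohort label, one of `"NSR"`, `"CHF"`, `"AF"`.
#' @param intervals Numeric vector of RR intervals in seconds; all positive.
#' @param annotations Character vector of single-character beat codes, one per
#'   interval. Defaults to all-`"N"`.
#'
#' @return An object of class `rr_series`: a list with fields `subject_id`,
#'   `label`, `intervals`, `annotations`.
#' @examples
#' s <- rr_series("s01", "NSR", c(0.8, 0.75, 0.82), c("N", "V", "N"))
#' s
#' @export
rr_series <- function(subject_id, label, intervals,
                      annotations = rep("N", length(intervals))) {
  label <- match.arg(label, c("NSR", "CHF", "AF"))
  x <- structure(
    list(subject_id = as.character(subject_id), label = label,
         intervals = as.numeric(intervals),
         annotations = as.character(annotations)),
    class = "rr_series")
  validate_rr_series(x)
  x
}

validate_rr_series <- function(x) {
  if (!nzchar(x$subject_id)) stop_invalid("subject_id must be non-empty")
  if (length(x$intervals) != length(x$annotations))
    stop_invalid("intervals and annotations differ in length (",
                 length(x$intervals), " vs ", length(x$annotations), ")")
  if (length(x$intervals) && any(!is.finite(x$intervals) | x$intervals <= 0))
    stop_invalid("all RR intervals must be finite and positive")
  invisible(x)
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("RR series: subject %s [%s], %d intervals\n",
              x$subject_id, x$label, n))
  if (n) {
    cat(sprintf("  mean RR %.3f s, SD %.4f s, %d non-'N' beats, %d > 2 s\n",
                mean(x$intervals), stats::sd(x$intervals),
                sum(x$annotations != "N"), sum(x$intervals > 2)))
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)
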