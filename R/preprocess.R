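#' RR-interval cleaning filters
#'
#' Two pointwise filters precede segmentation: intervals whose terminating
#' beat is annotated as anything but `"N"` are discarded (ectopic beats
#' distort the tachogram), and intervals longer than 2 s are discarded
#' (almost always missed-beat artefacts of the upstream R-peak detector).
#' The 2 s boundary is read strictly: an interval of exactly 2.0 s is kept.
#' Survivors are concatenated in their original order; no gap markers or
#' resampling.
#'
#' @param series An [rr_series()] object.
#' @return `remove_abnormal_intervals()` and `remove_long_intervals()` return
#'   a filtered `rr_series`; `clean_rr()` applies both and marks the result
#'   clean (attribute `clean = TRUE`).
#' @examples
#' s <- rr_series("s01", "NSR", c(0.8, 2.5, 0.7, 0.9), c("N", "N", "V", "N"))
#' clean_rr(s)$intervals  # 0.8 0.9
#' @export
remove_abnormal_intervals <- function(series) {
  validate_rr_series(series)
  keep <- series$annotations == "N"
  subset_rr(series, keep)
}

#' @rdname remove_abnormal_intervals
#' @export
remove_long_intervals <- function(series) {
  validate_rr_series(series)
  keep <- series$intervals <= 2.0
  subset_rr(series, keep)
}

#' @rdname remove_abnormal_intervals
#' @export
clean_rr <- function(series) {
  out <- remove_long_intervals(remove_abnormal_intervals(series))
  attr(out, "clean") <- TRUE
  out
}

subset_rr <- function(series, keep) {
  series$intervals <- series$intervals[keep]
  series$annotations <- series$annotations[keep]
  series
}

#' Cut a cleaned RR series into fixed-length segments
#'
#' Consecutive, non-overlapping, left-aligned windows of exactly `n`
#' intervals; a trailing remainder shorter than `n` is dropped. `n` is
#' typically 500, 1000 or 2000 (shorter values are convenient in tests).
#'
#' @param series A cleaned [rr_series()].
#' @param n Segment length in intervals.
#' @return A list of numeric vectors, each of length `n`, with attributes
#'   `subject_id` and `label` copied onto each element's enclosing structure
#'   via the returned object's attributes.
#' @examples
#' s <- rr_series("s01", "NSR", rep(0.8, 1050))
#' length(segment_series(clean_rr(s), 500))  # 2
#' @export
segment_series <- function(series, n) {
  if (length(n) != 1 || !is.finite(n) || n <= 0 || n != round(n))
    stop_invalid("segment length n must be a positive integer")
  validate_rr_series(series)
  n <- as.integer(n)
  k <- length(series$intervals) %/% n
  segs <- vector("list", k)
  for (i in seq_len(k)) {
    segs[[i]] <- series$intervals[((i - 1L) * n + 1L):(i * n)]
  }
  attr(segs, "subject_id") <- series$subject_id
  attr(segs, "label") <- series$label
  segs
}

#' Zero-pad a segment to the network's length grid
#'
#' An encoder with `depth` max-pooling stages halves the time axis `depth`
#' times, so the input length must be a multiple of `2^depth`. The padded
#' length is the smallest such multiple at or above `n`; zeros are appended
#' at the tail so the physiological sequence stays causally intact. With
#' `depth = 4` this maps the three standard segment lengths 500, 1000 and
#' 2000 to 512, 1008 and 2000.
#'
#' @param values Numeric vector: one segment of `n` RR intervals.
#' @param depth Encoder depth (number of down-sampling stages), `>= 1`.
#' @return Numeric vector of length `padded_length(length(values), depth)`.
#' @examples
#' length(pad_segment(rep(0.8, 500), 4))  # 512
#' @export
pad_segment <- function(values, depth = 4L) {
  m <- padded_length(length(values), depth)
  c(values, numeric(m - length(values)))
}

#' @rdname pad_segment
#' @param n Unpadded segment length.
#' @export
padded_length <- function(n, depth = 4L) {
  if (depth < 1 || depth != round(depth))
    stop_invalid("depth must be a positive integer")
  block <- 2L^as.integer(depth)
  as.integer(ceiling(n / block) * block)
}

#' Clean, segment and pad a whole cohort
#'
#' Runs the full preprocessing cascade over a list of beat-annotated RR
#' series and collects every segment into one labelled design object. The
#' per-stage interval counts (raw, after long-interval removal, after
#' abnormal-beat removal) are tabulated per cohort label, mirroring the
#' filter-cascade bookkeeping used when the pipeline is applied to the
#' PhysioNet NSR-RR / CHF-RR databases.
#'
#' @param cohort List of [rr_series()] objects with unique subject ids.
#' @param n Segment length (intervals).
#' @param depth Encoder depth used for the padding rule.
#' @param normalize If `TRUE`, z-score each segment (mean 0, SD 1) before
#'   padding. Off by default: the network consumes raw RR seconds, whose
#'   absolute level (mean heart rate) is itself discriminative.
#' @return An object of class `rr_segments`: list with
#'   \describe{
#'     \item{values}{numeric matrix, one row per segment, `n` columns}
#'     \item{padded}{numeric matrix, one row per segment, `M` columns}
#'     \item{subject}{character vector of subject ids per segment}
#'     \item{cohort}{cohort label per segment (`NSR`/`CHF`/`AF`)}
#'     \item{label}{binary response per segment: 1 = CHF, 0 = non-CHF}
#'     \item{counts}{data.frame of per-label segment counts per filter stage}
#'     \item{n, m, depth}{segment length, padded length, encoder depth}
#'   }
#' @examples
#' coh <- generate_cohort(n_per_class = 2, n_beats = 600, seed = 1)
#' ds <- build_dataset(coh, n = 250)
#' table(ds$label)
#' @export
build_dataset <- function(cohort, n, depth = 4L, normalize = FALSE) {
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_invalid("duplicate subject_id in cohort: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- padded_length(n, depth)

  labels_seen <- unique(vapply(cohort, function(s) s$label, character(1)))
  stage_names <- c("none", "after_long_removal", "after_abnormal_removal")
  counts <- expand.grid(cohort = labels_seen, stage = stage_names,
                        stringsAsFactors = FALSE)
  counts$segments <- integer(nrow(counts))

  vals <- list(); subj <- character(0); cohl <- character(0)
  for (s in cohort) {
    validate_rr_series(s)
    n_raw <- length(s$intervals) %/% n
    s1 <- remove_long_intervals(s)
    n_long <- length(s1$intervals) %/% n
    s2 <- remove_abnormal_intervals(s1)
    n_both <- length(s2$intervals) %/% n
    for (st in seq_along(stage_names)) {
      i <- counts$cohort == s$label & counts$stage == stage_names[st]
      counts$segments[i] <- counts$segments[i] +
        c(n_raw, n_long, n_both)[st]
    }
    segs <- segment_series(s2, n)
    vals <- c(vals, segs)
    subj <- c(subj, rep(s$subject_id, length(segs)))
    cohl <- c(cohl, rep(s$label, length(segs)))
  }

  values <- if (length(vals)) do.call(rbind, vals) else
    matrix(numeric(0), 0, n)
  if (normalize && nrow(values)) {
    mu <- rowMeans(values)
    sdv <- apply(values, 1, stats::sd)
    sdv[sdv == 0] <- 1
    values <- (values - mu) / sdv
  }
  padded <- cbind(values, matrix(0, nrow(values), m - n))
  structure(
    list(values = values, padded = padded, subject = subj, cohort = cohl,
         label = as.integer(cohl == "CHF"), counts = counts,
         n = as.integer(n), m = m, depth = as.integer(depth)),
    class = "rr_segments")
}

#' @export
print.rr_segments <- function(x, ...) {
  cat(sprintf(
    "RR segment set: %d segments of %d intervals (padded to %d), %d subjects\n",
    nrow(x$values), x$n, x$m, length(unique(x$subject))))
  if (nrow(x$values)) print(table(cohort = x$cohort))
  invisible(x)
}
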