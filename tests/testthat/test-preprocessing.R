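test_that("abnormal-beat filter keeps exactly the 'N'-annotated intervals", {
  s <- rr_series("s01", "NSR", c(0.8, 0.7, 0.9), c("N", "V", "N"))
  out <- remove_abnormal_intervals(s)
  expect_equal(out$intervals, c(0.8, 0.9))
  expect_true(all(out$annotations == "N"))

  all_n <- rr_series("s02", "NSR", c(0.8, 0.9))
  expect_equal(remove_abnormal_intervals(all_n)$intervals, all_n$intervals)

  empty <- rr_series("s03", "NSR", numeric(0), character(0))
  expect_length(remove_abnormal_intervals(empty)$intervals, 0)
})

test_that("long-interval filter removes > 2 s strictly (2.0 s kept)", {
  s <- rr_series("s01", "CHF", c(0.8, 2.5, 0.9))
  expect_equal(remove_long_intervals(s)$intervals, c(0.8, 0.9))
  expect_equal(remove_long_intervals(rr_series("b", "NSR", 2.0))$intervals,
               2.0)
  ok <- rr_series("c", "NSR", c(0.7, 1.9, 2.0))
  expect_equal(remove_long_intervals(ok)$intervals, ok$intervals)
})

test_that("invalid series are rejected", {
  expect_error(rr_series("s", "NSR", c(0.8, 0.9), c("N")), "length")
  expect_error(rr_series("s", "NSR", c(0.8, -0.1)), "positive")
  expect_error(rr_series("", "NSR", 0.8), "non-empty")
})

test_that("clean_rr composes both filters and is idempotent", {
  s <- rr_series("s01", "CHF", c(0.8, 2.5, 0.7, 0.9),
                 c("N", "N", "V", "N"))
  out <- clean_rr(s)
  expect_equal(out$intervals, c(0.8, 0.9))
  again <- clean_rr(out)
  expect_equal(again$intervals, out$intervals)
})

test_that("the two filters commute and never grow the series", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:80, 1)
    iv <- round(runif(n, 0.3, 2.6), 3)
    ann <- sample(c("N", "N", "N", "V", "A"), n, replace = TRUE)
    s <- rr_series("p", "NSR", iv, ann)
    a <- remove_long_intervals(remove_abnormal_intervals(s))
    b <- remove_abnormal_intervals(remove_long_intervals(s))
    expect_identical(a$intervals, b$intervals)
    expect_lte(length(a$intervals), n)
    expect_lte(length(remove_abnormal_intervals(s)$intervals), n)
  }
})

test_that("segmentation gives floor(len/n) aligned windows", {
  s1050 <- clean_rr(rr_series("s", "NSR", seq_len(1050) / 1000))
  segs <- segment_series(s1050, 500)
  expect_length(segs, 2)
  expect_equal(segs[[1]], (1:500) / 1000)
  expect_equal(segs[[2]], (501:1000) / 1000)

  expect_length(segment_series(clean_rr(rr_series("s", "NSR",
                                                  rep(0.8, 499))), 500), 0)

  s2000 <- clean_rr(rr_series("s", "NSR", seq_len(2000) / 1200))
  two <- segment_series(s2000, 1000)
  expect_length(two, 2)
  # conservation: concatenated segments reproduce the leading intervals
  expect_equal(unlist(two), s2000$intervals[1:2000])

  expect_error(segment_series(s2000, 0), "positive")
  expect_error(segment_series(s2000, -5), "positive")
})

test_that("padding rule: smallest multiple of 2^depth at or above n", {
  expect_identical(padded_length(500, 4), 512L)
  expect_identical(padded_length(1000, 4), 1008L)
  expect_identical(padded_length(2000, 4), 2000L)
  expect_identical(padded_length(16, 4), 16L)
  for (n in 1:128) {
    m <- padded_length(n, 4)
    expect_identical(m %% 16L, 0L)
    expect_gte(m, n)
    expect_lt(m - n, 16)
    expect_identical(m, if (n %% 16 == 0) n else n + (16L - n %% 16L))
  }
  pd <- pad_segment(rep(0.8, 500), 4)
  expect_length(pd, 512)
  expect_equal(pd[1:500], rep(0.8, 500))
  expect_true(all(pd[501:512] == 0))
})

test_that("build_dataset cleans, segments, pads and tallies the cascade", {
  mk <- function(id, lab, niv) rr_series(id, lab, rep(0.8, niv))
  coh <- list(mk("a", "NSR", 1200), mk("b", "CHF", 1200))
  ds <- build_dataset(coh, n = 500)
  expect_s3_class(ds, "rr_segments")
  expect_identical(nrow(ds$values), 4L)
  expect_identical(ds$m, 512L)
  expect_equal(sort(unique(ds$cohort)), c("CHF", "NSR"))
  expect_equal(ds$label, as.integer(ds$cohort == "CHF"))
  expect_true(all(ds$padded[, 1:500] == ds$values))
  expect_true(all(ds$padded[, 501:512] == 0))
  # cascade counts keyed by both labels and all three stages
  expect_setequal(unique(ds$counts$cohort), c("NSR", "CHF"))
  expect_setequal(unique(ds$counts$stage),
                  c("none", "after_long_removal", "after_abnormal_removal"))

  expect_identical(nrow(build_dataset(list(), n = 500)$values), 0L)
  expect_error(build_dataset(list(mk("a", "NSR", 600), mk("a", "CHF", 600)),
                             n = 500), "duplicate")
})

test_that("optional per-segment z-scoring standardizes each row", {
  coh <- tiny_cohort(n_per_class = 2, n_beats = 300, seed = 5)
  ds <- build_dataset(coh, n = 100, normalize = TRUE)
  expect_equal(rowMeans(ds$values), rep(0, nrow(ds$values)),
               tolerance = 1e-12)
  expect_equal(apply(ds$values, 1, sd), rep(1, nrow(ds$values)),
               tolerance = 1e-12)
  # padding stays zero after scaling
  expect_true(all(ds$padded[, (ds$n + 1):ds$m] == 0))
})

test_that("cascade counts are monotone when artefacts are present", {
  coh <- tiny_cohort(n_per_class = 2, n_beats = 900, seed = 5)
  ds <- build_dataset(coh, n = 100)
  for (lab in unique(ds$counts$cohort)) {
    cc <- ds$counts[ds$counts$cohort == lab, ]
    raw <- cc$segments[cc$stage == "none"]
    lng <- cc$segments[cc$stage == "after_long_removal"]
    both <- cc$segments[cc$stage == "after_abnormal_removal"]
    expect_lte(lng, raw)
    expect_lte(both, lng)
  }
})
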