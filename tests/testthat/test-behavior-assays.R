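test_that("boldness transform matches its definition and printed example", {
  expect_equal(boldness_index(3600), 0)
  expect_equal(boldness_index(360, log_base = "ten"), 1)
  expect_equal(boldness_index(70.15, log_base = "ten"), 1.71,
               tolerance = 0.005 / 1.71)
  # strictly decreasing in latency
  lat <- sort(runif(50, 1, 3600))
  expect_true(all(diff(boldness_index(lat)) < 0))
  expect_error(boldness_index(0), "positive")
  expect_error(boldness_index(-5), "positive")
  expect_error(boldness_index(4000), "t_max")
})

test_that("boldness transform is a bijection: round-trip recovers latency", {
  set.seed(42)
  lat <- runif(200, 1e-3, 3600)
  for (base in c("ten", "natural")) {
    idx <- boldness_index(lat, log_base = base)
    expect_true(all(idx >= 0))
    back <- latency_from_boldness(idx, log_base = base)
    expect_equal(back, lat, tolerance = 1e-9)
  }
})

test_that("asociability is the mean distance to the stimulus point in cm", {
  # every frame at the stimulus point
  rec0 <- make_recording(rep(5, 10), rep(7, 10), stimuli = c(5, 7))
  expect_equal(asociability_index(rec0, start_rule = "from_start"), 0)

  # two frames at 10 px and 30 px from the stimulus, 2 px/cm -> 10 cm
  rec2 <- make_recording(c(10, 30), c(0, 0), px_per_cm = 2, stimuli = c(0, 0))
  expect_equal(asociability_index(rec2), 10)

  # brute-force oracle over a random recording
  rec <- random_walk_recording(1)
  got <- asociability_index(rec)
  d <- sqrt((rec$frames$x_px - rec$stimuli_point["x"])^2 +
              (rec$frames$y_px - rec$stimuli_point["y"])^2)
  disp <- sqrt(diff(rec$frames$x_px)^2 + diff(rec$frames$y_px)^2)
  start <- which(disp > 0)[1]
  expect_equal(got, sum(d[start:length(d)]) / (length(d) - start + 1) /
                 rec$px_per_cm)

  # never-moving fish: exclusion, not a crash
  frozen <- make_recording(rep(3, 5), rep(4, 5))
  expect_true(is.na(asociability_index(frozen)))
  expect_match(attr(asociability_index(frozen), "exclusion_reason"),
               "no movement")

  # normalized form rides along as an attribute
  both <- asociability_index(rec2, normalize_by = 26.5)
  expect_equal(attr(both, "normalized"), 10 / 26.5)
})

test_that("activity counts strictly-greater-than-1-cm moves", {
  still <- make_recording(rep(1, 20), rep(1, 20))
  expect_equal(activity_index(still), 0)

  # 11 frames alternating between points 2 cm apart
  alt <- make_recording(rep(c(0, 2), length.out = 11), rep(0, 11))
  expect_equal(activity_index(alt), 10)
  expect_equal(activity_index(alt, as_percent = TRUE), 100)

  # strictness: a displacement of exactly 1 cm does not count
  exact <- make_recording(c(0, 1, 2), c(0, 0, 0))
  expect_equal(activity_index(exact, min_move_cm = 1), 0)

  # brute-force oracle on a random walk
  rec <- random_walk_recording(2)
  d_cm <- sqrt(diff(rec$frames$x_px)^2 + diff(rec$frames$y_px)^2) /
    rec$px_per_cm
  expect_equal(activity_index(rec), sum(d_cm > 1))
  # count = percent * n_intervals / 100
  n_int <- nrow(rec$frames) - 1L
  expect_equal(activity_index(rec),
               activity_index(rec, as_percent = TRUE) * n_int / 100)

  one <- make_recording(1, 1)
  expect_true(is.na(activity_index(one)))
})

test_that("asociability and activity are invariant to rigid translation", {
  rec <- random_walk_recording(3)
  shift <- c(123.4, -56.7)
  moved <- make_recording(rec$frames$x_px + shift[1],
                          rec$frames$y_px + shift[2],
                          px_per_cm = rec$px_per_cm,
                          stimuli = rec$stimuli_point + shift)
  expect_equal(asociability_index(moved), asociability_index(rec))
  expect_equal(activity_index(moved), activity_index(rec))
})

test_that("the 30-minute no-movement exclusion rule applies at the boundary", {
  n <- 600  # frames every 6 s -> covers 3600 s
  t <- 6 * seq_len(n)
  still_then_move <- make_recording(c(rep(0, 350), seq(1, 250)), rep(0, n),
                                    times = t)
  expect_true(exclude_inactive(still_then_move))  # first move at t = 2106 s

  early <- make_recording(c(0, 5, rep(5, n - 2)), rep(0, n),
                          times = c(4, 10, t[-(1:2)]))
  expect_false(exclude_inactive(early))  # movement at t = 10 s

  # movement lands exactly one second past the window
  boundary <- make_recording(c(rep(0, 5), 10, 10), rep(0, 7),
                             times = c(1, 500, 1000, 1500, 1795, 1801, 2000))
  expect_true(exclude_inactive(boundary))

  short <- make_recording(c(0, 1), c(0, 0), times = c(6, 12))
  expect_true(is.na(exclude_inactive(short)))
  expect_match(attr(exclude_inactive(short), "exclusion_reason"), "shorter")
})

test_that("score_assays keeps excluded fish with reasons and round-trips CSV", {
  active <- random_walk_recording(4, n_frames = 650)
  frozen <- make_recording(rep(1, 650), rep(1, 650), fish_id = "frozen")
  scores <- score_assays(list(active, frozen))
  expect_equal(nrow(scores), 2)
  expect_false(scores$excluded[1])
  expect_true(scores$excluded[2])
  expect_match(scores$exclusion_reason[2], "no movement")
  expect_true(is.na(scores$boldness[2]))
  expect_equal(attr(scores, "log_base"), "ten")
  expect_equal(scores$boldness[1],
               boldness_index(active$latency_s, active$t_max))

  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_scores_csv(scores, path)
  back <- read.csv(path)
  expect_equal(back$activity[1], scores$activity[1])
})

test_that("recordings round-trip through frame/metadata CSVs", {
  rec <- random_walk_recording(5, n_frames = 40)
  frames <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, frames, meta)
  back <- read_recording_csv(frames, meta)
  expect_equal(back$frames$x_px, rec$frames$x_px, tolerance = 1e-12)
  expect_equal(back$latency_s, rec$latency_s)
  expect_equal(back$stimuli_point, rec$stimuli_point)
  expect_equal(activity_index(back), activity_index(rec))
})

test_that("assay recording constructor validates its invariants", {
  expect_error(make_recording(c(1, 2), c(1, 2), times = c(6, 6)),
               "strictly increasing")
  expect_error(assay_recording("f", 10, data.frame(time_s = 1, x_px = 1,
                                                   y_px = 1),
                               px_per_cm = 0, stimuli_point = c(0, 0)),
               "px_per_cm")
  expect_error(make_recording(1, 1, latency = 5000), "t_max")
})
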