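test_that("compute_thresholds takes arithmetic trait means of the front cohort", {
  same <- data.frame(boldness = rep(1.4, 6), activity = rep(0.9, 6),
                     asociability = rep(1.1, 6))
  thr <- compute_thresholds(same)
  expect_equal(thr$boldness_mean, 1.4)
  expect_equal(thr$activity_mean, 0.9)
  expect_equal(thr$asociability_mean, 1.1)

  # engineered to the printed front means
  eng <- data.frame(boldness = c(1.0, 1.26), activity = c(1.0, 1.34),
                    asociability = c(0.9, 1.0))
  thr <- compute_thresholds(eng)
  expect_equal(thr$boldness_mean, 1.13)
  expect_equal(thr$activity_mean, 1.17)
  expect_equal(thr$asociability_mean, 0.95)

  # brute-force sum/n oracle
  set.seed(31)
  rnd <- data.frame(boldness = runif(57), activity = runif(57),
                    asociability = runif(57))
  thr <- compute_thresholds(rnd)
  expect_equal(thr$boldness_mean, sum(rnd$boldness) / 57)

  expect_error(compute_thresholds(rnd[0, ]), "nonempty")
})

test_that("personality rule counts strict exceedances, 2 of 3 compensatory", {
  # printed worked example: 1.71 > 1.13, 1.76 > 1.17, 0.47 < 0.95
  res <- decision_personality(1.71, 1.76, 0.47)
  expect_equal(res$traits_above, 2L)
  expect_equal(res$decision, 1L)

  expect_equal(decision_personality(1.0, 1.0, 0.5)$decision, 0L)

  # exhaustive enumeration of the 8 above/below patterns at 2-of-3
  thr <- threshold_set(boldness_mean = 1, activity_mean = 1,
                       asociability_mean = 1)
  for (b in 0:1) for (a in 0:1) for (s in 0:1) {
    vals <- c(b, a, s) * 0.5 + 0.75  # 0.75 below, 1.25 above
    res <- decision_personality(vals[1], vals[2], vals[3], thr)
    expect_equal(res$traits_above, b + a + s)
    expect_equal(res$decision, as.integer(b + a + s >= 2))
  }

  # ties fail: a trait exactly at the mean is not "above"
  res <- decision_personality(1.13, 1.17, 0.95)
  expect_equal(res$traits_above, 0L)
  expect_equal(res$decision, 0L)

  # missing trait is an exclusion, not an error
  res <- decision_personality(NA, 1.5, 1.5)
  expect_true(is.na(res$decision))
  expect_match(attr(res, "exclusion_reason"), "missing")

  expect_error(threshold_set(min_traits_above = 4), "min_traits_above")
})

test_that("the worked-example individual ascends against the shipped fixture", {
  tr <- run_decision_matrix(worked_fish(), example_flow_profile())
  expect_equal(tr$decision_swim, 1L)
  expect_equal(tr$decision_endurance, 1L)
  expect_equal(tr$traits_above, 2L)
  expect_equal(tr$decision_personality, 1L)
  expect_equal(tr$overall, 1L)
  expect_equal(tr$ucrit_m_s, 0.61, tolerance = 1e-12)
  expect_equal(tr$flow_limit_m_s, 0.5)
  expect_equal(tr$distance_limit_m, 4.54)
  # the computed traversable distance from the printed formula
  expect_equal(tr$distance_m, 6.53, tolerance = 1e-3)
})

test_that("failing the swim gate closes the overall decision regardless of traits", {
  slowpoke <- data.frame(fish_id = "small", tl_cm = 4,  # ucrit 0.2 < 0.5
                         boldness = 2, activity = 2, asociability = 2)
  tr <- run_decision_matrix(slowpoke, example_flow_profile())
  expect_equal(tr$decision_swim, 0L)
  expect_equal(tr$decision_personality, 1L)
  expect_equal(tr$overall, 0L)
})

test_that("traces are self-consistent and permutation invariant", {
  cohort <- random_cohort(41, n = 120)
  tr <- run_decision_matrix(cohort, example_flow_profile())
  expect_equal(nrow(tr), 120)
  # overall recomputed independently from the three stored decisions
  expect_equal(tr$overall,
               as.integer(tr$decision_swim & tr$decision_endurance &
                            tr$decision_personality))
  # every intermediate is recorded and reproducible from the inputs
  expect_equal(tr$ucrit_m_s, ucrit_from_length(cohort$tl_cm))
  expect_equal(tr$distance_m,
               traversable_distance(tr$ucrit_m_s,
                                    endurance_minutes(50, cohort$tl_cm)))

  perm <- sample(nrow(cohort))
  tr2 <- run_decision_matrix(cohort[perm, ], example_flow_profile())
  reord <- tr2[match(tr$fish_id, tr2$fish_id), ]
  rownames(reord) <- NULL
  expect_equal(as.data.frame(reord), as.data.frame(tr))
})

test_that("increasing length can never flip an ascent to a failure", {
  set.seed(53)
  cohort <- random_cohort(53, n = 10000)
  tr1 <- run_decision_matrix(cohort, example_flow_profile())
  bigger <- cohort
  bigger$tl_cm <- bigger$tl_cm + runif(nrow(bigger), 0.1, 5)
  tr2 <- run_decision_matrix(bigger, example_flow_profile())
  expect_false(any(tr1$overall == 1L & tr2$overall == 0L))
})

test_that("missing traits are excluded with a reason, never dropped", {
  cohort <- random_cohort(61, n = 10)
  cohort$boldness[3] <- NA
  tr <- run_decision_matrix(cohort, example_flow_profile())
  expect_equal(nrow(tr), 10)
  expect_true(tr$excluded[3])
  expect_match(tr$exclusion_reason[3], "missing")
  expect_true(is.na(tr$overall[3]))
  expect_false(any(tr$excluded[-3]))

  s <- summary(tr)
  expect_equal(s$n, 10)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$n + 0, sum(!tr$excluded) + s$n_excluded)
})

test_that("decision traces write a CSV plus JSON summary", {
  tr <- run_decision_matrix(random_cohort(71, 15), example_flow_profile())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_decision_traces_csv(tr, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 15)
  s <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(s$n, 15)
  expect_equal(s$fraction, mean(tr$overall[!tr$excluded]))
})
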