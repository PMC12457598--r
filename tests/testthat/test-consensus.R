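test_that("the initial consensus is the per-image mean of available ratings", {
  cohort <- make_cohort(rbind(c(100, 100, 100),
                              c(90, 100, 110),
                              c(96, 102, NA)))
  init <- initial_consensus(cohort)
  expect_equal(unname(init), c(100, 100, 99))
  expect_named(init, cohort$info$image_id)

  all_missing <- make_cohort(rbind(c(100, 100, 100), c(NA, NA, NA)))
  expect_error(initial_consensus(all_missing), "img_002")
})

test_that("exclusion thresholding follows the strict > 30 month rule", {
  cohort <- make_cohort(rbind(c(100, 100, 131),   # max deviation 20.67
                              c(100, 100, 145),   # max deviation exactly 30
                              c(100, 100, 146),   # max deviation 30.67
                              c(100, NA, 102)))
  res <- apply_exclusions(cohort)
  expect_equal(res$cohort$info$image_id, c("img_001", "img_002"))
  expect_equal(res$excluded$image_id, c("img_003", "img_004"))
  expect_setequal(res$excluded$reason[res$excluded$image_id == "img_003"],
                  "deviation_gt_threshold")
  expect_setequal(res$excluded$reason[res$excluded$image_id == "img_004"],
                  "missing_rating")

  keep_missing <- apply_exclusions(cohort, drop_missing = FALSE)
  expect_true("img_004" %in% keep_missing$cohort$info$image_id)
  expect_error(apply_exclusions(cohort, deviation_threshold = 0), "> 0")
})

test_that("rater profiles carry signed bias, MAD and normalized 1/MAD weights", {
  # rows built so deviations from the per-image mean have column biases 0
  # and column MADs exactly {4, 8, 8}
  cohort <- make_cohort(rbind(c(100, 112, 88),
                              c(100, 88, 112),
                              c(108, 96, 96),
                              c(92, 104, 104)))
  prof <- fit_rater_profiles(cohort)
  expect_equal(prof$smd_bias, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(prof$mad, c(4, 8, 8), tolerance = 1e-12)
  expect_equal(prof$weight, c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # a rater uniformly +6 months above the initial mean has bias +6
  base <- matrix(rep(c(90, 120, 150, 180), 3), 4, 3)
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 9  # initial mean rises by 3 => bias 9 - 3 = 6
  prof2 <- suppressWarnings(fit_rater_profiles(make_cohort(shifted)))
  expect_equal(prof2$smd_bias[2], 6, tolerance = 1e-12)

  # perfect-agreement panel triggers the MAD floor with a warning
  expect_warning(prof3 <- fit_rater_profiles(make_cohort(base)),
                 "perfect agreement")
  expect_equal(prof3$weight, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("the weighted consensus equals an independent hand computation", {
  ratings <- rbind(c(96, 108, 99),
                   c(120, 135, 126),
                   c(150, 168, 159))
  cohort <- make_cohort(ratings)
  prof <- fit_rater_profiles(cohort)
  cons <- build_consensus(cohort, prof)

  # spreadsheet-style oracle, written out step by step
  init <- rowMeans(ratings)
  bias <- colMeans(ratings - init)
  madv <- colMeans(abs(t(t(ratings - init) - bias)))
  w <- (1 / madv) / sum(1 / madv)
  oracle <- as.numeric((t(t(ratings) - bias)) %*% w)
  expect_equal(unname(cons), oracle, tolerance = 1e-12)

  # convexity: identical unbiased raters reproduce the common rating
  flat <- make_cohort(matrix(rep(c(80, 100, 120), 3), 3, 3))
  pf <- suppressWarnings(fit_rater_profiles(flat))
  expect_equal(unname(build_consensus(flat, pf)), c(80, 100, 120))

  expect_error(build_consensus(cohort, prof[c(2, 1, 3), ]), "mismatch")
})

test_that("consensus weights sum to one and absorb per-rater constant offsets", {
  set.seed(42)
  for (rep in 1:5) {
    ratings <- matrix(runif(7 * 20, 50, 200), 20, 7)
    cohort <- make_cohort(ratings)
    prof <- fit_rater_profiles(cohort)
    expect_equal(sum(prof$weight), 1, tolerance = 1e-9)
    expect_true(all(abs(prof$weight * prof$mad -
                          prof$weight[1] * prof$mad[1]) < 1e-9))

    # adding a constant c to one rater leaves weights and MADs untouched
    # and shifts the consensus uniformly by exactly c / k -- the shift of
    # the initial-mean anchor; the bias correction absorbs the rest, so
    # the shift does not depend on that rater's weight
    shifted <- ratings
    shifted[, 3] <- shifted[, 3] + 17
    sc <- make_cohort(shifted)
    prof_s <- fit_rater_profiles(sc)
    expect_equal(prof_s$weight, prof$weight, tolerance = 1e-9)
    expect_equal(prof_s$mad, prof$mad, tolerance = 1e-9)
    delta <- build_consensus(sc, prof_s) - build_consensus(cohort, prof)
    expect_equal(unname(delta), rep(17 / 7, 20), tolerance = 1e-9)

    # permutation invariance in rater order
    perm <- sample(7)
    pc <- make_cohort(ratings[, perm])
    expect_equal(unname(build_consensus(pc, fit_rater_profiles(pc))),
                 unname(build_consensus(cohort, prof)), tolerance = 1e-9)
  }
})

test_that("equal-MAD panels reduce to the unweighted mean of corrected ratings", {
  ratings <- 100 + rbind(c(0, 12, -12),   # Latin square of deviations:
                         c(12, -12, 0),   # every column sees {0, +12, -12}
                         c(-12, 0, 12))
  cohort <- make_cohort(ratings)
  prof <- fit_rater_profiles(cohort)
  expect_equal(prof$mad, rep(prof$mad[1], 3))
  corrected <- t(t(ratings) - prof$smd_bias)
  expect_equal(unname(build_consensus(cohort, prof)),
               unname(rowMeans(corrected)), tolerance = 1e-12)
})

test_that("leave-one-out consensus equals the pipeline on the reduced panel", {
  sim <- generate_cohort(default_gbad_like_config(seed = 21, n_images = 80))
  cohort <- sim$cohort
  cohort$ratings[5, 1] <- NA  # exercise the exclusion path too

  loo <- leave_one_out_consensus(cohort, "rater_4")
  reduced <- ba_cohort(cohort$info,
                       cohort$ratings[, setdiff(cohort$rater_ids, "rater_4")],
                       relax_age_range = TRUE)
  oracle <- consensus_pipeline(reduced)
  expect_identical(loo$consensus, oracle$consensus)
  expect_identical(loo$profiles, oracle$profiles)
  expect_identical(loo$excluded, oracle$excluded)

  expect_error(leave_one_out_consensus(cohort, "rater_9"), "unknown rater_id")
  tiny <- make_cohort(matrix(100, 3, 2))
  expect_error(leave_one_out_consensus(tiny, "rater_1"), "k >= 3")
})

test_that("holding out a rater identical to the others leaves the consensus unchanged", {
  base <- matrix(rep(c(90, 120, 150, 180), 4), 4, 4)
  cohort <- make_cohort(base)
  full <- suppressWarnings(consensus_pipeline(cohort))
  loo <- suppressWarnings(leave_one_out_consensus(cohort, "rater_2"))
  expect_equal(loo$consensus, full$consensus, tolerance = 1e-12)
})

test_that("the optional iterative mode converges to a proper consensus", {
  sim <- generate_cohort(default_gbad_like_config(seed = 4, n_images = 60))
  it <- consensus_pipeline(sim$cohort, iterate = TRUE)
  expect_equal(sum(it$profiles$weight), 1, tolerance = 1e-9)
  one <- consensus_pipeline(sim$cohort)
  expect_lt(max(abs(it$consensus - one$consensus)), 1.5)
})
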