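test_that("stratified splits are deterministic, disjoint and disorder-aware", {
  cfg <- default_gbad_like_config(seed = 51, n_images = 200)
  cohort <- generate_cohort(cfg)$cohort
  s1 <- stratified_split(cohort, seed = 9)
  s2 <- stratified_split(cohort, seed = 9)
  expect_identical(s1, s2)
  s3 <- stratified_split(cohort, seed = 10)
  expect_false(identical(s1$train_ids, s3$train_ids))

  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_setequal(c(s1$train_ids, s1$test_ids), cohort$info$image_id)
  disorder_ids <- cohort$info$image_id[cohort$info$disorder]
  expect_true(all(disorder_ids %in% s1$test_ids))

  expect_error(stratified_split(cohort, train_fraction = 0), "between 0 and 1")
  expect_error(stratified_split(cohort, train_fraction = 1), "between 0 and 1")
})

test_that("split sizes follow largest-remainder rounding of the train fraction", {
  # 381 images, 19 with a disorder; fraction 121/362 of the 362 eligible
  # must yield exactly 121 train / 260 test
  withr::with_seed(77, {
    info <- data.frame(image_id = sprintf("i%03d", 1:381),
                       sex = sample(c("female", "male"), 381, TRUE),
                       ca_months = runif(381, 0, 216),
                       ai_ba_months = runif(381, 0, 216),
                       disorder = sample(rep(c(TRUE, FALSE), c(19, 362))))
    ratings <- matrix(runif(381 * 2, 0, 216), 381, 2)
  })
  cohort <- ba_cohort(info, ratings)
  split <- stratified_split(cohort, train_fraction = 121 / 362, seed = 3)
  expect_length(split$train_ids, 121)
  expect_length(split$test_ids, 260)

  # 9 eligible images in a single stratum at fraction 1/3 -> exactly 3 train
  one <- ba_cohort(data.frame(image_id = letters[1:9], sex = "f",
                              ca_months = 30 + 1:9,
                              ai_ba_months = 30 + 1:9, disorder = FALSE),
                   matrix(30, 9, 2))
  sp <- stratified_split(one, train_fraction = 1 / 3, seed = 1)
  expect_length(sp$train_ids, 3)
  expect_length(sp$test_ids, 6)
})

test_that("bootstrap re-partitioning is reproducible and summarizes correctly", {
  sim <- generate_cohort(default_gbad_like_config(seed = 5, n_images = 150))
  cons <- consensus_pipeline(sim$cohort)
  b1 <- bootstrap_repartition(cons$cohort, cons, n_replicates = 40,
                              master_seed = 17)
  b2 <- bootstrap_repartition(cons$cohort, cons, n_replicates = 40,
                              master_seed = 17)
  expect_identical(b1, b2)
  expect_equal(b1$failed, 0)
  expect_equal(nrow(b1$replicates), 40)

  # percentile interval bounds are ordered around the median at every grid point
  for (s in c("female", "male")) {
    cur <- b1$curves[[s]]
    expect_true(all(cur$lower <= cur$median & cur$median <= cur$upper))
  }

  expect_error(bootstrap_repartition(cons$cohort,
                                     cons$consensus[-(1:5)],
                                     n_replicates = 5, master_seed = 1),
               "cover")
})

test_that("bootstrap percentile bounds equal sort-based order statistics", {
  # with 41 replicates the type-7 quantile index 1 + (n-1)p is integral at
  # p = 0.025 (2nd order statistic) and p = 0.975 (40th)
  sim <- generate_cohort(default_gbad_like_config(seed = 23, n_images = 120))
  cons <- consensus_pipeline(sim$cohort)
  boot <- bootstrap_repartition(cons$cohort, cons, n_replicates = 41,
                                master_seed = 2)
  mads <- sort(boot$replicates$mad)
  expect_identical(boot$ci$mad[1], mads[2])
  expect_identical(boot$ci$mad[2], mads[40])
})

test_that("a noise-free cohort collapses every bootstrap distribution to a point", {
  cfg <- zero_noise_config(n = 90, seed = 2)
  cfg$ai_slope <- 0.95
  cfg$ai_offset <- 10
  sim <- generate_cohort(cfg)
  cons <- suppressWarnings(consensus_pipeline(sim$cohort))
  boot <- suppressWarnings(  # exact fits trip summary.lm's warning
    bootstrap_repartition(cons$cohort, cons, n_replicates = 25,
                          master_seed = 4))
  expect_equal(sd(boot$replicates$slope_female), 0, tolerance = 1e-10)
  expect_equal(diff(boot$ci$mad), 0, tolerance = 1e-10)
  expect_equal(unique(round(boot$replicates$slope_male, 10)),
               round(1 / 0.95, 10))
  for (s in c("female", "male")) {
    expect_equal(boot$curves[[s]]$upper - boot$curves[[s]]$lower,
                 rep(0, length(boot$grid)), tolerance = 1e-9)
  }
})

test_that("a single replicate reduces to one split-fit-evaluate run", {
  sim <- generate_cohort(default_gbad_like_config(seed = 6, n_images = 140))
  cons <- consensus_pipeline(sim$cohort)
  boot <- bootstrap_repartition(cons$cohort, cons, n_replicates = 1,
                                master_seed = 11)
  seed1 <- derive_seed(11, 1)
  split <- stratified_split(cons$cohort, 1 / 3, seq(0, 216, 24), seed = seed1)
  info <- cons$cohort$info
  tr <- match(split$train_ids, info$image_id)
  te <- match(split$test_ids, info$image_id)
  model <- fit_calibration(info$ai_ba_months[tr],
                           cons$consensus[split$train_ids], info$sex[tr])
  cal <- suppressWarnings(apply_calibration(model, info$ai_ba_months[te],
                                            info$sex[te]))
  ref <- cons$consensus[split$test_ids]
  expect_equal(boot$replicates$mad, ba_mad(cal, ref))
  expect_equal(boot$replicates$rmse, sqrt(mean((cal - ref)^2)))
  expect_equal(boot$replicates$slope_female, model$models$female$slope)
})

test_that("replicate-averaged slopes recover the generative inverse distortion", {
  cfg <- default_gbad_like_config(seed = 29, n_images = 381)
  sim <- generate_cohort(cfg)
  cons <- consensus_pipeline(sim$cohort)
  boot <- bootstrap_repartition(cons$cohort, cons, n_replicates = 120,
                                master_seed = 8)
  for (s in c("female", "male")) {
    sl <- boot$replicates[[paste0("slope_", s)]]
    true_slope <- if (s == "female") 1.032 else 1.040
    expect_lt(abs(mean(sl) - true_slope), 2 * sd(sl))
  }
})

test_that("the band check flags calibrations outside the bootstrap corridor", {
  sim <- generate_cohort(default_gbad_like_config(seed = 9, n_images = 200))
  cons <- consensus_pipeline(sim$cohort)
  boot <- bootstrap_repartition(cons$cohort, cons, n_replicates = 60,
                                master_seed = 3)
  # a model at the replicate medians sits deep inside the corridor
  med <- structure(list(models = list(
    female = list(slope = median(boot$replicates$slope_female),
                  intercept = median(boot$replicates$intercept_female)),
    male = list(slope = median(boot$replicates$slope_male),
                intercept = median(boot$replicates$intercept_male))),
    conf = 0.95), class = "ba_calibration")
  res <- correction_within_band(med, boot)
  expect_gt(res$female$coverage, 0.9)
  expect_gt(res$male$coverage, 0.9)

  shifted <- med
  shifted$models$male$intercept <- shifted$models$male$intercept + 24
  res2 <- correction_within_band(shifted, boot)
  expect_false(res2$male$pass)
  expect_false(res2$overall_pass)
})
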