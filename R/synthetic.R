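# Synthetic cohort generator: known true bone ages, a biased and noisy
# rater panel, and a black-box AI whose raw output is a linear distortion
# of the true bone age. The forward model
#     ai_raw = a_sex * BA_true + c_sex + N(0, ai_sd)
# makes the correct recalibration parameters analytically known
# (slope = 1/a, intercept = -c/a), which is what makes parameter-recovery
# checks on the downstream calibration crisp.

#' Configuration of the synthetic cohort generator
#'
#' @param n_images number of images to simulate.
#' @param sex_ratio fraction of female images in [0, 1].
#' @param age_range chronological-age sampling range, months.
#' @param age_sampler \code{"uniform"} over \code{age_range} (default) or
#'   \code{"truncnorm"} (normal with \code{age_mean}/\code{age_sd},
#'   truncated to \code{age_range}).
#' @param age_mean,age_sd parameters of the truncated-normal age sampler.
#' @param ba_ca_sd SD (months) of true bone age around chronological age.
#' @param n_raters panel size k.
#' @param rater_biases per-rater additive offset, months (length
#'   \code{n_raters}).
#' @param rater_sds per-rater noise SD, months (length \code{n_raters}).
#' @param rater_noise_mode \code{"constant"} (homoscedastic, default) or
#'   \code{"age_proportional"} (SD scaled by BA_true / mean age).
#' @param ai_slope,ai_offset,ai_sd linear distortion a (unitless), offset c
#'   (months) and noise SD (months) of the simulated AI; used for both
#'   sexes unless \code{sex_specific_ai} is given.
#' @param sex_specific_ai optional list with elements \code{female} and
#'   \code{male}, each \code{c(slope = a, offset = c)}.
#' @param disorder_rate fraction of images flagged with a known genetic
#'   disorder.
#' @param seed integer RNG seed; the same config always yields the
#'   identical cohort.
#' @return a list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_images = 381L, sex_ratio = 0.5,
                             age_range = c(12, 216),
                             age_sampler = c("uniform", "truncnorm"),
                             age_mean = 114, age_sd = 60,
                             ba_ca_sd = 12,
                             n_raters = 7L,
                             rater_biases = rep(0, n_raters),
                             rater_sds = rep(0, n_raters),
                             rater_noise_mode = c("constant", "age_proportional"),
                             ai_slope = 1, ai_offset = 0, ai_sd = 0,
                             sex_specific_ai = NULL,
                             disorder_rate = 0, seed = 1L) {
  age_sampler <- match.arg(age_sampler)
  rater_noise_mode <- match.arg(rater_noise_mode)
  stopifnot_scalar_number(n_images, "n_images", lower = 0)
  stopifnot_scalar_number(sex_ratio, "sex_ratio", lower = 0, upper = 1)
  stopifnot_scalar_number(disorder_rate, "disorder_rate", lower = 0, upper = 1)
  stopifnot_scalar_number(ba_ca_sd, "ba_ca_sd", lower = 0)
  stopifnot_scalar_number(ai_sd, "ai_sd", lower = 0)
  if (length(rater_biases) != n_raters || length(rater_sds) != n_raters) {
    stop("rater_biases and rater_sds must have length n_raters", call. = FALSE)
  }
  if (any(rater_sds < 0)) stop("rater noise SDs must be >= 0", call. = FALSE)
  if (!is.null(sex_specific_ai)) {
    if (!all(SEX_LEVELS %in% names(sex_specific_ai))) {
      stop("sex_specific_ai must have elements 'female' and 'male'",
           call. = FALSE)
    }
  }
  structure(list(n_images = as.integer(n_images), sex_ratio = sex_ratio,
                 age_range = age_range, age_sampler = age_sampler,
                 age_mean = age_mean, age_sd = age_sd, ba_ca_sd = ba_ca_sd,
                 n_raters = as.integer(n_raters),
                 rater_biases = rater_biases, rater_sds = rater_sds,
                 rater_noise_mode = rater_noise_mode,
                 ai_slope = ai_slope, ai_offset = ai_offset, ai_sd = ai_sd,
                 sex_specific_ai = sex_specific_ai,
                 disorder_rate = disorder_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generator configuration emulating the Georgian bone-age study cohort
#'
#' Defaults reproduce, in expectation, the headline structure of the study
#' cohort this package is designed to analyse: 381 images (19 with a known
#' disorder), a 7-rater panel whose signed biases span [-3.07, +1.55]
#' months, and a sex-specific AI distortion equal to the inverse of the
#' published calibration fits, so that the uncalibrated AI overestimates
#' the consensus bone age by roughly +2.8 months in females and +5.1
#' months in males.
#'
#' @param seed integer RNG seed.
#' @param n_images cohort size (default 381).
#' @return a \code{\link{synthetic_config}}.
#' @export
default_gbad_like_config <- function(seed = 1L, n_images = 381L) {
  synthetic_config(
    n_images = n_images,
    sex_ratio = 184 / 381,
    age_range = c(12, 216),
    ba_ca_sd = 12,
    n_raters = 7L,
    rater_biases = c(-3.07, -0.8, -0.2, 0.3, 0.9, 1.32, 1.55),
    rater_sds = c(7, 8, 8.5, 9, 9.5, 10.5, 12),
    ai_sd = 5.5,
    sex_specific_ai = list(
      female = c(slope = 1 / 1.032, offset = 6.532 / 1.032),
      male = c(slope = 1 / 1.040, offset = 9.860 / 1.040)),
    disorder_rate = 19 / 381,
    seed = seed)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per image: chronological age is drawn from the configured age sampler;
#' true bone age is CA plus normal biological variation (SD
#' \code{ba_ca_sd}); each rater reports BA_true plus their fixed bias plus
#' noise; the AI reports \code{a_sex * BA_true + c_sex} plus noise.
#' Simulated bone ages are floored at 0 months. The ground truth is
#' returned separately and never enters the cohort CSV.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{cohort} (a \code{ba_cohort}) and
#'   \code{truth} (data.frame \code{image_id}, \code{ba_true_months}).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_images
  k <- config$n_raters
  withr::with_seed(config$seed, {
    sex <- factor(ifelse(stats::runif(n) < config$sex_ratio,
                         "female", "male"), levels = SEX_LEVELS)
    ca <- switch(config$age_sampler,
      uniform = stats::runif(n, config$age_range[1L], config$age_range[2L]),
      truncnorm = {
        lo <- stats::pnorm(config$age_range[1L], config$age_mean, config$age_sd)
        hi <- stats::pnorm(config$age_range[2L], config$age_mean, config$age_sd)
        stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
      })
    ba_true <- pmax(0, ca + stats::rnorm(n, 0, config$ba_ca_sd))
    ratings <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      sd_j <- switch(config$rater_noise_mode,
                     constant = rep(config$rater_sds[j], n),
                     age_proportional =
                       config$rater_sds[j] * ba_true / mean(config$age_range))
      ratings[, j] <- pmax(0, ba_true + config$rater_biases[j] +
                                stats::rnorm(n, 0, sd_j))
    }
    colnames(ratings) <- paste0("rater_", seq_len(k))
    if (is.null(config$sex_specific_ai)) {
      a <- rep(config$ai_slope, n)
      cc <- rep(config$ai_offset, n)
    } else {
      pars <- config$sex_specific_ai
      a <- ifelse(sex == "female", pars$female[["slope"]], pars$male[["slope"]])
      cc <- ifelse(sex == "female", pars$female[["offset"]], pars$male[["offset"]])
    }
    ai <- pmax(0, a * ba_true + cc + stats::rnorm(n, 0, config$ai_sd))
    disorder <- stats::runif(n) < config$disorder_rate
    info <- data.frame(image_id = sprintf("img_%04d", seq_len(n)),
                       sex = sex, ca_months = ca, ai_ba_months = ai,
                       disorder = disorder, stringsAsFactors = FALSE)
    cohort <- ba_cohort(info, ratings,
                        provenance = list(source = "synthetic",
                                          seed = config$seed,
                                          config = unclass(config)),
                        relax_age_range = TRUE)
    list(cohort = cohort,
         truth = data.frame(image_id = info$image_id,
                            ba_true_months = ba_true,
                            stringsAsFactors = FALSE))
  })
}
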