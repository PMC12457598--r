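# Consensus reference bone age from a multi-rater panel:
#   1. initial, uncorrected consensus = per-image mean rating;
#   2. exclusions (missing assessments; any rating deviating > threshold
#      months from the initial mean);
#   3. per-rater signed bias (SMD vs the initial mean) and MAD of the
#      bias-corrected rater vs the initial mean;
#   4. performance-weighted average with weights proportional to 1/MAD.

#' Initial, uncorrected consensus bone age
#'
#' Unweighted arithmetic mean of the available ratings per image.
#'
#' @param cohort a \code{ba_cohort}.
#' @return named numeric vector of mean ratings (months), one per image.
#' @export
initial_consensus <- function(cohort) {
  r <- cohort$ratings
  none <- rowSums(!is.na(r)) == 0L
  if (any(none)) {
    stop("image(s) without any rating: ",
         paste(cohort$info$image_id[none], collapse = ", "), call. = FALSE)
  }
  stats::setNames(rowMeans(r, na.rm = TRUE), cohort$info$image_id)
}

#' Apply the study exclusion rules
#'
#' Removes images with a missing rating (if \code{drop_missing}) and images
#' where any single rating deviates strictly more than
#' \code{deviation_threshold} months from the initial, uncorrected mean.
#'
#' @param cohort a \code{ba_cohort}.
#' @param initial initial consensus as returned by
#'   \code{\link{initial_consensus}} on the same cohort.
#' @param deviation_threshold months; exclusion is strict
#'   (deviation > threshold).
#' @param drop_missing exclude images with any missing rating.
#' @return list with \code{cohort} (filtered) and \code{excluded}
#'   (data.frame \code{image_id}, \code{reason} in
#'   \{missing_rating, deviation_gt_threshold\}).
#' @export
apply_exclusions <- function(cohort, initial = initial_consensus(cohort),
                             deviation_threshold = 30, drop_missing = TRUE) {
  if (!is.numeric(deviation_threshold) || deviation_threshold <= 0) {
    stop("deviation_threshold must be > 0", call. = FALSE)
  }
  r <- cohort$ratings
  init <- initial[cohort$info$image_id]
  has_missing <- rowSums(is.na(r)) > 0L
  dev <- abs(r - init)
  deviates <- rowSums(dev > deviation_threshold, na.rm = TRUE) > 0L
  reason <- rep(NA_character_, n_images(cohort))
  if (drop_missing) reason[has_missing] <- "missing_rating"
  reason[is.na(reason) & deviates] <- "deviation_gt_threshold"
  drop <- !is.na(reason)
  excluded <- data.frame(image_id = cohort$info$image_id[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  list(cohort = subset_cohort(cohort, cohort$info$image_id[!drop]),
       excluded = excluded)
}

#' Fit per-rater bias, MAD and consensus weight
#'
#' For rater j against the initial uncorrected mean:
#' \code{smd_bias_j = mean(rating_j - initial)};
#' \code{mad_j = mean(|rating_j - smd_bias_j - initial|)} (the
#' bias-corrected rater vs the initial mean);
#' \code{weight_j = (1/mad_j) / sum_l (1/mad_l)}.
#'
#' @param cohort a \code{ba_cohort} with complete ratings (run
#'   \code{\link{apply_exclusions}} first).
#' @param initial initial consensus on the same cohort.
#' @param mad_floor months; a rater in perfect agreement (MAD 0) is floored
#'   here so the weight stays finite (a warning is emitted).
#' @return data.frame of class \code{"rater_profiles"} with columns
#'   \code{rater_id}, \code{smd_bias}, \code{mad}, \code{weight}.
#' @export
fit_rater_profiles <- function(cohort, initial = initial_consensus(cohort),
                               mad_floor = 1e-6) {
  r <- cohort$ratings
  if (anyNA(r)) {
    stop("ratings contain missing values; apply exclusions before fitting ",
         "rater profiles", call. = FALSE)
  }
  init <- initial[cohort$info$image_id]
  dev <- r - init
  smd_bias <- colMeans(dev)
  mad <- colMeans(abs(sweep(dev, 2L, smd_bias)))
  if (any(mad < mad_floor)) {
    warning("rater(s) in (near-)perfect agreement with the initial mean: ",
            paste(cohort$rater_ids[mad < mad_floor], collapse = ", "),
            "; MAD floored at ", mad_floor, " months", call. = FALSE)
    mad <- pmax(mad, mad_floor)
  }
  w <- (1 / mad) / sum(1 / mad)
  structure(data.frame(rater_id = cohort$rater_ids, smd_bias = smd_bias,
                       mad = mad, weight = w, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("rater_profiles", "data.frame"))
}

#' Performance-weighted, bias-corrected consensus
#'
#' \code{consensus_i = sum_j weight_j * (rating_ij - smd_bias_j)}.
#'
#' @param cohort a \code{ba_cohort} with complete ratings.
#' @param profiles \code{\link{fit_rater_profiles}} output for this cohort.
#' @return named numeric vector of consensus bone ages (months).
#' @export
build_consensus <- function(cohort, profiles) {
  if (!identical(as.character(profiles$rater_id), cohort$rater_ids)) {
    stop("rater panel mismatch between cohort and profiles", call. = FALSE)
  }
  if (anyNA(cohort$ratings)) {
    stop("ratings contain missing values", call. = FALSE)
  }
  corrected <- sweep(cohort$ratings, 2L, profiles$smd_bias)
  stats::setNames(drop(corrected %*% profiles$weight),
                  cohort$info$image_id)
}

#' Full consensus pipeline
#'
#' Runs initial mean, exclusions, profile fitting and the weighted
#' consensus in one pass (optionally iterating bias/MAD re-estimation
#' against the current weighted consensus until convergence).
#'
#' @param cohort a \code{ba_cohort} (k >= 2 raters).
#' @param deviation_threshold months, see \code{\link{apply_exclusions}}.
#' @param drop_missing exclude images with missing ratings.
#' @param mad_floor months, see \code{\link{fit_rater_profiles}}.
#' @param iterate if \code{TRUE}, re-anchor bias/MAD estimation on the
#'   weighted consensus and repeat to convergence (off by default; the
#'   reference procedure is single-pass, anchored on the initial mean).
#' @param tol convergence tolerance (months) for the iterative mode.
#' @return object of class \code{"ba_consensus"}: list with
#'   \code{consensus} (named vector, months), \code{profiles},
#'   \code{excluded}, \code{included_count}, \code{initial}, and
#'   \code{settings}.
#' @export
consensus_pipeline <- function(cohort, deviation_threshold = 30,
                               drop_missing = TRUE, mad_floor = 1e-6,
                               iterate = FALSE, tol = 1e-8) {
  if (n_raters(cohort) < 2L) stop("consensus needs k >= 2 raters", call. = FALSE)
  init_all <- initial_consensus(cohort)
  excl <- apply_exclusions(cohort, init_all, deviation_threshold, drop_missing)
  kept <- excl$cohort
  if (n_images(kept) == 0L) {
    stop("no images survive the exclusion rules", call. = FALSE)
  }
  init <- initial_consensus(kept)
  profiles <- fit_rater_profiles(kept, init, mad_floor = mad_floor)
  consensus <- build_consensus(kept, profiles)
  if (iterate) {
    for (pass in seq_len(25L)) {
      ref <- consensus
      dev <- kept$ratings - ref
      smd_bias <- colMeans(dev)
      mad <- pmax(colMeans(abs(sweep(dev, 2L, smd_bias))), mad_floor)
      w <- (1 / mad) / sum(1 / mad)
      profiles$smd_bias <- smd_bias
      profiles$mad <- mad
      profiles$weight <- w
      consensus <- build_consensus(kept, profiles)
      if (max(abs(consensus - ref)) < tol) break
    }
  }
  structure(list(consensus = consensus, profiles = profiles,
                 excluded = excl$excluded, included_count = n_images(kept),
                 initial = init, cohort = kept,
                 settings = list(deviation_threshold = deviation_threshold,
                                 drop_missing = drop_missing,
                                 mad_floor = mad_floor, iterate = iterate)),
            class = "ba_consensus")
}

#' @export
print.ba_consensus <- function(x, ...) {
  cat(sprintf("<ba_consensus> %d images included, %d excluded\n",
              x$included_count, nrow(x$excluded)))
  cat("rater profiles (bias / MAD / weight):\n")
  print(x$profiles, digits = 4)
  invisible(x)
}

#' Leave-one-rater-out consensus
#'
#' Re-runs the full consensus pipeline on the panel without the named
#' rater: initial mean, exclusions, bias and 1/MAD weights are all
#' recomputed from the remaining k - 1 raters, exactly as running the
#' standard pipeline on a cohort with that rater column deleted. The
#' held-out rater (and any AI version) can then be scored against the
#' returned consensus.
#'
#' @param cohort a \code{ba_cohort} with k >= 3 raters.
#' @param left_out rater label to hold out.
#' @param ... passed to \code{\link{consensus_pipeline}}.
#' @return a \code{"ba_consensus"} built from the remaining raters.
#' @export
leave_one_out_consensus <- function(cohort, left_out, ...) {
  if (n_raters(cohort) < 3L) {
    stop("leave-one-out consensus needs k >= 3 raters", call. = FALSE)
  }
  consensus_pipeline(drop_rater(cohort, left_out), ...)
}
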