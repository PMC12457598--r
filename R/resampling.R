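# Age/sex-stratified train-test partitioning and the bootstrap
# re-partitioning stability analysis: repeated random 1/3-2/3 splits
# (without replacement), refitting the sex-specific calibration on each
# calibration set and scoring it on the complementary test set.

#' Age- and sex-stratified train/test split
#'
#' Images of children with a known disorder are always assigned to the
#' test set. The remaining images are allocated to the train set per
#' (age-bin x sex) stratum with largest-remainder rounding so that the
#' global train count equals \code{round(train_fraction * n_eligible)}
#' exactly; membership within a stratum is drawn with the given seed.
#'
#' @param cohort a \code{ba_cohort}.
#' @param train_fraction fraction of non-disorder images assigned to the
#'   train (calibration) set, in (0, 1).
#' @param age_bins bin edges in months for the age stratification
#'   (chronological age); ages beyond the last edge fall into an open
#'   top bin.
#' @param seed integer seed; splits are deterministic given the seed.
#' @return object of class \code{"partition_spec"}: list with
#'   \code{train_ids}, \code{test_ids}, \code{train_fraction},
#'   \code{age_bins}, \code{seed}.
#' @export
stratified_split <- function(cohort, train_fraction = 1 / 3,
                             age_bins = seq(0, 216, by = 24), seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  info <- cohort$info
  disorder <- which(info$disorder)
  eligible <- which(!info$disorder)
  n_el <- length(eligible)
  target <- round(train_fraction * n_el)
  breaks <- sort(unique(c(age_bins, Inf)))
  bin <- cut(info$ca_months[eligible], breaks = breaks, include.lowest = TRUE,
             right = TRUE)
  stratum <- interaction(bin, info$sex[eligible], drop = TRUE)
  sizes <- tabulate(stratum, nbins = nlevels(stratum))
  quota <- sizes * train_fraction
  base <- floor(quota)
  remainder <- quota - base
  extra <- target - sum(base)
  take <- base
  if (extra > 0) {
    # largest remainders first; ties broken by stratum order
    ord <- order(remainder, decreasing = TRUE)
    ord <- ord[sizes[ord] > base[ord]]
    take[ord[seq_len(min(extra, length(ord)))]] <-
      base[ord[seq_len(min(extra, length(ord)))]] + 1L
  }
  train_idx <- integer(0)
  withr::with_seed(seed, {
    for (g in seq_len(nlevels(stratum))) {
      members <- eligible[stratum == levels(stratum)[g]]
      if (take[g] > 0L) {
        train_idx <- c(train_idx, sort(members[sample.int(length(members),
                                                          take[g])]))
      }
    }
  })
  train_ids <- info$image_id[sort(train_idx)]
  test_ids <- setdiff(info$image_id, train_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 train_fraction = train_fraction, age_bins = age_bins,
                 seed = as.integer(seed)),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("<partition_spec> %d train / %d test (fraction %.3f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$train_fraction,
              x$seed))
  invisible(x)
}

eval_partition <- function(cohort, consensus_ba, split, conf = 0.95,
                           one_year_threshold = 12) {
  info <- cohort$info
  tr <- match(split$train_ids, info$image_id)
  te <- match(split$test_ids, info$image_id)
  model <- fit_calibration(info$ai_ba_months[tr],
                           consensus_ba[split$train_ids], info$sex[tr],
                           conf = conf)
  cal <- suppressWarnings(apply_calibration(model, info$ai_ba_months[te],
                                            info$sex[te]))
  ref <- consensus_ba[split$test_ids]
  list(model = model,
       mad = ba_mad(cal, ref),
       rmse = sqrt(mean((cal - ref)^2)),
       accuracy = one_year_accuracy(cal, ref, one_year_threshold))
}

#' Bootstrap re-partitioning stability analysis
#'
#' Draws \code{n_replicates} fresh stratified train/test partitions
#' (replicate seeds derived deterministically from \code{master_seed} via
#' \code{\link{derive_seed}}), refits the sex-specific calibration on each
#' train part, and scores the calibrated AI on the complementary test
#' part. Summaries are percentile intervals (linear-interpolation
#' quantiles, R type 7) of the per-replicate calibration parameters and
#' test metrics, plus per-sex correction-curve bands: the correction
#' \code{(slope - 1) * raw + intercept} evaluated on a raw bone-age grid.
#'
#' @param cohort a filtered \code{ba_cohort} (no missing ratings).
#' @param consensus a \code{ba_consensus} (or a named consensus vector)
#'   covering all images of \code{cohort}.
#' @param n_replicates number of re-partitions (study default 1000).
#' @param train_fraction fraction for the calibration set (default 1/3).
#' @param age_bins stratification bin edges, months.
#' @param master_seed integer master seed.
#' @param grid raw bone-age grid (months) for the correction curves.
#' @param conf confidence level of the percentile intervals.
#' @param one_year_threshold months, accuracy threshold.
#' @return object of class \code{"ba_bootstrap"}: list with
#'   \code{replicates} (data.frame of per-replicate parameters and
#'   metrics), \code{ci} (percentile intervals), \code{curves} (per-sex
#'   data.frame raw/lower/median/upper), counts and seeds.
#' @export
bootstrap_repartition <- function(cohort, consensus, n_replicates = 1000L,
                                  train_fraction = 1 / 3,
                                  age_bins = seq(0, 216, by = 24),
                                  master_seed = 1L,
                                  grid = seq(12, 216, by = 12),
                                  conf = 0.95, one_year_threshold = 12) {
  consensus_ba <- if (inherits(consensus, "ba_consensus")) consensus$consensus
                  else consensus
  if (!all(cohort$info$image_id %in% names(consensus_ba))) {
    stop("consensus does not cover every image of the cohort", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  cols <- c("slope_female", "intercept_female", "slope_male",
            "intercept_male", "mad", "rmse", "accuracy")
  reps <- as.data.frame(matrix(NA_real_, n_replicates, length(cols),
                               dimnames = list(NULL, cols)))
  reps$seed <- derive_seed(master_seed, seq_len(n_replicates))
  reps$ok <- FALSE
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      split <- stratified_split(cohort, train_fraction, age_bins,
                                seed = reps$seed[r])
      eval_partition(cohort, consensus_ba, split, conf, one_year_threshold)
    }, error = function(e) e)
    if (inherits(res, "error")) next
    m <- res$model$models
    reps$slope_female[r] <- m$female$slope %||% NA_real_
    reps$intercept_female[r] <- m$female$intercept %||% NA_real_
    reps$slope_male[r] <- m$male$slope %||% NA_real_
    reps$intercept_male[r] <- m$male$intercept %||% NA_real_
    reps$mad[r] <- res$mad
    reps$rmse[r] <- res$rmse
    reps$accuracy[r] <- res$accuracy
    reps$ok[r] <- TRUE
  }
  failed <- sum(!reps$ok)
  if (failed > 0.01 * n_replicates) {
    stop(failed, " of ", n_replicates, " bootstrap replicates failed ",
         "(singular fits or empty strata); check the cohort", call. = FALSE)
  }
  probs <- c((1 - conf) / 2, 0.5, 1 - (1 - conf) / 2)
  ok <- reps$ok
  ci <- lapply(cols, function(cl) {
    stats::quantile(reps[[cl]][ok], probs = probs[c(1L, 3L)], names = FALSE,
                    type = 7)
  })
  names(ci) <- cols
  curves <- lapply(SEX_LEVELS, function(s) {
    sl <- reps[[paste0("slope_", s)]][ok]
    ic <- reps[[paste0("intercept_", s)]][ok]
    corr <- outer(sl - 1, grid) + ic  # replicates x grid
    q <- apply(corr, 2L, stats::quantile, probs = probs, names = FALSE,
               type = 7)
    data.frame(raw = grid, lower = q[1L, ], median = q[2L, ], upper = q[3L, ])
  })
  names(curves) <- SEX_LEVELS
  structure(list(replicates = reps, ci = ci, curves = curves,
                 n_replicates = n_replicates, failed = failed,
                 master_seed = as.integer(master_seed),
                 train_fraction = train_fraction, age_bins = age_bins,
                 grid = grid, conf = conf,
                 quantile_type = 7L),
            class = "ba_bootstrap")
}

#' @export
print.ba_bootstrap <- function(x, ...) {
  cat(sprintf("<ba_bootstrap> %d re-partitions (%d failed), master seed %d\n",
              x$n_replicates, x$failed, x$master_seed))
  cat(sprintf("  test MAD %s[%.2f, %.2f], RMSE [%.2f, %.2f], 1-year accuracy [%.1f%%, %.1f%%]\n",
              "", x$ci$mad[1L], x$ci$mad[2L], x$ci$rmse[1L], x$ci$rmse[2L],
              x$ci$accuracy[1L], x$ci$accuracy[2L]))
  invisible(x)
}

#' Check the primary calibration against the bootstrap band
#'
#' Evaluates the primary model's correction \code{(slope - 1) * raw +
#' intercept} on the bootstrap grid and checks, per sex, whether it lies
#' inside the bootstrap percentile band at every grid point.
#'
#' @param primary_model a \code{ba_calibration} fitted on the primary
#'   partition.
#' @param summary a \code{\link{bootstrap_repartition}} result from the
#'   same cohort.
#' @return list per sex with \code{inside} (logical per grid point),
#'   \code{coverage} (fraction inside) and \code{pass} (all inside), plus
#'   \code{overall_pass}.
#' @export
correction_within_band <- function(primary_model, summary) {
  stopifnot(inherits(primary_model, "ba_calibration"),
            inherits(summary, "ba_bootstrap"))
  out <- list()
  for (s in names(summary$curves)) {
    if (is.null(primary_model$models[[s]])) next
    band <- summary$curves[[s]]
    m <- primary_model$models[[s]]
    corr <- (m$slope - 1) * band$raw + m$intercept
    inside <- corr >= band$lower - 1e-9 & corr <= band$upper + 1e-9
    out[[s]] <- list(inside = inside, coverage = mean(inside),
                     pass = all(inside))
  }
  out$overall_pass <- all(vapply(out, function(z) z$pass, TRUE))
  out
}
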