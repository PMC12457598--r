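# End-to-end study pipeline: consensus -> exclusions -> stratified split
# -> sex-specific calibration on the train part -> agreement evaluation of
# the uncalibrated and calibrated AI on the test part -> leave-one-rater-
# out benchmark -> bootstrap re-partitioning -> BA-minus-CA summaries.

#' Study configuration
#'
#' @param deviation_threshold months; image exclusion rule (any rating
#'   deviating strictly more than this from the initial mean).
#' @param drop_missing exclude images with a missing rating.
#' @param mad_floor months; floor for a zero-MAD rater weight.
#' @param train_fraction fraction of eligible images in the calibration
#'   set.
#' @param age_bins stratification bin edges, months.
#' @param seed master seed; the split seed and bootstrap seed stream are
#'   derived from it deterministically.
#' @param n_replicates bootstrap re-partitions (study default 1000).
#' @param run_bootstrap run the bootstrap stability analysis.
#' @param leave_one_out compute the leave-one-rater-out benchmark table.
#' @param one_year_threshold months; accuracy threshold.
#' @param conf confidence level used throughout.
#' @return list of class \code{"study_config"}.
#' @export
study_config <- function(deviation_threshold = 30, drop_missing = TRUE,
                         mad_floor = 1e-6, train_fraction = 1 / 3,
                         age_bins = seq(0, 216, by = 24), seed = 1L,
                         n_replicates = 1000L, run_bootstrap = TRUE,
                         leave_one_out = TRUE, one_year_threshold = 12,
                         conf = 0.95) {
  structure(list(deviation_threshold = deviation_threshold,
                 drop_missing = drop_missing, mad_floor = mad_floor,
                 train_fraction = train_fraction, age_bins = age_bins,
                 seed = as.integer(seed),
                 split_seed = derive_seed(seed, 1L),
                 bootstrap_seed = derive_seed(seed, 2L),
                 n_replicates = as.integer(n_replicates),
                 run_bootstrap = run_bootstrap,
                 leave_one_out = leave_one_out,
                 one_year_threshold = one_year_threshold, conf = conf),
            class = "study_config")
}

loo_benchmark <- function(cohort, test_ids, model, config) {
  rows <- lapply(cohort$rater_ids, function(rid) {
    loo <- leave_one_out_consensus(cohort, rid,
                                   deviation_threshold = config$deviation_threshold,
                                   drop_missing = config$drop_missing,
                                   mad_floor = config$mad_floor)
    ids <- intersect(test_ids, names(loo$consensus))
    ref <- loo$consensus[ids]
    idx <- match(ids, cohort$info$image_id)
    manual <- cohort$ratings[idx, rid]
    raw <- cohort$info$ai_ba_months[idx]
    cal <- suppressWarnings(apply_calibration(model, raw,
                                              cohort$info$sex[idx]))
    one <- function(pred) {
      r <- rmse_with_ci(pred, ref, config$conf)
      c(mad = ba_mad(pred, ref), rmse = r$rmse, rmse_lo = r$ci[1L],
        rmse_hi = r$ci[2L])
    }
    data.frame(left_out_rater = rid, n = length(ids),
               t(c(manual = one(manual), ai = one(raw), cal = one(cal))),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("\\.", "_", names(out))
  rownames(out) <- NULL
  out
}

#' Run the full calibration-and-validation study
#'
#' @param cohort a \code{ba_cohort} (read with \code{\link{read_cohort}}
#'   or simulated with \code{\link{generate_cohort}}).
#' @param config a \code{\link{study_config}}.
#' @return object of class \code{"ba_study"}: list with the consensus
#'   result, partition, calibration model, uncalibrated/calibrated
#'   \code{\link{agreement_report}}s (overall and per sex), the
#'   leave-one-out table, bootstrap summary with the band check, BA-CA
#'   summaries and a provenance block (seeds and counts).
#' @export
run_study <- function(cohort, config = study_config()) {
  stopifnot(inherits(cohort, "ba_cohort"), inherits(config, "study_config"))
  cons <- consensus_pipeline(cohort,
                             deviation_threshold = config$deviation_threshold,
                             drop_missing = config$drop_missing,
                             mad_floor = config$mad_floor)
  included <- cons$cohort
  split <- stratified_split(included, config$train_fraction,
                            config$age_bins, seed = config$split_seed)
  info <- included$info
  tr <- match(split$train_ids, info$image_id)
  te <- match(split$test_ids, info$image_id)
  model <- fit_calibration(info$ai_ba_months[tr],
                           cons$consensus[split$train_ids], info$sex[tr],
                           conf = config$conf)
  raw_te <- info$ai_ba_months[te]
  cal_te <- suppressWarnings(apply_calibration(model, raw_te, info$sex[te]))
  ref_te <- cons$consensus[split$test_ids]
  sex_te <- info$sex[te]
  report_set <- function(pred, label) {
    overall <- agreement_report(pred, ref_te, label = label,
                                one_year_threshold = config$one_year_threshold,
                                conf = config$conf)
    by_sex <- lapply(stats::setNames(SEX_LEVELS, SEX_LEVELS), function(s) {
      i <- sex_te == s
      if (sum(i) < 2L) return(NULL)
      agreement_report(pred[i], ref_te[i], label = paste(label, s),
                       one_year_threshold = config$one_year_threshold,
                       conf = config$conf)
    })
    list(overall = overall, by_sex = by_sex)
  }
  uncal <- report_set(raw_te, "uncalibrated")
  cal <- report_set(cal_te, "calibrated")
  loo <- if (config$leave_one_out && n_raters(included) >= 3L) {
    loo_benchmark(included, split$test_ids, model, config)
  }
  boot <- band <- NULL
  if (config$run_bootstrap) {
    boot <- bootstrap_repartition(included, cons,
                                  n_replicates = config$n_replicates,
                                  train_fraction = config$train_fraction,
                                  age_bins = config$age_bins,
                                  master_seed = config$bootstrap_seed,
                                  conf = config$conf,
                                  one_year_threshold = config$one_year_threshold)
    band <- correction_within_band(model, boot)
  }
  cal_all <- suppressWarnings(apply_calibration(model, info$ai_ba_months,
                                                info$sex))
  ba_ca <- list(
    consensus = ba_minus_ca_summary(cons$consensus[info$image_id],
                                    info$ca_months, info$sex),
    raw_ai = ba_minus_ca_summary(info$ai_ba_months, info$ca_months, info$sex),
    calibrated_ai = ba_minus_ca_summary(cal_all, info$ca_months, info$sex))
  structure(list(consensus = cons, split = split, model = model,
                 uncalibrated = uncal, calibrated = cal,
                 leave_one_out = loo, bootstrap = boot,
                 correction_band = band, ba_minus_ca = ba_ca,
                 provenance = list(seed = config$seed,
                                   split_seed = config$split_seed,
                                   bootstrap_seed = config$bootstrap_seed,
                                   n_input = n_images(cohort),
                                   n_included = cons$included_count,
                                   n_excluded = nrow(cons$excluded),
                                   n_train = length(split$train_ids),
                                   n_test = length(split$test_ids),
                                   config = unclass(config))),
            class = "ba_study")
}

#' @export
print.ba_study <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<ba_study> %d images (%d excluded) -> %d train / %d test\n",
              p$n_input, p$n_excluded, p$n_train, p$n_test))
  print(x$model)
  cat("test set, uncalibrated:\n")
  print(x$uncalibrated$overall)
  cat("test set, calibrated:\n")
  print(x$calibrated$overall)
  if (!is.null(x$bootstrap)) print(x$bootstrap)
  invisible(x)
}

report_row <- function(r) {
  data.frame(n = r$n, mad = r$mad, rmse = r$rmse, rmse_lo = r$rmse_ci[1L],
             rmse_hi = r$rmse_ci[2L], smd = r$smd, smd_lo = r$smd_ci[1L],
             smd_hi = r$smd_ci[2L], one_year_accuracy = r$one_year_accuracy,
             icc = r$icc, icc_lo = r$icc_ci[1L], icc_hi = r$icc_ci[2L],
             ba_pct_within = r$bland_altman$pct_within, ks_p = r$ks_p)
}

#' Render the study's summary tables to CSV
#'
#' Writes an accuracy table (uncalibrated vs calibrated AI on the test
#' set, overall and per sex) and, when available, the leave-one-rater-out
#' benchmark table and the correction-curve bands.
#'
#' @param report a \code{\link{run_study}} result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "ba_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  rows <- list()
  for (which in c("uncalibrated", "calibrated")) {
    set <- report[[which]]
    rows[[length(rows) + 1L]] <-
      cbind(predictor = which, subset = "all", report_row(set$overall))
    for (s in SEX_LEVELS) {
      if (!is.null(set$by_sex[[s]])) {
        rows[[length(rows) + 1L]] <-
          cbind(predictor = which, subset = s, report_row(set$by_sex[[s]]))
      }
    }
  }
  t1 <- file.path(dir, "accuracy_table.csv")
  utils::write.csv(do.call(rbind, rows), t1, row.names = FALSE)
  files["accuracy"] <- t1
  if (!is.null(report$leave_one_out)) {
    t2 <- file.path(dir, "leave_one_out_table.csv")
    utils::write.csv(report$leave_one_out, t2, row.names = FALSE)
    files["leave_one_out"] <- t2
  }
  if (!is.null(report$bootstrap)) {
    curves <- do.call(rbind, lapply(SEX_LEVELS, function(s) {
      cbind(sex = s, report$bootstrap$curves[[s]])
    }))
    t3 <- file.path(dir, "correction_curves.csv")
    utils::write.csv(curves, t3, row.names = FALSE)
    files["correction_curves"] <- t3
  }
  invisible(files)
}

#' Write the study report as JSON
#'
#' Serializes the numeric content of a study report (calibration
#' parameters, agreement statistics, bootstrap intervals, exclusions,
#' provenance) to a JSON file.
#'
#' @param report a \code{\link{run_study}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "ba_study"))
  strip <- function(r) r[setdiff(names(r), c("label"))]
  payload <- list(
    provenance = report$provenance,
    excluded = report$consensus$excluded,
    rater_profiles = report$consensus$profiles,
    model = report$model$models,
    uncalibrated = c(list(overall = strip(unclass(report$uncalibrated$overall))),
                     lapply(report$uncalibrated$by_sex,
                            function(r) if (!is.null(r)) strip(unclass(r)))),
    calibrated = c(list(overall = strip(unclass(report$calibrated$overall))),
                   lapply(report$calibrated$by_sex,
                          function(r) if (!is.null(r)) strip(unclass(r)))),
    leave_one_out = report$leave_one_out,
    bootstrap = if (!is.null(report$bootstrap)) {
      list(n_replicates = report$bootstrap$n_replicates,
           failed = report$bootstrap$failed,
           master_seed = report$bootstrap$master_seed,
           ci = report$bootstrap$ci,
           curves = report$bootstrap$curves)
    },
    correction_band = if (!is.null(report$correction_band)) {
      lapply(report$correction_band[SEX_LEVELS], function(b) {
        if (!is.null(b)) list(pass = b$pass, coverage = b$coverage)
      })
    },
    ba_minus_ca = report$ba_minus_ca)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
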