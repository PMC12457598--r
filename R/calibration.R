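# Sex-specific linear recalibration of raw AI bone-age predictions:
#     BA_calibrated = slope_sex * BA_raw + intercept_sex
# fitted by ordinary least squares of the consensus reference on the raw
# prediction, separately per sex.

#' Fit the sex-specific linear calibration
#'
#' OLS of \code{reference_ba} on \code{raw_ba} within each sex stratum;
#' 95\% CIs from the t-distribution on the coefficient standard errors.
#' The regression direction (reference as response) is forced by the form
#' of the calibration equation.
#'
#' @param raw_ba raw AI bone-age predictions, months.
#' @param reference_ba consensus reference bone ages, months.
#' @param sex per-image sex labels (anything \code{\link{parse_sex}}
#'   accepts).
#' @param conf confidence level for the coefficient intervals.
#' @return object of class \code{"ba_calibration"}: per-sex list with
#'   \code{slope}, \code{intercept}, \code{slope_ci}, \code{intercept_ci},
#'   \code{n_fit}, \code{residual_sd}.
#' @export
fit_calibration <- function(raw_ba, reference_ba, sex, conf = 0.95) {
  if (length(raw_ba) != length(reference_ba) ||
      length(raw_ba) != length(sex)) {
    stop("raw_ba, reference_ba and sex must have equal length", call. = FALSE)
  }
  sex <- parse_sex(sex)
  models <- list()
  for (s in levels(sex)) {
    idx <- which(sex == s)
    if (!length(idx)) next
    if (length(idx) < 3L) {
      stop("sex stratum '", s, "' has ", length(idx),
           " image(s); >= 3 required for calibration", call. = FALSE)
    }
    x <- raw_ba[idx]
    y <- reference_ba[idx]
    if (stats::var(x) == 0) {
      stop("singular fit: raw_ba has zero variance in stratum '", s, "'",
           call. = FALSE)
    }
    fit <- stats::lm(y ~ x)
    est <- stats::coef(fit)
    ci <- suppressMessages(stats::confint(fit, level = conf))
    models[[s]] <- list(slope = unname(est[2L]),
                        intercept = unname(est[1L]),
                        slope_ci = unname(ci[2L, ]),
                        intercept_ci = unname(ci[1L, ]),
                        n_fit = length(idx),
                        residual_sd = stats::sigma(fit))
  }
  structure(list(models = models, conf = conf), class = "ba_calibration")
}

#' @export
print.ba_calibration <- function(x, ...) {
  cat("<ba_calibration> reference ~ raw, per sex\n")
  for (s in names(x$models)) {
    m <- x$models[[s]]
    cat(sprintf("  %-6s slope %.4f [%.4f, %.4f]  intercept %.3f [%.3f, %.3f] months  (n = %d, residual SD %.2f)\n",
                s, m$slope, m$slope_ci[1L], m$slope_ci[2L],
                m$intercept, m$intercept_ci[1L], m$intercept_ci[2L],
                m$n_fit, m$residual_sd))
  }
  invisible(x)
}

#' Apply a fitted calibration to raw predictions
#'
#' Returns \code{slope_sex * raw + intercept_sex}. Outputs are not clamped;
#' a warning is emitted if any calibrated bone age is negative.
#'
#' @param model a \code{\link{fit_calibration}} result.
#' @param raw_ba raw AI bone-age predictions, months.
#' @param sex per-image sex labels.
#' @return calibrated bone ages, months.
#' @export
apply_calibration <- function(model, raw_ba, sex) {
  stopifnot(inherits(model, "ba_calibration"))
  sex <- parse_sex(sex)
  missing_sex <- setdiff(unique(as.character(sex)), names(model$models))
  if (length(missing_sex)) {
    stop("calibration model has no parameters for sex: ",
         paste(missing_sex, collapse = ", "), call. = FALSE)
  }
  slope <- vapply(as.character(sex), function(s) model$models[[s]]$slope, 0)
  inter <- vapply(as.character(sex), function(s) model$models[[s]]$intercept, 0)
  out <- unname(slope * raw_ba + inter)
  if (any(out < 0)) {
    warning(sum(out < 0), " calibrated bone age(s) below 0 months ",
            "(outputs are not clamped)", call. = FALSE)
  }
  out
}

#' Serialize a calibration model to JSON
#' @param model a \code{ba_calibration}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "ba_calibration"))
  jsonlite::write_json(list(conf = model$conf, models = model$models),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path file written by \code{\link{write_calibration}}.
#' @return a \code{ba_calibration}.
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(raw$models, function(m) {
    list(slope = m$slope, intercept = m$intercept,
         slope_ci = as.numeric(m$slope_ci),
         intercept_ci = as.numeric(m$intercept_ci),
         n_fit = as.integer(m$n_fit), residual_sd = m$residual_sd)
  })
  structure(list(models = models, conf = raw$conf), class = "ba_calibration")
}
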