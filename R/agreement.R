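# Agreement statistics between a bone-age predictor and a reference:
# MAD, RMSE with chi-squared CI, signed mean difference with t CI,
# 1-year accuracy, ICC(2,k), Bland-Altman limits of agreement, and a
# Lilliefors (KS) normality check of the signed residuals.

check_pair <- function(pred, ref, min_n = 1L) {
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length", call. = FALSE)
  }
  if (length(pred) < min_n) {
    stop("need at least ", min_n, " paired value(s)", call. = FALSE)
  }
  if (anyNA(pred) || anyNA(ref)) {
    stop("pred and ref must not contain missing values", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean absolute difference (months)
#'
#' @param pred predictor bone ages, months.
#' @param ref reference bone ages, months.
#' @return mean of |pred - ref|, months.
#' @export
ba_mad <- function(pred, ref) {
  check_pair(pred, ref, 1L)
  mean(abs(pred - ref))
}

#' Chi-squared confidence interval for an RMSE
#'
#' Interval
#' \code{(sqrt(n RMSE^2 / chisq_{0.975,n}), sqrt(n RMSE^2 / chisq_{0.025,n}))}
#' under normally distributed residuals; the chi-squared quantiles use n
#' degrees of freedom. Useful on its own to reconstruct an interval from a
#' reported RMSE and sample size.
#'
#' @param rmse root mean squared error, months.
#' @param n sample size.
#' @param conf confidence level.
#' @return numeric interval c(lower, upper), months.
#' @export
rmse_ci_chisq <- function(rmse, n, conf = 0.95) {
  stopifnot_scalar_number(rmse, "rmse", lower = 0)
  stopifnot_scalar_number(n, "n", lower = 2)
  alpha <- 1 - conf
  c(sqrt(n * rmse^2 / stats::qchisq(1 - alpha / 2, df = n)),
    sqrt(n * rmse^2 / stats::qchisq(alpha / 2, df = n)))
}

#' Root mean squared error with chi-squared confidence interval
#'
#' @inheritParams ba_mad
#' @param conf confidence level.
#' @return list with \code{rmse} (months), \code{ci} (months) and \code{n}.
#' @export
rmse_with_ci <- function(pred, ref, conf = 0.95) {
  check_pair(pred, ref, 2L)
  n <- length(pred)
  rmse <- sqrt(mean((pred - ref)^2))
  list(rmse = rmse, ci = rmse_ci_chisq(rmse, n, conf), n = n)
}

#' Signed mean difference with t-based confidence interval
#'
#' \code{d_bar = mean(pred - ref)}; \code{SE = sd(d) / sqrt(n)} with the
#' n - 1 denominator in the sample SD; interval
#' \code{d_bar +/- t_{0.975, n-1} * SE}.
#'
#' @inheritParams ba_mad
#' @param conf confidence level.
#' @return list with \code{smd}, \code{ci}, \code{se}, \code{sd} (all
#'   months) and \code{n}.
#' @export
smd_with_ci <- function(pred, ref, conf = 0.95) {
  check_pair(pred, ref, 2L)
  d <- pred - ref
  n <- length(d)
  s <- stats::sd(d)
  se <- s / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
  list(smd = mean(d), ci = mean(d) + c(-1, 1) * tcrit * se,
       se = se, sd = s, n = n)
}

#' One-year accuracy (percent)
#'
#' Percentage of images whose absolute error is within the threshold
#' (inclusive: |pred - ref| <= 12 months counts as accurate).
#'
#' @inheritParams ba_mad
#' @param threshold months (default 12).
#' @return percent in [0, 100].
#' @export
one_year_accuracy <- function(pred, ref, threshold = 12) {
  check_pair(pred, ref, 1L)
  100 * mean(abs(pred - ref) <= threshold)
}

#' Intraclass correlation ICC(2,k), absolute agreement
#'
#' Two-way random-effects ICC for the average of k measurements on
#' absolute agreement (McGraw & Wong ICC(A,k)), with the F-based 95\% CI
#' (Satterthwaite degrees of freedom, average-measure bounds obtained from
#' the single-measure bounds via the Spearman-Brown step-up).
#'
#' @param ratings numeric matrix, images in rows, rating sources in
#'   columns; no missing cells.
#' @param conf confidence level.
#' @return list with \code{icc}, \code{ci}, the single-measure
#'   \code{icc_single} and \code{ci_single}, \code{n}, \code{k}, and the
#'   ANOVA mean squares \code{msr}, \code{msc}, \code{mse}.
#' @export
icc_2k <- function(ratings, conf = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ICC requires a complete-case matrix", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("ICC needs >= 2 images and >= 2 rating sources", call. = FALSE)
  }
  grand <- mean(x)
  rm <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm - grand)^2) / (n - 1L)
  msc <- n * sum((cm - grand)^2) / (k - 1L)
  mse <- sum((x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand)^2) /
    ((n - 1L) * (k - 1L))
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  if (1 - icc_1 < 1e-12) {
    ci1 <- c(icc_1, icc_1)  # degenerate: perfect absolute agreement
  } else {
    a <- k * icc_1 / (n * (1 - icc_1))
    b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fu <- stats::qf(1 - alpha / 2, n - 1, v)
    fl <- stats::qf(1 - alpha / 2, v, n - 1)
    ci1 <- c(n * (msr - fu * mse) /
               (fu * (k * msc + (k * n - k - n) * mse) + n * msr),
             n * (fl * msr - mse) /
               (k * msc + (k * n - k - n) * mse + n * fl * msr))
  }
  step_up <- function(r) r * k / (1 + (k - 1) * r)
  list(icc = icc_k, ci = step_up(ci1), icc_single = icc_1, ci_single = ci1,
       n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement summary
#'
#' Mean difference mu with limits of agreement mu +/- 1.96 sigma (sample
#' SD of the differences) and the percentage of cases falling inside the
#' closed interval.
#'
#' @inheritParams ba_mad
#' @return list with \code{mu}, \code{lower}, \code{upper}, \code{sd}
#'   (months) and \code{pct_within} (percent).
#' @export
bland_altman <- function(pred, ref) {
  check_pair(pred, ref, 2L)
  d <- pred - ref
  mu <- mean(d)
  s <- stats::sd(d)
  lower <- mu - 1.96 * s
  upper <- mu + 1.96 * s
  list(mu = mu, lower = lower, upper = upper, sd = s,
       pct_within = 100 * mean(d >= lower & d <= upper))
}

#' Normality check of signed residuals (Lilliefors/KS)
#'
#' Kolmogorov-Smirnov test against the normal distribution with mean and
#' SD estimated from the sample, using the Lilliefors correction of the
#' null distribution. A degenerate sample (zero SD) returns p = 0 with a
#' warning.
#'
#' @param diffs signed residuals, months (n >= 5).
#' @return the p-value.
#' @export
ks_normality <- function(diffs) {
  if (anyNA(diffs)) stop("diffs must not contain missing values", call. = FALSE)
  if (length(diffs) < 5L) stop("normality test needs n >= 5", call. = FALSE)
  if (stats::sd(diffs) == 0) {
    warning("degenerate sample (zero SD); returning p = 0", call. = FALSE)
    return(0)
  }
  unname(nortest::lillie.test(diffs)$p.value)
}

#' Per-sex summary of bone age minus chronological age
#'
#' Descriptive summary (n, mean, SD, quartiles) of BA - CA within each
#' sex, computable for any BA source (consensus, raw AI, calibrated AI).
#'
#' @param ba bone ages, months.
#' @param ca chronological ages, months.
#' @param sex per-image sex labels.
#' @return data.frame with one row per sex.
#' @export
ba_minus_ca_summary <- function(ba, ca, sex) {
  check_pair(ba, ca, 1L)
  sex <- parse_sex(sex)
  if (length(sex) != length(ba)) {
    stop("sex must have the same length as ba", call. = FALSE)
  }
  d <- ba - ca
  do.call(rbind, lapply(levels(sex), function(s) {
    ds <- d[sex == s]
    if (!length(ds)) {
      return(data.frame(sex = s, n = 0L, mean = NA_real_, sd = NA_real_,
                        q25 = NA_real_, median = NA_real_, q75 = NA_real_))
    }
    q <- unname(stats::quantile(ds, c(0.25, 0.5, 0.75)))
    data.frame(sex = s, n = length(ds), mean = mean(ds),
               sd = if (length(ds) > 1L) stats::sd(ds) else NA_real_,
               q25 = q[1L], median = q[2L], q75 = q[3L],
               stringsAsFactors = FALSE)
  }))
}

#' Full agreement report for one predictor-vs-reference comparison
#'
#' Bundles every agreement statistic reported by the validation study:
#' MAD, RMSE with chi-squared CI, SMD with t CI, 1-year accuracy,
#' ICC(2,k), Bland-Altman summary and the normality p-value of the signed
#' residuals.
#'
#' The ICC matrix is either the (reference, predictor) pair (k = 2,
#' \code{icc_mode = "pair"}) or the predictor against the individual rater
#' panel (\code{icc_mode = "panel"}, requires \code{raters}); the report
#' records which mode was used.
#'
#' @inheritParams ba_mad
#' @param label free-text label stored in the report.
#' @param one_year_threshold months, see \code{\link{one_year_accuracy}}.
#' @param icc_mode \code{"pair"} or \code{"panel"}.
#' @param raters optional matrix of individual rater bone ages (needed for
#'   \code{icc_mode = "panel"}).
#' @param conf confidence level for all intervals.
#' @return object of class \code{"agreement_report"}.
#' @export
agreement_report <- function(pred, ref, label = NULL,
                             one_year_threshold = 12,
                             icc_mode = c("pair", "panel"), raters = NULL,
                             conf = 0.95) {
  icc_mode <- match.arg(icc_mode)
  check_pair(pred, ref, 2L)
  icc_mat <- if (icc_mode == "pair") cbind(reference = ref, predictor = pred)
  else {
    if (is.null(raters)) stop("icc_mode = 'panel' requires `raters`",
                              call. = FALSE)
    cbind(predictor = pred, raters)
  }
  rmse <- rmse_with_ci(pred, ref, conf)
  smd <- smd_with_ci(pred, ref, conf)
  icc <- icc_2k(icc_mat, conf)
  structure(list(label = label, n = length(pred),
                 mad = ba_mad(pred, ref),
                 rmse = rmse$rmse, rmse_ci = rmse$ci,
                 smd = smd$smd, smd_ci = smd$ci, smd_se = smd$se,
                 diff_sd = smd$sd,
                 one_year_accuracy = one_year_accuracy(pred, ref,
                                                       one_year_threshold),
                 one_year_threshold = one_year_threshold,
                 icc = icc$icc, icc_ci = icc$ci, icc_mode = icc_mode,
                 bland_altman = bland_altman(pred, ref),
                 ks_p = if (length(pred) >= 5L) ks_normality(pred - ref)
                        else NA_real_,
                 conf = conf),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report>%s  n = %d\n",
              if (is.null(x$label)) "" else paste0(" ", x$label), x$n))
  cat(sprintf("  MAD  %.2f months   RMSE %.2f [%.2f, %.2f] months\n",
              x$mad, x$rmse, x$rmse_ci[1L], x$rmse_ci[2L]))
  cat(sprintf("  SMD  %+.2f [%+.2f, %+.2f] months   %d-month accuracy %.1f%%\n",
              x$smd, x$smd_ci[1L], x$smd_ci[2L], x$one_year_threshold,
              x$one_year_accuracy))
  cat(sprintf("  ICC(2,k) %.4f [%.2f, %.2f] (%s)   Bland-Altman %.1f%% within %+.2f/%+.2f\n",
              x$icc, x$icc_ci[1L], x$icc_ci[2L], x$icc_mode,
              x$bland_altman$pct_within, x$bland_altman$lower,
              x$bland_altman$upper))
  cat(sprintf("  normality (Lilliefors) p = %.3f\n", x$ks_p))
  invisible(x)
}
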