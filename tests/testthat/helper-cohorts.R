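# Fixtures are built in code; no data files.

# small hand-specified cohort from a ratings matrix
make_cohort <- function(ratings, sex = NULL, ca = NULL, ai = NULL,
                        disorder = NULL, ids = NULL) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  if (is.null(colnames(ratings))) {
    colnames(ratings) <- paste0("rater_", seq_len(ncol(ratings)))
  }
  info <- data.frame(
    image_id = ids %||% sprintf("img_%03d", seq_len(n)),
    sex = sex %||% rep_len(c("female", "male"), n),
    ca_months = ca %||% pmin(216, rowMeans(ratings, na.rm = TRUE)),
    ai_ba_months = ai %||% rowMeans(ratings, na.rm = TRUE),
    disorder = disorder %||% rep(FALSE, n),
    stringsAsFactors = FALSE)
  ba_cohort(info, ratings)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# noise-free generator settings: every rater and the AI report true BA
zero_noise_config <- function(n = 60, seed = 1, n_raters = 3) {
  synthetic_config(n_images = n, n_raters = n_raters,
                   rater_biases = rep(0, n_raters),
                   rater_sds = rep(0, n_raters),
                   ba_ca_sd = 0, ai_slope = 1, ai_offset = 0, ai_sd = 0,
                   disorder_rate = 0, seed = seed)
}

# independent ICC(2,k) oracle: ANOVA mean squares via lm()/anova(), then
# the two-way random-effects absolute-agreement average-measure formula
icc_2k_oracle <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- stats::anova(stats::lm(y ~ subj + rater, data = df))
  msr <- ms["subj", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}
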