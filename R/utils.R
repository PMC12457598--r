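# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

SEX_LEVELS <- c("female", "male")

#' Parse sex labels
#'
#' Maps free-form sex labels (\code{"f"}, \code{"m"}, \code{"female"},
#' \code{"male"}, any case) onto the factor levels used throughout the
#' package.
#'
#' @param x character or factor vector of sex labels.
#' @return factor with levels \code{c("female", "male")}.
#' @export
parse_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("f", "female")] <- "female"
  out[key %in% c("m", "male")] <- "male"
  if (anyNA(out)) {
    stop("unrecognised sex label(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "),
         " (expected one of f, m, female, male)", call. = FALSE)
  }
  factor(out, levels = SEX_LEVELS)
}

# strict logical parser for CSV flag columns; NA input stays NA
parse_flag <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("1", "true", "t", "yes")] <- TRUE
  out[key %in% c("0", "false", "f", "no")] <- FALSE
  bad <- !is.na(key) & key != "" & is.na(out)
  if (any(bad)) {
    stop("unrecognised logical value(s): ",
         paste(unique(key[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Derive a replicate seed from a master seed
#'
#' Deterministic counter-keyed seed stream used by the bootstrap and by the
#' command-line tools, so that replicate \code{i} is reproducible on its own
#' (replicates can be recomputed independently and in any order).
#'
#' @param master_seed integer master seed.
#' @param i replicate counter (vectorised).
#' @return integer seed(s) in [0, 2^31).
#' @export
derive_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(i)) %% 2147483587)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
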