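# Cohort data model: one row per hand X-ray, a panel of k rater bone-age
# estimates (months), the raw black-box AI prediction, and metadata.

#' Column mapping for rating-table CSV files
#'
#' Describes how the columns of a rating-table CSV map onto the cohort data
#' model. Rater columns are found either via an explicit character vector
#' (\code{raters}) or by prefix matching (\code{rater_prefix}).
#'
#' @param image_id name of the image identifier column.
#' @param sex name of the sex column (values parsed case-insensitively from
#'   f/m/female/male).
#' @param ca name of the chronological-age column (months).
#' @param ai name of the raw AI bone-age column (months).
#' @param disorder name of the known-disorder flag column (0/1 or
#'   true/false).
#' @param raters optional explicit character vector of rater column names
#'   (in panel order); overrides \code{rater_prefix}.
#' @param rater_prefix prefix identifying rater columns when \code{raters}
#'   is \code{NULL}.
#' @return a list of class \code{"cohort_schema"}.
#' @export
cohort_schema <- function(image_id = "image_id", sex = "sex",
                          ca = "ca_months", ai = "ai_ba_months",
                          disorder = "disorder", raters = NULL,
                          rater_prefix = "rater_") {
  structure(list(image_id = image_id, sex = sex, ca = ca, ai = ai,
                 disorder = disorder, raters = raters,
                 rater_prefix = rater_prefix),
            class = "cohort_schema")
}

#' Construct a bone-age cohort
#'
#' @param info data.frame with columns \code{image_id}, \code{sex},
#'   \code{ca_months}, \code{ai_ba_months}, \code{disorder} (one row per
#'   image).
#' @param ratings numeric matrix of rater bone-age estimates (months), one
#'   row per image, one column per rater; missing assessments are \code{NA}.
#' @param rater_ids ordered rater labels; defaults to the matrix column
#'   names.
#' @param provenance free-form list of metadata (source, seed, generator
#'   config).
#' @param relax_age_range if \code{TRUE}, chronological ages outside
#'   [0, 216] months are allowed.
#' @return an object of class \code{"ba_cohort"}.
#' @export
ba_cohort <- function(info, ratings, rater_ids = colnames(ratings),
                      provenance = list(), relax_age_range = FALSE) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  if (is.null(rater_ids)) rater_ids <- paste0("rater_", seq_len(ncol(ratings)))
  colnames(ratings) <- rater_ids
  rownames(ratings) <- info$image_id
  info$image_id <- as.character(info$image_id)
  info$sex <- parse_sex(info$sex)
  info$disorder <- as.logical(info$disorder)
  x <- structure(list(info = info, ratings = ratings,
                      rater_ids = as.character(rater_ids),
                      provenance = provenance),
                 class = "ba_cohort")
  validate_cohort(x, relax_age_range = relax_age_range)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks identifier uniqueness, non-negative ages/ratings, the rating-panel
#' shape, and (unless relaxed) the 0-216 month study age range.
#'
#' @param x a \code{ba_cohort}.
#' @param relax_age_range allow chronological ages outside [0, 216] months.
#' @return \code{x}, invisibly usable; errors describe offending images.
#' @export
validate_cohort <- function(x, relax_age_range = FALSE) {
  info <- x$info
  ratings <- x$ratings
  if (nrow(info) != nrow(ratings)) {
    stop("info and ratings disagree on the number of images", call. = FALSE)
  }
  dup <- duplicated(info$image_id)
  if (any(dup)) {
    stop("duplicate image_id(s): ",
         paste(unique(info$image_id[dup]), collapse = ", "), call. = FALSE)
  }
  neg_ca <- !is.na(info$ca_months) & info$ca_months < 0
  neg_ai <- !is.na(info$ai_ba_months) & info$ai_ba_months < 0
  neg_rating <- rowSums(ratings < 0, na.rm = TRUE) > 0
  bad <- neg_ca | neg_ai | neg_rating
  if (any(bad)) {
    stop("negative age/bone-age value(s) for image_id(s): ",
         paste(info$image_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!relax_age_range) {
    out <- !is.na(info$ca_months) &
      (info$ca_months < 0 | info$ca_months > 216)
    if (any(out)) {
      stop("chronological age outside [0, 216] months for image_id(s): ",
           paste(info$image_id[out], collapse = ", "),
           " (use relax_age_range = TRUE to permit)", call. = FALSE)
    }
  }
  x
}

#' @export
print.ba_cohort <- function(x, ...) {
  cat(sprintf("<ba_cohort> %d images, %d raters (%s)\n",
              n_images(x), n_raters(x), paste(x$rater_ids, collapse = ", ")))
  cat(sprintf("  sex: %d female / %d male; disorder cases: %d; missing ratings: %d\n",
              sum(x$info$sex == "female"), sum(x$info$sex == "male"),
              sum(x$info$disorder), sum(is.na(x$ratings))))
  invisible(x)
}

#' Number of images in a cohort
#' @param x a \code{ba_cohort}.
#' @return integer count.
#' @export
n_images <- function(x) nrow(x$info)

#' Number of raters in a cohort
#' @param x a \code{ba_cohort}.
#' @return integer count.
#' @export
n_raters <- function(x) ncol(x$ratings)

#' Subset a cohort by image identifiers
#'
#' @param cohort a \code{ba_cohort}.
#' @param ids image identifiers to keep (order is preserved as given).
#' @return a \code{ba_cohort} restricted to \code{ids}.
#' @export
subset_cohort <- function(cohort, ids) {
  idx <- match(ids, cohort$info$image_id)
  if (anyNA(idx)) {
    stop("unknown image_id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  cohort$info <- cohort$info[idx, , drop = FALSE]
  rownames(cohort$info) <- NULL
  cohort$ratings <- cohort$ratings[idx, , drop = FALSE]
  cohort
}

#' Remove one rater from the panel
#'
#' Used by the leave-one-rater-out benchmark: the returned cohort carries
#' the remaining k - 1 rater columns, everything else unchanged.
#'
#' @param cohort a \code{ba_cohort}.
#' @param rater_id label of the rater to drop.
#' @return a \code{ba_cohort} with k - 1 raters.
#' @export
drop_rater <- function(cohort, rater_id) {
  j <- match(rater_id, cohort$rater_ids)
  if (is.na(j)) stop("unknown rater_id: ", rater_id, call. = FALSE)
  if (n_raters(cohort) <= 2L) {
    stop("cannot drop a rater from a panel of ", n_raters(cohort),
         " (k >= 2 required after removal)", call. = FALSE)
  }
  cohort$ratings <- cohort$ratings[, -j, drop = FALSE]
  cohort$rater_ids <- cohort$rater_ids[-j]
  cohort
}

#' Read a rating-table CSV into a cohort
#'
#' Missing rater cells (empty fields) become \code{NA}, never zero. Sex is
#' parsed case-insensitively; the disorder flag accepts 0/1 and true/false.
#'
#' @param path CSV file path (UTF-8, comma separated, header row).
#' @param schema a \code{\link{cohort_schema}} describing the column
#'   mapping.
#' @param relax_age_range allow chronological ages outside [0, 216] months.
#' @return a \code{ba_cohort}.
#' @export
read_cohort <- function(path, schema = cohort_schema(),
                        relax_age_range = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) && any(nf != nf[1L])) {
    stop("malformed CSV: line ", which(nf != nf[1L])[1L], " of ", path,
         " has ", nf[which(nf != nf[1L])[1L]], " fields, expected ", nf[1L],
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(schema$image_id, schema$sex, schema$ca, schema$ai,
                schema$disorder)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rater_cols <- schema$raters %||%
    grep(paste0("^", schema$rater_prefix), names(df), value = TRUE)
  if (length(rater_cols) < 2L) {
    stop("fewer than 2 rater columns found (prefix '", schema$rater_prefix,
         "')", call. = FALSE)
  }
  if (length(setdiff(rater_cols, names(df)))) {
    stop("rater column(s) not present: ",
         paste(setdiff(rater_cols, names(df)), collapse = ", "), call. = FALSE)
  }
  ratings <- as.matrix(df[rater_cols])
  storage.mode(ratings) <- "double"
  info <- data.frame(image_id = as.character(df[[schema$image_id]]),
                     sex = parse_sex(df[[schema$sex]]),
                     ca_months = as.numeric(df[[schema$ca]]),
                     ai_ba_months = as.numeric(df[[schema$ai]]),
                     disorder = parse_flag(df[[schema$disorder]]),
                     stringsAsFactors = FALSE)
  ba_cohort(info, ratings, rater_ids = rater_cols,
            provenance = list(source = path),
            relax_age_range = relax_age_range)
}

#' Write a cohort to a rating-table CSV
#'
#' Stable column order (image_id, sex, ca_months, rater columns,
#' ai_ba_months, disorder); missing ratings are written as empty cells, so
#' \code{read_cohort(write_cohort(x))} round-trips the cohort exactly.
#'
#' @param cohort a \code{ba_cohort}.
#' @param path output file path.
#' @param logical_format serialize the disorder flag as \code{"int"} (1/0)
#'   or \code{"logical"} (true/false).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path, logical_format = c("int", "logical")) {
  logical_format <- match.arg(logical_format)
  flag <- if (logical_format == "int") as.integer(cohort$info$disorder) else
    tolower(as.character(cohort$info$disorder))
  out <- data.frame(image_id = cohort$info$image_id,
                    sex = as.character(cohort$info$sex),
                    ca_months = cohort$info$ca_months,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[cohort$rater_ids] <- as.data.frame(cohort$ratings)
  out$ai_ba_months <- cohort$info$ai_ba_months
  out$disorder <- flag
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("could not write cohort CSV to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
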