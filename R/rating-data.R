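#' Rating tables for bounded-scale inter-rater data
#'
#' A `rating_table` holds long-format observer scores indexed by
#' (study, encounter, rater) with an encounter-level binary covariate
#' (e.g. whether a decision aid was used). Scores live on a native bounded
#' scale `[0, scale_max]`; [rescale_ratings()] maps them to the open unit
#' interval used by the hierarchical model.
#'
#' Validation enforces the structural invariants of the design:
#' * the covariate is constant across raters within an encounter;
#' * each (study, encounter, rater) triple occurs at most once;
#' * scores lie in `[0, scale_max]` and the covariate is 0/1.
#'
#' Rater identifiers are mapped to consecutive integers `1..R` in order of
#' first appearance, which is the numeric coding the rater-effect term of
#' the model requires. Rows are ordered deterministically by
#' (study, encounter, rater).
#'
#' @param df data frame with columns `study`, `encounter`, `rater`,
#'   `score`, `covariate`.
#' @param scale_max positive upper bound of the native scale (default 100).
#' @return An object of class `rating_table` (a data frame with attributes
#'   `scale_max`, `study_labels`, `n_encounters`, `n_raters`,
#'   `rater_levels`).
#' @examples
#' df <- data.frame(study = "s1", encounter = c(1, 1, 2, 2),
#'                  rater = c("A", "B", "A", "B"),
#'                  score = c(20, 40, 60, 80), covariate = 0)
#' rt <- rating_table(df, scale_max = 100)
#' n_encounters(rt)
#' @export
rating_table <- function(df, scale_max = 100) {
  required <- c("study", "encounter", "rater", "score", "covariate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("rating table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(scale_max) || length(scale_max) != 1L || scale_max <= 0) {
    stop("`scale_max` must be a single positive number", call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0L) {
    out <- df
    out$study <- as.character(out$study)
    out$encounter <- as.character(out$encounter)
    out$rater <- integer(0)
    out$score <- numeric(0)
    out$covariate <- integer(0)
    return(structure(out,
                     scale_max = scale_max,
                     study_labels = character(0),
                     n_encounters = integer(0),
                     n_raters = 0L,
                     rater_levels = character(0),
                     class = c("rating_table", "data.frame")))
  }

  df$study <- as.character(df$study)
  df$encounter <- as.character(df$encounter)
  df$score <- as.numeric(df$score)
  if (anyNA(df$study) || anyNA(df$encounter) || anyNA(df$rater) ||
      anyNA(df$score) || anyNA(df$covariate)) {
    stop("rating table contains missing values", call. = FALSE)
  }
  if (any(df$score < 0 | df$score > scale_max)) {
    bad <- which(df$score < 0 | df$score > scale_max)[1L]
    stop(sprintf("score %g (row %d) outside [0, %g]",
                 df$score[bad], bad, scale_max), call. = FALSE)
  }
  cov_num <- suppressWarnings(as.numeric(df$covariate))
  if (anyNA(cov_num) || !all(cov_num %in% c(0, 1))) {
    stop("`covariate` must be binary 0/1", call. = FALSE)
  }
  df$covariate <- as.integer(cov_num)

  # rater ids -> 1..R in first-appearance order
  rater_levels <- as.character(unique(df$rater))
  df$rater <- match(as.character(df$rater), rater_levels)

  key <- paste(df$study, df$encounter, sep = "\r")
  dup <- duplicated(paste(key, df$rater, sep = "\r"))
  if (any(dup)) {
    stop("duplicate (study, encounter, rater) record(s), first at row ",
         which(dup)[1L], call. = FALSE)
  }
  cov_by_enc <- tapply(df$covariate, key, function(x) length(unique(x)))
  if (any(cov_by_enc > 1L)) {
    bad <- names(cov_by_enc)[cov_by_enc > 1L][1L]
    stop("covariate differs between raters of encounter ",
         gsub("\r", "/", bad),
         " (covariate is encounter-level)", call. = FALSE)
  }

  ord <- order(df$study, df$encounter, df$rater)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  study_labels <- unique(df$study)
  enc_per_study <- vapply(study_labels, function(s) {
    length(unique(df$encounter[df$study == s]))
  }, integer(1))
  names(enc_per_study) <- study_labels

  structure(df,
            scale_max = scale_max,
            study_labels = study_labels,
            n_encounters = enc_per_study,
            n_raters = max(df$rater),
            rater_levels = rater_levels,
            class = c("rating_table", "data.frame"))
}

#' @rdname rating_table
#' @param x a `rating_table`.
#' @export
n_studies <- function(x) length(attr(x, "study_labels"))

#' @rdname rating_table
#' @export
n_encounters <- function(x) attr(x, "n_encounters")

#' @rdname rating_table
#' @export
n_raters <- function(x) attr(x, "n_raters")

#' @rdname rating_table
#' @export
scale_max <- function(x) attr(x, "scale_max")

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("Rating table: %d records, %d stud%s, %d encounters, %d raters (scale 0-%g)\n",
              nrow(x), n_studies(x), if (n_studies(x) == 1) "y" else "ies",
              sum(n_encounters(x)), n_raters(x), scale_max(x)))
  if (is_rescaled(x)) {
    cat(sprintf("Rescaled to (0,1) with epsilon = %g (%d score(s) clamped)\n",
                attr(x, "epsilon"), attr(x, "n_clamped")))
  }
  NextMethod()
  invisible(x)
}

#' Read / write rating tables as CSV
#'
#' The canonical on-disk form is a comma-separated UTF-8 file with header
#' `study,encounter,rater,score,covariate`. [read_ratings()] validates and
#' orders the table; [write_ratings()] writes it back so that a read of the
#' written file reproduces the table exactly.
#'
#' @param path file path.
#' @param scale_max native scale upper bound.
#' @return [read_ratings()] returns a [rating_table()];
#'   [write_ratings()] returns `path` invisibly.
#' @export
read_ratings <- function(path, scale_max = 100) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = TRUE, fileEncoding = "UTF-8")
  required <- c("study", "encounter", "rater", "score", "covariate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df)) {
    df$score <- as.numeric(df$score)
    df$covariate <- as.numeric(df$covariate)
  }
  rating_table(df, scale_max = scale_max)
}

#' @rdname read_ratings
#' @param table a `rating_table`.
#' @export
write_ratings <- function(table, path) {
  stopifnot(inherits(table, "rating_table"))
  out <- as.data.frame(table)[c("study", "encounter", "rater",
                                "score", "covariate")]
  # restore original rater labels so a round trip is the identity
  lev <- attr(table, "rater_levels")
  if (nrow(out)) out$rater <- lev[out$rater]
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write ratings to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Rescale scores to the open unit interval
#'
#' Divides scores by `scale_max` and clamps the result to
#' `[epsilon, 1 - epsilon]`. The truncated-normal likelihood lives on the
#' open interval (0, 1), so exact-boundary scores (0 or `scale_max`) would
#' have zero density; clamping by a small `epsilon` keeps them in the
#' analysis. The number of clamped scores is recorded in the `n_clamped`
#' attribute and reported via a message so the adjustment is auditable.
#'
#' @param table a [rating_table()].
#' @param epsilon clamp margin, in (0, 0.5); default 0.005 (half a point on
#'   a 0-100 scale).
#' @return the table with an added column `y` (rescaled score) and
#'   attributes `epsilon`, `n_clamped`, `rescaled = TRUE`.
#' @export
rescale_ratings <- function(table, epsilon = 0.005) {
  stopifnot(inherits(table, "rating_table"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must lie strictly between 0 and 0.5", call. = FALSE)
  }
  y <- table$score / attr(table, "scale_max")
  clamped <- y < epsilon | y > 1 - epsilon
  y <- pmin(pmax(y, epsilon), 1 - epsilon)
  out <- table
  out$y <- y
  attr(out, "epsilon") <- epsilon
  attr(out, "n_clamped") <- sum(clamped)
  attr(out, "rescaled") <- TRUE
  if (any(clamped)) {
    message(sum(clamped), " score(s) clamped to [",
            epsilon, ", ", 1 - epsilon, "]")
  }
  out
}

#' @rdname rescale_ratings
#' @param x an object.
#' @export
is_rescaled <- function(x) isTRUE(attr(x, "rescaled"))

# Internal: flatten a rescaled table into the index arrays the likelihood,
# sampler and simulator share. Records arrive sorted by (study, encounter,
# rater) so each encounter's records are contiguous.
prepare_model_data <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  if (!is_rescaled(table)) table <- rescale_ratings(table)
  if (nrow(table) == 0L) stop("empty rating table", call. = FALSE)
  study_labels <- attr(table, "study_labels")
  study <- match(table$study, study_labels)
  enc_key <- paste(table$study, table$encounter, sep = "\r")
  enc <- match(enc_key, unique(enc_key))          # 1..E, contiguous blocks
  E <- max(enc)
  first <- !duplicated(enc)
  enc_study <- study[first]
  x_enc <- table$covariate[first]
  x_bar <- mean(x_enc)                            # centering over encounters
  R <- attr(table, "n_raters")
  list(
    y = table$y,
    study = study,
    enc = enc,
    rater_code = table$rater - (R + 1) / 2,
    x_centered = table$covariate - x_bar,
    enc_study = enc_study,
    x_enc = x_enc,
    x_bar = x_bar,
    M = length(study_labels),
    E = E,
    R = R,
    N_h = as.integer(tabulate(enc_study, nbins = length(study_labels))),
    study_labels = study_labels,
    epsilon = attr(table, "epsilon")
  )
}
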