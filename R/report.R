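#' Assemble a full analysis report
#'
#' Bundles everything the analysis produces into one structure: posterior
#' summaries per fitted variant, the four-member ICC family
#' (point/average x within/pooled) for each variant, pairwise study
#' comparisons (full variant), the empirical variance-function table,
#' convergence diagnostics, and provenance (seeds, prior configuration,
#' package version) so published numbers are auditable. Variants beyond
#' the required full fit are optional; missing ones are noted, not
#' errors.
#'
#' @param data the analysed [rating_table()].
#' @param fits named list of `icc_draws` objects; names among `"full"`,
#'   `"homogeneous_binomial"`, `"homogeneous_constant"`. The full variant
#'   is required.
#' @param theta_star trait level for the point-mode ICC entries
#'   (default 0.5).
#' @return object of class `icc_report` (a nested list of plain data
#'   frames and scalars, JSON-serializable via [report_to_json()]).
#' @export
build_report <- function(data, fits, theta_star = 0.5) {
  if (!length(fits) || is.null(names(fits))) {
    stop("`fits` must be a named list of icc_draws; required variant: full",
         call. = FALSE)
  }
  if (!"full" %in% names(fits)) {
    stop("missing required variant: full", call. = FALSE)
  }
  notes <- character(0)
  for (v in setdiff(c("homogeneous_binomial", "homogeneous_constant"),
                    names(fits))) {
    notes <- c(notes, paste0("variant '", v, "' not fitted; section omitted"))
  }
  queries <- list(
    point_within = icc_query("point", theta_star = theta_star),
    point_pooled = icc_query("point", theta_star = theta_star, pooled = TRUE),
    average_within = icc_query("average"),
    average_pooled = icc_query("average", pooled = TRUE)
  )
  per_variant <- lapply(fits, function(f) {
    icc <- lapply(queries, function(q) {
      s <- icc_posterior(f, q)
      attr(s, "icc_draws") <- NULL
      attr(s, "query") <- NULL
      as.data.frame(s)
    })
    list(summary = posterior_summary(f),
         icc = icc,
         convergence = f$diagnostics)
  })
  vf <- empirical_variance_check(data)
  bundle <- list(
    model_summaries = per_variant,
    pairwise = icc_pairwise(fits$full, icc_query("average")),
    variance_function = as.data.frame(vf),
    variance_function_fits = list(
      c_hat = attr(vf, "c_hat"),
      constant_hat = attr(vf, "constant_hat")
    ),
    provenance = list(
      package_version = as.character(utils::packageVersion("bayesicc")),
      seeds = lapply(fits, function(f) f$seed),
      priors = lapply(fits, function(f) unclass(f$prior)),
      theta_star = theta_star,
      data_shape = list(M = n_studies(data),
                        N_h = as.list(n_encounters(data)),
                        R = n_raters(data),
                        scale_max = scale_max(data))
    ),
    notes = notes
  )
  class(bundle) <- "icc_report"
  bundle
}

#' @export
print.icc_report <- function(x, ...) {
  cat("=== ICC analysis report ===\n")
  for (v in names(x$model_summaries)) {
    cat("\n--- Variant:", v, "---\n")
    print(x$model_summaries[[v]]$summary, digits = 3)
    cat("ICC family (posterior medians):\n")
    for (q in names(x$model_summaries[[v]]$icc)) {
      s <- x$model_summaries[[v]]$icc[[q]]
      cat(sprintf("  %-15s %s\n", q,
                  paste(sprintf("%s=%.3f", s$group, s$median),
                        collapse = "  ")))
    }
  }
  cat("\nPairwise ICC differences (average-mode):\n")
  print(x$pairwise, digits = 3)
  if (length(x$notes)) cat("\nNotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' JSON round trip for reports
#'
#' @param report an `icc_report`.
#' @param path optional file to write.
#' @return `report_to_json()` returns (invisibly, when `path` given) the
#'   JSON string; `report_from_json()` the parsed bundle.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname report_to_json
#' @param json JSON string or file path.
#' @export
report_from_json <- function(json) {
  jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
}
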