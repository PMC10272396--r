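# Cohort-level statistics: GH-count vs genome-size correlation, sequential
# variance partitioning of clustered-gene counts, and per-lineage summaries.

#' Pearson correlation and regression slope of GH count on genome size
#'
#' Computes the Pearson product-moment correlation (with two-sided p) and the
#' ordinary least-squares slope (with p) of one cohort column on another —
#' by default the number of GH genes on the number of PEGs.
#'
#' @param cohort A cohort data frame (see \code{\link{build_cohort}}).
#' @param x,y Column names of predictor and response.
#' @return A \code{regression_summary} list: \code{r}, \code{r_p},
#'   \code{slope}, \code{slope_p}, \code{intercept}, \code{n},
#'   \code{degenerate} (\code{TRUE} when the response has zero variance, in
#'   which case r is reported as 0).
#' @export
correlation_and_slope <- function(cohort, x = "n_pegs", y = "n_gh") {
  miss <- setdiff(c(x, y), names(cohort))
  if (length(miss)) stop2("cohort missing column(s): ",
                          paste(miss, collapse = ", "))
  xv <- cohort[[x]]; yv <- cohort[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop2("need at least 3 genomes, got ", n)
  if (stats::sd(xv) == 0) stop2("zero variance in predictor ", x)

  degenerate <- stats::sd(yv) == 0
  if (degenerate) {
    res <- list(r = 0, r_p = NA_real_, slope = 0, slope_p = NA_real_,
                intercept = mean(yv), n = n, degenerate = TRUE)
  } else {
    ct <- stats::cor.test(xv, yv, method = "pearson")
    fit <- stats::lm(yv ~ xv)
    # a noise-free cohort is a legitimate input; silence the perfect-fit note
    cf <- suppressWarnings(summary(fit))$coefficients
    res <- list(r = unname(ct$estimate), r_p = ct$p.value,
                slope = unname(cf["xv", "Estimate"]),
                slope_p = unname(cf["xv", "Pr(>|t|)"]),
                intercept = unname(cf["(Intercept)", "Estimate"]),
                n = n, degenerate = FALSE)
  }
  class(res) <- "regression_summary"
  res
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %s), slope = %.4g (p = %s), n = %d%s\n",
              x$r, format(x$r_p, digits = 3), x$slope,
              format(x$slope_p, digits = 3), x$n,
              if (x$degenerate) " [degenerate: constant response]" else ""))
  invisible(x)
}

#' Sequential variance partition of clustered-gene counts
#'
#' Fits the linear model \code{response ~ n_pegs * n_gh} and reports the
#' percentage of the total sum of squares attributed to each term by the
#' sequential (type-I) decomposition, in the fixed order genome size, GH-gene
#' count, their interaction, and the residual. The four parts sum to 100.
#'
#' @param cohort Cohort data frame.
#' @param response Response column; the count of clustered GH genes
#'   (\code{n_clustered_5}) by default, or the corresponding frequency column.
#' @param predictors Two predictor columns, entered in this order.
#' @return A \code{variance_partition} list: \code{pct_variance} (named
#'   vector with the two predictors, the interaction and \code{residual}),
#'   \code{p_values} per fitted term, \code{anova} (the underlying type-I
#'   table), \code{n}.
#' @export
variance_partition <- function(cohort, response = "n_clustered_5",
                               predictors = c("n_pegs", "n_gh")) {
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop2("cohort missing column(s): ",
                          paste(miss, collapse = ", "))
  if (length(predictors) != 2L) stop2("exactly two predictors required")
  df <- cohort[stats::complete.cases(cohort[, cols]), cols]
  if (nrow(df) < 5L) stop2("need at least 5 genomes, got ", nrow(df))
  names(df) <- c(".y", ".x1", ".x2")
  if (stats::cor(df$.x1, df$.x2) ^ 2 > 1 - 1e-12) {
    stop2("predictors ", predictors[1L], " and ", predictors[2L],
          " are collinear")
  }
  fit <- stats::lm(.y ~ .x1 * .x2, data = df)
  # sequential (type-I) sums of squares; a perfect fit is legitimate input
  an <- suppressWarnings(stats::anova(fit))
  ss <- an[["Sum Sq"]]
  total <- sum(ss)
  pct <- if (total > 0) 100 * ss / total else rep(NA_real_, length(ss))
  labels <- c(predictors[1L], predictors[2L],
              paste0(predictors[1L], ":", predictors[2L]), "residual")
  res <- list(pct_variance = stats::setNames(pct, labels),
              p_values = stats::setNames(an[["Pr(>F)"]], labels),
              anova = an, response = response, n = nrow(df))
  class(res) <- "variance_partition"
  res
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Sequential variance partition of", x$response, "(n =", x$n, ")\n")
  stars <- function(p) {
    if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "(NS)"
  }
  for (i in seq_along(x$pct_variance)) {
    cat(sprintf("  %-18s %6.1f%% %s\n", names(x$pct_variance)[i],
                x$pct_variance[i], stars(x$p_values[i])))
  }
  invisible(x)
}

#' Per-lineage mean and standard deviation of cohort statistics
#'
#' @param cohort Cohort data frame.
#' @param by Name of the grouping column (e.g. \code{"genus"} or
#'   \code{"phylum"}).
#' @param stats_cols Statistic columns to summarize; defaults to the main
#'   per-genome fractions.
#' @return Data frame with one row per group: \code{n} genomes, then
#'   \code{<col>_mean} and \code{<col>_sd} for each statistic (sd is
#'   \code{NA} for singleton groups).
#' @export
group_summary <- function(cohort, by,
                          stats_cols = c("f_gh", "f_clustered_5",
                                         "f_codir_clustered",
                                         "f_colocalized")) {
  if (!by %in% names(cohort)) stop2("unknown grouping column: ", by)
  stats_cols <- intersect(stats_cols, names(cohort))
  groups <- split(cohort, cohort[[by]])
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    row <- data.frame(group = gn, n = nrow(g), stringsAsFactors = FALSE)
    for (cl in stats_cols) {
      row[[paste0(cl, "_mean")]] <- mean(g[[cl]], na.rm = TRUE)
      row[[paste0(cl, "_sd")]] <- if (nrow(g) > 1L)
        stats::sd(g[[cl]], na.rm = TRUE) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}
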