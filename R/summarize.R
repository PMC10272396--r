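# Per-genome report combining all pipeline stages.

#' Summarize a genome's GH-gene organization
#'
#' Computes the full per-genome report: GH-gene counts and frequency,
#' clustered counts and fractions at the requested SSc thresholds,
#' codirectionality of all and of clustered sequential pairs with the exact
#' binomial test, GH:TR colocalization, and (optionally) the comparison with
#' a matched randomized null.
#'
#' Percentages in the printed report are truncated to one decimal; the raw
#' full-precision values are kept in the summary object.
#'
#' @param genome An \code{annotated_genome} with at least one PEG.
#' @param thresholds SSc thresholds for clustered counts (default 1, 5, 10;
#'   5 is the cluster-defining threshold).
#' @param coloc_threshold GH:TR colocalization threshold (default 10).
#' @param null_iterations If > 0, a matched null with this many
#'   randomizations is computed and its median clustered fraction and the
#'   empirical p of the observed value are reported (needs >= 2 GH genes).
#' @param seed Seed for the matched null.
#' @return A \code{genome_summary} list; use \code{as.data.frame} to get the
#'   one-row cohort form.
#' @export
summarize_genome <- function(genome, thresholds = c(1L, 5L, 10L),
                             coloc_threshold = 10L, null_iterations = 0L,
                             seed = 1L) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (genome$counts$n_pegs == 0L) stop2("genome has zero PEGs")
  n_pegs <- genome$counts$n_pegs
  n_gh <- genome$counts$n_gh

  s <- list(genome_id = genome$genome_id, n_pegs = n_pegs, n_gh = n_gh,
            f_gh = 100 * n_gh / n_pegs)

  prof <- if (n_gh > 0L) synteny_scores(genome) else NULL
  for (t in thresholds) {
    key <- as.character(t)
    if (n_gh > 0L) {
      ssc <- prof$scores$ssc
      nc <- sum(!is.na(ssc) & ssc <= t)
      s[[paste0("n_clustered_", key)]] <- nc
      s[[paste0("f_clustered_", key)]] <- nc / n_gh
    } else {
      s[[paste0("n_clustered_", key)]] <- 0L
      s[[paste0("f_clustered_", key)]] <- NA_real_
    }
  }

  pairs_all <- sequential_pairs(genome, "all")
  pairs_cl <- sequential_pairs(genome, "clustered", threshold = 5L)
  s$n_pairs_all <- nrow(pairs_all)
  s$n_pairs_clustered <- nrow(pairs_cl)
  s$f_codir_all <- if (nrow(pairs_all)) codirectional_fraction(pairs_all)
    else NA_real_
  s$f_codir_clustered <- if (nrow(pairs_cl)) codirectional_fraction(pairs_cl)
    else NA_real_
  s$binom_p <- if (nrow(pairs_all))
    binomial_codirectionality_test(sum(pairs_all$codirectional),
                                   nrow(pairs_all))$p_value else NA_real_

  if (n_gh > 0L) {
    cs <- colocalization_summary(genome, coloc_threshold)
    s$f_colocalized <- cs$f_colocalized
    for (cl in TR_CLASSES) {
      s[[paste0("n_coloc_", tolower(sub("^TR_", "", cl)))]] <-
        unname(cs$n_by_class[cl])
    }
    s$n_coloc_multi <- cs$n_multi_class
  } else {
    s$f_colocalized <- NA_real_
    for (cl in TR_CLASSES)
      s[[paste0("n_coloc_", tolower(sub("^TR_", "", cl)))]] <- 0L
    s$n_coloc_multi <- 0L
  }

  if (null_iterations > 0L && n_gh >= 2L) {
    nd <- matched_null(genome, iterations = null_iterations, seed = seed,
                       thresholds = thresholds)
    s$null_median_f_clustered_5 <- unname(
      nd$summaries["median", "f_clustered_5"])
    s$null_p_f_clustered_5 <- empirical_p(s$f_clustered_5, nd,
                                          side = "greater",
                                          statistic = "f_clustered_5")
  }
  class(s) <- "genome_summary"
  s
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("Genome summary:", x$genome_id, "\n")
  cat(sprintf("  PEGs: %d   GH genes: %d (%s%%)\n", x$n_pegs, x$n_gh,
              format_pct1(x$f_gh)))
  for (t in c(1, 5, 10)) {
    nk <- paste0("n_clustered_", t); fk <- paste0("f_clustered_", t)
    if (!is.null(x[[nk]]) && !is.na(x[[fk]])) {
      cat(sprintf("  clustered (SSc <= %d): %d (%s%%)\n", t, x[[nk]],
                  format_pct1(100 * x[[fk]])))
    }
  }
  if (!is.na(x$f_codir_all)) {
    cat(sprintf("  codirectional pairs: %s%% of %d (all), ",
                format_pct1(100 * x$f_codir_all), x$n_pairs_all))
    cat(if (!is.na(x$f_codir_clustered))
      sprintf("%s%% of %d (clustered)\n", format_pct1(100 * x$f_codir_clustered),
              x$n_pairs_clustered) else "no clustered pairs\n")
    cat(sprintf("  binomial test vs 50%%: p = %s\n",
                format(x$binom_p, digits = 3)))
  }
  if (!is.na(x$f_colocalized)) {
    cat(sprintf("  GH:TR colocalized: %s%% (MFS %d, ABC %d, PTS %d, SUS %d)\n",
                format_pct1(100 * x$f_colocalized), x$n_coloc_mfs,
                x$n_coloc_abc, x$n_coloc_pts, x$n_coloc_sus))
  }
  if (!is.null(x$null_median_f_clustered_5)) {
    cat(sprintf("  matched null: median clustered %s%%, empirical p = %s\n",
                format_pct1(100 * x$null_median_f_clustered_5),
                format(x$null_p_f_clustered_5, digits = 3)))
  }
  invisible(x)
}

#' @export
as.data.frame.genome_summary <- function(x, ...) {
  flat <- x[!vapply(x, is.null, logical(1))]
  class(flat) <- NULL
  as.data.frame(flat, stringsAsFactors = FALSE)
}

#' Assemble a cohort table from genome summaries
#'
#' @param summaries List of \code{genome_summary} objects.
#' @param metadata Optional data frame with a \code{genome_id} column and
#'   taxonomy/environment labels, joined onto the cohort rows.
#' @return A data frame with one row per genome.
#' @export
build_cohort <- function(summaries, metadata = NULL) {
  rows <- lapply(summaries, as.data.frame)
  cohort <- do.call(rbind, rows)
  if (anyDuplicated(cohort$genome_id)) stop2("duplicate genome_id in cohort")
  if (!is.null(metadata)) {
    if (!"genome_id" %in% names(metadata)) {
      stop2("metadata needs a genome_id column")
    }
    cohort <- merge(cohort, metadata, by = "genome_id", all.x = TRUE,
                    sort = FALSE)
  }
  rownames(cohort) <- NULL
  cohort
}

#' Per-gene synteny table for export
#'
#' Joins the per-gene synteny scores with cluster membership at a threshold,
#' in the package's output TSV layout.
#'
#' @param genome An \code{annotated_genome}.
#' @param threshold Cluster threshold.
#' @return Data frame: \code{gene_id}, \code{replicon_id}, \code{ordinal},
#'   \code{strand}, \code{ssc}, \code{cluster_id}, \code{cluster_size}.
#' @export
synteny_table <- function(genome, threshold = 5L) {
  prof <- synteny_scores(genome)
  cl <- find_clusters(genome, threshold)
  tab <- prof$scores
  tab$cluster_id <- NA_character_
  tab$cluster_size <- NA_integer_
  for (i in seq_len(nrow(cl))) {
    idx <- match(cl$members[[i]], tab$gene_id)
    tab$cluster_id[idx] <- cl$cluster_id[i]
    tab$cluster_size[idx] <- cl$size[i]
  }
  tab
}
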