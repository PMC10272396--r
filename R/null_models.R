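# Randomized-genome null models for GH-gene clustering.
#
# Bacterial genomes of 1,000-15,000 PEGs carrying 0.5-10% GH genes are
# emulated by placing the GH genes uniformly at random (without replacement)
# among the PEG slots; synteny statistics computed on many such replicates
# give the clustering expected in the absence of selection.

#' Uniform random placement of class genes
#'
#' Samples \code{n_gh} distinct PEG ordinals uniformly without replacement
#' from \code{1..n_pegs}.
#'
#' @param n_pegs Number of PEG slots.
#' @param n_gh Number of genes to place.
#' @param rng_seed Optional integer seed for reproducibility; if \code{NULL}
#'   the current RNG state is used.
#' @return Sorted integer vector of \code{n_gh} ordinals.
#' @export
randomize_placement <- function(n_pegs, n_gh, rng_seed = NULL) {
  if (!is_count(n_pegs)) stop2("n_pegs must be an integer >= 1")
  if (!is_count(n_gh)) stop2("n_gh must be an integer >= 1")
  if (n_gh > n_pegs) stop2("n_gh (", n_gh, ") exceeds n_pegs (", n_pegs, ")")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sort(sample.int(n_pegs, n_gh))
}

#' Specification of a null-model simulation
#'
#' @param n_pegs Genome size in PEGs.
#' @param n_gh Number of GH genes placed per replicate.
#' @param topology Replicon topology.
#' @param iterations Number of randomized replicates (default 5,000).
#' @param seed Master RNG seed for the simulation.
#' @param thresholds Cluster thresholds at which the clustered fraction is
#'   recorded per replicate.
#' @param s_max Largest SSc value tabulated.
#' @return A \code{null_spec} list.
#' @export
null_spec <- function(n_pegs, n_gh, topology = c("circular", "linear"),
                      iterations = 5000L, seed = 1L,
                      thresholds = c(1L, 5L, 10L), s_max = 20L) {
  topology <- match.arg(topology)
  if (!is_count(n_pegs) || !is_count(n_gh) || n_gh > n_pegs) {
    stop2("need 1 <= n_gh <= n_pegs")
  }
  if (!is_count(iterations)) stop2("iterations must be an integer >= 1")
  spec <- list(n_pegs = as.integer(n_pegs), n_gh = as.integer(n_gh),
               topology = topology, iterations = as.integer(iterations),
               seed = as.integer(seed),
               thresholds = as.integer(thresholds), s_max = as.integer(s_max))
  class(spec) <- "null_spec"
  spec
}

# Statistics of one randomized replicate, from the ordinal set alone.
null_replicate_stats <- function(ordinals, n_pegs, topology, thresholds,
                                 s_max) {
  res <- ssc_from_ordinals(ordinals, n_pegs, topology)
  ssc <- res$ssc
  def <- ssc[!is.na(ssc)]
  k <- length(ssc)
  c(mean_ssc = if (length(def)) mean(def) else NA_real_,
    stats::setNames(tabulate(def[def <= s_max], nbins = s_max),
                    paste0("n_ssc_", seq_len(s_max))),
    stats::setNames(vapply(thresholds, function(t) sum(def <= t) / k,
                           numeric(1)),
                    paste0("f_clustered_", thresholds)))
}

#' Simulate a null distribution of synteny statistics
#'
#' For each replicate, places \code{n_gh} genes uniformly among
#' \code{n_pegs} slots, computes the per-gene synteny scores, and records the
#' mean SSc, the SSc histogram (\code{n_ssc_s} for s = 1..\code{s_max}), and
#' the clustered fraction at each requested threshold.
#'
#' @param spec A \code{\link{null_spec}}.
#' @return A \code{null_distribution}: list with \code{spec}, \code{values}
#'   (replicates-by-statistics matrix) and \code{summaries} (mean, sd,
#'   median, 2.5/50/97.5% quantiles per statistic).
#' @export
#' @examples
#' nd <- simulate_null(null_spec(500, 30, iterations = 200, seed = 7))
#' nd$summaries["mean", "n_ssc_1"]
simulate_null <- function(spec) {
  stopifnot(inherits(spec, "null_spec"))
  set.seed(spec$seed)
  vals <- matrix(NA_real_, nrow = spec$iterations,
                 ncol = 1L + spec$s_max + length(spec$thresholds))
  for (i in seq_len(spec$iterations)) {
    ords <- sort(sample.int(spec$n_pegs, spec$n_gh))
    st <- null_replicate_stats(ords, spec$n_pegs, spec$topology,
                               spec$thresholds, spec$s_max)
    if (i == 1L) colnames(vals) <- names(st)
    vals[i, ] <- st
  }
  new_null_distribution(spec, vals)
}

new_null_distribution <- function(spec, vals) {
  qs <- apply(vals, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  summaries <- rbind(mean = colMeans(vals, na.rm = TRUE),
                     sd = apply(vals, 2L, stats::sd, na.rm = TRUE),
                     median = qs["50%", ],
                     q2.5 = qs["2.5%", ], q97.5 = qs["97.5%", ])
  nd <- list(spec = spec, values = vals, summaries = summaries)
  class(nd) <- "null_distribution"
  nd
}

#' @export
print.null_distribution <- function(x, ...) {
  s <- x$spec
  cat("Null distribution:", s$iterations, "randomizations of", s$n_gh,
      "genes among", s$n_pegs, "PEGs (", s$topology, ")\n")
  show <- intersect(c("mean_ssc", "n_ssc_1", "f_clustered_5"),
                    colnames(x$values))
  print(round(x$summaries[, show, drop = FALSE], 4))
  invisible(x)
}

#' Expected number of genes with SSc = 1 under random placement
#'
#' Closed-form (hypergeometric) expectation of the number of class genes
#' adjacent to another class gene when \code{n_gh} genes are placed uniformly
#' without replacement among \code{n_pegs} slots. On a circular replicon every
#' gene has two flanking slots; on a linear replicon the two end slots have
#' one. Exact for all inputs; the Monte-Carlo simulator must agree with it
#' within sampling error.
#'
#' @param n_pegs Genome size in PEGs.
#' @param n_gh Number of placed genes (at least 2).
#' @param topology Replicon topology.
#' @return Expected count of genes at SSc = 1.
#' @export
#' @examples
#' expected_adjacent_count(5000, 300)  # ~34.8, the "about 35" expectation
expected_adjacent_count <- function(n_pegs, n_gh,
                                    topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is_count(n_pegs)) stop2("n_pegs must be an integer >= 1")
  if (!is_count(n_gh, min = 2L)) stop2("n_gh must be an integer >= 2")
  if (n_gh > n_pegs) stop2("n_gh exceeds n_pegs")
  n <- n_pegs; g <- n_gh
  # P[a specific set of m slots holds none of the other g-1 genes]
  p_empty <- function(m) {
    if (n - 1L - m < g - 1L) return(0)
    exp(lchoose(n - 1L - m, g - 1L) - lchoose(n - 1L, g - 1L))
  }
  if (topology == "circular") {
    if (n <= 2L) return(g)      # every slot adjacent to every other
    g * (1 - p_empty(2L))
  } else {
    if (n <= 2L) return(g)
    p_end <- 1 - p_empty(1L)    # gene sits at one of the 2 chromosome ends
    p_int <- 1 - p_empty(2L)
    g * ((2 / n) * p_end + ((n - 2) / n) * p_int)
  }
}

#' Null distribution matched to an observed genome
#'
#' Builds randomized counterparts of a genome preserving its replicon
#' partition: each replicon keeps its PEG count, topology and number of GH
#' genes, and the GH genes are re-placed uniformly within it. Per replicate
#' the genome-wide clustered fractions, SSc histogram and mean SSc are
#' recorded, pooling genes across replicons.
#'
#' @param genome An \code{annotated_genome} with at least 2 GH genes.
#' @param iterations Number of randomizations (default 5,000).
#' @param seed RNG seed.
#' @param thresholds Cluster thresholds recorded per replicate.
#' @param s_max Largest SSc value tabulated.
#' @param gene_class Gene class randomized.
#' @return A \code{null_distribution}.
#' @export
matched_null <- function(genome, iterations = 5000L, seed = 1L,
                         thresholds = c(1L, 5L, 10L), s_max = 20L,
                         gene_class = "GH") {
  stopifnot(inherits(genome, "annotated_genome"))
  reps <- names(genome$topology)
  sizes <- vapply(reps, function(r)
    sum(genome$genes$replicon_id == r), integer(1))
  counts <- vapply(reps, function(r)
    length(class_ordinals(genome, r, gene_class)), integer(1))
  total <- sum(counts)
  if (total < 2L) stop2("matched_null needs at least 2 ", gene_class,
                        " genes")
  if (!is_count(iterations)) stop2("iterations must be an integer >= 1")
  keep <- counts > 0L
  sizes <- sizes[keep]; counts <- counts[keep]
  topo <- genome$topology[keep]

  set.seed(seed)
  ncol_out <- 1L + s_max + length(thresholds)
  vals <- matrix(NA_real_, nrow = iterations, ncol = ncol_out)
  for (i in seq_len(iterations)) {
    ssc_all <- unlist(lapply(seq_along(sizes), function(j) {
      ords <- sort(sample.int(sizes[j], counts[j]))
      ssc_from_ordinals(ords, sizes[j], topo[[j]])$ssc
    }))
    def <- ssc_all[!is.na(ssc_all)]
    st <- c(mean_ssc = if (length(def)) mean(def) else NA_real_,
            stats::setNames(tabulate(def[def <= s_max], nbins = s_max),
                            paste0("n_ssc_", seq_len(s_max))),
            stats::setNames(
              vapply(thresholds, function(t) sum(def <= t) / total,
                     numeric(1)),
              paste0("f_clustered_", thresholds)))
    if (i == 1L) colnames(vals) <- names(st)
    vals[i, ] <- st
  }
  new_null_distribution(
    null_spec(sum(sizes), total,
              topology = if (all(topo == "linear")) "linear" else "circular",
              iterations = iterations, seed = seed,
              thresholds = thresholds, s_max = s_max),
    vals)
}

#' Empirical p-value against a null distribution
#'
#' Add-one empirical p: \code{(1 + #null values at least as extreme) /
#' (1 + iterations)}, so a p-value of exactly zero is never reported.
#'
#' @param observed Observed statistic value.
#' @param null A \code{null_distribution} or a numeric vector of null values.
#' @param side \code{"greater"} (observed unusually large) or \code{"less"}.
#' @param statistic Column of the null's value matrix to compare against,
#'   when \code{null} is a \code{null_distribution}.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null, side = c("greater", "less"),
                        statistic = "f_clustered_5") {
  side <- match.arg(side)
  vals <- if (inherits(null, "null_distribution")) {
    if (!statistic %in% colnames(null$values)) {
      stop2("statistic ", statistic, " not recorded in null distribution")
    }
    null$values[, statistic]
  } else as.numeric(null)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop2("empty null distribution")
  extreme <- if (side == "greater") sum(vals >= observed) else
    sum(vals <= observed)
  (1 + extreme) / (1 + length(vals))
}

#' Shapiro-Wilk normality summary of a simulated statistic
#'
#' Applies the Shapiro-Wilk test to a sample of a statistic (for example the
#' per-replicate mean SSc of a null distribution). Samples larger than 5,000
#' values — the test's implementation limit — are subsampled with the given
#' seed before testing.
#'
#' @param values Numeric sample (at least 3 non-identical values).
#' @param seed Seed used only when subsampling is needed.
#' @return A \code{stat_result} list: \code{statistic = "shapiro_wilk"},
#'   \code{W}, \code{p_value}, \code{n} (values actually tested).
#' @export
normality_summary <- function(values, seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop2("need at least 3 values")
  if (stats::sd(values) == 0) stop2("zero variance: constant vector")
  if (length(values) > 5000L) {
    set.seed(seed)
    values <- sample(values, 5000L)
  }
  sw <- stats::shapiro.test(values)
  res <- list(statistic = "shapiro_wilk", W = unname(sw$statistic),
              p_value = sw$p.value, n = length(values))
  class(res) <- "stat_result"
  res
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$statistic, ": W = ", format(x$W, digits = 4),
      ", p = ", format(x$p_value, digits = 3), " (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}
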