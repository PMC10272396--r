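# Strand codirectionality of sequential same-class gene pairs.
#
# Under no selection, whether two sequential GH genes share a strand is a
# fair-coin Bernoulli trial, so 50% of sequential pairs are expected to be
# codirectional; an exact binomial test quantifies departures.

#' Sequential pairs of same-class genes
#'
#' Enumerates the pairs of successive genes of a class along each replicon.
#' On a circular replicon with at least two members the wrap pair (last
#' member, first member) is included, so the number of pairs equals the
#' number of members; on a linear replicon it is one less. Each pair carries
#' its gap in PEGs — which is exactly the pair's synteny score — and a
#' codirectionality flag.
#'
#' @param genome An \code{annotated_genome}.
#' @param restriction \code{"all"} for every sequential pair, or
#'   \code{"clustered"} to keep only pairs with gap at most \code{threshold}.
#' @param threshold Gap threshold used when \code{restriction = "clustered"}.
#' @param gene_class Gene class to pair.
#' @return A \code{pair_set} data frame: \code{replicon_id}, \code{gene_a},
#'   \code{gene_b}, \code{ordinal_a}, \code{ordinal_b}, \code{gap},
#'   \code{codirectional}; the restriction is recorded as an attribute.
#' @export
sequential_pairs <- function(genome, restriction = c("all", "clustered"),
                             threshold = 5L, gene_class = "GH") {
  stopifnot(inherits(genome, "annotated_genome"))
  restriction <- match.arg(restriction)
  rows <- list()
  for (rep in names(genome$topology)) {
    g <- genome$genes[genome$genes$replicon_id == rep, , drop = FALSE]
    sel <- which(class_members(g, gene_class))
    k <- length(sel)
    if (k < 2L) next
    topo <- genome$topology[[rep]]
    a <- seq_len(k - 1L); b <- a + 1L
    gaps <- diff(g$ordinal[sel])
    if (topo == "circular") {
      a <- c(a, k); b <- c(b, 1L)
      gaps <- c(gaps, nrow(g) - g$ordinal[sel[k]] + g$ordinal[sel[1L]])
    }
    rows[[rep]] <- data.frame(
      replicon_id = rep,
      gene_a = g$gene_id[sel[a]], gene_b = g$gene_id[sel[b]],
      ordinal_a = g$ordinal[sel[a]], ordinal_b = g$ordinal[sel[b]],
      gap = as.integer(gaps),
      codirectional = g$strand[sel[a]] == g$strand[sel[b]],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon_id = character(), gene_a = character(),
               gene_b = character(), ordinal_a = integer(),
               ordinal_b = integer(), gap = integer(),
               codirectional = logical(), stringsAsFactors = FALSE)
  if (restriction == "clustered") {
    if (!is_count(threshold)) stop2("threshold must be an integer >= 1")
    pairs <- pairs[pairs$gap <= threshold, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  attr(pairs, "restriction") <- if (restriction == "clustered")
    sprintf("clustered(%d)", as.integer(threshold)) else "all"
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

#' Fraction of codirectional pairs
#'
#' @param pairs A \code{pair_set} from \code{\link{sequential_pairs}}.
#' @return Fraction of pairs whose two genes share a strand.
#' @export
codirectional_fraction <- function(pairs) {
  if (nrow(pairs) == 0L) stop2("no pairs")
  mean(pairs$codirectional)
}

#' Exact binomial test of codirectionality
#'
#' Two-sided exact binomial test of the number of codirectional pairs against
#' a null probability of 0.5, using equal-tail doubling: twice the smaller of
#' P(X <= k) and P(X >= k), capped at 1. The exact test is preferred over a
#' normal approximation because most genomes contribute few pairs.
#'
#' @param k Number of codirectional pairs.
#' @param n Total number of pairs.
#' @param p0 Null codirectionality probability.
#' @return List with \code{k}, \code{n}, \code{estimate} (k/n), \code{p0} and
#'   the two-sided \code{p_value}.
#' @export
#' @examples
#' binomial_codirectionality_test(10, 10)$p_value  # ~0.00195
binomial_codirectionality_test <- function(k, n, p0 = 0.5) {
  if (!is_count(n)) stop2("n must be an integer >= 1")
  if (!is_count(k, min = 0L) || k > n) stop2("k must be an integer in [0, n]")
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) stop2("p0 must be in (0, 1)")
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
  list(k = as.integer(k), n = as.integer(n), estimate = k / n, p0 = p0,
       p_value = min(1, 2 * min(lower, upper)))
}
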