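# Synteny scores, SSc histograms and cluster detection.
#
# The synteny score (SSc) of a gene of interest is the shortest distance,
# upstream or downstream and expressed in PEG ordinals, to the next gene of
# the same class on the same replicon. Contiguous genes have SSc = 1. On a
# circular replicon the distance wraps across the origin; a replicon with a
# single class member yields an undefined SSc (NA).

# Kernel shared by synteny_scores() and the null-model simulator: given the
# sorted ordinals of class members on one replicon, return the inter-member
# gaps and the per-member SSc.
ssc_from_ordinals <- function(ordinals, n_pegs, topology) {
  k <- length(ordinals)
  if (k == 0L) return(list(ssc = integer(), gaps = integer()))
  if (k == 1L) return(list(ssc = NA_integer_, gaps = integer()))
  fwd <- diff(ordinals)
  if (topology == "circular") {
    wrap <- n_pegs - ordinals[k] + ordinals[1L]
    gaps <- c(fwd, wrap)                      # gaps[i]: member i -> i+1 (cyclic)
    prev <- c(wrap, fwd)                      # gap from previous member
    ssc <- pmin(prev, gaps)
  } else {
    gaps <- fwd
    ssc <- c(fwd[1L],
             if (k > 2L) pmin(fwd[-(k - 1L)], fwd[-1L]) else integer(),
             fwd[k - 1L])
  }
  list(ssc = as.integer(ssc), gaps = as.integer(gaps))
}

#' Per-gene synteny scores and SSc histogram
#'
#' Computes the synteny score of every gene of a class (GH by default) in a
#' genome, together with the number (\code{n_ssc}) and frequency
#' (\code{f_ssc}) of genes at each SSc value from 1 to \code{s_max}.
#' Distances never cross replicons; plasmids are scored independently.
#'
#' @param genome An \code{annotated_genome}.
#' @param gene_class \code{"GH"} or one of \code{"TR_MFS"}, \code{"TR_ABC"},
#'   \code{"TR_PTS"}, \code{"TR_SUS"}.
#' @param s_max Largest SSc value tabulated in the histogram.
#' @return A \code{synteny_profile}: list with \code{scores} (data frame:
#'   \code{gene_id}, \code{replicon_id}, \code{ordinal}, \code{strand},
#'   \code{ssc}; \code{ssc} is \code{NA} when the gene is its replicon's only
#'   class member), \code{n_ssc}, \code{f_ssc}, \code{s_max}, \code{n_class}.
#' @export
#' @examples
#' g <- generate_genome(synth_spec(n_pegs = 200, n_gh = 20, seed = 1))
#' prof <- synteny_scores(g)
#' head(prof$scores)
synteny_scores <- function(genome, gene_class = "GH", s_max = 20L) {
  stopifnot(inherits(genome, "annotated_genome"))
  out <- list()
  for (rep in names(genome$topology)) {
    g <- genome$genes[genome$genes$replicon_id == rep, , drop = FALSE]
    sel <- class_members(g, gene_class)
    if (!any(sel)) next
    res <- ssc_from_ordinals(g$ordinal[sel], nrow(g), genome$topology[[rep]])
    out[[rep]] <- data.frame(
      gene_id = g$gene_id[sel], replicon_id = rep,
      ordinal = g$ordinal[sel], strand = g$strand[sel],
      ssc = res$ssc, stringsAsFactors = FALSE)
  }
  scores <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), replicon_id = character(),
               ordinal = integer(), strand = character(), ssc = integer(),
               stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  n_class <- nrow(scores)
  n_ssc <- tabulate(scores$ssc[!is.na(scores$ssc) & scores$ssc <= s_max],
                    nbins = s_max)
  prof <- list(scores = scores,
               n_ssc = stats::setNames(n_ssc, seq_len(s_max)),
               f_ssc = stats::setNames(
                 if (n_class > 0L) n_ssc / n_class else rep(0, s_max),
                 seq_len(s_max)),
               s_max = as.integer(s_max), n_class = n_class,
               gene_class = gene_class)
  class(prof) <- "synteny_profile"
  prof
}

#' @export
print.synteny_profile <- function(x, ...) {
  cat("Synteny profile (", x$gene_class, "): ", x$n_class, " genes\n",
      sep = "")
  def <- x$scores$ssc[!is.na(x$scores$ssc)]
  if (length(def)) {
    cat("  mean SSc:", round(mean(def), 2),
        " median:", stats::median(def), "\n")
    cat("  SSc = 1:", sum(def == 1L), " genes;  SSc <= 5:", sum(def <= 5L),
        " genes\n")
  }
  if (anyNA(x$scores$ssc))
    cat("  undefined SSc (single class member on replicon):",
        sum(is.na(x$scores$ssc)), "\n")
  invisible(x)
}

#' Maximal clusters of closely linked genes
#'
#' A cluster is a maximal chain of same-class genes in which every gap between
#' consecutive members is at most \code{threshold} PEGs (the gap being exactly
#' the pair's synteny score). On a circular replicon the chain may wrap across
#' the origin; if every gap on a circular replicon is within the threshold,
#' one cluster containing all members is returned. Genes with no neighbour
#' within the threshold form size-1 clusters.
#'
#' @param genome An \code{annotated_genome}.
#' @param threshold Maximum gap (in PEGs) joining consecutive members;
#'   the cluster-defining default is 5.
#' @param gene_class Gene class to cluster.
#' @return A \code{gh_clusters} data frame, one row per cluster, with columns
#'   \code{cluster_id}, \code{replicon_id}, \code{size}, \code{span},
#'   \code{n_codirectional} (codirectional consecutive member pairs) and
#'   list-columns \code{members} (gene ids in chain order), \code{ordinals}
#'   and \code{gaps}.
#' @export
find_clusters <- function(genome, threshold = 5L, gene_class = "GH") {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is_count(threshold)) stop2("threshold must be an integer >= 1")
  rows <- list()
  for (rep in names(genome$topology)) {
    g <- genome$genes[genome$genes$replicon_id == rep, , drop = FALSE]
    sel <- which(class_members(g, gene_class))
    k <- length(sel)
    if (k == 0L) next
    ords <- g$ordinal[sel]
    topo <- genome$topology[[rep]]
    chains <- if (k == 1L) list(1L) else {
      res <- ssc_from_ordinals(ords, nrow(g), topo)
      gaps <- res$gaps
      if (topo == "circular") {
        # gaps[i] joins member i to i+1 (cyclic); break where gap > threshold
        brk <- which(gaps > threshold)
        if (!length(brk)) list(seq_len(k)) else {
          # chains start after each break, in cyclic order
          starts <- (brk %% k) + 1L
          lens <- diff(c(brk, brk[1L] + k))
          mapply(function(s, l) ((s - 1L + seq_len(l) - 1L) %% k) + 1L,
                 starts, lens, SIMPLIFY = FALSE)
        }
      } else {
        brk <- which(gaps > threshold)
        bounds <- c(0L, brk, k)
        lapply(seq_len(length(bounds) - 1L), function(i)
          (bounds[i] + 1L):bounds[i + 1L])
      }
    }
    for (ch in chains) {
      idx <- sel[ch]
      o <- g$ordinal[idx]
      n <- nrow(g)
      gp <- if (length(ch) > 1L) {
        d <- diff(g$ordinal[idx])
        # wrap-spanning chains have negative forward differences
        as.integer(ifelse(d > 0L, d, d + n))
      } else integer()
      strands <- g$strand[idx]
      rows[[length(rows) + 1L]] <- list(
        replicon_id = rep, size = length(ch),
        span = if (length(ch) > 1L) sum(gp) + 1L else 1L,
        n_codirectional = if (length(ch) > 1L)
          sum(strands[-length(strands)] == strands[-1L]) else 0L,
        members = g$gene_id[idx], ordinals = o, gaps = gp)
    }
  }
  cl <- data.frame(
    cluster_id = if (length(rows)) sprintf("cl%03d", seq_along(rows))
      else character(),
    replicon_id = vapply(rows, `[[`, "", "replicon_id"),
    size = vapply(rows, `[[`, 0L, "size"),
    span = vapply(rows, `[[`, 0L, "span"),
    n_codirectional = vapply(rows, `[[`, 0L, "n_codirectional"),
    stringsAsFactors = FALSE)
  cl$members <- lapply(rows, `[[`, "members")
  cl$ordinals <- lapply(rows, `[[`, "ordinals")
  cl$gaps <- lapply(rows, `[[`, "gaps")
  attr(cl, "threshold") <- as.integer(threshold)
  attr(cl, "gene_class") <- gene_class
  class(cl) <- c("gh_clusters", "data.frame")
  cl
}

#' Fraction of class genes in clusters
#'
#' The fraction of genes of a class whose synteny score is defined and at most
#' \code{threshold}. Genes with undefined SSc (sole class member on their
#' replicon) count as unclustered.
#'
#' @inheritParams find_clusters
#' @return A fraction in \[0, 1\].
#' @export
clustered_fraction <- function(genome, threshold = 5L, gene_class = "GH") {
  prof <- synteny_scores(genome, gene_class,
                         s_max = max(20L, as.integer(threshold)))
  if (prof$n_class == 0L) stop2("no ", gene_class, " genes in genome")
  ssc <- prof$scores$ssc
  sum(!is.na(ssc) & ssc <= threshold) / prof$n_class
}
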