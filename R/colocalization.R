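# GH:transporter colocalization.
#
# A GH gene forms a GH:TR cluster with a transporter class when a gene of
# that class lies within the colocalization threshold (default 10 PEGs,
# i.e. SSc <= 10) on the same replicon. Distance is the ordinal PEG
# difference, wrap-aware on circular replicons; strand is ignored.

# Nearest member of `targets` (sorted ordinals) to position o, excluding o
# itself. Returns c(distance, partner_ordinal) or c(NA, NA). Ties between the
# upstream and downstream candidate are broken in favour of the upstream
# (lower-ordinal, wrap-aware) gene.
nearest_ordinal <- function(o, targets, n, topology) {
  targets <- targets[targets != o]
  if (!length(targets)) return(c(NA_real_, NA_real_))
  if (topology == "circular") {
    # upstream distance for each target: (o - t) mod n
    dist_up <- (o - targets) %% n
    dist_dn <- (targets - o) %% n
    d <- pmin(dist_up, dist_dn)
    best <- min(d)
    cand <- targets[d == best]
    # prefer a candidate reached moving upstream
    up_cand <- targets[d == best & dist_up <= dist_dn]
    partner <- if (length(up_cand)) up_cand[1L] else cand[1L]
    c(best, partner)
  } else {
    d <- abs(targets - o)
    best <- min(d)
    cand <- targets[d == best]
    up_cand <- cand[cand < o]
    partner <- if (length(up_cand)) up_cand[1L] else cand[1L]
    c(best, partner)
  }
}

#' GH-gene / transporter-gene associations
#'
#' For every GH gene, finds the nearest gene of each transporter class
#' (MFS, ABC, PTS, SUS) on the same replicon and records the class when the
#' distance is within the threshold. A gene carrying both GH and transporter
#' domains never partners itself. GH genes with no transporter class within
#' the threshold are flagged isolated.
#'
#' @param genome An \code{annotated_genome}.
#' @param threshold Maximum GH-transporter distance in PEGs (default 10).
#' @return Data frame with one row per GH gene: \code{gene_id},
#'   \code{replicon_id}, \code{ordinal}, then per class \code{<class>_dist}
#'   and \code{<class>_partner} (\code{NA} beyond the threshold), and
#'   \code{isolated}.
#' @export
gh_tr_associations <- function(genome, threshold = 10L) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is_count(threshold)) stop2("threshold must be an integer >= 1")
  out <- list()
  for (rep in names(genome$topology)) {
    g <- genome$genes[genome$genes$replicon_id == rep, , drop = FALSE]
    gh_idx <- which(g$is_gh)
    if (!length(gh_idx)) next
    n <- nrow(g)
    topo <- genome$topology[[rep]]
    row <- data.frame(gene_id = g$gene_id[gh_idx], replicon_id = rep,
                      ordinal = g$ordinal[gh_idx], stringsAsFactors = FALSE)
    for (cl in TR_CLASSES) {
      tr_ord <- g$ordinal[class_members(g, cl)]
      res <- t(vapply(g$ordinal[gh_idx], nearest_ordinal,
                      numeric(2), targets = tr_ord, n = n, topology = topo))
      dist <- res[, 1L]; partner <- res[, 2L]
      within <- !is.na(dist) & dist <= threshold
      key <- tolower(sub("^TR_", "", cl))
      row[[paste0(key, "_dist")]] <- ifelse(within, as.integer(dist),
                                            NA_integer_)
      row[[paste0(key, "_partner")]] <- ifelse(
        within, g$gene_id[match(partner, g$ordinal)], NA_character_)
    }
    out[[rep]] <- row
  }
  assoc <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), replicon_id = character(),
               ordinal = integer(), stringsAsFactors = FALSE)
  if (nrow(assoc)) {
    dist_cols <- paste0(tolower(sub("^TR_", "", TR_CLASSES)), "_dist")
    assoc$isolated <- rowSums(!is.na(assoc[, dist_cols, drop = FALSE])) == 0L
  } else assoc$isolated <- logical()
  rownames(assoc) <- NULL
  attr(assoc, "threshold") <- as.integer(threshold)
  assoc
}

#' Genome-level GH:TR colocalization summary
#'
#' @param genome An \code{annotated_genome} with at least one GH gene.
#' @param threshold Maximum GH-transporter distance in PEGs (default 10).
#' @return List with \code{f_colocalized} (fraction of GH genes with at least
#'   one transporter class within the threshold), \code{n_by_class} (GH-gene
#'   counts per transporter class), \code{n_multi_class} (GH genes associated
#'   with more than one class), \code{n_gh}, \code{threshold}.
#' @export
colocalization_summary <- function(genome, threshold = 10L) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (genome$counts$n_gh == 0L) stop2("no GH genes in genome")
  assoc <- gh_tr_associations(genome, threshold)
  dist_cols <- paste0(tolower(sub("^TR_", "", TR_CLASSES)), "_dist")
  has <- !is.na(assoc[, dist_cols, drop = FALSE])
  list(
    f_colocalized = if (nrow(assoc)) mean(!assoc$isolated) else 0,
    n_by_class = stats::setNames(colSums(has), TR_CLASSES),
    n_multi_class = sum(rowSums(has) > 1L),
    n_gh = nrow(assoc),
    threshold = as.integer(threshold))
}
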