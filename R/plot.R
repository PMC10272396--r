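# Genome-map rendering: GH genes coloured by strand, GH:TR links.

#' Plot a genome map of GH genes and transporter associations
#'
#' Draws each replicon as a horizontal track with GH genes as ticks coloured
#' by coding strand (forward above the line, reverse below) and, when
#' requested, vertical connectors between GH genes and their associated
#' transporter genes (GH:TR clusters).
#'
#' @param x An \code{annotated_genome}.
#' @param show_tr Draw transporter genes and GH:TR links?
#' @param coloc_threshold Association threshold used for the links.
#' @param ... Passed to \code{plot.default}.
#' @return Invisibly, \code{x}.
#' @export
plot.annotated_genome <- function(x, show_tr = TRUE, coloc_threshold = 10L,
                                  ...) {
  reps <- names(x$topology)
  nrep <- length(reps)
  graphics::plot(NA, xlim = c(0, max(table(x$genes$replicon_id))),
                 ylim = c(0.5, nrep + 0.5), yaxt = "n",
                 xlab = "PEG ordinal", ylab = "",
                 main = paste("GH-gene map:", x$genome_id), ...)
  graphics::axis(2, at = seq_len(nrep), labels = reps, las = 1)

  assoc <- if (show_tr && x$counts$n_gh > 0L)
    gh_tr_associations(x, coloc_threshold) else NULL
  tr_cols <- stats::setNames(c("#1b9e77", "#7570b3", "#e7298a", "#66a61e"),
                             TR_CLASSES)
  for (i in seq_len(nrep)) {
    g <- x$genes[x$genes$replicon_id == reps[i], , drop = FALSE]
    graphics::segments(1, i, nrow(g), i, col = "grey60")
    gh <- g[g$is_gh, , drop = FALSE]
    if (nrow(gh)) {
      fwd <- gh$strand == "+"
      graphics::segments(gh$ordinal, i, gh$ordinal,
                         i + ifelse(fwd, 0.25, -0.25),
                         col = ifelse(fwd, "darkorange", "firebrick"))
    }
    if (show_tr) {
      for (cl in TR_CLASSES) {
        tr <- g[class_members(g, cl), , drop = FALSE]
        if (nrow(tr)) graphics::points(tr$ordinal, rep(i, nrow(tr)),
                                       pch = 17, cex = 0.5,
                                       col = tr_cols[cl])
      }
    }
    if (!is.null(assoc)) {
      a <- assoc[assoc$replicon_id == reps[i], , drop = FALSE]
      for (cl in tolower(sub("^TR_", "", TR_CLASSES))) {
        pc <- a[[paste0(cl, "_partner")]]
        ok <- !is.na(pc)
        if (any(ok)) {
          po <- g$ordinal[match(pc[ok], g$gene_id)]
          graphics::segments(a$ordinal[ok], i - 0.35, po, i - 0.35,
                             col = "grey40", lwd = 0.5)
        }
      }
    }
  }
  if (show_tr) {
    graphics::legend("topright",
                     legend = c("GH +", "GH -",
                                sub("^TR_", "", TR_CLASSES)),
                     col = c("darkorange", "firebrick", tr_cols),
                     pch = c(NA, NA, rep(17, 4)),
                     lty = c(1, 1, rep(NA, 4)), cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Render a genome map to an image file
#'
#' @param genome An \code{annotated_genome}.
#' @param file Output path (\code{.png} or \code{.svg}).
#' @param width,height Device size in pixels (png) or inches (svg).
#' @param ... Passed to \code{\link{plot.annotated_genome}}.
#' @return The output path, invisibly.
#' @export
render_genome_map <- function(genome, file, width = 1200, height = 400,
                              ...) {
  dir <- dirname(file)
  if (!dir.exists(dir)) stop2("output directory does not exist: ", dir)
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    grDevices::svg(file, width = width / 120, height = height / 120)
  } else {
    grDevices::png(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  plot(genome, ...)
  invisible(file)
}
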