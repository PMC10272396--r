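# Synthetic annotated genomes with controlled GH content, planted
# codirectional clusters and transporter co-placement.
#
# The generator emulates single-replicon bacterial genomes in the regimes
# studied with the null models: 1,000-15,000 PEGs carrying 0.5-10% GH genes,
# placed either uniformly at random or in planted clusters of closely linked
# genes. Transporter genes of each class can be co-placed near GH clusters
# with a configurable probability. No sequences are generated; genes are
# ordinal slots with a strand and a domain annotation.

#' Specification of a synthetic genome
#'
#' @param n_pegs Genome size in PEGs (default 5,000).
#' @param n_gh Total number of GH genes (default 300, i.e. 6%); genes not
#'   used by planted clusters are placed uniformly at random.
#' @param topology Replicon topology.
#' @param cluster_count Number of planted GH clusters (default 0: fully
#'   random placement, the null-model regime).
#' @param cluster_size Members per planted cluster (single value or vector
#'   sampled from; default 4).
#' @param gap_choices Within-cluster gaps are sampled uniformly from this set
#'   (default \code{1:5}, so planted clusters are clustered at the SSc <= 5
#'   threshold).
#' @param codir_prob Probability that each consecutive within-cluster member
#'   keeps the strand of the previous member (default 0.9, the
#'   codirectionality level seen in strongly clustered lineages).
#' @param strand_prob Background probability of the forward strand (0.5).
#' @param tr_counts Named integer vector of transporter genes per class,
#'   e.g. \code{c(TR_ABC = 20, TR_SUS = 10)}; default none.
#' @param coplace_prob Probability that a transporter gene is placed within
#'   \code{coplace_window} PEGs of a GH gene rather than uniformly.
#' @param coplace_window Window used for transporter co-placement (default
#'   10, the GH:TR colocalization threshold).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A \code{synth_spec} list.
#' @export
synth_spec <- function(n_pegs = 5000L, n_gh = 300L,
                       topology = c("circular", "linear"),
                       cluster_count = 0L, cluster_size = 4L,
                       gap_choices = 1:5, codir_prob = 0.9,
                       strand_prob = 0.5, tr_counts = integer(),
                       coplace_prob = 0.9, coplace_window = 10L,
                       seed = 1L) {
  topology <- match.arg(topology)
  if (!is_count(n_pegs)) stop2("n_pegs must be an integer >= 1")
  if (!is_count(n_gh, min = 0L)) stop2("n_gh must be an integer >= 0")
  if (n_gh > n_pegs) stop2("n_gh exceeds n_pegs")
  if (!is_count(cluster_count, min = 0L)) stop2("cluster_count must be >= 0")
  for (p in c(codir_prob, strand_prob, coplace_prob)) {
    if (!is.numeric(p) || p < 0 || p > 1) stop2("probabilities must be in [0,1]")
  }
  if (length(tr_counts) && is.null(names(tr_counts))) {
    stop2("tr_counts must be named by transporter class")
  }
  bad <- setdiff(names(tr_counts), TR_CLASSES)
  if (length(bad)) stop2("unknown transporter class: ",
                         paste(bad, collapse = ", "))
  spec <- list(n_pegs = as.integer(n_pegs), n_gh = as.integer(n_gh),
               topology = topology, cluster_count = as.integer(cluster_count),
               cluster_size = as.integer(cluster_size),
               gap_choices = as.integer(gap_choices),
               codir_prob = codir_prob, strand_prob = strand_prob,
               tr_counts = tr_counts, coplace_prob = coplace_prob,
               coplace_window = as.integer(coplace_window),
               seed = as.integer(seed))
  class(spec) <- "synth_spec"
  spec
}

sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Generate a synthetic annotated genome
#'
#' Plants \code{cluster_count} clusters of GH genes (members separated by
#' gaps sampled from \code{gap_choices}, strands correlated with probability
#' \code{codir_prob}), fills the remaining GH genes uniformly among free
#' slots, places transporter genes (optionally co-placed near GH genes), and
#' assigns every GH gene the representative GH13 accession (PF00128) and
#' every transporter gene its class's representative accession, so that the
#' written files exercise the annotation stage realistically. Cluster
#' layouts that cannot be placed without overlap are rejection-sampled with
#' a retry cap of 1,000.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param genome_id Identifier for the generated genome.
#' @param replicon_id Identifier for its single replicon.
#' @return An \code{annotated_genome}.
#' @export
#' @examples
#' g <- generate_genome(synth_spec(n_pegs = 1000, n_gh = 40,
#'                                 cluster_count = 5, seed = 3))
#' g
generate_genome <- function(spec, genome_id = "synth1",
                            replicon_id = "chr1") {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_pegs

  occupied <- logical(n)        # slots holding GH genes
  gh_slots <- integer()
  cluster_strands <- rep(NA, n) # strands fixed by planted clusters

  # plant clusters by rejection sampling
  if (spec$cluster_count > 0L) {
    planted <- 0L
    tries <- 0L
    while (planted < spec$cluster_count) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop2("could not place ", spec$cluster_count,
              " clusters in ", n, " PEGs after 1000 attempts")
      }
      size <- sample1(spec$cluster_size)
      gaps <- if (size > 1L)
        spec$gap_choices[sample.int(length(spec$gap_choices), size - 1L,
                                    replace = TRUE)] else integer()
      offsets <- c(0L, cumsum(gaps))
      span <- offsets[length(offsets)]
      start <- sample.int(n, 1L)
      slots <- start + offsets
      if (spec$topology == "circular") {
        slots <- ((slots - 1L) %% n) + 1L
      } else if (slots[length(slots)] > n) next
      if (any(occupied[slots])) next
      if (sum(!occupied) - length(slots) < 0L) next
      # leave at least gap_choices-max+1 free PEGs around? Not required:
      # maximality is a property of the analysis, not the plant.
      occupied[slots] <- TRUE
      gh_slots <- c(gh_slots, slots)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      st <- character(length(slots))
      st[1L] <- strand
      for (j in seq_len(length(slots) - 1L)) {
        st[j + 1L] <- if (stats::runif(1) < spec$codir_prob) st[j] else
          setdiff(c("+", "-"), st[j])
      }
      cluster_strands[slots] <- st
      planted <- planted + 1L
    }
  }
  if (length(gh_slots) > spec$n_gh) {
    stop2("planted clusters use ", length(gh_slots),
          " GH genes but n_gh is only ", spec$n_gh)
  }

  # background GH genes fill uniformly among free slots
  n_bg <- spec$n_gh - length(gh_slots)
  if (n_bg > 0L) {
    free <- which(!occupied)
    bg <- free[sample.int(length(free), n_bg)]
    occupied[bg] <- TRUE
    gh_slots <- c(gh_slots, bg)
  }
  gh_slots <- sort(gh_slots)

  # transporter genes: per class, co-placed near GH genes or uniform
  tr_slot_class <- rep(NA_character_, n)
  for (cl in names(spec$tr_counts)) {
    cnt <- spec$tr_counts[[cl]]
    for (i in seq_len(cnt)) {
      free <- which(!occupied & is.na(tr_slot_class))
      if (!length(free)) stop2("no free slots left for transporters")
      slot <- NA_integer_
      if (length(gh_slots) && stats::runif(1) < spec$coplace_prob) {
        anchor <- gh_slots[sample.int(length(gh_slots), 1L)]
        win <- anchor + setdiff(-spec$coplace_window:spec$coplace_window, 0L)
        if (spec$topology == "circular") win <- ((win - 1L) %% n) + 1L
        win <- win[win >= 1L & win <= n]
        win <- intersect(win, free)
        if (length(win)) slot <- win[sample.int(length(win), 1L)]
      }
      if (is.na(slot)) slot <- free[sample.int(length(free), 1L)]
      tr_slot_class[slot] <- cl
    }
  }

  strands <- ifelse(stats::runif(n) < spec$strand_prob, "+", "-")
  fixed <- !is.na(cluster_strands)
  strands[fixed] <- cluster_strands[fixed]

  is_gh <- seq_len(n) %in% gh_slots
  genes <- data.frame(
    genome_id = genome_id, replicon_id = replicon_id,
    ordinal = seq_len(n), strand = strands,
    gene_id = sprintf("%s.peg.%d", genome_id, seq_len(n)),
    is_gh = is_gh,
    gh_families = ifelse(is_gh, "GH13", ""),
    tr_classes = ifelse(is.na(tr_slot_class), "", tr_slot_class),
    stringsAsFactors = FALSE)
  g <- new_annotated_genome(genes,
                            stats::setNames(spec$topology, replicon_id))
  attr(g, "synth_spec") <- spec
  g
}

#' Generate a cohort of synthetic genomes with metadata
#'
#' @param specs List of \code{\link{synth_spec}} objects (each spec's own
#'   seed is replaced by one derived deterministically from \code{seed} and
#'   the spec's index).
#' @param metadata Optional data frame with one row per spec; typical columns
#'   are \code{genome_id}, \code{phylum}, \code{genus}, \code{environment}.
#'   A \code{genome_id} column is generated when absent.
#' @param dir If non-\code{NULL}, feature and hit files for every genome are
#'   written there along with a \code{metadata.tsv}.
#' @param seed Master seed for the cohort.
#' @return List with \code{genomes} (named list of \code{annotated_genome}),
#'   \code{metadata} (data frame) and, when files were written,
#'   \code{files}.
#' @export
generate_cohort <- function(specs, metadata = NULL, dir = NULL, seed = 1L) {
  if (!length(specs)) stop2("need at least one spec")
  ids <- if (!is.null(metadata) && "genome_id" %in% names(metadata)) {
    as.character(metadata$genome_id)
  } else sprintf("synth%03d", seq_along(specs))
  if (anyDuplicated(ids)) stop2("duplicate genome ids in cohort")
  if (!is.null(metadata) && nrow(metadata) != length(specs)) {
    stop2("metadata must have one row per spec")
  }
  genomes <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    # derived per-genome stream, kept within 32-bit integer range
    sp$seed <- as.integer((as.numeric(seed) * 10007 + i * 7919) %% .Machine$integer.max)
    genomes[[i]] <- generate_genome(sp, genome_id = ids[i])
  }
  names(genomes) <- ids
  md <- if (is.null(metadata)) data.frame(genome_id = ids,
                                          stringsAsFactors = FALSE) else {
    metadata$genome_id <- ids
    metadata
  }
  out <- list(genomes = genomes, metadata = md)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- lapply(genomes, write_genome_files, dir = dir)
    write_tsv(md, file.path(dir, "metadata.tsv"))
    out$files <- files
  }
  out
}
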