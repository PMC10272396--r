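# End-to-end orchestration over one or many genomes.

#' Run the full analysis pipeline from a config
#'
#' Reads every configured genome, annotates it, and writes per-genome synteny
#' and association tables, a cohort table, optional matched-null summaries
#' (as JSON) and a log to the output directory. The run is deterministic
#' given the config and seed. All input paths are validated before any
#' computation starts; a failure on one genome is logged and the run
#' continues with the others.
#'
#' The config is a YAML file (or an equivalent named list) with keys:
#' \preformatted{
#' output_dir: out
#' seed: 1
#' thresholds: [1, 5, 10]
#' coloc_threshold: 10
#' min_score: 25
#' null_iterations: 0        # > 0 enables matched nulls
#' family_map: map.tsv       # optional
#' genomes:
#'   - id: genomeA
#'     features: genomeA.features.tsv
#'     features_dialect: tsv     # or gff3
#'     hits: genomeA.hits.tsv
#'     hits_dialect: tsv         # or domtblout
#'     topology: circular        # gff3 only
#' metadata: metadata.tsv    # optional, joined by genome_id
#' }
#'
#' @param config Path to a YAML config file, or a named list with the same
#'   structure.
#' @return Invisibly, a list with \code{cohort} (data frame), \code{outputs}
#'   (paths written), \code{errors} (named list of per-genome failure
#'   messages) and \code{status} (0 if all genomes succeeded, 1 otherwise).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$genomes) || !length(config$genomes)) {
    stop2("config lists no genomes")
  }
  out_dir <- config$output_dir %||% "ghsynteny_out"
  seed <- as.integer(config$seed %||% 1L)
  thresholds <- as.integer(config$thresholds %||% c(1L, 5L, 10L))
  coloc_threshold <- as.integer(config$coloc_threshold %||% 10L)
  min_score <- as.numeric(config$min_score %||% 25)
  null_iterations <- as.integer(config$null_iterations %||% 0L)

  # validate every input path before doing any work
  for (gc in config$genomes) {
    for (key in c("features", "hits")) {
      if (is.null(gc[[key]])) stop2("genome entry missing '", key, "' path")
      if (!file.exists(gc[[key]])) stop2("input not found: ", gc[[key]])
    }
  }
  if (!is.null(config$family_map) && !file.exists(config$family_map)) {
    stop2("family map not found: ", config$family_map)
  }
  if (!is.null(config$metadata) && !file.exists(config$metadata)) {
    stop2("metadata not found: ", config$metadata)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(
    sprintf("seed: %d", seed),
    sprintf("thresholds: %s", paste(thresholds, collapse = ",")),
    sprintf("coloc_threshold: %d", coloc_threshold),
    sprintf("min_score: %g", min_score),
    sprintf("null_iterations: %d", null_iterations))

  map <- load_family_map(config$family_map)
  summaries <- list()
  outputs <- character()
  errors <- list()

  for (gc in config$genomes) {
    gid <- gc$id %||% sub("\\.[^.]*$", "", basename(gc$features))
    res <- tryCatch({
      feats <- read_feature_table(gc$features,
                                  dialect = gc$features_dialect %||% "tsv",
                                  genome_id = gid,
                                  topology = gc$topology %||% "circular")
      hits <- read_domain_hits(gc$hits,
                               dialect = gc$hits_dialect %||% "tsv",
                               min_score = min_score)
      genome <- annotate(feats, hits, map, strict = FALSE)
      log_lines <- c(log_lines, sprintf(
        "genome %s: %d PEGs, %d GH, replicons [%s]", gid,
        genome$counts$n_pegs, genome$counts$n_gh,
        paste(names(genome$topology), genome$topology, collapse = "; ")))

      syn_path <- file.path(out_dir, paste0(gid, ".synteny.tsv"))
      write_tsv(synteny_table(genome, threshold = thresholds[
        which.min(abs(thresholds - 5L))]), syn_path)
      assoc_path <- file.path(out_dir, paste0(gid, ".ghtr.tsv"))
      if (genome$counts$n_gh > 0L) {
        write_tsv(gh_tr_associations(genome, coloc_threshold), assoc_path)
      }
      outputs <- c(outputs, syn_path, assoc_path)

      summ <- summarize_genome(genome, thresholds = thresholds,
                               coloc_threshold = coloc_threshold,
                               null_iterations = null_iterations,
                               seed = seed)
      if (null_iterations > 0L && genome$counts$n_gh >= 2L) {
        nd <- matched_null(genome, iterations = null_iterations,
                           seed = seed, thresholds = thresholds)
        null_path <- file.path(out_dir, paste0(gid, ".null.json"))
        jsonlite::write_json(
          list(spec = unclass(nd$spec),
               summaries = as.data.frame(nd$summaries)),
          null_path, auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, null_path)
      }
      summ
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[gid]] <- conditionMessage(res)
      log_lines <- c(log_lines,
                     sprintf("genome %s: ERROR %s", gid, errors[[gid]]))
    } else {
      summaries[[gid]] <- res
    }
  }

  cohort <- NULL
  if (length(summaries)) {
    metadata <- if (!is.null(config$metadata)) read_tsv(config$metadata)
      else NULL
    cohort <- build_cohort(summaries, metadata)
    cohort_path <- file.path(out_dir, "cohort.tsv")
    write_tsv(cohort, cohort_path)
    outputs <- c(outputs, cohort_path)
  }
  writeLines(log_lines, log_path)

  invisible(list(cohort = cohort, outputs = outputs, errors = errors,
                 status = if (length(errors)) 1L else 0L))
}
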