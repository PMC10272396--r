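#' Read an ordered gene feature table
#'
#' Reads protein-encoding gene (PEG) coordinates for one genome, either from a
#' GFF3 file (CDS features only; PEG ordinals are assigned by coordinate order
#' within each replicon) or from the package's TSV feature dialect, which
#' carries explicit ordinals. The ordinal rank of a gene within its replicon is
#' the unit of chromosomal distance used throughout the package.
#'
#' The TSV dialect is tab-separated with header columns \code{genome_id},
#' \code{replicon_id}, \code{ordinal}, \code{strand} (\code{+}/\code{-}),
#' \code{gene_id}, \code{topology} (\code{circular}/\code{linear}).
#'
#' @param path File to read.
#' @param dialect \code{"tsv"} or \code{"gff3"}.
#' @param genome_id Genome identifier used for GFF3 input (defaults to the
#'   file name without extension); ignored for TSV, which carries its own.
#' @param topology Default replicon topology for GFF3 input, which does not
#'   record one. Either a single value or a named vector by replicon.
#' @return A list with \code{genes} (data frame: \code{genome_id},
#'   \code{replicon_id}, \code{ordinal}, \code{strand}, \code{gene_id},
#'   ordered by replicon then ordinal) and \code{topology} (named character
#'   vector by replicon).
#' @export
read_feature_table <- function(path, dialect = c("tsv", "gff3"),
                               genome_id = NULL, topology = "circular") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("feature table not found: ", path)
  if (dialect == "tsv") read_feature_tsv(path) else
    read_feature_gff3(path, genome_id, topology)
}

read_feature_tsv <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  req <- c("genome_id", "replicon_id", "ordinal", "strand", "gene_id",
           "topology")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop2("feature TSV missing column(s): ",
                          paste(miss, collapse = ", "))
  df$ordinal <- as.integer(df$ordinal)
  check_strand(df$strand)
  check_topology(df$topology)
  genes <- df[order(df$replicon_id, df$ordinal),
              c("genome_id", "replicon_id", "ordinal", "strand", "gene_id")]
  rownames(genes) <- NULL
  validate_ordinals(genes)
  topo <- tapply(df$topology, df$replicon_id, function(x) {
    u <- unique(x)
    if (length(u) > 1L) stop2("conflicting topology within a replicon")
    u
  })
  list(genes = genes, topology = stats::setNames(as.character(topo),
                                                 names(topo)))
}

read_feature_gff3 <- function(path, genome_id, topology) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.gff3?$", "", basename(path))
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$type == "CDS", , drop = FALSE]
  if (!nrow(gr)) stop2("no CDS features in ", path)
  strand <- as.character(gr$strand)
  check_strand(strand)
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) {
    stop2("GFF3 CDS features need an ID (or Name) attribute")
  }
  df <- data.frame(
    genome_id = genome_id,
    replicon_id = as.character(gr$seqnames),
    start = gr$start,
    strand = strand,
    gene_id = as.character(ids),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$replicon_id, df$start), ]
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$replicon_id,
                           FUN = seq_along)
  genes <- df[, c("genome_id", "replicon_id", "ordinal", "strand", "gene_id")]
  rownames(genes) <- NULL
  reps <- unique(genes$replicon_id)
  if (length(topology) == 1L && is.null(names(topology))) {
    topo <- stats::setNames(rep(topology, length(reps)), reps)
  } else {
    topo <- stats::setNames(
      ifelse(reps %in% names(topology), topology[reps], "circular"), reps)
  }
  check_topology(topo)
  list(genes = genes, topology = topo)
}

validate_ordinals <- function(genes) {
  for (rep in unique(genes$replicon_id)) {
    o <- genes$ordinal[genes$replicon_id == rep]
    if (anyDuplicated(o)) {
      stop2("duplicate ordinal in replicon ", rep, ": ",
            paste(unique(o[duplicated(o)]), collapse = ", "))
    }
    if (!identical(sort(o), seq_len(length(o)))) {
      stop2("ordinals in replicon ", rep,
            " must be consecutive 1..n with no gaps")
    }
  }
  invisible(genes)
}

#' Read a protein-domain hit table
#'
#' Reads gene-to-Pfam-domain assignments either from the hmmscan
#' \code{--domtblout} format (whitespace-separated, \code{#} comment lines;
#' the query name is taken as the gene id, the target accession as the domain
#' accession, and the per-domain bit score as the score) or from a TSV dialect
#' with header \code{gene_id}, \code{accession}, \code{score},
#' \code{ali_from}, \code{ali_to}.
#'
#' Accession version suffixes are stripped (\code{PF00128.15} becomes
#' \code{PF00128}) and hits scoring below \code{min_score} are discarded.
#'
#' @param path File to read.
#' @param dialect \code{"tsv"} or \code{"domtblout"}.
#' @param min_score Bit-score threshold; hits below it are dropped.
#' @return Data frame with columns \code{gene_id}, \code{accession},
#'   \code{score}, \code{ali_from}, \code{ali_to} (alignment interval may be
#'   \code{NA}).
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "domtblout"),
                             min_score = 25) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("domain hit table not found: ", path)
  if (!is.numeric(min_score) || length(min_score) != 1L || is.na(min_score) ||
      min_score < 0) {
    stop2("min_score must be a single non-negative number")
  }
  hits <- if (dialect == "tsv") read_hits_tsv(path) else
    read_hits_domtblout(path)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  hits$accession <- strip_accession_version(hits$accession)
  bad <- !is.na(hits$ali_from) & !is.na(hits$ali_to) &
    hits$ali_from > hits$ali_to
  if (any(bad)) stop2("alignment interval with start > end for gene(s): ",
                      paste(unique(hits$gene_id[bad]), collapse = ", "))
  rownames(hits) <- NULL
  hits
}

read_hits_tsv <- function(path) {
  df <- tryCatch(read_tsv(path), error = function(e) {
    stop2("unparseable hit TSV (", path, "): ", conditionMessage(e))
  })
  if (nrow(df) == 0L) {
    return(data.frame(gene_id = character(), accession = character(),
                      score = numeric(), ali_from = integer(),
                      ali_to = integer(), stringsAsFactors = FALSE))
  }
  req <- c("gene_id", "accession", "score")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop2("hit TSV missing column(s): ",
                          paste(miss, collapse = ", "))
  df$score <- as.numeric(df$score)
  if (anyNA(df$score)) {
    stop2("non-numeric score in hit TSV row ",
          which(is.na(df$score))[1L])
  }
  df$ali_from <- if ("ali_from" %in% names(df))
    suppressWarnings(as.integer(df$ali_from)) else NA_integer_
  df$ali_to <- if ("ali_to" %in% names(df))
    suppressWarnings(as.integer(df$ali_to)) else NA_integer_
  df[, c("gene_id", "accession", "score", "ali_from", "ali_to")]
}

# hmmscan domtblout: fixed whitespace-separated columns; the fields used are
# target accession (2), query name (4), per-domain bit score (14) and the
# alignment coordinates (18, 19).
read_hits_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(gene_id = character(), accession = character(),
                      score = numeric(), ali_from = integer(),
                      ali_to = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(f) < 19L) {
      stop2("unparseable domtblout row ", i, " in ", path,
            " (", length(f), " fields, need >= 19)")
    }
    score <- suppressWarnings(as.numeric(f[14]))
    if (is.na(score)) stop2("non-numeric score in domtblout row ", i)
    data.frame(gene_id = f[4], accession = f[2], score = score,
               ali_from = suppressWarnings(as.integer(f[18])),
               ali_to = suppressWarnings(as.integer(f[19])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate a genome's genes with GH and transporter classes
#'
#' Combines an ordered gene table, a domain-hit table and a family map into an
#' \code{annotated_genome}. A gene is a GH gene if at least one of its domain
#' hits maps to the GH class; its transporter classes are the set of
#' \code{TR_*} classes among its hits. A gene carrying both a GH and a
#' transporter domain keeps both flags.
#'
#' @param features Output of \code{\link{read_feature_table}} (or a list with
#'   the same \code{genes}/\code{topology} shape).
#' @param hits Domain-hit data frame from \code{\link{read_domain_hits}}.
#' @param map A \code{family_map}; defaults to the built-in one.
#' @param strict If \code{TRUE}, a hit whose \code{gene_id} does not occur in
#'   the gene table is an error; if \code{FALSE} such hits are ignored.
#' @return An \code{annotated_genome}: list with \code{genome_id},
#'   \code{genes} (gene table with \code{is_gh}, \code{gh_families},
#'   \code{tr_classes} columns), \code{topology}, and cached \code{counts}.
#' @export
#' @examples
#' fm <- default_family_map()
#' feats <- list(
#'   genes = data.frame(genome_id = "g", replicon_id = "chr", ordinal = 1:3,
#'                      strand = c("+", "+", "-"),
#'                      gene_id = c("a", "b", "c")),
#'   topology = c(chr = "circular"))
#' hits <- data.frame(gene_id = "b", accession = "PF00128", score = 60,
#'                    ali_from = NA, ali_to = NA)
#' g <- annotate(feats, hits, fm)
#' g$counts$n_gh
annotate <- function(features, hits, map = default_family_map(),
                     strict = TRUE) {
  genes <- features$genes
  validate_ordinals(genes)
  check_strand(genes$strand)
  topology <- check_topology(features$topology)
  if (!all(unique(genes$replicon_id) %in% names(topology))) {
    stop2("every replicon needs a topology entry")
  }
  if (anyDuplicated(genes$gene_id)) stop2("duplicate gene_id in gene table")

  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(gene_id = character(), accession = character(),
                       score = numeric(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(hits$gene_id), genes$gene_id)
  if (length(unknown)) {
    if (strict) stop2("domain hit(s) reference unknown gene_id: ",
                      paste(utils::head(unknown, 5L), collapse = ", "))
    hits <- hits[hits$gene_id %in% genes$gene_id, , drop = FALSE]
  }

  mapped <- map_accessions(hits$accession, map)
  mapped$gene_id <- hits$gene_id

  gh_fams <- tr_cls <- rep("", nrow(genes))
  if (nrow(mapped)) {
    gh <- mapped[mapped$functional_class == "GH", , drop = FALSE]
    fam_by_gene <- tapply(gh$family_label, gh$gene_id, function(x)
      paste(sort(unique(x)), collapse = ";"))
    idx <- match(genes$gene_id, names(fam_by_gene))
    gh_fams <- ifelse(is.na(idx), "", as.character(fam_by_gene)[idx])

    tr <- mapped[mapped$functional_class %in% TR_CLASSES, , drop = FALSE]
    cls_by_gene <- tapply(tr$functional_class, tr$gene_id, function(x)
      paste(sort(unique(x)), collapse = ";"))
    idx <- match(genes$gene_id, names(cls_by_gene))
    tr_cls <- ifelse(is.na(idx), "", as.character(cls_by_gene)[idx])
  }
  genes$is_gh <- nzchar(gh_fams)
  genes$gh_families <- gh_fams
  genes$tr_classes <- tr_cls

  new_annotated_genome(genes, topology)
}

new_annotated_genome <- function(genes, topology) {
  genes <- genes[order(genes$replicon_id, genes$ordinal), , drop = FALSE]
  rownames(genes) <- NULL
  n_tr <- vapply(TR_CLASSES, function(cl)
    sum(grepl(cl, genes$tr_classes, fixed = TRUE)), integer(1))
  g <- list(
    genome_id = unique(genes$genome_id)[1L],
    genes = genes,
    topology = topology,
    counts = list(n_pegs = nrow(genes), n_gh = sum(genes$is_gh), n_tr = n_tr)
  )
  class(g) <- "annotated_genome"
  g
}

# Ordinals of genes in a class on one replicon. gene_class is "GH" or one of
# the TR_* labels.
class_ordinals <- function(genome, replicon_id, gene_class = "GH") {
  g <- genome$genes[genome$genes$replicon_id == replicon_id, , drop = FALSE]
  sel <- class_members(g, gene_class)
  g$ordinal[sel]
}

class_members <- function(genes, gene_class) {
  if (gene_class == "GH") genes$is_gh
  else if (gene_class %in% TR_CLASSES)
    grepl(gene_class, genes$tr_classes, fixed = TRUE)
  else stop2("unknown gene class: ", gene_class)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated genome:", x$genome_id, "\n")
  cat("  replicons:", length(x$topology), "(",
      paste(names(x$topology), x$topology, collapse = "; "), ")\n")
  cat("  PEGs:", x$counts$n_pegs, "  GH genes:", x$counts$n_gh,
      sprintf("(%s%%)", format_pct1(100 * x$counts$n_gh /
                                      max(1L, x$counts$n_pegs))), "\n")
  cat("  transporters:",
      paste(sprintf("%s=%d", sub("^TR_", "", names(x$counts$n_tr)),
                    x$counts$n_tr), collapse = "  "), "\n")
  invisible(x)
}

#' Write a genome back to the feature-TSV and hit-TSV dialects
#'
#' Emits files that, re-read with \code{\link{read_feature_table}},
#' \code{\link{read_domain_hits}} and \code{\link{annotate}}, reproduce the
#' in-memory genome exactly. Each annotated gene is given one representative
#' accession per GH family / transporter class, looked up in \code{map}.
#'
#' @param genome An \code{annotated_genome}.
#' @param dir Output directory (created if needed).
#' @param map Family map used to pick representative accessions.
#' @return Named character vector with the \code{features} and \code{hits}
#'   paths.
#' @export
write_genome_files <- function(genome, dir, map = default_family_map()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- genome$genes
  feat <- data.frame(genome_id = g$genome_id, replicon_id = g$replicon_id,
                     ordinal = g$ordinal, strand = g$strand,
                     gene_id = g$gene_id,
                     topology = genome$topology[g$replicon_id],
                     stringsAsFactors = FALSE)
  fpath <- file.path(dir, paste0(genome$genome_id, ".features.tsv"))
  write_tsv(feat, fpath)

  rows <- list()
  for (i in seq_len(nrow(g))) {
    fams <- if (nzchar(g$gh_families[i]))
      strsplit(g$gh_families[i], ";", fixed = TRUE)[[1]] else character()
    for (fam in fams) {
      acc <- map$accession[match(fam, map$family_label)]
      if (is.na(acc)) stop2("no accession in map for family ", fam)
      rows[[length(rows) + 1L]] <- c(g$gene_id[i], acc)
    }
    cls <- if (nzchar(g$tr_classes[i]))
      strsplit(g$tr_classes[i], ";", fixed = TRUE)[[1]] else character()
    for (cl in cls) {
      acc <- map$accession[match(cl, map$functional_class)]
      if (is.na(acc)) stop2("no accession in map for class ", cl)
      rows[[length(rows) + 1L]] <- c(g$gene_id[i], acc)
    }
  }
  hits <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(gene_id = m[, 1], accession = m[, 2], score = 100,
               ali_from = NA_integer_, ali_to = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), accession = character(),
               score = numeric(), ali_from = integer(), ali_to = integer(),
               stringsAsFactors = FALSE)
  }
  hpath <- file.path(dir, paste0(genome$genome_id, ".hits.tsv"))
  write_tsv(hits, hpath)
  c(features = fpath, hits = hpath)
}
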