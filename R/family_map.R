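#' Built-in family map: Pfam accession to GH family / transporter class
#'
#' The map assigns each (version-stripped) Pfam accession a family label and a
#' functional class used throughout the pipeline: \code{GH} for glycoside
#' hydrolase domains, \code{TR_MFS}/\code{TR_ABC}/\code{TR_PTS}/\code{TR_SUS}
#' for the four sugar-transporter classes (major facilitator superfamily,
#' ATP-binding cassette, phosphotransferase system, and the
#' TonB-dependent/SusC starch-utilization-system transporters of
#' Bacteroidetes), and \code{OTHER} for everything else.
#'
#' The GH entries cover the ten most common GH families among bacterial
#' genomes (amylases, beta-glucosidases, cellulases, xylanases, chitinases).
#' The SUS entries are the TonB-dependent transporter core: the outer-membrane
#' barrel (PF00593), the periplasmic plug (PF07715), and the optional
#' N-terminal extension (PF13715) and secretin/TonB short N-terminal domain
#' (PF07660). The MFS, ABC and PTS accession lists are provisional defaults
#' built from the canonical Pfam families for each transporter class; they are
#' meant to be replaced or extended via \code{\link{load_family_map}} when a
#' curated list is available.
#'
#' @return A \code{family_map}: a data frame with columns \code{accession},
#'   \code{family_label} and \code{functional_class}.
#' @seealso \code{\link{load_family_map}}
#' @export
#' @examples
#' fm <- default_family_map()
#' fm[fm$accession == "PF00128", ]
default_family_map <- function() {
  entries <- rbind(
    # glycoside hydrolase domains
    c("PF00128", "GH13", "GH"),   # alpha-amylase
    c("PF00232", "GH1",  "GH"),   # beta-glucosidase
    c("PF00933", "GH3",  "GH"),   # beta-glucosidase
    c("PF00150", "GH5",  "GH"),   # cellulase
    c("PF01270", "GH8",  "GH"),   # cellulase
    c("PF01341", "GH6",  "GH"),   # cellobiohydrolase
    c("PF00331", "GH10", "GH"),   # xylanase
    c("PF00457", "GH11", "GH"),   # xylanase
    c("PF00704", "GH18", "GH"),   # chitinase
    c("PF00182", "GH19", "GH"),   # chitinase
    # SUS / TonB-dependent transporter core
    c("PF00593", "TBDT_barrel", "TR_SUS"),
    c("PF07715", "TBDT_plug",   "TR_SUS"),
    c("PF13715", "TBDT_NTE",    "TR_SUS"),
    c("PF07660", "TBDT_STN",    "TR_SUS"),
    # provisional MFS / ABC / PTS defaults (editable)
    c("PF07690", "MFS_1",       "TR_MFS"),
    c("PF00083", "Sugar_tr",    "TR_MFS"),
    c("PF00005", "ABC_tran",    "TR_ABC"),
    c("PF00528", "BPD_transp_1", "TR_ABC"),
    c("PF01547", "SBP_bac_1",   "TR_ABC"),
    c("PF00358", "PTS_EIIA_1",  "TR_PTS"),
    c("PF00367", "PTS_EIIB",    "TR_PTS"),
    c("PF02378", "PTS_EIIC",    "TR_PTS")
  )
  fm <- data.frame(accession = entries[, 1], family_label = entries[, 2],
                   functional_class = entries[, 3],
                   stringsAsFactors = FALSE)
  class(fm) <- c("family_map", "data.frame")
  fm
}

validate_family_map <- function(fm) {
  req <- c("accession", "family_label", "functional_class")
  miss <- setdiff(req, names(fm))
  if (length(miss)) stop2("family map missing column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(fm$accession)) {
    dup <- unique(fm$accession[duplicated(fm$accession)])
    stop2("duplicate accession in family map: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(fm$functional_class), FUNCTIONAL_CLASSES)
  if (length(bad)) {
    stop2("invalid functional_class value(s): ", paste(bad, collapse = ", "),
          " (must be one of ", paste(FUNCTIONAL_CLASSES, collapse = ", "), ")")
  }
  if (any(!nzchar(fm$family_label) | is.na(fm$family_label))) {
    stop2("every family map entry needs a nonempty family_label")
  }
  fm
}

#' Load a family map from a YAML or TSV file
#'
#' Reads a user-supplied accession map and (by default) merges it over the
#' built-in defaults, so a file entry for an accession overrides the default
#' classification of that accession. Accession version suffixes are stripped
#' before the map is used.
#'
#' The TSV dialect has a header with columns \code{accession},
#' \code{family_label}, \code{functional_class}. The YAML dialect is a list of
#' mappings with those same keys, e.g.
#' \preformatted{
#' - accession: PF00128
#'   family_label: GH13
#'   functional_class: GH
#' }
#'
#' @param path Path to a \code{.yml}/\code{.yaml} or \code{.tsv} file, or
#'   \code{NULL} to return the defaults unchanged.
#' @param include_defaults Merge over \code{\link{default_family_map}}?
#' @return A \code{family_map} data frame.
#' @export
load_family_map <- function(path = NULL, include_defaults = TRUE) {
  base <- if (include_defaults) default_family_map() else
    default_family_map()[0, ]
  if (is.null(path)) return(validate_family_map(base))
  if (!file.exists(path)) stop2("family map file not found: ", path)

  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) {
    raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop2("malformed family map YAML (", path, "): ", conditionMessage(e))
    })
    if (!length(raw)) {
      data.frame(accession = character(), family_label = character(),
                 functional_class = character(), stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_along(raw), function(i) {
        e <- raw[[i]]
        if (!all(c("accession", "family_label", "functional_class") %in%
                 names(e))) {
          stop2("malformed family map entry ", i, " in ", path,
                ": needs accession, family_label, functional_class")
        }
        data.frame(accession = as.character(e$accession),
                   family_label = as.character(e$family_label),
                   functional_class = as.character(e$functional_class),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  } else {
    read_tsv(path)
  }
  user$accession <- strip_accession_version(user$accession)
  if (anyDuplicated(user$accession)) {
    stop2("duplicate accession in ", path, ": ",
          paste(unique(user$accession[duplicated(user$accession)]),
                collapse = ", "))
  }
  validate_family_map(user)

  merged <- rbind(base[!base$accession %in% user$accession, , drop = FALSE],
                  user)
  merged <- merged[order(merged$accession), , drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("family_map", "data.frame")
  validate_family_map(merged)
}

# Look up (family_label, functional_class) for version-stripped accessions;
# unmapped accessions classify as OTHER.
map_accessions <- function(accessions, map) {
  idx <- match(strip_accession_version(accessions), map$accession)
  data.frame(
    accession = strip_accession_version(accessions),
    family_label = ifelse(is.na(idx), NA_character_, map$family_label[idx]),
    functional_class = ifelse(is.na(idx), "OTHER", map$functional_class[idx]),
    stringsAsFactors = FALSE
  )
}
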