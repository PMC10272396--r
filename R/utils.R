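# Internal helpers shared across modules.

TR_CLASSES <- c("TR_MFS", "TR_ABC", "TR_PTS", "TR_SUS")
FUNCTIONAL_CLASSES <- c("GH", TR_CLASSES, "OTHER")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

check_topology <- function(topology) {
  if (!all(topology %in% c("circular", "linear"))) {
    stop2("topology must be 'circular' or 'linear'")
  }
  topology
}

check_strand <- function(strand) {
  bad <- setdiff(unique(strand), c("+", "-"))
  if (length(bad)) {
    stop2("unknown strand symbol: ", paste(sQuote(bad), collapse = ", "),
          " (expected '+' or '-')")
  }
  strand
}

# Strip Pfam-style version suffixes: "PF00128.15" -> "PF00128".
strip_accession_version <- function(accession) {
  sub("\\.[0-9]+$", "", accession)
}

# Ordinal distance between two positions on a replicon of n PEGs.
ordinal_distance <- function(a, b, n, topology) {
  d <- abs(a - b)
  if (topology == "circular") pmin(d, n - d) else d
}

# Truncate a percentage to one decimal (never rounds up), as used in reports.
format_pct1 <- function(x) {
  sprintf("%.1f", trunc(x * 10) / 10)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", ...)
}
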