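# Shared fixtures: hand-built genomes and brute-force oracles used to check
# the synteny machinery by exhaustive enumeration.

# Build an annotated genome through the annotation path itself: GH genes get
# a GH13 hit, transporter genes their class's representative accession.
mk_genome <- function(n, gh = integer(), tr = list(), strands = NULL,
                      topo = "circular", genome_id = "t", replicon_id = "chr") {
  s <- if (is.null(strands)) rep("+", n) else strands
  genes <- data.frame(genome_id = genome_id, replicon_id = replicon_id,
                      ordinal = seq_len(n), strand = s,
                      gene_id = paste0("g", seq_len(n)),
                      stringsAsFactors = FALSE)
  acc_for <- c(TR_MFS = "PF07690", TR_ABC = "PF00005", TR_PTS = "PF00358",
               TR_SUS = "PF00593")
  hit_rows <- list()
  for (o in gh) hit_rows[[length(hit_rows) + 1L]] <- c(paste0("g", o), "PF00128")
  for (cl in names(tr)) for (o in tr[[cl]]) {
    hit_rows[[length(hit_rows) + 1L]] <- c(paste0("g", o), acc_for[[cl]])
  }
  hits <- if (length(hit_rows)) {
    m <- do.call(rbind, hit_rows)
    data.frame(gene_id = m[, 1], accession = m[, 2], score = 60,
               ali_from = NA_integer_, ali_to = NA_integer_,
               stringsAsFactors = FALSE)
  } else NULL
  annotate(list(genes = genes,
                topology = stats::setNames(topo, replicon_id)), hits)
}

# Two-replicon genome for cross-replicon independence checks.
mk_genome2 <- function(n1, gh1, n2, gh2, topo1 = "circular",
                       topo2 = "circular") {
  g1 <- data.frame(genome_id = "t2", replicon_id = "chr",
                   ordinal = seq_len(n1), strand = "+",
                   gene_id = paste0("a", seq_len(n1)),
                   stringsAsFactors = FALSE)
  g2 <- data.frame(genome_id = "t2", replicon_id = "pls",
                   ordinal = seq_len(n2), strand = "+",
                   gene_id = paste0("b", seq_len(n2)),
                   stringsAsFactors = FALSE)
  hits <- data.frame(
    gene_id = c(paste0("a", gh1), paste0("b", gh2)),
    accession = "PF00128", score = 60, ali_from = NA, ali_to = NA,
    stringsAsFactors = FALSE)
  annotate(list(genes = rbind(g1, g2),
                topology = c(chr = topo1, pls = topo2)), hits)
}

# Oracle: per-member SSc by scanning distances 1..n in both directions.
brute_ssc <- function(n, members, topo) {
  vapply(members, function(o) {
    others <- setdiff(members, o)
    if (!length(others)) return(NA_integer_)
    d <- if (topo == "circular") {
      pmin((o - others) %% n, (others - o) %% n)
    } else abs(o - others)
    as.integer(min(d))
  }, integer(1))
}

# Oracle: cluster partition by union-find; two members join when one arc
# between them holds no other member and spans at most `threshold` PEGs.
brute_cluster_partition <- function(n, members, topo, threshold) {
  k <- length(members)
  if (k == 0L) return(list())
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  arc_ok <- function(a, b, fwd_len) {
    if (fwd_len > threshold) return(FALSE)
    if (fwd_len == 0L) return(FALSE)
    between <- if (topo == "circular") {
      any(vapply(setdiff(members, c(a, b)), function(m)
        ((m - a) %% n) < fwd_len && ((m - a) %% n) > 0, logical(1)))
    } else {
      any(members > min(a, b) & members < max(a, b) &
            !(members %in% c(a, b)))
    }
    !between
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    a <- members[i]; b <- members[j]
    fwd <- if (topo == "circular") (b - a) %% n else
      if (b > a) b - a else Inf
    if (is.finite(fwd) && arc_ok(a, b, fwd)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  unname(lapply(split(members, roots), sort))
}

# Canonical form of a cluster result for partition comparison.
cluster_partition <- function(clusters) {
  unname(lapply(clusters$ordinals, sort))
}

setequal_partitions <- function(p1, p2) {
  f <- function(p) sort(vapply(p, function(x) paste(x, collapse = ","), ""))
  identical(f(p1), f(p2))
}
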