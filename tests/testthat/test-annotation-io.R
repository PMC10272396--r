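# Reading feature tables and domain hits, family-map semantics, annotation.

test_that("default family map classifies the canonical accessions", {
  fm <- default_family_map()
  expect_equal(fm$family_label[fm$accession == "PF00128"], "GH13")
  expect_equal(fm$functional_class[fm$accession == "PF00128"], "GH")
  expect_equal(fm$functional_class[fm$accession == "PF00593"], "TR_SUS")
  expect_equal(fm$functional_class[fm$accession == "PF07715"], "TR_SUS")
  expect_false(anyDuplicated(fm$accession) > 0)
})

test_that("family map files merge over defaults and are validated", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tfamily_label\tfunctional_class",
               "PF00128\tGH13\tOTHER",          # override
               "PF99999.3\tGHX\tGH"), tsv)      # new, versioned
  fm <- load_family_map(tsv)
  expect_equal(fm$functional_class[fm$accession == "PF00128"], "OTHER")
  expect_equal(fm$functional_class[fm$accession == "PF99999"], "GH")
  expect_true("PF00593" %in% fm$accession)      # defaults retained

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("- accession: PF11111", "  family_label: GH99",
               "  functional_class: GH"), yml)
  fm2 <- load_family_map(yml)
  expect_equal(fm2$family_label[fm2$accession == "PF11111"], "GH99")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tfamily_label\tfunctional_class",
               "PF1\tX\tGH", "PF1\tY\tGH"), bad)
  expect_error(load_family_map(bad), "duplicate accession")
  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tfamily_label\tfunctional_class",
               "PF1\tX\tNOT_A_CLASS"), bad2)
  expect_error(load_family_map(bad2), "invalid functional_class")
})

test_that("feature TSV reading validates ordinals and strands", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tordinal\tstrand\tgene_id\ttopology",
               "g\tchr\t1\t+\ta\tcircular",
               "g\tchr\t2\t+\tb\tcircular",
               "g\tchr\t3\t-\tc\tcircular"), tsv)
  ft <- read_feature_table(tsv, "tsv")
  expect_equal(ft$genes$ordinal, 1:3)
  expect_equal(ft$genes$strand, c("+", "+", "-"))
  expect_equal(unname(ft$topology["chr"]), "circular")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tordinal\tstrand\tgene_id\ttopology",
               "g\tchr\t1\t+\ta\tcircular",
               "g\tchr\t2\t+\tb\tcircular",
               "g\tchr\t2\t-\tc\tcircular"), dup)
  expect_error(read_feature_table(dup, "tsv"), "duplicate ordinal")

  gap <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tordinal\tstrand\tgene_id\ttopology",
               "g\tchr\t1\t+\ta\tcircular",
               "g\tchr\t3\t+\tb\tcircular"), gap)
  expect_error(read_feature_table(gap, "tsv"), "consecutive")

  bs <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tordinal\tstrand\tgene_id\ttopology",
               "g\tchr\t1\t?\ta\tcircular"), bs)
  expect_error(read_feature_table(bs, "tsv"), "strand")
})

test_that("GFF3 CDS features get ordinals by coordinate order", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctg1\tsrc\tCDS\t900\t1100\t.\t-\t0\tID=c3",
               "ctg1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=c1",
               "ctg1\tsrc\tgene\t100\t400\t.\t+\t.\tID=skipme",
               "ctg1\tsrc\tCDS\t500\t800\t.\t+\t0\tID=c2"), gff)
  ft <- read_feature_table(gff, "gff3", genome_id = "gX",
                           topology = "linear")
  expect_equal(ft$genes$gene_id, c("c1", "c2", "c3"))
  expect_equal(ft$genes$ordinal, 1:3)
  expect_equal(ft$genes$strand, c("+", "+", "-"))
  expect_equal(unname(ft$topology["ctg1"]), "linear")
})

test_that("domain hits: version stripping, score filter, dialects", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\taccession\tscore\tali_from\tali_to",
               "pegA\tPF00128.15\t60\t10\t200",
               "pegB\tPF00232\t10\t5\t100"), tsv)
  hits <- read_domain_hits(tsv, "tsv", min_score = 25)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$accession, "PF00128")

  expect_equal(nrow(read_domain_hits(tsv, "tsv", min_score = 5)), 2L)
  expect_error(read_domain_hits(tsv, "tsv", min_score = -1), "non-negative")

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene_id\taccession\tscore\tali_from\tali_to", empty)
  expect_equal(nrow(read_domain_hits(empty, "tsv")), 0L)

  dom <- tempfile(fileext = ".domtblout")
  writeLines(c(
    "# hmmscan domtblout",
    paste("Alpha-amylase PF00128.15 350 pegA - 512 1.2e-50 170.1 0.1 1 1",
          "3e-52 1.1e-50 168.0 0.1 5 340 20 355 15 360 0.95 desc"),
    paste("Glyco_hydro_1 PF00232.20 440 pegB - 470 2e-8 20.0 0.0 1 1",
          "5e-9 3e-8 12.0 0.0 1 400 10 420 8 430 0.90 desc")), dom)
  dh <- read_domain_hits(dom, "domtblout", min_score = 25)
  expect_equal(dh$gene_id, "pegA")
  expect_equal(dh$accession, "PF00128")
  expect_equal(dh$ali_from, 20L)
  expect_equal(dh$ali_to, 355L)

  badrow <- tempfile()
  writeLines("too few fields", badrow)
  expect_error(read_domain_hits(badrow, "domtblout"), "row 1")
})

test_that("annotation flags GH, transporter and dual genes", {
  g <- mk_genome(5, gh = 2, tr = list(TR_SUS = 4))
  expect_equal(g$counts$n_gh, 1L)
  expect_true(g$genes$is_gh[2])
  expect_equal(g$genes$gh_families[2], "GH13")
  expect_equal(g$genes$tr_classes[4], "TR_SUS")
  expect_equal(unname(g$counts$n_tr["TR_SUS"]), 1L)

  # dual GH + SUS gene keeps both flags
  genes <- data.frame(genome_id = "d", replicon_id = "chr", ordinal = 1:3,
                      strand = "+", gene_id = c("x", "y", "z"),
                      stringsAsFactors = FALSE)
  hits <- data.frame(gene_id = c("y", "y", "z"),
                     accession = c("PF00232", "PF00593", "PF07715"),
                     score = 60, ali_from = NA, ali_to = NA)
  gd <- annotate(list(genes = genes, topology = c(chr = "circular")), hits)
  expect_true(gd$genes$is_gh[2])
  expect_equal(gd$genes$tr_classes[2], "TR_SUS")
  expect_false(gd$genes$is_gh[3])
  expect_equal(gd$genes$tr_classes[3], "TR_SUS")

  # strict vs lenient unknown gene ids
  orphan <- data.frame(gene_id = "nope", accession = "PF00128", score = 60,
                       ali_from = NA, ali_to = NA)
  expect_error(annotate(list(genes = genes, topology = c(chr = "circular")),
                        orphan, strict = TRUE), "unknown gene_id")
  g0 <- annotate(list(genes = genes, topology = c(chr = "circular")),
                 orphan, strict = FALSE)
  expect_equal(g0$counts$n_gh, 0L)
})

test_that("annotation is order-independent and empty hits give n_gh = 0", {
  genes <- data.frame(genome_id = "o", replicon_id = "chr", ordinal = 1:4,
                      strand = "+", gene_id = paste0("g", 1:4),
                      stringsAsFactors = FALSE)
  hits <- data.frame(gene_id = c("g3", "g1", "g3"),
                     accession = c("PF00933", "PF00128", "PF00150"),
                     score = 60, ali_from = NA, ali_to = NA)
  feats <- list(genes = genes, topology = c(chr = "circular"))
  a1 <- annotate(feats, hits)
  a2 <- annotate(feats, hits[c(3, 1, 2), ])
  expect_identical(a1$genes, a2$genes)
  expect_equal(a1$genes$gh_families[3], "GH3;GH5")
  a0 <- annotate(feats, NULL)
  expect_equal(a0$counts$n_gh, 0L)
})

test_that("write + re-read + re-annotate round-trips a genome exactly", {
  g <- mk_genome(30, gh = c(2, 3, 7, 20), tr = list(TR_ABC = 10, TR_SUS = 25),
                 strands = rep(c("+", "-"), 15))
  dir <- tempfile(); dir.create(dir)
  paths <- write_genome_files(g, dir)
  ft <- read_feature_table(paths["features"], "tsv")
  hits <- read_domain_hits(paths["hits"], "tsv")
  g2 <- annotate(ft, hits)
  expect_identical(g$genes, g2$genes)
  expect_identical(g$topology, g2$topology)
  expect_identical(g$counts, g2$counts)
})
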