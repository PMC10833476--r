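ft_header <- paste(c("# feature", "class", "assembly", "assembly_unit",
                     "seq_type", "chromosome", "genomic_accession", "start",
                     "end", "strand", "product_accession",
                     "non-redundant_refseq", "related_accession", "name",
                     "symbol", "GeneID", "locus_tag",
                     "feature_interval_length", "product_length",
                     "attributes"), collapse = "\t")

ft_row <- function(feature, acc, start, end, strand, name, locus,
                   class = "with_protein", symbol = "", attrs = "") {
  paste(feature, class, "asm1", "Primary Assembly", "chromosome", "", acc,
        start, end, strand, "", "", "", name, symbol, "", locus,
        end - start + 1, "", attrs, sep = "\t")
}

test_that("feature tables parse by column name with gene/CDS merging and pseudo flags", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(ft_header,
               ft_row("gene", "ctg1", 100, 500, "+", "", "L001",
                      class = "protein_coding", symbol = "rplV"),
               ft_row("CDS", "ctg1", 100, 500, "+", "50S ribosomal protein L22", "L001"),
               ft_row("gene", "ctg1", 600, 900, "-", "", "L002",
                      class = "pseudogene", attrs = "pseudo"),
               ft_row("CDS", "ctg1", 600, 900, "-", "50S ribosomal protein L18", "L002",
                      attrs = "pseudo")),
             path)
  ann <- read_feature_table(path)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$genes), 2L)
  expect_identical(ann$genes$product[1], "50S ribosomal protein L22")
  expect_identical(ann$genes$symbol[1], "rplV")
  expect_false(ann$genes$pseudo[1])
  expect_true(ann$genes$pseudo[2])
  expect_identical(ann$genes$strand, c("+", "-"))
})

test_that("feature tables with coordinate or column defects raise format errors", {
  bad1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(ft_header,
               ft_row("CDS", "ctg1", 900, 500, "+", "x", "L001")), bad1)
  expect_error(read_feature_table(bad1), class = "rpc_format_error")
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(sub("\tlocus_tag", "\tsomething", ft_header),
               ft_row("CDS", "ctg1", 1, 30, "+", "x", "L1")), bad2)
  expect_error(read_feature_table(bad2), regexp = "locus_tag",
               class = "rpc_format_error")
  bad3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a feature table", bad3)
  expect_error(read_feature_table(bad3), class = "rpc_format_error")
})

test_that("GFF3 parses coordinates, flags and contig edges; malformed rows name the line", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region ctg1 1 5000",
               paste("ctg1", "src", "CDS", 11, 400, ".", "+", ".",
                     "ID=g1;locus_tag=g1;product=50S ribosomal protein L22", sep = "\t"),
               paste("ctg1", "src", "CDS", 500, 760, ".", "-", ".",
                     "ID=g2;locus_tag=g2;product=30S ribosomal protein S3;partial=true", sep = "\t"),
               paste("ctg1", "src", "CDS", 4500, 5000, ".", "+", ".",
                     "ID=g3;locus_tag=g3;product=hypothetical protein", sep = "\t")),
             path)
  ann <- read_gff3(path)
  expect_equal(ann$genes$start, c(11L, 500L, 4500L))
  expect_equal(ann$contigs$length, 5000L)
  expect_true(ann$genes$partial[2])
  expect_true(ann$genes$contig_edge[3])   # feature ends at contig length
  expect_false(any(ann$genes$contig_edge[1:2]))

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "ctg1\tsrc\tCDS\t1\t30"), bad)
  expect_error(read_gff3(bad), regexp = "line 2", class = "rpc_format_error")
})

test_that("GenBank records parse qualifiers, translations and fuzzy locations", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       ctg1              9000 bp    DNA     linear   CON 01-JAN-2026",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    "     gene            complement(201..500)",
    '                     /locus_tag="G1"',
    '                     /gene="rplV"',
    "     CDS             complement(201..500)",
    '                     /locus_tag="G1"',
    '                     /product="50S ribosomal protein L22"',
    '                     /translation="MKVAPKRPL',
    '                     WWKK"',
    "     CDS             <601..900",
    '                     /locus_tag="G2"',
    '                     /product="30S ribosomal protein S3"',
    "                     /pseudo",
    "//"), path)
  ann <- read_genbank(path)
  expect_equal(nrow(ann$genes), 2L)
  expect_identical(ann$genes$strand, c("-", "+"))
  expect_identical(ann$genes$protein_seq[1], "MKVAPKRPLWWKK")
  expect_identical(ann$genes$symbol[1], "rplV")
  expect_true(ann$genes$pseudo[2])
  expect_true(ann$genes$partial[2])      # fuzzy "<" bound
  expect_true(ann$genes$contig_edge[2])
  expect_equal(ann$contigs$length, 9000L)
  bad <- withr::local_tempfile(fileext = ".gbk")
  writeLines("no locus here", bad)
  expect_error(read_genbank(bad), class = "rpc_format_error")
})

test_that("one genome expressed in all three formats yields the same annotation", {
  ann <- test_build("thor_hsp20", 1)$annotation
  dir <- withr::local_tempdir()
  write_gff3(ann, file.path(dir, "g.gff3"))
  write_feature_table(ann, file.path(dir, "ft.txt"))
  write_genbank(ann, file.path(dir, "g.gbk"))
  a_gff <- read_gff3(file.path(dir, "g.gff3"))
  a_ft <- read_feature_table(file.path(dir, "ft.txt"), genome_id = ann$genome_id)
  a_gbk <- read_genbank(file.path(dir, "g.gbk"), genome_id = ann$genome_id)
  skip_cols <- "protein_seq"   # feature tables and GFF3 carry no sequences
  for (other in list(a_ft, a_gbk)) {
    for (cc in setdiff(names(a_gff$genes), skip_cols))
      expect_identical(unname(other$genes[[cc]]), unname(a_gff$genes[[cc]]))
    expect_identical(other$contigs, a_gff$contigs)
  }
  # GenBank additionally round-trips the protein sequences
  expect_identical(a_gbk$genes$protein_seq, ann$genes$protein_seq)
})

test_that("the internal genome JSON dump round-trips exactly", {
  ann <- test_build("bin6_split", 1)$annotation
  path <- withr::local_tempfile(fileext = ".json")
  write_genome_json(ann, path)
  back <- read_genome_json(path)
  expect_identical(back$genes, ann$genes)
  expect_identical(back$contigs, ann$contigs)
  expect_identical(back$complete, ann$complete)
})

test_that("duplicate locus tags are suffixed deterministically with a warning", {
  g <- data.frame(contig_id = "c1", start = c(1L, 400L, 800L),
                  end = c(300L, 700L, 1100L), strand = "+",
                  locus_tag = c("A", "A", "A"), stringsAsFactors = FALSE)
  expect_warning(ann <- genome_annotation("dup", g), "duplicate locus_tag")
  expect_identical(ann$genes$locus_tag, c("A", "A_2", "A_3"))
})

test_that("occurrence reports are deterministic and the JSON mirror round-trips", {
  built <- test_build("bin6_split", 1)
  occs <- map_genome(built$annotation, "archaeal")
  dir <- withr::local_tempdir()
  t1 <- file.path(dir, "r1.tsv"); t2 <- file.path(dir, "r2.tsv")
  write_occurrence_report(occs, t1, "tsv")
  write_occurrence_report(occs, t2, "tsv")
  expect_identical(readLines(t1), readLines(t2))
  tab <- utils::read.delim(t1, check.names = FALSE)
  expect_setequal(tab$model, vapply(occs, function(o) o$model$name, ""))
  core_row <- tab[tab$model == "S10-spc-core", ]
  expect_equal(core_row$n_segments, 3L)
  absent_rows <- tab[tab$status == "absent", ]
  expect_true(all(absent_rows$segment == "" | is.na(absent_rows$segment)))
  jp <- file.path(dir, "r.json")
  write_occurrence_report(occs, jp, "json")
  back <- read_occurrence_json(jp)
  expect_equal(lapply(back, unclass), lapply(occs, unclass))
})
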