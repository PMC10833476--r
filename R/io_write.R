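gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("&", "%26", x, fixed = TRUE)
}

#' Write a genome annotation to GFF3
#'
#' Deterministic writer used for synthetic genome bundles and report
#' round-trips: `##sequence-region` pragmas carry contig lengths, and
#' `product`, `pseudo` and `partial` attributes carry the record flags.
#'
#' @param ann A [genome_annotation].
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", ann$contigs$contig_id, ann$contigs$length))
  g <- ann$genes
  attrs <- sprintf("ID=%s;locus_tag=%s", g$locus_tag, g$locus_tag)
  has_sym <- nzchar(g$symbol)
  attrs[has_sym] <- paste0(attrs[has_sym], ";gene=", gff3_escape(g$symbol[has_sym]))
  has_prod <- nzchar(g$product)
  attrs[has_prod] <- paste0(attrs[has_prod], ";product=", gff3_escape(g$product[has_prod]))
  attrs[g$pseudo] <- paste0(attrs[g$pseudo], ";pseudo=true")
  attrs[g$partial] <- paste0(attrs[g$partial], ";partial=true")
  rows <- sprintf("%s\trpclustermap\t%s\t%d\t%d\t.\t%s\t.\t%s",
                  g$contig_id, g$feature, g$start, g$end, g$strand, attrs)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a genome annotation as an NCBI-style assembly feature table
#'
#' Emits the tab-delimited dialect read back by [read_feature_table()]:
#' a `gene` row and a feature row (CDS/tRNA/...) per locus, flags in the
#' `attributes` column.
#'
#' @inheritParams write_gff3
#' @export
write_feature_table <- function(ann, path) {
  cols <- c("# feature", "class", "assembly", "assembly_unit", "seq_type",
            "chromosome", "genomic_accession", "start", "end", "strand",
            "product_accession", "non-redundant_refseq", "related_accession",
            "name", "symbol", "GeneID", "locus_tag", "feature_interval_length",
            "product_length", "attributes")
  g <- ann$genes
  att <- ifelse(g$pseudo, "pseudo", "")
  att <- ifelse(g$partial, ifelse(nzchar(att), paste0(att, ";partial"), "partial"), att)
  mk <- function(feature, class, name) {
    paste(feature, class, ann$genome_id, "Primary Assembly", "chromosome", "",
          g$contig_id, g$start, g$end, g$strand, "", "", "",
          name, g$symbol, "", g$locus_tag, g$end - g$start + 1L, "", att,
          sep = "\t")
  }
  gene_rows <- mk("gene", ifelse(g$pseudo, "pseudogene", "protein_coding"), "")
  feat_rows <- mk(g$feature, "with_protein", g$product)
  inter <- as.vector(rbind(gene_rows, feat_rows))
  writeLines(c(paste(cols, collapse = "\t"), inter), path)
  invisible(path)
}

wrap_qualifier <- function(text, width = 58L) {
  n <- nchar(text)
  starts <- seq(1L, n, by = width)
  substring(text, starts, pmin(starts + width - 1L, n))
}

#' Write a genome annotation as a GenBank flat file
#'
#' One record per contig. Pseudo records get a `/pseudo` qualifier,
#' protein sequences a `/translation`, and records flagged partial at a
#' contig edge get fuzzy location bounds.
#'
#' @inheritParams write_gff3
#' @export
write_genbank <- function(ann, path) {
  out <- character()
  for (ci in seq_len(nrow(ann$contigs))) {
    cid <- ann$contigs$contig_id[ci]
    clen <- ann$contigs$length[ci]
    out <- c(out, sprintf("LOCUS       %-17s %d bp    DNA     linear   CON 01-JAN-2026",
                          cid, clen),
             sprintf("DEFINITION  %s synthetic annotation.", ann$genome_id),
             sprintf("ACCESSION   %s", cid),
             "FEATURES             Location/Qualifiers")
    g <- ann$genes[ann$genes$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      lo <- if (g$partial[i]) sprintf("<%d..%d", g$start[i], g$end[i])
            else sprintf("%d..%d", g$start[i], g$end[i])
      if (g$strand[i] == "-") lo <- sprintf("complement(%s)", lo)
      key <- sprintf("     %-16s%s", g$feature[i], lo)
      quals <- sprintf('                     /locus_tag="%s"', g$locus_tag[i])
      if (nzchar(g$symbol[i]))
        quals <- c(quals, sprintf('                     /gene="%s"', g$symbol[i]))
      if (nzchar(g$product[i]))
        quals <- c(quals, sprintf('                     /product="%s"', g$product[i]))
      if (g$pseudo[i]) quals <- c(quals, "                     /pseudo")
      if (!is.na(g$protein_seq[i])) {
        tr <- wrap_qualifier(paste0('/translation="', g$protein_seq[i], '"'))
        quals <- c(quals, paste0("                     ", tr))
      }
      out <- c(out, key, quals)
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write or attach per-locus protein sequences
#'
#' `write_protein_fasta` dumps the protein sequences carried by an
#' annotation (FASTA headers are locus tags); `attach_proteins` reads such
#' a file back and fills the `protein_seq` column by locus tag.
#'
#' @param ann A [genome_annotation].
#' @param path FASTA path.
#' @return `attach_proteins` returns the updated annotation.
#' @export
write_protein_fasta <- function(ann, path) {
  g <- ann$genes[!is.na(ann$genes$protein_seq), , drop = FALSE]
  seqs <- Biostrings::AAStringSet(g$protein_seq)
  names(seqs) <- g$locus_tag
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
attach_proteins <- function(ann, path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  hit <- match(ann$genes$locus_tag, ids)
  ann$genes$protein_seq[!is.na(hit)] <- as.character(seqs)[hit[!is.na(hit)]]
  ann
}
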