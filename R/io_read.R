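#' Read an NCBI assembly feature table
#'
#' Parses the tab-delimited `*_feature_table.txt` dialect. Columns are
#' located by name, never by position; the header row starts with
#' `# feature`. One gene record is produced per CDS row (and per
#' pseudogene-only row); `gene` rows without a CDS are merged into their
#' locus by `locus_tag`, contributing symbol and pseudo/partial flags.
#'
#' @param path Path to the feature table.
#' @param genome_id Genome identifier; defaults to the `assembly` column
#'   when present, else the file name.
#' @param keep_noncoding Keep tRNA/rRNA/ncRNA rows as (non-coding) gene
#'   order positions. Default `TRUE`.
#' @return A [genome_annotation].
#' @export
read_feature_table <- function(path, genome_id = NULL, keep_noncoding = TRUE) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*feature", first))
    rpc_format_error("not a feature table: header must start with '# feature'")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  names(tab)[1] <- sub("^#\\s*", "", names(tab)[1])
  need <- c("feature", "genomic_accession", "start", "end", "strand", "locus_tag")
  for (col in need)
    if (is.null(tab[[col]]))
      rpc_format_error(paste0("feature table lacks mandatory column '", col, "'"))
  col_or <- function(nm, default = "") {
    if (is.null(tab[[nm]])) return(rep(default, nrow(tab)))
    v <- as.character(tab[[nm]])
    v[is.na(v)] <- default
    v
  }
  attrs <- col_or("attributes")
  cls <- col_or("class")
  rows <- data.frame(
    feature = as.character(tab$feature),
    contig_id = as.character(tab$genomic_accession),
    start = suppressWarnings(as.integer(tab$start)),
    end = suppressWarnings(as.integer(tab$end)),
    strand = as.character(tab$strand),
    locus_tag = as.character(tab$locus_tag),
    symbol = col_or("symbol"),
    product = col_or("name"),
    pseudo = grepl("pseudo", attrs, ignore.case = TRUE) | cls == "pseudogene",
    partial = grepl("partial", attrs, ignore.case = TRUE),
    stringsAsFactors = FALSE)
  keep_types <- c("CDS", if (keep_noncoding) c("tRNA", "rRNA", "ncRNA", "misc_RNA"))
  recs <- lapply(split(rows, rows$locus_tag), function(lr) {
    prim <- lr[lr$feature %in% keep_types, , drop = FALSE]
    if (nrow(prim) == 0L) {
      if (!keep_noncoding && any(!lr$feature %in% c("gene", "CDS"))) return(NULL)
      prim <- lr[lr$feature == "gene", , drop = FALSE]   # pseudogene-only locus
      if (nrow(prim) == 0L) return(NULL)
      prim$feature <- "CDS"
    }
    prim <- prim[1L, , drop = FALSE]
    sym <- c(lr$symbol[nzchar(lr$symbol)], "")[1L]
    prod <- c(prim$product[nzchar(prim$product)], lr$product[nzchar(lr$product)], "")[1L]
    prim$symbol <- sym
    prim$product <- prod
    prim$pseudo <- any(lr$pseudo)
    prim$partial <- any(lr$partial)
    prim
  })
  genes <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(genes)) genes <- rows[0, ]
  gid <- genome_id %||% {
    asm <- col_or("assembly")[1]
    if (nzchar(asm %||% "")) asm else sub("\\.[^.]*$", "", basename(path))
  }
  genome_annotation(gid, genes)
}

#' Read a GFF3 annotation
#'
#' Uses 1-based inclusive coordinates as native to GFF3. CDS rows sharing
#' an `ID`/`locus_tag` (multi-interval joined CDS) collapse to their outer
#' span. Contig lengths are taken from `##sequence-region` pragmas when
#' present, otherwise inferred from the last feature. Recognized
#' attributes: `locus_tag`, `ID`, `gene` (symbol), `product`, `pseudo`,
#' `partial`.
#'
#' @inheritParams read_feature_table
#' @return A [genome_annotation].
#' @export
read_gff3 <- function(path, genome_id = NULL, keep_noncoding = TRUE) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    rpc_format_error(paste0("malformed GFF3: line ", bad, " has ",
                            nfield[which(nfield != 9L)[1L]], " columns, expected 9"))
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  keep_types <- c("CDS", if (keep_noncoding) c("tRNA", "rRNA", "ncRNA", "misc_RNA"))
  g <- g[g$type %in% keep_types, , drop = FALSE]
  att <- function(nm, default = "") {
    if (is.null(g[[nm]])) return(rep(default, nrow(g)))
    v <- as.character(g[[nm]])
    v[is.na(v)] <- default
    v
  }
  truthy <- function(v) {
    if (is.null(v)) return(rep(FALSE, nrow(g)))
    !is.na(v) & tolower(as.character(v)) %in% c("true", "1", "yes")
  }
  lt <- att("locus_tag")
  id <- att("ID")
  key <- ifelse(nzchar(lt), lt, ifelse(nzchar(id), id, as.character(seq_len(nrow(g)))))
  rows <- data.frame(
    feature = as.character(g$type),
    contig_id = as.character(g$seqid),
    start = as.integer(g$start), end = as.integer(g$end),
    strand = as.character(g$strand),
    locus_tag = key,
    symbol = att("gene"),
    product = att("product"),
    pseudo = truthy(g$pseudo), partial = truthy(g$partial),
    stringsAsFactors = FALSE)
  # collapse multi-interval (joined) CDS to the outer span
  recs <- lapply(split(rows, rows$locus_tag), function(lr) {
    out <- lr[1L, , drop = FALSE]
    out$start <- min(lr$start); out$end <- max(lr$end)
    out$pseudo <- any(lr$pseudo); out$partial <- any(lr$partial)
    out
  })
  genes <- do.call(rbind, recs)
  if (is.null(genes)) genes <- rows[0, ]
  contigs <- NULL
  pragmas <- grep("^##sequence-region", lines, value = TRUE)
  if (length(pragmas)) {
    parts <- strsplit(trimws(pragmas), "\\s+")
    contigs <- data.frame(
      contig_id = vapply(parts, `[`, "", 2L),
      length = as.integer(vapply(parts, `[`, "", 4L)),
      stringsAsFactors = FALSE)
    contigs <- contigs[contigs$contig_id %in% c(genes$contig_id, contigs$contig_id), , drop = FALSE]
  }
  gid <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  genome_annotation(gid, genes, contigs = contigs)
}
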