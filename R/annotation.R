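#' Construct a genome annotation object
#'
#' The in-memory representation shared by all readers: a table of gene
#' records with 1-based inclusive coordinates (start <= end always; the
#' strand column carries orientation), grouped into contigs. Within a
#' contig genes are kept sorted by start, so the 0-based positional index
#' ("gene order index") is derivable and stable.
#'
#' @param genome_id Genome identifier.
#' @param genes Data frame with columns `contig_id`, `start`, `end`,
#'   `strand` and `locus_tag`; optional columns `symbol`, `product`,
#'   `pseudo`, `partial`, `contig_edge`, `protein_seq`, `feature` are
#'   filled with defaults.
#' @param contigs Data frame with `contig_id` and `length`; if `NULL`,
#'   contigs and their lengths are inferred from the gene spans.
#' @return Object of class `genome_annotation` with elements `genome_id`,
#'   `contigs`, `genes` and `complete` (single-contig assembly).
#' @export
genome_annotation <- function(genome_id, genes, contigs = NULL) {
  defaults <- list(symbol = "", product = "", pseudo = FALSE, partial = FALSE,
                   contig_edge = FALSE, protein_seq = NA_character_,
                   feature = "CDS")
  need <- c("contig_id", "start", "end", "strand", "locus_tag")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    rpc_format_error(paste0("gene table lacks column(s): ", paste(miss, collapse = ", ")))
  for (nm in names(defaults))
    if (is.null(genes[[nm]])) genes[[nm]] <- defaults[[nm]]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (any(is.na(genes$start) | is.na(genes$end)))
      rpc_format_error("non-numeric gene coordinates")
    if (any(genes$start < 1L))
      rpc_format_error("gene coordinates must be 1-based (start >= 1)")
    if (any(genes$start > genes$end))
      rpc_format_error("gene with start > end; strand must carry orientation")
    if (!all(genes$strand %in% c("+", "-")))
      rpc_format_error("strand must be '+' or '-'")
  }
  if (is.null(contigs)) {
    ids <- unique(genes$contig_id)
    contigs <- data.frame(contig_id = ids,
                          length = vapply(ids, function(cid)
                            max(genes$end[genes$contig_id == cid]), 1L),
                          stringsAsFactors = FALSE)
  }
  contigs$length <- as.integer(contigs$length)
  if (nrow(contigs) < 1L) rpc_format_error("annotation must have at least one contig")
  ord <- order(match(genes$contig_id, contigs$contig_id), genes$start, genes$end)
  genes <- genes[ord, , drop = FALSE]
  if (anyDuplicated(genes$locus_tag)) {
    dup <- duplicated(genes$locus_tag)
    counts <- stats::ave(seq_len(nrow(genes)), genes$locus_tag, FUN = seq_along)
    warning("duplicate locus_tag(s) ",
            paste(unique(genes$locus_tag[dup]), collapse = ", "),
            "; suffixed deterministically", call. = FALSE)
    genes$locus_tag[counts > 1L] <-
      paste0(genes$locus_tag[counts > 1L], "_", counts[counts > 1L])
  }
  rownames(contigs) <- NULL
  canon_cols <- c("contig_id", "start", "end", "strand", "locus_tag", "symbol",
                  "product", "pseudo", "partial", "contig_edge", "protein_seq",
                  "feature")
  genes <- genes[, c(canon_cols, setdiff(names(genes), canon_cols)), drop = FALSE]
  clen <- contigs$length[match(genes$contig_id, contigs$contig_id)]
  genes$contig_edge <- genes$contig_edge | genes$start == 1L | genes$end == clen
  rownames(genes) <- NULL
  out <- list(genome_id = genome_id, contigs = contigs, genes = genes,
              complete = nrow(contigs) == 1L)
  class(out) <- "genome_annotation"
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>", x$genome_id, "-", nrow(x$genes), "genes on",
      nrow(x$contigs), if (x$complete) "contig (complete)\n" else "contigs\n")
  invisible(x)
}

# 0-based positional index of every gene within its contig
gene_order_index <- function(ann) {
  stats::ave(seq_len(nrow(ann$genes)), ann$genes$contig_id, FUN = seq_along) - 1L
}

#' Serialize / restore a genome annotation as JSON
#'
#' The internal dump format; `read_genome_json(write_genome_json(x))` is
#' the identity.
#'
#' @param ann A `genome_annotation`.
#' @param path Output (input) file path.
#' @return `read_genome_json` returns the `genome_annotation`.
#' @export
write_genome_json <- function(ann, path) {
  obj <- list(genome_id = ann$genome_id, complete = ann$complete,
              contigs = ann$contigs, genes = ann$genes)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- as.data.frame(obj$genes, stringsAsFactors = FALSE)
  if (is.null(genes$protein_seq)) genes$protein_seq <- NA_character_
  genes$protein_seq <- as.character(genes$protein_seq)
  genome_annotation(obj$genome_id, genes,
                    contigs = as.data.frame(obj$contigs, stringsAsFactors = FALSE))
}
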