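#' Read a GenBank flat file
#'
#' Minimal parser for annotated GenBank records: one contig per record
#' (separated by `//`), CDS and RNA features with their qualifiers. A
#' `/pseudo` qualifier sets the pseudo flag, `/translation` is captured as
#' the protein sequence, and fuzzy location bounds (`<` / `>`) mark the
#' record partial and at a contig edge. Joined (multi-interval) locations
#' collapse to their outer span. `gene` features are merged into the
#' coding record sharing their locus_tag.
#'
#' @inheritParams read_feature_table
#' @return A [genome_annotation].
#' @export
read_genbank <- function(path, genome_id = NULL, keep_noncoding = TRUE) {
  lines <- readLines(path)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L)
    rpc_format_error("not a GenBank flat file: no LOCUS line found")
  ends <- c(starts[-1] - 1L, length(lines))
  contigs <- list(); feats <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    loc_fields <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    contig_id <- loc_fields[2]
    clen <- suppressWarnings(as.integer(loc_fields[3]))
    contigs[[r]] <- data.frame(contig_id = contig_id,
                               length = clen %||% NA_integer_,
                               stringsAsFactors = FALSE)
    fstart <- grep("^FEATURES", rec)
    if (length(fstart) == 0L) next
    fend <- grep("^(ORIGIN|CONTIG)", rec)
    fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(rec)
    frec <- rec[(fstart[1] + 1L):fend]
    # feature starts: key in column 6, continuation lines are deeper-indented
    is_key <- grepl("^ {5}\\S", frec)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      span <- frec[idx[k]:(if (k < length(idx)) idx[k + 1] - 1L else length(frec))]
      key <- sub("^ {5}(\\S+).*$", "\\1", span[1])
      if (!key %in% c("CDS", "gene", "tRNA", "rRNA", "ncRNA", "misc_RNA")) next
      body <- trimws(span)
      body[1] <- trimws(sub("^ {5}\\S+", "", span[1]))
      # location may continue until the first qualifier line
      qual_at <- grep("^/", body)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
      loc <- paste(body[1:loc_end], collapse = "")
      quals <- parse_gbk_qualifiers(body[seq_along(body) > loc_end])
      pos <- parse_gbk_location(loc)
      feats[[length(feats) + 1L]] <- data.frame(
        feature = key, contig_id = contig_id,
        start = pos$start, end = pos$end, strand = pos$strand,
        locus_tag = quals[["locus_tag"]] %||% quals[["gene"]] %||%
          paste0(contig_id, "_", idx[k]),
        symbol = quals[["gene"]] %||% "",
        product = quals[["product"]] %||% "",
        pseudo = isTRUE(quals[["pseudo"]]),
        partial = pos$fuzzy,
        contig_edge = pos$fuzzy,
        protein_seq = quals[["translation"]] %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, feats)
  keep_types <- c("CDS", if (keep_noncoding) c("tRNA", "rRNA", "ncRNA", "misc_RNA"))
  recs <- if (is.null(rows)) NULL else
    lapply(split(rows, rows$locus_tag), function(lr) {
      prim <- lr[lr$feature %in% keep_types, , drop = FALSE]
      if (nrow(prim) == 0L) {
        if (!keep_noncoding && any(!lr$feature %in% c("gene", "CDS"))) return(NULL)
        prim <- lr[lr$feature == "gene", , drop = FALSE]
        if (nrow(prim) == 0L) return(NULL)
        prim$feature <- "CDS"
      }
      prim <- prim[1L, , drop = FALSE]
      prim$symbol <- c(lr$symbol[nzchar(lr$symbol)], "")[1L]
      prim$pseudo <- any(lr$pseudo)
      prim$partial <- any(lr$partial)
      prim$contig_edge <- any(lr$contig_edge)
      prim
    })
  genes <- if (is.null(recs)) NULL else
    do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  contig_tab <- do.call(rbind, contigs)
  if (is.null(genes))
    genes <- data.frame(contig_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        locus_tag = character(), stringsAsFactors = FALSE)
  if (anyNA(contig_tab$length))
    contig_tab$length[is.na(contig_tab$length)] <-
      vapply(contig_tab$contig_id[is.na(contig_tab$length)], function(cid)
        max(c(genes$end[genes$contig_id == cid], 1L)), 1L)
  gid <- genome_id %||% contig_tab$contig_id[1]
  genome_annotation(gid, genes, contigs = contig_tab)
}

parse_gbk_location <- function(loc) {
  fuzzy <- grepl("[<>]", loc)
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) == 0L) rpc_format_error(paste0("unparseable GenBank location: ", loc))
  list(start = min(nums), end = max(nums), strand = strand, fuzzy = fuzzy)
}

parse_gbk_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  # re-split into qualifier chunks (qualifiers may wrap across lines)
  chunk <- cumsum(grepl("^/", lines))
  out <- list()
  for (q in split(lines[chunk > 0], chunk[chunk > 0])) {
    txt <- paste(q, collapse = if (grepl("^/translation", q[1])) "" else " ")
    m <- regmatches(txt, regexec('^/([A-Za-z_]+)(=(.*))?$', txt))[[1]]
    key <- m[2]
    val <- m[4]
    if (!nzchar(val %||% "")) out[[key]] <- TRUE
    else out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}
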