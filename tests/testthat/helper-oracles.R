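# Independent oracles used to cross-check the implementation.

.oracle_env <- new.env(parent = emptyenv())

oracle_blosum62 <- function() {
  if (is.null(.oracle_env$B)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .oracle_env$B <- e$BLOSUM62
  }
  .oracle_env$B
}

# plain O(nm) Smith-Waterman with affine gaps (open + L * extend for a gap
# of length L), written independently of the package's alignment path
sw_oracle <- function(a, b, open = 11, ext = 1) {
  S <- oracle_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1); Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                     S[av[i - 1], bv[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

# definition-based segment oracle: walks the gene list one record at a
# time and counts intervening foreign genes explicitly between member
# hits; returns the member locus tags of every segment, per contig
segment_oracle <- function(ann, model, gap_tolerance,
                           registry = default_registry()) {
  segs <- list()
  for (cid in ann$contigs$contig_id) {
    g <- ann$genes[ann$genes$contig_id == cid, , drop = FALSE]
    current <- character(); foreign_run <- 0L
    for (i in seq_len(nrow(g))) {
      nm <- canonicalize_gene_name(g$symbol[i], g$product[i], registry)
      if (!is.na(nm) && nm %in% model$members) {
        if (length(current) && foreign_run > gap_tolerance) {
          segs[[length(segs) + 1L]] <- current
          current <- character()
        }
        current <- c(current, g$locus_tag[i])
        foreign_run <- 0L
      } else if (!is.na(nm) && nm %in% model$accessory) {
        # accessory: tolerated, does not count against the gap
      } else if (length(current)) {
        foreign_run <- foreign_run + 1L
      }
    }
    if (length(current)) segs[[length(segs) + 1L]] <- current
  }
  segs
}

# token count of a template's gene blocks straight from the shipped JSON
template_token_count <- function(name, provenance_pattern = NULL) {
  path <- system.file("extdata", "templates.json", package = "rpclustermap")
  tpl <- jsonlite::read_json(path)[[name]]
  total <- 0L
  for (ct in tpl$contigs) for (blk in ct$blocks) {
    if (identical(blk$kind, "filler")) next
    if (!is.null(provenance_pattern) &&
        !grepl(provenance_pattern, blk$provenance %||% "")) next
    total <- total + length(blk$genes)
  }
  total
}

# filler-block positions of a template (genes outside any arrangement)
template_filler_count <- function(name) {
  path <- system.file("extdata", "templates.json", package = "rpclustermap")
  tpl <- jsonlite::read_json(path)[[name]]
  total <- 0L
  for (ct in tpl$contigs) for (blk in ct$blocks)
    if (identical(blk$kind, "filler")) total <- total + blk$n
  total
}

gene_length_of <- function(gene) {
  reg <- default_registry()
  reg$genes$length[match(gene, reg$genes$name)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
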