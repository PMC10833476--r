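AA_ALPHABET20X <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                    "P","S","T","W","Y","V","X")

check_protein <- function(seq, what) {
  if (is.na(seq) || !nzchar(seq))
    rpc_input_error(paste0(what, " sequence is empty"))
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET20X)
  if (length(bad))
    rpc_input_error(paste0("invalid residue '", chars[bad[1]], "' at position ",
                           bad[1], " of ", what, " sequence"))
  invisible(seq)
}

blosum62 <- function() {
  if (is.null(.rpc_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .rpc_env$BLOSUM62 <- e$BLOSUM62
  }
  .rpc_env$BLOSUM62
}

#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1: a gap of length L costs 11 + L). Returns the
#' optimal score together with the identity (matches per alignment
#' column) and the coverage (fraction of the reference aligned), the two
#' quantities the rescue thresholds are expressed in.
#'
#' @param query,reference Amino-acid strings (20 residues + X).
#' @param gap_open,gap_extend Affine gap parameters in scoring-matrix units.
#' @return List with `score`, `identity`, `coverage`, and the aligned
#'   spans `query_range` / `reference_range` (1-based inclusive).
#' @examples
#' local_align("MKV", "MKV")            # identity 1, coverage 1
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
#' @export
local_align <- function(query, reference, gap_open = 11, gap_extend = 1) {
  check_protein(query, "query")
  check_protein(reference, "reference")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  qr <- as.integer(c(Biostrings::start(Biostrings::pattern(al)),
                     Biostrings::end(Biostrings::pattern(al))))
  rr <- as.integer(c(Biostrings::start(Biostrings::subject(al)),
                     Biostrings::end(Biostrings::subject(al))))
  cols <- nchar(as.character(Biostrings::pattern(al)))
  list(score = Biostrings::score(al),
       identity = if (cols > 0) Biostrings::nmatch(al) / cols else 0,
       coverage = (rr[2] - rr[1] + 1L) / nchar(reference),
       query_range = qr, reference_range = rr)
}

#' Reference panels of cluster-member proteins
#'
#' A reference panel maps canonical gene names to reference amino-acid
#' sequences and typical lengths; the rescue stage aligns unannotated
#' proteins against it. `default_reference_panel()` builds the synthetic
#' panel matching the packaged synthetic genomes (the unmutated base
#' sequence of every cluster member); real panels can be read from FASTA
#' with headers `>canonicalName source=...`.
#'
#' @param registry A `cluster_registry`.
#' @return Object of class `reference_panel`: data frame `entries`
#'   (gene, source, seq) plus named integer vector `typical_length`.
#' @export
default_reference_panel <- function(registry = default_registry()) {
  members <- sort(unique(unlist(lapply(registry$models, `[[`, "members"))))
  members <- members[registry$genes$coding[match(members, registry$genes$name)]]
  seqs <- vapply(members, function(g) generate_protein_seq(g, 0L, 0, registry), "")
  reference_panel(data.frame(gene = members, source = "synthetic", seq = seqs,
                             stringsAsFactors = FALSE), registry)
}

#' @rdname default_reference_panel
#' @param entries Data frame with columns `gene`, `source`, `seq`.
#' @export
reference_panel <- function(entries, registry = default_registry()) {
  bad <- setdiff(entries$gene, registry$genes$name)
  if (length(bad))
    rpc_registry_error(paste0("panel names unregistered gene(s): ",
                              paste(bad, collapse = ", ")))
  entries$seq <- toupper(entries$seq)
  for (i in seq_len(nrow(entries))) check_protein(entries$seq[i], entries$gene[i])
  tl <- vapply(split(nchar(entries$seq), entries$gene), function(x)
    as.integer(round(mean(x))), 1L)
  out <- list(entries = entries[order(entries$gene), , drop = FALSE],
              typical_length = tl)
  class(out) <- "reference_panel"
  out
}

#' @rdname default_reference_panel
#' @param path FASTA path.
#' @export
read_reference_panel <- function(path, registry = default_registry()) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  gene <- sub("\\s.*$", "", hdr)
  source <- ifelse(grepl("source=", hdr), sub(".*source=(\\S+).*", "\\1", hdr), "")
  reference_panel(data.frame(gene = gene, source = source,
                             seq = as.character(seqs), stringsAsFactors = FALSE),
                  registry)
}

#' @rdname default_reference_panel
#' @param panel A `reference_panel`.
#' @export
write_reference_panel <- function(panel, path) {
  seqs <- Biostrings::AAStringSet(panel$entries$seq)
  names(seqs) <- paste0(panel$entries$gene, " source=", panel$entries$source)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>", nrow(x$entries), "sequences for",
      length(unique(x$entries$gene)), "genes\n")
  invisible(x)
}

# align queries against every panel entry in one vectorized call
# (references as pattern, queries as subject); returns long-format stats
panel_align <- function(queries, panel, gap_open = 11, gap_extend = 1) {
  n <- nrow(panel$entries); m <- length(queries)
  pat <- Biostrings::AAStringSet(panel$entries$seq)[rep(seq_len(n), m)]
  sub <- Biostrings::AAStringSet(queries)[rep(seq_len(m), each = n)]
  al <- Biostrings::pairwiseAlignment(
    pat, sub, type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  cols <- nchar(as.character(Biostrings::pattern(al)))
  refspan <- Biostrings::end(Biostrings::pattern(al)) -
    Biostrings::start(Biostrings::pattern(al)) + 1L
  nm <- Biostrings::nmatch(al)
  reflen <- rep(nchar(panel$entries$seq), m)
  data.frame(query = rep(seq_len(m), each = n),
             gene = rep(panel$entries$gene, m),
             score = Biostrings::score(al),
             identity = ifelse(cols > 0, nm / cols, 0),
             coverage = refspan / reflen,
             global_identity = nm / reflen,
             stringsAsFactors = FALSE)
}

#' Rescue cluster members misannotated as hypothetical proteins
#'
#' Every gene whose product resolves to no canonical name is aligned
#' against all panel entries; the best-scoring entry (score ties broken by
#' the lexicographically smallest gene name) yields a call, accepted when
#' identity and reference coverage meet the thresholds. The annotation is
#' not mutated: the calls are returned for the mapping stage to overlay.
#' Unresolved records without a protein sequence are skipped with one
#' warning.
#'
#' @param ann A [genome_annotation] (protein sequences attached).
#' @param panel A `reference_panel`.
#' @param min_identity,min_coverage Acceptance thresholds (defaults 0.30
#'   and 0.50 of the reference length).
#' @param registry A `cluster_registry`.
#' @return Data frame of class `rescue_calls`: one row per candidate with
#'   `locus_tag`, `assigned`, `identity`, `coverage`, `score`, `accepted`.
#' @export
rescue_hypotheticals <- function(ann, panel, min_identity = 0.30,
                                 min_coverage = 0.50,
                                 registry = default_registry()) {
  empty <- data.frame(locus_tag = character(), assigned = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("rescue_calls", "data.frame")
  if (is.null(panel) || nrow(panel$entries) == 0L) return(empty)
  canon <- canonicalize_many(ann$genes$symbol, ann$genes$product, registry)
  cand <- which(is.na(canon) & ann$genes$feature == "CDS")
  if (length(cand) == 0L) return(empty)
  noseq <- cand[is.na(ann$genes$protein_seq[cand])]
  if (length(noseq))
    warning(length(noseq), " unresolved record(s) lack a protein sequence; skipped",
            call. = FALSE)
  cand <- setdiff(cand, noseq)
  if (length(cand) == 0L) return(empty)
  hits <- panel_align(ann$genes$protein_seq[cand], panel)
  rows <- lapply(seq_along(cand), function(k) {
    h <- hits[hits$query == k, , drop = FALSE]
    h <- h[order(-h$score, h$gene), , drop = FALSE]
    best <- h[1L, ]
    data.frame(locus_tag = ann$genes$locus_tag[cand[k]], assigned = best$gene,
               identity = best$identity, coverage = best$coverage,
               score = best$score,
               accepted = best$identity >= min_identity &
                 best$coverage >= min_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  class(out) <- c("rescue_calls", "data.frame")
  out
}

#' Flag partial genes against reference lengths
#'
#' A gene whose assigned cluster member has a known typical length is
#' flagged partial when its coding length falls below
#' `min_length_fraction` of that length, or when it is truncated at a
#' contig edge (shorter than the reference while touching the boundary).
#' Returns a modified copy; the genome-wide partial fraction over cluster
#' genes is attached as attribute `partial_fraction` (percent).
#'
#' @param ann A [genome_annotation].
#' @param panel A `reference_panel` (provides typical lengths).
#' @param min_length_fraction Length-fraction threshold (default 0.7).
#' @param rescue_calls Optional calls used to resolve unannotated members.
#' @param registry A `cluster_registry`.
#' @export
flag_partials <- function(ann, panel, min_length_fraction = 0.7,
                          rescue_calls = NULL, registry = default_registry()) {
  canon <- canonical_names(ann, rescue_calls, registry)
  tl <- panel$typical_length[canon]
  res <- ifelse(!is.na(ann$genes$protein_seq), nchar(ann$genes$protein_seq),
                pmax((ann$genes$end - ann$genes$start + 1L) %/% 3L - 1L, 0L))
  known <- !is.na(tl)
  short <- known & res < min_length_fraction * tl
  truncated <- known & ann$genes$contig_edge & res < tl
  ann$genes$partial <- ann$genes$partial | short | truncated
  cluster_gene <- !is.na(canon) &
    canon %in% unlist(lapply(registry$models, `[[`, "members"))
  frac <- if (any(cluster_gene))
    100 * sum(ann$genes$partial[cluster_gene]) / sum(cluster_gene) else 0
  attr(ann, "partial_fraction") <- frac
  ann
}
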