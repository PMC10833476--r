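#' Map a cluster model onto a genome
#'
#' The core operation: genes whose canonical name (after overlaying
#' accepted rescue calls) belongs to the model are grouped, per contig and
#' left to right, into maximal runs in which consecutive member hits are
#' separated by at most `gap_tolerance` foreign genes. Accessory genes of
#' the model neither break a run nor count as insertions; segments never
#' span contigs. The resulting occurrence is classified as
#' `complete_contiguous` (all members, one segment), `split` (two or more
#' segments with at most `allowed_missing` members absent), `absent` (no
#' member found) or `partial` otherwise. Pseudogene members count as
#' present but are listed separately.
#'
#' @param ann A [genome_annotation].
#' @param model A `cluster_model` from [get_cluster_model()].
#' @param rescue_calls Optional rescue calls from [rescue_hypotheticals()];
#'   accepted calls overlay the annotation's product-based names.
#' @param gap_tolerance Maximum number of intervening non-member,
#'   non-accessory genes tolerated inside a segment (default 2).
#' @param allowed_missing Maximum number of missing members for a
#'   multi-segment occurrence to still be classified `split` (default 2).
#' @param registry A `cluster_registry`.
#' @return Object of class `cluster_occurrence`: model, genome_id,
#'   segments (each with genome-ordered hits, 0-based gene-order index
#'   range, orientation and contig-edge flag), status, missing members,
#'   insertions, pseudo/partial member sets and extra (paralogous) copies.
#' @export
map_cluster <- function(ann, model, rescue_calls = NULL, gap_tolerance = 2L,
                        allowed_missing = 2L, registry = default_registry()) {
  stopifnot(inherits(ann, "genome_annotation"), inherits(model, "cluster_model"))
  if (gap_tolerance < 0L) rpc_input_error("gap_tolerance must be >= 0")
  g <- ann$genes
  canon <- canonical_names(ann, rescue_calls, registry)
  is_member <- !is.na(canon) & canon %in% model$members
  is_acc <- !is.na(canon) & canon %in% model$accessory
  ord <- gene_order_index(ann)
  segments <- list(); interior_foreign <- list()
  for (cid in ann$contigs$contig_id) {
    rows <- which(g$contig_id == cid)
    if (length(rows) == 0L) next
    mem <- rows[is_member[rows]]
    if (length(mem) == 0L) next
    foreign_cum <- cumsum(!(is_member[rows] | is_acc[rows]))
    pos <- match(mem, rows)
    gap <- if (length(pos) > 1L)
      foreign_cum[pos[-1] - 1L] - foreign_cum[pos[-length(pos)]] else integer()
    run_id <- cumsum(c(0L, as.integer(gap > gap_tolerance)))
    for (rid in unique(run_id)) {
      hit_rows <- mem[run_id == rid]
      span <- seq(min(hit_rows), max(hit_rows))
      inseg <- span[is_member[span] | is_acc[span]]
      hits <- data.frame(
        index = ord[inseg], locus_tag = g$locus_tag[inseg],
        gene = canon[inseg], strand = g$strand[inseg],
        accessory = is_acc[inseg], pseudo = g$pseudo[inseg],
        partial = g$partial[inseg],
        via_rescue = rescued_flag(g$locus_tag[inseg], rescue_calls),
        contig_edge = g$contig_edge[inseg],
        stringsAsFactors = FALSE)
      fo <- span[!(is_member[span] | is_acc[span])]
      if (length(fo))
        interior_foreign[[length(interior_foreign) + 1L]] <- data.frame(
          contig_id = cid, index = ord[fo], locus_tag = g$locus_tag[fo],
          gene = canon[fo], product = g$product[fo],
          segment = NA_integer_, stringsAsFactors = FALSE)
      segments[[length(segments) + 1L]] <- list(
        contig_id = cid,
        first_index = ord[min(hit_rows)], last_index = ord[max(hit_rows)],
        hits = hits, orientation = NA_character_,
        at_contig_edge = min(hit_rows) == rows[1L] || max(hit_rows) == rows[length(rows)] ||
          any(g$contig_edge[hit_rows]))
    }
  }
  kept <- prune_paralog_runs(segments)
  segments <- kept$segments
  # renumber interior foreign genes by containing segment
  if_tab <- if (length(interior_foreign)) do.call(rbind, interior_foreign) else
    data.frame(contig_id = character(), index = integer(), locus_tag = character(),
               gene = character(), product = character(), segment = integer(),
               stringsAsFactors = FALSE)
  if (nrow(if_tab)) {
    seg_of <- rep(NA_integer_, nrow(if_tab))
    for (si in seq_along(segments)) {
      s <- segments[[si]]
      inside <- if_tab$contig_id == s$contig_id &
        if_tab$index > s$first_index & if_tab$index < s$last_index
      seg_of[inside] <- si
    }
    if_tab$segment <- seg_of
    if_tab <- if_tab[!is.na(seg_of), , drop = FALSE]
  }
  member_hits <- function(s) s$hits[!s$hits$accessory, , drop = FALSE]
  found <- as.character(unique(unlist(lapply(segments, function(s) member_hits(s)$gene))))
  missing <- setdiff(model$members, found)
  n_seg <- length(segments)
  status <- if (length(found) == 0L) "absent"
  else if (length(missing) == 0L && n_seg == 1L) "complete_contiguous"
  else if (n_seg >= 2L && length(missing) <= allowed_missing) "split"
  else "partial"
  all_hits <- do.call(rbind, lapply(segments, member_hits))
  occ <- list(
    model = model, genome_id = ann$genome_id,
    segments = segments, status = status,
    found = found, missing = missing,
    pseudo_members = as.character(sort(unique(all_hits$gene[all_hits$pseudo]))),
    partial_members = as.character(sort(unique(all_hits$gene[all_hits$partial]))),
    rescued_members = as.character(sort(unique(all_hits$gene[all_hits$via_rescue]))),
    extra_copies = kept$extra,
    interior_foreign = if_tab,
    complete_genome = ann$complete,
    gap_tolerance = as.integer(gap_tolerance))
  class(occ) <- "cluster_occurrence"
  occ$insertions <- detect_insertions(occ)
  normalize_orientation(occ)
}

# canonical name per gene record, with accepted rescue calls overlaid
canonical_names <- function(ann, rescue_calls = NULL, registry = default_registry()) {
  canon <- canonicalize_many(ann$genes$symbol, ann$genes$product, registry)
  if (!is.null(rescue_calls) && nrow(rescue_calls)) {
    acc <- rescue_calls[rescue_calls$accepted, , drop = FALSE]
    hit <- match(ann$genes$locus_tag, acc$locus_tag)
    canon[!is.na(hit)] <- acc$assigned[hit[!is.na(hit)]]
  }
  canon
}

rescued_flag <- function(locus_tags, rescue_calls) {
  if (is.null(rescue_calls) || nrow(rescue_calls) == 0L)
    return(rep(FALSE, length(locus_tags)))
  locus_tags %in% rescue_calls$locus_tag[rescue_calls$accepted]
}

# paralog handling: runs contributing no member name beyond those carried
# by larger runs are set aside as extra copies (duplicate genes adjacent to
# each other stay inside their run and are reported as extra copies too)
prune_paralog_runs <- function(segments) {
  if (length(segments) <= 1L) {
    extra <- data.frame(gene = character(), locus_tag = character(),
                        stringsAsFactors = FALSE)
    if (length(segments) == 1L) {
      h <- segments[[1]]$hits
      h <- h[!h$accessory, , drop = FALSE]
      dup <- duplicated(h$gene)
      extra <- data.frame(gene = h$gene[dup], locus_tag = h$locus_tag[dup],
                          stringsAsFactors = FALSE)
    }
    return(list(segments = segments, extra = extra))
  }
  names_of <- lapply(segments, function(s) unique(s$hits$gene[!s$hits$accessory]))
  span_of <- vapply(segments, function(s) s$last_index - s$first_index + 1L, 1L)
  ord <- order(-lengths(names_of), span_of,
               vapply(segments, function(s) s$contig_id, ""),
               vapply(segments, function(s) s$first_index, 1L))
  seen <- character(); keep <- logical(length(segments))
  for (i in ord) {
    new <- setdiff(names_of[[i]], seen)
    if (length(new)) { keep[i] <- TRUE; seen <- c(seen, new) }
  }
  extra_rows <- lapply(segments[!keep], function(s) {
    h <- s$hits[!s$hits$accessory, , drop = FALSE]
    data.frame(gene = h$gene, locus_tag = h$locus_tag, stringsAsFactors = FALSE)
  })
  kept_segs <- segments[keep]
  dup_rows <- lapply(kept_segs, function(s) {
    h <- s$hits[!s$hits$accessory, , drop = FALSE]
    dup <- duplicated(h$gene)
    data.frame(gene = h$gene[dup], locus_tag = h$locus_tag[dup],
               stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, c(extra_rows, dup_rows,
                            list(data.frame(gene = character(), locus_tag = character(),
                                            stringsAsFactors = FALSE))))
  list(segments = kept_segs, extra = extra)
}

#' Foreign genes inserted inside cluster segments
#'
#' Reports every gene lying strictly inside a segment's gene-order range
#' that is neither a member nor an accessory gene of the model and that
#' resolves to a registered gene name. Unnamed spacers (hypothetical
#' proteins) are tolerated silently: they count against the gap tolerance
#' during mapping but are not reported as insertions.
#'
#' @param occurrence A `cluster_occurrence`.
#' @return Data frame with columns `gene`, `locus_tag`, `segment`,
#'   `after_member`, `before_member`, in genome order.
#' @export
detect_insertions <- function(occurrence) {
  fo <- occurrence$interior_foreign
  fo <- fo[!is.na(fo$gene), , drop = FALSE]
  if (nrow(fo) == 0L)
    return(data.frame(gene = character(), locus_tag = character(),
                      segment = integer(), after_member = character(),
                      before_member = character(), stringsAsFactors = FALSE))
  fo <- fo[order(fo$segment, fo$index), , drop = FALSE]
  after <- character(nrow(fo)); before <- character(nrow(fo))
  for (i in seq_len(nrow(fo))) {
    s <- occurrence$segments[[fo$segment[i]]]
    mh <- s$hits[!s$hits$accessory, , drop = FALSE]
    after[i] <- utils::tail(mh$gene[mh$index < fo$index[i]], 1L)
    before[i] <- mh$gene[mh$index > fo$index[i]][1L]
  }
  data.frame(gene = fo$gene, locus_tag = fo$locus_tag, segment = fo$segment,
             after_member = after, before_member = before,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harmonize segment orientation with the model's canonical order
#'
#' A segment is flagged `reverse` when its member hits run against the
#' model's reference order (ties broken by the majority hit strand; a
#' single-gene segment is `forward` by convention). Hits are stored in
#' genome order; reports and cluster maps present reverse segments
#' flipped, so that every segment reads in model order. The operation is
#' idempotent, and mapping results are invariant under
#' reverse-complementing the whole genome.
#'
#' @param occurrence A `cluster_occurrence`.
#' @return The occurrence with `orientation` set on each segment.
#' @export
normalize_orientation <- function(occurrence) {
  mod_pos <- function(genes) match(genes, occurrence$model$members)
  occurrence$segments <- lapply(occurrence$segments, function(s) {
    mh <- s$hits[!s$hits$accessory, , drop = FALSE]
    p <- mod_pos(mh$gene)
    d <- diff(p)
    inc <- sum(d > 0); dec <- sum(d < 0)
    s$orientation <- if (dec > inc) "reverse"
    else if (inc > dec) "forward"
    else if (nrow(mh) > 1L && mean(mh$strand == "-") > 0.5) "reverse"
    else "forward"
    s
  })
  occurrence
}

# hits of a segment in presentation (model) order
segment_display_hits <- function(segment) {
  if (identical(segment$orientation, "reverse"))
    segment$hits[rev(seq_len(nrow(segment$hits))), , drop = FALSE]
  else segment$hits
}

#' @export
print.cluster_occurrence <- function(x, ...) {
  cat("<cluster_occurrence>", x$model$name, paste0("(", x$model$variant, ")"),
      "on", x$genome_id, "-", x$status, "\n")
  cat("  segments:", length(x$segments),
      " members found:", length(x$found), "/", length(x$model$members), "\n")
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  if (nrow(x$insertions)) cat("  insertions:", paste(x$insertions$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Map every registered model of a variant onto a genome
#'
#' @inheritParams map_cluster
#' @param variant `"archaeal"` or `"bacterial"`.
#' @return List of `cluster_occurrence`, one per registered model of the
#'   variant.
#' @export
map_genome <- function(ann, variant, rescue_calls = NULL, gap_tolerance = 2L,
                       allowed_missing = 2L, registry = default_registry()) {
  mods <- Filter(function(m) m$variant == variant, registry$models)
  lapply(mods, function(m)
    map_cluster(ann, m, rescue_calls, gap_tolerance, allowed_missing, registry))
}

#' Detect co-occurring cluster families
#'
#' Two cluster families co-occur when a segment of one lies within
#' `adjacency_window` gene positions of a segment of the other on the same
#' contig; co-occurrence groups are the transitive closures of that
#' relation. The window is deliberately wider than the segment gap
#' tolerance, so clusters separated by short runs of unrelated ORFs still
#' form one contiguous group.
#'
#' @param occurrences List of `cluster_occurrence` from one genome.
#' @param adjacency_window Maximum number of intervening gene positions
#'   between segments of co-occurring families (default 12).
#' @return List of groups; each group has `families` (ordered as in the
#'   registry), and `segments`, a data frame of the contributing segment
#'   intervals.
#' @export
detect_cooccurrence <- function(occurrences, adjacency_window = 12L,
                                registry = default_registry()) {
  gids <- unique(vapply(occurrences, function(o) o$genome_id, ""))
  if (length(gids) > 1L)
    rpc_input_error("co-occurrence is defined within one genome")
  segs <- do.call(rbind, lapply(occurrences, function(o) {
    if (length(o$segments) == 0L) return(NULL)
    do.call(rbind, lapply(o$segments, function(s)
      data.frame(family = o$model$family, model = o$model$name,
                 contig_id = s$contig_id, first = s$first_index,
                 last = s$last_index, stringsAsFactors = FALSE)))
  }))
  if (is.null(segs) || nrow(segs) == 0L) return(list())
  fams <- unique(segs$family)
  # union-find over families
  parent <- seq_along(fams)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(segs) - 1L)) for (j in seq(i + 1L, nrow(segs))) {
    if (segs$contig_id[i] != segs$contig_id[j]) next
    gap <- max(segs$first[i], segs$first[j]) - min(segs$last[i], segs$last[j]) - 1L
    if (gap <= adjacency_window) {
      ri <- find(match(segs$family[i], fams)); rj <- find(match(segs$family[j], fams))
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_along(fams), find, 1L)
  groups <- lapply(unique(roots), function(r) {
    f <- fams[roots == r]
    f <- f[order(match(f, registry$families))]
    list(families = f,
         segments = segs[segs$family %in% f, , drop = FALSE])
  })
  ord <- order(vapply(groups, function(gr) min(gr$segments$first), 1L))
  groups[ord]
}
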