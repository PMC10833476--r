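status_rank <- function(status)
  match(status, c("complete_contiguous", "split", "partial", "absent"))

# pick the representative occurrence of a family: the model with most
# members found (the informative one, e.g. the split core rather than a
# small complete sub-cluster), then best status, fewest segments, name
family_representative <- function(occs) {
  ord <- order(-vapply(occs, function(o) length(o$found), 1L),
               status_rank(vapply(occs, `[[`, "", "status")),
               vapply(occs, function(o) length(o$segments), 1L),
               vapply(occs, function(o) o$model$name, ""))
  occs[[ord[1L]]]
}

#' Aggregate occurrences into a genomes-by-families status matrix
#'
#' Each cell summarizes the representative occurrence of a cluster family
#' in one genome (the model with the best status; families with no model
#' hit are `absent`). Cells carry the status, segment count, fraction of
#' members found and fraction of found members flagged partial. The matrix
#' is a pure function of the occurrences: re-aggregation is idempotent.
#'
#' @param occurrences_by_genome Named list: `genome_id` -> list of
#'   `cluster_occurrence` (e.g. from [map_genome()]).
#' @param registry A `cluster_registry`.
#' @return Object of class `status_matrix`: long-format data frame
#'   (genome, family, status, n_segments, fraction_members_found,
#'   partial_fraction).
#' @export
build_status_matrix <- function(occurrences_by_genome,
                                registry = default_registry()) {
  gids <- names(occurrences_by_genome)
  if (is.null(gids) || any(!nzchar(gids)))
    rpc_input_error("occurrences_by_genome must be a named list (genome ids)")
  if (anyDuplicated(gids))
    rpc_input_error(paste0("duplicate genome_id: ",
                           paste(unique(gids[duplicated(gids)]), collapse = ", ")))
  rows <- list()
  for (gid in gids) {
    occs <- occurrences_by_genome[[gid]]
    for (fam in registry$families) {
      fo <- Filter(function(o) o$model$family == fam, occs)
      if (length(fo) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome = gid, family = fam, model = NA_character_, status = "absent",
          n_segments = 0L, fraction_members_found = 0, partial_fraction = 0,
          stringsAsFactors = FALSE)
        next
      }
      rep_occ <- family_representative(fo)
      nf <- length(rep_occ$found)
      rows[[length(rows) + 1L]] <- data.frame(
        genome = gid, family = fam, model = rep_occ$model$name,
        status = rep_occ$status, n_segments = length(rep_occ$segments),
        fraction_members_found = nf / length(rep_occ$model$members),
        partial_fraction = if (nf) length(rep_occ$partial_members) / nf else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("status_matrix", "data.frame")
  out
}

#' @export
print.status_matrix <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x)[, c("genome", "family", "status")],
                         idvar = "genome", timevar = "family", direction = "wide")
  names(wide) <- sub("^status\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Per-genome dispersion and completeness of cluster organization
#'
#' For each genome, over the families present (status not `absent`):
#' `dispersion` is the mean number of segments per present family (1 for a
#' genome whose clusters are all contiguous, larger the more fragmented
#' the arrangement), and `completeness` the fraction of present families
#' that occur complete and contiguous. Both metrics are descriptive
#' summaries of the occurrence table, not statements from the underlying
#' survey.
#'
#' @param matrix A `status_matrix`.
#' @return Data frame: genome, n_present, dispersion, completeness.
#' @export
dispersion_metrics <- function(matrix) {
  if (nrow(matrix) == 0L) rpc_input_error("empty status matrix")
  out <- lapply(split(as.data.frame(matrix), matrix$genome), function(m) {
    pres <- m[m$status != "absent", , drop = FALSE]
    data.frame(genome = m$genome[1L], n_present = nrow(pres),
               dispersion = if (nrow(pres)) mean(pres$n_segments) else NA_real_,
               completeness = if (nrow(pres))
                 mean(pres$status == "complete_contiguous") else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[match(unique(matrix$genome), res$genome), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assembly / annotation quality concerns for a genome
#'
#' Heuristics for arrangements more plausibly explained by misassembly or
#' mis-binning than by biology: a universal gene annotated as a
#' pseudogene, universal genes (uL3-uL4-uL23) missing genome-wide, the
#' S10-spc core split on a complete genome, or a high fraction of partial
#' cluster genes.
#'
#' @param occurrences List of `cluster_occurrence` for one genome.
#' @param partial_threshold Fraction of partial cluster genes above which
#'   the genome is flagged (default 0.10).
#' @param registry A `cluster_registry`.
#' @return Data frame `genome`, `reason` (zero rows when no concern).
#' @export
flag_assembly_concerns <- function(occurrences, partial_threshold = 0.10,
                                   registry = default_registry()) {
  gid <- unique(vapply(occurrences, function(o) o$genome_id, ""))
  if (length(gid) != 1L) rpc_input_error("concerns are flagged per genome")
  reasons <- character()
  found_all <- unique(unlist(lapply(occurrences, `[[`, "found")))
  if (length(setdiff(c("uL3", "uL4", "uL23"), found_all)) > 0L)
    reasons <- c(reasons, "universal_genes_missing")
  core14 <- get_cluster_model("S10-spc-core", "bacterial", registry)$core
  pseudo_all <- unique(unlist(lapply(occurrences, `[[`, "pseudo_members")))
  if (length(intersect(pseudo_all, core14)))
    reasons <- c(reasons, "universal_gene_pseudo")
  for (o in occurrences)
    if (o$model$name == "S10-spc-core" && length(o$segments) >= 2L &&
        isTRUE(o$complete_genome)) {
      reasons <- c(reasons, "core_split")
      break
    }
  nf <- sum(vapply(occurrences, function(o) length(o$found), 1L))
  np <- length(unique(unlist(lapply(occurrences, `[[`, "partial_members"))))
  denom <- length(unique(found_all))
  if (denom > 0L && np / denom >= partial_threshold)
    reasons <- c(reasons, "high_partial_fraction")
  data.frame(genome = rep(gid, length(reasons)), reason = reasons,
             stringsAsFactors = FALSE)
}

#' Render a cluster occurrence as a text map
#'
#' One line per segment, hits presented in model order (reverse segments
#' flipped). Markers: `^` pseudogene, `~` partial gene, `*` at a contig
#' edge, parentheses for accessory genes, and a trailing list of missing
#' members prefixed with the empty-set sign. Deterministic.
#'
#' @param occurrence A `cluster_occurrence`.
#' @return Character vector of lines (also printed invisibly-friendly).
#' @export
render_cluster_map <- function(occurrence) {
  hdr <- sprintf("%s/%s %s on %s: %s", occurrence$model$name,
                 occurrence$model$variant, occurrence$model$family,
                 occurrence$genome_id, occurrence$status)
  seg_lines <- vapply(seq_along(occurrence$segments), function(i) {
    s <- occurrence$segments[[i]]
    h <- segment_display_hits(s)
    tok <- vapply(seq_len(nrow(h)), function(k) {
      marks <- paste0(if (h$pseudo[k]) "^" else "", if (h$partial[k]) "~" else "",
                      if (h$contig_edge[k]) "*" else "")
      if (h$accessory[k]) paste0("(", h$gene[k], marks, ")")
      else paste0("[", h$gene[k], marks, "]")
    }, "")
    sprintf("  segment %d %s:%d-%d:%s %s", i, s$contig_id, s$first_index,
            s$last_index, s$orientation, paste(tok, collapse = ""))
  }, "")
  miss <- if (length(occurrence$missing))
    paste0("  missing: ", paste0("∅", occurrence$missing, collapse = " "))
  else character()
  c(hdr, seg_lines, miss)
}
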