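occurrence_to_list <- function(o) {
  list(model = unclass(o$model), genome_id = o$genome_id,
       status = o$status,
       segments = lapply(o$segments, function(s)
         list(contig_id = s$contig_id, first_index = s$first_index,
              last_index = s$last_index, orientation = s$orientation,
              at_contig_edge = s$at_contig_edge, hits = s$hits)),
       found = as.character(o$found), missing = as.character(o$missing),
       insertions = o$insertions, pseudo_members = o$pseudo_members,
       partial_members = o$partial_members, rescued_members = o$rescued_members,
       extra_copies = o$extra_copies, interior_foreign = o$interior_foreign,
       complete_genome = o$complete_genome, gap_tolerance = o$gap_tolerance)
}

as_df <- function(x, int_cols = character(), lgl_cols = character()) {
  df <- as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) df <- as.data.frame(lapply(x, function(col) unlist(col) %||% character()))
  for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(lgl_cols, names(df))) df[[cc]] <- as.logical(df[[cc]])
  for (cc in setdiff(names(df), c(int_cols, lgl_cols))) df[[cc]] <- as.character(df[[cc]])
  df
}

occurrence_from_list <- function(x) {
  model <- x$model
  model$members <- as.character(unlist(model$members))
  model$core <- as.character(unlist(model$core))
  model$accessory <- as.character(unlist(model$accessory))
  class(model) <- "cluster_model"
  hit_df <- function(h) as_df(h, int_cols = "index",
                              lgl_cols = c("accessory", "pseudo", "partial",
                                           "via_rescue", "contig_edge"))
  o <- list(model = model, genome_id = x$genome_id, status = x$status,
            segments = lapply(x$segments, function(s)
              list(contig_id = s$contig_id,
                   first_index = as.integer(s$first_index),
                   last_index = as.integer(s$last_index),
                   hits = hit_df(s$hits), orientation = s$orientation,
                   at_contig_edge = isTRUE(s$at_contig_edge))),
            found = as.character(unlist(x$found)),
            missing = as.character(unlist(x$missing)),
            pseudo_members = as.character(unlist(x$pseudo_members)),
            partial_members = as.character(unlist(x$partial_members)),
            rescued_members = as.character(unlist(x$rescued_members)),
            extra_copies = as_df(x$extra_copies),
            interior_foreign = as_df(x$interior_foreign,
                                     int_cols = c("index", "segment")),
            complete_genome = isTRUE(x$complete_genome),
            gap_tolerance = as.integer(x$gap_tolerance))
  o$insertions <- as_df(x$insertions, int_cols = "segment")
  class(o) <- "cluster_occurrence"
  # restore canonical element order
  o[c("model", "genome_id", "segments", "status", "found", "missing",
      "pseudo_members", "partial_members", "rescued_members", "extra_copies",
      "interior_foreign", "complete_genome", "gap_tolerance", "insertions")]
}

#' Write cluster occurrences as TSV or JSON
#'
#' The TSV is one row per occurrence with segments encoded
#' `contig:firstIndex-lastIndex:orientation` (gene-order indices, 0-based)
#' and comma-joined member lists; the JSON mirrors the full data model and
#' round-trips through [read_occurrence_json()]. Identical input produces
#' byte-identical output.
#'
#' @param occurrences List of `cluster_occurrence`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_occurrence_report <- function(occurrences, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(lapply(occurrences, occurrence_to_list), path,
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    return(invisible(path))
  }
  rows <- vapply(occurrences, function(o) {
    segs <- paste(vapply(o$segments, function(s)
      sprintf("%s:%d-%d:%s", s$contig_id, s$first_index, s$last_index,
              s$orientation), ""), collapse = ";")
    paste(o$genome_id, o$model$family, o$model$name, o$status,
          length(o$segments), segs,
          paste(o$found, collapse = ","), paste(o$missing, collapse = ","),
          paste(o$insertions$gene, collapse = ","),
          paste(o$pseudo_members, collapse = ","),
          paste(o$partial_members, collapse = ","), sep = "\t")
  }, "")
  hdr <- paste("genome", "family", "model", "status", "n_segments", "segment",
               "members_found", "members_missing", "insertions",
               "pseudo_members", "partial_members", sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_occurrence_report
#' @export
read_occurrence_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, occurrence_from_list)
}

#' Write a status matrix as TSV (wide) and JSON (long)
#'
#' @param matrix A `status_matrix`.
#' @param path Output path without extension restrictions; `format` picks
#'   the serialization.
#' @param format `"tsv"` or `"json"`.
#' @export
write_status_matrix <- function(matrix, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(matrix), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    m <- as.data.frame(matrix)
    cell <- sprintf("%s:%d:%.3f", m$status, m$n_segments, m$fraction_members_found)
    wide <- stats::reshape(data.frame(genome = m$genome, family = m$family,
                                      cell = cell, stringsAsFactors = FALSE),
                           idvar = "genome", timevar = "family", direction = "wide")
    names(wide) <- sub("^cell\\.", "", names(wide))
    utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
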