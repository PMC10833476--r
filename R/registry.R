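#' Cluster-model registry
#'
#' The registry holds the closed set of gene names used by the cluster
#' models, an alias table mapping annotation symbols and product strings to
#' canonical names, and the cluster models themselves: for each of the five
#' top-level cluster families (`S10-spc`, `str-L30e`, `alpha-L18e`,
#' `L7ae-S24e`, `L31e-L11`) one or more ordered gene lists with a conserved
#' core, in an archaeal and/or bacterial variant. Models record, besides
#' their ordered members, the accessory genes that are tolerated inside a
#' cluster segment without counting as foreign insertions (for example the
#' SUI1 translation-factor homolog and secY inside the archaeal S10-spc
#' block).
#'
#' @param registry_file,alias_file Paths to JSON documents; defaults are the
#'   documents shipped with the package.
#' @return An object of class `cluster_registry`: a list with elements
#'   `genes` (data frame of canonical names, categories and reference
#'   lengths), `models` (list of `cluster_model` objects), `families`,
#'   `aliases` (named character vector keyed by normalized alias), and
#'   `hp_labels` (labels reserved for unannotated genes).
#' @export
read_registry <- function(registry_file = rpc_extdata("cluster_registry.json"),
                          alias_file = rpc_extdata("gene_aliases.json")) {
  raw <- jsonlite::read_json(registry_file)
  genes <- do.call(rbind, lapply(raw$genes, function(g) {
    data.frame(name = g$name, category = g$category,
               product = g$product, subunit = g$subunit %||% NA_character_,
               coding = isTRUE(g$coding), length = as.integer(g$length),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(genes$name))
    rpc_registry_error("duplicate canonical gene names in registry")
  models <- lapply(raw$models, function(m) {
    mod <- list(name = m$name, family = m$family, variant = m$variant,
                members = as.character(unlist(m$members)),
                core = as.character(unlist(m$core)),
                accessory = as.character(unlist(m$accessory)))
    class(mod) <- "cluster_model"
    mod
  })
  fams <- as.character(unlist(raw$families))
  al_raw <- jsonlite::read_json(alias_file)$aliases
  aliases <- vapply(al_raw, as.character, "")
  names(aliases) <- normalize_label(names(al_raw))
  if (anyDuplicated(names(aliases)))
    rpc_registry_error("alias table maps one alias to multiple canonical names")
  reg <- list(genes = genes, models = models, families = fams,
              aliases = aliases,
              hp_labels = normalize_label(as.character(unlist(raw$hp_labels))))
  class(reg) <- "cluster_registry"
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  known <- reg$genes$name
  for (m in reg$models) {
    if (length(m$members) == 0L)
      rpc_registry_error(paste0("model ", m$name, " has no members"))
    if (!all(m$core %in% m$members))
      rpc_registry_error(paste0("model ", m$name, ": core is not a subset of members"))
    bad <- setdiff(c(m$members, m$accessory), known)
    if (length(bad))
      rpc_registry_error(paste0("model ", m$name, ": unregistered gene(s) ",
                                paste(bad, collapse = ", ")))
    if (!m$family %in% reg$families)
      rpc_registry_error(paste0("model ", m$name, ": unknown family ", m$family))
  }
  bad_alias <- setdiff(unname(reg$aliases), known)
  if (length(bad_alias))
    rpc_registry_error(paste0("aliases point at unregistered gene(s): ",
                              paste(bad_alias, collapse = ", ")))
  invisible(reg)
}

# registry cache: loading parses ~30 KB of JSON, so keep one per session
.rpc_env <- new.env(parent = emptyenv())

#' @rdname read_registry
#' @export
default_registry <- function() {
  if (is.null(.rpc_env$registry)) .rpc_env$registry <- read_registry()
  .rpc_env$registry
}

#' @export
print.cluster_registry <- function(x, ...) {
  cat("<cluster_registry>", nrow(x$genes), "genes,", length(x$models),
      "models in", length(x$families), "families\n")
  invisible(x)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model>", x$name, paste0("(", x$variant, ", family ", x$family, ")\n"))
  cat("  members:", paste(x$members, collapse = "-"), "\n")
  cat("  core   :", paste(x$core, collapse = "-"), "\n")
  if (length(x$accessory))
    cat("  accessory:", paste(x$accessory, collapse = ", "), "\n")
  invisible(x)
}

#' Resolve an annotated gene to a canonical registry name
#'
#' Symbol matches take precedence over product matches; both are
#' case-insensitive after whitespace normalization. Labels of the
#' "hypothetical protein" kind are reserved for the rescue stage and
#' resolve to nothing, as do unknown products.
#'
#' @param raw_symbol Gene symbol from the annotation (may be empty).
#' @param raw_product Product description (may be empty).
#' @param registry A `cluster_registry`.
#' @return The canonical gene name, or `NA_character_` when the record does
#'   not resolve. Never throws for unknown input.
#' @examples
#' canonicalize_gene_name("uL22", "")
#' canonicalize_gene_name("", "ribonuclease P protein component 1")
#' canonicalize_gene_name("", "hypothetical protein")   # NA: reserved
#' @export
canonicalize_gene_name <- function(raw_symbol = "", raw_product = "",
                                   registry = default_registry()) {
  if (!nzchar(raw_symbol %||% "") && !nzchar(raw_product %||% ""))
    return(NA_character_)
  canonicalize_many(raw_symbol %||% "", raw_product %||% "", registry)
}

# vectorized canonicalization used by the mapping stage
canonicalize_many <- function(symbols, products, registry = default_registry()) {
  symbols[is.na(symbols)] <- ""
  products[is.na(products)] <- ""
  out <- unname(registry$aliases[normalize_label(symbols)])
  prod_norm <- normalize_label(products)
  prod_hit <- unname(registry$aliases[prod_norm])
  prod_hit[prod_norm %in% registry$hp_labels] <- NA_character_
  take <- is.na(out)
  out[take] <- prod_hit[take]
  out
}

# TRUE for records whose product is a hypothetical-protein style label
is_hp_label <- function(products, registry = default_registry()) {
  normalize_label(products) %in% registry$hp_labels
}

#' Retrieve a cluster model from the registry
#'
#' @param name Model name, e.g. `"S10-spc-core"`, `"L7ae"`.
#' @param variant `"archaeal"` or `"bacterial"`.
#' @inheritParams canonicalize_gene_name
#' @return A `cluster_model` object (ordered members, core, accessory set).
#' @export
get_cluster_model <- function(name, variant, registry = default_registry()) {
  for (m in registry$models)
    if (m$name == name && m$variant == variant) return(m)
  opts <- vapply(registry$models, function(m) paste0(m$name, "/", m$variant), "")
  rpc_registry_error(paste0("unknown cluster model ", name, "/", variant,
                            "; registered models: ", paste(opts, collapse = ", ")))
}

#' List registered cluster models
#'
#' @param variant Optional filter, `"archaeal"` or `"bacterial"`.
#' @inheritParams canonicalize_gene_name
#' @return Data frame with one row per model: name, family, variant, sizes.
#' @export
list_cluster_models <- function(variant = NULL, registry = default_registry()) {
  keep <- registry$models
  if (!is.null(variant)) keep <- Filter(function(m) m$variant == variant, keep)
  do.call(rbind, lapply(keep, function(m)
    data.frame(name = m$name, family = m$family, variant = m$variant,
               n_members = length(m$members), n_core = length(m$core),
               stringsAsFactors = FALSE)))
}

#' Symmetric membership difference between two cluster models
#'
#' Order-insensitive comparison of the member lists, used e.g. to recover
#' the Archaea-Eukarya-specific additions of the archaeal S10-spc cluster
#' relative to its bacterial counterpart.
#'
#' @param a,b `cluster_model` objects.
#' @return List with character vectors `only_in_a` and `only_in_b`.
#' @export
model_diff <- function(a, b) {
  list(only_in_a = setdiff(a$members, b$members),
       only_in_b = setdiff(b$members, a$members))
}

# category lookup for a vector of canonical names
gene_category <- function(genes, registry = default_registry()) {
  registry$genes$category[match(genes, registry$genes$name)]
}

# reference protein length lookup (residues)
gene_length <- function(genes, registry = default_registry()) {
  registry$genes$length[match(genes, registry$genes$name)]
}

# the genes treated as universal for assembly-concern flags:
# the 14-gene S10-spc core plus uL3, uL4, uL23, uL2 and uS10
universal_gene_set <- function(registry = default_registry()) {
  core14 <- get_cluster_model("S10-spc-core", "bacterial", registry)$core
  union(core14, c("uL3", "uL4", "uL23", "uL2", "uS10"))
}
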