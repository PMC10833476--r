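# Fixture builders shared across test files. Expensive shared objects
# (reference panel, template builds) are memoized per test run.

.fix_env <- new.env(parent = emptyenv())

test_panel <- function() {
  if (is.null(.fix_env$panel)) .fix_env$panel <- default_reference_panel()
  .fix_env$panel
}

test_build <- function(name, seed = 1L) {
  key <- paste0(name, "::", seed)
  if (is.null(.fix_env[[key]]))
    .fix_env[[key]] <- build_from_template(name, seed, panel = test_panel())
  .fix_env[[key]]
}

# quick annotation from canonical tokens ("HP" = hypothetical filler);
# products are the registry's NCBI-style strings, no protein sequences
toy_annotation <- function(tokens, strand = "+", genome_id = "toy",
                           contig_id = "c1", locus_prefix = "TOY",
                           registry = default_registry()) {
  strand <- rep_len(strand, length(tokens))
  product <- ifelse(tokens == "HP", "hypothetical protein",
                    registry$genes$product[match(tokens, registry$genes$name)])
  stopifnot(!anyNA(product))
  n <- length(tokens)
  start <- 1L + 400L * (seq_len(n) - 1L)
  genome_annotation(genome_id,
                    data.frame(contig_id = contig_id, start = start,
                               end = start + 299L, strand = strand,
                               locus_tag = sprintf("%s_%03d", locus_prefix, seq_len(n)),
                               product = product, stringsAsFactors = FALSE))
}

# canonical names of the given loci, resolved record by record through the
# scalar public canonicalizer (independent of the vectorized path)
canonical_of_loci <- function(ann, loci, registry = default_registry()) {
  idx <- match(loci, ann$genes$locus_tag)
  vapply(idx, function(i)
    canonicalize_gene_name(ann$genes$symbol[i], ann$genes$product[i], registry), "")
}

# reverse-complement a whole genome: per contig, mirror coordinates,
# reverse gene order, flip strands
rc_annotation <- function(ann) {
  g <- ann$genes
  clen <- ann$contigs$length[match(g$contig_id, ann$contigs$contig_id)]
  new_start <- clen - g$end + 1L
  g$end <- clen - g$start + 1L
  g$start <- new_start
  g$strand <- ifelse(g$strand == "+", "-", "+")
  genome_annotation(ann$genome_id, g, contigs = ann$contigs)
}

run_synthetic_pipeline <- function(built, registry = default_registry()) {
  calls <- suppressWarnings(rescue_hypotheticals(built$annotation, test_panel(),
                                                 registry = registry))
  occs <- map_genome(built$annotation, built$truth$variant, calls,
                     registry = registry)
  list(calls = calls, occurrences = occs)
}

occurrence_of <- function(occurrences, model_name) {
  hit <- Filter(function(o) o$model$name == model_name, occurrences)
  stopifnot(length(hit) == 1L)
  hit[[1L]]
}

# compare a mapped genome against its planted truth; returns character()
# when everything matches, else human-readable mismatch descriptions
truth_mismatches <- function(built, pipeline, check_cooccurrence = TRUE) {
  truth <- built$truth
  occs <- pipeline$occurrences
  probs <- character()
  for (tm in truth$models) {
    o <- occurrence_of(occs, tm$model)
    if (o$status != tm$status)
      probs <- c(probs, sprintf("%s status %s != %s", tm$model, o$status, tm$status))
    if (length(o$segments) != tm$n_segments)
      probs <- c(probs, sprintf("%s segments %d != %d", tm$model,
                                length(o$segments), tm$n_segments))
    if (!setequal(o$missing, tm$missing))
      probs <- c(probs, sprintf("%s missing set", tm$model))
    if (!setequal(o$pseudo_members, tm$pseudo_members))
      probs <- c(probs, sprintf("%s pseudo set", tm$model))
    if (!setequal(o$partial_members, tm$partial_members))
      probs <- c(probs, sprintf("%s partial set", tm$model))
    if (!setequal(o$insertions$gene, tm$insertions))
      probs <- c(probs, sprintf("%s insertions", tm$model))
    if (!is.null(tm$orientations)) {
      got <- vapply(o$segments, `[[`, "", "orientation")
      if (!identical(got, tm$orientations))
        probs <- c(probs, sprintf("%s orientations", tm$model))
    }
  }
  acc <- pipeline$calls[pipeline$calls$accepted, , drop = FALSE]
  want <- truth$rescuable
  if (length(want)) {
    got <- stats::setNames(acc$assigned, acc$locus_tag)
    if (!setequal(names(got), names(want)) ||
        !all(got[names(want)] == want))
      probs <- c(probs, "rescued hypotheticals")
  } else if (nrow(acc)) probs <- c(probs, "spurious rescue call")
  concerns <- flag_assembly_concerns(occs)
  if (!setequal(concerns$reason, truth$concerns))
    probs <- c(probs, sprintf("concerns [%s] != [%s]",
                              paste(concerns$reason, collapse = ","),
                              paste(truth$concerns, collapse = ",")))
  if (check_cooccurrence) {
    groups <- lapply(detect_cooccurrence(occs), `[[`, "families")
    want_g <- truth$cooccurrence
    if (!(length(groups) == length(want_g) &&
          all(mapply(setequal, groups, want_g))))
      probs <- c(probs, "co-occurrence groups")
  }
  probs
}

# a randomized but always-consistent perturbation spec for a built genome:
# targets are distinct coding members that are present and unflagged
random_perturbation_spec <- function(built, seed) {
  truth <- built$truth
  reg <- default_registry()
  coding <- reg$genes$name[reg$genes$coding]
  withr::with_seed(seed, {
    pool <- unique(unlist(lapply(truth$models, function(tm) unlist(tm$segments))))
    pool <- setdiff(intersect(pool, coding),
                    c(unlist(lapply(truth$models, `[[`, "pseudo_members")),
                      unlist(lapply(truth$models, `[[`, "partial_members")),
                      unname(truth$rescuable)))
    pool <- sample(pool)
    take <- function(n) { out <- utils::head(pool, n); pool <<- utils::tail(pool, -n); out }
    ops <- list()
    if (runif(1) < 0.5 && length(pool) >= 1) {
      tm <- truth$models[[sample(length(truth$models), 1)]]
      seg <- tm$segments[[sample(length(tm$segments), 1)]]
      seg <- intersect(seg, pool)
      if (length(seg) >= 2) {
        gene <- seg[sample(length(seg) - 1, 1)]
        pool <- setdiff(pool, gene)
        ops <- c(ops, list(list(op = "split_at", after = gene, distance = 5L)))
      }
    }
    if (runif(1) < 0.4 && length(pool) >= 2)
      ops <- c(ops, list(list(op = "relabel_hp", genes = as.list(take(2)))))
    if (runif(1) < 0.35 && length(pool) >= 1)
      ops <- c(ops, list(list(op = "mark_pseudo", gene = take(1))))
    if (runif(1) < 0.35 && length(pool) >= 1)
      ops <- c(ops, list(list(op = "truncate_partial", gene = take(1), fraction = 0.4)))
    if (runif(1) < 0.3 && length(pool) >= 1)
      ops <- c(ops, list(list(op = "delete", genes = as.list(take(1)))))
    if (runif(1) < 0.3 && length(pool) >= 1)
      ops <- c(ops, list(list(op = "insert", gene = "Hsp20", after = take(1))))
    if (runif(1) < 0.25) {
      tm <- truth$models[[sample(length(truth$models), 1)]]
      seg <- tm$segments[[sample(length(tm$segments), 1)]]
      if (length(seg) >= 1)
        ops <- c(ops, list(list(op = "invert", from = seg[1], to = seg[length(seg)])))
    }
    fragmented <- runif(1) < 0.3
    if (fragmented)
      ops <- c(ops, list(list(op = "fragment_contigs", k = sample(2:3, 1))))
    list(spec = list(seed = seed, ops = ops), fragmented = fragmented)
  })
}
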