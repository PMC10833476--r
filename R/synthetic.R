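AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

templates_db <- function() {
  if (is.null(.rpc_env$templates))
    .rpc_env$templates <- jsonlite::read_json(rpc_extdata("templates.json"))
  .rpc_env$templates
}

#' List the packaged synthetic genome templates
#'
#' @return Data frame of template names, variants and descriptions.
#' @export
list_templates <- function() {
  db <- templates_db()
  data.frame(name = names(db),
             variant = vapply(db, `[[`, "", "variant"),
             description = vapply(db, `[[`, "", "description"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deterministic synthetic protein sequence for a registered gene
#'
#' Every registered gene has a fixed base sequence (drawn once from a
#' gene-specific RNG stream, at the reference length recorded in the
#' registry) which is point-mutated at `mutation_rate` under the given
#' seed. The same (gene, seed, rate) triple always yields the same string;
#' rate 0 yields the base sequence used by the default reference panel.
#'
#' @param gene Canonical gene name.
#' @param seed Integer seed for the mutation stream.
#' @param mutation_rate Per-residue substitution probability in `[0, 1)`.
#' @param registry A `cluster_registry`.
#' @return Amino-acid string.
#' @export
generate_protein_seq <- function(gene, seed, mutation_rate = 0,
                                 registry = default_registry()) {
  len <- gene_length(gene, registry)
  if (is.na(len))
    rpc_registry_error(paste0("unregistered gene: ", gene))
  if (mutation_rate < 0 || mutation_rate >= 1)
    rpc_input_error("mutation_rate must be in [0, 1)")
  base <- with_seed(str_hash(paste0("base::", gene)),
                    sample(AA20, len, replace = TRUE))
  if (mutation_rate > 0) {
    with_seed(hash_combine(str_hash(paste0("mut::", gene)), seed), {
      hit <- which(stats::runif(len) < mutation_rate)
      for (i in hit) base[i] <- sample(setdiff(AA20, base[i]), 1L)
    })
  }
  paste(base, collapse = "")
}

# random background proteins kept dissimilar from every panel entry:
# rejection sampling enforces global identity (matches over reference
# length) < max_identity AND that no panel entry would fire the rescue
# acceptance rule on the filler (with a safety margin), so rescue never
# triggers on background; batched so one genome needs few alignment calls
filler_proteins <- function(tags, seed, panel, len = 60L, max_identity = 0.2,
                            min_identity = 0.30, min_coverage = 0.50) {
  out <- stats::setNames(rep(NA_character_, length(tags)), tags)
  pending <- tags
  for (try in 1:25) {
    cand <- vapply(pending, function(tag)
      with_seed(hash_combine(hash_combine(str_hash(tag), seed), try),
                paste(sample(AA20, len, replace = TRUE), collapse = "")), "")
    if (is.null(panel)) { out[pending] <- cand; return(out) }
    ga <- panel_align(unname(cand), panel)
    bad <- ga$global_identity >= max_identity |
      (ga$identity >= 0.9 * min_identity & ga$coverage >= 0.9 * min_coverage)
    ok <- !vapply(split(bad, ga$query), any, TRUE)
    out[pending[ok]] <- cand[ok]
    pending <- pending[!ok]
    if (length(pending) == 0L) return(out)
  }
  rpc_input_error("could not sample background proteins distant from the panel")
}

filler_protein <- function(tag, seed, panel, len = 60L, max_identity = 0.2) {
  unname(filler_proteins(tag, seed, panel, len, max_identity)[tag])
}

#' Build a synthetic genome with planted truth from a packaged template
#'
#' Templates transcribe the cluster arrangements and annotation
#' pathologies described for the study's genomes (complete Asgard core,
#' bacterial S10+spc block, B. subtilis str region, the bin6 three-way
#' split, B-35 hypothetical-protein mislabels, the Thorarchaeote Hsp20
#' insertion with a uL18 pseudogene, the bin132 missing uL3-uL4-uL23, the
#' AR10 superstring, and the PR6 strand mosaic). The generated annotation
#' carries deterministic protein sequences: cluster members at
#' `1 - mutation_rate` expected identity to the default reference panel,
#' background genes kept below 20% global identity to every panel entry by
#' rejection sampling.
#'
#' @param name Template name (see [list_templates()]).
#' @param seed Integer seed; the same (name, seed) yields byte-identical
#'   output files.
#' @param include_proteins Attach protein sequences (default `TRUE`).
#' @param registry A `cluster_registry`.
#' @param panel Reference panel used for background-sequence rejection
#'   sampling; defaults to [default_reference_panel()].
#' @return List with `annotation` (a [genome_annotation]) and `truth`
#'   (a `planted_truth` object consumed by tests and reports).
#' @export
build_from_template <- function(name, seed, include_proteins = TRUE,
                                registry = default_registry(), panel = NULL) {
  db <- templates_db()
  tpl <- db[[name]]
  if (is.null(tpl))
    rpc_input_error(paste0("unknown template '", name, "'; available: ",
                           paste(names(db), collapse = ", ")))
  if (include_proteins && is.null(panel)) panel <- default_reference_panel(registry)
  rate <- tpl$mutation_rate
  counter <- 0L
  recs <- list(); contig_rows <- list()
  rescuable <- character(); gene_of_locus <- character()
  prefix <- toupper(gsub("[^A-Za-z0-9]", "", name))
  for (ct in tpl$contigs) {
    pos <- 1L
    for (blk in ct$blocks) {
      toks <- if (identical(blk$kind, "filler")) rep("HP", blk$n)
              else as.character(unlist(blk$genes))
      strand <- if (identical(blk$kind, "filler")) "+" else blk$strand
      pseudo_set <- if (is.null(blk$pseudo)) character() else unlist(blk$pseudo)
      hp_set <- if (is.null(blk$hp_relabel)) character() else unlist(blk$hp_relabel)
      partial_set <- if (is.null(blk$partial)) character() else unlist(blk$partial)
      for (tok in toks) {
        counter <- counter + 1L
        locus <- sprintf("%s_%04d", prefix, counter)
        if (tok == "HP") {
          aa <- 60L
          rec <- list(feature = "CDS", contig_id = ct$id, start = pos,
                      end = pos + 3L * (aa + 1L) - 1L,
                      strand = strand, locus_tag = locus, symbol = "",
                      product = "hypothetical protein", pseudo = FALSE,
                      partial = FALSE, protein_seq = NA_character_)
        } else {
          gi <- match(tok, registry$genes$name)
          if (is.na(gi))
            rpc_input_error(paste0("template gene not in registry: ", tok))
          coding <- registry$genes$coding[gi]
          aa <- registry$genes$length[gi]
          is_pseudo <- tok %in% pseudo_set
          is_hp <- tok %in% hp_set
          is_partial <- tok %in% partial_set
          seq <- if (include_proteins && coding && !is_pseudo)
            generate_protein_seq(tok, seed, rate, registry) else NA_character_
          if (is_partial && !is.na(seq)) seq <- substr(seq, 1L, max(3L, floor(0.4 * nchar(seq))))
          nt <- if (coding) 3L * ((if (!is.na(seq)) nchar(seq) else aa) + 1L) else 85L
          rec <- list(feature = if (coding) "CDS" else "tRNA",
                      contig_id = ct$id,
                      start = pos, end = pos + nt - 1L, strand = strand,
                      locus_tag = locus, symbol = "",
                      product = if (is_hp) "hypothetical protein" else registry$genes$product[gi],
                      pseudo = is_pseudo, partial = is_partial, protein_seq = seq)
          gene_of_locus[locus] <- tok
          if (is_hp) rescuable[locus] <- tok
        }
        recs[[length(recs) + 1L]] <- rec
        pos <- rec$end + 31L
      }
    }
    contig_rows[[length(contig_rows) + 1L]] <-
      data.frame(contig_id = ct$id, length = pos - 31L, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (include_proteins) {
    bg <- which(genes$product == "hypothetical protein" &
                  !genes$locus_tag %in% names(rescuable))
    if (length(bg)) {
      tags <- paste0(name, "::", genes$locus_tag[bg])
      genes$protein_seq[bg] <- unname(filler_proteins(tags, seed, panel))
    }
  }
  ann <- genome_annotation(paste0(name, "-s", seed), genes,
                           contigs = do.call(rbind, contig_rows))
  truth <- truth_from_template(tpl, name, seed, ann, rescuable, gene_of_locus, registry)
  list(annotation = ann, truth = truth)
}

# materialize the transcribed truth: per-model expected segments as member
# name lists (genome order partitioned by the recorded segment sizes)
truth_from_template <- function(tpl, name, seed, ann, rescuable, gene_of_locus,
                                registry) {
  models <- lapply(tpl$truth$models, function(tm) {
    model <- get_cluster_model(tm$model, tm$variant, registry)
    hits <- gene_of_locus[gene_of_locus %in% model$members]
    sizes <- as.integer(unlist(tm$segment_sizes))
    if (sum(sizes) != length(hits))
      rpc_input_error(paste0("template truth inconsistent for ", tm$model))
    seg_end <- cumsum(sizes)
    segments <- lapply(seq_along(sizes), function(i)
      unname(hits[(c(0L, seg_end)[i] + 1L):seg_end[i]]))
    list(model = tm$model, variant = tm$variant, status = tm$status,
         n_segments = as.integer(tm$n_segments),
         segments = segments,
         missing = as.character(unlist(tm$missing)),
         insertions = as.character(unlist(tm$insertions)),
         pseudo_members = as.character(unlist(tm$pseudo_members)),
         partial_members = as.character(unlist(tm$partial_members)),
         orientations = if (length(tm$orientations) == 0L) NULL
                        else as.character(unlist(tm$orientations)))
  })
  names(models) <- vapply(models, function(m) paste0(m$model, "/", m$variant), "")
  truth <- list(template = name, seed = seed, variant = tpl$variant,
                mutation_rate = tpl$mutation_rate,
                genome_id = ann$genome_id,
                n_contigs = length(tpl$contigs),
                models = models,
                cooccurrence = lapply(tpl$truth$cooccurrence,
                                      function(g) as.character(unlist(g))),
                concerns = as.character(unlist(tpl$truth$concerns)),
                rescuable = rescuable,
                gene_of_locus = gene_of_locus)
  class(truth) <- "planted_truth"
  truth
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>", x$template, "seed", x$seed, "-", length(x$models),
      "expected model occurrence(s)\n")
  for (m in x$models)
    cat("  ", m$model, "/", m$variant, ": ", m$status, ", ",
        m$n_segments, " segment(s)\n", sep = "")
  invisible(x)
}

# status classification rule shared with the documentation: recomputed
# here from planted structure, independently of the mapping code path
truth_status <- function(n_members, missing, n_segments, allowed_missing = 2L) {
  found <- n_members - length(missing)
  if (found == 0L) "absent"
  else if (length(missing) == 0L && n_segments == 1L) "complete_contiguous"
  else if (n_segments >= 2L && length(missing) <= allowed_missing) "split"
  else "partial"
}

locus_of_gene <- function(truth, gene) {
  hit <- names(truth$gene_of_locus)[truth$gene_of_locus == gene]
  if (length(hit) == 0L)
    rpc_input_error(paste0("perturbation references absent gene: ", gene))
  hit[1L]
}

refresh_model_truth <- function(tm, registry) {
  model <- get_cluster_model(tm$model, tm$variant, registry)
  tm$segments <- Filter(length, tm$segments)
  tm$n_segments <- length(tm$segments)
  tm$status <- truth_status(length(model$members), tm$missing, tm$n_segments)
  # segment structure changed: recorded orientation expectations no longer apply
  tm$orientations <- NULL
  tm
}

#' Apply a seeded perturbation list to a synthetic genome
#'
#' Perturbations emulate the annotation pathologies of real MAGs and are
#' applied in order, keeping the planted truth consistent: `split_at`
#' inserts a run of background genes after a named gene (incrementing the
#' expected segment count of every affected model), `relabel_hp` hides
#' members behind "hypothetical protein" labels (recorded as rescuable),
#' `mark_pseudo`, `truncate_partial` and `delete` update the expected
#' pseudo/partial/missing sets, `insert` places a foreign gene inside a
#' cluster (recorded as an expected insertion), `fragment_contigs` breaks
#' the genome into `k` contigs at points outside planted segments, and
#' `invert` reverse-complements a block in place.
#'
#' @param ann A [genome_annotation] from [build_from_template()].
#' @param truth Its `planted_truth`.
#' @param spec List with `seed` and `ops`, each op a list with an `op`
#'   field (see details) and its arguments.
#' @param registry A `cluster_registry`.
#' @param panel Panel for background sequences (defaults to the synthetic
#'   panel when needed).
#' @return List with updated `annotation` and `truth`.
#' @export
perturb <- function(ann, truth, spec, registry = default_registry(), panel = NULL) {
  seed <- spec$seed %||% truth$seed
  include_proteins <- any(!is.na(ann$genes$protein_seq))
  if (include_proteins && is.null(panel)) panel <- default_reference_panel(registry)
  for (k in seq_along(spec$ops)) {
    op <- spec$ops[[k]]
    g <- ann$genes
    switch(op$op,
      split_at = {
        distance <- op$distance %||% 5L
        locus <- locus_of_gene(truth, op$after)
        at <- match(locus, g$locus_tag)
        ins <- lapply(seq_len(distance), function(i) {
          lt <- sprintf("SPLIT%02d_%04d", k, i)
          seq <- if (include_proteins)
            filler_protein(paste0(truth$template, "::", lt), seed, panel) else NA_character_
          data.frame(contig_id = g$contig_id[at], start = 0L, end = 0L,
                     strand = "+", locus_tag = lt, symbol = "",
                     product = "hypothetical protein", pseudo = FALSE,
                     partial = FALSE, contig_edge = FALSE, protein_seq = seq,
                     feature = "CDS", stringsAsFactors = FALSE)
        })
        g <- rbind(g[seq_len(at), ], do.call(rbind, ins),
                   if (at < nrow(g)) g[(at + 1L):nrow(g), ])
        ann <- relayout(ann, g)
        gene <- op$after
        truth$models <- lapply(truth$models, function(tm) {
          for (si in seq_along(tm$segments)) {
            pos <- match(gene, tm$segments[[si]])
            if (!is.na(pos) && pos < length(tm$segments[[si]])) {
              before <- tm$segments[[si]][seq_len(pos)]
              after <- tm$segments[[si]][(pos + 1L):length(tm$segments[[si]])]
              tm$segments <- append(tm$segments[-si], list(before, after), after = si - 1L)
              break
            }
          }
          refresh_model_truth(tm, registry)
        })
      },
      relabel_hp = {
        for (gene in unlist(op$genes)) {
          locus <- locus_of_gene(truth, gene)
          i <- match(locus, g$locus_tag)
          g$product[i] <- "hypothetical protein"; g$symbol[i] <- ""
          if (include_proteins && is.na(g$protein_seq[i]))
            g$protein_seq[i] <- generate_protein_seq(gene, seed,
                                                     truth$mutation_rate, registry)
          truth$rescuable[locus] <- gene
        }
        ann$genes <- g
      },
      mark_pseudo = {
        locus <- locus_of_gene(truth, op$gene)
        g$pseudo[match(locus, g$locus_tag)] <- TRUE
        ann$genes <- g
        truth$models <- lapply(truth$models, function(tm) {
          model <- get_cluster_model(tm$model, tm$variant, registry)
          if (op$gene %in% model$members && !op$gene %in% tm$missing)
            tm$pseudo_members <- sort(union(tm$pseudo_members, op$gene))
          tm
        })
      },
      truncate_partial = {
        locus <- locus_of_gene(truth, op$gene)
        i <- match(locus, g$locus_tag)
        frac <- op$fraction %||% 0.4
        if (!is.na(g$protein_seq[i]))
          g$protein_seq[i] <- substr(g$protein_seq[i], 1L,
                                     max(3L, floor(frac * nchar(g$protein_seq[i]))))
        g$end[i] <- g$start[i] +
          3L * ((if (!is.na(g$protein_seq[i])) nchar(g$protein_seq[i])
                 else max(3L, floor(frac * (g$end[i] - g$start[i] + 1L) %/% 3L))) + 1L) - 1L
        g$partial[i] <- TRUE
        ann <- relayout(ann, g)
        truth$models <- lapply(truth$models, function(tm) {
          model <- get_cluster_model(tm$model, tm$variant, registry)
          if (op$gene %in% model$members && !op$gene %in% tm$missing)
            tm$partial_members <- sort(union(tm$partial_members, op$gene))
          tm
        })
      },
      delete = {
        for (gene in unlist(op$genes)) {
          locus <- locus_of_gene(truth, gene)
          g <- g[g$locus_tag != locus, , drop = FALSE]
          truth$gene_of_locus <- truth$gene_of_locus[names(truth$gene_of_locus) != locus]
          truth$rescuable <- truth$rescuable[names(truth$rescuable) != locus]
          truth$models <- lapply(truth$models, function(tm) {
            model <- get_cluster_model(tm$model, tm$variant, registry)
            if (gene %in% model$members) {
              tm$segments <- lapply(tm$segments, function(s) setdiff(s, gene))
              tm$missing <- sort(union(tm$missing, gene))
              tm <- refresh_model_truth(tm, registry)
            }
            tm
          })
        }
        ann$genes <- g
        ann <- relayout(ann, g)
      },
      insert = {
        locus <- locus_of_gene(truth, op$after)
        at <- match(locus, g$locus_tag)
        gi <- match(op$gene, registry$genes$name)
        if (is.na(gi)) rpc_input_error(paste0("insert of unregistered gene ", op$gene))
        lt <- sprintf("INS%02d_%s", k, op$gene)
        seq <- if (include_proteins && registry$genes$coding[gi])
          generate_protein_seq(op$gene, seed, truth$mutation_rate, registry) else NA_character_
        row <- data.frame(contig_id = g$contig_id[at], start = 0L, end = 0L,
                          strand = g$strand[at], locus_tag = lt, symbol = "",
                          product = registry$genes$product[gi], pseudo = FALSE,
                          partial = FALSE, contig_edge = FALSE, protein_seq = seq,
                          feature = if (registry$genes$coding[gi]) "CDS" else "tRNA",
                          stringsAsFactors = FALSE)
        g <- rbind(g[seq_len(at), ], row, if (at < nrow(g)) g[(at + 1L):nrow(g), ])
        ann <- relayout(ann, g)
        truth$models <- lapply(truth$models, function(tm) {
          model <- get_cluster_model(tm$model, tm$variant, registry)
          if (op$gene %in% c(model$members, model$accessory)) return(tm)
          inside <- any(vapply(tm$segments, function(s) {
            pos <- match(op$after, s)
            !is.na(pos) && pos < length(s)
          }, TRUE))
          if (inside) tm$insertions <- c(tm$insertions, op$gene)
          tm
        })
      },
      fragment_contigs = {
        k_target <- as.integer(op$k)
        ann <- fragment_annotation(ann, truth, k_target, seed, registry)
        truth$n_contigs <- nrow(ann$contigs)
      },
      invert = {
        from <- locus_of_gene(truth, op$from); to <- locus_of_gene(truth, op$to)
        i <- match(from, g$locus_tag); j <- match(to, g$locus_tag)
        if (i > j) { tmp <- i; i <- j; j <- tmp }
        rng <- i:j
        block <- g[rev(rng), , drop = FALSE]
        block$strand <- ifelse(block$strand == "+", "-", "+")
        g[rng, ] <- block
        ann <- relayout(ann, g)
        # statuses and segment structure are orientation-invariant; recorded
        # orientation expectations are dropped for the affected models
        truth$models <- lapply(truth$models, function(tm) {
          touched <- any(vapply(tm$segments, function(s)
            any(s %in% truth$gene_of_locus[g$locus_tag[rng]]), TRUE))
          if (touched) tm$orientations <- NULL
          tm
        })
      },
      rpc_input_error(paste0("unknown perturbation op: ", op$op))
    )
  }
  truth$concerns <- recompute_concerns(truth, registry)
  list(annotation = ann, truth = truth)
}

# re-derive the expected assembly concerns from the planted structure
# (the same rules flag_assembly_concerns documents, applied to truth)
recompute_concerns <- function(truth, registry, partial_threshold = 0.10) {
  found <- unique(unlist(lapply(truth$models, function(tm)
    setdiff(get_cluster_model(tm$model, tm$variant, registry)$members, tm$missing))))
  pseudo <- unique(unlist(lapply(truth$models, `[[`, "pseudo_members")))
  partial <- unique(unlist(lapply(truth$models, `[[`, "partial_members")))
  core14 <- get_cluster_model("S10-spc-core", "bacterial", registry)$core
  concerns <- character()
  if (length(setdiff(c("uL3", "uL4", "uL23"), found)))
    concerns <- c(concerns, "universal_genes_missing")
  if (length(intersect(pseudo, core14)))
    concerns <- c(concerns, "universal_gene_pseudo")
  if ((truth$n_contigs %||% 1L) == 1L &&
      any(vapply(truth$models, function(tm)
        tm$model == "S10-spc-core" && tm$n_segments >= 2L, TRUE)))
    concerns <- c(concerns, "core_split")
  if (length(found) && length(partial) / length(found) >= partial_threshold)
    concerns <- c(concerns, "high_partial_fraction")
  concerns
}

# recompute gene coordinates after structural edits: genes keep their
# order, spacing is re-laid deterministically (30 bp intergenic)
relayout <- function(ann, genes = ann$genes) {
  out <- list(); ctg <- list()
  for (cid in unique(genes$contig_id)) {
    rows <- genes[genes$contig_id == cid, , drop = FALSE]
    pos <- 1L
    for (i in seq_len(nrow(rows))) {
      w <- rows$end[i] - rows$start[i]
      if (w < 0L || rows$start[i] == 0L)
        w <- 3L * ((if (!is.na(rows$protein_seq[i])) nchar(rows$protein_seq[i]) else 60L) + 1L) - 1L
      rows$start[i] <- pos; rows$end[i] <- pos + w
      pos <- rows$end[i] + 31L
    }
    rows$contig_edge <- FALSE
    out[[length(out) + 1L]] <- rows
    ctg[[length(ctg) + 1L]] <- data.frame(contig_id = cid, length = pos - 31L,
                                          stringsAsFactors = FALSE)
  }
  genome_annotation(ann$genome_id, do.call(rbind, out), contigs = do.call(rbind, ctg))
}

fragment_annotation <- function(ann, truth, k, seed, registry) {
  if (k < 2L) return(ann)
  g <- ann$genes
  # candidate breakpoints: boundaries not crossed by any planted segment
  member_rows <- lapply(truth$models, function(tm) {
    lapply(tm$segments, function(s) {
      loci <- names(truth$gene_of_locus)[match(s, truth$gene_of_locus)]
      range(match(loci, g$locus_tag))
    })
  })
  blocked <- rep(FALSE, nrow(g) - 1L)
  for (tm in member_rows) for (r in tm)
    if (all(is.finite(r)) && r[2] > r[1]) blocked[r[1]:(r[2] - 1L)] <- TRUE
  cand <- which(!blocked)
  if (length(cand) < k - 1L)
    rpc_input_error("not enough breakpoints outside planted segments")
  cuts <- sort(with_seed(hash_combine(str_hash("fragment"), seed),
                         sample(cand, k - 1L)))
  cid_new <- paste0("c", findInterval(seq_len(nrow(g)), cuts + 1L) + 1L)
  g$contig_id <- cid_new
  relayout(ann, g)
}

#' Write a synthetic genome bundle
#'
#' Emits `genome.gff3`, `proteins.faa`, `feature_table.txt` and
#' `truth.json` into a directory.
#'
#' @param built Result of [build_from_template()] / [perturb()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_genome_bundle <- function(built, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gff3(built$annotation, file.path(dir, "genome.gff3"))
  write_feature_table(built$annotation, file.path(dir, "feature_table.txt"))
  write_protein_fasta(built$annotation, file.path(dir, "proteins.faa"))
  tr <- built$truth
  tr$gene_of_locus <- as.list(tr$gene_of_locus)
  tr$rescuable <- as.list(tr$rescuable)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
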