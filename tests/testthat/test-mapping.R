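test_that("a complete archaeal core maps to one contiguous segment", {
  built <- test_build("asgard_core", 1)
  occ <- map_cluster(built$annotation, get_cluster_model("S10-spc-core", "archaeal"))
  expect_identical(occ$status, "complete_contiguous")
  expect_length(occ$segments, 1L)
  expect_length(occ$missing, 0L)
  expect_equal(nrow(occ$insertions), 0L)
  expect_identical(occ$segments[[1]]$orientation, "forward")
  # hits come back in model order
  mh <- occ$segments[[1]]$hits
  expect_identical(mh$gene[!mh$accessory],
                   get_cluster_model("S10-spc-core", "archaeal")$members)
})

test_that("the bin6 emulation splits into three segments with ten genes first", {
  built <- test_build("bin6_split", 1)
  occ <- map_cluster(built$annotation, get_cluster_model("S10-spc-core", "archaeal"))
  expect_identical(occ$status, "split")
  expect_length(occ$segments, 3L)
  sizes <- vapply(occ$segments, function(s) sum(!s$hits$accessory), 1L)
  expect_equal(sizes, c(10L, 2L, 6L))
  expect_identical(occ$missing, "uS19")
})

test_that("degenerate inputs map to absent without errors", {
  empty <- genome_annotation("void",
    data.frame(contig_id = "c1", start = 1L, end = 90L, strand = "+",
               locus_tag = "X1", product = "hypothetical protein",
               stringsAsFactors = FALSE))
  occ <- map_cluster(empty, get_cluster_model("L7ae", "archaeal"))
  expect_identical(occ$status, "absent")
  expect_length(occ$segments, 0L)
  expect_setequal(occ$missing, get_cluster_model("L7ae", "archaeal")$members)
  expect_error(map_cluster(empty, get_cluster_model("L7ae", "archaeal"),
                           gap_tolerance = -1), class = "rpc_input_error")
})

test_that("named foreign genes inside a segment are reported as insertions in order", {
  built <- test_build("thor_hsp20", 1)
  occ <- map_cluster(built$annotation, get_cluster_model("S10-spc-core", "archaeal"))
  expect_identical(occ$insertions$gene, "Hsp20")
  expect_identical(occ$insertions$after_member, "uS14")
  expect_identical(occ$insertions$before_member, "uS8")
  expect_identical(occ$pseudo_members, "uL18")
  expect_identical(occ$status, "complete_contiguous")
  # two adjacent foreign genes inside a tolerant segment: both reported,
  # genome order preserved
  toks <- c("uL22", "uS3", "Hsp20", "ftsZ", "uL29", "uS17")
  ann <- toy_annotation(toks)
  occ2 <- map_cluster(ann, get_cluster_model("S10-spc-core", "archaeal"),
                      gap_tolerance = 2)
  expect_identical(occ2$insertions$gene, c("Hsp20", "ftsZ"))
  # every reported insertion lies strictly inside the segment index range
  s <- occ2$segments[[1]]
  idx <- match(occ2$insertions$locus_tag, ann$genes$locus_tag) - 1L
  expect_true(all(idx > s$first_index & idx < s$last_index))
})

test_that("unnamed hypothetical spacers count against the gap but are not insertions", {
  toks <- c("uL22", "uS3", "HP", "uL29", "HP", "HP", "HP", "uS17")
  ann <- toy_annotation(toks)
  model <- get_cluster_model("S10-spc-core", "archaeal")
  occ <- map_cluster(ann, model, gap_tolerance = 2)
  expect_length(occ$segments, 2L)                 # 3 HPs split the run
  expect_equal(nrow(occ$insertions), 0L)          # 1 HP inside is tolerated silently
  occ3 <- map_cluster(ann, model, gap_tolerance = 3)
  expect_length(occ3$segments, 1L)
})

test_that("accessory genes neither break runs nor count as insertions", {
  toks <- c("uS19", "uL22", "uS3", "uL29", "SUI1", "RNP1", "uS17")
  occ <- map_cluster(toy_annotation(toks),
                     get_cluster_model("S10-spc-core", "archaeal"))
  expect_length(occ$segments, 1L)
  expect_equal(nrow(occ$insertions), 0L)
  h <- occ$segments[[1]]$hits
  expect_true(h$accessory[h$gene == "SUI1"])
})

test_that("segment grouping equals the definition-based oracle on small genomes", {
  reg <- default_registry()
  model <- get_cluster_model("S10-spc-core", "archaeal")
  vocab <- c(model$members, model$accessory, "HP", "ftsZ", "Hsp20", "rbsK")
  withr::with_seed(99, {
    for (k in 1:40) {
      n <- sample(5:30, 1)
      toks <- sample(vocab, n, replace = TRUE)
      gt <- sample(0:3, 1)
      ann <- toy_annotation(toks, genome_id = paste0("rand", k))
      occ <- map_cluster(ann, model, gap_tolerance = gt, registry = reg)
      want <- segment_oracle(ann, model, gt, reg)
      # paralog pruning may drop runs carrying only duplicate names; the
      # oracle enumerates raw runs, so compare on the pruned subset
      got <- lapply(occ$segments, function(s) s$hits$locus_tag[!s$hits$accessory])
      kept <- want[vapply(want, function(w)
        any(vapply(got, function(g) identical(g, w), TRUE)), TRUE)]
      expect_identical(length(got), length(kept))
      # and every member name found by the oracle is found by the mapper
      oracle_names <- unique(canonical_of_loci(ann, unlist(want), reg))
      expect_setequal(occ$found, oracle_names)
      # conservation: found + missing = model size
      expect_equal(length(occ$found) + length(occ$missing), length(model$members))
    }
  })
})

test_that("segment count is monotone non-increasing in the gap tolerance", {
  for (tpl in c("bin6_split", "ar10", "pr6_strand_mix")) {
    ann <- test_build(tpl, 1)$annotation
    for (model in list(get_cluster_model("S10-spc-core", "archaeal"),
                       get_cluster_model("L31e", "archaeal"))) {
      prev <- Inf
      for (gt in c(0, 1, 2, 5, 10, 50, 10000)) {
        occ <- map_cluster(ann, model, gap_tolerance = gt)
        expect_lte(length(occ$segments), prev)
        prev <- length(occ$segments)
      }
      # at genome-scale tolerance all hits on one contig form one segment
      expect_lte(prev, nrow(ann$contigs))
    }
  }
})

test_that("mapping is invariant under reverse-complementing the genome", {
  for (tpl in c("asgard_core", "bin6_split", "ar10", "thor_hsp20")) {
    ann <- test_build(tpl, 1)$annotation
    rc <- rc_annotation(ann)
    for (m in Filter(function(m) m$variant == "archaeal",
                     default_registry()$models)) {
      a <- map_cluster(ann, m); b <- map_cluster(rc, m)
      expect_identical(a$status, b$status, info = paste(tpl, m$name))
      expect_identical(length(a$segments), length(b$segments))
      expect_setequal(a$missing, b$missing)
      expect_setequal(a$insertions$gene, b$insertions$gene)
      # presentation order still reads in model order on both strands
      fwd_sizes <- sort(vapply(a$segments, function(s) nrow(s$hits), 1L))
      rev_sizes <- sort(vapply(b$segments, function(s) nrow(s$hits), 1L))
      expect_identical(fwd_sizes, rev_sizes)
    }
  }
})

test_that("segment orientation follows model order with a forward tie convention", {
  # a clean template emitted on the minus strand in reversed order
  ann <- test_build("asgard_core", 1)$annotation
  rc <- rc_annotation(ann)
  model <- get_cluster_model("S10-spc-core", "archaeal")
  occ <- map_cluster(rc, model)
  expect_identical(occ$status, "complete_contiguous")
  expect_identical(occ$segments[[1]]$orientation, "reverse")
  h <- occ$segments[[1]]$hits
  expect_identical(rev(h$gene[!h$accessory]), model$members)
  # single-gene segment: forward by convention
  occ1 <- map_cluster(toy_annotation("uL22", strand = "-"), model)
  expect_identical(occ1$segments[[1]]$orientation, "forward")
  # PR6-like alternating strands: per-segment orientations differ
  pr6 <- test_build("pr6_strand_mix", 1)
  l31 <- map_cluster(pr6$annotation, get_cluster_model("L31e", "archaeal"))
  expect_identical(vapply(l31$segments, `[[`, "", "orientation"),
                   c("forward", "reverse"))
  expect_identical(l31$status, "split")
})

test_that("duplicate member copies are reported as extras, not new segments", {
  toks <- c("uL22", "uS3", "uS3", "uL29", "uS17")
  occ <- map_cluster(toy_annotation(toks),
                     get_cluster_model("S10-spc-core", "archaeal"))
  expect_length(occ$segments, 1L)
  expect_equal(occ$extra_copies$gene, "uS3")
  expect_equal(sum(occ$found == "uS3"), 1L)
  # a distant lone duplicate of an already-found gene is an extra copy
  toks2 <- c("uL22", "uS3", "uL29", rep("HP", 6), "uS3")
  occ2 <- map_cluster(toy_annotation(toks2),
                      get_cluster_model("S10-spc-core", "archaeal"))
  expect_length(occ2$segments, 1L)
  expect_equal(occ2$extra_copies$gene, "uS3")
})

test_that("co-occurrence groups reproduce the AR10 and B. subtilis neighborhoods", {
  ar10 <- test_build("ar10", 1)
  occs <- map_genome(ar10$annotation, "archaeal")
  groups <- detect_cooccurrence(occs)
  fams <- lapply(groups, `[[`, "families")
  big <- fams[[which.max(lengths(fams))]]
  expect_setequal(big, c("S10-spc", "str-L30e", "alpha-L18e", "L7ae-S24e"))
  expect_false("L31e-L11" %in% big)
  expect_true(any(vapply(fams, function(f) identical(f, "L31e-L11"), TRUE)))
  # B. subtilis-like: the str cluster is adjacent to the L11-containing family
  bs <- test_build("bsubtilis_str", 1)
  gb <- detect_cooccurrence(map_genome(bs$annotation, "bacterial"))
  fb <- lapply(gb, `[[`, "families")
  joint <- fb[[which(vapply(fb, function(f) "str-L30e" %in% f, TRUE))]]
  expect_true("L31e-L11" %in% joint)
  # two clusters on different contigs never group
  two <- genome_annotation("twoctg", rbind(
    toy_annotation(c("uL11", "uL1"), contig_id = "cA", locus_prefix = "A")$genes,
    toy_annotation(c("uL10", "uL12", "rpoB", "rpoC", "uS12", "uS7", "fusA",
                     "tufA", "ybaC"), contig_id = "cB", locus_prefix = "B")$genes))
  occs2 <- map_genome(two, "bacterial")
  g2 <- lapply(detect_cooccurrence(occs2), `[[`, "families")
  expect_true(all(lengths(g2) == 1L))
})
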