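# merA anchoring, operon-run growth, architecture/completeness/spectrum
# classification, merging and context annotation.

test_that("anchor finding matches the merA lexicon only", {
  g <- mk_genome(list(
    list(1000, 2650, "+", "", "mercuric reductase MerA"),
    list(3000, 3800, "+", "", "copper oxidase"),
    list(5000, 5900, "+", "", "DNA polymerase III subunit")))
  expect_equal(find_mer_anchors(g), "G1_f01")
  g2 <- mk_genome(list(list(100, 900, "+", "", "hypothetical protein")))
  expect_equal(find_mer_anchors(g2), character(0))
})

test_that("word-boundary matching keeps polymerase/isomerase out", {
  g <- mk_genome(list(
    list(1000, 2000, "+", "", "DNA polymerase I"),
    list(3000, 4000, "+", "", "triosephosphate isomerase")))
  expect_equal(find_mer_anchors(g), character(0))
})

test_that("two merA genes on different replicons give two anchors", {
  reps <- data.frame(replicon_id = c("c1", "p1"),
                     length = c(5e4, 5e4), topology = "circular",
                     kind = c("chromosome", "plasmid"),
                     stringsAsFactors = FALSE)
  feat <- data.frame(
    feature_id = c("fA", "fB"), replicon_id = c("c1", "p1"),
    start = c(1000, 2000), end = c(2650, 3650), strand = "+",
    gene_name = "merA", product = "mercuric reductase MerA",
    stringsAsFactors = FALSE)
  g <- new_genome("G2", reps, feat)
  expect_equal(find_mer_anchors(g), c("fA", "fB"))
})

test_that("a planted merR/TPCAB cassette is called complete and broad", {
  g <- mk_genome(lay_genes(c("merR", "merT", "merP", "merC", "merA",
                             "merB"), gap = 120))
  call <- call_operon(g, find_mer_anchors(g)[1])
  expect_equal(call$architecture, "merR-merT-merP-merC-merA-merB")
  expect_true(call$complete)
  expect_equal(call$spectrum, "broad")
  expect_equal(nrow(call$members), 6L)
})

test_that("merF substitutes for transport in completeness", {
  g <- mk_genome(lay_genes(c("merR", "merT", "merP", "merF", "merA")))
  call <- call_operon(g, find_mer_anchors(g)[1])
  expect_true(call$complete)
  expect_equal(call$spectrum, "narrow")
})

test_that("the gap rule isolates a lone merA from distant accessories", {
  rows <- c(lay_genes("merA", at = 10000),
            lay_genes("merT", at = 13400))  # 3 kb away
  g <- mk_genome(rows)
  call <- call_operon(g, find_mer_anchors(g)[1])
  expect_equal(call$architecture, "merA")
  expect_false(call$complete)
  expect_equal(call$spectrum, "narrow")
})

test_that("a divergently transcribed merR is admitted, other strand flips stop the run", {
  rows <- lay_genes(c("merR", "merT", "merP", "merA"),
                    strands = c("-", "+", "+", "+"))
  g <- mk_genome(rows)
  call <- call_operon(g, find_mer_anchors(g)[1])
  expect_equal(call$architecture, "merR-merT-merP-merA")
  expect_true(call$complete)
  p_off <- detector_params(allow_divergent_merR = FALSE)
  call2 <- call_operon(g, find_mer_anchors(g)[1], p_off)
  expect_equal(call2$architecture, "merT-merP-merA")
  # a non-merR gene on the opposite strand always stops the run
  rows3 <- lay_genes(c("merT", "merA", "merB"),
                     strands = c("+", "+", "-"))
  call3 <- call_operon(mk_genome(rows3),
                       find_mer_anchors(mk_genome(rows3))[1])
  expect_equal(call3$architecture, "merT-merA")
})

test_that("at most max_embedded_nonmer hypothetical genes are bridged", {
  rows1 <- lay_genes(c("merA", "hyp", "merD"))
  g1 <- mk_genome(rows1)
  call1 <- call_operon(g1, find_mer_anchors(g1)[1])
  expect_equal(call1$architecture, "merA-hyp-merD")
  rows2 <- lay_genes(c("merA", "hyp", "hyp", "merD"))
  g2 <- mk_genome(rows2)
  call2 <- call_operon(g2, find_mer_anchors(g2)[1])
  expect_equal(call2$architecture, "merA")
})

test_that("minus-strand operons read 5'->3' in the architecture", {
  # genomic left-to-right is merB..merR reversed for a minus cassette
  genes <- c("merB", "merA", "merC", "merP", "merT", "merR")
  g <- mk_genome(lay_genes(genes, strand = "-"))
  call <- call_operon(g, find_mer_anchors(g)[1])
  expect_equal(call$architecture, "merR-merT-merP-merC-merA-merB")
  expect_true(call$complete)
  expect_equal(call$spectrum, "broad")
})

test_that("overlapping calls merge; distinct operons stay separate", {
  g <- mk_genome(lay_genes(c("merR", "merT", "merA", "merA", "merB")))
  anchors <- find_mer_anchors(g)
  expect_length(anchors, 2L)
  calls <- merge_calls(lapply(anchors, function(a) call_operon(g, a)))
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$architecture, "merR-merT-merA-merA-merB")
  expect_equal(merge_calls(list()), list())

  reps <- data.frame(replicon_id = c("c1", "p1"), length = 5e4,
                     topology = "circular",
                     kind = c("chromosome", "plasmid"),
                     stringsAsFactors = FALSE)
  rows1 <- lay_genes(c("merR", "merT", "merA"))
  rows2 <- lay_genes(c("merR", "merT", "merA"))
  feat <- rbind(
    do.call(rbind, lapply(seq_along(rows1), function(i) data.frame(
      feature_id = paste0("a", i), replicon_id = "c1",
      start = rows1[[i]][[1]], end = rows1[[i]][[2]],
      strand = rows1[[i]][[3]], gene_name = rows1[[i]][[4]],
      product = rows1[[i]][[5]], stringsAsFactors = FALSE))),
    do.call(rbind, lapply(seq_along(rows2), function(i) data.frame(
      feature_id = paste0("b", i), replicon_id = "p1",
      start = rows2[[i]][[1]], end = rows2[[i]][[2]],
      strand = rows2[[i]][[3]], gene_name = rows2[[i]][[4]],
      product = rows2[[i]][[5]], stringsAsFactors = FALSE))))
  g2 <- new_genome("G3", reps, feat)
  calls2 <- merge_calls(lapply(find_mer_anchors(g2), function(a)
    call_operon(g2, a)))
  expect_length(calls2, 2L)
})

test_that("context annotation reports tni modules and czc loci with side and distance", {
  op <- lay_genes(c("merR", "merT", "merA"), at = 20000)
  rows <- c(
    list(list(17000, 17400, "+", "tniA", "transposition protein TniA"),
         list(17600, 18000, "+", "tniB", "transposition protein TniB"),
         list(18200, 18600, "+", "tniQ", "transposition protein TniQ")),
    op,
    list(list(23000, 23700, "+", "czcC",
              "cobalt-zinc-cadmium resistance protein CzcC"),
         list(23900, 24600, "+", "czcB",
              "cobalt-zinc-cadmium resistance protein CzcB"),
         list(24800, 25500, "+", "czcA",
              "cobalt-zinc-cadmium resistance protein CzcA")))
  g <- assign_categories(mk_genome(rows))
  call <- call_operon(g, find_mer_anchors(g)[1])
  ctx <- annotate_context(g, call)
  expect_equal(nrow(ctx$flank_mges), 3L)
  expect_true(all(ctx$flank_mges$subtype == "insertion"))
  expect_true(all(ctx$flank_mges$side == "upstream"))
  expect_equal(nrow(ctx$coresident_mrgs), 3L)
  expect_true(all(ctx$coresident_mrgs$subtype == "czc"))
  expect_true(all(ctx$coresident_mrgs$side == "downstream"))
  # nearest edge distances: operon span is [20000, 21400)
  expect_equal(min(ctx$flank_mges$distance), 20000 - 18600)
  expect_equal(min(ctx$coresident_mrgs$distance), 23000 - 21400)
})

test_that("context annotation requires assigned categories and respects the window", {
  g <- mk_genome(lay_genes(c("merR", "merA")))
  call <- call_operon(g, find_mer_anchors(g)[1])
  expect_error(annotate_context(g, call), "assign_categories")
  rows <- c(lay_genes(c("merR", "merA"), at = 20000),
            list(list(35000, 35600, "+", "", "phage tail protein")))
  g2 <- assign_categories(mk_genome(rows))
  call2 <- call_operon(g2, find_mer_anchors(g2)[1])
  ctx2 <- annotate_context(g2, call2)
  expect_equal(nrow(ctx2$flank_mges), 0L)   # 13.6 kb away, outside 10 kb
  expect_equal(nrow(ctx2$coresident_mrgs), 0L)
})

test_that("detection is invariant under feature-order shuffling", {
  sim <- generate_cohort(default_cohort_spec(n_genomes = 4,
                                             n_operon_genomes = 3,
                                             seed = 5))
  co <- sim$cohort
  set.seed(99)
  shuffled <- co
  for (id in names(shuffled$genomes)) {
    f <- shuffled$genomes[[id]]$features
    shuffled$genomes[[id]]$features <- f[sample(nrow(f)), , drop = FALSE]
  }
  d1 <- detect_all(co)
  d2 <- detect_all(shuffled)
  expect_equal(d1$calls[order(d1$calls$call_id), ],
               d2$calls[order(d2$calls$call_id), ],
               ignore_attr = TRUE)
})

test_that("mirror-reversing a replicon mirrors the call set", {
  g <- assign_categories(mk_genome(
    lay_genes(c("merR", "merT", "merP", "merC", "merA", "merB"))))
  call <- call_operon(g, find_mer_anchors(g)[1])
  L <- g$replicons$length
  gm <- g
  gm$features$start <- L - g$features$end
  gm$features$end <- L - g$features$start
  gm$features$strand <- ifelse(g$features$strand == "+", "-", "+")
  gm <- validate_genome(gm)
  callm <- call_operon(gm, find_mer_anchors(gm)[1])
  expect_equal(callm$architecture, call$architecture)
  expect_equal(callm$complete, call$complete)
  expect_equal(callm$spectrum, call$spectrum)
  expect_equal(callm$start, L - call$end)
  expect_equal(callm$end, L - call$start)
})

test_that("cohort-level detection summarizes completeness and merB carriage", {
  spec <- default_cohort_spec(n_genomes = 10, n_operon_genomes = 6,
                              seed = 2)
  sim <- generate_cohort(spec)
  det <- detect_all(sim$cohort)
  truth <- sim$truth$planted_operons
  expect_equal(det$summary$fraction_complete,
               length(unique(truth$genome_id[truth$complete])) / 10)
  neg <- generate_cohort(cohort_spec(n_genomes = 3, seed = 3))
  detn <- detect_all(neg$cohort)
  expect_equal(nrow(detn$calls), 0L)
  expect_equal(detn$summary$fraction_complete, 0)
})
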