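# Synthetic cohort generator: determinism, ground-truth conservation,
# geometric invariants, alignment and family-matrix simulation.

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- default_cohort_spec(n_genomes = 5, n_operon_genomes = 3,
                              seed = 17)
  s1 <- generate_cohort(spec)
  s2 <- generate_cohort(spec)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(s1$cohort, d1)
  write_cohort(s2$cohort, d2)
  f1 <- list.files(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
})

test_that("planted spans lie inside replicons and never overlap", {
  sim <- generate_cohort(default_cohort_spec(n_genomes = 12,
                                             n_operon_genomes = 10,
                                             seed = 23))
  tr <- sim$truth$planted_operons
  for (i in seq_len(nrow(tr))) {
    g <- sim$cohort$genomes[[tr$genome_id[i]]]
    rlen <- g$replicons$length[g$replicons$replicon_id ==
                                 tr$replicon_id[i]]
    expect_gte(tr$start[i], 0)
    expect_lte(tr$end[i], rlen)
  }
  by_rep <- split(tr, tr$replicon_id)
  for (b in by_rep) {
    if (nrow(b) > 1) {
      b <- b[order(b$start), ]
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
})

test_that("zero-operon specs yield mer-free cohorts", {
  sim <- generate_cohort(cohort_spec(n_genomes = 3, seed = 9))
  expect_equal(nrow(sim$truth$planted_operons), 0L)
  det <- detect_all(sim$cohort)
  expect_equal(nrow(det$calls), 0L)
})

test_that("ground-truth counts equal a direct recount of planted features", {
  sim <- generate_cohort(default_cohort_spec(n_genomes = 6,
                                             n_operon_genomes = 4,
                                             seed = 31))
  co <- assign_categories(sim$cohort)
  cen <- census(co)
  truth <- sim$truth$category_counts
  expect_equal(cen$matrix[, colnames(truth)], truth)
  expect_equal(colSums(cen$matrix[, colnames(truth)]), colSums(truth))
})

test_that("background products never match the lexicon", {
  lex <- default_lexicon()
  for (p in merscape:::NEUTRAL_PRODUCTS) {
    expect_false(any(merscape:::matches_any_keyword(p, lex$keyword)),
                 label = p)
  }
})

test_that("category product pools map to exactly their intended category", {
  lex <- default_lexicon()
  pools <- merscape:::CATEGORY_PRODUCTS
  for (cat in names(pools)) {
    for (p in pools[[cat]]) {
      g <- assign_categories(mk_genome(list(list(100, 900, "+", "", p))),
                             lex)
      expect_equal(g$features$categories, cat, label = p)
    }
  }
})

test_that("operon overflow of a replicon is a spec error", {
  tiny <- cohort_spec(n_genomes = 1,
                      operon_plan = list("merR_TPCAB"),
                      chromosome_length = 2.5e4, plasmid_length = 2e4,
                      second_chromosome_prob = 0, seed = 1)
  expect_error(generate_cohort(tiny), "cannot place operon")
})

test_that("alignment simulation respects the zero-rate limit and widths", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);")
  sim0 <- generate_alignment(tree, substitution_rate = 0, seed = 4)
  for (aln in sim0$alignments) {
    expect_length(unique(aln$seqs), 1L)
  }
  sim <- generate_alignment(tree, seed = 4)
  cat_aln <- concatenate_alignments(sim$alignments)
  expect_equal(cat_aln$width,
               sum(vapply(sim$alignments, function(a) a$width,
                          numeric(1))))
  expect_setequal(cat_aln$names, tree$tip.label)
  expect_error(generate_alignment("((A:0.1,B:0.1)"), "malformed")
})

test_that("NJ on simulated alignments recovers a long internal branch", {
  tree <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.4,(C:0.05,D:0.05):0.4);")
  hits <- 0L
  for (s in 1:10) {
    sim <- generate_alignment(tree, seed = s)
    est <- neighbor_joining(jc_protein_distance(
      concatenate_alignments(sim$alignments)))
    if (ape::dist.topo(ape::unroot(tree), est) == 0) hits <- hits + 1L
  }
  expect_gte(hits, 10L * 0.95)
})

test_that("family matrices follow the lifestyle prevalences", {
  labels <- stats::setNames(rep(c("soil", "human"), each = 500),
                            sprintf("g%03d", 1:1000))
  prev <- matrix(c(1.0, 0.6,
                   0.0, 0.6), 2, 2, byrow = TRUE,
                 dimnames = list(c("fixed", "varying"),
                                 c("soil", "human")))
  fam <- generate_family_matrix(list(labels = labels, prevalence = prev),
                                seed = 2)
  soil <- fam$matrix[labels == "soil", ]
  expect_true(all(soil[, "fixed"] == 1))
  emp <- mean(fam$matrix[, "varying"][labels == "human"])
  expect_lt(abs(emp - 0.6), 0.05)
  bad <- list(labels = labels,
              prevalence = matrix(1.5, 1, 2,
                                  dimnames = list("f", c("soil",
                                                         "human"))))
  expect_error(generate_family_matrix(bad), "prevalence")
})

test_that("planted lifestyle structure separates groups in PCoA", {
  labels <- stats::setNames(rep(c("soil", "human"), each = 15),
                            sprintf("g%02d", 1:30))
  plan <- default_lifestyle_plan(labels)
  fam <- generate_family_matrix(plan, seed = 6)
  d <- bray_curtis(fam$matrix)
  p <- pcoa_ordination(d)
  co <- p$coordinates[, 1:2, drop = FALSE]
  # silhouette-style check: mean within-group distance below between
  within <- mean(c(as.vector(dist(co[labels == "soil", ])),
                   as.vector(dist(co[labels == "human", ]))))
  between <- mean(as.matrix(dist(co))[labels == "soil",
                                      labels == "human"])
  expect_gt(between, within)
})
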