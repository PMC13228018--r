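# Concatenation, Jukes-Cantor protein distances, neighbor joining,
# bootstrap supports and Newick round trips.

test_that("concatenation appends columns in order and pads missing taxa", {
  a1 <- protein_alignment(c(A = "MKLV", B = "MKIV", C = "MRLV"))
  a2 <- protein_alignment(c(A = "GG", B = "GA", C = "GG"))
  cc <- concatenate_alignments(list(MerR = a1, MerT = a2))
  expect_equal(cc$width, 6L)
  expect_equal(cc$spans$start, c(1, 5))
  expect_equal(cc$spans$end, c(4, 6))
  expect_equal(unname(cc$seqs["A"]), "MKLVGG")
  # missing taxon padded with gaps
  a3 <- protein_alignment(c(A = "WW", B = "WF"))
  expect_warning(cc2 <- concatenate_alignments(
    list(MerR = a1, MerP = a3)), "padded")
  expect_equal(unname(cc2$seqs["C"]), "MRLV--")
  # single alignment passes through
  cc3 <- concatenate_alignments(list(MerA = a1))
  expect_equal(cc3$seqs, a1$seqs)
  expect_error(concatenate_alignments(
    list(X = protein_alignment(c(A = "ML")),
         Y = protein_alignment(c(B = "ML")))), "shared")
})

test_that("JC protein distances follow the 20-state closed form", {
  same <- protein_alignment(c(a = "ACDEF", b = "ACDEF"))
  expect_equal(jc_protein_distance(same)$d["a", "b"], 0)
  x <- paste(rep("A", 100), collapse = "")
  y <- paste(c(rep("A", 95), rep("C", 5)), collapse = "")
  d <- jc_protein_distance(protein_alignment(c(a = x, b = y)))
  expect_equal(d$p["a", "b"], 0.05)
  expect_equal(d$d["a", "b"], -(19 / 20) * log(1 - 20 * 0.05 / 19),
               tolerance = 1e-12)
  # saturation ceiling
  z <- paste(rep("W", 100), collapse = "")
  ds <- jc_protein_distance(protein_alignment(c(a = x, b = z)))
  expect_equal(ds$d["a", "b"], 5.0)
  expect_true(ds$saturated["a", "b"])
  # gap/X columns are pairwise-deleted
  g1 <- protein_alignment(c(a = "AC-EX", b = "ACDE-", c = "ACDEF"))
  dg <- jc_protein_distance(g1)
  expect_equal(dg$p["a", "b"], 0)   # only columns 1,2 comparable
  expect_error(jc_protein_distance(protein_alignment(
    c(a = "--", b = "AA", c = "AA"))), "a / b")
})

test_that("JC distance is monotone in p below saturation", {
  ps <- seq(0, 0.9, by = 0.05)
  ds <- -(19 / 20) * log(1 - 20 * ps / 19)
  expect_true(all(diff(ds) > 0))
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, .2, .3,
                .2, 0, .4,
                .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.05, tolerance = 1e-12)
  expect_equal(bl[["B"]], 0.15, tolerance = 1e-12)
  expect_equal(bl[["C"]], 0.25, tolerance = 1e-12)
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
})

test_that("NJ reconstructs additive matrices exactly", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, tip.label = paste0("t", 1:n))
    true$edge.length <- stats::runif(nrow(true$edge), 0.05, 0.4)
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    rec <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(rec, D, tolerance = 1e-9)
  }
})

test_that("NJ ties break lexicographically and deterministically", {
  D <- matrix(0.3, 4, 4,
              dimnames = list(c("d", "b", "c", "a"),
                              c("d", "b", "c", "a")))
  diag(D) <- 0
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
  # negative branch lengths are clipped and flagged
  Dn <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 8,
                 9, 10, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(Dn)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports behave at both signal extremes", {
  tree <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.5,(C:0.05,D:0.05):0.5);")
  sim <- generate_alignment(tree, seed = 8)
  aln <- concatenate_alignments(sim$alignments)
  bt <- bootstrap_support(aln, n_reps = 200, seed = 3)
  expect_gte(min(attr(bt, "supports")), 95)
  # one replicate: supports are 0 or 100
  bt1 <- bootstrap_support(aln, n_reps = 1, seed = 3)
  expect_true(all(attr(bt1, "supports") %in% c(0, 100)))
  # star-like data: no split dominates
  star <- ape::read.tree(
    text = "((A:0.3,B:0.3):0.0001,(C:0.3,D:0.3):0.0001);")
  sims <- generate_alignment(star, n_sites_per_protein = c(MerA = 200),
                             seed = 9)
  bts <- bootstrap_support(concatenate_alignments(sims$alignments),
                           n_reps = 200, seed = 5)
  if (length(attr(bts, "supports"))) {
    expect_lt(max(attr(bts, "supports")), 90)
  }
  expect_error(bootstrap_support(protein_alignment(
    c(A = "ML", B = "ML", C = "ML"))), "4 taxa")
})

test_that("supports are invariant to taxon order", {
  tree <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.4,(C:0.05,D:0.05):0.4);")
  sim <- generate_alignment(tree, seed = 12)
  aln <- concatenate_alignments(sim$alignments)
  perm <- protein_alignment(aln$seqs[c("D", "B", "A", "C")])
  s1 <- sort(unname(attr(bootstrap_support(aln, 50, seed = 2),
                         "supports")))
  s2 <- sort(unname(attr(bootstrap_support(perm, 50, seed = 2),
                         "supports")))
  expect_equal(s1, s2)
})

test_that("Newick I/O round-trips topology, lengths and supports", {
  set.seed(71)
  for (rep in 1:5) {
    tr <- ape::rtree(sample(4:9, 1))
    tr$node.label <- as.character(sample(50:100, tr$Nnode,
                                         replace = TRUE))
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    tr2 <- read_newick(path)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
    expect_setequal(tr2$node.label, tr$node.label)
  }
  bad <- withr::local_tempfile()
  writeLines("((A:1,B:1", bad)
  expect_error(read_newick(bad), "malformed")
})

test_that("outgroup rooting preserves bipartitions", {
  tree <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2,E:0.3);")
  rooted <- root_on_outgroup(tree, "E")
  expect_true(ape::is.rooted(rooted))
  expect_equal(ape::dist.topo(ape::unroot(rooted), tree), 0,
               ignore_attr = TRUE)
  expect_error(root_on_outgroup(tree, "Z"), "not in tree")
})
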