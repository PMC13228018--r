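# Small fixture builders shared across the suite.  Everything is built
# in code; no files ship with the tests.

# One-replicon genome from a compact feature description.
# rows: list of c(start, end, strand, gene_name, product) entries.
mk_genome <- function(rows, rep_len = 50000, genome_id = "G1",
                      replicon_id = "chr1", kind = "chromosome",
                      ...) {
  if (length(rows)) {
    feat <- do.call(rbind, lapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      data.frame(feature_id = sprintf("%s_f%02d", genome_id, i),
                 replicon_id = replicon_id,
                 start = as.numeric(r[[1]]), end = as.numeric(r[[2]]),
                 strand = r[[3]], gene_name = r[[4]], product = r[[5]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    feat <- NULL
  }
  new_genome(genome_id,
             data.frame(replicon_id = replicon_id, length = rep_len,
                        topology = "circular", kind = kind,
                        stringsAsFactors = FALSE),
             feat, ...)
}

# Lay out a run of genes left-to-right from `at`, with given intergenic
# gaps; returns the rows list for mk_genome.  products/gene names follow
# the generator's mer vocabulary.
mer_products <- c(
  merR = "mercuric resistance operon regulatory protein MerR",
  merT = "mercuric transport protein MerT",
  merP = "periplasmic mercuric ion binding protein MerP",
  merC = "mercuric ion transporter MerC",
  merF = "mercuric ion transport protein MerF",
  merA = "mercuric reductase MerA",
  merB = "organomercurial lyase MerB",
  merD = "mercuric resistance co-regulator MerD",
  merE = "mercury transporter MerE",
  hyp  = "hypothetical protein")

lay_genes <- function(genes, at = 10000, gap = 100, len = 400,
                      strand = "+", strands = NULL) {
  if (is.null(strands)) strands <- rep(strand, length(genes))
  rows <- list()
  pos <- at
  for (i in seq_along(genes)) {
    g <- genes[i]
    rows[[i]] <- list(pos, pos + len, strands[i],
                      if (g == "hyp") "" else g, mer_products[[g]])
    pos <- pos + len + gap
  }
  rows
}

# Random valid genome for round-trip property tests.
random_genome <- function(seed, genome_id = paste0("R", seed)) {
  set.seed(seed)
  n_rep <- sample(1:3, 1)
  reps <- data.frame(
    replicon_id = paste0(genome_id, "_r", seq_len(n_rep)),
    length = sample(2e4:1e5, n_rep),
    topology = sample(c("circular", "linear"), n_rep, replace = TRUE),
    kind = sample(c("chromosome", "plasmid", "unknown"), n_rep,
                  replace = TRUE),
    stringsAsFactors = FALSE)
  rows <- list()
  fid <- 0
  for (r in seq_len(n_rep)) {
    pos <- 100
    for (k in seq_len(sample(3:15, 1))) {
      len <- sample(200:1200, 1)
      if (pos + len >= reps$length[r]) break
      fid <- fid + 1
      rows[[fid]] <- data.frame(
        feature_id = sprintf("%s_f%03d", genome_id, fid),
        replicon_id = reps$replicon_id[r],
        start = pos, end = pos + len,
        strand = sample(c("+", "-"), 1),
        gene_name = sample(c("", "merA", "czcA", "tniQ"), 1),
        product = sample(c("hypothetical protein",
                           "mercuric reductase MerA",
                           "phage tail protein", "copper oxidase"), 1),
        stringsAsFactors = FALSE)
      pos <- pos + len + sample(20:800, 1)
    }
  }
  new_genome(genome_id, reps, do.call(rbind, rows),
             species_label = "Synthetica mercurii",
             isolation_source = sample(c("human", "food", "water"), 1))
}

# Tiny cohort wrapper.
mk_cohort <- function(...) new_cohort(list(...))

# One-lifestyle presence/absence matrix with exact planted counts.
mk_pam <- function(counts, n, lifestyle = "soil") {
  fams <- names(counts)
  m <- vapply(fams, function(f)
    c(rep(1L, counts[[f]]), rep(0L, n - counts[[f]])), integer(n))
  rownames(m) <- sprintf("%s_g%03d", lifestyle, seq_len(n))
  labels <- stats::setNames(rep(lifestyle, n), rownames(m))
  list(matrix = m, labels = labels)
}
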