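# Synthetic annotated-genome generator with machine-readable ground
# truth.  Cohorts emulate multi-replicon bacterial genomes carrying
# planted mer operons of configurable architecture, flanking
# mobile-element cassettes, co-localized metal-resistance loci,
# scattered resistance genes and lifestyle-structured gene families.
# Background gene products come from a neutral vocabulary that matches
# no lexicon keyword, so census ground truth is exact by construction.

MER_GENE_LENGTHS <- c(merR = 435, merT = 351, merP = 273, merC = 420,
                      merF = 243, merA = 1650, merB = 639, merD = 363,
                      merE = 237, merG = 417, hyp = 300)

MER_GENE_PRODUCTS <- c(
  merR = "mercuric resistance operon regulatory protein MerR",
  merT = "mercuric transport protein MerT",
  merP = "periplasmic mercuric ion binding protein MerP",
  merC = "mercuric ion transporter MerC",
  merF = "mercuric ion transport protein MerF",
  merA = "mercuric reductase MerA",
  merB = "organomercurial lyase MerB",
  merD = "mercuric resistance co-regulator MerD",
  merE = "mercury transporter MerE",
  merG = "phenylmercury resistance protein MerG",
  hyp  = "hypothetical protein")

# Product pools whose members match exactly one lexicon category.
CATEGORY_PRODUCTS <- list(
  "ARG" = c("class A beta-lactamase",
            "aminoglycoside O-phosphotransferase",
            "fluoroquinolone resistance pentapeptide protein QnrB",
            "phosphomycin resistance kinase FomA",
            "multidrug efflux RND permease"),
  "MRG:copper" = c("copper resistance protein CopA",
                   "copper-translocating P-type ATPase"),
  "MRG:czc" = c("cobalt-zinc-cadmium resistance protein CzcA",
                "cobalt-zinc-cadmium resistance protein CzcB",
                "cobalt-zinc-cadmium resistance protein CzcC"),
  "MRG:chromate" = c("chromate transport protein ChrA"),
  "MRG:silver" = c("silver exporting P-type ATPase SilP"),
  "MRG:arsenic" = c("arsenical resistance pump membrane protein"),
  "MGE:phage" = c("phage tail protein", "phage capsid protein",
                  "phage terminase large subunit",
                  "phage portal protein"),
  "MGE:insertion" = c("IS3 family transposase",
                      "site-specific integrase",
                      "tyrosine recombinase"),
  "MGE:plasmid" = c("plasmid replication initiator protein RepA",
                    "conjugative transfer protein TraG",
                    "plasmid stabilization protein ParE",
                    "plasmid partition protein ParA"))

NEUTRAL_PRODUCTS <- c(
  "hypothetical protein", "conserved hypothetical protein",
  "ribosomal protein L22", "ribosomal protein S9",
  "elongation factor Tu", "chaperonin GroEL",
  "cell division protein FtsZ", "ATP synthase subunit beta",
  "malate dehydrogenase", "threonine synthase",
  "ABC transporter ATP-binding protein",
  "two-component sensor histidine kinase", "outer membrane porin",
  "glutamine synthetase", "aconitate hydratase", "signal peptidase I",
  "tRNA-dihydrouridine synthase")

#' Define a mer operon template
#'
#' @param name Template name.
#' @param genes Ordered mer gene symbols (5'->3' on the operon strand),
#'   from merR/merT/merP/merC/merF/merA/merB/merD/merE/merG plus
#'   embedded \code{"hyp"}.
#' @param strand Operon strand.
#' @param divergent_merR Place a leading merR on the opposite strand
#'   (divergently transcribed regulator).
#' @param gaps Optional integer vector of intergenic gaps (length
#'   \code{length(genes) - 1}); when \code{NULL}, gaps are drawn
#'   uniformly from \code{gap_range} at generation time.
#' @param gap_range Range for random intergenic gaps (default 10-150
#'   bp).
#' @param flank_left,flank_right Lists of context-gene descriptors
#'   (each a list with \code{gene_name}, \code{product},
#'   \code{category}) planted upstream/downstream of the cassette,
#'   within the detector window but beyond the operon gap rule.
#' @return List of class \code{operon_template}.
#' @export
operon_template <- function(name, genes, strand = "+",
                            divergent_merR = FALSE, gaps = NULL,
                            gap_range = c(10, 150),
                            flank_left = list(), flank_right = list()) {
  stopifnot(length(genes) >= 1L,
            all(genes %in% names(MER_GENE_LENGTHS)))
  if (!is.null(gaps)) {
    stopifnot(length(gaps) == length(genes) - 1L, all(gaps >= 0))
  }
  structure(list(name = name, genes = genes, strand = strand,
                 divergent_merR = divergent_merR, gaps = gaps,
                 gap_range = gap_range, flank_left = flank_left,
                 flank_right = flank_right),
            class = "operon_template")
}

#' @noRd
flank_gene <- function(gene_name, product, category) {
  list(gene_name = gene_name, product = product, category = category)
}

#' Default operon template families
#'
#' Seven architectures spanning the canonical variants: the
#' merR/TPCAB broad-spectrum cassette, its extended merR/TPCAB-DE form,
#' a merF-substituted transport variant, an inorganic-only
#' merR/TPCA-DE cassette lacking merB, an isolated merA, a
#' tniABQ-flanked transposon-borne cassette, and a czc-adjacent
#' cassette with a downstream cobalt-zinc-cadmium efflux locus.
#'
#' @return Named list of \code{\link{operon_template}}.
#' @export
default_operon_templates <- function() {
  tni <- list(
    flank_gene("tniA", "transposition protein TniA", "MGE:insertion"),
    flank_gene("tniB", "transposition protein TniB", "MGE:insertion"),
    flank_gene("tniQ", "transposition protein TniQ", "MGE:insertion"))
  czc <- list(
    flank_gene("czcC", "cobalt-zinc-cadmium resistance protein CzcC",
               "MRG:czc"),
    flank_gene("czcB", "cobalt-zinc-cadmium resistance protein CzcB",
               "MRG:czc"),
    flank_gene("czcA", "cobalt-zinc-cadmium resistance protein CzcA",
               "MRG:czc"))
  list(
    merR_TPCAB = operon_template(
      "merR_TPCAB", c("merR", "merT", "merP", "merC", "merA", "merB")),
    merR_TPCABDE = operon_template(
      "merR_TPCABDE",
      c("merR", "merT", "merP", "merC", "merA", "merB", "merD", "merE")),
    merF_substituted = operon_template(
      "merF_substituted", c("merR", "merT", "merP", "merF", "merA")),
    inorganic_TPCADE = operon_template(
      "inorganic_TPCADE",
      c("merR", "merT", "merP", "merC", "merA", "merD", "merE")),
    isolated_merA = operon_template("isolated_merA", "merA"),
    tniABQ_flanked = operon_template(
      "tniABQ_flanked",
      c("merR", "merT", "merP", "merC", "merA", "merB", "merD", "merE"),
      flank_left = tni),
    czc_adjacent = operon_template(
      "czc_adjacent",
      c("merR", "merT", "merP", "merC", "merA", "merB", "merE"),
      flank_right = czc))
}

#' @noRd
template_architecture <- function(tpl) paste(tpl$genes, collapse = "-")

#' @noRd
template_complete <- function(tpl) {
  all(c("merR", "merA") %in% tpl$genes) &&
    any(c("merT", "merP", "merC", "merF") %in% tpl$genes)
}

#' @noRd
template_spectrum <- function(tpl) {
  if ("merB" %in% tpl$genes) "broad" else "narrow"
}

#' Cohort specification for the generator
#'
#' @param n_genomes Number of genomes.
#' @param operon_plan List (length \code{n_genomes}) of character
#'   vectors of template names planted in each genome (empty vector =
#'   mer-negative genome), or \code{NULL} for no operons anywhere.
#' @param templates Named template list (default
#'   \code{\link{default_operon_templates}}).
#' @param operon_replicon_kind Replicon kind targeted by planted
#'   operons, recycled over the plan (\code{"chromosome"} or
#'   \code{"plasmid"}).
#' @param category_rates Expected scattered-gene counts per genome and
#'   category (Poisson means).
#' @param mer_mge_multiplier Multiplier applied to the MGE:phage and
#'   MGE:insertion rates of operon-carrying genomes, emulating the
#'   elevated phage/insertion-sequence load of mer-positive genomes.
#' @param n_background Neutral background CDSs per genome.
#' @param chromosome_length,plasmid_length Replicon lengths (bp).
#' @param second_chromosome_prob Probability a genome carries a second
#'   chromosome.
#' @param isolation_sources Isolation-source labels, recycled.
#' @param lifestyle_labels Optional lifestyle labels, recycled.
#' @param species_label Species label for all genomes.
#' @param seed Master seed; per-genome streams are derived by stable
#'   hashing of (seed, genome index).
#' @return List of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_genomes,
                        operon_plan = NULL,
                        templates = default_operon_templates(),
                        operon_replicon_kind = "chromosome",
                        category_rates = c(
                          "ARG" = 8, "MRG:copper" = 4, "MRG:czc" = 3,
                          "MRG:chromate" = 2, "MRG:silver" = 1,
                          "MRG:arsenic" = 1, "MGE:phage" = 10,
                          "MGE:insertion" = 8, "MGE:plasmid" = 5),
                        mer_mge_multiplier = 2,
                        n_background = 150,
                        chromosome_length = 8e5,
                        plasmid_length = 1.5e5,
                        second_chromosome_prob = 0.5,
                        isolation_sources = "soil_sediment",
                        lifestyle_labels = NULL,
                        species_label = "Synthetica mercurii",
                        seed = 1) {
  stopifnot(n_genomes >= 1, all(category_rates >= 0))
  if (is.null(operon_plan)) {
    operon_plan <- rep(list(character(0)), n_genomes)
  }
  stopifnot(length(operon_plan) == n_genomes)
  for (plan in operon_plan) {
    if (length(plan) && !all(plan %in% names(templates))) {
      stop("cohort_spec: unknown template(s): ",
           paste(setdiff(plan, names(templates)), collapse = ", "))
    }
  }
  structure(list(
    n_genomes = n_genomes, operon_plan = operon_plan,
    templates = templates,
    operon_replicon_kind = operon_replicon_kind,
    category_rates = category_rates,
    mer_mge_multiplier = mer_mge_multiplier,
    n_background = n_background,
    chromosome_length = chromosome_length,
    plasmid_length = plasmid_length,
    second_chromosome_prob = second_chromosome_prob,
    isolation_sources = isolation_sources,
    lifestyle_labels = lifestyle_labels,
    species_label = species_label, seed = seed),
    class = "cohort_spec")
}

#' Default benchmark cohort specification
#'
#' A 30-genome cohort in which 20 genomes carry planted operons cycling
#' through all template families, with varied strands, target replicons
#' and isolation sources.
#'
#' @param n_genomes Cohort size (default 30).
#' @param n_operon_genomes Genomes carrying one planted operon
#'   (default 20).
#' @param seed Master seed.
#' @return A \code{cohort_spec}.
#' @export
default_cohort_spec <- function(n_genomes = 30, n_operon_genomes = 20,
                                seed = 1) {
  stopifnot(n_operon_genomes <= n_genomes)
  tpl_names <- names(default_operon_templates())
  plan <- rep(list(character(0)), n_genomes)
  for (i in seq_len(n_operon_genomes)) {
    plan[[i]] <- tpl_names[((i - 1L) %% length(tpl_names)) + 1L]
  }
  cohort_spec(
    n_genomes = n_genomes, operon_plan = plan,
    operon_replicon_kind = rep(c("chromosome", "plasmid"),
                               length.out = n_operon_genomes),
    isolation_sources = c("soil_sediment", "human", "food", "water",
                          "other"),
    lifestyle_labels = c("soil_free_living", "human_opportunistic"),
    seed = seed)
}

# Non-overlapping interval placement on one replicon.  occupied is a
# 2-column matrix of half-open intervals; returns a start or NA.
#' @noRd
place_span <- function(len, replicon_length, occupied, margin = 20,
                       max_tries = 300) {
  if (len + 2 * margin >= replicon_length) return(NA_real_)
  for (t in seq_len(max_tries)) {
    s <- floor(stats::runif(1, margin, replicon_length - len - margin))
    if (nrow(occupied) == 0L ||
        all(s + len + margin <= occupied[, 1L] |
            s - margin >= occupied[, 2L])) {
      return(s)
    }
  }
  NA_real_
}

#' Generate a synthetic annotated cohort with ground truth
#'
#' Deterministic for a fixed spec and seed.  Planted operons are
#' inserted intact with template gene order, strand and gaps; flanking
#' context genes are placed 200-2000 bp from the cassette ends (inside
#' the default detector window); scattered category genes carry
#' products the default lexicon maps to exactly their intended
#' category; background genes carry neutral products matching no
#' keyword.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List with \code{cohort} (a \code{mer_cohort}) and
#'   \code{truth}: \code{planted_operons} (one row per planted operon:
#'   span, expected architecture/completeness/spectrum),
#'   \code{category_counts} (genome x category matrix of planted
#'   features) and \code{operon_genomes} (ids of mer-positive genomes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  categories <- sort(unique(c(names(spec$category_rates), "MRG:mercury",
                              names(CATEGORY_PRODUCTS))))
  genomes <- vector("list", spec$n_genomes)
  truth_rows <- list()
  counts <- matrix(0L, spec$n_genomes, length(categories),
                   dimnames = list(NULL, categories))
  ids <- sprintf("SYN%03d", seq_len(spec$n_genomes))
  kinds <- rep(spec$operon_replicon_kind,
               length.out = max(1L, spec$n_genomes))
  for (i in seq_len(spec$n_genomes)) {
    set.seed(derive_seed(spec$seed, i))
    gid <- ids[i]
    replicons <- data.frame(
      replicon_id = paste0(gid, "_chr1"),
      length = spec$chromosome_length,
      topology = "circular", kind = "chromosome",
      stringsAsFactors = FALSE)
    if (stats::runif(1) < spec$second_chromosome_prob) {
      replicons <- rbind(replicons, data.frame(
        replicon_id = paste0(gid, "_chr2"),
        length = spec$chromosome_length / 2,
        topology = "circular", kind = "chromosome",
        stringsAsFactors = FALSE))
    }
    replicons <- rbind(replicons, data.frame(
      replicon_id = paste0(gid, "_p1"), length = spec$plasmid_length,
      topology = "circular", kind = "plasmid",
      stringsAsFactors = FALSE))
    occupied <- stats::setNames(
      rep(list(matrix(numeric(0), 0L, 2L)), nrow(replicons)),
      replicons$replicon_id)
    feat_rows <- list()
    fid <- 0L
    add_feature <- function(replicon_id, start, end, strand, gene_name,
                            product) {
      fid <<- fid + 1L
      feat_rows[[length(feat_rows) + 1L]] <<- data.frame(
        feature_id = sprintf("%s_g%04d", gid, fid),
        replicon_id = replicon_id, start = start, end = end,
        strand = strand, gene_name = gene_name, product = product,
        stringsAsFactors = FALSE)
      occupied[[replicon_id]] <<- rbind(occupied[[replicon_id]],
                                        c(start, end))
    }

    # --- planted operons -------------------------------------------------
    plan <- spec$operon_plan[[i]]
    for (tname in plan) {
      tpl <- spec$templates[[tname]]
      kind <- kinds[((i - 1L) %% length(kinds)) + 1L]
      cand <- replicons$replicon_id[replicons$kind == kind]
      if (!length(cand)) cand <- replicons$replicon_id
      rid <- cand[1L]
      rlen <- replicons$length[replicons$replicon_id == rid]
      strand <- tpl$strand
      ng <- length(tpl$genes)
      gaps <- tpl$gaps %||%
        (if (ng > 1L) floor(stats::runif(ng - 1L, tpl$gap_range[1L],
                                         tpl$gap_range[2L] + 1)) else
           numeric(0))
      glens <- MER_GENE_LENGTHS[tpl$genes]
      span_len <- sum(glens) + sum(gaps)
      # reserve room for flanks on both sides
      flank_budget <- 12000
      if (span_len + 2 * flank_budget >= rlen) {
        stop("generate_cohort: cannot place operon '", tname,
             "' on replicon ", rid, " (cassette too long for replicon)")
      }
      s0 <- NA_real_
      for (t in seq_len(200L)) {
        s_try <- floor(stats::runif(1, flank_budget,
                                    rlen - span_len - flank_budget))
        occ <- occupied[[rid]]
        lo <- s_try - flank_budget
        hi <- s_try + span_len + flank_budget
        if (nrow(occ) == 0L || all(hi <= occ[, 1L] | lo >= occ[, 2L])) {
          s0 <- s_try
          break
        }
      }
      if (is.na(s0)) {
        stop("generate_cohort: cannot place operon '", tname,
             "' on replicon ", rid, " (overlap or too long)")
      }
      # genomic order of genes: template order along + strand, reversed
      # for - strand so that the template order reads 5'->3'
      order_idx <- if (strand == "+") seq_len(ng) else rev(seq_len(ng))
      pos <- s0
      gene_coords <- matrix(NA_real_, ng, 2L)
      for (k in seq_along(order_idx)) {
        gi2 <- order_idx[k]
        gene_coords[gi2, ] <- c(pos, pos + glens[gi2])
        pos <- pos + glens[gi2] +
          if (k < ng) gaps[if (strand == "+") gi2 else gi2 - 1L] else 0
      }
      op_start <- min(gene_coords[, 1L])
      op_end <- max(gene_coords[, 2L])
      for (gi2 in seq_len(ng)) {
        sym <- tpl$genes[gi2]
        gstrand <- strand
        if (tpl$divergent_merR && gi2 == 1L && sym == "merR") {
          gstrand <- if (strand == "+") "-" else "+"
        }
        add_feature(rid, gene_coords[gi2, 1L], gene_coords[gi2, 2L],
                    gstrand,
                    if (sym == "hyp") "" else sym,
                    MER_GENE_PRODUCTS[[sym]])
        if (sym != "hyp") {
          counts[i, "MRG:mercury"] <- counts[i, "MRG:mercury"] + 1L
        }
      }
      # flanking context genes, 200-2000 bp from the cassette ends
      place_flank <- function(descriptors, side) {
        edge <- if (side == "left") op_start else op_end
        offset <- floor(stats::runif(1, 200, 2000))
        for (d in descriptors) {
          len <- 700
          if (side == "left") {
            e <- edge - offset; s <- e - len
          } else {
            s <- edge + offset; e <- s + len
          }
          add_feature(rid, s, e, strand, d$gene_name, d$product)
          counts[i, d$category] <<- counts[i, d$category] + 1L
          offset <- offset + len + floor(stats::runif(1, 50, 300))
        }
      }
      place_flank(rev(tpl$flank_left), "left")
      place_flank(tpl$flank_right, "right")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        genome_id = gid, replicon_id = rid, start = op_start,
        end = op_end, strand = strand, template = tname,
        architecture = template_architecture(tpl),
        complete = template_complete(tpl),
        spectrum = template_spectrum(tpl),
        n_members = ng, stringsAsFactors = FALSE)
    }

    # --- scattered category genes ----------------------------------------
    has_operon <- length(plan) > 0L
    for (cat in names(spec$category_rates)) {
      rate <- spec$category_rates[[cat]]
      if (has_operon && cat %in% c("MGE:phage", "MGE:insertion")) {
        rate <- rate * spec$mer_mge_multiplier
      }
      n_genes <- stats::rpois(1, rate)
      pool <- CATEGORY_PRODUCTS[[cat]]
      for (k in seq_len(n_genes)) {
        rid <- sample(replicons$replicon_id, 1L,
                      prob = replicons$length)
        len <- floor(stats::runif(1, 500, 1400))
        s <- place_span(len, replicons$length[
          replicons$replicon_id == rid], occupied[[rid]])
        if (is.na(s)) next
        add_feature(rid, s, s + len,
                    sample(c("+", "-"), 1L), "",
                    pool[((k - 1L) %% length(pool)) + 1L])
        counts[i, cat] <- counts[i, cat] + 1L
      }
    }

    # --- neutral background ----------------------------------------------
    for (k in seq_len(spec$n_background)) {
      rid <- sample(replicons$replicon_id, 1L, prob = replicons$length)
      len <- floor(stats::runif(1, 300, 1500))
      s <- place_span(len, replicons$length[replicons$replicon_id == rid],
                      occupied[[rid]])
      if (is.na(s)) next
      add_feature(rid, s, s + len, sample(c("+", "-"), 1L), "",
                  NEUTRAL_PRODUCTS[((k - 1L) %% length(NEUTRAL_PRODUCTS))
                                   + 1L])
    }

    features <- do.call(rbind, feat_rows)
    features <- features[order(features$replicon_id, features$start), ,
                         drop = FALSE]
    rownames(features) <- NULL
    src <- spec$isolation_sources[((i - 1L) %%
                                     length(spec$isolation_sources)) + 1L]
    life <- if (is.null(spec$lifestyle_labels)) NA_character_ else
      spec$lifestyle_labels[((i - 1L) %% length(spec$lifestyle_labels))
                            + 1L]
    genomes[[i]] <- new_genome(gid, replicons, features,
                               species_label = spec$species_label,
                               isolation_source = src,
                               lifestyle_label = life)
  }
  rownames(counts) <- ids
  planted <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(genome_id = character(), replicon_id = character(),
               start = numeric(), end = numeric(), strand = character(),
               template = character(), architecture = character(),
               complete = logical(), spectrum = character(),
               n_members = integer(), stringsAsFactors = FALSE)
  list(cohort = new_cohort(genomes,
                           provenance = paste0("generate_cohort seed=",
                                               spec$seed)),
       truth = list(planted_operons = planted,
                    category_counts = counts,
                    operon_genomes = unique(planted$genome_id)))
}

#' Generate a lifestyle-structured gene-family presence/absence matrix
#'
#' Each family is drawn independently per genome as Bernoulli with its
#' lifestyle's prevalence.
#'
#' @param lifestyle_plan List with \code{labels} (named character
#'   vector: genome id -> lifestyle) and \code{prevalence} (families x
#'   lifestyles matrix of probabilities in [0, 1]).
#' @param seed Integer seed.
#' @return List with \code{matrix} (genomes x families, 0/1),
#'   \code{labels}.
#' @export
generate_family_matrix <- function(lifestyle_plan, seed = 1) {
  labels <- lifestyle_plan$labels
  prev <- as.matrix(lifestyle_plan$prevalence)
  if (any(prev < 0 | prev > 1)) {
    stop("generate_family_matrix: prevalence outside [0, 1]")
  }
  if (!all(unique(labels) %in% colnames(prev))) {
    stop("generate_family_matrix: lifestyle missing from prevalence ",
         "matrix")
  }
  set.seed(derive_seed(seed, 4242))
  m <- matrix(0L, length(labels), nrow(prev),
              dimnames = list(names(labels), rownames(prev)))
  for (g in seq_along(labels)) {
    p <- prev[, labels[[g]]]
    m[g, ] <- as.integer(stats::runif(nrow(prev)) < p)
  }
  list(matrix = m, labels = labels)
}

#' Default lifestyle plan for a cohort
#'
#' Two-lifestyle plan with planted restrictive (prevalence 0.9 in the
#' focal lifestyle, 0.05 elsewhere), lax (0.5 / 0.05) and background
#' (0.3 everywhere) gene families.
#'
#' @param labels Named character vector genome id -> lifestyle.
#' @param n_restrictive,n_lax,n_background Family counts per block.
#' @return A lifestyle plan consumable by
#'   \code{\link{generate_family_matrix}}.
#' @export
default_lifestyle_plan <- function(labels, n_restrictive = 10,
                                   n_lax = 10, n_background = 80) {
  lifestyles <- sort(unique(labels))
  fams <- character(0)
  rows <- list()
  for (ls in lifestyles) {
    for (k in seq_len(n_restrictive)) {
      fams <- c(fams, sprintf("%s_restrictive_%02d", ls, k))
      rows[[length(rows) + 1L]] <-
        ifelse(lifestyles == ls, 0.9, 0.05)
    }
    for (k in seq_len(n_lax)) {
      fams <- c(fams, sprintf("%s_lax_%02d", ls, k))
      rows[[length(rows) + 1L]] <- ifelse(lifestyles == ls, 0.5, 0.05)
    }
  }
  for (k in seq_len(n_background)) {
    fams <- c(fams, sprintf("shared_bg_%03d", k))
    rows[[length(rows) + 1L]] <- rep(0.3, length(lifestyles))
  }
  prev <- do.call(rbind, rows)
  dimnames(prev) <- list(fams, lifestyles)
  list(labels = labels, prevalence = prev)
}

AA_ALPHABET <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))

#' Simulate Mer-protein alignments along a tree
#'
#' Simulates gapless protein alignments down a given tree under a
#' Poisson substitution process: the number of replacements per site on
#' a branch is Poisson(rate x branch length), and each replacement
#' draws uniformly among the other 19 amino acids — the process whose
#' pairwise divergence the Jukes-Cantor protein correction inverts.
#'
#' @param true_tree An \code{ape::phylo} (or Newick string) with >= 3
#'   leaves and non-negative branch lengths.
#' @param n_sites_per_protein Named integer vector of alignment widths
#'   (default MerR/MerT/MerP/MerA-like widths).
#' @param substitution_rate Expected substitutions per site per unit
#'   branch length.
#' @param seed Integer seed.
#' @return List with \code{alignments} (named list of
#'   \code{protein_alignment}, leaf order matching the tree) and
#'   \code{tree} (the simulating tree).
#' @export
generate_alignment <- function(true_tree,
                               n_sites_per_protein = c(
                                 MerR = 130, MerT = 110, MerP = 90,
                                 MerA = 550),
                               substitution_rate = 1, seed = 1) {
  if (is.character(true_tree)) {
    true_tree <- tryCatch(suppressWarnings(ape::read.tree(text = true_tree)),
                          error = function(e)
                            stop("malformed Newick: ",
                                 conditionMessage(e)))
    if (is.null(true_tree)) stop("malformed Newick tree")
  }
  stopifnot(inherits(true_tree, "phylo"))
  if (length(true_tree$tip.label) < 3L) {
    stop("generate_alignment: tree needs >= 3 leaves")
  }
  if (any(true_tree$edge.length < 0)) {
    stop("generate_alignment: negative branch lengths")
  }
  set.seed(derive_seed(seed, 777))
  tr <- stats::reorder(true_tree, "cladewise")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  alignments <- list()
  for (prot in names(n_sites_per_protein)) {
    L <- n_sites_per_protein[[prot]]
    node_seq <- vector("list", ntip + tr$Nnode)
    node_seq[[root]] <- sample(AA_ALPHABET, L, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]
      child <- tr$edge[e, 2L]
      s <- node_seq[[parent]]
      nk <- stats::rpois(L, substitution_rate * tr$edge.length[e])
      for (site in which(nk > 0L)) {
        cur <- s[site]
        for (rep_i in seq_len(nk[site])) {
          cur <- sample(setdiff(AA_ALPHABET, cur), 1L)
        }
        s[site] <- cur
      }
      node_seq[[child]] <- s
    }
    seqs <- vapply(seq_len(ntip), function(t)
      paste(node_seq[[t]], collapse = ""), character(1))
    names(seqs) <- tr$tip.label
    alignments[[prot]] <- protein_alignment(seqs)
  }
  list(alignments = alignments, tree = true_tree)
}
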