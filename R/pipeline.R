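# End-to-end orchestration: simulate (or load) -> detect -> census ->
# statistics -> phylogeny -> LAGs, producing a deterministic report
# bundle with a checksum manifest.  Every stage derives its own seed
# stream from the global seed, so reruns with an identical config are
# byte-identical.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Global seed; all stage streams derive from it.
#' @param simulate Generate a synthetic cohort (\code{TRUE}) or load an
#'   existing one from \code{metadata_path}/\code{genome_dir}.
#' @param n_genomes,n_operon_genomes Cohort size of the simulation.
#' @param metadata_path,genome_dir,annotation_format Cohort location
#'   when \code{simulate = FALSE}.
#' @param lexicon Category lexicon (data frame or TSV path).
#' @param detector \code{\link{detector_params}}.
#' @param factors Metadata factors tested by PERMANOVA / dispersion /
#'   rank tests; the derived factor \code{"mer_operon_presence"}
#'   (genome carries >= 1 complete operon) is always available.
#' @param alpha Significance level gating post hoc tests.
#' @param permutations PERMANOVA/dispersion permutations (default
#'   10000).
#' @param bootstrap_reps Bootstrap replicates for the Mer-protein tree.
#' @param run_phylogeny,run_lags Toggle the optional stages (both need
#'   simulated inputs or are skipped with a note).
#' @return List of class \code{mer_run_config}.
#' @export
run_config <- function(out_dir,
                       seed = 1,
                       simulate = TRUE,
                       n_genomes = 30,
                       n_operon_genomes = 20,
                       metadata_path = NULL,
                       genome_dir = NULL,
                       annotation_format = "gff3",
                       lexicon = default_lexicon(),
                       detector = detector_params(),
                       factors = c("isolation_source",
                                   "mer_operon_presence"),
                       alpha = 0.05,
                       permutations = 10000,
                       bootstrap_reps = 1000,
                       run_phylogeny = TRUE,
                       run_lags = TRUE) {
  stopifnot(alpha > 0, alpha < 1, permutations >= 1)
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
  validate_lexicon(lexicon)
  if (!simulate && (is.null(metadata_path) || is.null(genome_dir))) {
    stop("run_config: metadata_path and genome_dir required when ",
         "simulate = FALSE")
  }
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 n_genomes = n_genomes,
                 n_operon_genomes = n_operon_genomes,
                 metadata_path = metadata_path, genome_dir = genome_dir,
                 annotation_format = annotation_format,
                 lexicon = lexicon, detector = detector,
                 factors = factors, alpha = alpha,
                 permutations = permutations,
                 bootstrap_reps = bootstrap_reps,
                 run_phylogeny = run_phylogeny, run_lags = run_lags),
            class = "mer_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of \code{\link{run_config}} may be set in a YAML file;
#' unset fields keep their defaults.
#'
#' @param path YAML file.
#' @param out_dir Output directory (overrides the YAML value when
#'   given).
#' @return A \code{mer_run_config}.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), c("lexicon", "detector"))
  bad <- setdiff(names(y), c(allowed, "lexicon_path", "detector"))
  if (length(bad)) {
    stop("read_run_config: unknown field(s): ", paste(bad, collapse = ", "))
  }
  args <- y[intersect(names(y), allowed)]
  if (!is.null(y$lexicon_path)) args$lexicon <- y$lexicon_path
  if (!is.null(y$detector)) {
    args$detector <- do.call(detector_params, y$detector)
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

#' @noRd
config_checksum <- function(config) {
  clean <- config
  clean$out_dir <- NULL  # bundle identity is independent of location
  clean$detector <- unclass(clean$detector)
  tmp <- tempfile()
  jsonlite::write_json(clean, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and writes the report
#' bundle: cohort (if simulated), operon calls and contexts with a
#' detection summary, category census with z-scores and per-replicon
#' proportions, multivariate and rank statistics per factor (post hoc
#' tests only when the global test passes \code{alpha}), the
#' Mer-protein NJ tree with bootstrap supports, LAG tables, and a
#' manifest with per-file MD5 checksums.
#'
#' @param config A \code{\link{run_config}}.
#' @return List of class \code{mer_report_bundle} (invisibly): all
#'   stage results plus \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mer_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))

  # --- stage 1: cohort --------------------------------------------------
  if (config$simulate) {
    spec <- default_cohort_spec(n_genomes = config$n_genomes,
                                n_operon_genomes = config$n_operon_genomes,
                                seed = derive_seed(config$seed, 1))
    sim <- generate_cohort(spec)
    cohort <- sim$cohort
    truth <- sim$truth
    write_cohort(cohort, file.path(out, "cohort"))
    note("simulated cohort of ", config$n_genomes, " genomes")
  } else {
    cohort <- read_cohort(config$metadata_path, config$genome_dir,
                          format = config$annotation_format)
    truth <- NULL
  }
  cohort <- assign_categories(cohort, config$lexicon)

  # --- stage 2: detection -----------------------------------------------
  det <- detect_all(cohort, config$detector, config$lexicon)
  write_tsv_file(det$calls, file.path(out, "operon_calls.tsv"))
  write_tsv_file(det$contexts, file.path(out, "operon_contexts.tsv"))
  write_json_file(det$summary, file.path(out, "detection_summary.json"))

  # --- stage 3: census --------------------------------------------------
  cen <- census(cohort)
  write_tsv_file(data.frame(genome_id = rownames(cen$matrix),
                            cen$matrix, check.names = FALSE),
                 file.path(out, "census.tsv"))
  z <- zscore_standardize(cen)
  write_tsv_file(data.frame(genome_id = rownames(z$matrix),
                            round(z$matrix, 6), check.names = FALSE),
                 file.path(out, "zscores.tsv"))
  props <- do.call(rbind, lapply(cohort$genomes, function(g)
    cbind(genome_id = g$genome_id,
          replicon_proportions(g),
          stringsAsFactors = FALSE)))
  rownames(props) <- NULL
  num <- vapply(props, is.numeric, logical(1))
  props[num] <- lapply(props[num], round, 6)
  write_tsv_file(props, file.path(out, "replicon_proportions.tsv"))

  # --- stage 4: statistics ----------------------------------------------
  stats_dir <- file.path(out, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  meta <- cohort$metadata
  complete_ids <- unique(det$calls$genome_id[det$calls$complete])
  factor_values <- list(
    mer_operon_presence = ifelse(meta$genome_id %in% complete_ids,
                                 "mer_positive", "mer_negative"))
  for (f in setdiff(config$factors, "mer_operon_presence")) {
    if (f %in% names(meta)) factor_values[[f]] <- as.character(meta[[f]])
  }
  bc <- bray_curtis(cen$matrix)
  write_tsv_file(data.frame(genome_id = rownames(bc), round(bc, 8),
                            check.names = FALSE),
                 file.path(stats_dir, "bray_curtis.tsv"))
  clus <- hcluster(bc)
  writeLines(clus$newick, file.path(stats_dir, "dendrogram.nwk"))
  stat_results <- list()
  group_totals <- function(prefix) {
    cols <- startsWith(colnames(cen$matrix), prefix)
    rowSums(cen$matrix[, cols, drop = FALSE])
  }
  totals <- list(ARG = group_totals("ARG"), MRG = group_totals("MRG"),
                 MGE = group_totals("MGE"))
  fi <- 0L
  for (f in config$factors) {
    fi <- fi + 1L
    labels <- factor_values[[f]]
    if (is.null(labels) || length(unique(labels)) < 2L ||
        any(table(labels) == length(labels))) {
      note("factor '", f, "' skipped (fewer than 2 groups)")
      next
    }
    pm <- permanova(bc, labels, n_perm = config$permutations,
                    seed = derive_seed(config$seed, 100 + fi))
    bd <- beta_dispersion(bc, labels,
                          n_perm = min(config$permutations, 999),
                          seed = derive_seed(config$seed, 200 + fi))
    res <- list(factor = f,
                permanova = pm[c("pseudo_F", "R2", "p_value",
                                 "n_permutations", "exhaustive")],
                dispersion = list(F_stat = bd$F_stat,
                                  p_value = bd$p_value,
                                  degenerate = bd$degenerate),
                rank_tests = list())
    for (grp in names(totals)) {
      kw <- kruskal_dunn(totals[[grp]], labels, alpha = config$alpha)
      entry <- list(H = kw$H, df = kw$df, p_value = kw$p_value)
      # post hoc pairwise comparisons only after a significant global test
      if (kw$p_value < config$alpha) {
        entry$dunn <- kw$pairwise
      }
      res$rank_tests[[grp]] <- entry
    }
    stat_results[[f]] <- res
    write_json_file(res, file.path(stats_dir,
                                   paste0("tests_", f, ".json")))
  }
  cors <- list()
  mge_subtypes <- grep("^MGE:", colnames(cen$matrix), value = TRUE)
  for (sub in mge_subtypes) {
    dc <- dual_correlation(totals$MRG, cen$matrix[, sub],
                           alpha = config$alpha)
    cors[[paste0("MRG_vs_", sub)]] <-
      dc[c("pearson_r", "pearson_p", "spearman_rho", "spearman_p",
           "reported")]
  }
  dc <- dual_correlation(totals$MRG, totals$ARG, alpha = config$alpha)
  cors[["MRG_vs_ARG"]] <- dc[c("pearson_r", "pearson_p", "spearman_rho",
                               "spearman_p", "reported")]
  write_json_file(cors, file.path(stats_dir, "correlations.json"))
  pca <- pca_ordination(cen$matrix)
  write_tsv_file(data.frame(genome_id = rownames(pca$coordinates),
                            round(pca$coordinates[, 1:2, drop = FALSE],
                                  8),
                            check.names = FALSE),
                 file.path(stats_dir, "pca.tsv"))
  pco <- pcoa_ordination(bc)
  write_tsv_file(data.frame(genome_id = rownames(pco$coordinates),
                            round(pco$coordinates[, 1:2, drop = FALSE],
                                  8),
                            check.names = FALSE),
                 file.path(stats_dir, "pcoa.tsv"))
  write_json_file(
    list(pca_explained = pca$explained,
         pcoa_explained = pco$explained,
         pcoa_negative_eigenvalue_mass = pco$negative_eigenvalue_mass),
    file.path(stats_dir, "ordination.json"))

  # --- stage 5: phylogeny -----------------------------------------------
  phylo <- NULL
  if (config$run_phylogeny) {
    mer_ids <- sort(complete_ids)
    if (config$simulate && length(mer_ids) >= 4L) {
      set.seed(derive_seed(config$seed, 300))
      true_tree <- ape::rtree(length(mer_ids), tip.label = mer_ids)
      true_tree$edge.length <- true_tree$edge.length * 0.15
      sim_aln <- generate_alignment(true_tree,
                                    seed = derive_seed(config$seed, 301))
      aln <- concatenate_alignments(sim_aln$alignments)
      tree <- bootstrap_support(aln, n_reps = config$bootstrap_reps,
                                seed = derive_seed(config$seed, 302))
      phy_dir <- file.path(out, "phylo")
      dir.create(phy_dir, showWarnings = FALSE)
      write_newick(tree, file.path(phy_dir, "mer_tree.nwk"))
      write_newick(true_tree, file.path(phy_dir, "true_tree.nwk"))
      for (p in names(sim_aln$alignments)) {
        write_alignment(sim_aln$alignments[[p]],
                        file.path(phy_dir, paste0(p, ".faa")))
      }
      supports <- attr(tree, "supports")
      write_json_file(
        list(n_taxa = length(mer_ids), n_sites = aln$width,
             n_replicates = config$bootstrap_reps,
             n_valid = attr(tree, "n_valid"),
             n_skipped = attr(tree, "n_skipped"),
             mean_support = if (length(supports)) mean(supports) else
               NA),
        file.path(phy_dir, "phylo_report.json"))
      phylo <- list(tree = tree, alignment = aln,
                    true_tree = true_tree)
    } else {
      note("phylogeny stage skipped (needs a simulated cohort with ",
           ">= 4 complete-operon genomes)")
    }
  }

  # --- stage 6: lifestyle-associated genes --------------------------------
  lags <- NULL
  if (config$run_lags) {
    life <- meta$lifestyle_label
    if (!is.null(life) && !anyNA(life) &&
        length(unique(life)) >= 2L && config$simulate) {
      plan <- default_lifestyle_plan(
        stats::setNames(life, meta$genome_id))
      fam <- generate_family_matrix(plan,
                                    seed = derive_seed(config$seed, 400))
      prev <- lag_prevalence(fam$matrix, fam$labels)
      tab <- classify_lags(prev)
      focal <- if (length(complete_ids)) sort(complete_ids)[1L] else
        meta$genome_id[1L]
      summ <- lag_summary(tab, focal)
      lag_dir <- file.path(out, "lags")
      dir.create(lag_dir, showWarnings = FALSE)
      write_tsv_file(data.frame(family = rownames(tab$class),
                                tab$class,
                                shared = tab$shared,
                                check.names = FALSE),
                     file.path(lag_dir, "lag_table.tsv"))
      write_json_file(list(counts = summ$counts,
                           n_shared = summ$n_shared,
                           focal_genome = summ$focal_genome,
                           focal_restrictive_fraction =
                             summ$focal_restrictive_fraction),
                      file.path(lag_dir, "lag_summary.json"))
      lags <- list(matrix = fam$matrix, table = tab, summary = summ)
    } else {
      note("LAG stage skipped (needs >= 2 lifestyle labels)")
    }
  }

  # --- manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  checksums <- tools::md5sum(file.path(out, files))
  manifest <- list(seed = config$seed,
                   config_checksum = config_checksum(config),
                   notes = notes,
                   files = data.frame(path = files,
                                      md5 = unname(checksums),
                                      stringsAsFactors = FALSE))
  write_json_file(manifest, file.path(out, "manifest.json"))
  invisible(structure(list(
    cohort = cohort, truth = truth, detection = det, census = cen,
    zscores = z, bray_curtis = bc, statistics = stat_results,
    correlations = cors, pca = pca, pcoa = pco, phylo = phylo,
    lags = lags, manifest = manifest, out_dir = out),
    class = "mer_report_bundle"))
}
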