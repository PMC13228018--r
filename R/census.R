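# Lexicon-based gene categorization and the resistance-gene census.
#
# Categories are hierarchical "GROUP:subtype" tags (ARG, MRG:mercury,
# MGE:phage, ...).  Assignment is case-insensitive substring matching of
# lexicon keywords against gene_name and product; within one top-level
# group the highest-priority matching category wins, so a gene is never
# double-counted inside a group, while distinct groups are independent.

#' Default category lexicon
#'
#' Keyword lexicon mapping annotation product strings to resistance and
#' mobility categories: antibiotic-resistance genes (ARG), metal-resistance
#' genes (MRG: mercury, copper, cobalt-zinc-cadmium \code{czc}, chromate,
#' silver, arsenic) and mobile-genetic-element genes (MGE: phage,
#' insertion-sequence/transposon, plasmid-associated).  The lexicon is a
#' declared approximation of database-driven annotation screens; edit or
#' replace it via \code{\link{read_lexicon}}.
#'
#' @return \code{data.frame} with columns \code{category}, \code{keyword},
#'   \code{priority} (higher wins within a top-level group).
#' @export
default_lexicon <- function() {
  rows <- list(
    # antibiotic resistance (annotation-product keywords)
    c("ARG", "beta-lactamase", 1),
    c("ARG", "aminoglycoside", 1),
    c("ARG", "fluoroquinolone", 1),
    c("ARG", "phosphomycin", 1),
    c("ARG", "multidrug efflux", 1),
    # metal resistance
    c("MRG:mercury", "mercuric", 2),
    c("MRG:mercury", "mercury resistance", 2),
    c("MRG:mercury", "organomercurial", 2),
    c("MRG:mercury", "mercury transporter", 2),
    c("MRG:mercury", "phenylmercury", 2),
    c("MRG:czc", "cobalt-zinc-cadmium", 2),
    c("MRG:czc", "czc", 2),
    c("MRG:copper", "copper", 1),
    c("MRG:chromate", "chromate", 1),
    c("MRG:silver", "silver", 1),
    c("MRG:arsenic", "arsenic", 1),
    # mobile genetic elements
    c("MGE:phage", "phage", 2),
    c("MGE:phage", "capsid", 2),
    c("MGE:phage", "tail fiber", 2),
    c("MGE:insertion", "transposase", 2),
    c("MGE:insertion", "transposition protein", 2),
    c("MGE:insertion", "integrase", 1),
    c("MGE:insertion", "recombinase", 1),
    c("MGE:insertion", "insertion sequence", 2),
    c("MGE:plasmid", "plasmid", 1),
    c("MGE:plasmid", "conjugative transfer", 1),
    c("MGE:plasmid", "replication initiator", 1),
    c("MGE:plasmid", "stabilization protein", 1)
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("category", "keyword", "priority")
  df$priority <- as.integer(df$priority)
  df
}

#' Read / write a lexicon TSV
#'
#' @param path TSV with columns \code{category}, \code{keyword},
#'   \code{priority}.
#' @return The lexicon \code{data.frame}.
#' @export
read_lexicon <- function(path) {
  lex <- read_tsv_file(path)
  need <- c("category", "keyword", "priority")
  if (!all(need %in% names(lex))) {
    stop("lexicon must have columns: ", paste(need, collapse = ", "))
  }
  lex$priority <- as.integer(lex$priority)
  validate_lexicon(lex)
  lex
}

#' @rdname read_lexicon
#' @param lexicon Lexicon \code{data.frame}.
#' @export
write_lexicon <- function(lexicon, path) {
  write_tsv_file(lexicon, path)
  invisible(path)
}

#' @noRd
validate_lexicon <- function(lexicon) {
  if (is.null(lexicon) || nrow(lexicon) == 0L) {
    stop("empty lexicon")
  }
  if (any(is.na(lexicon$keyword) | lexicon$keyword == "")) {
    stop("lexicon keywords must be non-empty")
  }
  invisible(lexicon)
}

# Stable checksum of a lexicon (provenance for census outputs).
#' @noRd
lexicon_checksum <- function(lexicon) {
  lexicon <- lexicon[order(lexicon$category, lexicon$keyword), ]
  txt <- paste(lexicon$category, lexicon$keyword, lexicon$priority,
               sep = "\t", collapse = "\n")
  tmp <- tempfile()
  writeLines(txt, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' @noRd
category_group <- function(category) sub(":.*$", "", category)

#' Assign resistance/mobility categories to genome features
#'
#' Every CDS gains the set of categories whose keywords match its
#' \code{gene_name} or \code{product} (case-insensitive substring).  When
#' several categories of one top-level group (ARG / MRG / MGE) match, the
#' highest-priority category wins within that group (ties broken by
#' category name), so no gene is counted twice inside a group.
#'
#' @param x A \code{mer_genome} or \code{mer_cohort}.
#' @param lexicon Lexicon \code{data.frame}; defaults to
#'   \code{\link{default_lexicon}}.
#' @return The input with a filled \code{categories} column
#'   (comma-separated tags, \code{""} for uncategorized genes).
#' @export
assign_categories <- function(x, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  if (inherits(x, "mer_cohort")) {
    x$genomes <- lapply(x$genomes, assign_categories, lexicon = lexicon)
    attr(x, "lexicon_checksum") <- lexicon_checksum(lexicon)
    return(x)
  }
  stopifnot(inherits(x, "mer_genome"))
  feat <- x$features
  if (nrow(feat) == 0L) {
    x$features$categories <- character(0)
    attr(x, "lexicon_checksum") <- lexicon_checksum(lexicon)
    return(x)
  }
  text <- paste(feat$gene_name, feat$product, sep = " \r ")
  # match matrix: features x lexicon rows
  hit <- matrix(FALSE, nrow(feat), nrow(lexicon))
  for (j in seq_len(nrow(lexicon))) {
    hit[, j] <- grepl(tolower(lexicon$keyword[j]), tolower(text),
                      fixed = TRUE)
  }
  groups <- category_group(lexicon$category)
  cats <- character(nrow(feat))
  for (i in seq_len(nrow(feat))) {
    js <- which(hit[i, ])
    if (!length(js)) next
    picked <- character(0)
    for (grp in sort(unique(groups[js]))) {
      jg <- js[groups[js] == grp]
      jg <- jg[order(-lexicon$priority[jg], lexicon$category[jg])]
      picked <- c(picked, lexicon$category[jg[1L]])
    }
    cats[i] <- paste(sort(unique(picked)), collapse = ",")
  }
  x$features$categories <- cats
  attr(x, "lexicon_checksum") <- lexicon_checksum(lexicon)
  x
}

#' @noRd
has_categories <- function(genome) {
  nrow(genome$features) == 0L ||
    !anyNA(genome$features$categories)
}

#' @noRd
feature_category_list <- function(genome) {
  x <- as.character(genome$features$categories)
  x[is.na(x)] <- ""
  strsplit(x, ",", fixed = TRUE)
}

#' Per-genome gene-category census
#'
#' Counts categorized CDSs per genome and category over a cohort whose
#' categories were assigned with \code{\link{assign_categories}}.
#'
#' @param cohort A categorized \code{mer_cohort}.
#' @param categories Optional fixed category set (columns); defaults to
#'   all categories in the lexicon-assigned cohort plus any observed.
#' @return An object of class \code{mer_census}: list with \code{matrix}
#'   (genome x category integer counts), \code{totals} (CDS counts per
#'   genome) and \code{lexicon_checksum}.
#' @export
census <- function(cohort, categories = NULL) {
  stopifnot(inherits(cohort, "mer_cohort"))
  not_assigned <- !vapply(cohort$genomes, has_categories, logical(1))
  if (any(not_assigned)) {
    stop("categories not assigned for genome(s): ",
         paste(names(cohort$genomes)[not_assigned], collapse = ", "),
         "; run assign_categories() first")
  }
  per_genome <- lapply(cohort$genomes, function(g) {
    tags <- unlist(feature_category_list(g))
    table(tags[tags != ""])
  })
  if (is.null(categories)) {
    categories <- sort(unique(c(default_lexicon()$category,
                                unlist(lapply(per_genome, names)))))
  }
  m <- matrix(0L, length(per_genome), length(categories),
              dimnames = list(names(cohort$genomes), categories))
  for (i in seq_along(per_genome)) {
    t <- per_genome[[i]]
    common <- intersect(names(t), categories)
    m[i, common] <- as.integer(t[common])
  }
  structure(list(
    matrix = m,
    totals = vapply(cohort$genomes, function(g) nrow(g$features),
                    numeric(1)),
    lexicon_checksum = attr(cohort, "lexicon_checksum") %||% NA_character_
  ), class = "mer_census")
}

#' z-score standardization of a census
#'
#' Standardizes each category column to mean 0 and sample SD 1
#' (denominator n-1), then clips to \code{[-clip, +clip]}.  Categories
#' with zero SD map to all-zero columns.
#'
#' @param x A \code{mer_census} or a plain genome x category matrix.
#' @param clip Absolute clipping bound (default 4).
#' @return List with \code{matrix} (clipped z-scores), \code{clip}, and
#'   \code{n_clipped} (number of entries clipped).
#' @export
zscore_standardize <- function(x, clip = 4.0) {
  m <- if (inherits(x, "mer_census")) x$matrix else as.matrix(x)
  if (nrow(m) < 2L) {
    stop("z-score standardization needs at least 2 genomes")
  }
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  z <- sweep(m, 2L, mu, "-")
  nz <- sd > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sd[nz], "/")
  z[, !nz] <- 0
  n_clipped <- sum(abs(z) > clip)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  list(matrix = z, clip = clip, n_clipped = n_clipped)
}

#' Per-replicon category proportions
#'
#' For each replicon, the percentage of its CDSs falling in each
#' category; a genome-level aggregate row is appended.  Replicons with
#' zero CDSs report 0 with a warning.
#'
#' @param genome A categorized \code{mer_genome}.
#' @param categories Optional fixed category set.
#' @return \code{data.frame}: one row per replicon plus one
#'   \code{"<genome>"} aggregate row; columns \code{replicon_id},
#'   \code{n_cds}, then one percent column per category.
#' @export
replicon_proportions <- function(genome, categories = NULL) {
  stopifnot(inherits(genome, "mer_genome"))
  if (!has_categories(genome)) {
    stop("categories not assigned; run assign_categories() first")
  }
  cat_list <- feature_category_list(genome)
  all_tags <- unlist(cat_list)
  if (is.null(categories)) {
    categories <- sort(unique(c(default_lexicon()$category,
                                all_tags[all_tags != ""])))
  }
  reps <- genome$replicons$replicon_id
  out <- matrix(0, length(reps) + 1L, length(categories),
                dimnames = list(c(reps, genome$genome_id), categories))
  n_cds <- numeric(length(reps) + 1L)
  for (i in seq_along(reps)) {
    idx <- which(genome$features$replicon_id == reps[i])
    n_cds[i] <- length(idx)
    if (n_cds[i] == 0L) {
      warning("replicon '", reps[i], "' has zero CDSs; proportions ",
              "reported as 0")
      next
    }
    tags <- unlist(cat_list[idx])
    t <- table(tags[tags != ""])
    common <- intersect(names(t), categories)
    out[i, common] <- 100 * as.numeric(t[common]) / n_cds[i]
  }
  n_cds[length(reps) + 1L] <- nrow(genome$features)
  if (n_cds[length(reps) + 1L] > 0L) {
    t <- table(all_tags[all_tags != ""])
    common <- intersect(names(t), categories)
    out[length(reps) + 1L, common] <-
      100 * as.numeric(t[common]) / n_cds[length(reps) + 1L]
  }
  data.frame(replicon_id = rownames(out), n_cds = n_cds, out,
             check.names = FALSE, row.names = NULL,
             stringsAsFactors = FALSE)
}
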