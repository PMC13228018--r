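# Genome and cohort data model plus GFF3 / feature-table I/O.
#
# Internal coordinates are 0-based half-open; all GFF3 I/O is 1-based
# inclusive.  Only CDS rows are retained as gene features; replicon
# metadata travels as GFF3 "region" rows and ##sequence-region pragmas.

ISOLATION_SOURCES <- c("human", "food", "soil_sediment", "water",
                       "insect", "other", "unknown")
REPLICON_KINDS <- c("chromosome", "plasmid", "unknown")
REPLICON_TOPOLOGIES <- c("circular", "linear")

#' Construct a genome object
#'
#' A genome is a set of replicons (chromosomes/plasmids) carrying
#' positioned, stranded, product-labeled CDS features.  Coordinates are
#' stored 0-based half-open; \code{\link{read_genome}} and
#' \code{\link{write_genome}} convert to and from the 1-based inclusive
#' GFF3 convention.
#'
#' @param genome_id Unique genome identifier.
#' @param replicons \code{data.frame} with columns \code{replicon_id},
#'   \code{length} (bp), \code{topology} (\code{"circular"}/\code{"linear"}),
#'   \code{kind} (\code{"chromosome"}/\code{"plasmid"}/\code{"unknown"}).
#' @param features \code{data.frame} with columns \code{feature_id},
#'   \code{replicon_id}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{gene_name},
#'   \code{product}; an optional \code{categories} column holds
#'   comma-separated category tags assigned by
#'   \code{\link{assign_categories}}.
#' @param species_label Species label for cohort metadata.
#' @param isolation_source One of \code{"human"}, \code{"food"},
#'   \code{"soil_sediment"}, \code{"water"}, \code{"insect"},
#'   \code{"other"}, \code{"unknown"}; anything else maps to
#'   \code{"unknown"}.
#' @param lifestyle_label Optional lifestyle label (\code{NA} if absent).
#' @return An object of class \code{mer_genome}.
#' @export
new_genome <- function(genome_id, replicons, features,
                       species_label = NA_character_,
                       isolation_source = "unknown",
                       lifestyle_label = NA_character_) {
  if (is.null(features) || nrow(features) == 0L) {
    features <- empty_features()
  }
  if (!"categories" %in% names(features)) {
    features$categories <- NA_character_
  }
  replicons$length <- as.numeric(replicons$length)
  features$start <- as.numeric(features$start)
  features$end <- as.numeric(features$end)
  g <- structure(list(
    genome_id = as.character(genome_id),
    species_label = as.character(species_label),
    isolation_source = normalize_isolation_source(isolation_source),
    lifestyle_label = as.character(lifestyle_label),
    replicons = as.data.frame(replicons, stringsAsFactors = FALSE),
    features = as.data.frame(features, stringsAsFactors = FALSE)
  ), class = "mer_genome")
  validate_genome(g)
}

#' @noRd
empty_features <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = numeric(), end = numeric(), strand = character(),
             gene_name = character(), product = character(),
             categories = character(), stringsAsFactors = FALSE)
}

#' @noRd
normalize_isolation_source <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !(x %in% ISOLATION_SOURCES)] <- "unknown"
  x
}

#' Validate a genome object
#'
#' Checks the structural invariants of the data model: positive replicon
#' lengths, unique replicon and feature ids, features resolving to a
#' replicon, 0 <= start < end <= replicon length, and strand in
#' \code{+}/\code{-}.
#'
#' @param genome A \code{mer_genome}.
#' @return The genome, invisibly unchanged, or an error.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "mer_genome"))
  rep <- genome$replicons
  feat <- genome$features
  if (nrow(rep) == 0L) {
    stop("genome '", genome$genome_id, "': no replicons")
  }
  if (anyDuplicated(rep$replicon_id)) {
    stop("genome '", genome$genome_id, "': duplicate replicon_id")
  }
  if (any(rep$length <= 0)) {
    stop("genome '", genome$genome_id, "': non-positive replicon length")
  }
  if (!all(rep$topology %in% REPLICON_TOPOLOGIES)) {
    stop("genome '", genome$genome_id, "': invalid replicon topology")
  }
  if (!all(rep$kind %in% REPLICON_KINDS)) {
    stop("genome '", genome$genome_id, "': invalid replicon kind")
  }
  if (nrow(feat) > 0L) {
    if (anyDuplicated(feat$feature_id)) {
      stop("genome '", genome$genome_id, "': duplicate feature_id")
    }
    bad <- !(feat$replicon_id %in% rep$replicon_id)
    if (any(bad)) {
      stop("genome '", genome$genome_id, "': feature(s) ",
           paste(feat$feature_id[bad], collapse = ", "),
           " reference unknown replicons")
    }
    if (!all(feat$strand %in% c("+", "-"))) {
      stop("genome '", genome$genome_id, "': invalid strand symbol")
    }
    rlen <- stats::setNames(rep$length, rep$replicon_id)
    oob <- feat$start < 0 | feat$start >= feat$end |
      feat$end > rlen[feat$replicon_id]
    if (any(oob)) {
      stop("genome '", genome$genome_id, "': feature(s) ",
           paste(feat$feature_id[oob], collapse = ", "),
           " out of replicon bounds")
    }
  }
  genome
}

#' Read an annotated genome
#'
#' Reads CDS features from GFF3 (1-based inclusive, converted to internal
#' 0-based half-open coordinates) or from a flat feature table.  Replicon
#' lengths come from \code{##sequence-region} pragmas, from the optional
#' FASTA, or from the table's \code{replicon_length} column; replicon
#' kind/topology are read from GFF3 \code{region} rows (attributes
#' \code{mer_kind}, \code{mer_topology}) when present.  Non-CDS feature
#' rows are dropped with a message.
#'
#' @param annotation_path Path to the GFF3 or TSV file.
#' @param sequence_path Optional FASTA with replicon sequences; only the
#'   sequence lengths are used.
#' @param format \code{"gff3"} or \code{"feature_tsv"}.
#' @param genome_id Genome id; defaults to the file name without
#'   extension.
#' @param ... Metadata fields passed to \code{\link{new_genome}}
#'   (\code{species_label}, \code{isolation_source},
#'   \code{lifestyle_label}).
#' @return A validated \code{mer_genome}.
#' @export
read_genome <- function(annotation_path, sequence_path = NULL,
                        format = c("gff3", "feature_tsv"),
                        genome_id = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(annotation_path))
  }
  if (format == "gff3") {
    read_genome_gff3(annotation_path, sequence_path, genome_id, ...)
  } else {
    read_genome_tsv(annotation_path, genome_id, ...)
  }
}

#' @noRd
read_genome_gff3 <- function(path, sequence_path, genome_id, ...) {
  lines <- readLines(path, warn = FALSE)
  # replicon lengths from ##sequence-region pragmas
  sr <- grep("^##sequence-region", lines, value = TRUE)
  seq_lengths <- NULL
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "[ \t]+")
    ids <- vapply(parts, function(p) p[2L], character(1))
    ends <- suppressWarnings(vapply(parts, function(p) as.numeric(p[4L]),
                                    numeric(1)))
    if (anyNA(ends)) {
      bad <- which(is.na(ends))[1L]
      stop("malformed ##sequence-region pragma at line ",
           grep("^##sequence-region", lines)[bad], " of ", path)
    }
    seq_lengths <- stats::setNames(ends, ids)
  }
  g <- tryCatch(
    as.data.frame(rtracklayer::readGFF(
      path, tags = c("ID", "gene", "product", "mer_kind", "mer_topology"))),
    error = function(e) stop("parse error in GFF3 '", path, "': ",
                             conditionMessage(e))
  )
  if (!is.null(sequence_path)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package")
    }
    fa <- Biostrings::readDNAStringSet(sequence_path)
    ids <- sub("\\s.*$", "", names(fa))
    fa_len <- stats::setNames(Biostrings::width(fa), ids)
    seq_lengths <- if (is.null(seq_lengths)) fa_len else
      c(seq_lengths, fa_len[setdiff(names(fa_len), names(seq_lengths))])
  }
  is_region <- g$type == "region"
  is_cds <- g$type == "CDS"
  n_other <- sum(!is_region & !is_cds)
  if (n_other > 0L) {
    message("read_genome: ignored ", n_other, " non-CDS feature row(s) in ",
            basename(path))
  }
  reg <- g[is_region, , drop = FALSE]
  rep_ids <- unique(c(as.character(g$seqid), names(seq_lengths)))
  rep_len <- seq_lengths[rep_ids]
  # fall back to max feature end when a replicon has no declared length
  if (anyNA(rep_len)) {
    for (i in which(is.na(rep_len))) {
      rid <- rep_ids[i]
      rep_len[i] <- max(g$end[g$seqid == rid], 1)
    }
  }
  kind <- stats::setNames(rep("unknown", length(rep_ids)), rep_ids)
  topo <- stats::setNames(rep("linear", length(rep_ids)), rep_ids)
  if (nrow(reg)) {
    ok <- !is.na(reg$mer_kind)
    kind[as.character(reg$seqid)[ok]] <- reg$mer_kind[ok]
    ok <- !is.na(reg$mer_topology)
    topo[as.character(reg$seqid)[ok]] <- reg$mer_topology[ok]
  }
  replicons <- data.frame(replicon_id = rep_ids,
                          length = as.numeric(rep_len),
                          topology = unname(topo), kind = unname(kind),
                          stringsAsFactors = FALSE)
  cds <- g[is_cds, , drop = FALSE]
  if (nrow(cds) > 0L) {
    strand <- as.character(cds$strand)
    if (any(!strand %in% c("+", "-"))) {
      stop("genome '", genome_id, "': unknown strand symbol '",
           strand[!strand %in% c("+", "-")][1L], "' in ", path)
    }
    features <- data.frame(
      feature_id = ifelse(is.na(cds$ID),
                          paste0(genome_id, "_f", seq_len(nrow(cds))),
                          as.character(cds$ID)),
      replicon_id = as.character(cds$seqid),
      start = as.numeric(cds$start) - 1,  # GFF3 1-based -> 0-based
      end = as.numeric(cds$end),
      strand = strand,
      gene_name = ifelse(is.na(cds$gene), "", as.character(cds$gene)),
      product = ifelse(is.na(cds$product), "", as.character(cds$product)),
      stringsAsFactors = FALSE)
  } else {
    features <- empty_features()
  }
  new_genome(genome_id, replicons, features, ...)
}

#' @noRd
read_genome_tsv <- function(path, genome_id, ...) {
  df <- read_tsv_file(path)
  need <- c("replicon_id", "replicon_length", "replicon_topology",
            "replicon_kind", "feature_id", "start", "end", "strand",
            "gene_name", "product")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("feature table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rep_rows <- !duplicated(df$replicon_id)
  replicons <- data.frame(replicon_id = df$replicon_id[rep_rows],
                          length = as.numeric(df$replicon_length[rep_rows]),
                          topology = df$replicon_topology[rep_rows],
                          kind = df$replicon_kind[rep_rows],
                          stringsAsFactors = FALSE)
  has_feat <- !is.na(df$feature_id) & df$feature_id != ""
  feat <- df[has_feat, , drop = FALSE]
  features <- data.frame(
    feature_id = feat$feature_id, replicon_id = feat$replicon_id,
    start = as.numeric(feat$start) - 1, end = as.numeric(feat$end),
    strand = feat$strand,
    gene_name = ifelse(is.na(feat$gene_name), "", feat$gene_name),
    product = ifelse(is.na(feat$product), "", feat$product),
    stringsAsFactors = FALSE)
  new_genome(genome_id, replicons, features, ...)
}

#' Write an annotated genome
#'
#' Emits GFF3 (1-based inclusive coordinates, \code{##sequence-region}
#' pragmas, one \code{region} row per replicon carrying kind/topology)
#' or the flat feature table read by \code{\link{read_genome}}.
#' \code{read_genome(write_genome(g))} is the identity on the data model.
#'
#' @param genome A validated \code{mer_genome}.
#' @param path Output file path.
#' @param format \code{"gff3"} or \code{"feature_tsv"}.
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path, format = c("gff3", "feature_tsv")) {
  format <- match.arg(format)
  validate_genome(genome)
  if (format == "gff3") {
    write_genome_gff3(genome, path)
  } else {
    write_genome_tsv(genome, path)
  }
  invisible(path)
}

#' @noRd
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

#' @noRd
write_genome_gff3 <- function(genome, path) {
  rep <- genome$replicons
  feat <- genome$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", rep$replicon_id,
                     as.integer(rep$length)))
  lines <- c(lines, sprintf(
    "%s\tmerscape\tregion\t1\t%d\t.\t.\t.\tID=%s;mer_kind=%s;mer_topology=%s",
    rep$replicon_id, as.integer(rep$length), gff3_escape(rep$replicon_id),
    rep$kind, rep$topology))
  if (nrow(feat) > 0L) {
    ord <- order(feat$replicon_id, feat$start, feat$feature_id)
    feat <- feat[ord, , drop = FALSE]
    attrs <- paste0("ID=", gff3_escape(feat$feature_id))
    has_gene <- !is.na(feat$gene_name) & feat$gene_name != ""
    attrs[has_gene] <- paste0(attrs[has_gene], ";gene=",
                              gff3_escape(feat$gene_name[has_gene]))
    has_prod <- !is.na(feat$product) & feat$product != ""
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                              gff3_escape(feat$product[has_prod]))
    lines <- c(lines, sprintf(
      "%s\tmerscape\tCDS\t%d\t%d\t.\t%s\t0\t%s",
      feat$replicon_id, as.integer(feat$start) + 1L, as.integer(feat$end),
      feat$strand, attrs))
  }
  writeLines(lines, path)
}

#' @noRd
write_genome_tsv <- function(genome, path) {
  rep <- genome$replicons
  feat <- genome$features
  rlen <- stats::setNames(rep$length, rep$replicon_id)
  rtop <- stats::setNames(rep$topology, rep$replicon_id)
  rkind <- stats::setNames(rep$kind, rep$replicon_id)
  if (nrow(feat) > 0L) {
    ord <- order(feat$replicon_id, feat$start, feat$feature_id)
    feat <- feat[ord, , drop = FALSE]
    rows <- data.frame(
      replicon_id = feat$replicon_id,
      replicon_length = as.integer(rlen[feat$replicon_id]),
      replicon_topology = rtop[feat$replicon_id],
      replicon_kind = rkind[feat$replicon_id],
      feature_id = feat$feature_id,
      start = as.integer(feat$start) + 1L, end = as.integer(feat$end),
      strand = feat$strand, gene_name = feat$gene_name,
      product = feat$product, stringsAsFactors = FALSE)
  } else {
    rows <- NULL
  }
  # replicons without features still need a row so lengths round-trip
  bare <- setdiff(rep$replicon_id, feat$replicon_id)
  if (length(bare)) {
    rows <- rbind(rows, data.frame(
      replicon_id = bare, replicon_length = as.integer(rlen[bare]),
      replicon_topology = rtop[bare], replicon_kind = rkind[bare],
      feature_id = "", start = NA_integer_, end = NA_integer_,
      strand = "", gene_name = "", product = "",
      stringsAsFactors = FALSE))
  }
  write_tsv_file(rows, path)
}

#' Read a cohort of genomes
#'
#' The metadata TSV must carry columns \code{genome_id},
#' \code{species_label}, \code{isolation_source}, \code{annotation_file}
#' and optionally \code{lifestyle_label}.  Each \code{annotation_file} is
#' resolved relative to \code{genome_dir}; unknown isolation sources map
#' to \code{"unknown"}.
#'
#' @param metadata_path Path to the metadata TSV.
#' @param genome_dir Directory holding the per-genome annotation files.
#' @param format Annotation format passed to \code{\link{read_genome}}.
#' @return An object of class \code{mer_cohort}: a list with elements
#'   \code{genomes} (named list of \code{mer_genome}), \code{metadata}
#'   (the table as read) and \code{provenance}.
#' @export
read_cohort <- function(metadata_path, genome_dir,
                        format = c("gff3", "feature_tsv")) {
  format <- match.arg(format)
  meta <- read_tsv_file(metadata_path)
  need <- c("genome_id", "species_label", "isolation_source",
            "annotation_file")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("cohort metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$genome_id)) {
    stop("duplicate genome_id in cohort metadata: ",
         paste(unique(meta$genome_id[duplicated(meta$genome_id)]),
               collapse = ", "))
  }
  missing_files <- !file.exists(file.path(genome_dir, meta$annotation_file))
  if (any(missing_files)) {
    stop("missing annotation file(s) for genome(s): ",
         paste(meta$genome_id[missing_files], collapse = ", "))
  }
  genomes <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    genomes[[i]] <- read_genome(
      file.path(genome_dir, meta$annotation_file[i]), format = format,
      genome_id = meta$genome_id[i],
      species_label = meta$species_label[i],
      isolation_source = meta$isolation_source[i],
      lifestyle_label = if ("lifestyle_label" %in% names(meta))
        meta$lifestyle_label[i] else NA_character_)
  }
  names(genomes) <- meta$genome_id
  new_cohort(genomes, metadata = meta,
             provenance = paste0("read_cohort: ", metadata_path))
}

#' Construct a cohort from genome objects
#'
#' @param genomes List of \code{mer_genome} objects.
#' @param metadata Optional metadata \code{data.frame}; reconstructed
#'   from the genomes when omitted.
#' @param provenance Free-text provenance string.
#' @return A \code{mer_cohort}.
#' @export
new_cohort <- function(genomes, metadata = NULL, provenance = "") {
  if (length(genomes) == 0L) stop("cohort must contain at least one genome")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome_id in cohort")
  names(genomes) <- ids
  if (is.null(metadata)) {
    metadata <- data.frame(
      genome_id = ids,
      species_label = vapply(genomes, function(g) g$species_label,
                             character(1)),
      isolation_source = vapply(genomes, function(g) g$isolation_source,
                                character(1)),
      lifestyle_label = vapply(genomes, function(g) g$lifestyle_label,
                               character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(genomes = genomes, metadata = metadata,
                 provenance = provenance), class = "mer_cohort")
}

#' Write a cohort to disk
#'
#' Writes one annotation file per genome plus the metadata TSV consumed
#' by \code{\link{read_cohort}}.
#'
#' @param cohort A \code{mer_cohort}.
#' @param dir Output directory (created if needed).
#' @param format Annotation format.
#' @return The metadata path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("gff3", "feature_tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "gff3") ".gff3" else ".tsv"
  files <- character(length(cohort$genomes))
  for (i in seq_along(cohort$genomes)) {
    g <- cohort$genomes[[i]]
    files[i] <- paste0(g$genome_id, ext)
    write_genome(g, file.path(dir, files[i]), format = format)
  }
  meta <- cohort$metadata
  meta$annotation_file <- files
  meta_path <- file.path(dir, "metadata.tsv")
  write_tsv_file(meta, meta_path)
  invisible(meta_path)
}

#' @export
print.mer_genome <- function(x, ...) {
  cat("<mer_genome> ", x$genome_id, " (", x$species_label, ")\n",
      "  replicons: ", nrow(x$replicons),
      "  CDS features: ", nrow(x$features),
      "  source: ", x$isolation_source, "\n", sep = "")
  invisible(x)
}

#' @export
print.mer_cohort <- function(x, ...) {
  cat("<mer_cohort> ", length(x$genomes), " genome(s)\n", sep = "")
  invisible(x)
}

# Field-by-field equality on the data model (used by round-trip tests).
#' @noRd
genomes_equal <- function(a, b) {
  norm <- function(g) {
    f <- g$features[order(g$features$replicon_id, g$features$start,
                          g$features$feature_id),
                    c("feature_id", "replicon_id", "start", "end",
                      "strand", "gene_name", "product"), drop = FALSE]
    rownames(f) <- NULL
    r <- g$replicons[order(g$replicons$replicon_id), , drop = FALSE]
    rownames(r) <- NULL
    list(id = g$genome_id, r = r, f = f)
  }
  isTRUE(all.equal(norm(a), norm(b)))
}
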