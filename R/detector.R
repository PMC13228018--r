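# mer operon detection by merA anchoring and gene-neighborhood screening.
#
# The detector anchors on CDSs annotated as mercuric reductase (merA),
# screens +/- window_bp around each anchor for accessory mer genes, and
# grows the operon as a contiguous run: extension stops when the
# intergenic gap between directly adjacent genes exceeds
# max_intergenic_gap_bp, when the strand flips (a divergently
# transcribed merR immediately adjacent is admitted as the one standard
# exception), or when more than max_embedded_nonmer unannotated genes
# would have to be skipped.  Skipped genes inside the run are retained
# as "hyp" members.

#' Detector parameters
#'
#' @param window_bp Neighborhood half-width screened around the merA
#'   anchor, measured from the anchor CDS edges (default 10000 bp,
#'   operationalizing the ~10 kb screen).
#' @param max_intergenic_gap_bp Largest allowed gap between directly
#'   adjacent genes inside an operon run (default 500 bp).
#' @param max_embedded_nonmer Largest number of consecutive
#'   non-mer CDSs that may be embedded in the run (default 1).
#' @param require_same_strand Require operon members on the anchor
#'   strand (default \code{TRUE}).
#' @param allow_divergent_merR Admit a merR on the opposite strand
#'   immediately adjacent to the run (merR is frequently divergently
#'   transcribed from the structural genes; default \code{TRUE}).
#' @param anchor_lexicon Keywords identifying merA.
#' @param accessory_lexicon Named list: mer gene symbol -> keyword
#'   vector.  Keywords of the form \code{mer[A-Z]} are matched at word
#'   boundaries against gene name and product (so \code{"merA"} does not
#'   fire on "polymerase"); longer phrases are matched as
#'   case-insensitive substrings.
#' @return List of class \code{mer_detector_params}.
#' @export
detector_params <- function(window_bp = 10000,
                            max_intergenic_gap_bp = 500,
                            max_embedded_nonmer = 1,
                            require_same_strand = TRUE,
                            allow_divergent_merR = TRUE,
                            anchor_lexicon = c("merA", "mercuric reductase"),
                            accessory_lexicon = default_mer_lexicon()) {
  stopifnot(window_bp > 0, max_intergenic_gap_bp >= 0,
            max_embedded_nonmer >= 0)
  structure(list(window_bp = window_bp,
                 max_intergenic_gap_bp = max_intergenic_gap_bp,
                 max_embedded_nonmer = max_embedded_nonmer,
                 require_same_strand = require_same_strand,
                 allow_divergent_merR = allow_divergent_merR,
                 anchor_lexicon = anchor_lexicon,
                 accessory_lexicon = accessory_lexicon),
            class = "mer_detector_params")
}

#' Default mer gene keyword lexicon
#'
#' @return Named list mapping each mer gene symbol to its recognition
#'   keywords.
#' @export
default_mer_lexicon <- function() {
  list(
    merR = c("merR", "mercuric resistance operon regulatory"),
    merT = c("merT", "mercuric transport protein"),
    merP = c("merP", "periplasmic mercuric ion binding"),
    merC = c("merC", "mercuric ion transporter merc"),
    merF = c("merF"),
    merA = c("merA", "mercuric reductase"),
    merB = c("merB", "organomercurial lyase"),
    merD = c("merD", "mercuric resistance co-regulator"),
    merE = c("merE", "mercury transporter mere"),
    merG = c("merG", "phenylmercury resistance")
  )
}

# Match one keyword set against gene_name/product text; symbol-style
# keywords (mer + capital) get word-boundary semantics.
#' @noRd
keyword_hits <- function(gene_name, product, keywords) {
  text <- tolower(paste(gene_name, product, sep = " | "))
  out <- rep(FALSE, length(text))
  for (kw in keywords) {
    if (grepl("^mer[A-Z]$", kw)) {
      out <- out | grepl(paste0("\\b", tolower(kw), "\\b"), text)
    } else {
      out <- out | grepl(tolower(kw), text, fixed = TRUE)
    }
  }
  out
}

# Per-feature mer gene symbol (NA when no symbol matches).  First
# matching symbol in lexicon order wins.
#' @noRd
mer_symbols_of <- function(features, accessory_lexicon) {
  sym <- rep(NA_character_, nrow(features))
  for (s in names(accessory_lexicon)) {
    hit <- keyword_hits(features$gene_name, features$product,
                        accessory_lexicon[[s]])
    sym[is.na(sym) & hit] <- s
  }
  sym
}

#' Find merA anchor features
#'
#' Returns all CDSs whose gene name or product matches the merA anchor
#' lexicon, sorted by (replicon, start).
#'
#' @param genome A \code{mer_genome}.
#' @param params \code{\link{detector_params}}.
#' @return Character vector of feature ids (possibly empty).
#' @export
find_mer_anchors <- function(genome, params = detector_params()) {
  stopifnot(inherits(genome, "mer_genome"))
  feat <- genome$features
  if (nrow(feat) == 0L) return(character(0))
  hit <- keyword_hits(feat$gene_name, feat$product, params$anchor_lexicon)
  feat <- feat[hit, , drop = FALSE]
  feat <- feat[order(feat$replicon_id, feat$start, feat$feature_id), ,
               drop = FALSE]
  feat$feature_id
}

#' Call one mer operon from an anchor
#'
#' Grows the operon run outward from a merA anchor within
#' \code{window_bp}, applying the gap / strand / embedded-gene rules
#' described in \code{\link{detector_params}}, then derives the
#' architecture string (members 5'->3' on the operon strand),
#' completeness (merR, merA and at least one of merT/merP/merC/merF
#' present) and spectrum (broad iff merB present, i.e. the operon also
#' detoxifies organomercurials).
#'
#' @param genome A \code{mer_genome}.
#' @param anchor Feature id of a merA match.
#' @param params \code{\link{detector_params}}.
#' @return An object of class \code{mer_operon_call}.
#' @export
call_operon <- function(genome, anchor, params = detector_params()) {
  feat <- genome$features
  ai <- which(feat$feature_id == anchor)
  if (length(ai) != 1L) {
    stop("anchor feature '", anchor, "' not found in genome '",
         genome$genome_id, "'")
  }
  arow <- feat[ai, ]
  repfeat <- feat[feat$replicon_id == arow$replicon_id, , drop = FALSE]
  repfeat <- repfeat[order(repfeat$start, repfeat$feature_id), ,
                     drop = FALSE]
  sym <- mer_symbols_of(repfeat, params$accessory_lexicon)
  pos <- which(repfeat$feature_id == anchor)
  strand <- arow$strand
  win_lo <- arow$start - params$window_bp
  win_hi <- arow$end + params$window_bp

  walk <- function(dir) {
    members <- integer(0)
    pending <- integer(0)
    prev <- pos
    k <- pos + dir
    while (k >= 1L && k <= nrow(repfeat)) {
      f <- repfeat[k, ]
      if (f$end <= win_lo || f$start >= win_hi) break
      gap <- if (dir > 0L) f$start - repfeat$end[prev]
             else repfeat$start[prev] - f$end
      if (max(0, gap) > params$max_intergenic_gap_bp) break
      s <- sym[k]
      if (is.na(s)) {
        pending <- c(pending, k)
        if (length(pending) > params$max_embedded_nonmer) break
        prev <- k
        k <- k + dir
        next
      }
      if (params$require_same_strand && f$strand != strand) {
        if (identical(s, "merR") && params$allow_divergent_merR &&
            length(pending) == 0L) {
          members <- c(members, k)   # divergent merR terminates the run
        }
        break
      }
      members <- c(members, pending, k)
      pending <- integer(0)
      prev <- k
      k <- k + dir
    }
    members
  }

  idx <- sort(unique(c(pos, walk(-1L), walk(+1L))))
  m <- repfeat[idx, , drop = FALSE]
  msym <- sym[idx]
  msym[is.na(msym)] <- "hyp"
  build_operon_call(genome$genome_id, m, msym, strand, anchor)
}

#' @noRd
build_operon_call <- function(genome_id, members, symbols, strand,
                              anchor_feature_id) {
  ord <- order(members$start, members$feature_id)
  members <- members[ord, , drop = FALSE]
  symbols <- symbols[ord]
  arch_syms <- if (strand == "-") rev(symbols) else symbols
  present <- unique(symbols)
  complete <- all(c("merR", "merA") %in% present) &&
    any(c("merT", "merP", "merC", "merF") %in% present)
  structure(list(
    genome_id = genome_id,
    replicon_id = members$replicon_id[1L],
    start = min(members$start),
    end = max(members$end),
    strand = strand,
    members = data.frame(feature_id = members$feature_id,
                         symbol = symbols,
                         start = members$start, end = members$end,
                         strand = members$strand,
                         stringsAsFactors = FALSE),
    architecture = paste(arch_syms, collapse = "-"),
    complete = complete,
    spectrum = if ("merB" %in% present) "broad" else "narrow",
    anchor_feature_id = anchor_feature_id
  ), class = "mer_operon_call")
}

#' Merge overlapping operon calls
#'
#' Calls from one genome whose member sets intersect (two merA anchors
#' inside one cassette) are merged into a single call; distinct operons
#' are preserved.  Output is sorted by (replicon, start).
#'
#' @param calls List of \code{mer_operon_call} from one genome.
#' @return List of merged \code{mer_operon_call}.
#' @export
merge_calls <- function(calls) {
  if (length(calls) == 0L) return(list())
  n <- length(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq(i + 1L, n)) {
      if (length(intersect(calls[[i]]$members$feature_id,
                           calls[[j]]$members$feature_id))) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(unique(roots), function(r) {
    grp <- calls[roots == r]
    if (length(grp) == 1L) return(grp[[1L]])
    mem <- do.call(rbind, lapply(grp, function(c) {
      cbind(c$members, stringsAsFactors = FALSE)
    }))
    keep <- !duplicated(mem$feature_id)
    mem <- mem[keep, , drop = FALSE]
    mem$replicon_id <- grp[[1L]]$replicon_id
    build_operon_call(grp[[1L]]$genome_id, mem, mem$symbol,
                      grp[[1L]]$strand, grp[[1L]]$anchor_feature_id)
  })
  ord <- order(vapply(merged, function(c) c$replicon_id, character(1)),
               vapply(merged, function(c) c$start, numeric(1)))
  merged[ord]
}

#' Annotate the mobile-element / metal-resistance context of a call
#'
#' Lists every MGE-category CDS (flanking mobile elements) and every
#' non-mercury MRG-category CDS (co-resident metal-resistance genes)
#' within \code{window_bp} of the operon span, excluding operon members.
#' Distances are between nearest feature edges (0 if abutting); sides
#' are upstream/downstream relative to the operon strand.
#'
#' @param genome A categorized \code{mer_genome}
#'   (\code{\link{assign_categories}}).
#' @param call A \code{mer_operon_call} from this genome.
#' @param params \code{\link{detector_params}}.
#' @return List with data frames \code{flank_mges} (feature_id, subtype,
#'   side, distance) and \code{coresident_mrgs} (feature_id, subtype,
#'   side, distance).
#' @export
annotate_context <- function(genome, call, params = detector_params()) {
  stopifnot(inherits(call, "mer_operon_call"))
  if (!has_categories(genome)) {
    stop("categories not assigned; run assign_categories() before ",
         "annotate_context()")
  }
  feat <- genome$features
  feat <- feat[feat$replicon_id == call$replicon_id, , drop = FALSE]
  feat <- feat[!(feat$feature_id %in% call$members$feature_id), ,
               drop = FALSE]
  dist <- pmax(0, pmax(call$start - feat$end, feat$start - call$end))
  inside <- dist <= params$window_bp
  feat <- feat[inside, , drop = FALSE]
  dist <- dist[inside]
  left <- feat$end <= call$start
  right <- feat$start >= call$end
  # features overlapping the span without being members: side by midpoint
  mid <- (feat$start + feat$end) / 2
  side_geo <- ifelse(left, "left",
                     ifelse(right, "right",
                            ifelse(mid < (call$start + call$end) / 2,
                                   "left", "right")))
  side <- if (call$strand == "+") {
    ifelse(side_geo == "left", "upstream", "downstream")
  } else {
    ifelse(side_geo == "left", "downstream", "upstream")
  }
  cat_str <- as.character(feat$categories)
  cat_str[is.na(cat_str)] <- ""
  cats <- strsplit(cat_str, ",", fixed = TRUE)
  pick <- function(prefix, exclude = character(0)) {
    rows <- lapply(seq_len(nrow(feat)), function(i) {
      c <- cats[[i]]
      c <- c[startsWith(c, prefix) & !(c %in% exclude)]
      if (!length(c)) return(NULL)
      data.frame(feature_id = feat$feature_id[i],
                 subtype = sub("^[^:]*:?", "", c[1L]),
                 side = side[i], distance = dist[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(feature_id = character(), subtype = character(),
                        side = character(), distance = numeric(),
                        stringsAsFactors = FALSE)
    }
    out[order(out$distance, out$feature_id), , drop = FALSE]
  }
  list(flank_mges = pick("MGE:"),
       coresident_mrgs = pick("MRG:", exclude = "MRG:mercury"))
}

#' Detect all mer operons in a cohort
#'
#' Runs anchor finding, operon calling, merging and context annotation
#' over every genome, and summarizes the cohort: fraction of genomes
#' with at least one complete operon and fraction with merB
#' (broad-spectrum resistance including organomercurials).
#'
#' @param cohort A \code{mer_cohort}; categories are assigned with
#'   \code{lexicon} when absent.
#' @param params \code{\link{detector_params}}.
#' @param lexicon Category lexicon for context annotation.
#' @return List of class \code{mer_detection}: \code{calls} (one row per
#'   operon call), \code{contexts} (one row per context gene),
#'   \code{call_objects} (per-genome lists of \code{mer_operon_call}),
#'   and \code{summary}.
#' @export
detect_all <- function(cohort, params = detector_params(),
                       lexicon = default_lexicon()) {
  stopifnot(inherits(cohort, "mer_cohort"))
  not_assigned <- !vapply(cohort$genomes, has_categories, logical(1))
  if (any(not_assigned)) {
    cohort <- assign_categories(cohort, lexicon)
  }
  call_rows <- list()
  ctx_rows <- list()
  call_objects <- list()
  has_complete <- logical(length(cohort$genomes))
  has_merB <- logical(length(cohort$genomes))
  for (gi in seq_along(cohort$genomes)) {
    g <- cohort$genomes[[gi]]
    anchors <- find_mer_anchors(g, params)
    calls <- merge_calls(lapply(anchors, function(a)
      call_operon(g, a, params)))
    call_objects[[g$genome_id]] <- calls
    has_complete[gi] <- any(vapply(calls, function(c) c$complete,
                                   logical(1)))
    has_merB[gi] <- any(vapply(calls, function(c)
      "merB" %in% c$members$symbol, logical(1)))
    for (c in calls) {
      call_id <- paste(c$genome_id, c$replicon_id,
                       as.integer(c$start) + 1L, sep = ":")
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        call_id = call_id, genome_id = c$genome_id,
        replicon_id = c$replicon_id, start = c$start, end = c$end,
        strand = c$strand, architecture = c$architecture,
        complete = c$complete, spectrum = c$spectrum,
        anchor_feature_id = c$anchor_feature_id,
        n_members = nrow(c$members),
        member_ids = paste(c$members$feature_id, collapse = ";"),
        stringsAsFactors = FALSE)
      ctx <- annotate_context(g, c, params)
      for (type in c("flank_mges", "coresident_mrgs")) {
        d <- ctx[[type]]
        if (nrow(d)) {
          ctx_rows[[length(ctx_rows) + 1L]] <- data.frame(
            call_id = call_id, genome_id = c$genome_id,
            kind = if (type == "flank_mges") "MGE" else "MRG",
            feature_id = d$feature_id, subtype = d$subtype,
            side = d$side, distance = d$distance,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_calls <- data.frame(
    call_id = character(), genome_id = character(),
    replicon_id = character(), start = numeric(), end = numeric(),
    strand = character(), architecture = character(),
    complete = logical(), spectrum = character(),
    anchor_feature_id = character(), n_members = integer(),
    member_ids = character(), stringsAsFactors = FALSE)
  empty_ctx <- data.frame(
    call_id = character(), genome_id = character(), kind = character(),
    feature_id = character(), subtype = character(), side = character(),
    distance = numeric(), stringsAsFactors = FALSE)
  structure(list(
    calls = if (length(call_rows)) do.call(rbind, call_rows) else
      empty_calls,
    contexts = if (length(ctx_rows)) do.call(rbind, ctx_rows) else
      empty_ctx,
    call_objects = call_objects,
    summary = list(
      n_genomes = length(cohort$genomes),
      n_calls = length(call_rows),
      fraction_complete = mean(has_complete),
      fraction_merB = mean(has_merB))
  ), class = "mer_detection")
}
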