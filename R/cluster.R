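# Gene-cluster organisation and ortholog assignment: pairwise global
# (end-gap-free) protein alignment, percent identity over the shorter
# sequence, best-hit ortholog naming, single-linkage clustering of loci
# along scaffolds, flanking-marker labelling, and locus naming anchored on
# the markers that delimit defensin/ovodefensin clusters.

#' Global pairwise protein alignment
#'
#' End-gap-free global alignment (Needleman-Wunsch with free end gaps)
#' through [Biostrings::pairwiseAlignment()].  Suitable for the short,
#' nearly colinear AMP peptides for which published similarity tables were
#' built; for such pairs the pairwise optimum reproduces the published
#' multiple-alignment layout.
#'
#' @param a,b Peptide sequences (character or `AAString`).
#' @param matrix_name Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (positive values).
#' @return List of class `"alignment_result"`: `query_id`, `subject_id`,
#'   `aligned_query`, `aligned_subject` (gapped strings of equal length),
#'   `identities`, `percent_identity` (identities over the shorter
#'   ungapped length, 2 decimals) and `score`.
#' @examples
#' global_align("FRWRRFFRKAKRFLKRHGVSIAIGTVRLLRRFG",
#'              "RRWRRFFQKAKRFVKRHGVSIAVGAYRIIG")
#' @export
global_align <- function(a, b, matrix_name = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  a <- paste(.aa_vector(a), collapse = "")
  b <- paste(.aa_vector(b), collapse = "")
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  mat <- .get_submat(matrix_name)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  qa <- as.character(Biostrings::pattern(pa))
  sa <- as.character(Biostrings::subject(pa))
  qv <- strsplit(qa, "", fixed = TRUE)[[1L]]
  sv <- strsplit(sa, "", fixed = TRUE)[[1L]]
  ident <- sum(qv == sv & qv != "-")
  structure(list(
    query_id = NULL, subject_id = NULL,
    aligned_query = qa, aligned_subject = sa,
    identities = ident,
    percent_identity = round(100 * ident / min(nchar(a), nchar(b)), 2),
    score = Biostrings::score(pa)
  ), class = "alignment_result")
}

.get_submat <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_query, "\n", x$aligned_subject, "\n", sep = "")
  cat(sprintf("%d identities, %.2f%% identity, score %.1f\n",
              x$identities, x$percent_identity, x$score))
  invisible(x)
}

#' Percent identity between two peptides
#'
#' Identities of the optimal end-gap-free global alignment divided by the
#' shorter ungapped sequence length, times 100, rounded to 2 decimals.
#'
#' @inheritParams global_align
#' @return Numeric percent identity in \[0, 100\].
#' @export
percent_identity <- function(a, b, matrix_name = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5) {
  global_align(a, b, matrix_name, gap_open, gap_extend)$percent_identity
}

#' Assign query peptides to reference orthologs by best hit
#'
#' Each query is aligned against every reference; the best hit by percent
#' identity (ties broken by alignment score, then reference id) is assigned
#' when it reaches `threshold`.
#'
#' @param queries,references `AAStringSet` or named character vectors.
#' @param threshold Minimum percent identity for assignment.
#' @inheritParams global_align
#' @return Data frame with columns `query_id`, `best_reference_id` (`NA`
#'   below threshold or with empty references), `percent_identity`,
#'   `score` and `assigned`.
#' @export
assign_orthologs <- function(queries, references, threshold = 40,
                             matrix_name = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.5) {
  q <- if (is.character(queries)) queries else as.character(queries)
  r <- if (is.character(references)) references else as.character(references)
  if (is.null(names(q))) names(q) <- paste0("query", seq_along(q))
  if (length(r) == 0L) {
    warning("empty reference set; all queries unassigned")
    return(data.frame(query_id = names(q),
                      best_reference_id = NA_character_,
                      percent_identity = NA_real_, score = NA_real_,
                      assigned = FALSE, stringsAsFactors = FALSE))
  }
  if (is.null(names(r))) names(r) <- paste0("ref", seq_along(r))
  rows <- lapply(names(q), function(qn) {
    res <- lapply(names(r), function(rn) {
      al <- global_align(q[[qn]], r[[rn]], matrix_name, gap_open, gap_extend)
      data.frame(ref = rn, pid = al$percent_identity, score = al$score,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res <- res[order(-res$pid, -res$score, res$ref), ]
    best <- res[1L, ]
    ok <- best$pid >= threshold
    data.frame(query_id = qn,
               best_reference_id = if (ok) best$ref else NA_character_,
               percent_identity = best$pid, score = best$score,
               assigned = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group gene loci into clusters along scaffolds
#'
#' Single-linkage grouping: loci on the same scaffold belong to one
#' cluster when consecutive inter-locus gaps are at most `max_gap` bases.
#' The default of 100 kb resolves AMP gene clusters separated by
#' intercluster regions of several hundred kb.
#'
#' @param loci Data frame with columns `scaffold_id`, `start`, `end` and
#'   optionally `strand`, `peptide_id`, `class`.
#' @param max_gap Maximum intra-cluster gap in bases.
#' @return List of objects of class `"gene_cluster"`, each with
#'   `scaffold_id`, `loci` (rows sorted by `start`), `left_marker`,
#'   `right_marker` (filled by [label_clusters()]) and `label`.
#' @export
build_clusters <- function(loci, max_gap = 1e5) {
  stopifnot(all(c("scaffold_id", "start", "end") %in% names(loci)))
  if (nrow(loci) == 0L) return(list())
  if (any(loci$start > loci$end)) stop("locus with start > end")
  clusters <- list()
  for (sc in unique(loci$scaffold_id)) {
    sub <- loci[loci$scaffold_id == sc, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      utils::tail(sub$start, -1L) - utils::head(sub$end, -1L) - 1L > max_gap)))
    for (g in unique(grp)) {
      rows <- sub[grp == g, , drop = FALSE]
      rownames(rows) <- NULL
      clusters[[length(clusters) + 1L]] <- structure(
        list(scaffold_id = sc, loci = rows,
             left_marker = NA_character_, right_marker = NA_character_,
             anomalous_markers = character(0),
             label = NA_character_),
        class = "gene_cluster")
    }
  }
  clusters
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("gene_cluster on %s: %d loci [%d-%d]%s\n",
              x$scaffold_id, nrow(x$loci), min(x$loci$start),
              max(x$loci$end),
              if (is.na(x$label)) "" else paste0(" <", x$label, ">")))
  invisible(x)
}

#' Label clusters by their flanking marker genes
#'
#' Records the nearest marker upstream and downstream of each cluster and
#' assigns a type label: `"ovodefensin"` for MTMR9-adjacent clusters,
#' `"defensin"` for CTSB-adjacent clusters, otherwise `NA` (unlabelled).
#' A marker falling inside a cluster span is flagged as anomalous, not
#' used as a flank.
#'
#' @param clusters List of `"gene_cluster"` from [build_clusters()].
#' @param markers Data frame with columns `scaffold_id`, `start`, `end`,
#'   `name` (e.g. CTSB, MTMR9, XKR6, FDFT1, BLK, FAM167A, TRAM2, XPO1).
#' @param ovodefensin_marker,defensin_marker Marker names defining the two
#'   cluster types.
#' @return The cluster list with `left_marker`, `right_marker`,
#'   `anomalous_markers` and `label` filled in.
#' @export
label_clusters <- function(clusters, markers,
                           ovodefensin_marker = "MTMR9",
                           defensin_marker = "CTSB") {
  if (is.null(markers) || nrow(markers) == 0L) return(clusters)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    mk <- markers[markers$scaffold_id == cl$scaffold_id, , drop = FALSE]
    if (nrow(mk) == 0L) next
    span <- c(min(cl$loci$start), max(cl$loci$end))
    inside <- mk$start <= span[2L] & mk$end >= span[1L]
    cl$anomalous_markers <- mk$name[inside]
    up <- mk[!inside & mk$end < span[1L], , drop = FALSE]
    dn <- mk[!inside & mk$start > span[2L], , drop = FALSE]
    if (nrow(up)) cl$left_marker <- up$name[which.max(up$end)]
    if (nrow(dn)) cl$right_marker <- dn$name[which.min(dn$start)]
    flanks <- c(cl$left_marker, cl$right_marker)
    cl$label <- if (ovodefensin_marker %in% flanks) "ovodefensin"
      else if (defensin_marker %in% flanks) "defensin"
      else NA_character_
    clusters[[i]] <- cl
  }
  clusters
}

#' Assign marker-anchored names to cluster loci
#'
#' Loci in defensin-labelled clusters are named `<prefix>1..n` in order of
#' increasing distance from the anchoring marker (CTSB by convention);
#' ovodefensin clusters are numbered from their anchor (MTMR9).  The
#' ordering is by distance from the marker, so reversing scaffold
#' orientation preserves the numbering.  Loci in unlabelled clusters get
#' ordinal fallback names prefixed with the scaffold id.
#'
#' @param clusters Labelled cluster list from [label_clusters()].
#' @param markers Marker data frame as in [label_clusters()].
#' @param prefixes Named character vector mapping cluster label to name
#'   prefix.
#' @param suffix Appended to every assigned name.
#' @param anchors Named character vector mapping cluster label to the
#'   anchoring marker name.
#' @return The cluster list, with a `name` column added to each cluster's
#'   `loci` and numbering continuing across clusters of the same label.
#' @export
assign_names <- function(clusters, markers = NULL,
                         prefixes = c(defensin = "VkBD",
                                      ovodefensin = "VkOVOD"),
                         suffix = "_VARKO",
                         anchors = c(defensin = "CTSB",
                                     ovodefensin = "MTMR9")) {
  counters <- stats::setNames(rep(0L, length(prefixes)), names(prefixes))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    n <- nrow(cl$loci)
    if (is.na(cl$label) || !(cl$label %in% names(prefixes))) {
      cl$loci$name <- paste0(cl$scaffold_id, "_locus", seq_len(n))
      clusters[[i]] <- cl
      next
    }
    anchor_pos <- NA_real_
    if (!is.null(markers)) {
      mk <- markers[markers$scaffold_id == cl$scaffold_id &
                      markers$name == anchors[[cl$label]], , drop = FALSE]
      if (nrow(mk)) anchor_pos <- (mk$start[1L] + mk$end[1L]) / 2
    }
    mid <- (cl$loci$start + cl$loci$end) / 2
    ord <- if (is.na(anchor_pos)) order(mid) else order(abs(mid - anchor_pos))
    idx <- counters[[cl$label]] + seq_len(n)
    counters[[cl$label]] <- counters[[cl$label]] + n
    cl$loci$name[ord] <- paste0(prefixes[[cl$label]], idx, suffix)
    clusters[[i]] <- cl
  }
  clusters
}
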