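# Cysteine-spacing motif scanner for beta-defensin and beta-ovodefensin
# domains.  A domain is a run of cysteines whose inter-cysteine gap vector
# fits one of the configured gap-range "forms" (the canonical six-cysteine
# beta-defensin motif is C-X6-C-X(3-5)-C-X(8-10)-C-X6-CC).  Matching is
# deterministic: within a stop-free segment, matches over consecutive
# cysteines are preferred, then leftmost start, then the larger cysteine
# count; skipped-cysteine (subset) parses are admitted only when no
# consecutive parse exists, in which case every cysteine inside the matched
# span is captured into the domain.  Trailing cysteines within
# `extend_max` residues extend a domain (covering 8- and 10-cysteine
# variants) but never across the next match.

#' Spacing configuration for the domain scanner
#'
#' A configuration holds one or more "forms": ordered lists of
#' `[min, max]` gap ranges between consecutive cysteines (a `[0, 0]` entry
#' demands an adjacent CC pair).  Three presets are provided:
#'
#' * `"canonical"` -- the textbook six-cysteine beta-defensin motif,
#'   gaps `6, 3-5, 8-10, 6`, then CC.
#' * `"relaxed"` -- gap ranges widened to the spread observed across the
#'   published Komodo dragon beta-defensin set (`1-7, 2-10, 3-16, 5-7`,
#'   then CC), plus a lowest-priority degenerate 5-cysteine form
#'   (`1-16, 2-16, 5-7`, then CC) that captures eroded domains lacking the
#'   first cysteine, e.g. in pseudogenes or near-identical gene
#'   duplicates.
#' * `"ovodefensin"` -- a 6-cysteine form (`3-14, 3-6, 3-13, 2-6`, CC) and
#'   an 8-cysteine form (`3-9, 2-6, 3-4, 8-12, 1, 4-6`, CC) derived from
#'   the published ovodefensin spacing patterns.
#'
#' @param mode One of `"relaxed"`, `"canonical"`, `"ovodefensin"`.
#' @param gap_ranges Optional list of forms overriding the preset; each
#'   form is a list of length-2 numeric vectors.
#' @param degenerate_ranges Optional list of fallback forms tried only when
#'   no `gap_ranges` form matches.
#' @param extend_max Maximum gap (residues) over which trailing cysteines
#'   are absorbed into a domain; 0 disables extension.
#' @return An object of class `"spacing_config"`.
#' @export
spacing_config <- function(mode = c("relaxed", "canonical", "ovodefensin"),
                           gap_ranges = NULL, degenerate_ranges = NULL,
                           extend_max = NULL) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    canonical = list(
      forms = list(list(c(6, 6), c(3, 5), c(8, 10), c(6, 6), c(0, 0))),
      degenerate = list(),
      extend_max = 0L),
    relaxed = list(
      forms = list(list(c(1, 7), c(2, 10), c(3, 16), c(5, 7), c(0, 0))),
      degenerate = list(list(c(1, 16), c(2, 16), c(5, 7), c(0, 0))),
      extend_max = 12L),
    ovodefensin = list(
      forms = list(
        list(c(3, 9), c(2, 6), c(3, 4), c(8, 12), c(1, 1), c(4, 6), c(0, 0)),
        list(c(3, 14), c(3, 6), c(3, 13), c(2, 6), c(0, 0))),
      degenerate = list(),
      # 8-cysteine ovodefensins are matched directly by the long form, so
      # no trailing extension: extension here could chain across an
      # adjacent domain that only the other mode recognises
      extend_max = 0L))
  if (!is.null(gap_ranges)) preset$forms <- gap_ranges
  if (!is.null(degenerate_ranges)) preset$degenerate <- degenerate_ranges
  if (!is.null(extend_max)) preset$extend_max <- as.integer(extend_max)
  .validate_forms(preset$forms)
  .validate_forms(preset$degenerate)
  if (preset$extend_max < 0L) stop("extend_max must be >= 0")
  structure(list(mode = mode, forms = preset$forms,
                 degenerate = preset$degenerate,
                 extend_max = preset$extend_max),
            class = "spacing_config")
}

.validate_forms <- function(forms) {
  for (f in forms) {
    for (r in f) {
      if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 0) {
        stop("each gap range must be c(min, max) with 0 <= min <= max")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.spacing_config <- function(x, ...) {
  cat("spacing_config (mode:", x$mode, ")\n")
  for (f in x$forms) {
    cat("  form:", paste(vapply(f, function(r)
      if (r[1L] == r[2L]) as.character(r[1L])
      else paste0(r[1L], "-", r[2L]), ""), collapse = ", "), "\n")
  }
  if (length(x$degenerate)) cat("  +", length(x$degenerate),
                                "degenerate fallback form(s)\n")
  cat("  trailing extension up to", x$extend_max, "residues\n")
  invisible(x)
}

# gap vector between consecutive positions
.gaps_of <- function(pos) diff(pos) - 1L

.fits_form <- function(gaps, form) {
  length(gaps) == length(form) &&
    all(vapply(seq_along(form), function(i)
      gaps[i] >= form[[i]][1L] && gaps[i] <= form[[i]][2L], logical(1L)))
}

# All matches over windows of consecutive cysteines.
.consecutive_matches <- function(cys, forms) {
  out <- list()
  for (f in forms) {
    k <- length(f) + 1L
    n <- length(cys)
    if (n >= k) {
      for (i in seq_len(n - k + 1L)) {
        w <- cys[i:(i + k - 1L)]
        if (.fits_form(.gaps_of(w), f)) out[[length(out) + 1L]] <- w
      }
    }
  }
  out
}

# Depth-first search for subset matches (cysteines may be skipped; a
# skipped cysteine counts as ordinary gap residue).  Gap ranges prune the
# search, so this stays fast even on cysteine-rich decoys.
.subset_matches_from <- function(cys, start_idx, form) {
  res <- list()
  recurse <- function(chain, depth) {
    if (depth > length(form)) {
      res[[length(res) + 1L]] <<- chain
      return(invisible(NULL))
    }
    rng <- form[[depth]]
    prev <- chain[length(chain)]
    nxt <- cys[cys > prev & cys >= prev + rng[1L] + 1L &
                 cys <= prev + rng[2L] + 1L]
    for (p in nxt) recurse(c(chain, p), depth + 1L)
  }
  recurse(cys[start_idx], 1L)
  res
}

.subset_matches <- function(cys, forms) {
  out <- list()
  for (f in forms) {
    for (i in seq_along(cys)) {
      out <- c(out, .subset_matches_from(cys, i, f))
    }
  }
  out
}

# Select one match from candidates: leftmost start, then most cysteines,
# then longest span.
.pick <- function(cands) {
  starts <- vapply(cands, function(w) w[1L], numeric(1L))
  cands <- cands[starts == min(starts)]
  sizes <- vapply(cands, length, integer(1L))
  cands <- cands[sizes == max(sizes)]
  ends <- vapply(cands, function(w) w[length(w)], numeric(1L))
  cands[[which.max(ends)]]
}

# Core per-segment matcher; returns list of cysteine-position vectors.
.match_segment <- function(seg_cys, config) {
  hits <- list()
  remaining <- seg_cys
  repeat {
    sel <- NULL
    cm <- .consecutive_matches(remaining, config$forms)
    if (length(cm)) {
      sel <- .pick(cm)
    } else {
      sm <- .subset_matches(remaining, config$forms)
      if (length(sm)) {
        sel <- .pick(sm)
        # capture every cysteine inside the matched span
        sel <- remaining[remaining >= min(sel) & remaining <= max(sel)]
      } else if (length(config$degenerate)) {
        dm <- .consecutive_matches(remaining, config$degenerate)
        if (length(dm)) sel <- .pick(dm)
      }
    }
    if (is.null(sel)) break
    hits[[length(hits) + 1L]] <- sel
    remaining <- remaining[remaining > max(sel)]
    if (!length(remaining)) break
  }
  # trailing extension, never across the next match
  if (length(hits) && config$extend_max > 0L) {
    for (i in seq_along(hits)) {
      nxt <- if (i < length(hits)) hits[[i + 1L]][1L] else Inf
      h <- hits[[i]]
      repeat {
        cand <- seg_cys[seg_cys > max(h) & seg_cys < nxt]
        if (!length(cand) || cand[1L] - max(h) - 1L > config$extend_max) break
        h <- c(h, cand[1L])
      }
      hits[[i]] <- h
    }
  }
  hits
}

.empty_hits <- function() {
  out <- data.frame(source_id = character(), start = integer(),
                    end = integer(), n_cys = integer(),
                    spacing = character(), mode = character(),
                    stringsAsFactors = FALSE)
  out$cys_positions <- list()
  out$gaps <- list()
  out
}

#' Find defensin domains in a peptide sequence
#'
#' Scans an amino-acid sequence for cysteine-spacing domains under a
#' [spacing_config()].  Matches never span a stop (`*`), `X` never counts
#' as cysteine, and overlapping candidates are resolved deterministically
#' (see the configuration help page).  An empty sequence yields an empty
#' hit table, not an error.
#'
#' @param seq Peptide sequence (character or `AAString`); may contain `*`.
#' @param config A [spacing_config()]; default relaxed beta-defensin.
#' @param source_id Identifier recorded with each hit.
#' @return Data frame with one row per domain: `source_id`, `start`, `end`
#'   (1-based residue coordinates of the first and last domain cysteine),
#'   `n_cys`, `spacing` (hyphen-joined non-zero gaps), `mode`, and
#'   list-columns `cys_positions` and `gaps`.
#' @examples
#' fa <- read_fasta(amp_fixture("komodo_beta_defensins.fasta"), "protein")
#' find_defensin_domains(fa[["VkBD1_VARKO"]], source_id = "VkBD1")
#' @export
find_defensin_domains <- function(seq, config = spacing_config("relaxed"),
                                  source_id = "peptide") {
  stopifnot(inherits(config, "spacing_config"))
  a <- .aa_vector(seq)
  if (length(a) == 0L) return(.empty_hits())
  stops <- which(a == "*")
  cys <- which(a == "C")
  bounds <- c(0L, stops, length(a) + 1L)
  all_hits <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s] + 1L
    hi <- bounds[s + 1L] - 1L
    if (hi < lo) next
    seg_cys <- cys[cys >= lo & cys <= hi]
    if (length(seg_cys) < 5L) next
    all_hits <- c(all_hits, .match_segment(seg_cys, config))
  }
  if (!length(all_hits)) return(.empty_hits())
  out <- data.frame(
    source_id = source_id,
    start = vapply(all_hits, function(h) as.integer(h[1L]), integer(1L)),
    end = vapply(all_hits, function(h) as.integer(h[length(h)]), integer(1L)),
    n_cys = vapply(all_hits, length, integer(1L)),
    spacing = vapply(all_hits, function(h) spacing_string(.gaps_of(h)),
                     character(1L)),
    mode = config$mode,
    stringsAsFactors = FALSE)
  out$cys_positions <- lapply(all_hits, as.integer)
  out$gaps <- lapply(all_hits, function(h) as.integer(.gaps_of(h)))
  out
}

#' Find ovodefensin domains in a peptide sequence
#'
#' Convenience wrapper around [find_defensin_domains()] with the
#' ovodefensin spacing preset (6- and 8-cysteine forms).
#'
#' @inheritParams find_defensin_domains
#' @export
find_ovodefensin_domains <- function(seq,
                                     config = spacing_config("ovodefensin"),
                                     source_id = "peptide") {
  if (config$mode != "ovodefensin") {
    stop("config mode must be 'ovodefensin'")
  }
  find_defensin_domains(seq, config, source_id)
}

#' Spacing string of a domain
#'
#' Joins the inter-cysteine gaps with `-`, omitting zero gaps (adjacent CC
#' pairs), the convention of published cysteine-spacing columns.  Accepts
#' either a gap vector or a hit row from [find_defensin_domains()].
#'
#' @param gaps Integer vector of gaps, or a one-row hit data frame.
#' @return Character scalar, e.g. `"6-3-9-6"`; `""` for a degenerate
#'   CC-only input.
#' @export
spacing_string <- function(gaps) {
  if (is.data.frame(gaps)) {
    stopifnot(nrow(gaps) == 1L)
    gaps <- gaps$gaps[[1L]]
  }
  gaps <- as.integer(gaps)
  paste(gaps[gaps > 0L], collapse = "-")
}

#' Terminal-gap category of a gene's domains
#'
#' Classifies a gene by the gap between the last two non-adjacent cysteines
#' of its canonical six-cysteine parse -- the census statistic used for
#' beta-defensin repertoires.  For multi-domain genes the last domain is
#' used.  A domain with exactly six cysteines is categorised by the gap
#' between C4 and C5 (the gap preceding the terminal CC doublet).  For a
#' domain with more than six cysteines a canonical parse is attempted on
#' its first six cysteines (requiring C5 and C6 adjacent); if none exists
#' -- including domains with fewer than six cysteines -- the gene is
#' `"complex"`.
#'
#' @param hits Hit table from [find_defensin_domains()] for one gene
#'   (at least one row).
#' @return List of class `"domain_classification"` with elements `gene_id`,
#'   `n_domains` and `terminal_gap_category` (a character such as `"5"`,
#'   `"6"`, `"7"` or `"complex"`).
#' @export
terminal_gap_category <- function(hits) {
  if (!is.data.frame(hits) || nrow(hits) == 0L) {
    stop("at least one domain hit is required")
  }
  last <- hits[nrow(hits), ]
  pos <- last$cys_positions[[1L]]
  category <- if (length(pos) < 6L) {
    # degenerate domain: no six-cysteine parse exists
    "complex"
  } else {
    g6 <- .gaps_of(pos[1:6])
    if (g6[5L] == 0L) as.character(g6[4L]) else "complex"
  }
  structure(list(gene_id = last$source_id, n_domains = nrow(hits),
                 terminal_gap_category = category),
            class = "domain_classification")
}

#' Scan genome scaffolds for cysteine-spacing domains
#'
#' Six-frame translates every scaffold and runs the domain scanner on each
#' frame.  Hits are reported in genomic coordinates (1-based inclusive,
#' interval of the codons encoding the first through last domain cysteine)
#' with strand, and deduplicated across frames.
#'
#' @param scaffolds A `DNAStringSet` (or named character vector) of
#'   scaffold sequences.
#' @param config A [spacing_config()].
#' @param degenerate Keep the configuration's degenerate fallback forms
#'   during genome scanning.  Off by default: the 5-cysteine fallback is
#'   meant for annotating candidate peptides (pseudogenes, eroded
#'   duplicates) and is loose enough to hit random six-frame background at
#'   genome scale.
#' @return Data frame with columns `scaffold_id`, `start`, `end`, `strand`,
#'   `frame_offset`, `n_cys`, `spacing`, `mode` and `peptide` (the domain
#'   residues, first to last cysteine).
#' @export
scan_genome <- function(scaffolds, config = spacing_config("relaxed"),
                        degenerate = FALSE) {
  if (!degenerate) config$degenerate <- list()
  if (is.character(scaffolds)) {
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  }
  ids <- names(scaffolds)
  if (is.null(ids)) ids <- paste0("scaffold", seq_along(scaffolds))
  rows <- list()
  for (i in seq_along(scaffolds)) {
    if (length(scaffolds[[i]]) < 3L) next
    frames <- six_frame_translate(scaffolds[[i]], id = ids[i])
    for (fr in frames) {
      hits <- find_defensin_domains(fr$peptide, config, source_id = ids[i])
      if (nrow(hits) == 0L) next
      for (j in seq_len(nrow(hits))) {
        gen <- frame_to_genomic(fr, hits$start[j], hits$end[j])
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = ids[i], start = gen[["start"]], end = gen[["end"]],
          strand = fr$strand, frame_offset = fr$frame_offset,
          n_cys = hits$n_cys[j], spacing = hits$spacing[j],
          mode = config$mode,
          peptide = substr(fr$peptide, hits$start[j], hits$end[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame_offset = integer(), n_cys = integer(),
                      spacing = character(), mode = character(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("scaffold_id", "start", "end", "strand")]), ]
  out <- out[order(out$scaffold_id, out$start), ]
  rownames(out) <- NULL
  out
}

#' Scan a genome with both defensin and ovodefensin configurations
#'
#' Runs [scan_genome()] under the two spacing configurations and merges
#' the call sets.  Calls overlapping on the same scaffold and strand are
#' reported once: the call capturing more cysteines wins (an 8-cysteine
#' ovodefensin parse beats a 6-cysteine sub-parse of the same locus);
#' ties keep the beta-defensin call.  The provisional `class` column
#' records the scan mode of the surviving call; downstream cluster
#' labelling may override it from flanking-marker context.
#'
#' @inheritParams scan_genome
#' @param defensin_config,ovodefensin_config The two [spacing_config()]s.
#' @return As [scan_genome()], plus a `class` column.
#' @export
merged_scan <- function(scaffolds,
                        defensin_config = spacing_config("relaxed"),
                        ovodefensin_config = spacing_config("ovodefensin"),
                        degenerate = FALSE) {
  hd <- scan_genome(scaffolds, defensin_config, degenerate = degenerate)
  ho <- scan_genome(scaffolds, ovodefensin_config, degenerate = degenerate)
  hd$class <- rep("defensin", nrow(hd))
  ho$class <- rep("ovodefensin", nrow(ho))
  hits <- rbind(hd, ho)
  if (nrow(hits) == 0L) return(hits)
  # priority: more cysteines, then defensin mode
  hits <- hits[order(hits$scaffold_id, -hits$n_cys,
                     hits$class != "defensin"), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$scaffold_id == hits$scaffold_id[i] &
                 hits$strand == hits$strand[i] &
                 hits$start <= hits$end[i] & hits$end >= hits$start[i])
    keep[j] <- FALSE
  }
  hits <- hits[keep, ]
  hits <- hits[order(hits$scaffold_id, hits$start), ]
  rownames(hits) <- NULL
  hits
}
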