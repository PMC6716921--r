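# Cathelicidin precursor classification.  A functional cathelicidin
# precursor carries an N-terminal cathelin domain with (at least) four
# cysteines; a short cleavage motif (VRR, VTR or similar) shortly after the
# last cathelin cysteine marks the start of the C-terminal cationic
# antimicrobial peptide, which is typically about 35 residues long (range
# 25-37) and net positive.

#' Cleavage-motif configuration
#'
#' The motif marking the start of the mature C-terminal peptide: a set of
#' literal tripeptides plus a position pattern, searched within a window of
#' residues after the fourth (last cathelin-domain) cysteine.
#'
#' @param motifs Character vector of literal tripeptides.
#' @param pattern A regular expression for "similar" motifs; `NULL`
#'   disables pattern matching.
#' @param window Number of residues after the reference cysteine within
#'   which the motif must start.
#' @return A list of class `"cleavage_motif_config"`.
#' @export
cleavage_motif_config <- function(motifs = c("VRR", "VTR"),
                                  pattern = "[VIA][TR]R", window = 10L) {
  if (length(motifs) == 0L && is.null(pattern)) {
    stop("at least one motif or a pattern is required")
  }
  if (window <= 0L) stop("window must be positive")
  structure(list(motifs = toupper(motifs), pattern = pattern,
                 window = as.integer(window)),
            class = "cleavage_motif_config")
}

#' Cathelin-domain cysteine census
#'
#' Counts cysteines in a precursor up to and including the fourth, the
#' reference point ("last cysteine" of the cathelin domain) used by the
#' downstream cleavage-motif search.
#'
#' @param seq Precursor amino-acid sequence.
#' @return List with `n_cys` (total cysteines, capped at 4), `positions`
#'   (1-based positions of the first up-to-four cysteines), `total`
#'   (uncapped count) and `reference` (position of the 4th cysteine, or
#'   `NA` if fewer than four).
#' @export
census_cathelin_cys <- function(seq) {
  a <- .aa_vector(seq)
  pos <- which(a == "C")
  list(n_cys = min(length(pos), 4L),
       positions = utils::head(pos, 4L),
       total = length(pos),
       reference = if (length(pos) >= 4L) pos[4L] else NA_integer_)
}

#' Search for the cleavage motif after the cathelin domain
#'
#' Finds the first motif occurrence whose first residue lies within
#' `config$window` residues after the fourth cysteine.
#'
#' @param seq Precursor amino-acid sequence.
#' @param config A [cleavage_motif_config()].
#' @return 1-based position of the motif start, or `NA_integer_` if the
#'   motif is absent (or fewer than four cysteines are present).
#' @export
find_cleavage_motif <- function(seq, config = cleavage_motif_config()) {
  stopifnot(inherits(config, "cleavage_motif_config"))
  cen <- census_cathelin_cys(seq)
  if (is.na(cen$reference)) return(NA_integer_)
  s <- paste(.aa_vector(seq), collapse = "")
  from <- cen$reference + 1L
  to <- min(nchar(s), cen$reference + config$window + 2L)  # motif may end past the window
  if (from + 2L > nchar(s)) return(NA_integer_)
  region <- substr(s, from, to)
  hits <- integer(0)
  for (m in config$motifs) {
    p <- regexpr(m, region, fixed = TRUE)
    if (p > 0L) hits <- c(hits, from + as.integer(p) - 1L)
  }
  if (!is.null(config$pattern)) {
    p <- regexpr(config$pattern, region)
    if (p > 0L) hits <- c(hits, from + as.integer(p) - 1L)
  }
  hits <- hits[hits - cen$reference <= config$window]
  if (!length(hits)) NA_integer_ else min(hits)
}

#' Extract the C-terminal peptide following the cleavage motif
#'
#' @param seq Precursor amino-acid sequence.
#' @param motif_pos Motif start position from [find_cleavage_motif()].
#' @return The peptide from the residue after the (3-residue) motif to the
#'   precursor end; `""` when the motif ends the precursor.
#' @export
extract_cterm_peptide <- function(seq, motif_pos) {
  if (is.na(motif_pos)) stop("motif position is NA; no peptide to extract")
  s <- paste(.aa_vector(seq), collapse = "")
  if (motif_pos + 3L > nchar(s)) return("")
  substr(s, motif_pos + 3L, nchar(s))
}

#' Classify a cathelicidin precursor
#'
#' Applies the acceptance rules in order: (1) at least four cathelin-domain
#' cysteines; (2) cleavage motif within the window after the fourth
#' cysteine; (3) C-terminal peptide length within `len_range`; (4) integer
#' net charge of the C-terminal peptide positive (His-neutral model,
#' matching APD3-style integer charges).  A precursor is accepted only if
#' all rules pass; every rule outcome is reported, not just the first
#' failure.  When no motif is found, rules 3 and 4 are evaluated on the
#' last `fallback_len` residues, mirroring how candidate C-termini are
#' assessed for precursors lacking the motif.
#'
#' @param seq Precursor amino-acid sequence.
#' @param id Identifier stored in the verdict.
#' @param config A [cleavage_motif_config()].
#' @param len_range Acceptable mature-peptide length range (residues).
#' @param fallback_len C-terminal window assessed when no motif is found.
#' @return List of class `"cathelicidin_verdict"`: `id`, `n_cathelin_cys`,
#'   `motif_found`, `motif_position`, `cterm_peptide`, `cterm_length`,
#'   `cterm_charge_int`, `accepted` and `reasons` (named logical vector of
#'   rule outcomes).
#' @examples
#' fa <- read_fasta(amp_fixture("komodo_cathelicidins.fasta"), "protein")
#' classify_precursor(fa[["Cathelicidin4.1_VARKO"]], id = "VK-CATH4.1")
#' @export
classify_precursor <- function(seq, id = "precursor",
                               config = cleavage_motif_config(),
                               len_range = c(25L, 37L),
                               fallback_len = 35L) {
  s <- paste(.aa_vector(seq), collapse = "")
  if (!nzchar(s)) stop("empty precursor sequence")
  cen <- census_cathelin_cys(s)
  rule_cys <- cen$n_cys >= 4L
  motif_pos <- if (rule_cys) find_cleavage_motif(s, config) else NA_integer_
  rule_motif <- !is.na(motif_pos)
  cterm <- if (rule_motif) {
    extract_cterm_peptide(s, motif_pos)
  } else {
    substr(s, max(1L, nchar(s) - fallback_len + 1L), nchar(s))
  }
  n <- nchar(cterm)
  rule_len <- n >= len_range[1L] && n <= len_range[2L]
  charge <- if (n > 0L) {
    suppressWarnings(net_charge(cterm, model = "integer"))
  } else {
    NA_real_
  }
  rule_charge <- !is.na(charge) && charge > 0
  reasons <- c(cathelin_cysteines = rule_cys,
               cleavage_motif = rule_motif,
               cterm_length = rule_len,
               cterm_cationic = rule_charge)
  structure(list(
    id = id,
    n_cathelin_cys = cen$n_cys,
    motif_found = rule_motif,
    motif_position = motif_pos,
    cterm_peptide = if (rule_motif) cterm else "",
    cterm_length = if (rule_motif) n else 0L,
    cterm_charge_int = charge,
    accepted = all(reasons),
    reasons = reasons
  ), class = "cathelicidin_verdict")
}

#' @export
print.cathelicidin_verdict <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$id,
              if (x$accepted) "ACCEPTED" else "rejected"))
  if (x$accepted) {
    cat(sprintf("  C-terminal peptide (%d aa, charge %+d): %s\n",
                x$cterm_length, as.integer(x$cterm_charge_int),
                x$cterm_peptide))
  } else {
    failed <- names(x$reasons)[!x$reasons]
    cat("  failed rules:", paste(failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a set of cathelicidin precursors
#'
#' @param x An `AAStringSet` or named character vector of precursors.
#' @inheritParams classify_precursor
#' @return Data frame with one row per precursor: `id`, `n_cathelin_cys`,
#'   `motif_found`, `cterm_peptide`, `cterm_length`, `cterm_charge_int`,
#'   `accepted` and `failed_rules`.
#' @export
classify_precursors <- function(x, config = cleavage_motif_config(),
                                len_range = c(25L, 37L)) {
  seqs <- if (is.character(x)) x else as.character(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("precursor", seq_along(seqs))
  rows <- lapply(names(seqs), function(n) {
    v <- classify_precursor(seqs[[n]], id = n, config = config,
                            len_range = len_range)
    data.frame(id = n, n_cathelin_cys = v$n_cathelin_cys,
               motif_found = v$motif_found,
               cterm_peptide = v$cterm_peptide,
               cterm_length = v$cterm_length,
               cterm_charge_int = v$cterm_charge_int,
               accepted = v$accepted,
               failed_rules = paste(names(v$reasons)[!v$reasons],
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
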