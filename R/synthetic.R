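# Synthetic genomes with planted AMP genes, cysteine-rich decoys and truth
# tables.  Planted genes are single-exon: each peptide is reverse-translated
# (uniform choice among synonymous codons), flanked by in-frame stop codons
# and written over the background at a stated position and strand.  One
# integer seed determines every sequence byte; individual operations derive
# sub-seeds from it so fixtures are reproducible piecemeal.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic sub-seed derivation, kept within the 32-bit integer range
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Random background scaffold sequence
#'
#' I.i.d. nucleotides at a target GC content.  For lengths of 10 kb or
#' more the realised GC fraction is within 2 percentage points of the
#' target (binomial concentration).
#'
#' @param length Scaffold length in bases.
#' @param gc Target GC fraction in \[0, 1\].
#' @param seed Integer seed; the same seed always yields the same
#'   sequence.
#' @return Character scalar of `A/C/G/T`.
#' @export
random_background <- function(length, gc = 0.443, seed = 1L) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (length < 1L) stop("length must be positive")
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Reverse-translate a peptide to a coding nucleotide sequence
#'
#' Chooses uniformly at random among the synonymous codons of each residue
#' (standard genetic code).  Translating the result in frame 0 returns the
#' input exactly.
#'
#' @param peptide Amino-acid sequence.  `*` is rejected unless
#'   `allow_stop = TRUE` (used when planting pseudogene peptides carrying
#'   internal stops).
#' @param seed Integer seed.
#' @param allow_stop Permit `*` (encoded by a random stop codon).
#' @return Character scalar of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide, seed = 1L, allow_stop = FALSE) {
  a <- .aa_vector(peptide)
  if (length(a) == 0L) stop("empty peptide")
  if (any(a == "*") && !allow_stop) {
    stop("peptide contains a stop (*); set allow_stop = TRUE to encode it")
  }
  if (any(a == "X")) stop("cannot reverse-translate unknown residue X")
  gc <- Biostrings::GENETIC_CODE
  codons <- split(names(gc), gc)
  bad <- setdiff(unique(a), names(codons))
  if (length(bad)) stop("no codon for residue: ", paste(bad, collapse = ", "))
  .with_seed(seed, {
    paste(vapply(a, function(r) {
      ch <- codons[[r]]
      if (length(ch) == 1L) ch else sample(ch, 1L)
    }, character(1L)), collapse = "")
  })
}

#' Specification of a synthetic genome
#'
#' @param lengths Integer vector of scaffold lengths (bases); its length
#'   sets the number of scaffolds.
#' @param gc Background GC fraction.
#' @param planted Data frame with columns `peptide_id`, `peptide`,
#'   `scaffold` (index into `lengths`), `position` (1-based start of the
#'   inserted cassette), `strand` (`+`/`-`) and `class`; may be empty.
#' @param n_decoys Number of certified non-matching cysteine-rich decoy
#'   peptides to add at random free positions.
#' @param seed Integer master seed.
#' @return List of class `"synthetic_genome_spec"`.
#' @export
synthetic_genome_spec <- function(lengths, gc = 0.443, planted = NULL,
                                  n_decoys = 0L, seed = 1L) {
  if (is.null(planted)) {
    planted <- data.frame(peptide_id = character(), peptide = character(),
                          scaffold = integer(), position = integer(),
                          strand = character(), class = character(),
                          stringsAsFactors = FALSE)
  }
  req <- c("peptide_id", "peptide", "scaffold", "position", "strand", "class")
  miss <- setdiff(req, names(planted))
  if (length(miss)) stop("planted is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(planted$strand %in% c("+", "-"))) stop("strand must be + or -")
  # cassette footprint: stop + ORF + stop
  width <- 3L * (nchar(planted$peptide) + 2L)
  ends <- planted$position + width - 1L
  if (any(planted$position < 1L) ||
      any(ends > lengths[planted$scaffold])) {
    stop("planted cassette exceeds scaffold bounds")
  }
  for (sc in unique(planted$scaffold)) {
    idx <- which(planted$scaffold == sc)
    o <- idx[order(planted$position[idx])]
    if (length(o) > 1L &&
        any(utils::tail(planted$position[o], -1L) <=
              utils::head(ends[o], -1L))) {
      stop("planted cassettes overlap on scaffold ", sc)
    }
  }
  structure(list(lengths = as.integer(lengths), gc = gc, planted = planted,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

#' Generate certified decoy peptides
#'
#' Cysteine-rich peptides (at least six cysteines) whose gap vectors
#' violate the given spacing configurations; every candidate is certified
#' by running the domain scanner and regenerated until it produces zero
#' hits under each configuration, so precision tests are never vacuous.
#'
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @param configs List of [spacing_config()] objects the decoys must not
#'   match (default: relaxed beta-defensin and ovodefensin presets).
#' @return Named character vector of `n` peptides.
#' @export
generate_decoys <- function(n, seed = 1L,
                            configs = list(spacing_config("relaxed"),
                                           spacing_config("ovodefensin"))) {
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  aa_bg <- setdiff(names(AA_AVERAGE_MASS), "C")
  .with_seed(.sub_seed(seed, 17L), {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        n_cys <- sample(6:9, 1L)
        # deliberately invalid spacing: most gaps far outside any range
        gaps <- sample(c(17:25, 0:1), n_cys - 1L, replace = TRUE)
        body <- unlist(lapply(gaps, function(g)
          c(sample(aa_bg, g, replace = TRUE), "C")))
        pep <- paste(c(sample(aa_bg, 3L, replace = TRUE), "C", body,
                       sample(aa_bg, 3L, replace = TRUE)), collapse = "")
        ok <- all(vapply(configs, function(cf)
          nrow(find_defensin_domains(pep, cf)) == 0L, logical(1L)))
        if (ok) break
      }
      out[i] <- pep
    }
    names(out) <- sprintf("decoy%03d", seq_len(n))
    out
  })
}

#' Build a synthetic genome with planted genes and decoys
#'
#' Generates background scaffolds, writes each planted cassette
#' (stop + reverse-translated ORF + stop; reverse-complemented for `-`
#' strand insertions) over the background, then places the requested
#' number of certified decoys at random positions that do not collide with
#' planted genes.  Every truth coordinate is verified by re-translating
#' the inserted interval back to the source peptide.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List with `scaffolds` (a `DNAStringSet` named `scaffold1..n`)
#'   and `truth` (data frame: `scaffold_id`, `start`, `end`, `strand`,
#'   `peptide_id`, `class`, `peptide`; coordinates of the ORF, excluding
#'   the flanking stops).
#' @export
plant_genes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  n_sc <- length(spec$lengths)
  scaff <- vapply(seq_len(n_sc), function(i)
    random_background(spec$lengths[i], spec$gc, .sub_seed(spec$seed, i)),
    character(1L))
  names(scaff) <- paste0("scaffold", seq_len(n_sc))

  planted <- spec$planted
  if (spec$n_decoys > 0L) {
    dec <- generate_decoys(spec$n_decoys, seed = spec$seed)
    planted <- rbind(planted, .place_decoys(dec, spec, planted))
  }
  truth <- vector("list", nrow(planted))
  if (nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      p <- planted[k, ]
      orf <- reverse_translate(p$peptide, seed = .sub_seed(spec$seed, 100L + k),
                               allow_stop = TRUE)
      cassette <- paste0("TAA", orf, "TAA")
      if (p$strand == "-") {
        cassette <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cassette)))
      }
      s <- scaff[[p$scaffold]]
      pos <- p$position
      substr(s, pos, pos + nchar(cassette) - 1L) <- cassette
      scaff[[p$scaffold]] <- s
      # ORF interval excluding flanking stops, on the stated strand
      start <- pos + 3L
      end <- pos + nchar(cassette) - 4L
      truth[[k]] <- data.frame(
        scaffold_id = names(scaff)[p$scaffold], start = start, end = end,
        strand = p$strand, peptide_id = p$peptide_id, class = p$class,
        peptide = p$peptide, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), strand = character(),
               peptide_id = character(), class = character(),
               peptide = character(), stringsAsFactors = FALSE)
  out <- list(scaffolds = Biostrings::DNAStringSet(scaff), truth = truth)
  .verify_truth(out)
  out
}

# random non-colliding positions for decoys, derived from the master seed
.place_decoys <- function(decoys, spec, planted) {
  occupied <- lapply(seq_along(spec$lengths), function(sc) {
    idx <- planted$scaffold == sc
    cbind(planted$position[idx],
          planted$position[idx] + 3L * (nchar(planted$peptide[idx]) + 2L) - 1L)
  })
  rows <- vector("list", length(decoys))
  .with_seed(.sub_seed(spec$seed, 23L), {
    for (i in seq_along(decoys)) {
      w <- 3L * (nchar(decoys[i]) + 2L)
      repeat {
        sc <- sample(seq_along(spec$lengths), 1L)
        if (spec$lengths[sc] < w + 2L) next
        pos <- sample(spec$lengths[sc] - w, 1L)
        occ <- occupied[[sc]]
        if (is.null(occ) || nrow(occ) == 0L ||
            all(pos + w - 1L < occ[, 1L] | pos > occ[, 2L])) {
          occupied[[sc]] <- rbind(occ, c(pos, pos + w - 1L))
          rows[[i]] <- data.frame(
            peptide_id = names(decoys)[i], peptide = unname(decoys[i]),
            scaffold = sc, position = pos,
            strand = sample(c("+", "-"), 1L), class = "decoy",
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  })
  do.call(rbind, rows)
}

# re-translate every truth interval and compare with the source peptide
.verify_truth <- function(genome) {
  tr <- genome$truth
  for (k in seq_len(nrow(tr))) {
    seq <- Biostrings::subseq(genome$scaffolds[[tr$scaffold_id[k]]],
                              tr$start[k], tr$end[k])
    if (tr$strand[k] == "-") seq <- Biostrings::reverseComplement(seq)
    pep <- as.character(suppressWarnings(
      Biostrings::translate(seq, if.fuzzy.codon = "X",
                            no.init.codon = TRUE)))
    if (!identical(pep, tr$peptide[k])) {
      stop("layout error: truth record ", tr$peptide_id[k],
           " does not re-translate to its peptide")
    }
  }
  invisible(TRUE)
}

#' Refine gene-level truth records to domain-level intervals
#'
#' A motif scanner recovers the cysteine-spacing domain, not the full open
#' reading frame, so evaluation against long planted genes uses the
#' genomic interval of each domain.  Domains are located by running the
#' scanner on the known planted peptide (annotation of ground truth) and
#' mapping residue spans onto the gene's genomic coordinates.
#'
#' @param truth Truth table from [plant_genes()].
#' @param configs Named list mapping class to [spacing_config()]; classes
#'   without an entry (e.g. decoys) are dropped.
#' @return Data frame in the same shape as `truth`, one row per domain.
#' @export
domain_truth <- function(truth,
                         configs = list(
                           defensin = spacing_config("relaxed"),
                           ovodefensin = spacing_config("ovodefensin"))) {
  rows <- list()
  for (k in seq_len(nrow(truth))) {
    cls <- truth$class[k]
    if (!cls %in% names(configs)) next
    hits <- find_defensin_domains(truth$peptide[k], configs[[cls]],
                                  source_id = truth$peptide_id[k])
    for (j in seq_len(nrow(hits))) {
      s <- hits$start[j]; e <- hits$end[j]
      if (truth$strand[k] == "+") {
        ds <- truth$start[k] + 3L * (s - 1L)
        de <- truth$start[k] + 3L * e - 1L
      } else {
        de <- truth$end[k] - 3L * (s - 1L)
        ds <- truth$end[k] - 3L * e + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = truth$scaffold_id[k], start = ds, end = de,
        strand = truth$strand[k],
        peptide_id = paste0(truth$peptide_id[k], ".d", j),
        class = cls, peptide = substr(truth$peptide[k], s, e),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(truth[0, , drop = FALSE])
  }
  do.call(rbind, rows)
}

#' Evaluate scanner calls against a truth table
#'
#' A call matches a truth record when scaffold and strand agree and the
#' two intervals (each expanded by `tolerance` bases) overlap at least
#' 50\% reciprocally.  Matching is one-to-one (greedy, by descending
#' overlap).
#'
#' @param calls Data frame with columns `scaffold_id`, `start`, `end`,
#'   `strand`.
#' @param truth Data frame with the same coordinate columns.
#' @param tolerance Slack in bases applied to both interval ends.
#' @param min_overlap Minimum reciprocal overlap fraction.
#' @return List of class `"evaluation_report"`: `recall`, `precision`,
#'   `matched`, `missed`, `spurious`.
#' @export
evaluate_calls <- function(calls, truth, tolerance = 0L,
                           min_overlap = 0.5) {
  nc <- nrow(calls); nt <- nrow(truth)
  adj <- matrix(FALSE, nrow = nc, ncol = nt)
  for (i in seq_len(nc)) {
    for (j in seq_len(nt)) {
      if (calls$scaffold_id[i] != truth$scaffold_id[j] ||
          calls$strand[i] != truth$strand[j]) next
      a <- c(calls$start[i] - tolerance, calls$end[i] + tolerance)
      b <- c(truth$start[j] - tolerance, truth$end[j] + tolerance)
      ov <- min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L
      if (ov <= 0L) next
      adj[i, j] <- ov / (a[2L] - a[1L] + 1L) >= min_overlap &&
        ov / (b[2L] - b[1L] + 1L) >= min_overlap
    }
  }
  # maximum bipartite matching (Kuhn's augmenting paths)
  match_t <- rep(0L, nt)
  try_call <- function(i, seen) {
    for (j in which(adj[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L) {
        match_t[j] <<- i
        return(TRUE)
      }
      old <- match_t[j]
      match_t[j] <<- i
      res <- try_call(old, seen)
      if (res) return(TRUE)
      match_t[j] <<- old
    }
    FALSE
  }
  for (i in seq_len(nc)) try_call(i, rep(FALSE, nt))
  matched <- sum(match_t > 0L)
  missed <- nrow(truth) - matched
  spurious <- nrow(calls) - matched
  structure(list(
    recall = if (nrow(truth)) matched / nrow(truth) else NA_real_,
    precision = if (nrow(calls)) matched / nrow(calls) else NA_real_,
    matched = matched, missed = missed, spurious = spurious
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("recall %.3f (%d matched, %d missed); precision %.3f (%d spurious)\n",
              x$recall, x$matched, x$missed, x$precision, x$spurious))
  invisible(x)
}

#' Remove spurious background domains from a synthetic genome
#'
#' Random six-frame background occasionally contains chance
#' cysteine-spacing matches.  For a benchmark genome these would
#' contaminate precision estimates with events unrelated to the planted
#' decoys, so the background is certified at generation time (the same
#' principle as decoy certification): every scan call that is not a
#' genuine match to a truth record is disrupted by recoding one of its
#' background cysteine codons to alanine, and the genome is rescanned
#' until clean.  Planted intervals are never touched.
#'
#' @param genome List with `scaffolds` and `truth`, as from
#'   [plant_genes()].
#' @param configs List of [spacing_config()] objects to certify against.
#' @param min_overlap Reciprocal-overlap fraction qualifying a call as a
#'   genuine match.
#' @param max_iter Maximum rescan rounds.
#' @return The genome, with a certified background.
#' @export
sanitize_genome <- function(genome,
                            configs = list(spacing_config("relaxed"),
                                           spacing_config("ovodefensin")),
                            min_overlap = 0.5, max_iter = 10L) {
  truth <- genome$truth
  for (iter in seq_len(max_iter)) {
    calls <- do.call(rbind, lapply(configs, function(cf)
      scan_genome(genome$scaffolds, cf)))
    if (is.null(calls) || nrow(calls) == 0L) return(genome)
    bad <- vapply(seq_len(nrow(calls)), function(i) {
      !.matches_truth(calls[i, ], truth, min_overlap)
    }, logical(1L))
    if (!any(bad)) return(genome)
    scaff <- as.character(genome$scaffolds)
    for (i in which(bad)) {
      scaff <- .disrupt_call(scaff, calls[i, ], truth)
    }
    genome$scaffolds <- Biostrings::DNAStringSet(scaff)
  }
  stop("background sanitisation did not converge")
}

.matches_truth <- function(call, truth, min_overlap) {
  for (j in seq_len(nrow(truth))) {
    if (call$scaffold_id != truth$scaffold_id[j] ||
        call$strand != truth$strand[j]) next
    ov <- min(call$end, truth$end[j]) - max(call$start, truth$start[j]) + 1L
    if (ov <= 0L) next
    if (ov / (call$end - call$start + 1L) >= min_overlap ||
        ov / (truth$end[j] - truth$start[j] + 1L) >= min_overlap) {
      return(TRUE)
    }
  }
  FALSE
}

# recode one background cysteine codon of a spurious call to alanine
.disrupt_call <- function(scaff, call, truth) {
  pep <- strsplit(call$peptide, "", fixed = TRUE)[[1L]]
  cys_idx <- which(pep == "C")
  tr_sc <- truth[truth$scaffold_id == call$scaffold_id, , drop = FALSE]
  for (k in cys_idx) {
    if (call$strand == "+") {
      cs <- call$start + 3L * (k - 1L)
      ce <- cs + 2L
      codon <- "GCT"
    } else {
      ce <- call$end - 3L * (k - 1L)
      cs <- ce - 2L
      codon <- "AGC"  # reverse complement of GCT
    }
    clear <- !nrow(tr_sc) ||
      all(ce < tr_sc$start - 3L | cs > tr_sc$end + 3L)
    if (clear) {
      s <- scaff[[call$scaffold_id]]
      substr(s, cs, ce) <- codon
      scaff[[call$scaffold_id]] <- s
      return(scaff)
    }
  }
  scaff
}

#' Benchmark genome with all shipped AMP genes and certified decoys
#'
#' Builds a compact multi-scaffold synthetic genome carrying every shipped
#' Komodo dragon beta-defensin (66) and beta-ovodefensin (6) peptide as a
#' planted single-exon gene, plus certified non-matching cysteine-rich
#' decoys, over a sanitised background.  This is the standard end-to-end
#' evaluation input: a scanner with correct coordinate arithmetic should
#' recover every scannable domain (recall 1) and call nothing else
#' (precision 1).
#'
#' @param seed Integer master seed.
#' @param n_decoys Number of certified decoys to plant.
#' @param n_scaffolds Number of scaffolds.
#' @return List with `scaffolds`, `truth` (gene-level records incl.
#'   decoys) and `domain_truth` (per-domain intervals of the planted
#'   defensin/ovodefensin genes, built with the genome-scan
#'   configurations).
#' @export
benchmark_genome <- function(seed = 1L, n_decoys = 50L, n_scaffolds = 4L) {
  def <- komodo_peptides("defensin")
  ovo <- komodo_peptides("ovodefensin")
  peps <- c(as.character(def), as.character(ovo))
  cls <- c(rep("defensin", length(def)), rep("ovodefensin", length(ovo)))
  n <- length(peps)
  sc <- rep(seq_len(n_scaffolds), length.out = n)
  widths <- 3L * (nchar(peps) + 2L)
  pos <- integer(n)
  cursor <- rep(501L, n_scaffolds)
  for (i in seq_len(n)) {
    pos[i] <- cursor[sc[i]]
    cursor[sc[i]] <- cursor[sc[i]] + widths[i] + 400L
  }
  lengths <- rep(max(cursor) + 20000L, n_scaffolds)  # room for decoys
  planted <- data.frame(
    peptide_id = names(peps), peptide = unname(peps), scaffold = sc,
    position = pos, strand = rep(c("+", "-"), length.out = n),
    class = cls, stringsAsFactors = FALSE)
  spec <- synthetic_genome_spec(lengths = lengths, gc = 0.443,
                                planted = planted, n_decoys = n_decoys,
                                seed = seed)
  genome <- plant_genes(spec)
  genome <- sanitize_genome(genome)
  no_degen <- spacing_config("relaxed", degenerate_ranges = list())
  genome$domain_truth <- domain_truth(
    genome$truth,
    configs = list(defensin = no_degen,
                   ovodefensin = spacing_config("ovodefensin")))
  genome
}
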