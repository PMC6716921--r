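# Independent brute-force oracles.  These re-derive expected results by
# exhaustive enumeration and stay deliberately naive; they share no code
# with the package internals they check.

# --- domain scanner oracle -------------------------------------------------

oracle_gaps <- function(pos) diff(pos) - 1L

oracle_fits <- function(gaps, form) {
  length(gaps) == length(form) &&
    all(mapply(function(g, r) g >= r[1] && g <= r[2], gaps, form))
}

# every size-k subset of cysteine positions fitting a form, via combn
# (vectorised over the subset columns; still a plain exhaustive sweep)
oracle_enumerate <- function(cys, form) {
  k <- length(form) + 1L
  if (length(cys) < k) return(list())
  idx <- utils::combn(length(cys), k)
  pos <- matrix(cys[idx], nrow = k)
  gaps <- pos[-1L, , drop = FALSE] - pos[-k, , drop = FALSE] - 1L
  lo <- vapply(form, `[`, numeric(1), 1L)
  hi <- vapply(form, `[`, numeric(1), 2L)
  ok <- colSums(gaps >= lo & gaps <= hi) == k - 1L
  cons <- colSums(idx[-1L, , drop = FALSE] - idx[-k, , drop = FALSE] == 1L) ==
    k - 1L
  lapply(which(ok), function(j) list(pos = pos[, j], consecutive = cons[j]))
}

oracle_pick <- function(cands) {
  starts <- sapply(cands, function(x) x$pos[1])
  cands <- cands[starts == min(starts)]
  sizes <- sapply(cands, function(x) length(x$pos))
  cands <- cands[sizes == max(sizes)]
  ends <- sapply(cands, function(x) max(x$pos))
  cands[[which.max(ends)]]$pos
}

# full oracle: stop-bounded segments, consecutive-first selection, span
# capture for subset parses, degenerate fallback, trailing extension
oracle_find_domains <- function(seq, config) {
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  stops <- which(a == "*")
  cys <- which(a == "C")
  bounds <- c(0L, stops, length(a) + 1L)
  hits <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    seg <- cys[cys > bounds[s] & cys < bounds[s + 1L]]
    remaining <- seg
    seg_hits <- list()
    repeat {
      all_m <- unlist(lapply(config$forms, oracle_enumerate, cys = remaining),
                      recursive = FALSE)
      consec <- Filter(function(x) x$consecutive, all_m)
      sel <- NULL
      if (length(consec)) {
        sel <- oracle_pick(consec)
      } else if (length(all_m)) {
        sel <- oracle_pick(all_m)
        sel <- remaining[remaining >= min(sel) & remaining <= max(sel)]
      } else if (length(config$degenerate)) {
        dm <- unlist(lapply(config$degenerate, oracle_enumerate,
                            cys = remaining), recursive = FALSE)
        dm <- Filter(function(x) x$consecutive, dm)
        if (length(dm)) sel <- oracle_pick(dm)
      }
      if (is.null(sel)) break
      seg_hits[[length(seg_hits) + 1L]] <- sel
      remaining <- remaining[remaining > max(sel)]
      if (!length(remaining)) break
    }
    if (length(seg_hits) && config$extend_max > 0L) {
      for (i in seq_along(seg_hits)) {
        nxt <- if (i < length(seg_hits)) seg_hits[[i + 1L]][1] else Inf
        h <- seg_hits[[i]]
        repeat {
          nc <- seg[seg > max(h) & seg < nxt]
          if (!length(nc) || nc[1] - max(h) - 1L > config$extend_max) break
          h <- c(h, nc[1])
        }
        seg_hits[[i]] <- h
      }
    }
    hits <- c(hits, seg_hits)
  }
  hits
}

# compare scanner output with the oracle on one sequence
expect_scanner_equals_oracle <- function(seq, config) {
  got <- find_defensin_domains(seq, config)$cys_positions
  want <- lapply(oracle_find_domains(seq, config), as.integer)
  expect_identical(got, want, info = seq)
}

# --- random peptides -------------------------------------------------------

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# cysteine-enriched so that motif matches actually occur
random_peptide <- function(n, p_cys = 0.15) {
  prob <- rep((1 - p_cys) / 19, 20)
  prob[AA20 == "C"] <- p_cys
  paste(sample(AA20, n, replace = TRUE, prob = prob), collapse = "")
}

# --- alignment oracle ------------------------------------------------------

# exhaustive affine-gap, end-gap-free alignment score by recursion over all
# monotone paths (only feasible for short sequences)
oracle_overlap_score <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  best <- 0  # the all-gap path (empty overlap) scores zero
  rec <- function(i, j, sc, state, started) {
    # dovetail: the path ends once either sequence is exhausted; the
    # remaining suffix of the other is a free end gap
    if (i > n || j > m) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    # align av[i] with bv[j]
    rec(i + 1L, j + 1L, sc + mat[av[i], bv[j]], "m", TRUE)
    if (started) {
      # internal gaps only once the aligned region has begun
      pen_a <- if (state == "ga") gap_extend else gap_open + gap_extend
      rec(i + 1L, j, sc - pen_a, "ga", TRUE)
      pen_b <- if (state == "gb") gap_extend else gap_open + gap_extend
      rec(i, j + 1L, sc - pen_b, "gb", TRUE)
    }
  }
  # free leading gaps: any starting offsets
  for (i in seq_len(n)) rec(i, 1L, 0, "m", FALSE)
  for (j in seq_len(m)) rec(1L, j, 0, "m", FALSE)
  best
}

# --- evaluation oracle -----------------------------------------------------

# maximum bipartite matching by exhaustive recursion over truth assignment
oracle_max_matching <- function(adj, n_calls, n_truth) {
  best <- 0L
  rec <- function(t, used, count) {
    best <<- max(best, count)
    if (t > n_truth) return(invisible(NULL))
    rec(t + 1L, used, count)
    for (cc in which(adj[, t])) {
      if (!used[cc]) {
        used[cc] <- TRUE
        rec(t + 1L, used, count + 1L)
        used[cc] <- FALSE
      }
    }
  }
  if (n_truth > 0L && n_calls > 0L) rec(1L, rep(FALSE, n_calls), 0L)
  best
}
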