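# Alignment, ortholog assignment, clustering, labelling and naming

test_that("the published cathelicidin pair aligns at 70.00% identity", {
  a <- "FRWRRFFRKAKRFLKRHGVSIAIGTVRLLRRFG"
  b <- "RRWRRFFQKAKRFVKRHGVSIAVGAYRIIG"
  al <- global_align(a, b)
  expect_equal(al$identities, 21L)
  expect_equal(al$percent_identity, 70.00)
  expect_equal(nchar(al$aligned_query), nchar(al$aligned_subject))
})

test_that("self-alignment is gapless with 100% identity", {
  p <- "GLAKRKPRSRRECYSLDGSCYLGRCPSVLKKYGWCGTLKRCCIR"
  al <- global_align(p, p)
  expect_equal(al$percent_identity, 100.00)
  expect_false(grepl("-", al$aligned_query, fixed = TRUE))
  expect_error(global_align("", p), "empty")
})

test_that("alignment scores match the exhaustive DP oracle on short pairs", {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  mat <- as.matrix(env$BLOSUM62)
  set.seed(31)
  for (i in 1:20) {
    a <- random_peptide(sample(4:9, 1), p_cys = 0.05)
    b <- random_peptide(sample(4:9, 1), p_cys = 0.05)
    got <- global_align(a, b)$score
    want <- oracle_overlap_score(a, b, mat, gap_open = 10, gap_extend = 0.5)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("percent identity is symmetric and bounded", {
  set.seed(33)
  for (i in 1:10) {
    a <- random_peptide(sample(10:30, 1), p_cys = 0.05)
    b <- random_peptide(sample(10:30, 1), p_cys = 0.05)
    pab <- percent_identity(a, b)
    expect_equal(pab, percent_identity(b, a))
    expect_gte(pab, 0); expect_lte(pab, 100)
  }
})

test_that("ortholog assignment picks the best hit above threshold", {
  refs <- c(LzBD1 = "MKVCRRGGHCFAAACPSGEIGKCGGGKCCK",
            LzBD2 = "GFWDEACLKNGGECTAAAACPPGLRWWWCK",
            LzBD3 = "PPPPQQQQNNNNSSSSTTTTGGGG")
  q <- refs[["LzBD2"]]
  res <- assign_orthologs(c(q1 = q), refs, threshold = 40)
  expect_true(res$assigned)
  expect_equal(res$best_reference_id, "LzBD2")
  expect_equal(res$percent_identity, 100)
  # best hit equals an exhaustive all-pairs scan
  set.seed(37)
  qs <- setNames(vapply(1:5, function(i) random_peptide(25, 0.1), ""),
                 paste0("q", 1:5))
  res <- assign_orthologs(qs, refs, threshold = 0)
  for (i in seq_len(nrow(res))) {
    pids <- vapply(refs, function(r) percent_identity(qs[[res$query_id[i]]], r),
                   numeric(1))
    expect_equal(res$percent_identity[i], max(pids))
  }
  # below threshold -> unassigned; empty references warn
  far <- assign_orthologs(c(q = "WWWWWWWWWW"), refs["LzBD3"], threshold = 90)
  expect_false(far$assigned)
  expect_warning(assign_orthologs(c(q = "MKV"), character(0)), "empty")
})

test_that("single-linkage clustering groups loci within the gap", {
  loci <- data.frame(scaffold_id = "s", start = c(1000, 2000, 50000),
                     end = c(1100, 2100, 50100),
                     stringsAsFactors = FALSE)
  cl <- build_clusters(loci, max_gap = 10000)
  expect_length(cl, 2)
  expect_equal(nrow(cl[[1]]$loci), 2L)
  expect_equal(nrow(cl[[2]]$loci), 1L)
  expect_length(build_clusters(loci[0, ]), 0)
})

test_that("clustering equals transitive closure and ignores input order", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 12
    start <- sort(sample(1e6, n))
    loci <- data.frame(scaffold_id = sample(c("s1", "s2"), n, replace = TRUE),
                       start = start, end = start + 200,
                       stringsAsFactors = FALSE)
    gap <- 5e4
    cl <- build_clusters(loci, max_gap = gap)
    # oracle: transitive closure of the pairwise proximity relation
    key <- paste(loci$scaffold_id)
    groups <- seq_len(n)
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in 1:n) for (j in 1:n) {
        if (i != j && key[i] == key[j] && groups[i] != groups[j] &&
            max(loci$start[i], loci$start[j]) -
              min(loci$end[i], loci$end[j]) - 1 <= gap) {
          groups[groups == groups[j]] <- groups[i]
          changed <- TRUE
        }
      }
    }
    expect_length(cl, length(unique(groups)))
    # permutation invariance
    perm <- sample(n)
    cl2 <- build_clusters(loci[perm, ], max_gap = gap)
    sig <- function(cls) sort(vapply(cls, function(x)
      paste(x$scaffold_id, min(x$loci$start), max(x$loci$end)), ""))
    expect_equal(sig(cl), sig(cl2))
  }
})

fig3_loci <- function() {
  # hand-built arrangement: XKR6 | 3 ovodefensins | MTMR9 | ... | CTSB | 4 defensins
  loci <- data.frame(
    scaffold_id = "s210",
    start = c(10000, 13000, 16000, 460000, 463000, 466000, 469000),
    end = c(10100, 13100, 16100, 460100, 463100, 466100, 469100),
    strand = "+",
    peptide_id = paste0("p", 1:7),
    class = c(rep("ovodefensin", 3), rep("defensin", 4)),
    stringsAsFactors = FALSE)
  markers <- data.frame(
    scaffold_id = "s210",
    start = c(4000, 48000, 250000, 450000),
    end = c(5000, 49000, 251000, 451000),
    name = c("XKR6", "MTMR9", "BLK", "CTSB"),
    stringsAsFactors = FALSE)
  list(loci = loci, markers = markers)
}

test_that("marker labelling identifies ovodefensin and defensin clusters", {
  fx <- fig3_loci()
  cl <- label_clusters(build_clusters(fx$loci), fx$markers)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$label, "ovodefensin")
  expect_equal(cl[[1]]$left_marker, "XKR6")
  expect_equal(cl[[1]]$right_marker, "MTMR9")
  expect_equal(cl[[2]]$label, "defensin")
  expect_equal(cl[[2]]$left_marker, "CTSB")
  # no markers -> unlabelled
  cl0 <- build_clusters(fx$loci)
  expect_true(all(is.na(vapply(cl0, `[[`, "", "label"))))
  # a marker inside the cluster span is an anomaly, not a flank
  mk <- rbind(fx$markers,
              data.frame(scaffold_id = "s210", start = 13500, end = 13600,
                         name = "ODD"))
  cl2 <- label_clusters(build_clusters(fx$loci), mk)
  expect_equal(cl2[[1]]$anomalous_markers, "ODD")
})

test_that("naming numbers loci outward from the anchoring marker", {
  fx <- fig3_loci()
  cl <- assign_names(label_clusters(build_clusters(fx$loci), fx$markers),
                     fx$markers)
  ovo <- cl[[1]]$loci
  expect_equal(ovo$name[order(ovo$start)],
               c("VkOVOD3_VARKO", "VkOVOD2_VARKO", "VkOVOD1_VARKO"))
  def <- cl[[2]]$loci
  expect_equal(def$name[order(def$start)],
               paste0("VkBD", 1:4, "_VARKO"))
  # reversing the scaffold preserves numbering relative to the marker
  L <- 600000
  flip <- fx
  flip$loci[, c("start", "end")] <- cbind(L - fx$loci$end, L - fx$loci$start)
  flip$markers[, c("start", "end")] <-
    cbind(L - fx$markers$end, L - fx$markers$start)
  clf <- assign_names(label_clusters(build_clusters(flip$loci),
                                     flip$markers), flip$markers)
  deff <- clf[[which(vapply(clf, `[[`, "", "label") == "defensin")]]$loci
  expect_equal(deff$name[order(-deff$start)], paste0("VkBD", 1:4, "_VARKO"))
  # clusters without a label fall back to scaffold-prefixed ordinals
  cl_nolab <- assign_names(build_clusters(fx$loci))
  expect_true(all(grepl("^s210_locus", cl_nolab[[1]]$loci$name)))
})
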