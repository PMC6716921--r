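# Synthetic genome generator: backgrounds, planting, decoys, evaluation

test_that("random background hits the target GC and is seed-stable", {
  s <- random_background(10000, gc = 0.443, seed = 7)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 10000
  expect_gte(gc, 0.423); expect_lte(gc, 0.463)
  expect_identical(s, random_background(10000, gc = 0.443, seed = 7))
  expect_false(identical(s, random_background(10000, gc = 0.443, seed = 8)))
  at <- random_background(500, gc = 0, seed = 1)
  expect_false(grepl("[GC]", at))
  expect_error(random_background(100, gc = 1.2), "gc")
})

test_that("reverse translation round-trips through the standard code", {
  mk <- reverse_translate("MK", seed = 1)
  expect_equal(nchar(mk), 6L)
  expect_true(startsWith(mk, "ATG"))
  set.seed(55)
  for (i in 1:100) {
    p <- random_peptide(sample(5:60, 1))
    orf <- reverse_translate(p, seed = i)
    back <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                               no.init.codon = TRUE))
    expect_identical(back, p)
  }
  expect_identical(reverse_translate("ACDEFG", seed = 9),
                   reverse_translate("ACDEFG", seed = 9))
  expect_error(reverse_translate("MK*", seed = 1), "stop")
  # pseudogene planting: stops are encodable on request
  orf <- reverse_translate("MK*MK", seed = 1, allow_stop = TRUE)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                                  no.init.codon = TRUE)),
               "MK*MK")
})

test_that("planted genes re-translate from their truth coordinates", {
  planted <- data.frame(
    peptide_id = c("a", "b"),
    peptide = c("MKVLLRCGGAHW", "GGCAAAAAACAAAACAAAAAAAAACAAAAACC"),
    scaffold = c(1L, 2L), position = c(101L, 501L),
    strand = c("+", "-"), class = "defensin", stringsAsFactors = FALSE)
  spec <- synthetic_genome_spec(lengths = c(2000L, 3000L), planted = planted,
                                seed = 11)
  g <- plant_genes(spec)
  expect_equal(nrow(g$truth), 2L)
  expect_equal(g$truth$strand, c("+", "-"))
  for (k in 1:2) {
    seq <- Biostrings::subseq(g$scaffolds[[g$truth$scaffold_id[k]]],
                              g$truth$start[k], g$truth$end[k])
    if (g$truth$strand[k] == "-") seq <- Biostrings::reverseComplement(seq)
    expect_equal(as.character(Biostrings::translate(seq,
                                                    no.init.codon = TRUE)),
                 g$truth$peptide[k])
  }
  # identical spec + seed => byte-identical output
  g2 <- plant_genes(spec)
  expect_identical(as.character(g$scaffolds), as.character(g2$scaffolds))
  expect_identical(g$truth, g2$truth)
  # zero planted genes -> background only
  g0 <- plant_genes(synthetic_genome_spec(lengths = 1000L, seed = 3))
  expect_equal(nrow(g0$truth), 0L)
  # overlap is a layout error
  bad <- planted; bad$scaffold <- 1L; bad$position <- c(101L, 110L)
  expect_error(synthetic_genome_spec(lengths = 2000L, planted = bad),
               "overlap")
})

test_that("decoys are certified non-matching by scanner and oracle", {
  dec <- generate_decoys(10, seed = 13)
  expect_length(dec, 10)
  cfg_d <- spacing_config("relaxed")
  cfg_o <- spacing_config("ovodefensin")
  for (p in dec) {
    expect_gte(sum(strsplit(p, "")[[1]] == "C"), 6)
    expect_equal(nrow(find_defensin_domains(p, cfg_d)), 0L)
    expect_equal(nrow(find_defensin_domains(p, cfg_o)), 0L)
    # independent certification
    expect_length(oracle_find_domains(p, cfg_d), 0)
    expect_length(oracle_find_domains(p, cfg_o), 0)
  }
  expect_identical(dec, generate_decoys(10, seed = 13))
  expect_length(generate_decoys(0), 0)
})

test_that("call evaluation computes recall and precision correctly", {
  truth <- data.frame(scaffold_id = "s", start = c(100, 1000, 5000),
                      end = c(200, 1100, 5100), strand = "+",
                      stringsAsFactors = FALSE)
  ev <- evaluate_calls(truth, truth)
  expect_equal(ev$recall, 1); expect_equal(ev$precision, 1)
  half <- truth[1:2, ]
  # miss one truth record entirely
  ev2 <- evaluate_calls(half[1, , drop = FALSE], half)
  expect_equal(ev2$recall, 0.5)
  expect_equal(ev2$precision, 1)
  # below-threshold overlap does not match
  shifted <- transform(truth[1, , drop = FALSE],
                       start = start + 80, end = end + 80)
  ev3 <- evaluate_calls(shifted, truth[1, , drop = FALSE])
  expect_equal(ev3$matched, 0L)
  # strand must agree
  flip <- transform(truth, strand = "-")
  expect_equal(evaluate_calls(flip, truth)$matched, 0L)
})

test_that("greedy matching attains the exhaustive maximum matching", {
  set.seed(61)
  for (rep in 1:20) {
    n_t <- sample(2:5, 1); n_c <- sample(2:5, 1)
    truth <- data.frame(scaffold_id = "s",
                        start = sample(seq(100, 2000, by = 60), n_t),
                        strand = "+", stringsAsFactors = FALSE)
    truth$end <- truth$start + sample(50:150, n_t, replace = TRUE)
    calls <- data.frame(scaffold_id = "s",
                        start = sample(seq(100, 2000, by = 45), n_c),
                        strand = "+", stringsAsFactors = FALSE)
    calls$end <- calls$start + sample(50:150, n_c, replace = TRUE)
    ev <- evaluate_calls(calls, truth)
    adj <- matrix(FALSE, n_c, n_t)
    for (i in 1:n_c) for (j in 1:n_t) {
      ov <- min(calls$end[i], truth$end[j]) -
        max(calls$start[i], truth$start[j]) + 1
      adj[i, j] <- ov > 0 &&
        ov / (calls$end[i] - calls$start[i] + 1) >= 0.5 &&
        ov / (truth$end[j] - truth$start[j] + 1) >= 0.5
    }
    expect_equal(ev$matched, oracle_max_matching(adj, n_c, n_t))
  }
})
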