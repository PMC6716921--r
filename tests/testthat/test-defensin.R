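# Cysteine-spacing domain scanner

def_fix <- function() read_fasta(amp_fixture("komodo_beta_defensins.fasta"),
                                 "protein")
ovo_fix <- function() read_fasta(amp_fixture("komodo_ovodefensins.fasta"),
                                 "protein")

test_that("single-domain and multi-domain fixtures are parsed correctly", {
  fa <- def_fix()
  h1 <- find_defensin_domains(fa[["VkBD1_VARKO"]], source_id = "VkBD1")
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$gaps[[1]], c(6L, 3L, 9L, 6L, 0L))
  expect_equal(h1$spacing, "6-3-9-6")

  expect_equal(nrow(find_defensin_domains(fa[["VkBD39_VARKO"]])), 3L)
  for (id in c("VkBD7_VARKO", "VkBD34_VARKO", "VkBD43_VARKO")) {
    expect_equal(nrow(find_defensin_domains(fa[[id]])), 2L)
  }
  # every shipped beta-defensin peptide carries at least one domain
  ndom <- vapply(names(fa), function(n)
    nrow(find_defensin_domains(fa[[n]])), integer(1))
  expect_true(all(ndom >= 1L))

  # no spurious matches on cysteine-free sequence
  expect_equal(nrow(find_defensin_domains(strrep("A", 200))), 0L)
  expect_equal(nrow(find_defensin_domains("")), 0L)
})

test_that("ovodefensin mode recovers 6- and 8-cysteine domain variants", {
  ovo <- ovo_fix()
  h2 <- find_ovodefensin_domains(ovo[["VkOVOD2_VARKO"]])
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$gaps[[1]], c(6L, 3L, 13L, 6L, 0L))

  h4 <- find_ovodefensin_domains(ovo[["VkOVOD4_VARKO"]])
  expect_equal(h4$n_cys, 8L)
  expect_equal(h4$spacing, "3-3-3-9-1-6")

  # five cysteines cannot form an ovodefensin domain
  expect_equal(nrow(find_ovodefensin_domains("GGCAAACAAACAAACAAACGG")), 0L)
  ndom <- vapply(names(ovo), function(n)
    nrow(find_ovodefensin_domains(ovo[[n]])), integer(1))
  expect_true(all(ndom == 1L))
})

test_that("spacing strings join non-zero gaps with hyphens", {
  expect_equal(spacing_string(c(6, 3, 9, 6, 0)), "6-3-9-6")
  expect_equal(spacing_string(c(6, 2, 3, 10, 3, 3, 0)), "6-2-3-10-3-3")
  expect_equal(spacing_string(0L), "")
})

test_that("terminal-gap categories follow the canonical six-cysteine parse", {
  fa <- def_fix()
  cat_of <- function(id) {
    h <- find_defensin_domains(fa[[id]], source_id = id)
    terminal_gap_category(h)$terminal_gap_category
  }
  expect_equal(cat_of("VkBD12_VARKO"), "7")
  # eight cysteines without a CC-terminated first-six parse
  expect_equal(cat_of("VkBD16_VARKO"), "complex")
  # degenerate five-cysteine domains have no six-cysteine parse
  expect_equal(cat_of("VkBD59_VARKO"), "complex")
  # synthetic canonical domain C-X6-C-X4-C-X9-C-X5-CC
  syn <- paste0("GG", "C", strrep("A", 6), "C", strrep("A", 4), "C",
                strrep("A", 9), "C", strrep("A", 5), "CC", "GG")
  expect_equal(terminal_gap_category(
    find_defensin_domains(syn))$terminal_gap_category, "5")
  expect_error(terminal_gap_category(find_defensin_domains("AAA")),
               "at least one domain")
})

test_that("domains never span a stop and X never counts as cysteine", {
  base <- paste0("C", strrep("A", 6), "C", strrep("A", 4), "C",
                 strrep("A", 9), "C", strrep("A", 5), "CC")
  expect_equal(nrow(find_defensin_domains(base)), 1L)
  # a stop inside the motif kills it
  broken <- sub("AAAAAAAAA", "AAAA*AAAA", base)
  expect_equal(nrow(find_defensin_domains(broken)), 0L)
  # X in place of a required cysteine does not match (degenerate fallback
  # off: with five cysteines left it would report an eroded domain)
  xed <- sub("^C", "X", base)
  strict <- spacing_config("relaxed", degenerate_ranges = list())
  expect_equal(nrow(find_defensin_domains(xed, strict)), 0L)
  # with the fallback enabled the remaining five cysteines are reported
  # as a degenerate domain, classified complex
  h <- find_defensin_domains(xed)
  expect_equal(h$n_cys, 5L)
  expect_equal(terminal_gap_category(h)$terminal_gap_category, "complex")
})

test_that("scanner agrees with the exhaustive subset-enumeration oracle", {
  set.seed(101)
  cfg_d <- spacing_config("relaxed")
  cfg_o <- spacing_config("ovodefensin")
  for (i in 1:150) {
    p <- random_peptide(100)
    expect_scanner_equals_oracle(p, cfg_d)
    expect_scanner_equals_oracle(p, cfg_o)
  }
  # and on every shipped fixture peptide
  for (fa in list(def_fix(), ovo_fix())) {
    for (n in names(fa)) {
      expect_scanner_equals_oracle(as.character(fa[[n]]), cfg_d)
      expect_scanner_equals_oracle(as.character(fa[[n]]), cfg_o)
    }
  }
})

test_that("genome scanning maps domains to correct strand and interval", {
  pep <- "GGCAAAAAACAAAACAAAAAAAAACAAAAACCGG"  # C-X6-C-X4-C-X9-C-X5-CC
  expect_equal(nrow(find_defensin_domains(pep)), 1L)
  orf <- reverse_translate(pep, seed = 4)
  bg <- random_background(3000, seed = 5)
  s <- bg
  pos <- 1001L
  cassette <- paste0("TAA", orf, "TAA")
  rc_cass <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cassette)))
  substr(s, pos, pos + nchar(rc_cass) - 1L) <- rc_cass
  scaff <- Biostrings::DNAStringSet(c(syn = s))
  hits <- scan_genome(scaff, spacing_config("relaxed"))
  hits <- hits[hits$strand == "-", ]
  expect_gte(nrow(hits), 1L)
  # the called interval re-translates to the domain residues
  h <- hits[1, ]
  sub <- Biostrings::subseq(scaff[[1]], h$start, h$end)
  sub <- Biostrings::reverseComplement(sub)
  expect_equal(as.character(Biostrings::translate(sub,
                                                  no.init.codon = TRUE)),
               h$peptide)
  # domain residues 3..32 of the planted peptide (first to last cysteine)
  orf_start <- pos + 3L  # ORF begins after the flanking stop
  orf_end <- pos + nchar(cassette) - 4L
  expect_equal(h$end, orf_end - 3L * 2L)        # domain starts at residue 3
  expect_equal(h$start, orf_end - 3L * 32L + 1L)  # ends at residue 32

  # all-N scaffold yields nothing
  expect_equal(nrow(scan_genome(c(n = strrep("N", 300)))), 0L)
})

test_that("scanning a scaffold and its reverse complement mirrors hits", {
  g <- cached_fig3()
  s <- as.character(g$scaffolds[[1]])
  sub <- substr(s, 1, 60000)  # ovodefensin cluster region
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  h1 <- scan_genome(c(a = sub), spacing_config("ovodefensin"))
  h2 <- scan_genome(c(a = rc), spacing_config("ovodefensin"))
  expect_equal(nrow(h1), nrow(h2))
  L <- nchar(sub)
  mirrored <- data.frame(start = L - h2$end + 1L, end = L - h2$start + 1L,
                         strand = chartr("+-", "-+", h2$strand))
  mirrored <- mirrored[order(mirrored$start), ]
  h1o <- h1[order(h1$start), ]
  expect_equal(h1o$start, mirrored$start)
  expect_equal(h1o$end, mirrored$end)
  expect_equal(h1o$strand, mirrored$strand)
})
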