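# Access to the shipped Komodo dragon AMP fixtures: the published
# beta-defensin, beta-ovodefensin and cathelicidin peptide sets and the
# corresponding property tables (length, molecular weight, cysteine
# spacing, charge, isoelectric point).

#' Path to a shipped fixture file
#'
#' @param name File name under the package's `extdata` directory, e.g.
#'   `"komodo_beta_defensins.fasta"`.
#' @return Absolute path to the file.
#' @export
amp_fixture <- function(name) {
  p <- system.file("extdata", name, package = "ampminer")
  if (!nzchar(p)) stop("no such fixture: ", name)
  p
}

#' Load the Komodo dragon peptide fixtures
#'
#' @param class `"defensin"` (66 peptides), `"ovodefensin"` (6) or
#'   `"cathelicidin"` (3 precursors).
#' @return An `AAStringSet`.
#' @export
komodo_peptides <- function(class = c("defensin", "ovodefensin",
                                      "cathelicidin")) {
  class <- match.arg(class)
  f <- switch(class,
              defensin = "komodo_beta_defensins.fasta",
              ovodefensin = "komodo_ovodefensins.fasta",
              cathelicidin = "komodo_cathelicidins.fasta")
  read_fasta(amp_fixture(f), alphabet = "protein")
}

#' Load a published golden property table
#'
#' The published per-peptide property rows: identifier, length, average
#' molecular weight, cysteine-spacing string (dash glyphs normalised to
#' `-`), net charge and isoelectric point; for cathelicidins the mature
#' peptide, its length, integer net charge and molecular weight.
#'
#' @param class `"defensin"`, `"ovodefensin"` or `"cathelicidin"`.
#' @return A data frame.
#' @export
golden_table <- function(class = c("defensin", "ovodefensin",
                                   "cathelicidin")) {
  class <- match.arg(class)
  f <- switch(class,
              defensin = "golden_beta_defensins.tsv",
              ovodefensin = "golden_ovodefensins.tsv",
              cathelicidin = "golden_cathelicidins.tsv")
  utils::read.delim(amp_fixture(f), stringsAsFactors = FALSE)
}
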