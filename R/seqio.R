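# Sequence input/output and six-frame translation with genomic coordinate
# mapping.  Internally all arithmetic is done on 1-based residue indices and
# converted to genomic base intervals (1-based, inclusive) only at the
# boundary; serialized output (GFF3, TSV) is always 1-based inclusive.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

#' Read a FASTA file of scaffolds or peptides
#'
#' Reads a nucleotide or protein FASTA file into a
#' [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].  Sequences are
#' uppercased on ingest and validated against a strict alphabet: nucleotide
#' records may use `A C G T N` only, protein records the 20 standard amino
#' acids plus `X` (unknown) and `*` (stop).  Selenocysteine (`U`) and IUPAC
#' ambiguity codes other than `N` are rejected, as are records with empty
#' identifiers or empty sequences.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A `DNAStringSet` (nucleotide) or `AAStringSet` (protein), one
#'   element per record, in file order.
#' @examples
#' fa <- read_fasta(amp_fixture("komodo_cathelicidins.fasta"), "protein")
#' names(fa)
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA (line 1 must be a '>' header): ", path)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path)
  nms <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(nms))) {
    stop("record ", which(!nzchar(nms))[1L], " in '", path,
         "' has an empty identifier")
  }
  if (any(Biostrings::width(raw) == 0L)) {
    bad <- nms[Biostrings::width(raw) == 0L][1L]
    stop("record '", bad, "' in '", path, "' has an empty sequence")
  }
  seqs <- toupper(as.character(raw))
  names(seqs) <- nms
  allowed <- if (alphabet == "nucleotide") NUC_ALPHABET else AA_ALPHABET
  .check_alphabet(seqs, allowed, path)
  if (alphabet == "nucleotide") {
    Biostrings::DNAStringSet(seqs)
  } else {
    if (anyDuplicated(nms)) {
      stop("duplicated record id in '", path, "': ",
           nms[duplicated(nms)][1L])
    }
    Biostrings::AAStringSet(seqs)
  }
}

.check_alphabet <- function(seqs, allowed, path) {
  pat <- paste0("[^", paste(gsub("\\*", "\\\\*", allowed), collapse = ""), "]")
  bad <- regexpr(pat, seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    ch <- substr(seqs[i], bad[i], bad[i])
    stop("disallowed character '", ch, "' in record '", names(seqs)[i],
         "' of '", path, "'")
  }
  invisible(TRUE)
}

#' Write sequences to a 60-column wrapped FASTA file
#'
#' @param x A `DNAStringSet`, `AAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (length(x) == 0L) stop("no records to write")
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("character input to write_fasta() must be fully named")
    }
    x <- Biostrings::BStringSet(x)
  }
  ok <- tryCatch({
    Biostrings::writeXStringSet(x, filepath = path, width = 60L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write FASTA to: ", path)
  invisible(path)
}

#' Translate a scaffold in all six reading frames
#'
#' Translates a nucleotide sequence with the standard genetic code in the
#' three forward frames and the three frames of the reverse complement.
#' Codons containing `N` translate to `X`.  Each frame records enough
#' information to map any peptide position back to the genomic interval of
#' its codon (see [codon_interval()]).
#'
#' @param seq A `DNAString`, single-element `DNAStringSet` or character
#'   scalar of length at least 3.
#' @param id Scaffold identifier attached to every frame.
#' @return A list of six objects of class `"translated_frame"`, in order
#'   `+0, +1, +2, -0, -1, -2`.  Each has elements `scaffold_id`, `strand`,
#'   `frame_offset`, `peptide` (character, `*` at stops) and
#'   `scaffold_length`.
#' @examples
#' fr <- six_frame_translate("ATGAAATAA", id = "s")
#' fr[[1]]$peptide  # "MK*"
#' @export
six_frame_translate <- function(seq, id = "scaffold") {
  dna <- .as_dna(seq)
  len <- length(dna)
  if (len < 3L) stop("scaffold shorter than one codon (length ", len, ")")
  rc <- Biostrings::reverseComplement(dna)
  frames <- vector("list", 6L)
  k <- 1L
  for (strand in c("+", "-")) {
    src <- if (strand == "+") dna else rc
    for (off in 0:2) {
      n_codon <- (len - off) %/% 3L
      pep <- if (n_codon == 0L) "" else {
        sub <- Biostrings::subseq(src, start = off + 1L,
                                  width = 3L * n_codon)
        as.character(suppressWarnings(
          Biostrings::translate(sub, if.fuzzy.codon = "X",
                                no.init.codon = TRUE)))
      }
      frames[[k]] <- structure(
        list(scaffold_id = id, strand = strand, frame_offset = off,
             peptide = pep, scaffold_length = len),
        class = "translated_frame")
      k <- k + 1L
    }
  }
  frames
}

.as_dna <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  seq
}

#' Genomic interval of one codon of a translated frame
#'
#' @param frame A `"translated_frame"` from [six_frame_translate()].
#' @param i Peptide position (1-based).
#' @return Integer vector `c(start, end)`, the 3-base genomic interval
#'   (1-based inclusive) encoding residue `i` on the frame's strand.
#' @export
codon_interval <- function(frame, i) {
  stopifnot(inherits(frame, "translated_frame"))
  n <- nchar(frame$peptide)
  if (any(i < 1L | i > n)) stop("peptide index out of range")
  if (frame$strand == "+") {
    s <- frame$frame_offset + 3L * (i - 1L) + 1L
    c(start = s, end = s + 2L)
  } else {
    e <- frame$scaffold_length - frame$frame_offset - 3L * (i - 1L)
    c(start = e - 2L, end = e)
  }
}

#' Map a peptide interval of a frame to genomic coordinates
#'
#' @param frame A `"translated_frame"`.
#' @param res_start,res_end First and last peptide position (1-based,
#'   inclusive) of the region of interest.
#' @return Integer vector `c(start, end)` in genomic coordinates.
#' @export
frame_to_genomic <- function(frame, res_start, res_end) {
  stopifnot(res_start <= res_end)
  a <- codon_interval(frame, res_start)
  b <- codon_interval(frame, res_end)
  c(start = min(a[1L], b[1L]), end = max(a[2L], b[2L]))
}

#' Write feature annotations as GFF3
#'
#' Serializes a data frame of features through [rtracklayer::export()],
#' which emits the `##gff-version 3` pragma and percent-escapes reserved
#' characters in attribute values.
#'
#' @param hits Data frame with columns `scaffold_id`, `start`, `end`,
#'   `strand` (`+`, `-` or `.`), `feature_type` and `name`.  Additional
#'   columns are carried as GFF3 attributes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(hits, path) {
  req <- c("scaffold_id", "start", "end", "strand", "feature_type", "name")
  miss <- setdiff(req, names(hits))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(hits) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (any(hits$start > hits$end)) stop("feature with start > end")
  if (any(hits$start < 1L)) stop("feature with start < 1")
  strand <- ifelse(hits$strand %in% c("+", "-"), hits$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = hits$scaffold_id,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- hits$feature_type
  S4Vectors::mcols(gr)$Name <- hits$name
  S4Vectors::mcols(gr)$source <- "ampminer"
  extra <- setdiff(names(hits), req)
  for (cl in extra) S4Vectors::mcols(gr)[[cl]] <- hits[[cl]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a feature data frame
#'
#' Inverse of [write_gff3()]: parses through [rtracklayer::import()] and
#' returns the coordinate columns plus any attributes.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `scaffold_id`, `start`, `end`, `strand`,
#'   `feature_type`, `name` and any additional attributes.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_type = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    feature_type = as.character(S4Vectors::mcols(gr)$type),
    name = if (!is.null(S4Vectors::mcols(gr)$Name))
      as.character(S4Vectors::mcols(gr)$Name) else NA_character_,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(S4Vectors::mcols(gr)),
                   c("type", "Name", "source", "score", "phase"))
  for (cl in extra) out[[cl]] <- S4Vectors::mcols(gr)[[cl]]
  out
}
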