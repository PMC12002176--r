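#' Germline reference for VH186.2-style mutation calling
#'
#' Constructs a codon-framed germline V-segment reference. The analysed window
#' starts at `frame_offset` nucleotides into the sequence and must contain a
#' whole number of codons; the affinity-critical codon (codon 33 for the
#' VH186.2 / NP system, where the W33L replacement confers a ~10-fold affinity
#' gain) must encode tryptophan.
#'
#' @param seq Nucleotide string (A/C/G/T only).
#' @param name Reference name.
#' @param frame_offset Nucleotides before the first full codon (default 0).
#' @param key_codon_index 1-based codon index of the affinity-critical codon
#'   within the analysed window (default 33, sequential numbering).
#' @return An object of class `germline_reference` with fields `name`, `seq`,
#'   `frame_offset`, `key_codon_index`, `n_codons`.
#' @examples
#' ref <- make_reference(n_codons = 99, seed = 1)
#' ref$n_codons
#' @export
germline_reference <- function(seq, name = "reference", frame_offset = 0L,
                               key_codon_index = 33L) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq)) .stop2("reference sequence must be a single nonempty string")
  if (grepl("[^ACGT]", seq)) {
    if (grepl("N", seq, fixed = TRUE)) .stop2("ambiguous base in reference")
    .stop2("reference alphabet must be A/C/G/T")
  }
  frame_offset <- as.integer(frame_offset)
  key_codon_index <- as.integer(key_codon_index)
  if (frame_offset < 0L) .stop2("frame_offset must be >= 0")
  win_len <- nchar(seq) - frame_offset
  if (win_len < 3L || win_len %% 3L != 0L)
    .stop2("analysed window length (", win_len, " nt) is not a positive multiple of 3")
  n_codons <- win_len %/% 3L
  if (key_codon_index < 1L || key_codon_index > n_codons)
    .stop2("key_codon_index ", key_codon_index, " outside the ", n_codons, "-codon window")
  ref <- structure(
    list(name = name, seq = seq, frame_offset = frame_offset,
         key_codon_index = key_codon_index, n_codons = n_codons),
    class = "germline_reference")
  key_aa <- translate_codon(ref_codons(ref)[key_codon_index])
  if (!identical(key_aa, "W"))
    .stop2("key codon is ", key_aa, ", expected W")
  ref
}

#' Load a germline reference from a FASTA file
#'
#' @param path Path to a single-record FASTA file (A/C/G/T alphabet).
#' @param key_codon_index 1-based index of the tryptophan codon (default 33).
#' @param frame_offset Nucleotides before the first full codon.
#' @return A [germline_reference()].
#' @export
load_reference <- function(path, key_codon_index = 33L, frame_offset = 0L) {
  recs <- read_fasta(path)
  if (length(recs) != 1L) .stop2("reference FASTA must contain exactly one record, found ", length(recs))
  germline_reference(recs[[1L]], name = names(recs)[1L],
                     frame_offset = frame_offset, key_codon_index = key_codon_index)
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("<germline_reference> ", x$name, ": ", nchar(x$seq), " nt, ",
      x$n_codons, " codons, key codon ", x$key_codon_index, " (W)\n", sep = "")
  invisible(x)
}

# codons of the analysed window, in order
ref_codons <- function(ref) {
  win <- substr(ref$seq, ref$frame_offset + 1L, ref$frame_offset + 3L * ref$n_codons)
  substring(win, seq(1L, nchar(win), by = 3L), seq(3L, nchar(win), by = 3L))
}

# single-codon translation; NA for codons containing ambiguous bases
translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa
}

.leucine_codons <- function() names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "L"]
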