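#' Alignment scoring parameters
#'
#' Affine-gap scoring used when aligning Sanger reads to the germline
#' reference. Defaults (match 2, mismatch -1, gap open 6, gap extend 1) favour
#' substitution-only alignments for point-mutated reads while still exposing
#' genuine indels as gaps.
#'
#' @param match Match score.
#' @param mismatch Mismatch score.
#' @param gap_open Gap opening cost (positive).
#' @param gap_extend Gap extension cost (positive).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = 6, gap_extend = 1) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# substitution matrix over A/C/G/T/N; N is scored neutrally so ambiguous
# bases neither attract nor repel the alignment
.shm_submat <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align a read to the germline reference, codon by codon
#'
#' Performs a pairwise alignment of a Sanger read against the reference (the
#' read is aligned end-to-end; the reference is matched locally so that
#' partial reads yield reduced coverage rather than terminal gaps) and
#' projects the result onto the reference codon frame. Codon pairs are
#' emitted only for codons whose three reference positions are all covered by
#' read bases; any gap opening inside the analysed window sets `gap_flag`,
#' which downstream mutation counting treats as a frameshift.
#'
#' @param read Read sequence (string, possibly containing N) or a list with
#'   `read_id` and `seq`.
#' @param ref A [germline_reference()].
#' @param params An [align_params()] object.
#' @param read_id Optional read identifier (overrides names/list field).
#' @return An object of class `codon_alignment`: list with `read_id`,
#'   `pairs` (tibble: `codon_index`, `ref_codon`, `read_codon` for covered
#'   codons), `gap_flag`, `coverage`, `key_covered`.
#' @export
align_to_reference <- function(read, ref, params = align_params(), read_id = NULL) {
  seq <- if (is.list(read)) read$seq else read
  id <- read_id %||% (if (is.list(read)) read$read_id else names(read)) %||% "read"
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) .stop2("read sequence is empty")
  if (grepl("[^ACGTN]", seq)) .stop2("read alphabet must be A/C/G/T/N")

  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq),
    subject = Biostrings::DNAString(ref$seq),
    type = "global-local",
    substitutionMatrix = .shm_submat(params),
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend)

  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  s_start <- BiocGenerics::start(Biostrings::subject(aln))

  win_start <- ref$frame_offset + 1L
  win_end <- ref$frame_offset + 3L * ref$n_codons

  s_gap <- s == "-"
  p_gap <- p == "-"
  # reference coordinate of each alignment column (for insertion columns:
  # the reference position immediately to the left)
  s_pos <- cumsum(!s_gap) + s_start - 1L

  read_at <- rep(NA_character_, nchar(ref$seq))
  keep <- !s_gap & !p_gap
  read_at[s_pos[keep]] <- p[keep]

  del_pos <- s_pos[!s_gap & p_gap]               # read missing a reference base
  ins_pos <- s_pos[s_gap]                        # extra read base after this position
  gap_flag <- any(del_pos >= win_start & del_pos <= win_end) ||
    any(ins_pos >= win_start & ins_pos < win_end)

  codon_starts <- seq.int(win_start, win_end, by = 3L)
  read_codon <- vapply(codon_starts, function(st) {
    chars <- read_at[st:(st + 2L)]
    if (anyNA(chars)) NA_character_ else paste(chars, collapse = "")
  }, character(1L))
  covered <- !is.na(read_codon)

  pairs <- tibble::tibble(
    codon_index = which(covered),
    ref_codon = ref_codons(ref)[covered],
    read_codon = read_codon[covered])

  structure(
    list(read_id = id, pairs = pairs, gap_flag = gap_flag,
         coverage = mean(covered),
         key_covered = covered[ref$key_codon_index]),
    class = "codon_alignment")
}

#' Classify the affinity-critical codon of an aligned read
#'
#' Translates the read codon at the key position: tryptophan reads are `W`,
#' any leucine codon is `L` (the affinity-enhancing W33L class), any other
#' amino acid or a stop is `Other`, and codons containing N or not covered by
#' the read are `Undetermined`.
#'
#' @param aln A [align_to_reference()] result.
#' @param ref The [germline_reference()] used for the alignment.
#' @return One of `"W"`, `"L"`, `"Other"`, `"Undetermined"`.
#' @export
classify_codon33 <- function(aln, ref) {
  row <- aln$pairs[aln$pairs$codon_index == ref$key_codon_index, ]
  if (nrow(row) == 0L) return("Undetermined")
  codon <- row$read_codon[1L]
  if (grepl("N", codon, fixed = TRUE)) return("Undetermined")
  aa <- translate_codon(codon)
  if (is.na(aa)) return("Undetermined")
  if (aa == "W") "W" else if (aa == "L") "L" else "Other"
}
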