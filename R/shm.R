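#' Count replacement and silent mutations in an aligned read
#'
#' Walks the covered codon pairs of a read/reference alignment and emits one
#' mutation record per codon carrying at least one non-ambiguous mismatch.
#' All mismatching nucleotides within a codon inherit the codon-level class:
#' replacement if the translated amino acids differ, silent otherwise
#' (final-codon comparison, not a one-mutation-at-a-time decomposition).
#' Codons containing N contribute nothing. Reads with a gap inside the
#' analysed window are excluded as frameshifts; reads covering fewer than
#' `min_coverage` of the reference codons, or missing the key codon, are
#' excluded for low coverage. Excluded reads carry no partial counts.
#'
#' @param aln A [align_to_reference()] result.
#' @param ref The [germline_reference()] used.
#' @param min_coverage Minimum fraction of reference codons the read must
#'   cover (default 0.9); the key codon must always be covered.
#' @return An object of class `mutation_profile`: list with `read_id`,
#'   `codon33_class`, `n_replacement`, `n_silent`, `n_total`, `records`
#'   (tibble: `codon_index`, `nt_positions_changed`, `ref_codon`,
#'   `read_codon`, `ref_aa`, `read_aa`, `klass`), `excluded`, `reason`,
#'   `coverage`, `gap_flag`.
#' @export
count_rs_mutations <- function(aln, ref, min_coverage = 0.9) {
  empty_records <- tibble::tibble(
    codon_index = integer(), nt_positions_changed = character(),
    ref_codon = character(), read_codon = character(),
    ref_aa = character(), read_aa = character(), klass = character())

  profile <- function(n_r, n_s, records, excluded, reason) {
    structure(
      list(read_id = aln$read_id,
           codon33_class = classify_codon33(aln, ref),
           n_replacement = n_r, n_silent = n_s, n_total = n_r + n_s,
           records = records, excluded = excluded, reason = reason,
           coverage = aln$coverage, gap_flag = aln$gap_flag),
      class = "mutation_profile")
  }

  if (aln$gap_flag)
    return(profile(NA_integer_, NA_integer_, empty_records, TRUE, "frameshift"))
  if (aln$coverage < min_coverage || !isTRUE(aln$key_covered))
    return(profile(NA_integer_, NA_integer_, empty_records, TRUE, "low_coverage"))

  pairs <- aln$pairs
  n_r <- 0L
  n_s <- 0L
  recs <- list()
  for (i in seq_len(nrow(pairs))) {
    rc <- pairs$ref_codon[i]
    qc <- pairs$read_codon[i]
    if (grepl("N", qc, fixed = TRUE)) next
    if (rc == qc) next
    rch <- strsplit(rc, "")[[1L]]
    qch <- strsplit(qc, "")[[1L]]
    pos <- which(rch != qch)
    ref_aa <- translate_codon(rc)
    read_aa <- translate_codon(qc)
    klass <- if (!identical(ref_aa, read_aa)) "replacement" else "silent"
    if (klass == "replacement") n_r <- n_r + length(pos) else n_s <- n_s + length(pos)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      codon_index = pairs$codon_index[i],
      nt_positions_changed = paste(pos, collapse = ","),
      ref_codon = rc, read_codon = qc,
      ref_aa = ref_aa, read_aa = read_aa, klass = klass)
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else empty_records
  profile(n_r, n_s, records, FALSE, NA_character_)
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat("<mutation_profile> ", x$read_id, ": codon33 ", x$codon33_class,
      if (x$excluded) paste0(" [excluded: ", x$reason, "]")
      else paste0(", R=", x$n_replacement, " S=", x$n_silent), "\n", sep = "")
  invisible(x)
}

#' Call W33L status and R/S mutation counts for a set of reads
#'
#' End-to-end per-read pipeline: align each read to the germline reference,
#' classify the key codon, and count replacement/silent mutations. Optional
#' sample-sheet metadata (mouse, tissue, timepoint, compartment, ...) is
#' joined by `read_id` for downstream grouping.
#'
#' @param reads Named character vector of read sequences (names are read ids).
#' @param ref A [germline_reference()].
#' @param meta Optional data frame with a `read_id` column plus label columns.
#' @param params [align_params()] used for the alignments.
#' @param min_coverage Passed to [count_rs_mutations()].
#' @return A tibble with one row per read: `read_id`, `codon33_class`,
#'   `n_replacement`, `n_silent`, `n_total`, `coverage`, `gap_flag`,
#'   `excluded`, `reason`, plus any metadata columns.
#' @examples
#' ref <- make_reference(n_codons = 99, seed = 1)
#' sim <- simulate_shm_reads(ref, n_reads = 5, mu = 0.01, seed = 2)
#' shm_call(sim$reads, ref)
#' @export
shm_call <- function(reads, ref, meta = NULL, params = align_params(),
                     min_coverage = 0.9) {
  if (length(reads) == 0L) .stop2("no reads supplied")
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  if (anyDuplicated(ids)) .stop2("duplicate read ids")
  rows <- lapply(seq_along(reads), function(i) {
    aln <- align_to_reference(reads[[i]], ref, params = params, read_id = ids[i])
    pr <- count_rs_mutations(aln, ref, min_coverage = min_coverage)
    tibble::tibble(
      read_id = pr$read_id, codon33_class = pr$codon33_class,
      n_replacement = pr$n_replacement, n_silent = pr$n_silent,
      n_total = pr$n_total, coverage = pr$coverage, gap_flag = pr$gap_flag,
      excluded = pr$excluded, reason = pr$reason)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    if (!"read_id" %in% names(meta)) .stop2("meta must contain a read_id column")
    out <- dplyr::left_join(out, meta, by = "read_id")
  }
  out
}

#' Summarise W/L/Other fractions and pooled R/S ratios by group
#'
#' For each group (e.g. mouse x tissue x timepoint) reports the fraction of
#' classified reads calling tryptophan, leucine, or another amino acid at the
#' key codon, and the pooled replacement/silent mutation counts with their
#' ratio. Excluded reads and reads with an undetermined key codon are omitted
#' from the fractions and reported separately; R/S counts are pooled over all
#' non-excluded reads. A group whose pooled silent count is zero has an
#' undefined R/S ratio (`rs_ratio` NA, `rs_undefined` TRUE).
#'
#' @param profiles Per-read tibble from [shm_call()].
#' @param groupby Character vector of column names to group by (may be empty
#'   for a single overall summary).
#' @return A tibble with one row per group: `n_reads` (non-excluded),
#'   `n_excluded`, `n_undetermined`, `n_classified`, `frac_W`, `frac_L`,
#'   `frac_Other`, `sum_R`, `sum_S`, `rs_ratio`, `rs_undefined`.
#' @export
summarize_groups <- function(profiles, groupby = character()) {
  if (nrow(profiles) == 0L) .stop2("profiles is empty")
  missing_cols <- setdiff(groupby, names(profiles))
  if (length(missing_cols))
    .stop2("grouping column(s) not found: ", paste(missing_cols, collapse = ", "))
  profiles %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(groupby))) %>%
    dplyr::summarise(
      n_reads = sum(!excluded),
      n_excluded = sum(excluded),
      n_undetermined = sum(!excluded & codon33_class == "Undetermined"),
      n_classified = sum(!excluded & codon33_class %in% c("W", "L", "Other")),
      frac_W = ifelse(n_classified > 0,
                      sum(!excluded & codon33_class == "W") / n_classified, NA_real_),
      frac_L = ifelse(n_classified > 0,
                      sum(!excluded & codon33_class == "L") / n_classified, NA_real_),
      frac_Other = ifelse(n_classified > 0,
                          sum(!excluded & codon33_class == "Other") / n_classified, NA_real_),
      sum_R = sum(n_replacement[!excluded]),
      sum_S = sum(n_silent[!excluded]),
      rs_ratio = ifelse(sum_S > 0, sum_R / sum_S, NA_real_),
      rs_undefined = sum_S == 0,
      .groups = "drop")
}
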