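#' Read a FASTA file of nucleotide sequences
#'
#' Wrap-agnostic FASTA parsing; ids are the header up to the first
#' whitespace, must be unique, and sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stop2("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    .stop2("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) .stop2("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read an AIRR-style rearrangement table
#'
#' Accepts either a wide per-cell table (columns `cell_id`, `junction_vdj`,
#' `junction_vj`, plus labels) or a long one-chain-per-row table (columns
#' `cell_id`, `locus` or `chain`, `junction`, plus labels), which is pivoted
#' to the wide form. Heavy-chain rows are those with locus/chain matching
#' IGH/VDJ/heavy; all others are light. Cells lacking either chain are
#' dropped with a message giving the count (only cells with a single
#' productive pair per chain are analysable).
#'
#' @param path Path to a TSV file.
#' @return Tibble in wide form, one row per cell.
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  tab <- tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if ("junction_vdj" %in% names(tab)) {
    miss <- setdiff(c("cell_id", "junction_vdj", "junction_vj"), names(tab))
    if (length(miss)) .stop2("missing required column(s): ", paste(miss, collapse = ", "))
    wide <- tab
  } else {
    chain_col <- intersect(c("locus", "chain"), names(tab))[1L]
    miss <- setdiff(c("cell_id", "junction"), names(tab))
    if (is.na(chain_col)) miss <- c(miss, "locus (or chain)")
    if (length(miss)) .stop2("missing required column(s): ", paste(miss, collapse = ", "))
    heavy_pat <- "^(IGH|TRB|TRD|VDJ|heavy)$"
    tab$.chain <- ifelse(grepl(heavy_pat, tab[[chain_col]], ignore.case = TRUE),
                         "vdj", "vj")
    label_cols <- intersect(c("mouse", "tissue", "compartment", "timepoint"), names(tab))
    call_cols <- intersect(c("v_call", "j_call"), names(tab))
    long <- tab[, c("cell_id", ".chain", "junction", call_cols, label_cols)]
    wide <- tidyr::pivot_wider(
      long, id_cols = dplyr::all_of(c("cell_id", label_cols)),
      names_from = ".chain",
      names_glue = "{.value}_{.chain}",
      values_from = dplyr::all_of(c("junction", call_cols)),
      values_fn = function(x) x[1L])
    if (!"junction_vdj" %in% names(wide)) wide$junction_vdj <- NA_character_
    if (!"junction_vj" %in% names(wide)) wide$junction_vj <- NA_character_
  }
  n0 <- nrow(wide)
  keep <- !is.na(wide$junction_vdj) & nzchar(wide$junction_vdj) &
    !is.na(wide$junction_vj) & nzchar(wide$junction_vj)
  wide <- wide[keep, , drop = FALSE]
  if (sum(!keep) > 0)
    message("read_airr: dropped ", sum(!keep), " of ", n0, " cells lacking a paired chain")
  tibble::as_tibble(wide)
}

#' Write a tibble as a tab-separated file
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read per-GC cell coordinates from CSV
#'
#' Expected columns: `gc_id`, `x`, `y`, `cell_type`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_cells_csv <- function(path) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(c("gc_id", "x", "y", "cell_type"), names(tab))
  if (length(miss)) .stop2("missing required column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Read GC region polygons from CSV
#'
#' Expected columns: `gc_id`, `vertex_order`, `x`, `y`; one polygon per
#' `gc_id`, vertices sorted by `vertex_order`.
#'
#' @param path CSV path.
#' @return Named list of [gc_region()] objects, one per `gc_id`.
#' @export
read_regions_csv <- function(path) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gc_id", "vertex_order", "x", "y"), names(tab))
  if (length(miss)) .stop2("missing required column(s): ", paste(miss, collapse = ", "))
  lapply(split(tab, tab$gc_id), function(d) {
    d <- d[order(d$vertex_order), ]
    gc_region(d$x, d$y)
  })
}
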