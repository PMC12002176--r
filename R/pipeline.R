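#' Validated pipeline run configuration
#'
#' Builds and validates the parameter set for one pipeline stage. Unknown
#' keys are rejected; thresholds are checked against their documented ranges.
#'
#' @param stage One of `"shm"`, `"polarize"`, `"clones"`, `"simulate"`.
#' @param ... Stage parameters (see Details).
#' @details Common keys: `seed` (integer). Stage `shm`: `reads`, `reference`
#'   (paths), optional `sheet`, `key_codon` (default 33), `min_coverage`
#'   (0-1, default 0.9), `groupby`. Stage `polarize`: `cells`, `regions`
#'   (paths), optional `types`, `tol` (>= 0), `clip`. Stage `clones`:
#'   `airr` (path), `min_similarity` (0-1, default 0.85), `min_gc_cells`
#'   (>= 1, default 3), `require_same_vj`, `pool`. Stage `simulate`: `what`
#'   (`"shm"`, `"gc"`, or `"repertoire"`) plus the matching simulator
#'   arguments.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(stage = c("shm", "polarize", "clones", "simulate"), ...) {
  stage <- match.arg(stage)
  cfg <- list(...)
  known <- switch(stage,
    shm = c("reads", "reference", "sheet", "key_codon", "min_coverage",
            "groupby", "seed"),
    polarize = c("cells", "regions", "types", "tol", "clip", "seed"),
    clones = c("airr", "min_similarity", "min_gc_cells", "require_same_vj",
               "pool", "seed"),
    simulate = c("what", "seed", "n_reads", "mu", "p_w33l", "indel_rate",
                 "n_rate", "n_codons", "key_codon", "n_cells", "pi",
                 "n_clones", "clone_size_mean", "within_clone_div", "n_mice"))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    .stop2("unknown config key(s) for stage '", stage, "': ",
           paste(unknown, collapse = ", "))
  chk_range <- function(key, lo, hi) {
    if (!is.null(cfg[[key]]) && (cfg[[key]] < lo || cfg[[key]] > hi))
      .stop2(key, " must be in [", lo, ", ", hi, "]")
  }
  chk_range("min_coverage", 0, 1)
  chk_range("min_similarity", 0, 1)
  chk_range("mu", 0, 1)
  chk_range("p_w33l", 0, 1)
  chk_range("indel_rate", 0, 1)
  chk_range("n_rate", 0, 1)
  chk_range("pi", 0.5, 1)
  if (!is.null(cfg$tol) && cfg$tol < 0) .stop2("tol must be >= 0")
  if (!is.null(cfg$min_gc_cells) && cfg$min_gc_cells < 1)
    .stop2("min_gc_cells must be >= 1")
  if (stage == "simulate") {
    if (is.null(cfg$what) || !cfg$what %in% c("shm", "gc", "repertoire"))
      .stop2("simulate needs what = 'shm', 'gc', or 'repertoire'")
  }
  structure(c(list(stage = stage), cfg), class = "run_config")
}

#' Run one pipeline stage and write its outputs
#'
#' Executes the configured stage against the named input files and writes its
#' result tables plus a machine-readable `manifest.json` (package version,
#' seed, configuration, and MD5 checksums of the inputs) into `out_dir`.
#' Deterministic stages rerun with the same configuration reproduce their
#' outputs byte for byte. Inputs are checked before anything is written; a
#' failure mid-run leaves a `FAILED` marker file in `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  paths <- unlist(config[intersect(names(config),
                                   c("reads", "reference", "sheet", "cells",
                                     "regions", "airr"))])
  for (p in paths) if (!file.exists(p)) .stop2("input not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "FAILED")
  done <- FALSE
  on.exit(if (!done) file.create(marker), add = TRUE)

  switch(config$stage,
    shm = .stage_shm(config, out_dir),
    polarize = .stage_polarize(config, out_dir),
    clones = .stage_clones(config, out_dir),
    simulate = .stage_simulate(config, out_dir))

  manifest <- list(
    package = "ectopicgc",
    version = as.character(utils::packageVersion("ectopicgc")),
    stage = config$stage,
    seed = config$seed,
    config = config[setdiff(names(config), "stage")],
    inputs = if (length(paths))
      as.list(tools::md5sum(paths)) else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  done <- TRUE
  if (file.exists(marker)) file.remove(marker)
  invisible(out_dir)
}

.stage_shm <- function(cfg, out_dir) {
  ref <- load_reference(cfg$reference, key_codon_index = cfg$key_codon %||% 33L)
  reads <- read_fasta(cfg$reads)
  meta <- if (!is.null(cfg$sheet))
    tibble::as_tibble(utils::read.csv(cfg$sheet, stringsAsFactors = FALSE))
  profiles <- shm_call(reads, ref, meta = meta,
                       min_coverage = cfg$min_coverage %||% 0.9)
  write_tsv_table(profiles, file.path(out_dir, "read_profiles.tsv"))
  groupby <- cfg$groupby %||% intersect(c("mouse", "tissue", "timepoint", "compartment"),
                                        names(profiles))
  write_tsv_table(summarize_groups(profiles, groupby),
                  file.path(out_dir, "group_summary.tsv"))
}

.stage_polarize <- function(cfg, out_dir) {
  cells <- read_cells_csv(cfg$cells)
  regions <- read_regions_csv(cfg$regions)
  types <- cfg$types
  if (is.character(types) && length(types) == 1L && grepl(",", types))
    types <- strsplit(types, ",")[[1L]]
  rows <- lapply(names(regions), function(id) {
    sub <- cells[cells$gc_id == id, , drop = FALSE]
    smp <- spatial_sample(id, regions[[id]], sub[, c("x", "y", "cell_type")])
    spatial_summary(smp, types = types, tol = cfg$tol %||% 0,
                    clip = isTRUE(cfg$clip))
  })
  write_tsv_table(dplyr::bind_rows(rows), file.path(out_dir, "gc_summary.tsv"))
}

.stage_clones <- function(cfg, out_dir) {
  cells <- read_airr(cfg$airr)
  cs <- cluster_clonotypes(cells,
                           min_similarity = cfg$min_similarity %||% 0.85,
                           require_same_vj = isTRUE(cfg$require_same_vj),
                           pool = isTRUE(cfg$pool),
                           min_gc_cells = cfg$min_gc_cells %||% 3L)
  write_tsv_table(cs$cells[, c("cell_id", "clone_id")],
                  file.path(out_dir, "clone_membership.tsv"))
  write_tsv_table(cs$clones, file.path(out_dir, "clone_summary.tsv"))
  sh <- sharing_stats(cs)
  write_tsv_table(sh$pct, file.path(out_dir, "sharing_matrix.tsv"))
  jsonlite::write_json(sh$venn, file.path(out_dir, "venn_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.stage_simulate <- function(cfg, out_dir) {
  seed <- cfg$seed %||% 1L
  if (cfg$what == "shm") {
    ref <- make_reference(cfg$n_codons %||% 99L, seed = seed,
                          key_codon_index = cfg$key_codon %||% 33L)
    sim <- simulate_shm_reads(ref, cfg$n_reads %||% 100L, cfg$mu %||% 0.01,
                              p_w33l = cfg$p_w33l %||% 0,
                              indel_rate = cfg$indel_rate %||% 0,
                              n_rate = cfg$n_rate %||% 0, seed = seed + 1L)
    write_fasta(setNames(ref$seq, ref$name), file.path(out_dir, "reference.fasta"))
    write_fasta(sim$reads, file.path(out_dir, "reads.fasta"))
    write_tsv_table(sim$truth, file.path(out_dir, "truth.tsv"))
  } else if (cfg$what == "gc") {
    region <- gc_region(c(-100, 100, 100, -100), c(-100, -100, 100, 100))
    sim <- simulate_gc_sample(cfg$n_cells %||% 200L, cfg$pi %||% 0.75,
                              region, seed = seed)
    cells <- sim$sample$cells
    cells$gc_id <- sim$sample$gc_id
    write_tsv_table(cells, file.path(out_dir, "cells.tsv"))
    jsonlite::write_json(sim$truth[c("pi", "axis")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    sim <- simulate_repertoire(n_clones = cfg$n_clones %||% 50L,
                               clone_size_mean = cfg$clone_size_mean %||% 4,
                               within_clone_div = cfg$within_clone_div %||% 0.05,
                               n_mice = cfg$n_mice %||% 1L, seed = seed)
    write_tsv_table(sim$cells, file.path(out_dir, "rearrangements.tsv"))
    write_tsv_table(sim$truth, file.path(out_dir, "truth.tsv"))
  }
}
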