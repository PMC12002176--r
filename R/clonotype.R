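#' Normalized Hamming similarity between two junction sequences
#'
#' Junctions of equal length are compared position by position:
#' `1 - mismatches / length`. Comparison is case-insensitive; a position
#' carrying an ambiguous base (N) in either sequence is a mismatch. Junctions
#' of different lengths have undefined Hamming distance and score 0
#' (non-matching), mirroring common repertoire-tool behaviour.
#'
#' @param a,b Nonempty nucleotide strings.
#' @return Similarity in \[0, 1\].
#' @examples
#' junction_similarity("TGTGCAAGAGGGTACTAC", "TGTGCAAGAGGGTACTAC")
#' @export
junction_similarity <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L) .stop2("junction_similarity compares two single strings")
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) .stop2("empty junction sequence")
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) return(0)
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  mism <- sum(av != bv | av == "N" | bv == "N")
  1 - mism / nchar(a)
}

# pairwise similarity matrix for one chain; 0 across different lengths
.sim_matrix <- function(juncs) {
  n <- length(juncs)
  sim <- matrix(0, n, n)
  diag(sim) <- 1
  lens <- nchar(juncs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    k <- length(idx)
    if (k < 2L) next
    M <- do.call(rbind, strsplit(toupper(juncs[idx]), ""))
    isN <- M == "N"
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        mism <- sum(M[a, ] != M[b, ] | isN[a, ] | isN[b, ])
        s <- 1 - mism / L
        sim[idx[a], idx[b]] <- s
        sim[idx[b], idx[a]] <- s
      }
    }
  }
  sim
}

#' Cluster paired-chain rearrangements into clonotypes
#'
#' Builds a graph over cells with an edge when the heavy (VDJ) and light (VJ)
#' junctions both reach at least `min_similarity` normalized Hamming
#' similarity (the AND rule; `chain_rule = "or"` requires either chain), and
#' takes connected components (single linkage) as clonotypes. Mice are
#' clustered independently unless `pool = TRUE`. Clone ids are deterministic:
#' clusters are ordered by decreasing size, ties broken by the
#' lexicographically smallest member cell id.
#'
#' @param cells Data frame of rearrangements with columns `cell_id`,
#'   `junction_vdj`, `junction_vj`; optional `mouse`, `tissue`,
#'   `compartment`, `v_call_vdj`, `j_call_vdj`, `v_call_vj`, `j_call_vj`.
#' @param min_similarity Junction similarity threshold (default 0.85, i.e.
#'   at least 85% identity on both chains).
#' @param require_same_vj Additionally require identical V and J gene calls
#'   on both chains (default FALSE).
#' @param chain_rule `"and"` (default) or `"or"`: how the two chain
#'   thresholds combine.
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"` (hierarchical complete linkage cut at the threshold).
#' @param pool Cluster all mice together (default FALSE).
#' @param min_gc_cells GC-cell count at or above which a clone is flagged
#'   expanded (default 3).
#' @return Object of class `clone_set`: list with `cells` (input plus
#'   `clone_id`), `clones` (per-clone summary: `clone_id`, `mouse`, `size`,
#'   `n_gc`, `n_mbc`, `gc_tissues`, `expanded`), `counts` (long tibble of
#'   per-clone tissue x compartment counts), and `params`.
#' @examples
#' rep <- simulate_repertoire(n_clones = 5, seed = 1)
#' cs <- cluster_clonotypes(rep$cells)
#' cs$clones
#' @export
cluster_clonotypes <- function(cells, min_similarity = 0.85,
                               require_same_vj = FALSE,
                               chain_rule = c("and", "or"),
                               linkage = c("single", "complete"),
                               pool = FALSE, min_gc_cells = 3L) {
  chain_rule <- match.arg(chain_rule)
  linkage <- match.arg(linkage)
  cells <- tibble::as_tibble(cells)
  req <- c("cell_id", "junction_vdj", "junction_vj")
  miss <- setdiff(req, names(cells))
  if (length(miss)) .stop2("cells is missing column(s): ", paste(miss, collapse = ", "))
  params <- list(min_similarity = min_similarity, require_same_vj = require_same_vj,
                 chain_rule = chain_rule, linkage = linkage, pool = pool,
                 min_gc_cells = as.integer(min_gc_cells))
  if (nrow(cells) == 0L)
    return(structure(list(cells = cells, clones = tibble::tibble(),
                          counts = tibble::tibble(), params = params),
                     class = "clone_set"))
  if (anyDuplicated(cells$cell_id)) .stop2("duplicate cell_id values")
  if (any(!nzchar(cells$junction_vdj)) || any(!nzchar(cells$junction_vj)) ||
      anyNA(cells$junction_vdj) || anyNA(cells$junction_vj))
    .stop2("every cell needs both junction sequences (filter unpaired cells upstream)")
  if (require_same_vj) {
    vj_cols <- c("v_call_vdj", "j_call_vdj", "v_call_vj", "j_call_vj")
    if (!all(vj_cols %in% names(cells)))
      .stop2("require_same_vj = TRUE needs columns ", paste(vj_cols, collapse = ", "))
  }
  if (!"mouse" %in% names(cells)) cells$mouse <- "mouse1"

  groups <- if (pool) list(seq_len(nrow(cells))) else
    split(seq_len(nrow(cells)), cells$mouse)

  membership <- integer(nrow(cells))
  next_id <- 0L
  for (idx in groups) {
    sub <- cells[idx, , drop = FALSE]
    memb <- .cluster_group(sub, min_similarity, require_same_vj, chain_rule, linkage)
    membership[idx] <- memb + next_id
    next_id <- next_id + max(memb)
  }

  # deterministic clone ids: size desc, then smallest member cell_id
  key <- vapply(split(cells$cell_id, membership), min, character(1L))
  sizes <- table(membership)
  ord <- order(-as.integer(sizes[names(key)]), key)
  ranks <- setNames(seq_along(ord), names(key)[ord])
  width <- max(4L, nchar(length(ranks)))
  cells$clone_id <- sprintf(paste0("C%0", width, "d"), ranks[as.character(membership)])

  if (!"tissue" %in% names(cells)) cells$tissue <- NA_character_
  if (!"compartment" %in% names(cells)) cells$compartment <- NA_character_

  counts <- cells %>%
    dplyr::group_by(clone_id, mouse, tissue, compartment) %>%
    dplyr::summarise(n = dplyr::n(), .groups = "drop")

  clones <- cells %>%
    dplyr::group_by(clone_id, mouse) %>%
    dplyr::summarise(
      size = dplyr::n(),
      n_gc = sum(compartment %in% "GC"),
      n_mbc = sum(compartment %in% "MBC"),
      gc_tissues = paste(sort(unique(tissue[compartment %in% "GC"])), collapse = "+"),
      .groups = "drop") %>%
    dplyr::mutate(expanded = n_gc >= params$min_gc_cells) %>%
    dplyr::arrange(clone_id)

  structure(list(cells = cells, clones = clones, counts = counts, params = params),
            class = "clone_set")
}

# membership vector (1..k) for one mouse's cells
.cluster_group <- function(sub, min_similarity, require_same_vj, chain_rule, linkage) {
  n <- nrow(sub)
  if (n == 1L) return(1L)
  s_vdj <- .sim_matrix(sub$junction_vdj)
  s_vj <- .sim_matrix(sub$junction_vj)
  pass <- if (chain_rule == "and")
    s_vdj >= min_similarity & s_vj >= min_similarity
  else
    s_vdj >= min_similarity | s_vj >= min_similarity
  if (require_same_vj) {
    same <- outer(sub$v_call_vdj, sub$v_call_vdj, "==") &
      outer(sub$j_call_vdj, sub$j_call_vdj, "==") &
      outer(sub$v_call_vj, sub$v_call_vj, "==") &
      outer(sub$j_call_vj, sub$j_call_vj, "==")
    pass <- pass & same
  }
  diag(pass) <- TRUE
  if (linkage == "single") {
    g <- igraph::graph_from_adjacency_matrix(pass, mode = "undirected", diag = FALSE)
    as.integer(igraph::components(g)$membership)
  } else {
    score <- if (chain_rule == "and") pmin(s_vdj, s_vj) else pmax(s_vdj, s_vj)
    score[!pass] <- 0
    d <- stats::as.dist(1 - score)
    hc <- stats::hclust(d, method = "complete")
    as.integer(stats::cutree(hc, h = 1 - min_similarity))
  }
}

#' @export
print.clone_set <- function(x, ...) {
  cat("<clone_set> ", nrow(x$cells), " cells in ", nrow(x$clones), " clones (",
      sum(x$clones$expanded), " expanded; min_similarity ",
      x$params$min_similarity, ")\n", sep = "")
  invisible(x)
}

#' Expanded GC clones
#'
#' Restricts a clone set to clones with at least `min_gc_cells` GC-compartment
#' members (the paper's expansion definition: three or more GC B cells of the
#' same clone) and classifies each by the tissues of its GC members.
#'
#' @param clones A [cluster_clonotypes()] result.
#' @param min_gc_cells Minimum GC member count (default 3).
#' @return A `clone_set` restricted to expanded clones; its `clones` table
#'   gains `gc_tissue_class` (a single tissue name, or `"shared"` when GC
#'   members span more than one tissue).
#' @export
expanded_clones <- function(clones, min_gc_cells = 3L) {
  stopifnot(inherits(clones, "clone_set"))
  cl <- clones$clones
  cl$expanded <- cl$n_gc >= min_gc_cells
  keep <- cl$clone_id[cl$expanded]
  cl <- cl[cl$expanded, , drop = FALSE]
  cl$gc_tissue_class <- ifelse(grepl("+", cl$gc_tissues, fixed = TRUE),
                               "shared", cl$gc_tissues)
  out <- clones
  out$clones <- cl
  out$cells <- clones$cells[clones$cells$clone_id %in% keep, , drop = FALSE]
  out$counts <- clones$counts[clones$counts$clone_id %in% keep, , drop = FALSE]
  out$params$min_gc_cells <- as.integer(min_gc_cells)
  out
}

#' Cross-tissue and GC-to-memory clone sharing statistics
#'
#' For clones with at least one GC member: per-mouse counts of GC clones by
#' the set of tissues their GC members occupy (the Venn counts), and a
#' sharing matrix giving, for each source tissue, the percentage of its GC
#' clones that have at least one memory B cell (MBC) member in each target
#' tissue.
#'
#' @param clones A [cluster_clonotypes()] result.
#' @param per_mouse Compute the sharing matrix per mouse instead of pooled
#'   over mice (default FALSE: pooled).
#' @return List with `venn` (tibble: `mouse`, `gc_tissue_set`, `n_clones`)
#'   and `pct` (tibble: optionally `mouse`, `source_tissue`, `target_tissue`,
#'   `n_source_clones`, `n_shared`, `pct`, `undefined`).
#' @export
sharing_stats <- function(clones, per_mouse = FALSE) {
  stopifnot(inherits(clones, "clone_set"))
  cells <- clones$cells
  if (nrow(cells) == 0L) .stop2("empty clone set")
  tissues <- sort(unique(cells$tissue[!is.na(cells$tissue)]))

  gc_cells <- cells[cells$compartment %in% "GC", , drop = FALSE]
  mbc_cells <- cells[cells$compartment %in% "MBC", , drop = FALSE]

  gc_map <- gc_cells %>%
    dplyr::group_by(mouse, clone_id) %>%
    dplyr::summarise(gc_tissue_set = paste(sort(unique(tissue)), collapse = "+"),
                     .groups = "drop")
  venn <- gc_map %>%
    dplyr::group_by(mouse, gc_tissue_set) %>%
    dplyr::summarise(n_clones = dplyr::n(), .groups = "drop")

  mbc_by_clone <- split(mbc_cells$tissue, mbc_cells$clone_id)
  gc_by_clone <- split(gc_cells$tissue, gc_cells$clone_id)
  mouse_of_clone <- setNames(clones$clones$mouse, clones$clones$clone_id)

  pct_for <- function(clone_ids, mouse_label) {
    rows <- list()
    for (src in tissues) {
      src_clones <- clone_ids[vapply(gc_by_clone[clone_ids],
                                     function(tt) src %in% tt, logical(1L))]
      for (tgt in tissues) {
        n_src <- length(src_clones)
        n_sh <- sum(vapply(src_clones, function(cid) {
          tt <- mbc_by_clone[[cid]]
          !is.null(tt) && tgt %in% tt
        }, logical(1L)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mouse = mouse_label, source_tissue = src, target_tissue = tgt,
          n_source_clones = n_src, n_shared = n_sh,
          pct = if (n_src > 0) 100 * n_sh / n_src else NA_real_,
          undefined = n_src == 0)
      }
    }
    dplyr::bind_rows(rows)
  }

  gc_clone_ids <- names(gc_by_clone)
  pct <- if (per_mouse) {
    dplyr::bind_rows(lapply(sort(unique(cells$mouse)), function(m)
      pct_for(gc_clone_ids[mouse_of_clone[gc_clone_ids] == m], m)))
  } else {
    out <- pct_for(gc_clone_ids, NA_character_)
    out$mouse <- NULL
    out
  }
  list(venn = venn, pct = pct)
}
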