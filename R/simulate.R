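#' Generate a synthetic codon-framed germline reference
#'
#' Random codon sequence with no internal stop codons and TGG (tryptophan)
#' forced at the key codon, suitable as a VH186.2-style analysis window.
#'
#' @param n_codons Number of codons (must exceed the key codon index).
#' @param seed Random seed (optional).
#' @param key_codon_index 1-based key codon position (default 33).
#' @param name Reference name.
#' @return A [germline_reference()].
#' @examples
#' make_reference(n_codons = 99, seed = 1)
#' @export
make_reference <- function(n_codons, seed = NULL, key_codon_index = 33L,
                           name = "synthetic_VH") {
  if (!is.null(seed)) set.seed(seed)
  n_codons <- as.integer(n_codons)
  if (n_codons < key_codon_index + 1L)
    .stop2("n_codons must be at least key_codon_index + 1 (", key_codon_index + 1L, ")")
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- sample(sense, n_codons, replace = TRUE)
  codons[key_codon_index] <- "TGG"
  germline_reference(paste(codons, collapse = ""), name = name,
                     frame_offset = 0L, key_codon_index = key_codon_index)
}

.other_bases <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate somatically hypermutated reads with ground truth
#'
#' Emulates Sanger reads of sorted GC B cells: each base of the reference
#' mutates independently with probability `mu` (uniform over the three
#' alternative bases), the key codon is forced to the leucine codon TTG with
#' probability `p_w33l` (modelling selection for the affinity-enhancing
#' W33L replacement), single-base indels occur with probability `indel_rate`
#' per read, and bases are masked to N with probability `n_rate`. The truth
#' table records, per read, the substituted positions and the true key-codon
#' class and replacement/silent counts implied by the final sequence under
#' the codon-level counting convention.
#'
#' @param ref A [germline_reference()].
#' @param n_reads Number of reads.
#' @param mu Per-base substitution probability.
#' @param p_w33l Probability of forcing the key codon to TTG (leucine).
#' @param indel_rate Per-read probability of one random 1-nt insertion or
#'   deletion.
#' @param n_rate Per-base probability of masking to N.
#' @param seed Random seed (optional).
#' @param read_prefix Prefix for read ids.
#' @return List with `reads` (named character vector) and `truth` (tibble:
#'   `read_id`, `n_subs`, `sub_positions` (comma-separated 1-based
#'   positions), `codon33_class`, `n_replacement`, `n_silent`, `has_indel`,
#'   `n_n_masked`).
#' @examples
#' ref <- make_reference(99, seed = 1)
#' sim <- simulate_shm_reads(ref, 10, mu = 0.01, p_w33l = 0.4, seed = 2)
#' sim$truth
#' @export
simulate_shm_reads <- function(ref, n_reads, mu, p_w33l = 0, indel_rate = 0,
                               n_rate = 0, seed = NULL, read_prefix = "read") {
  for (p in c(mu, p_w33l, indel_rate, n_rate))
    if (p < 0 || p > 1) .stop2("probabilities must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ref_chars <- strsplit(ref$seq, "")[[1L]]
  L <- length(ref_chars)
  key_start <- ref$frame_offset + 3L * (ref$key_codon_index - 1L) + 1L
  bases <- c("A", "C", "G", "T")

  ids <- sprintf("%s%0*d", read_prefix, max(4L, nchar(n_reads)), seq_len(n_reads))
  reads <- character(n_reads)
  truth <- vector("list", n_reads)

  for (i in seq_len(n_reads)) {
    chars <- ref_chars
    sub_idx <- which(runif(L) < mu)
    for (j in sub_idx)
      chars[j] <- sample(.other_bases[[chars[j]]], 1L)
    if (runif(1L) < p_w33l)
      chars[key_start:(key_start + 2L)] <- c("T", "T", "G")
    # truth from the pre-masking, pre-indel sequence
    final_subs <- which(chars != ref_chars)
    n_idx <- which(runif(L) < n_rate)
    tr <- .shm_truth_counts(ref, chars, n_idx)
    chars[n_idx] <- "N"
    has_indel <- runif(1L) < indel_rate
    if (has_indel) {
      pos <- sample(L, 1L)
      if (runif(1L) < 0.5) {
        chars <- append(chars, sample(bases, 1L), after = pos)
      } else {
        chars <- chars[-pos]
      }
    }
    reads[i] <- paste(chars, collapse = "")
    truth[[i]] <- tibble::tibble(
      read_id = ids[i], n_subs = length(final_subs),
      sub_positions = paste(final_subs, collapse = ","),
      codon33_class = tr$codon33_class,
      n_replacement = tr$n_replacement, n_silent = tr$n_silent,
      has_indel = has_indel, n_n_masked = length(n_idx))
  }
  list(reads = setNames(reads, ids), truth = dplyr::bind_rows(truth))
}

# true codon-level R/S counts and key-codon class for a mutated sequence,
# skipping codons that will carry an N mask
.shm_truth_counts <- function(ref, chars, n_idx) {
  n_r <- 0L
  n_s <- 0L
  key_class <- "Undetermined"
  masked <- logical(length(chars))
  masked[n_idx] <- TRUE
  ref_chars <- strsplit(ref$seq, "")[[1L]]
  for (ci in seq_len(ref$n_codons)) {
    st <- ref$frame_offset + 3L * (ci - 1L) + 1L
    span <- st:(st + 2L)
    codon_masked <- any(masked[span])
    rc <- paste(ref_chars[span], collapse = "")
    qc <- paste(chars[span], collapse = "")
    if (ci == ref$key_codon_index) {
      key_class <- if (codon_masked) "Undetermined" else {
        aa <- translate_codon(qc)
        if (aa == "W") "W" else if (aa == "L") "L" else "Other"
      }
    }
    if (codon_masked || rc == qc) next
    k <- sum(ref_chars[span] != chars[span])
    if (identical(translate_codon(rc), translate_codon(qc))) n_s <- n_s + k
    else n_r <- n_r + k
  }
  list(codon33_class = key_class, n_replacement = n_r, n_silent = n_s)
}

#' Simulate a polarized GC point pattern with ground truth
#'
#' Draws a random axis through the region centroid; the half-region on one
#' side of the perpendicular line is "designated" and each cell falls in it
#' with probability `pi`, uniformly within its half (rejection sampling from
#' the region bounding box). `pi = 0.5` emulates an unpolarized GC,
#' `pi = 1.0` a fully compartmentalized cell type.
#'
#' @param n_cells Number of cells to place.
#' @param pi Polarization parameter in \[0.5, 1\]: probability mass on the
#'   designated half.
#' @param region A [gc_region()].
#' @param seed Random seed (optional).
#' @param gc_id Sample identifier.
#' @param cell_type Cell type label for the generated cells.
#' @return List with `sample` (a [spatial_sample()]) and `truth` (list:
#'   `pi`, `axis` unit vector, `seed`).
#' @export
simulate_gc_sample <- function(n_cells, pi, region, seed = NULL,
                               gc_id = "GC1", cell_type = "GCB") {
  if (pi < 0.5 || pi > 1) .stop2("pi must be in [0.5, 1]")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(region, "gc_region"))
  cen <- region_centroid(region)
  theta <- runif(1L, 0, 2 * base::pi)
  u <- c(cos(theta), sin(theta))
  poly <- rbind(region$xy, region$xy[1L, ])
  rng_x <- range(region$xy[, 1L])
  rng_y <- range(region$xy[, 2L])

  draw_in_half <- function(positive) {
    for (it in 1:10000) {
      p <- c(runif(1L, rng_x[1L], rng_x[2L]), runif(1L, rng_y[1L], rng_y[2L]))
      if (!mgcv::in.out(poly, matrix(p, 1L))) next
      s <- sum((p - cen) * u)
      if ((positive && s > 0) || (!positive && s < 0)) return(p)
    }
    .stop2("rejection sampling failed; is the region degenerate?")
  }

  designated <- runif(n_cells) < pi
  pts <- t(vapply(designated, draw_in_half, numeric(2L)))
  cells <- tibble::tibble(x = pts[, 1L], y = pts[, 2L], cell_type = cell_type)
  list(sample = spatial_sample(gc_id, region, cells),
       truth = list(pi = pi, axis = u, seed = seed))
}

.random_junction <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# mutates exactly round(div * length) positions so the realized divergence
# from the founder equals the requested fraction; any two members of a clone
# then differ at no more than 2 * div of positions
.mutate_junction <- function(junc, div) {
  if (div <= 0) return(junc)
  chars <- strsplit(junc, "")[[1L]]
  k <- round(div * length(chars))
  if (k == 0L) return(junc)
  idx <- sample(length(chars), k)
  for (j in idx) chars[j] <- sample(.other_bases[[chars[j]]], 1L)
  paste(chars, collapse = "")
}

#' Simulate a paired-chain B-cell repertoire with known clone labels
#'
#' Generates clonal families: each clone has founder heavy (VDJ) and light
#' (VJ) junctions and per-clone V/J gene calls; members copy the founders
#' with independent per-base divergence `within_clone_div`. Founder junctions
#' of equal length are regenerated (bounded rejection) until every pair is
#' below `max_founder_identity` identity, so distinct clones stay well below
#' the clustering threshold. Each clone belongs to one mouse; each member is
#' assigned a tissue and compartment by the given probabilities.
#'
#' @param n_clones Number of clones.
#' @param clone_size_mean Mean clone size; sizes are 1 + Poisson(mean - 1).
#' @param junction_len_vdj,junction_len_vj Candidate junction lengths (nt)
#'   sampled per clone.
#' @param within_clone_div Realized per-base divergence of each member from
#'   its clone founder (exactly `round(div * length)` positions are mutated).
#'   Member pairs then differ at no more than twice this fraction, so keep it
#'   below `(1 - threshold) / 2` for guaranteed clone recovery.
#' @param tissue_probs Named probabilities over tissues.
#' @param compartment_probs Named probabilities over compartments.
#' @param n_mice Number of mice; clones are assigned uniformly.
#' @param seed Random seed (optional).
#' @param max_founder_identity Maximum allowed pairwise founder identity.
#' @param max_attempts Rejection attempts per founder before erroring.
#' @return List with `cells` (tibble in wide AIRR-style form: `cell_id`,
#'   `mouse`, `tissue`, `compartment`, `junction_vdj`, `junction_vj`,
#'   `v_call_vdj`, `j_call_vdj`, `v_call_vj`, `j_call_vj`) and `truth`
#'   (tibble: `cell_id`, `clone_label`).
#' @examples
#' rep <- simulate_repertoire(n_clones = 10, seed = 3)
#' head(rep$cells)
#' @export
simulate_repertoire <- function(n_clones = 50, clone_size_mean = 4,
                                junction_len_vdj = seq(36, 57, by = 3),
                                junction_len_vj = seq(24, 39, by = 3),
                                within_clone_div = 0.05,
                                tissue_probs = c(lung = 0.5, mLN = 0.5),
                                compartment_probs = c(GC = 0.7, MBC = 0.3),
                                n_mice = 1L, seed = NULL,
                                max_founder_identity = 0.70,
                                max_attempts = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  if (within_clone_div < 0 || within_clone_div >= 1)
    .stop2("within_clone_div must be in [0, 1)")

  gen_founders <- function(len_choices) {
    founders <- character(n_clones)
    for (i in seq_len(n_clones)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        cand <- .random_junction(sample(len_choices, 1L))
        prev <- founders[seq_len(i - 1L)]
        same_len <- prev[nchar(prev) == nchar(cand)]
        if (all(vapply(same_len, function(s) junction_similarity(s, cand),
                       numeric(1L)) < max_founder_identity)) {
          founders[i] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) .stop2("could not generate sufficiently distinct founder junctions; ",
                      "increase junction lengths or reduce n_clones")
    }
    founders
  }

  founders_vdj <- gen_founders(junction_len_vdj)
  founders_vj <- gen_founders(junction_len_vj)
  v_genes_h <- paste0("IGHV1-", c(72, 53, 26, 9))
  j_genes_h <- paste0("IGHJ", 1:4)
  v_genes_l <- paste0("IGKV4-", c(50, 61, 74))
  j_genes_l <- paste0("IGKJ", 1:4)

  sizes <- 1L + rpois(n_clones, max(0, clone_size_mean - 1))
  mice <- paste0("mouse", sample.int(n_mice, n_clones, replace = TRUE))
  clone_v_h <- sample(v_genes_h, n_clones, TRUE)
  clone_j_h <- sample(j_genes_h, n_clones, TRUE)
  clone_v_l <- sample(v_genes_l, n_clones, TRUE)
  clone_j_l <- sample(j_genes_l, n_clones, TRUE)

  rows <- list()
  cell_i <- 0L
  for (cl in seq_len(n_clones)) {
    for (k in seq_len(sizes[cl])) {
      cell_i <- cell_i + 1L
      rows[[cell_i]] <- tibble::tibble(
        cell_id = sprintf("cell_%05d", cell_i),
        mouse = mice[cl],
        tissue = sample(names(tissue_probs), 1L, prob = tissue_probs),
        compartment = sample(names(compartment_probs), 1L, prob = compartment_probs),
        junction_vdj = .mutate_junction(founders_vdj[cl], within_clone_div),
        junction_vj = .mutate_junction(founders_vj[cl], within_clone_div),
        v_call_vdj = clone_v_h[cl], j_call_vdj = clone_j_h[cl],
        v_call_vj = clone_v_l[cl], j_call_vj = clone_j_l[cl],
        clone_label = sprintf("clone_%03d", cl))
    }
  }
  cells <- dplyr::bind_rows(rows)
  truth <- cells[, c("cell_id", "clone_label")]
  cells$clone_label <- NULL
  list(cells = cells, truth = truth)
}
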