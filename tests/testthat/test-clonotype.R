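mutate_at_positions <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

toy_cells <- function(junc_h, junc_l, tissue = NULL, compartment = NULL,
                      mouse = NULL) {
  n <- length(junc_h)
  tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(n)),
    mouse = mouse %||% rep("m1", n),
    tissue = tissue %||% rep("lung", n),
    compartment = compartment %||% rep("GC", n),
    junction_vdj = junc_h, junction_vj = junc_l)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("junction similarity is normalized Hamming with length and N rules", {
  j <- strrep("ACGTT", 4)  # length 20
  expect_equal(junction_similarity(j, j), 1.0)
  expect_equal(junction_similarity(j, mutate_at_positions(j, c(3, 17))), 0.9)
  expect_equal(junction_similarity(j, paste0(j, "A")), 0.0)
  expect_equal(junction_similarity(tolower(j), j), 1.0)
  # N positions always mismatch
  jn <- paste0("N", substr(j, 2, 20))
  expect_equal(junction_similarity(jn, jn), 1 - 1 / 20)
  expect_error(junction_similarity("", j), "empty junction")
})

test_that("single-linkage clustering joins chains through intermediate cells", {
  h <- strrep("ACGTT", 4)
  l <- strrep("GCTAA", 4)
  # A~B and B~C at 0.9 on both chains; A~C at 0.8 on both chains
  cells <- toy_cells(
    junc_h = c(h, mutate_at_positions(h, c(1, 2)), mutate_at_positions(h, c(1, 2, 6, 7))),
    junc_l = c(l, mutate_at_positions(l, c(4, 5)), mutate_at_positions(l, c(4, 5, 9, 10))))
  expect_equal(junction_similarity(cells$junction_vdj[1], cells$junction_vdj[3]), 0.8)
  cs <- cluster_clonotypes(cells)
  expect_equal(length(unique(cs$cells$clone_id)), 1L)

  # identical pair clusters together
  two <- toy_cells(c(h, h), c(l, l))
  expect_equal(length(unique(cluster_clonotypes(two)$cells$clone_id)), 1L)

  # passing on heavy only fails the AND rule...
  and_fail <- toy_cells(
    junc_h = c(h, mutate_at_positions(h, c(1, 2))),
    junc_l = c(l, mutate_at_positions(l, c(1, 2, 6, 7))))
  expect_equal(length(unique(cluster_clonotypes(and_fail)$cells$clone_id)), 2L)
  # ...but satisfies the OR rule
  expect_equal(length(unique(
    cluster_clonotypes(and_fail, chain_rule = "or")$cells$clone_id)), 1L)
})

test_that("gene-call agreement and per-mouse separation are honoured", {
  h <- strrep("ACGTT", 4); l <- strrep("GCTAA", 4)
  cells <- toy_cells(c(h, h), c(l, l))
  cells$v_call_vdj <- c("IGHV1-72", "IGHV1-53")
  cells$j_call_vdj <- "IGHJ2"
  cells$v_call_vj <- "IGKV4-50"
  cells$j_call_vj <- "IGKJ1"
  expect_equal(length(unique(
    cluster_clonotypes(cells, require_same_vj = TRUE)$cells$clone_id)), 2L)

  two_mice <- toy_cells(c(h, h), c(l, l), mouse = c("m1", "m2"))
  expect_equal(length(unique(cluster_clonotypes(two_mice)$cells$clone_id)), 2L)
  expect_equal(length(unique(
    cluster_clonotypes(two_mice, pool = TRUE)$cells$clone_id)), 1L)
})

test_that("clustering equals brute-force transitive closure on a 200-cell instance", {
  rep <- simulate_repertoire(n_clones = 40, clone_size_mean = 5,
                             within_clone_div = 0.07, n_mice = 2, seed = 21)
  cells <- head(rep$cells, 200)
  cs <- cluster_clonotypes(cells)
  expect_true(same_partition(cs$cells$clone_id, closure_oracle(cells)))
})

test_that("the partition ignores input row order and clone ids are deterministic", {
  rep <- simulate_repertoire(n_clones = 15, seed = 22)
  cs1 <- cluster_clonotypes(rep$cells)
  set.seed(23)
  perm <- sample(nrow(rep$cells))
  cs2 <- cluster_clonotypes(rep$cells[perm, ])
  m1 <- cs1$cells$clone_id[match(rep$cells$cell_id, cs1$cells$cell_id)]
  m2 <- cs2$cells$clone_id[match(rep$cells$cell_id, cs2$cells$cell_id)]
  expect_identical(m1, m2)
})

test_that("raising the similarity threshold only refines the partition", {
  rep <- simulate_repertoire(n_clones = 25, within_clone_div = 0.08, seed = 24)
  parts <- lapply(c(0.80, 0.85, 0.90), function(t)
    cluster_clonotypes(rep$cells, min_similarity = t)$cells$clone_id)
  refines <- function(fine, coarse) {
    # every fine cluster lies within one coarse cluster
    all(tapply(coarse, fine, function(x) length(unique(x))) == 1)
  }
  expect_true(refines(parts[[2]], parts[[1]]))
  expect_true(refines(parts[[3]], parts[[2]]))
})

test_that("simulated repertoires are recovered at ARI >= 0.99", {
  rep <- simulate_repertoire(n_clones = 50, within_clone_div = 0.05, seed = 25)
  cs <- cluster_clonotypes(rep$cells)
  truth <- rep$truth$clone_label[match(cs$cells$cell_id, rep$truth$cell_id)]
  expect_gte(mclust::adjustedRandIndex(cs$cells$clone_id, truth), 0.99)
})

test_that("expansion requires three or more GC members and tracks GC tissues", {
  h <- strrep("ACGTT", 4); l <- strrep("GCTAA", 4)
  # founders of distinct clones differ at 4 disjoint positions (similarity
  # 0.8, safely below the 0.85 threshold)
  mk <- function(i) c(mutate_at_positions(h, 4 * i + 1:4),
                      mutate_at_positions(l, 4 * i + 1:4))
  # clone 1: 3 GC lung; clone 2: 2 GC + 5 MBC; clone 3: GC in both tissues
  juncs <- rbind(
    t(replicate(3, mk(0))),
    t(replicate(7, mk(1))),
    t(replicate(4, mk(2))))
  cells <- toy_cells(
    junc_h = juncs[, 1], junc_l = juncs[, 2],
    tissue = c(rep("lung", 3), rep("lung", 7), c("lung", "lung", "mLN", "mLN")),
    compartment = c(rep("GC", 3), c("GC", "GC", rep("MBC", 5)), rep("GC", 4)))
  cs <- cluster_clonotypes(cells)
  expect_equal(nrow(cs$clones), 3)
  ex <- expanded_clones(cs)
  expect_equal(nrow(ex$clones), 2)
  expect_setequal(ex$clones$gc_tissue_class, c("lung", "shared"))
  not_exp <- setdiff(cs$clones$clone_id, ex$clones$clone_id)
  expect_equal(cs$clones$n_gc[cs$clones$clone_id == not_exp], 2L)
})

test_that("sharing statistics match hand enumeration on a toy clone table", {
  h <- strrep("ACGTT", 8); l <- strrep("GCTAA", 8)  # length 40
  # 10 clones with founders differing at disjoint 4-position blocks; each has
  # one GC lung cell; clones 1-2 also have a lung MBC member; clone 3 has an
  # mLN MBC member
  rows <- list()
  for (i in 1:10) {
    jh <- mutate_at_positions(h, 4 * (i - 1) + 1:4)
    jl <- mutate_at_positions(l, 4 * (i - 1) + 1:4)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cell_id = sprintf("gc%02d", i), mouse = "m1", tissue = "lung",
      compartment = "GC", junction_vdj = jh, junction_vj = jl)
    if (i <= 2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = sprintf("mb%02d", i), mouse = "m1", tissue = "lung",
        compartment = "MBC", junction_vdj = jh, junction_vj = jl)
    if (i == 3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = sprintf("mb%02d", i), mouse = "m1", tissue = "mLN",
        compartment = "MBC", junction_vdj = jh, junction_vj = jl)
  }
  cells <- dplyr::bind_rows(rows)
  cs <- cluster_clonotypes(cells)
  expect_equal(nrow(cs$clones), 10)
  sh <- sharing_stats(cs)
  lung_lung <- sh$pct[sh$pct$source_tissue == "lung" & sh$pct$target_tissue == "lung", ]
  expect_equal(lung_lung$n_source_clones, 10L)
  expect_equal(lung_lung$pct, 20)
  lung_mln <- sh$pct[sh$pct$source_tissue == "lung" & sh$pct$target_tissue == "mLN", ]
  expect_equal(lung_mln$pct, 10)
  # venn: all GC clones are lung-only
  expect_equal(sh$venn$gc_tissue_set, "lung")
  expect_equal(sh$venn$n_clones, 10L)
})

test_that("sharing is zero without memory cells and total with full membership", {
  h <- strrep("ACGTT", 4); l <- strrep("GCTAA", 4)
  mk_clone <- function(i, combos) {
    jh <- mutate_at_positions(h, i + 0:1)
    jl <- mutate_at_positions(l, i + 0:1)
    tibble::tibble(
      cell_id = sprintf("c%02d_%d", i, seq_len(nrow(combos))), mouse = "m1",
      tissue = combos$tissue, compartment = combos$compartment,
      junction_vdj = jh, junction_vj = jl)
  }
  all_gc <- dplyr::bind_rows(lapply(c(1, 5, 9), function(i)
    mk_clone(i, data.frame(tissue = c("lung", "mLN"), compartment = "GC"))))
  sh0 <- sharing_stats(cluster_clonotypes(all_gc))
  expect_true(all(sh0$pct$pct == 0))

  full <- dplyr::bind_rows(lapply(c(1, 5, 9), function(i)
    mk_clone(i, expand.grid(tissue = c("lung", "mLN"),
                            compartment = c("GC", "MBC"),
                            stringsAsFactors = FALSE))))
  shF <- sharing_stats(cluster_clonotypes(full))
  expect_true(all(shF$pct$pct == 100))
})
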