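# Independent oracles and fixture builders used across the suite.

# square region centered at the origin with half-width h
square_region <- function(h = 10) {
  gc_region(c(-h, h, h, -h), c(-h, -h, h, h))
}

# random star-shaped polygon: one vertex per angular slot keeps every gap
# below pi, which guarantees simplicity
random_polygon <- function(n_vert = sample(5:12, 1), scale = 1, center = c(0, 0)) {
  slot <- 2 * pi / n_vert
  ang <- (seq_len(n_vert) - 1) * slot + runif(n_vert, 0, 0.95 * slot)
  r <- runif(n_vert, 0.4, 1.5) * scale
  gc_region(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# Monte-Carlo polygon area by rejection sampling from the bounding box
mc_area <- function(region, n = 2e5) {
  xy <- region$xy
  poly <- rbind(xy, xy[1, ])
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  pts <- cbind(runif(n, rx[1], rx[2]), runif(n, ry[1], ry[2]))
  mean(mgcv::in.out(poly, pts)) * diff(rx) * diff(ry)
}

# pixel-average centroid on a grid rasterization of the polygon
raster_centroid <- function(region, grid = 600) {
  xy <- region$xy
  poly <- rbind(xy, xy[1, ])
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  gx <- seq(rx[1], rx[2], length.out = grid)
  gy <- seq(ry[1], ry[2], length.out = grid)
  pts <- cbind(rep(gx, times = grid), rep(gy, each = grid))
  inside <- mgcv::in.out(poly, pts)
  c(mean(pts[inside, 1]), mean(pts[inside, 2]))
}

bbox_diag <- function(region) {
  xy <- region$xy
  sqrt(diff(range(xy[, 1]))^2 + diff(range(xy[, 2]))^2)
}

# direct recount of the polarization fraction from its definition
polarization_oracle <- function(region, xy, tol = 0) {
  cen <- region_centroid(region)
  m <- colMeans(xy)
  d <- m - cen
  dn <- sqrt(sum(d^2))
  if (nrow(xy) < 2 || dn <= tol) return(0.5)
  u <- d / dn
  proj <- as.numeric((xy[, 1] - cen[1]) * u[1] + (xy[, 2] - cen[2]) * u[2])
  ties <- sum(abs(proj) <= tol)
  max(sum(proj > tol) + ties / 2, sum(proj < -tol) + ties / 2) / nrow(xy)
}

# brute-force position-wise R/S recount for an indel-free read, using
# seqinr's genetic code (independent of the package's translation path)
oracle_rs <- function(ref_seq, read_seq) {
  rc <- strsplit(ref_seq, "")[[1]]
  qc <- strsplit(toupper(read_seq), "")[[1]]
  stopifnot(length(rc) == length(qc))
  n_r <- 0L; n_s <- 0L
  for (st in seq(1, length(rc) - 2, by = 3)) {
    span <- st:(st + 2)
    if (any(qc[span] == "N")) next
    k <- sum(rc[span] != qc[span])
    if (k == 0) next
    aa_ref <- seqinr::translate(tolower(rc[span]))
    aa_read <- seqinr::translate(tolower(qc[span]))
    if (identical(aa_ref, aa_read)) n_s <- n_s + k else n_r <- n_r + k
  }
  c(n_replacement = n_r, n_silent = n_s)
}

# brute-force clonotype partition: pairwise threshold test + transitive
# closure by breadth-first search, one mouse at a time
closure_oracle <- function(cells, min_similarity = 0.85) {
  labels <- character(nrow(cells))
  for (m in unique(cells$mouse)) {
    idx <- which(cells$mouse == m)
    n <- length(idx)
    pass <- matrix(FALSE, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      pass[a, b] <-
        junction_similarity(cells$junction_vdj[idx[a]], cells$junction_vdj[idx[b]]) >= min_similarity &&
        junction_similarity(cells$junction_vj[idx[a]], cells$junction_vj[idx[b]]) >= min_similarity
    }
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(pass[v, ] & is.na(comp)))
      }
    }
    labels[idx] <- paste0(m, "_", comp)
  }
  labels
}

# two clusterings agree as partitions
same_partition <- function(a, b) {
  isTRUE(all.equal(mclust::adjustedRandIndex(a, b), 1))
}

# replace the codon at a 1-based codon index of a sequence
set_codon <- function(seq, codon_index, codon) {
  st <- 3 * (codon_index - 1) + 1
  paste0(substr(seq, 1, st - 1), codon, substr(seq, st + 3, nchar(seq)))
}
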