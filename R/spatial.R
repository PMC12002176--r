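#' Germinal-center region polygon
#'
#' A GC region is the CD95-delineated ROI as a simple polygon in micrometres.
#' Vertices may be given clockwise or counter-clockwise; a duplicated closing
#' vertex is dropped.
#'
#' @param x Numeric vector of x coordinates, or a two-column matrix /
#'   data frame of vertices.
#' @param y Numeric vector of y coordinates when `x` is a vector.
#' @param validate Check simplicity (no properly crossing edges) and
#'   positive area (default TRUE).
#' @return Object of class `gc_region`: list with `xy` (n x 2 matrix) and `n`.
#' @examples
#' sq <- gc_region(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' region_area(sq)
#' @export
gc_region <- function(x, y = NULL, validate = TRUE) {
  if (is.null(y)) {
    xy <- as.matrix(as.data.frame(x)[, 1:2])
  } else {
    xy <- cbind(x, y)
  }
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  n <- nrow(xy)
  if (n >= 4L && all(xy[1L, ] == xy[n, ])) {
    xy <- xy[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) .stop2("a region polygon needs at least 3 vertices")
  if (!all(is.finite(xy))) .stop2("region vertices must be finite")
  region <- structure(list(xy = xy, n = n), class = "gc_region")
  if (validate) {
    if (.self_intersects(xy)) .stop2("region polygon is self-intersecting")
    if (abs(.signed_area(xy)) < .Machine$double.eps * max(1, max(abs(xy))^2))
      .stop2("degenerate polygon: zero area")
  }
  region
}

#' @export
print.gc_region <- function(x, ...) {
  cat("<gc_region> ", x$n, " vertices, area ", signif(region_area(x), 6), "\n", sep = "")
  invisible(x)
}

.signed_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]) / 2
}

# proper edge crossings only; shared endpoints of adjacent edges are fine
.self_intersects <- function(xy) {
  n <- nrow(xy)
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (sharing a vertex)
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      a <- xy[i, ]; b <- xy[if (i == n) 1L else i + 1L, ]
      c <- xy[j, ]; d <- xy[if (j == n) 1L else j + 1L, ]
      o1 <- orient(a, b, c); o2 <- orient(a, b, d)
      o3 <- orient(c, d, a); o4 <- orient(c, d, b)
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

#' Polygon area of a GC region
#'
#' Shoelace area in square micrometres, positive regardless of vertex
#' orientation. This is the "GC area" measured from the CD95+ mask.
#'
#' @param region A [gc_region()].
#' @return Area (numeric scalar, same squared units as the coordinates).
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "gc_region"))
  abs(.signed_area(region$xy))
}

#' Area centroid of a GC region
#'
#' Continuous analogue of averaging the pixels inside the GC mask.
#'
#' @param region A [gc_region()].
#' @return Numeric vector `c(x, y)`.
#' @export
region_centroid <- function(region) {
  stopifnot(inherits(region, "gc_region"))
  xy <- region$xy
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cross <- xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]
  a <- sum(cross) / 2
  if (a == 0) .stop2("degenerate polygon: zero area")
  cx <- sum((xy[, 1L] + xy[j, 1L]) * cross) / (6 * a)
  cy <- sum((xy[, 2L] + xy[j, 2L]) * cross) / (6 * a)
  c(x = cx, y = cy)
}

#' One GC's region and typed cell coordinates
#'
#' @param gc_id Identifier for the GC.
#' @param region A [gc_region()].
#' @param cells Data frame with columns `x`, `y`, `cell_type` (coordinates in
#'   the same units as the region, typically micrometres).
#' @return Object of class `spatial_sample`.
#' @export
spatial_sample <- function(gc_id, region, cells) {
  stopifnot(inherits(region, "gc_region"))
  cells <- tibble::as_tibble(cells)
  req <- c("x", "y", "cell_type")
  miss <- setdiff(req, names(cells))
  if (length(miss)) .stop2("cells is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    .stop2("cell coordinates must be finite")
  structure(list(gc_id = gc_id, region = region, cells = cells),
            class = "spatial_sample")
}

#' @export
print.spatial_sample <- function(x, ...) {
  cat("<spatial_sample> ", x$gc_id, ": ", nrow(x$cells), " cells (",
      paste(unique(x$cells$cell_type), collapse = ", "), "), area ",
      signif(region_area(x$region), 6), "\n", sep = "")
  invisible(x)
}

.cells_of_type <- function(sample, cell_type) {
  cells <- sample$cells
  if (is.null(cell_type)) return(cells)
  avail <- unique(cells$cell_type)
  if (!cell_type %in% avail)
    .stop2("unknown cell_type '", cell_type, "'; available: ",
           paste(sort(avail), collapse = ", "))
  cells[cells$cell_type == cell_type, , drop = FALSE]
}

#' Germinal-center polarization fraction
#'
#' Measures how unevenly a cell type is distributed across the GC. A line is
#' drawn through the region centroid perpendicular to the axis joining the
#' region centroid and the cell-type centroid; cells are counted on each side
#' and the fraction is the larger count over the total, so it lies in
#' \[0.5, 1\]: 0.5 is an even split, 1.0 means all cells sit in one half (for
#' example all in the light zone). Cells whose perpendicular offset from the
#' line is within `tol` count half to each side. If the two centroids
#' coincide (within `tol`) or there are fewer than two cells, the direction
#' is undefined and the result is flagged degenerate with fraction 0.5
#' (maximally unpolarized).
#'
#' @param sample A [spatial_sample()].
#' @param cell_type Cell type to evaluate (NULL uses all cells).
#' @param tol Length tolerance for boundary cells and for the degenerate
#'   centroid-coincidence test, in coordinate units (default 0).
#' @return A tibble row: `cell_type`, `n_cells`, `fraction`, `degenerate`,
#'   `reason`.
#' @examples
#' sq <- gc_region(c(-10, 10, 10, -10), c(-10, -10, 10, 10))
#' cells <- data.frame(x = c(5, 6, 5, 6), y = c(0, 0, 1, 1), cell_type = "Tfh")
#' polarization_fraction(spatial_sample("gc1", sq, cells), "Tfh")
#' @export
polarization_fraction <- function(sample, cell_type = NULL, tol = 0) {
  stopifnot(inherits(sample, "spatial_sample"))
  cells <- .cells_of_type(sample, cell_type)
  n <- nrow(cells)
  label <- cell_type %||% "all"
  if (n < 1L) .stop2("no cells of type '", label, "'")
  out <- function(fraction, degenerate, reason = NA_character_)
    tibble::tibble(cell_type = label, n_cells = n, fraction = fraction,
                   degenerate = degenerate, reason = reason)
  if (n < 2L) return(out(0.5, TRUE, "fewer than 2 cells"))
  cen <- region_centroid(sample$region)
  m <- c(mean(cells$x), mean(cells$y))
  d <- m - cen
  dn <- sqrt(sum(d^2))
  if (dn <= tol) return(out(0.5, TRUE, "cell centroid coincides with region centroid"))
  u <- d / dn
  proj <- (cells$x - cen[1L]) * u[1L] + (cells$y - cen[2L]) * u[2L]
  ties <- sum(abs(proj) <= tol)
  pos <- sum(proj > tol) + ties / 2
  neg <- sum(proj < -tol) + ties / 2
  out(max(pos, neg) / n, FALSE)
}

#' Cell density within a GC
#'
#' Number of cells of a type divided by the region area, as in density
#' comparisons between lymph-node and ectopic lung GCs.
#'
#' @param sample A [spatial_sample()].
#' @param cell_type Cell type to count (NULL counts all cells).
#' @param clip Count only cells inside the region polygon (default FALSE:
#'   segmentation is normally restricted to the ROI already).
#' @return A tibble row: `cell_type`, `n_cells`, `area`, `density`.
#' @export
cell_density <- function(sample, cell_type = NULL, clip = FALSE) {
  stopifnot(inherits(sample, "spatial_sample"))
  cells <- sample$cells
  if (!is.null(cell_type)) cells <- cells[cells$cell_type == cell_type, , drop = FALSE]
  if (clip && nrow(cells) > 0L) {
    inside <- mgcv::in.out(rbind(sample$region$xy, sample$region$xy[1L, ]),
                           cbind(cells$x, cells$y))
    cells <- cells[inside, , drop = FALSE]
  }
  area <- region_area(sample$region)
  tibble::tibble(cell_type = cell_type %||% "all", n_cells = nrow(cells),
                 area = area, density = nrow(cells) / area)
}

#' Per-GC spatial summary table
#'
#' Density and polarization fraction for each requested cell type of one GC.
#'
#' @param sample A [spatial_sample()].
#' @param types Cell types to summarise (default: all types present).
#' @param tol Polarization tolerance, see [polarization_fraction()].
#' @param clip Passed to [cell_density()].
#' @return Tibble: `gc_id`, `cell_type`, `n_cells`, `area`, `density`,
#'   `fraction`, `degenerate`.
#' @export
spatial_summary <- function(sample, types = NULL, tol = 0, clip = FALSE) {
  types <- types %||% sort(unique(sample$cells$cell_type))
  rows <- lapply(types, function(ty) {
    dens <- cell_density(sample, ty, clip = clip)
    pol <- if (dens$n_cells >= 1L) {
      polarization_fraction(sample, ty, tol = tol)
    } else {
      tibble::tibble(fraction = NA_real_, degenerate = TRUE)
    }
    tibble::tibble(gc_id = sample$gc_id, cell_type = ty,
                   n_cells = dens$n_cells, area = dens$area,
                   density = dens$density, fraction = pol$fraction,
                   degenerate = pol$degenerate)
  })
  dplyr::bind_rows(rows)
}
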