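#' Equal-area concentric perfusion grid
#'
#' The grading grid is a disc partitioned into cells of identical area: one
#' central circular cell of radius \code{r0} surrounded by \code{n_rings}
#' annular rings, each of radial width \code{2 * r0}.  Ring \code{j} is split
#' into \code{8 * j} sectors, so every cell — central or sector — has area
#' \code{pi * r0^2}.  With the default 8 rings this gives 289 cells and a grid
#' radius of \code{17 * r0}.
#'
#' The innermost 121 cells (central cell plus rings 1–5) form the central
#' region used as an ETDRS seven-standard-fields equivalent; rings 6–8 (168
#' cells) form the peripheral region.
#'
#' @param n_rings Number of annular rings around the central cell (default 8).
#' @param r0 Radius of the central cell in grid units (default 1).
#' @param fovea_disc_fraction Fraction of the grid DIAMETER spanned by the
#'   fovea-to-disc distance after normalization (default 0.095).
#' @return An object of class \code{gridfa_grid} with fields \code{n_rings},
#'   \code{r0}, \code{total_radius}, \code{n_cells}, \code{fovea_disc_fraction}.
#' @examples
#' g <- grid_spec()
#' g$n_cells      # 289
#' g$total_radius # 17
#' @export
grid_spec <- function(n_rings = 8L, r0 = 1, fovea_disc_fraction = 0.095) {
  if (!is.numeric(n_rings) || length(n_rings) != 1L || n_rings < 1 ||
      n_rings != floor(n_rings))
    abort_invalid("`n_rings` must be a single integer >= 1")
  stopifnot_scalar_number(r0, "r0")
  if (r0 <= 0) abort_invalid("`r0` must be positive")
  stopifnot_scalar_number(fovea_disc_fraction, "fovea_disc_fraction")
  if (fovea_disc_fraction <= 0 || fovea_disc_fraction >= 1)
    abort_invalid("`fovea_disc_fraction` must be in (0, 1)")
  n_rings <- as.integer(n_rings)
  structure(
    list(
      n_rings = n_rings,
      r0 = r0,
      total_radius = (2 * n_rings + 1) * r0,
      n_cells = cell_count(n_rings),
      fovea_disc_fraction = fovea_disc_fraction
    ),
    class = "gridfa_grid"
  )
}

#' @export
print.gridfa_grid <- function(x, ...) {
  cat(sprintf(
    "Equal-area concentric grid: %d rings, %d cells, radius %g grid units (r0 = %g)\n",
    x$n_rings, x$n_cells, x$total_radius, x$r0
  ))
  invisible(x)
}

#' Total number of cells in an equal-area concentric grid
#'
#' Closed form \code{1 + 4 * n * (n + 1)}: a central cell plus \code{8 * j}
#' sectors in ring \code{j}.
#'
#' @param n_rings Number of rings (>= 0; 0 means the central cell only).
#' @return Integer cell count.
#' @examples
#' cell_count(8) # 289
#' cell_count(5) # 121
#' @export
cell_count <- function(n_rings) {
  if (!is.numeric(n_rings) || length(n_rings) != 1L || !is.finite(n_rings) ||
      n_rings < 0 || n_rings != floor(n_rings))
    abort_invalid("`n_rings` must be a single integer >= 0")
  n <- as.integer(n_rings)
  1L + 4L * n * (n + 1L)
}

#' Enumerate all cells of a grid with their geometry
#'
#' One row per cell in ring-major order (ring ascending, then sector
#' ascending).  Cell membership is half-open: a point belongs to the cell with
#' \code{r_inner <= r < r_outer} and \code{theta_start <= theta < theta_end},
#' so the cells partition the open disc of radius \code{total_radius}.
#'
#' @param grid A \code{gridfa_grid}.
#' @return data.frame with columns \code{id} (flat 0-based cell id),
#'   \code{ring}, \code{sector}, \code{r_inner}, \code{r_outer},
#'   \code{theta_start}, \code{theta_end}, \code{area}.
#' @export
grid_cells <- function(grid = grid_spec()) {
  check_grid(grid)
  n <- grid$n_rings
  r0 <- grid$r0
  ring <- rep.int(0:n, c(1L, 8L * seq_len(n)))
  sector <- unlist(c(list(0L), lapply(seq_len(n), function(j) 0:(8L * j - 1L))),
                   use.names = FALSE)
  n_sec <- pmax(8L * ring, 1L)
  r_inner <- ifelse(ring == 0L, 0, (2 * ring - 1) * r0)
  r_outer <- (2 * ring + 1) * r0
  theta_start <- 2 * pi * sector / n_sec
  theta_end <- 2 * pi * (sector + 1L) / n_sec
  area <- pi * (r_outer^2 - r_inner^2) / n_sec
  data.frame(
    id = cell_flat_id(ring, sector),
    ring = ring, sector = sector,
    r_inner = r_inner, r_outer = r_outer,
    theta_start = theta_start, theta_end = theta_end,
    area = area
  )
}

check_grid <- function(grid) {
  if (!inherits(grid, "gridfa_grid"))
    abort_invalid("`grid` must be created by grid_spec()")
  invisible(grid)
}

#' Flat cell id from (ring, sector) and back
#'
#' The flat id is 0 for the central cell; ring \code{j >= 1} occupies the
#' contiguous block starting at \code{1 + 4 * j * (j - 1)}.  Vectorized.
#'
#' @param ring,sector Integer vectors.
#' @return Integer flat ids (0-based).
#' @export
cell_flat_id <- function(ring, sector) {
  ring <- as.integer(ring); sector <- as.integer(sector)
  bad <- ring < 0L | sector < 0L | (ring == 0L & sector > 0L) |
    (ring > 0L & sector >= 8L * ring)
  if (any(bad, na.rm = TRUE)) abort_invalid("invalid (ring, sector) address")
  ifelse(ring == 0L, 0L, 1L + 4L * ring * (ring - 1L) + sector)
}

#' @rdname cell_flat_id
#' @param id Integer flat ids (0-based).
#' @param grid A \code{gridfa_grid} (bounds check).
#' @export
cell_from_flat_id <- function(id, grid = grid_spec()) {
  check_grid(grid)
  id <- as.integer(id)
  if (any(id < 0L | id >= grid$n_cells, na.rm = TRUE))
    abort_invalid("flat cell id out of range")
  # ring j occupies ids [(2j-1)^2, (2j+1)^2 - 1]; invert the square
  ring <- ifelse(id == 0L, 0L, floor((sqrt(id) + 1) / 2))
  ring <- as.integer(ring)
  # guard the floating-point square root at block boundaries
  ring <- ring - as.integer(id > 0L & (2L * ring - 1L)^2 > id)
  ring <- ring + as.integer((2L * ring + 1L)^2 <= id)
  sector <- ifelse(ring == 0L, 0L, id - (1L + 4L * ring * (ring - 1L)))
  data.frame(ring = ring, sector = as.integer(sector))
}

#' Locate grid-frame points in the grid
#'
#' Total function: points at radius >= \code{total_radius} get \code{NA}
#' ring/sector (the outside marker).  Membership follows the half-open
#' convention of \code{\link{grid_cells}}.
#'
#' @param x,y Numeric vectors of grid-unit coordinates.
#' @param grid A \code{gridfa_grid}.
#' @return data.frame with columns \code{ring}, \code{sector}, \code{id}
#'   (all NA for points outside the grid).
#' @export
locate_cell <- function(x, y, grid = grid_spec()) {
  check_grid(grid)
  r <- sqrt(x^2 + y^2) / grid$r0
  ring <- ifelse(r < 1, 0L, as.integer(floor((r + 1) / 2)))
  outside <- !is.finite(r) | r >= (2 * grid$n_rings + 1)
  theta <- atan2(y, x)
  theta <- ifelse(theta < 0, theta + 2 * pi, theta)
  nsec <- pmax(8L * ring, 1L)
  sector <- pmin(as.integer(floor(theta / (2 * pi) * nsec)), nsec - 1L)
  ring[outside] <- NA_integer_
  sector[outside] <- NA_integer_
  id <- rep(NA_integer_, length(r))
  ok <- !outside
  if (any(ok)) id[ok] <- cell_flat_id(ring[ok], sector[ok])
  data.frame(ring = ring, sector = sector, id = id)
}

# --- named regions -----------------------------------------------------------

region_names <- c("ENTIRE", "CENTRAL_ETDRS", "PERIPHERAL")

#' Named grid regions
#'
#' \code{CENTRAL_ETDRS} is the central cell plus rings 1–5 (121 cells on the
#' default grid), the equal-area equivalent of the ETDRS seven standard
#' fields; \code{PERIPHERAL} is everything outside it (rings 6+, 168 cells);
#' \code{ENTIRE} is the whole grid.
#'
#' @param name One of \code{"ENTIRE"}, \code{"CENTRAL_ETDRS"},
#'   \code{"PERIPHERAL"}.
#' @param grid A \code{gridfa_grid}.
#' @return List with \code{name} and the integer vector \code{rings}.
#' @export
region_def <- function(name, grid = grid_spec()) {
  check_grid(grid)
  if (!is.character(name) || length(name) != 1L || !(name %in% region_names))
    abort_invalid(sprintf(
      "unknown region '%s' (expected one of %s)",
      paste(name, collapse = ","), paste(region_names, collapse = ", ")
    ))
  central_max <- min(5L, grid$n_rings)
  rings <- switch(name,
    ENTIRE = 0:grid$n_rings,
    CENTRAL_ETDRS = 0:central_max,
    PERIPHERAL = if (grid$n_rings > central_max) (central_max + 1L):grid$n_rings else integer(0)
  )
  list(name = name, rings = as.integer(rings))
}

#' Cells of a named region, in deterministic ring-major order
#'
#' @inheritParams region_def
#' @return data.frame of cells (subset of \code{\link{grid_cells}} rows).
#' @examples
#' nrow(region_cells("CENTRAL_ETDRS")) # 121
#' nrow(region_cells("PERIPHERAL"))    # 168
#' @export
region_cells <- function(name, grid = grid_spec()) {
  rd <- region_def(name, grid)
  cells <- grid_cells(grid)
  cells[cells$ring %in% rd$rings, , drop = FALSE]
}

# --- rasterization -----------------------------------------------------------

#' Label raster of the grid in image space
#'
#' Maps every pixel center of an image of shape \code{image_shape}
#' (rows, cols) through \code{transform} into grid units and assigns it the
#' flat cell id + 1 (0 = outside the grid).  This is the quantitative path:
#' cell statistics are computed from pixels mapped INTO the grid, never from a
#' resampled image.
#'
#' @param grid A \code{gridfa_grid}.
#' @param transform A \code{gridfa_transform} (see
#'   \code{\link{compute_transform}}).
#' @param image_shape Integer (rows, cols).
#' @param chunk_rows Rows processed per block, to bound memory on large
#'   rasters.
#' @return Integer matrix of shape \code{image_shape}.
#' @export
grid_label_raster <- function(grid, transform, image_shape, chunk_rows = 1024L) {
  check_grid(grid)
  check_transform(transform)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    abort_invalid("`image_shape` must be (rows, cols), both >= 1")
  nr <- image_shape[1]; nc <- image_shape[2]
  out <- matrix(0L, nr, nc)
  for (row0 in seq(1L, nr, by = chunk_rows)) {
    rows <- row0:min(row0 + chunk_rows - 1L, nr)
    px <- rep(seq_len(nc), each = length(rows))     # x = column
    py <- rep(rows, times = nc)                     # y = row
    g <- grid_from_image(px, py, transform)
    loc <- locate_cell(g$x, g$y, grid)
    lab <- ifelse(is.na(loc$id), 0L, loc$id + 1L)
    out[rows, ] <- matrix(lab, nrow = length(rows))
  }
  out
}

#' Binary raster mask of one grid cell in image space
#'
#' Pixels whose centers map into the cell's half-open polar bounds.  Masks of
#' distinct cells are disjoint by construction.
#'
#' @param ring,sector Cell address.
#' @param grid A \code{gridfa_grid}.
#' @param transform A \code{gridfa_transform}.
#' @param image_shape Integer (rows, cols).
#' @return Logical matrix.
#' @export
cell_mask <- function(ring, sector, grid, transform, image_shape) {
  check_grid(grid)
  check_transform(transform)
  id <- cell_flat_id(ring, sector)
  lab <- grid_label_raster(grid, transform, image_shape)
  lab == (id + 1L)
}

#' Export the grid cell table to CSV
#'
#' @param grid A \code{gridfa_grid}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  cells <- grid_cells(grid)
  tryCatch(
    utils::write.csv(cells, path, row.names = FALSE),
    error = function(e) abort_io(sprintf("cannot write grid CSV to '%s': %s",
                                         path, conditionMessage(e)))
  )
  invisible(path)
}
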