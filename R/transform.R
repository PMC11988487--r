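#' Fovea / optic-disc landmarks
#'
#' Pixel coordinates use (x right, y down) with pixel centers at integer
#' coordinates; laterality is carried as metadata only (no mirroring is ever
#' applied, so sector identities are comparable within an eye, not across
#' OD/OS).
#'
#' @param fovea,disc_center Numeric (x, y) pixel coordinates.
#' @param laterality \code{"OD"}, \code{"OS"}, or \code{"unknown"}.
#' @return A \code{gridfa_landmarks} object.
#' @export
landmarks <- function(fovea, disc_center, laterality = "unknown") {
  if (length(fovea) != 2L || !all(is.finite(fovea)))
    abort_invalid("`fovea` must be finite (x, y)")
  if (length(disc_center) != 2L || !all(is.finite(disc_center)))
    abort_invalid("`disc_center` must be finite (x, y)")
  if (!laterality %in% c("OD", "OS", "unknown"))
    abort_invalid("`laterality` must be OD, OS or unknown")
  if (all(fovea == disc_center))
    abort_degenerate_landmarks("fovea and disc center coincide")
  structure(
    list(fovea = as.numeric(fovea), disc_center = as.numeric(disc_center),
         laterality = laterality),
    class = "gridfa_landmarks"
  )
}

#' Landmark similarity transform into the grid frame
#'
#' Solves the proper similarity (translation, rotation, isotropic scale — no
#' reflection) that sends the fovea to the grid origin and the optic-disc
#' center onto the positive horizontal grid axis at
#' \code{fovea_disc_fraction * 2 * total_radius} grid units from the origin,
#' i.e. the fovea–disc distance spans 9.5\% of the grid diameter by default.
#'
#' Convention: pixel y runs down; grid y runs up ("counterclockwise" in grid
#' units matches the displayed image).  Forward mapping of a pixel p:
#' \code{g = scale * R(theta) \%*\% flip(p - fovea)} with
#' \code{flip(x, y) = (x, -y)}.
#'
#' @param lm A \code{gridfa_landmarks}.
#' @param grid A \code{gridfa_grid}.
#' @return A \code{gridfa_transform} with fields \code{dx}, \code{dy}
#'   (translation in pixels, \code{= -fovea}), \code{theta} (radians),
#'   \code{scale} (grid units per pixel), \code{d_px} (fovea–disc pixel
#'   distance).
#' @export
compute_transform <- function(lm, grid = grid_spec()) {
  if (!inherits(lm, "gridfa_landmarks"))
    abort_invalid("`lm` must be created by landmarks()")
  check_grid(grid)
  v <- lm$disc_center - lm$fovea
  d_px <- sqrt(sum(v^2))
  if (d_px <= 0) abort_degenerate_landmarks("fovea and disc center coincide")
  target_x <- grid$fovea_disc_fraction * 2 * grid$total_radius
  # angle of the disc in the y-up frame; rotate by its negative
  alpha <- atan2(-v[2], v[1])
  structure(
    list(dx = -lm$fovea[1], dy = -lm$fovea[2],
         theta = -alpha, scale = target_x / d_px, d_px = d_px),
    class = "gridfa_transform"
  )
}

check_transform <- function(t) {
  if (!inherits(t, "gridfa_transform"))
    abort_invalid("`transform` must be created by compute_transform()")
  if (!is.finite(t$scale) || t$scale <= 0)
    abort_invalid("degenerate transform: scale must be positive")
  invisible(t)
}

#' Map pixel coordinates to grid units (and back)
#'
#' \code{grid_from_image} applies the forward similarity;
#' \code{image_from_grid} is its exact inverse (round trip is identity to
#' machine precision).  Vectorized over points.
#'
#' @param x,y Numeric coordinate vectors.
#' @param transform A \code{gridfa_transform}.
#' @return data.frame with columns \code{x}, \code{y}.
#' @export
grid_from_image <- function(x, y, transform) {
  check_transform(transform)
  vx <- x + transform$dx
  vy <- -(y + transform$dy)          # flip to y-up
  ct <- cos(transform$theta); st <- sin(transform$theta)
  data.frame(x = transform$scale * (ct * vx - st * vy),
             y = transform$scale * (st * vx + ct * vy))
}

#' @rdname grid_from_image
#' @export
image_from_grid <- function(x, y, transform) {
  check_transform(transform)
  ct <- cos(transform$theta); st <- sin(transform$theta)
  wx <- (ct * x + st * y) / transform$scale
  wy <- (-st * x + ct * y) / transform$scale
  data.frame(x = wx - transform$dx, y = -wy - transform$dy)
}

#' Physical calibration from the fovea–disc distance
#'
#' Assumes a constant anatomical fovea-to-disc distance (population mean
#' 4.76 mm, SD 0.34 mm from fundus photography), so that every grid cell
#' covers an equivalent retinal area across eyes.
#'
#' @param fovea_disc_mm Assumed anatomical distance, millimetres.
#' @param fovea_disc_sd_mm Population SD, metadata only.
#' @return A \code{gridfa_calibration}.
#' @export
physical_calibration <- function(fovea_disc_mm = 4.76, fovea_disc_sd_mm = 0.34) {
  stopifnot_scalar_number(fovea_disc_mm, "fovea_disc_mm")
  if (fovea_disc_mm <= 0) abort_invalid("`fovea_disc_mm` must be positive")
  structure(list(fovea_disc_mm = fovea_disc_mm,
                 fovea_disc_sd_mm = fovea_disc_sd_mm),
            class = "gridfa_calibration")
}

#' Millimetre calibration of an image and the grid
#'
#' @param lm A \code{gridfa_landmarks}.
#' @param cal A \code{gridfa_calibration}.
#' @param grid A \code{gridfa_grid}.
#' @return List: \code{mm_per_px}, \code{grid_diameter_mm}
#'   (\code{fovea_disc_mm / fovea_disc_fraction}), \code{cell_area_mm2}
#'   (grid disc area / cell count; about 6.8 mm^2 at defaults).
#' @export
mm_calibration <- function(lm, cal = physical_calibration(), grid = grid_spec()) {
  if (!inherits(cal, "gridfa_calibration"))
    abort_invalid("`cal` must be created by physical_calibration()")
  t <- compute_transform(lm, grid)
  diameter <- cal$fovea_disc_mm / grid$fovea_disc_fraction
  list(
    mm_per_px = cal$fovea_disc_mm / t$d_px,
    grid_diameter_mm = diameter,
    cell_area_mm2 = pi * (diameter / 2)^2 / grid$n_cells
  )
}

# --- display warping ---------------------------------------------------------

#' Warp an image into the grid frame (display only)
#'
#' Resamples the input so that output pixel centers correspond to regular
#' grid-frame coordinates: output pixel (row, col) sits at grid point
#' \code{((col - center[1]) * out_scale, -(row - center[2]) * out_scale)}.
#' Out-of-field samples are 0.  This warp is for presentation only; all
#' quantitative per-cell statistics map the grid into image space instead
#' (\code{\link{grid_label_raster}}), avoiding resampling bias.
#'
#' @param image Numeric matrix (grayscale, rows x cols).
#' @param transform A \code{gridfa_transform}.
#' @param out_shape Output (rows, cols); default same as input.
#' @param out_scale Grid units per output pixel; default \code{transform$scale}
#'   (input resolution).
#' @param center Output-pixel coordinates (x, y) of the grid origin; default
#'   the output center.
#' @param method \code{"bilinear"} or \code{"nearest"}.
#' @return Numeric matrix of shape \code{out_shape}.
#' @export
warp_image <- function(image, transform, out_shape = dim(image),
                       out_scale = transform$scale,
                       center = c((out_shape[2] + 1) / 2, (out_shape[1] + 1) / 2),
                       method = c("bilinear", "nearest")) {
  check_transform(transform)
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0L)
    abort_invalid("`image` must be a non-empty numeric matrix")
  out_shape <- as.integer(out_shape)
  nr <- out_shape[1]; nc <- out_shape[2]
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  gx <- (col - center[1]) * out_scale
  gy <- -(row - center[2]) * out_scale
  p <- image_from_grid(gx, gy, transform)
  matrix(sample_bilinear(image, p$x, p$y, method), nr, nc)
}

# Sample image at continuous (x = col, y = row) positions; 0 outside.
sample_bilinear <- function(image, x, y, method = "bilinear") {
  nr <- nrow(image); nc <- ncol(image)
  if (method == "nearest") {
    xi <- round(x); yi <- round(y)
    ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
    out <- numeric(length(x))
    out[ok] <- image[cbind(yi[ok], xi[ok])]
    return(out)
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  ok <- x0 >= 1 & (x0 + 1) <= nc & y0 >= 1 & (y0 + 1) <= nr
  if (any(ok)) {
    i00 <- cbind(y0[ok], x0[ok]);       i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok]);   i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- image[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      image[i01] * fx[ok] * (1 - fy[ok]) +
      image[i10] * (1 - fx[ok]) * fy[ok] +
      image[i11] * fx[ok] * fy[ok]
  }
  out
}

#' Extract matched assessment/control patches for one cell
#'
#' Returns the pixels of \code{cell} from the assessment image and from the
#' healthy-control image, each in its own grid frame, with the SAME brightness
#' gain applied to both (values clipped to [0, 1]) so the comparison stays
#' fair while visibility is adjusted.
#'
#' @param image,control_image Numeric matrices in [0, 1].
#' @param ring,sector Cell address.
#' @param t_image,t_control Transforms of the two images.
#' @param grid A \code{gridfa_grid}.
#' @param gain Positive brightness multiplier applied to both patches.
#' @return List with \code{assessment} and \code{control} (masked matrices
#'   cropped to the cell bounding box, NA outside the cell; NULL with
#'   \code{empty = TRUE} when the cell lies outside that image), plus
#'   \code{ring}, \code{sector}, \code{gain}.
#' @export
extract_cell_pair <- function(image, control_image, ring, sector,
                              t_image, t_control, grid = grid_spec(),
                              gain = 1) {
  stopifnot_scalar_number(gain, "gain")
  if (gain <= 0) abort_invalid("`gain` must be positive")
  one <- function(img, tr) {
    mask <- cell_mask(ring, sector, grid, tr, dim(img))
    if (!any(mask)) return(NULL)
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    patch <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    m <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    patch <- pmin(patch * gain, 1)
    patch[!m] <- NA_real_
    patch
  }
  a <- one(image, t_image)
  b <- one(control_image, t_control)
  list(assessment = a, control = b,
       empty = is.null(a) || is.null(b),
       ring = ring, sector = sector, gain = gain)
}
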