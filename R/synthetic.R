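#' Specification of a synthetic angiogram phantom
#'
#' The phantom emulates the gross appearance of a late arteriovenous phase
#' ultra-widefield angiogram: a bright branching vessel tree on a dark
#' background, dark nonperfusion blobs that locally erase the vasculature,
#' and peripheral lash-like occlusion wedges.  Per-cell ground-truth
#' perfusion (fraction of cell area outside all blobs) is emitted alongside
#' the image, so graders and statistics can be validated without patient
#' data.
#'
#' @param image_size Square image side in pixels (default 768).
#' @param seed Integer seed; the phantom is a pure function of (spec, seed).
#' @param vessel_density Main vessel branches per quadrant (default 6).
#' @param n_blobs Number of nonperfusion blobs.
#' @param blob_r_range Blob radius range in grid units.
#' @param blob_darkness Multiplier (< 1) applied to the background inside
#'   blobs.
#' @param artifact_bands Number of peripheral occlusion wedges.
#' @param landmark_jitter Uniform jitter (pixels) on the fovea/disc
#'   placements.
#' @param fovea_disc_px Fovea-to-disc distance in pixels before jitter;
#'   default 9\% of the image side, which lets the full grid fit the frame.
#' @return A \code{gridfa_phantom_spec}.
#' @export
phantom_spec <- function(image_size = 768L, seed = 1L, vessel_density = 6L,
                         n_blobs = 3L, blob_r_range = c(1.5, 3),
                         blob_darkness = 0.35, artifact_bands = 2L,
                         landmark_jitter = 2, fovea_disc_px = round(0.09 * image_size)) {
  if (image_size < 64) abort_invalid("`image_size` must be at least 64 pixels")
  if (n_blobs < 0 || vessel_density < 1 || artifact_bands < 0)
    abort_invalid("phantom counts must be nonnegative (vessel_density >= 1)")
  if (blob_r_range[1] > blob_r_range[2] || blob_r_range[1] < 0)
    abort_invalid("`blob_r_range` must be an increasing nonnegative range")
  structure(
    list(image_size = as.integer(image_size), seed = as.integer(seed),
         vessel_density = as.integer(vessel_density),
         n_blobs = as.integer(n_blobs), blob_r_range = blob_r_range,
         blob_darkness = blob_darkness,
         artifact_bands = as.integer(artifact_bands),
         landmark_jitter = landmark_jitter,
         fovea_disc_px = fovea_disc_px),
    class = "gridfa_phantom_spec"
  )
}

#' Generate a synthetic angiogram with known per-cell perfusion
#'
#' @param spec A \code{gridfa_phantom_spec}.
#' @param grid A \code{gridfa_grid}.
#' @return List: \code{image} (matrix in [0, 1]), \code{landmarks},
#'   \code{transform}, \code{truth} (data.frame ring, sector, fraction),
#'   \code{vessel_cells} (data.frame ring, sector, has_vessel),
#'   \code{artifact_cells} (data.frame ring, sector, artifact),
#'   \code{blobs}, \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec(), grid = grid_spec()) {
  if (!inherits(spec, "gridfa_phantom_spec"))
    abort_invalid("`spec` must be created by phantom_spec()")
  withr::with_seed(spec$seed, generate_phantom_impl(spec, grid))
}

generate_phantom_impl <- function(spec, grid) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  jit <- function() stats::runif(2, -spec$landmark_jitter, spec$landmark_jitter)
  fovea <- c(ctr, ctr) + jit()
  ang <- stats::runif(1, -pi, pi)
  disc <- fovea + spec$fovea_disc_px * c(cos(ang), sin(ang)) + jit()
  lm <- landmarks(fovea, disc, laterality = "OD")
  tr <- compute_transform(lm, grid)

  # blobs in grid units
  blobs <- NULL
  if (spec$n_blobs > 0) {
    br <- stats::runif(spec$n_blobs, spec$blob_r_range[1], spec$blob_r_range[2])
    bd <- sqrt(stats::runif(spec$n_blobs)) * (grid$total_radius - 2 * grid$r0)
    ba <- stats::runif(spec$n_blobs, 0, 2 * pi)
    blobs <- data.frame(x = bd * cos(ba), y = bd * sin(ba), r = br * grid$r0)
  }

  truth <- cell_truth_fractions(blobs, grid)
  if (mean(truth$fraction) < 0.05)
    abort_invalid("rejected phantom spec: blobs cover more than 95% of the grid")

  # peripheral lash-like occlusion wedges (angular intervals, outer rings)
  art <- NULL
  if (spec$artifact_bands > 0) {
    a0 <- stats::runif(spec$artifact_bands, 0, 2 * pi)
    aw <- stats::runif(spec$artifact_bands, 0.25, 0.6)
    art <- data.frame(start = a0, width = aw)
  }
  art_r_min <- (2 * 6 - 1) * grid$r0  # wedges occlude rings 6 and beyond

  vessels <- vessel_tree_points(spec, grid)
  vessel_cells <- vessel_presence(vessels, blobs, grid)
  artifact_cells <- artifact_overlap(art, grid)

  image <- render_phantom(spec, grid, tr, vessels, blobs, art, art_r_min)

  list(image = image, landmarks = lm, transform = tr, truth = truth,
       vessel_cells = vessel_cells, artifact_cells = artifact_cells,
       blobs = blobs, artifacts = art, spec = spec)
}

# Ground truth: fraction of each cell's area outside all blobs, by stratified
# midpoint integration uniform in area (16 x 16 sample points per cell).
cell_truth_fractions <- function(blobs, grid, k = 16L) {
  cells <- grid_cells(grid)
  u <- (seq_len(k) - 0.5) / k
  frac <- vapply(seq_len(nrow(cells)), function(i) {
    c_ <- cells[i, ]
    r <- sqrt(c_$r_inner^2 + u * (c_$r_outer^2 - c_$r_inner^2))
    th <- c_$theta_start + u * (c_$theta_end - c_$theta_start)
    px <- as.vector(outer(r, cos(th)))
    py <- as.vector(outer(r, sin(th)))
    if (is.null(blobs) || !nrow(blobs)) return(1)
    inside <- rep(FALSE, length(px))
    for (b in seq_len(nrow(blobs))) {
      inside <- inside |
        ((px - blobs$x[b])^2 + (py - blobs$y[b])^2 < blobs$r[b]^2)
    }
    1 - mean(inside)
  }, numeric(1))
  data.frame(ring = cells$ring, sector = cells$sector, fraction = frac)
}

# Random-walk branching vessel tree in grid units, rooted at the disc.
vessel_tree_points <- function(spec, grid) {
  root <- c(grid$fovea_disc_fraction * 2 * grid$total_radius, 0)
  rmax <- grid$total_radius
  pts_x <- numeric(0); pts_y <- numeric(0)
  walk <- function(p, dir, step, depth) {
    for (i in 1:120) {
      dir <- dir + stats::rnorm(1, 0, 0.18)
      q <- p + step * c(cos(dir), sin(dir))
      # dense interpolation for gapless rasterization
      tseq <- seq(0, 1, length.out = 4)
      pts_x <<- c(pts_x, p[1] + tseq * (q[1] - p[1]))
      pts_y <<- c(pts_y, p[2] + tseq * (q[2] - p[2]))
      p <- q
      if (sqrt(sum(p^2)) > rmax * 1.02) break
      if (depth < 2 && stats::runif(1) < 0.05)
        walk(p, dir + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9),
             step * 0.8, depth + 1)
    }
  }
  n_main <- 4L * spec$vessel_density
  angles <- seq(0, 2 * pi, length.out = n_main + 1)[-1] +
    stats::rnorm(n_main, 0, 0.1)
  for (a in angles) walk(root, a, 0.55 * grid$r0, 0)
  data.frame(x = pts_x, y = pts_y)
}

vessel_presence <- function(vessels, blobs, grid) {
  keep <- rep(TRUE, nrow(vessels))
  if (!is.null(blobs) && nrow(blobs)) {
    for (b in seq_len(nrow(blobs)))
      keep <- keep & ((vessels$x - blobs$x[b])^2 +
                        (vessels$y - blobs$y[b])^2 >= blobs$r[b]^2)
  }
  loc <- locate_cell(vessels$x[keep], vessels$y[keep], grid)
  ids <- unique(loc$id[!is.na(loc$id)])
  cells <- grid_cells(grid)
  data.frame(ring = cells$ring, sector = cells$sector,
             has_vessel = cells$id %in% ids)
}

artifact_overlap <- function(art, grid, first_ring = 6L) {
  cells <- grid_cells(grid)
  hit <- rep(FALSE, nrow(cells))
  if (!is.null(art) && nrow(art)) {
    for (i in seq_len(nrow(art))) {
      a0 <- art$start[i] %% (2 * pi)
      a1 <- a0 + art$width[i]
      s <- cells$theta_start; e <- cells$theta_end
      ov <- (s < a1 & e > a0) | (s < a1 - 2 * pi & e > a0 - 2 * pi) |
        (s < a1 + 2 * pi & e > a0 + 2 * pi)
      hit <- hit | (ov & cells$ring >= first_ring)
    }
  }
  data.frame(ring = cells$ring, sector = cells$sector, artifact = hit)
}

render_phantom <- function(spec, grid, tr, vessels, blobs, art, art_r_min) {
  n <- spec$image_size
  img <- matrix(0.05 + stats::rnorm(n * n, 0, 0.015), n, n)
  # vessel tree: stamp a small disc at each sampled point
  p <- image_from_grid(vessels$x, vessels$y, tr)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  rad <- sqrt(vessels$x^2 + vessels$y^2) / grid$total_radius
  bright <- 0.85 - 0.35 * rad  # vessels dim toward the periphery
  for (k in seq_len(nrow(off))) {
    xi <- round(p$x) + off$dx[k]; yi <- round(p$y) + off$dy[k]
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n
    idx <- cbind(yi[ok], xi[ok])
    img[idx] <- pmax(img[idx], bright[ok])
  }
  # nonperfusion blobs erase vessels and darken the background
  g <- grid_from_image(rep(seq_len(n), each = n), rep(seq_len(n), times = n), tr)
  if (!is.null(blobs) && nrow(blobs)) {
    inblob <- rep(FALSE, n * n)
    for (b in seq_len(nrow(blobs)))
      inblob <- inblob | ((g$x - blobs$x[b])^2 + (g$y - blobs$y[b])^2 < blobs$r[b]^2)
    img[matrix(inblob, n, n, byrow = FALSE)] <-
      0.05 * spec$blob_darkness
  }
  # peripheral lash-like wedges
  if (!is.null(art) && nrow(art)) {
    r <- sqrt(g$x^2 + g$y^2)
    th <- atan2(g$y, g$x) %% (2 * pi)
    inart <- rep(FALSE, n * n)
    for (i in seq_len(nrow(art))) {
      a0 <- art$start[i] %% (2 * pi); a1 <- a0 + art$width[i]
      in_a <- (th >= a0 & th < a1) | (th + 2 * pi >= a0 & th + 2 * pi < a1)
      inart <- inart | (in_a & r >= art_r_min & r < grid$total_radius)
    }
    m <- matrix(inart, n, n, byrow = FALSE)
    img[m] <- img[m] * 0.12
  }
  pmin(pmax(img, 0), 1)
}

# --- simulated graders -------------------------------------------------------

#' A simulated grader
#'
#' The grader perceives a latent perfusion fraction
#' \code{clamp(truth + Normal(0, noise_sd), 0, 1)}, bands it into the six
#' ordinal grades, shifts the band by \code{bias} levels (clamped), and marks
#' cells UNGRADABLE with probability \code{ungradable_base} wherever an
#' artifact overlaps the cell or the cell contains no vessel — the two
#' triggers of the ungradable rule.
#'
#' @param bias Signed shift in ordinal levels (positive = sees more
#'   perfusion).
#' @param noise_sd SD of the latent perturbation on the true perfusion
#'   fraction.
#' @param ungradable_base Probability of marking an eligible cell ungradable.
#' @param seed Integer seed.
#' @return A \code{gridfa_grader_model}.
#' @export
grader_model <- function(bias = 0L, noise_sd = 0, ungradable_base = 0, seed = 1L) {
  if (noise_sd < 0) abort_invalid("`noise_sd` must be nonnegative")
  if (ungradable_base < 0 || ungradable_base > 1)
    abort_invalid("`ungradable_base` must be in [0, 1]")
  structure(list(bias = as.integer(bias), noise_sd = noise_sd,
                 ungradable_base = ungradable_base, seed = as.integer(seed)),
            class = "gridfa_grader_model")
}

# Band a perfusion fraction into the ordinal grade index 0 (P0) .. 5 (P100).
# Half-open upward bands on the percent-label boundaries; exactly 1 -> P100.
band_index <- function(x) {
  ifelse(x >= 1, 5L,
    ifelse(x >= 0.76, 4L,
      ifelse(x >= 0.51, 3L,
        ifelse(x >= 0.26, 2L,
          ifelse(x > 0, 1L, 0L)))))
}

#' Simulate one grader's session from ground truth
#'
#' With zero noise and zero bias the session reproduces the banded ground
#' truth exactly.
#'
#' @param truth data.frame (ring, sector, fraction) covering the full grid.
#' @param model A \code{gridfa_grader_model}.
#' @param artifact_cells Optional data.frame (ring, sector, artifact).
#' @param vessel_cells Optional data.frame (ring, sector, has_vessel).
#' @param image_id,grader_id Session identifiers.
#' @param grid A \code{gridfa_grid}.
#' @return A \code{gridfa_session}.
#' @export
simulate_grader <- function(truth, model, artifact_cells = NULL,
                            vessel_cells = NULL, image_id = "phantom",
                            grader_id = "sim", grid = grid_spec()) {
  if (!inherits(model, "gridfa_grader_model"))
    abort_invalid("`model` must be created by grader_model()")
  if (nrow(truth) != grid$n_cells)
    abort_invalid("`truth` must cover every cell of the grid")
  withr::with_seed(model$seed, {
    latent <- pmin(pmax(truth$fraction + stats::rnorm(nrow(truth), 0, model$noise_sd), 0), 1)
    idx <- pmin(pmax(band_index(latent) + model$bias, 0L), 5L)
    grade <- grade_levels()[idx + 1L]
    eligible <- rep(FALSE, nrow(truth))
    if (!is.null(artifact_cells))
      eligible <- eligible | artifact_cells$artifact[
        match(cell_flat_id(truth$ring, truth$sector),
              cell_flat_id(artifact_cells$ring, artifact_cells$sector))]
    if (!is.null(vessel_cells))
      eligible <- eligible | !vessel_cells$has_vessel[
        match(cell_flat_id(truth$ring, truth$sector),
              cell_flat_id(vessel_cells$ring, vessel_cells$sector))]
    u <- eligible & (stats::runif(nrow(truth)) < model$ungradable_base)
    grade[u] <- "UNGRADABLE"
    grading_session(image_id, grader_id,
                    data.frame(ring = truth$ring, sector = truth$sector,
                               grade = grade),
                    grid = grid)
  })
}

# --- marginal-matched paired datasets ---------------------------------------

#' Paired categorical dataset with prescribed per-grader marginals
#'
#' Builds a paired per-cell category dataset whose per-grader category counts
#' equal the given marginals exactly.  The joint distribution is filled
#' diagonal-first (maximal agreement subject to the marginals) except that
#' the number of cells ungradable by BOTH graders can be pinned with
#' \code{both_ungradable}, which determines the survivor count after the
#' "drop if either grader marked ungradable" filter.  Count differences
#' between graders depend only on the marginals.
#'
#' @param counts1,counts2 Named integer vectors over
#'   \code{\link{category_levels}} with equal totals.
#' @param both_ungradable Cells ungradable by both graders; default
#'   \code{min} of the two ungradable counts (diagonal-first).
#' @param n_images Number of images the cells are spread over (bootstrap
#'   clusters).
#' @param seed Integer seed (cell shuffling / image assignment).
#' @return data.frame: \code{image_id}, \code{category1}, \code{category2},
#'   \code{grade1}, \code{grade2} (representative grades per category:
#'   P100, P51_75, P1_25, UNGRADABLE).
#' @export
marginal_matched_dataset <- function(counts1, counts2, both_ungradable = NULL,
                                     n_images = 50L, seed = 1L) {
  lv <- category_levels()
  counts1 <- check_marginal(counts1); counts2 <- check_marginal(counts2)
  total <- sum(counts1)
  if (total != sum(counts2))
    abort_invalid("marginal totals differ between graders")
  if (total < 1) abort_invalid("empty marginals")
  u1 <- counts1[["ungradable"]]; u2 <- counts2[["ungradable"]]
  if (is.null(both_ungradable)) both_ungradable <- min(u1, u2)
  if (both_ungradable > min(u1, u2) || both_ungradable < 0)
    abort_invalid("infeasible `both_ungradable`: exceeds a grader's ungradable count")
  if (both_ungradable < u1 + u2 - total)
    abort_invalid("infeasible `both_ungradable`: union would exceed the total")

  J <- matrix(0, 4, 4, dimnames = list(lv, lv))
  rem1 <- as.numeric(counts1); rem2 <- as.numeric(counts2)
  J[4, 4] <- both_ungradable
  rem1[4] <- rem1[4] - both_ungradable
  rem2[4] <- rem2[4] - both_ungradable
  give <- function(i, j) {
    take <- min(rem1[i], rem2[j])
    J[i, j] <<- J[i, j] + take
    rem1[i] <<- rem1[i] - take
    rem2[j] <<- rem2[j] - take
  }
  # remaining ungradable cells pair with the other grader's largest categories
  for (j in order(rem2[1:3], decreasing = TRUE)) give(4, j)
  for (i in order(rem1[1:3], decreasing = TRUE)) give(i, 4)
  for (k in 1:3) give(k, k)                      # diagonal first
  ods <- expand.grid(i = 1:3, j = 1:3)
  ods <- ods[ods$i != ods$j, ]
  for (r in order(abs(ods$i - ods$j)))           # then near-diagonal
    give(ods$i[r], ods$j[r])
  stopifnot(all(rem1 == 0), all(rem2 == 0))

  i1 <- rep(rep(1:4, times = 4), times = as.vector(J))
  i2 <- rep(rep(1:4, each = 4), times = as.vector(J))
  rep_grade <- c("P100", "P51_75", "P1_25", "UNGRADABLE")
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(total)
    img <- sprintf("img%03d", rep_len(seq_len(n_images), total))
    data.frame(image_id = img,
               category1 = lv[i1[ord]], category2 = lv[i2[ord]],
               grade1 = rep_grade[i1[ord]], grade2 = rep_grade[i2[ord]],
               row.names = NULL)
  })
}

check_marginal <- function(counts) {
  lv <- category_levels()
  if (is.null(names(counts)) || !all(lv %in% names(counts)))
    abort_invalid("marginal counts must be named with the four category levels")
  counts <- counts[lv]
  if (any(counts < 0) || any(counts != floor(counts)))
    abort_invalid("marginal counts must be nonnegative integers")
  counts
}

#' Reference inter-rater study marginal counts
#'
#' Per-grader category counts from the published two-grader ultra-widefield
#' angiography grading study this method implements: 50 angiograms, 11,900
#' graded segments over the entire retina, of which 4,900 fall in the central
#' ETDRS-equivalent region and 7,000 in the periphery.  The study reports
#' whole-percent category tables plus exact between-grader count differences
#' and exact survivor counts after removing cells either grader found
#' ungradable; those exact counts over-determine the rounded percentages, and
#' the counts returned here are the unique integer reconciliation consistent
#' with every reported difference (4760/4165/833/238 entire; 1911/1715/490/294
#' central) and every survivor count (3251 entire, 2712 central, 539
#' peripheral) — which requires grader 2's ungradable cells to be a subset of
#' grader 1's.  Peripheral counts are the entire-minus-central difference.
#'
#' @return List with elements \code{ENTIRE}, \code{CENTRAL_ETDRS},
#'   \code{PERIPHERAL}; each holds \code{grader1}, \code{grader2} (named
#'   category count vectors), \code{both_ungradable}, and \code{n_cells}.
#' @export
reference_marginals <- function() {
  entire1 <- c(perfused = 2418, hypoperfused = 595, nonperfused = 238, ungradable = 8649)
  entire2 <- c(perfused = 6583, hypoperfused = 357, nonperfused = 1071, ungradable = 3889)
  central1 <- c(perfused = 1977, hypoperfused = 539, nonperfused = 196, ungradable = 2188)
  central2 <- c(perfused = 3692, hypoperfused = 245, nonperfused = 686, ungradable = 277)
  list(
    ENTIRE = list(grader1 = entire1, grader2 = entire2,
                  both_ungradable = 3889, n_cells = 11900),
    CENTRAL_ETDRS = list(grader1 = central1, grader2 = central2,
                         both_ungradable = 277, n_cells = 4900),
    PERIPHERAL = list(grader1 = entire1 - central1, grader2 = entire2 - central2,
                      both_ungradable = 3889 - 277, n_cells = 7000)
  )
}
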