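#' Read a grayscale image (PNG or TIFF)
#'
#' Multi-channel images are averaged to one channel; an alpha channel is
#' dropped.  Values are in [0, 1].
#'
#' @param path Image path.
#' @return Numeric matrix (rows x cols).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("image '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort_io(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext))
  )
  if (length(dim(img)) == 3L) {
    ch <- min(dim(img)[3], 3L)  # drop alpha
    img <- apply(img[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Write a grayscale image (PNG or TIFF, by extension)
#'
#' @param image Numeric matrix in [0, 1].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    abort_io(sprintf("unsupported image format '.%s'", ext))
  )
  invisible(path)
}

#' Write the grid label raster as a 16-bit TIFF
#'
#' Pixel value 0 is background; cells are stored as flat id + 1.
#'
#' @param labels Integer matrix from \code{\link{grid_label_raster}}.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Landmark file I/O
#'
#' JSON schema: \code{\{image, fovea: [x, y], disc: [x, y], laterality\}}.
#'
#' @param path JSON path.
#' @return \code{read_landmarks_json}: list with \code{image} and a
#'   \code{gridfa_landmarks}.
#' @export
read_landmarks_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("landmark file '%s' does not exist", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(image = j$image %||% NA_character_,
       landmarks = landmarks(as.numeric(j$fovea), as.numeric(j$disc),
                             j$laterality %||% "unknown"))
}

#' @rdname read_landmarks_json
#' @param lm A \code{gridfa_landmarks}.
#' @param image Image path recorded in the file.
#' @export
write_landmarks_json <- function(lm, path, image = NA_character_) {
  jsonlite::write_json(
    list(image = image, fovea = lm$fovea, disc = lm$disc_center,
         laterality = lm$laterality),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Transform file I/O
#'
#' @param transform A \code{gridfa_transform}.
#' @param path JSON path.
#' @param mm_per_px Optional millimetre calibration to record.
#' @export
write_transform_json <- function(transform, path, mm_per_px = NULL) {
  check_transform(transform)
  out <- list(dx = transform$dx, dy = transform$dy, theta = transform$theta,
              scale = transform$scale, d_px = transform$d_px)
  if (!is.null(mm_per_px)) out$mm_per_px <- mm_per_px
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("transform file '%s' does not exist", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(dx = j$dx, dy = j$dy, theta = j$theta, scale = j$scale,
                 d_px = j$d_px %||% NA_real_),
            class = "gridfa_transform")
}

#' Grading session file I/O
#'
#' JSON schema: \code{\{image_id, grader_id, grid: \{n_rings\}, grades:
#' [\{ring, sector, grade\}], excluded: [\{ring, sector\}]\}}.
#'
#' @param session A \code{gridfa_session}.
#' @param path JSON path.
#' @export
write_session_json <- function(session, path) {
  check_session(session)
  out <- list(
    image_id = session$image_id,
    grader_id = session$grader_id,
    grid = list(n_rings = session$grid$n_rings),
    grades = session$grades,
    excluded = session$excluded
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("session file '%s' does not exist", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- grid_spec(n_rings = j$grid$n_rings %||% 8L)
  excl <- j$excluded
  if (is.null(excl) || !length(excl) || !NROW(excl)) excl <- NULL
  grading_session(j$image_id, j$grader_id, as.data.frame(j$grades),
                  excluded = if (!is.null(excl)) as.data.frame(excl),
                  grid = grid)
}

#' Write a phantom bundle to a directory
#'
#' Files: \code{image.png}, \code{landmarks.json}, \code{truth.csv}
#' (ring, sector, fraction), \code{spec.json}.
#'
#' @param phantom Result of \code{\link{generate_phantom}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom_bundle <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(phantom$image, file.path(dir, "image.png"))
  write_landmarks_json(phantom$landmarks, file.path(dir, "landmarks.json"),
                       image = "image.png")
  utils::write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(phantom$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Flat key=value run configuration files
#'
#' One \code{key = value} assignment per line; \code{#} starts a comment.
#' Values are parsed as numbers where possible.  CLI flags override config
#' values; every run writes the resolved configuration next to its outputs.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort_invalid(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

write_resolved_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}
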