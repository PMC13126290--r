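#' Default brain ROI polygons for synthetic ratio images
#'
#' Four rectangular regions (telencephalon, diencephalon, midbrain,
#' hindbrain) stacked along the anterior-posterior axis inside an
#' elliptical "brain" footprint, in (row, col) pixel coordinates.
#'
#' @param shape Image dimension `c(rows, cols)`.
#' @return Named list of polygons, each a list with vertex vectors `x`
#'   (columns) and `y` (rows).
#' @export
default_brain_rois <- function(shape = c(128, 96)) {
  nr <- shape[1]; nc <- shape[2]
  band <- function(r0, r1) {
    list(x = c(0.25 * nc, 0.75 * nc, 0.75 * nc, 0.25 * nc),
         y = c(r0 * nr, r0 * nr, r1 * nr, r1 * nr))
  }
  list(telencephalon = band(0.10, 0.28),
       diencephalon = band(0.30, 0.48),
       midbrain = band(0.50, 0.68),
       hindbrain = band(0.70, 0.88))
}

#' Simulate a co-registered pERK/ERK image pair
#'
#' The ERK channel equals `base_erk` inside an elliptical brain mask and a
#' small background outside, plus additive Gaussian noise. The pERK
#' channel is the noise-free ERK signal multiplied by an ROI-specific fold
#' (1 outside every ROI), plus independent noise. The truth table records
#' the configured fold per ROI.
#'
#' @param shape `c(rows, cols)` image size.
#' @param roi_polygons Named list of polygons (see [default_brain_rois()]);
#'   all vertices must fall inside the image.
#' @param base_erk ERK intensity inside the brain (a.u., default 1000).
#' @param perk_fold_by_roi Named numeric vector of pERK/ERK folds per ROI
#'   (> 0); ROIs not named get fold 1.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param seed RNG seed.
#' @param background Intensity outside the brain mask (default 0).
#' @return list with `perk` and `erk` (numeric matrices), `brain_mask`
#'   (logical matrix), and `truth` (data.frame of ROI name, fold,
#'   n_pixels).
#' @export
simulate_ratio_images <- function(shape = c(128, 96),
                                  roi_polygons = default_brain_rois(shape),
                                  base_erk = 1000,
                                  perk_fold_by_roi = c(midbrain = 2),
                                  noise_sd = 0, seed = 1L,
                                  background = 0) {
  check_pos(base_erk, "base_erk")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (any(perk_fold_by_roi <= 0)) stop("folds must be > 0", call. = FALSE)
  for (nm in names(roi_polygons)) {
    p <- roi_polygons[[nm]]
    if (any(p$x < 1 - 1e-9) || any(p$x > shape[2] + 1e-9) ||
        any(p$y < 1 - 1e-9) || any(p$y > shape[1] + 1e-9))
      stop("ROI `", nm, "` falls outside the image", call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  brain <- ((rows - nr / 2) / (0.46 * nr))^2 +
    ((cols - nc / 2) / (0.40 * nc))^2 <= 1
  erk_clean <- matrix(background, nr, nc)
  erk_clean[brain] <- base_erk
  fold_map <- matrix(1, nr, nc)
  truth <- list()
  for (nm in names(roi_polygons)) {
    p <- roi_polygons[[nm]]
    m <- polygon_mask(shape, p$x, p$y)
    fold <- if (nm %in% names(perk_fold_by_roi)) perk_fold_by_roi[[nm]] else 1
    fold_map[m] <- fold
    truth[[nm]] <- data.frame(roi = nm, fold = fold, n_pixels = sum(m))
  }
  perk_clean <- erk_clean * fold_map
  with_seed(seed, {
    erk <- erk_clean + stats::rnorm(nr * nc, sd = noise_sd)
    perk <- perk_clean + stats::rnorm(nr * nc, sd = noise_sd)
    list(perk = pmax(perk, 0), erk = pmax(erk, 0), brain_mask = brain,
         truth = do.call(rbind, truth))
  })
}

#' Write a matrix as a 16-bit TIFF
#'
#' Values are scaled by `max_value` (default 65535, i.e. raw 16-bit
#' counts) into the unit range the TIFF writer expects.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @param max_value Full-scale value (default 65535).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, max_value = 65535) {
  tiff::writeTIFF(pmin(pmax(image / max_value, 0), 1), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Read a single-channel TIFF or PNG image as a matrix
#'
#' @param path Image path (`.tif`, `.tiff`, or `.png`).
#' @param max_value Full-scale value used to undo the reader's unit
#'   scaling (default 65535).
#' @return Numeric matrix.
#' @export
read_image <- function(path, max_value = 65535) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the `png` package", call. = FALSE)
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * max_value
}
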