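#' Z-projection of an image stack
#'
#' Collapses a stack of 2-D slices into one image by per-pixel sum
#' (default) or mean.
#'
#' @param stack A 3-D array (rows x cols x slices), or a list of matrices.
#' @param method `"sum"` (default) or `"mean"`.
#' @return A numeric matrix.
#' @export
zproject <- function(stack, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  if (dim(stack)[3] < 1L) stop("empty stack", call. = FALSE)
  out <- apply(stack, c(1, 2), sum)
  if (method == "mean") out <- out / dim(stack)[3]
  out
}

#' Huang fuzzy-entropy threshold
#'
#' The automatic threshold of Huang and Wang: for every candidate cut of
#' the 256-bin histogram, pixels get a fuzzy membership to their class
#' based on the distance to the class mean, `u(g) = 1 / (1 + |g -
#' mu_class| / C)` with `C` the intensity range, and the threshold
#' minimizing the Shannon fuzzy entropy `-sum h(g) [u log u + (1-u)
#' log(1-u)]` is returned. The minimization is an exhaustive search over
#' all histogram cuts, so the result is deterministic. Matches the
#' algorithm behind the method of the same name in common image-analysis
#' software.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Histogram bins (default 256).
#' @return The threshold on the intensity scale of `image`; pixels with
#'   `image >= threshold` form the foreground.
#' @export
huang_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps)
    stop("constant image: threshold undefined", call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  C <- hi - lo
  cs <- cumsum(h)
  csx <- cumsum(h * centers)
  n <- length(v)
  sx <- csx[n_bins]
  ent <- rep(NA_real_, n_bins - 1)
  for (t in seq_len(n_bins - 1)) {
    n0 <- cs[t]
    if (n0 == 0 || n0 == n) next
    mu0 <- csx[t] / n0
    mu1 <- (sx - csx[t]) / (n - n0)
    mu <- c(rep(mu0, t), rep(mu1, n_bins - t))
    u <- 1 / (1 + abs(centers - mu) / C)
    s <- -(u * log(u) + (1 - u) * log(1 - u))
    s[!is.finite(s)] <- 0
    ent[t] <- sum(h * s)
  }
  t_star <- which.min(ent)
  # threshold between the last background bin and the first foreground bin
  breaks[t_star + 1]
}

#' Fill interior holes of a binary mask
#'
#' Border-connected background is identified by a 4-connectivity flood
#' fill from the image border; all remaining background pixels are
#' interior holes and are set to foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  # seed queue with all border background pixels
  border <- which((row(mask) == 1 | row(mask) == nr |
                     col(mask) == 1 | col(mask) == nc) & !mask)
  queue <- border
  outside[queue] <- TRUE
  while (length(queue)) {
    idx <- queue
    queue <- integer(0)
    r <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; ccc <- cc + d[2]
      ok <- rr >= 1L & rr <= nr & ccc >= 1L & ccc <= nc
      nb <- (ccc[ok] - 1L) * nr + rr[ok]
      nb <- nb[!outside[nb] & !mask[nb]]
      if (length(nb)) {
        outside[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    queue <- unique(queue)
  }
  mask | !outside
}

#' Ratio map and ROI means from a pERK/ERK image pair
#'
#' Computes `ratio = perk / (erk + epsilon)`, masks it by the
#' hole-filled Huang threshold of the ERK channel (the mask removes
#' background outside the tissue), zeroes the ratio outside the mask, and
#' averages it over each ROI polygon restricted to the mask. ROIs with no
#' in-mask pixels are reported as missing (`NA`), not zero. The inputs
#' are assumed co-registered.
#'
#' @param perk,erk Numeric matrices of equal dimension.
#' @param rois Named list of polygons (`x` = columns, `y` = rows).
#' @param epsilon Guard added to the ERK denominator; default `1e-6 *
#'   max(erk)`.
#' @return list with `ratio_map` (list: `ratio`, `mask`, `erk_threshold`,
#'   `epsilon`) and `roi_means` (data.frame: `roi`, `mean_ratio`,
#'   `n_pixels`).
#' @export
ratio_mask_measure <- function(perk, erk, rois, epsilon = NULL) {
  if (!all(dim(perk) == dim(erk)))
    stop("pERK and ERK images must have the same shape", call. = FALSE)
  if (is.null(epsilon)) epsilon <- 1e-6 * max(erk)
  thr <- huang_threshold(erk)
  mask <- fill_holes(erk >= thr)
  ratio <- perk / (erk + epsilon)
  ratio[!mask] <- 0
  rows <- lapply(names(rois), function(nm) {
    p <- rois[[nm]]
    pm <- polygon_mask(dim(erk), p$x, p$y) & mask
    n_px <- sum(pm)
    data.frame(roi = nm,
               mean_ratio = if (n_px > 0) mean(ratio[pm]) else NA_real_,
               n_pixels = n_px, stringsAsFactors = FALSE)
  })
  list(ratio_map = list(ratio = ratio, mask = mask, erk_threshold = thr,
                        epsilon = epsilon),
       roi_means = do.call(rbind, rows))
}

#' Normalize ratio measurements against the clutch reference
#'
#' For each clutch, the reference-group ratio images are averaged and the
#' maximum pixel of the average is used to normalize every measurement of
#' that clutch (the reference group is the unstimulated diploid set in the
#' baseline design, or the control set in stimulation designs).
#' Normalization is scale-invariant: multiplying a whole clutch's images
#' by a constant leaves the normalized values unchanged.
#'
#' @param measurements data.frame with columns `clutch`, `group`, `image_id`,
#'   `roi`, `mean_ratio`.
#' @param ratio_images Named list (by `image_id`) of ratio matrices used
#'   to build the clutch references.
#' @param image_groups data.frame with `image_id`, `clutch`, `group`.
#' @param reference_group Group defining the reference (default
#'   `"diploid"`).
#' @return `measurements` with an added `normalized_ratio` column.
#' @export
clutch_normalize <- function(measurements, ratio_images, image_groups,
                             reference_group = "diploid") {
  stopifnot(all(c("clutch", "mean_ratio") %in% names(measurements)))
  ref_max <- list()
  for (cl in unique(measurements$clutch)) {
    ids <- image_groups$image_id[image_groups$clutch == cl &
                                   image_groups$group == reference_group]
    if (!length(ids))
      stop("clutch `", cl, "` has no reference-group image", call. = FALSE)
    avg <- Reduce(`+`, ratio_images[ids]) / length(ids)
    ref_max[[cl]] <- max(avg)
  }
  measurements$normalized_ratio <- measurements$mean_ratio /
    unlist(ref_max[measurements$clutch])
  measurements
}

#' Read and write ROI polygons as JSON
#'
#' The on-disk ROI format is a JSON object mapping region names to vertex
#' arrays: `{"midbrain": {"x": [...], "y": [...]}, ...}` with `x` in
#' column and `y` in row pixel coordinates.
#'
#' @param path JSON path.
#' @return Named list of polygons (lists with `x` and `y`).
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  rois <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(rois, function(p) list(x = as.numeric(p$x), y = as.numeric(p$y)))
}

#' @rdname read_rois
#' @param rois Named list of polygons.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
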