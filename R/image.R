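# Image container, uniform-region selection, quality control, and RGB
# intensity extraction -- the computational core of the screening pipeline.

#' 8-bit RGB skin image
#'
#' A `height x width x 3` integer array of 8-bit intensities (0-255, channel
#' order red/green/blue) with acquisition metadata. Images are assumed
#' pre-cropped to the glabella patch; no face detection is performed.
#'
#' @param pixels integer array with `dim = c(height, width, 3)`, values 0-255.
#' @param method acquisition method: `"direct"` (camera pressed to skin),
#'   `"dermatoscope"`, or `"dermatoscope_filter"` (dermatoscope plus a
#'   yellow-green band-pass filter).
#' @param subject_id subject identifier string.
#' @param metadata free-form named list.
#' @return object of class `skin_image`.
#' @export
skin_image <- function(pixels, method = c("dermatoscope", "direct",
                                          "dermatoscope_filter"),
                       subject_id = "", metadata = list()) {
  method <- match.arg(method)
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    stopf("skin_image: 'pixels' must be a height x width x 3 array")
  if (d[1] < 8 || d[2] < 8)
    stopf("skin_image: height and width must be >= 8")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("skin_image: pixel values must be integers in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, method = method, subject_id = subject_id,
                 metadata = metadata),
            class = "skin_image")
}

#' @export
print.skin_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<skin_image> %dx%d px, method=%s, subject=%s\n",
              d[1], d[2], x$method, x$subject_id))
  invisible(x)
}

#' Write / read a skin image as 8-bit RGB PNG
#'
#' PNG is lossless, so a write/read round trip is bit-identical. TIFF is also
#' readable when the `tiff` package is installed. Lossy formats are not
#' supported: compression artifacts perturb the channel means the analysis
#' depends on.
#'
#' @param image a [skin_image()].
#' @param path file path.
#' @rdname skin_image_io
#' @export
write_skin_image <- function(image, path) {
  stopifnot(inherits(image, "skin_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' @param method,subject_id metadata to attach on read.
#' @rdname skin_image_io
#' @export
read_skin_image <- function(path, method = "dermatoscope", subject_id = "") {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("read_skin_image: reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    stopf("read_skin_image: unsupported format '%s' (use lossless PNG or TIFF)", ext)
  }
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  px <- round_half_away(arr[, , 1:3, drop = FALSE] * 255)
  skin_image(px, method = method, subject_id = subject_id,
             metadata = list(source = path))
}

# Per-window sums via integral images: sums[i, j] = sum of x over the
# side x side window whose top-left corner is (i, j).
window_sums <- function(x, side) {
  h <- nrow(x); w <- ncol(x)
  cs <- apply(x, 2, cumsum)        # cumulative over rows
  cs <- t(apply(cs, 1, cumsum))    # then over columns
  cs <- rbind(0, cbind(0, cs))     # cs[i+1, j+1] = sum x[1:i, 1:j]
  i <- seq_len(h - side + 1); j <- seq_len(w - side + 1)
  cs[i + side, j + side, drop = FALSE] - cs[i, j + side, drop = FALSE] -
    cs[i + side, j, drop = FALSE] + cs[i, j, drop = FALSE]
}

#' Select the most uniform square region of an image
#'
#' Scans every `window_side x window_side` window and returns the one
#' minimising the sum over channels of the within-window (population) pixel
#' variance -- an automated stand-in for an investigator manually marking the
#' most uniform area of the patch. Ties are broken by the smallest row, then
#' column, of the window's top-left corner, so the result is deterministic;
#' variance is translation-invariant, so adding a constant to every pixel
#' leaves the selection unchanged.
#'
#' @param image a [skin_image()].
#' @param window_side window side length in pixels, >= 4 and at most the
#'   smaller image dimension. Default 16 (a 256-pixel region).
#' @return logical `height x width` matrix marking the selected region.
#' @export
select_uniform_region <- function(image, window_side = 16) {
  stopifnot(inherits(image, "skin_image"))
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  if (window_side > min(h, w))
    stopf("select_uniform_region: window_side exceeds image size")
  if (window_side < 4) stopf("select_uniform_region: window_side must be >= 4")
  npix <- window_side^2
  score <- 0
  for (k in 1:3) {
    x <- image$pixels[, , k]
    s1 <- window_sums(x, window_side)
    s2 <- window_sums(x^2, window_side)
    score <- score + (s2 / npix - (s1 / npix)^2)
  }
  hits <- which(score == min(score), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  top <- hits[1, 1]; left <- hits[1, 2]
  mask <- matrix(FALSE, h, w)
  mask[top:(top + window_side - 1), left:(left + window_side - 1)] <- TRUE
  mask
}

#' Quality-control thresholds
#'
#' @param max_saturated_fraction maximum tolerated fraction of region pixels
#'   with any channel saturated at 255. Default 0.05.
#' @param max_artifact_fraction maximum tolerated fraction of region pixels
#'   deviating more than `artifact_k` channel SDs from the region mean.
#'   Default 0.10.
#' @param artifact_k SD multiplier for the local artifact rule (default 3,
#'   the same multiplier as the population-level outlier rule).
#' @param min_region_pixels minimum region size in pixels. Default 16.
#' @param max_channel_sd maximum tolerated mean within-region channel SD
#'   before the region is declared non-uniform. Default 40 intensity units.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_saturated_fraction = 0.05,
                          max_artifact_fraction = 0.10,
                          artifact_k = 3,
                          min_region_pixels = 16,
                          max_channel_sd = 40) {
  structure(list(max_saturated_fraction = max_saturated_fraction,
                 max_artifact_fraction = max_artifact_fraction,
                 artifact_k = artifact_k,
                 min_region_pixels = min_region_pixels,
                 max_channel_sd = max_channel_sd),
            class = "qc_thresholds")
}

#' Quality control of a selected region
#'
#' Flags regions unusable for intensity extraction: excessive saturation (any
#' channel at 255), excessive artifact pixels (deviating more than
#' `artifact_k` channel SDs from the region mean -- the local analogue of the
#' population outlier rule), too-small regions, and non-uniform regions.
#'
#' @param image a [skin_image()].
#' @param mask logical region mask matching the image dimensions.
#' @param thresholds a [qc_thresholds()].
#' @return object of class `qc_report`: list with `passed`, `reasons`
#'   (character subset of `saturation_excess`, `artifact_excess`,
#'   `region_too_small`, `low_uniformity`), `saturated_fraction`,
#'   `artifact_fraction`.
#' @export
qc_image <- function(image, mask, thresholds = qc_thresholds()) {
  stopifnot(inherits(image, "skin_image"))
  if (!identical(dim(mask), dim(image$pixels)[1:2]))
    stopf("qc_image: mask dimensions do not match image")
  n <- sum(mask)
  reasons <- character(0)
  if (n < thresholds$min_region_pixels) reasons <- c(reasons, "region_too_small")
  if (n == 0) {
    return(structure(list(passed = FALSE, reasons = reasons,
                          saturated_fraction = NA_real_,
                          artifact_fraction = NA_real_), class = "qc_report"))
  }
  chan <- matrix(vapply(1:3, function(k) as.numeric(image$pixels[, , k][mask]),
                        numeric(n)), nrow = n)
  sat <- mean(apply(chan == 255, 1, any))
  mu <- colMeans(chan)
  sds <- sqrt(colMeans(chan^2) - mu^2)  # population SD, denominator n
  dev <- sweep(abs(sweep(chan, 2, mu)), 2,
               pmax(thresholds$artifact_k * sds, .Machine$double.eps), "/")
  art <- mean(apply(dev > 1, 1, any))
  if (sat > thresholds$max_saturated_fraction)
    reasons <- c(reasons, "saturation_excess")
  if (art > thresholds$max_artifact_fraction)
    reasons <- c(reasons, "artifact_excess")
  if (mean(sds) > thresholds$max_channel_sd)
    reasons <- c(reasons, "low_uniformity")
  structure(list(passed = length(reasons) == 0, reasons = reasons,
                 saturated_fraction = sat, artifact_fraction = art),
            class = "qc_report")
}

channel_summary_row <- function(subject_id, method, channel, values, block) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(subject_id = subject_id, method = method, channel = channel,
             mean = mean(values), median = q[2], p25 = q[1], p75 = q[3],
             n_pixels = length(values), aggregation_block = block,
             stringsAsFactors = FALSE)
}

#' Extract per-channel intensity summaries over a region
#'
#' Computes the exact arithmetic mean, median, and 25th/75th percentiles
#' (linear interpolation between order statistics) of each RGB channel over
#' the masked pixels. The per-subject *mean* is the statistic the screening
#' analysis correlates with TsB.
#'
#' @param image a [skin_image()].
#' @param mask logical region mask; must contain at least one pixel and should
#'   have passed [qc_image()].
#' @return data.frame with one row per channel: `subject_id`, `method`,
#'   `channel`, `mean`, `median`, `p25`, `p75`, `n_pixels`,
#'   `aggregation_block` (1 = raw pixels).
#' @export
extract_intensity <- function(image, mask) {
  stopifnot(inherits(image, "skin_image"))
  if (!identical(dim(mask), dim(image$pixels)[1:2]))
    stopf("extract_intensity: mask dimensions do not match image")
  if (!any(mask)) stopf("extract_intensity: empty mask")
  out <- lapply(1:3, function(k)
    channel_summary_row(image$subject_id, image$method,
                        c("red", "green", "blue")[k],
                        as.numeric(image$pixels[, , k][mask]), 1L))
  do.call(rbind, out)
}

#' Block-aggregated intensity summaries
#'
#' Re-computes the channel summaries after averaging the region into
#' non-overlapping `block_side x block_side` pixel blocks (4, 9 or 16 pixels
#' per block), emulating a coarser effective sensor. The mask's bounding box
#' is tiled from its top-left corner; only blocks fully inside the mask
#' contribute, each represented by its pixel mean.
#'
#' @param image a [skin_image()].
#' @param mask logical region mask.
#' @param block_side block side length: 2, 3 or 4.
#' @return data.frame as [extract_intensity()], with `aggregation_block =
#'   block_side` and `n_pixels` the number of complete blocks.
#' @export
block_summaries <- function(image, mask, block_side) {
  stopifnot(inherits(image, "skin_image"))
  if (!block_side %in% 2:4)
    stopf("block_summaries: block_side must be 2, 3 or 4 (4-16 pixels per block)")
  if (!any(mask)) stopf("block_summaries: empty mask")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  tops <- seq(rows[1], rows[2] - block_side + 1, by = block_side)
  lefts <- seq(cols[1], cols[2] - block_side + 1, by = block_side)
  vals <- list(red = numeric(0), green = numeric(0), blue = numeric(0))
  for (t in tops) for (l in lefts) {
    ri <- t:(t + block_side - 1); ci <- l:(l + block_side - 1)
    if (all(mask[ri, ci])) {
      for (k in 1:3)
        vals[[k]] <- c(vals[[k]], mean(image$pixels[ri, ci, k]))
    }
  }
  if (length(vals$red) < 2)
    stopf("block_summaries: fewer than 2 complete blocks inside the mask")
  out <- lapply(1:3, function(k)
    channel_summary_row(image$subject_id, image$method,
                        c("red", "green", "blue")[k], vals[[k]],
                        as.integer(block_side)))
  do.call(rbind, out)
}

#' Write channel summaries to CSV
#' @param summaries data.frame of stacked [extract_intensity()] rows.
#' @param path output CSV path.
#' @export
write_channel_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}

#' Write a region mask as a single-channel PNG
#' @param mask logical matrix.
#' @param path output PNG path.
#' @export
write_region_mask <- function(mask, path) {
  png::writePNG(mask * 1, target = path)
  invisible(path)
}
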