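#' Imaging parameters for lignin quantification
#'
#' @param sigma Gaussian blur radius in pixels applied before thresholding
#'   (default 2.0).
#' @param histogram_bins number of histogram bins; 256 for 8-bit images.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(sigma = 2.0, histogram_bins = 256L) {
  check_scalar(sigma, "sigma", 0, open_lower = TRUE)
  if (histogram_bins != 256L) stopf("'histogram_bins' must be 256 for 8-bit images")
  structure(list(sigma = sigma, histogram_bins = 256L), class = "imaging_params")
}

#' Region-of-interest masks for a stem section
#'
#' Bundles the manually (or synthetically) annotated regions used by
#' [quantify_cortex_lignin()]: the whole section, the lignified xylem ring
#' and the cortex. The xylem and cortex must lie inside the section and be
#' disjoint, mirroring manual ROI selection on real sections.
#'
#' @param xylem_mask,cortex_mask,section_mask logical H x W matrices.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(xylem_mask, cortex_mask, section_mask) {
  dims <- lapply(list(xylem_mask, cortex_mask, section_mask), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stopf("ROI masks must share the same dimensions")
  }
  if (any(xylem_mask & !section_mask) || any(cortex_mask & !section_mask)) {
    stopf("xylem and cortex ROIs must be subsets of the section ROI")
  }
  if (any(xylem_mask & cortex_mask)) stopf("xylem and cortex ROIs must be disjoint")
  structure(list(xylem_mask = xylem_mask, cortex_mask = cortex_mask,
                 section_mask = section_mask), class = "roi_set")
}

#' Gaussian-blur an RGB section image
#'
#' Per-channel Gaussian convolution (kernel truncated at 3 sigma,
#' reflective border handling), re-quantised to 8 bits by rounding. Used to
#' suppress sensor noise before the adaptive histogram threshold.
#'
#' @param image a `section_image`.
#' @param params an [imaging_params()] (default sigma 2.0).
#' @return The smoothed `section_image`.
#' @export
gaussian_smooth <- function(image, params = imaging_params()) {
  stopifnot(inherits(image, "section_image"))
  out <- image
  for (ch in 1:3) {
    out$pixels[, , ch] <- quantize8(blur_matrix(image$pixels[, , ch], params$sigma))
  }
  out
}

#' Convert an 8-bit sRGB image to rescaled 8-bit CIELAB channels
#'
#' sRGB (D65) to CIELAB via XYZ, then each channel affinely rescaled to
#' `[0, 255]`: L* maps 0..100 to 0..255, a* and b* map -128..127 to 0..255
#' (so the neutral axis sits at 128). This is the 8-bit Lab convention of
#' common image-analysis software.
#'
#' @param image a `section_image`.
#' @return An object of class `lab_image`: list of integer H x W matrices
#'   `L8`, `a8`, `b8`.
#' @export
rgb_to_lab8 <- function(image) {
  stopifnot(inherits(image, "section_image"))
  d <- dim(image$pixels)
  m <- matrix(as.numeric(image$pixels), ncol = 3) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  structure(list(
    L8 = quantize8(matrix(lab[, 1] / 100 * 255, d[1], d[2])),
    a8 = quantize8(matrix(lab[, 2] + 128, d[1], d[2])),
    b8 = quantize8(matrix(lab[, 3] + 128, d[1], d[2]))
  ), class = "lab_image")
}

#' Histogram peak of an 8-bit channel
#'
#' Returns the intensity (0-based bin index over 256 bins) with the
#' maximal pixel count; ties are broken toward the lowest intensity.
#'
#' @param channel matrix (or vector) of values in `[0, 255]`.
#' @param bins number of bins (256 for 8-bit data).
#' @return Integer bin index in `0:(bins - 1)`.
#' @export
histogram_peak <- function(channel, bins = 256L) {
  v <- as.vector(channel)
  if (length(v) == 0L || all(is.na(v))) stopf("empty channel")
  if (any(v < 0 | v > 255, na.rm = TRUE)) stopf("channel values must lie in [0, 255]")
  counts <- tabulate(floor(v) + 1L, nbins = bins)
  which.max(counts) - 1L
}

#' Adaptive lignin mask from 8-bit Lab channels
#'
#' Applies the histogram-peak colour threshold for red (phloroglucinol
#' stained) areas: keep pixels whose lightness is at or below the L8
#' histogram peak AND whose green--red value is at or above the a8
#' histogram peak; the blue--yellow channel is unrestricted. Peaks are
#' recomputed on each image's own (smoothed) histograms, so the threshold
#' adapts per image. On a degenerate constant image every pixel equals both
#' peaks and the mask covers the whole frame; the procedure presupposes
#' that unstained pale tissue dominates the histograms.
#'
#' @param lab a [rgb_to_lab8()] result.
#' @return Logical H x W matrix.
#' @export
lignin_mask <- function(lab) {
  stopifnot(inherits(lab, "lab_image"))
  peak_l <- histogram_peak(lab$L8)
  peak_a <- histogram_peak(lab$a8)
  (lab$L8 <= peak_l) & (lab$a8 >= peak_a)
}

#' Quantify cortex lignin from a mask and ROI set
#'
#' Counts lignin-mask pixels in the whole section, subtracts the part
#' falling in the xylem ROI to obtain the cortex lignin area, and expresses
#' it as a percentage of the cortex ROI area. The percentage denominator is
#' the cortex ROI so that sections of different overall size remain
#' comparable.
#'
#' @param mask logical lignin mask (from [lignin_mask()]).
#' @param rois a [roi_set()] of the same dimensions.
#' @return An object of class `lignin_quant`: list with `total_lignin_px`,
#'   `xylem_lignin_px`, `cortex_lignin_px`, `cortex_area_px`,
#'   `cortex_lignin_pct`.
#' @export
quantify_cortex_lignin <- function(mask, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (!identical(dim(mask), dim(rois$section_mask))) {
    stopf("mask and ROIs must have the same dimensions")
  }
  cortex_area <- sum(rois$cortex_mask)
  if (cortex_area == 0L) stopf("cortex ROI is empty")
  total <- sum(mask & rois$section_mask)
  xylem <- sum(mask & rois$xylem_mask)
  cortex <- total - xylem
  structure(list(
    total_lignin_px = total,
    xylem_lignin_px = xylem,
    cortex_lignin_px = cortex,
    cortex_area_px = cortex_area,
    cortex_lignin_pct = 100 * cortex / cortex_area
  ), class = "lignin_quant")
}

#' @export
print.lignin_quant <- function(x, ...) {
  cat(sprintf(
    "<lignin_quant> total %d px | xylem %d px | cortex %d px (%.2f%% of %d cortex px)\n",
    x$total_lignin_px, x$xylem_lignin_px, x$cortex_lignin_px,
    x$cortex_lignin_pct, x$cortex_area_px))
  invisible(x)
}

#' Quantify cortex lignin in one section image
#'
#' Convenience wrapper running the full imaging chain: Gaussian blur,
#' Lab conversion, adaptive histogram-peak mask, ROI arithmetic.
#'
#' @param image a `section_image`.
#' @param rois a [roi_set()]; defaults to the image's own ground-truth
#'   masks when it was rendered synthetically.
#' @param params an [imaging_params()].
#' @return A `lignin_quant`, with the computed `mask` attached as attribute
#'   `"mask"`.
#' @export
quantify_section <- function(image, rois = NULL, params = imaging_params()) {
  if (is.null(rois)) {
    if (is.null(image$masks)) stopf("no ROIs supplied and image has no ground-truth masks")
    rois <- roi_set(image$masks$xylem, image$masks$cortex, image$masks$section)
  }
  sm <- gaussian_smooth(image, params)
  mask <- lignin_mask(rgb_to_lab8(sm))
  out <- quantify_cortex_lignin(mask, rois)
  attr(out, "mask") <- mask
  out
}

#' Write a QC overlay PNG for a lignin mask
#'
#' Marks mask pixels in saturated green over a dimmed copy of the image.
#'
#' @param image a `section_image`.
#' @param mask logical mask from [lignin_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, mask, path) {
  px <- image$pixels * 0.6
  px[, , 1][mask] <- 40
  px[, , 2][mask] <- 230
  px[, , 3][mask] <- 40
  png::writePNG(quantize8(px) / 255, target = path)
  invisible(path)
}
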