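#' Specify a synthetic stained stem cross-section
#'
#' Describes a concentric-ring tomato stem section as seen in
#' phloroglucinol-HCl (Wiesner) stained cross-sections: a central pith, a
#' lignified xylem ring, a cortex in which a controllable fraction of the
#' area carries the red lignin stain, and an epidermis boundary, all drawn
#' on a pale background. The geometry is deliberately simple (concentric
#' annuli) -- it reproduces the cortex-outside-xylem topology that the
#' imaging stage relies on, not histological detail.
#'
#' The stained part of the cortex is a contiguous angular wedge covering
#' `cortex_stain_fraction` of the cortex, so increasing the fraction grows
#' the stained region monotonically and keeps stained patches large enough
#' to survive the Gaussian blur applied during quantification.
#'
#' Unstained tissue carries a low-frequency colour mottle along the
#' green--red axis (amplitude `mottle_sd`, roughly constant lightness),
#' mimicking biological colour texture; stained pixels carry a
#' depth-of-staining intensity jitter (`stain_jitter`); and the whole frame
#' is shaded by a gentle radial vignette (`vignette`, the multiplicative
#' illumination drop at the image corners), as under a stereo microscope.
#' `noise_sd` is i.i.d. Gaussian sensor noise added to every 8-bit channel.
#'
#' @param image_size integer `c(H, W)` in pixels.
#' @param radii named list with entries `pith` (scalar), `xylem` (inner,
#'   outer), `cortex` (inner, outer) and `epidermis` (scalar), in pixels,
#'   strictly nested.
#' @param cortex_stain_fraction fraction of cortex area stained, in `[0, 1]`.
#' @param xylem_stained logical; is the xylem ring stained (lignified)?
#' @param stain_color,tissue_color,background_color 8-bit RGB triples.
#' @param mottle_sd amplitude (8-bit units) of the tissue colour mottle.
#' @param stain_jitter relative standard deviation of the stain depth.
#' @param vignette fractional illumination drop at the image corners.
#' @param noise_sd standard deviation (8-bit units) of the sensor noise.
#' @param seed integer seed controlling mottle and noise.
#' @return An object of class `section_spec`.
#' @seealso [render_section()]
#' @export
section_spec <- function(image_size = c(512L, 512L),
                         radii = list(pith = 60, xylem = c(110, 150),
                                      cortex = c(160, 230), epidermis = 240),
                         cortex_stain_fraction = 0.3,
                         xylem_stained = TRUE,
                         stain_color = c(120, 100, 103),
                         tissue_color = c(225, 231, 202),
                         background_color = c(252, 252, 252),
                         mottle_sd = 3,
                         stain_jitter = 0.10,
                         vignette = 0.055,
                         noise_sd = 2,
                         seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 16)) {
    stopf("'image_size' must be c(H, W) with both >= 16")
  }
  rr <- c(radii$pith, radii$xylem, radii$cortex, radii$epidermis)
  if (length(rr) != 6L || any(!is.finite(rr))) {
    stopf("'radii' must list pith, xylem (inner, outer), cortex (inner, outer) and epidermis")
  }
  if (any(diff(rr) <= 0) || rr[1] <= 0) {
    stopf("radii must be strictly nested: pith < xylem inner < xylem outer < cortex inner < cortex outer < epidermis")
  }
  check_scalar(cortex_stain_fraction, "cortex_stain_fraction", 0, 1)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(mottle_sd, "mottle_sd", 0)
  check_scalar(stain_jitter, "stain_jitter", 0, 1)
  check_scalar(vignette, "vignette", 0, 1)
  for (nm in c("stain_color", "tissue_color", "background_color")) {
    v <- get(nm)
    if (length(v) != 3L || any(v < 0 | v > 255)) stopf("'%s' must be an RGB triple in [0, 255]", nm)
  }
  structure(list(
    image_size = as.integer(image_size), radii = radii,
    cortex_stain_fraction = cortex_stain_fraction,
    xylem_stained = isTRUE(xylem_stained),
    stain_color = stain_color, tissue_color = tissue_color,
    background_color = background_color,
    mottle_sd = mottle_sd, stain_jitter = stain_jitter,
    vignette = vignette, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "section_spec")
}

#' Render a synthetic stained stem section with ground-truth masks
#'
#' Draws the section described by a [section_spec()] and returns the 8-bit
#' RGB image together with disjoint ground-truth tissue masks and the true
#' lignin (stained) mask. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [section_spec()].
#' @return An object of class `section_image`: a list with `pixels`
#'   (H x W x 3 integer array in `[0, 255]`), `masks` (logical H x W
#'   matrices: `section`, `pith`, `xylem`, `cortex`, `epidermis`,
#'   `stained_cortex`, `lignin`), and the `spec`.
#' @examples
#' img <- render_section(section_spec(image_size = c(96, 96),
#'   radii = list(pith = 10, xylem = c(18, 26), cortex = c(30, 42),
#'                epidermis = 45)))
#' sum(img$masks$lignin)
#' @export
render_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  r <- sqrt(yy^2 + xx^2)
  theta <- atan2(yy, xx) %% (2 * pi)

  rad <- spec$radii
  masks <- list(
    section   = r <= rad$epidermis,
    pith      = r <= rad$pith,
    xylem     = r > rad$xylem[1] & r <= rad$xylem[2],
    cortex    = r > rad$cortex[1] & r <= rad$cortex[2],
    epidermis = r > rad$cortex[2] & r <= rad$epidermis
  )
  masks$stained_cortex <- masks$cortex &
    (theta < 2 * pi * spec$cortex_stain_fraction)
  masks$lignin <- masks$stained_cortex |
    (if (spec$xylem_stained) masks$xylem else matrix(FALSE, H, W))

  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background_color[ch], H, W)
    plane[masks$section] <- spec$tissue_color[ch]
    plane[masks$lignin] <- spec$stain_color[ch]
    px[, , ch] <- plane
  }

  with_seed(spec$seed, {
    if (spec$mottle_sd > 0) {
      field <- blur_matrix(matrix(rnorm(H * W), H, W), sigma = 4)
      field <- field / sd(field) * spec$mottle_sd
      tissue <- masks$section & !masks$lignin
      ## redden/green the tissue while roughly preserving lightness
      px[, , 1][tissue] <- px[, , 1][tissue] + field[tissue]
      px[, , 2][tissue] <- px[, , 2][tissue] - 0.3 * field[tissue]
    }
    if (spec$stain_jitter > 0 && any(masks$lignin)) {
      depth <- blur_matrix(matrix(rnorm(H * W), H, W), sigma = 4)
      depth <- 1 + depth / sd(depth) * spec$stain_jitter
      for (ch in 1:3) {
        px[, , ch][masks$lignin] <- px[, , ch][masks$lignin] * depth[masks$lignin]
      }
    }
    if (spec$vignette > 0) {
      rc <- sqrt(cy^2 + cx^2)
      illum <- 1 - spec$vignette * (r / rc)^4
      for (ch in 1:3) px[, , ch] <- px[, , ch] * illum
    }
    if (spec$noise_sd > 0) {
      px <- px + array(rnorm(length(px), sd = spec$noise_sd), dim = dim(px))
    }
  })
  px <- quantize8(px)

  structure(list(pixels = px, masks = masks, spec = spec,
                 id = sprintf("synthetic-section-seed%d", spec$seed)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section_image> %d x %d px", d[1], d[2]))
  if (!is.null(x$masks)) {
    cat(sprintf(" | section %d px, cortex %d px, true lignin %d px",
                sum(x$masks$section), sum(x$masks$cortex), sum(x$masks$lignin)))
  }
  cat("\n")
  invisible(x)
}

#' Write a section image (or any 8-bit RGB array) as PNG
#'
#' @param image a `section_image` or an H x W x 3 array in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_section_png <- function(image, path) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read an RGB image (PNG) as a section image
#'
#' @param path PNG file path.
#' @param id optional identifier.
#' @return A `section_image` (without ground-truth masks).
#' @export
read_section_png <- function(path, id = basename(path)) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  structure(list(pixels = quantize8(a * 255), masks = NULL, spec = NULL, id = id),
            class = "section_image")
}
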