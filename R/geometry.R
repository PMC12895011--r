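#' Slide geometry
#'
#' Describes the pixel extent and physical resolution of a whole-slide image,
#' together with the physical patch size used for tiling. Patches are cut at a
#' constant physical size, so the pixel side length of a patch is derived from
#' the scan resolution: `side_px = round(patch_um / mpp)` (round half to even,
#' so the result is platform-independent).
#'
#' @param width_px,height_px Slide dimensions in pixels (integers >= 1).
#' @param mpp Microns per pixel of the scan (> 0). Slides whose metadata lack
#'   an MPP cannot be tiled at a fixed physical size and must be excluded;
#'   passing `NA` or a non-positive value raises an error saying so.
#' @param patch_um Patch side length in microns (> 0). Default 128, i.e.
#'   128 x 128 um^2 tiles.
#' @return An object of class `slide_geometry` with fields `width_px`,
#'   `height_px`, `mpp`, `patch_um` and the derived `side_px`.
#' @examples
#' g <- slide_geometry(1000, 600, mpp = 0.5)
#' g$side_px  # 256
#' @export
slide_geometry <- function(width_px, height_px, mpp, patch_um = 128) {
  if (length(mpp) != 1L || !is.numeric(mpp) || !is.finite(mpp) || mpp <= 0) {
    stop("invalid or missing microns-per-pixel (mpp); slide must be excluded",
         call. = FALSE)
  }
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || is.na(height_px) || width_px < 1L || height_px < 1L) {
    stop("slide dimensions must be integers >= 1", call. = FALSE)
  }
  if (!is.numeric(patch_um) || !is.finite(patch_um) || patch_um <= 0) {
    stop("patch_um must be a positive number", call. = FALSE)
  }
  side_px <- as.integer(round(patch_um / mpp))
  if (side_px < 1L) stop("derived patch side is below one pixel", call. = FALSE)
  structure(
    list(width_px = width_px, height_px = height_px, mpp = mpp,
         patch_um = patch_um, side_px = side_px),
    class = "slide_geometry"
  )
}

#' @export
print.slide_geometry <- function(x, ...) {
  cat(sprintf("slide geometry: %d x %d px, %.4g um/px, %g um patches (%d px)\n",
              x$width_px, x$height_px, x$mpp, x$patch_um, x$side_px))
  invisible(x)
}

#' Regular patch grid for a slide
#'
#' Tiles the slide with non-overlapping square patches of constant physical
#' size, anchored at pixel (0, 0). Only patches lying fully inside the slide
#' are kept (partial edge tiles are discarded), so the grid has
#' `floor(width_px / side_px) * floor(height_px / side_px)` patches, in
#' row-major order (y outer, x inner). Coordinates use a 0-based, top-left
#' pixel origin; a patch occupies the half-open extent
#' `[x, x + side_px) x [y, y + side_px)`.
#'
#' @param geometry A [slide_geometry()].
#' @return A data frame with integer columns `x` and `y` (top-left corners,
#'   pixels); zero rows when no full patch fits.
#' @export
compute_patch_grid <- function(geometry) {
  stopifnot(inherits(geometry, "slide_geometry"))
  s <- geometry$side_px
  nx <- geometry$width_px %/% s
  ny <- geometry$height_px %/% s
  if (nx < 1L || ny < 1L) {
    return(data.frame(x = integer(0), y = integer(0)))
  }
  xs <- (seq_len(nx) - 1L) * s
  ys <- (seq_len(ny) - 1L) * s
  data.frame(x = rep(xs, times = ny), y = rep(ys, each = nx))
}

#' Physical area of a patch set
#'
#' Area in mm^2 covered by `n_patches` square patches of side `patch_um`
#' microns, e.g. the footprint of a discovered sufficient patch set.
#'
#' @param n_patches Number of patches.
#' @param patch_um Patch side length in microns.
#' @return Area in mm^2.
#' @examples
#' patch_set_area_mm2(120, 128)  # ~2.0 mm^2
#' @export
patch_set_area_mm2 <- function(n_patches, patch_um = 128) {
  n_patches * (patch_um / 1000)^2
}
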