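#' Region mask for a slide
#'
#' A tissue region (e.g. the tumor-containing area) given either directly as
#' a set of patch row indices into a bag, or as one or more polygons in slide
#' pixel space. Index sets are the canonical form; polygons are resolved to
#' indices by [patches_intersecting_mask()].
#'
#' @param slide_id Slide the mask belongs to.
#' @param patch_indices Optional integer vector of 1-based bag row indices
#'   (duplicates are collapsed; set semantics).
#' @param polygons Optional list of polygons, each an `m x 2` numeric matrix
#'   of vertices (x, y) in slide pixels; closed implicitly (last vertex joins
#'   the first). Simple (non-self-intersecting) polygons are assumed.
#' @return Object of class `region_mask`.
#' @export
region_mask <- function(slide_id, patch_indices = NULL, polygons = NULL) {
  if (!is.null(patch_indices)) {
    patch_indices <- sort(unique(as.integer(patch_indices)))
    if (length(patch_indices) && any(patch_indices < 1L)) {
      stop("patch indices are 1-based and must be >= 1", call. = FALSE)
    }
  }
  if (!is.null(polygons)) {
    stopifnot(is.list(polygons))
    polygons <- lapply(polygons, function(p) {
      p <- as.matrix(p)
      stopifnot(is.numeric(p), ncol(p) == 2, nrow(p) >= 3)
      p
    })
  }
  structure(list(slide_id = as.character(slide_id),
                 patch_indices = patch_indices, polygons = polygons),
            class = "region_mask")
}

# Sutherland-Hodgman: clip polygon `poly` (m x 2) to the half-plane keep(p).
.clip_halfplane <- function(poly, inside, intersect) {
  if (nrow(poly) == 0) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  m <- nrow(poly)
  for (i in seq_len(m)) {
    cur <- poly[i, ]
    prev <- poly[if (i == 1) m else i - 1, ]
    cur_in <- inside(cur)
    prev_in <- inside(prev)
    if (cur_in) {
      if (!prev_in) out <- rbind(out, intersect(prev, cur))
      out <- rbind(out, cur)
    } else if (prev_in) {
      out <- rbind(out, intersect(prev, cur))
    }
  }
  out
}

# Area of the intersection between polygon (m x 2) and rectangle
# [x0, x1) x [y0, y1), by clipping then the shoelace formula.
.poly_rect_intersection_area <- function(poly, x0, y0, x1, y1) {
  edges <- list(
    list(inside = function(p) p[1] >= x0,
         t = function(a, b) (x0 - a[1]) / (b[1] - a[1])),
    list(inside = function(p) p[1] <= x1,
         t = function(a, b) (x1 - a[1]) / (b[1] - a[1])),
    list(inside = function(p) p[2] >= y0,
         t = function(a, b) (y0 - a[2]) / (b[2] - a[2])),
    list(inside = function(p) p[2] <= y1,
         t = function(a, b) (y1 - a[2]) / (b[2] - a[2]))
  )
  clipped <- poly
  for (e in edges) {
    intersect <- function(a, b) {
      t <- e$t(a, b)
      a + t * (b - a)
    }
    clipped <- .clip_halfplane(clipped, e$inside, intersect)
    if (nrow(clipped) < 3) return(0)
  }
  x <- clipped[, 1]; y <- clipped[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Patches of a bag intersecting a region mask
#'
#' Resolves a mask to the set of bag row indices it covers. An index-set mask
#' is returned clipped to `1..N`. A polygonal mask selects every patch whose
#' square pixel extent overlaps the mask with strictly positive area (a
#' boundary touch with zero area does not count; any positive sliver does).
#'
#' @param bag An [embedding_bag()].
#' @param mask A [region_mask()] for the same slide.
#' @return Sorted integer vector of 1-based patch indices (possibly empty).
#' @export
patches_intersecting_mask <- function(bag, mask) {
  stopifnot(inherits(bag, "embedding_bag"), inherits(mask, "region_mask"))
  if (!identical(bag$slide_id, mask$slide_id)) {
    stop(sprintf("mask is for slide '%s' but bag is slide '%s'",
                 mask$slide_id, bag$slide_id), call. = FALSE)
  }
  n <- n_patches(bag)
  idx <- integer(0)
  if (!is.null(mask$patch_indices)) {
    idx <- mask$patch_indices[mask$patch_indices <= n]
  }
  if (!is.null(mask$polygons) && length(mask$polygons)) {
    s <- bag$geometry$side_px
    hit <- vapply(seq_len(n), function(i) {
      x0 <- bag$coords$x[i]; y0 <- bag$coords$y[i]
      any(vapply(mask$polygons, function(p) {
        .poly_rect_intersection_area(p, x0, y0, x0 + s, y0 + s) > 1e-9
      }, logical(1)))
    }, logical(1))
    idx <- union(idx, which(hit))
  }
  sort(unique(as.integer(idx)))
}
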