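#' Embedding bag: one whole-slide image as a set of patch feature vectors
#'
#' The multiple-instance representation of a slide: an `N x d` matrix of patch
#' embeddings, patch coordinates aligned to its rows, and the slide geometry
#' they were tiled from. Rows are the instances of the bag; their order is
#' preserved but carries no meaning for prediction (the model is
#' permutation-invariant).
#'
#' @param features Numeric `N x d` matrix, all entries finite, `N >= 1`.
#' @param coords Data frame (or 2-column matrix) of patch top-left corners in
#'   slide pixels, columns `x` and `y`, one row per feature row. Coordinates
#'   are 0-based and each patch extent `[x, x + side_px) x [y, y + side_px)`
#'   must lie inside the slide. Duplicate coordinates are rejected.
#' @param geometry A [slide_geometry()].
#' @param slide_id,encoder_id Identifier strings for the slide and for the
#'   patch encoder that produced the embeddings.
#' @return An object of class `embedding_bag`.
#' @export
embedding_bag <- function(features, coords, geometry, slide_id,
                          encoder_id = "unknown") {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("features must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(features)
  if (n < 1L) stop("a bag needs at least one patch", call. = FALSE)
  if (any(!is.finite(features))) {
    stop("all feature values must be finite", call. = FALSE)
  }
  stopifnot(inherits(geometry, "slide_geometry"))
  coords <- as.data.frame(coords)
  if (ncol(coords) < 2L) stop("coords needs columns x and y", call. = FALSE)
  if (is.null(names(coords)) || !all(c("x", "y") %in% names(coords))) {
    names(coords)[1:2] <- c("x", "y")
  }
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  if (nrow(coords) != n) {
    stop("coords must have one row per feature row", call. = FALSE)
  }
  if (anyDuplicated(coords)) stop("duplicate patch coordinates", call. = FALSE)
  s <- geometry$side_px
  if (any(coords$x < 0L | coords$y < 0L |
          coords$x + s > geometry$width_px |
          coords$y + s > geometry$height_px)) {
    stop("patches must lie fully inside the slide", call. = FALSE)
  }
  structure(
    list(slide_id = as.character(slide_id),
         encoder_id = as.character(encoder_id),
         features = features, coords = coords, geometry = geometry),
    class = "embedding_bag"
  )
}

#' @export
print.embedding_bag <- function(x, ...) {
  cat(sprintf("embedding bag '%s' [%s]: %d patches x %d dims\n",
              x$slide_id, x$encoder_id, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Number of patches in a bag
#' @param bag An [embedding_bag()].
#' @export
n_patches <- function(bag) {
  stopifnot(inherits(bag, "embedding_bag"))
  nrow(bag$features)
}

# Fields every serialized bag must carry.
.bag_required_fields <- c("features", "coords", "slide_id", "encoder_id",
                          "mpp", "width_px", "height_px", "patch_um")

#' Write / read an embedding bag container
#'
#' One file per slide, in the package's native container: a versioned,
#' serialized record holding the feature matrix (`N x d` doubles), the
#' coordinate table (`N x 2` integers, x then y) and the slide metadata
#' (`slide_id`, `encoder_id`, `mpp`, `width_px`, `height_px`, `patch_um`,
#' `side_px`). The round trip is lossless: features are bit-identical and all
#' metadata are preserved. `read_bag()` validates the container and names any
#' missing field in its error.
#'
#' @param bag An [embedding_bag()].
#' @param path File path.
#' @return `write_bag()` returns `path` invisibly; `read_bag()` returns the
#'   reconstructed [embedding_bag()].
#' @export
write_bag <- function(bag, path) {
  stopifnot(inherits(bag, "embedding_bag"))
  rec <- list(container = "embedding_bag", version = 1L,
              features = bag$features,
              coords = as.matrix(bag$coords[, c("x", "y")]),
              slide_id = bag$slide_id, encoder_id = bag$encoder_id,
              mpp = bag$geometry$mpp,
              width_px = bag$geometry$width_px,
              height_px = bag$geometry$height_px,
              patch_um = bag$geometry$patch_um,
              side_px = bag$geometry$side_px)
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_bag
#' @export
read_bag <- function(path) {
  rec <- readRDS(path)
  if (!is.list(rec) || !identical(rec$container, "embedding_bag")) {
    stop("not an embedding bag container: ", path, call. = FALSE)
  }
  missing_fields <- setdiff(.bag_required_fields, names(rec))
  if (length(missing_fields)) {
    stop("bag container missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  geom <- slide_geometry(rec$width_px, rec$height_px, rec$mpp, rec$patch_um)
  embedding_bag(rec$features,
                data.frame(x = rec$coords[, 1], y = rec$coords[, 2]),
                geom, rec$slide_id, rec$encoder_id)
}
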