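#' Export per-patch attention weights as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection with one closed rectangular Polygon
#' per patch, in slide pixel coordinates, for review in slide viewers that
#' read GeoJSON annotations (e.g. QuPath). Each feature carries the raw
#' attention weight and its rank (`attention_rank`, 1 = highest attention;
#' ties keep bag row order, so exports are reproducible).
#'
#' @param bag An [embedding_bag()].
#' @param attention Numeric vector of attention weights aligned to the bag's
#'   rows; must sum to 1 within `1e-6`.
#' @param path Output file path.
#' @return The GeoJSON document as a list, invisibly (also written to `path`).
#' @export
export_attention_geojson <- function(bag, attention, path) {
  stopifnot(inherits(bag, "embedding_bag"))
  n <- n_patches(bag)
  if (length(attention) != n) {
    stop(sprintf("attention has length %d but bag has %d patches",
                 length(attention), n), call. = FALSE)
  }
  if (abs(sum(attention) - 1) > 1e-6) {
    stop("attention weights must sum to 1", call. = FALSE)
  }
  rk <- rank(-attention, ties.method = "first")
  s <- bag$geometry$side_px
  features <- lapply(seq_len(n), function(i) {
    x0 <- bag$coords$x[i]; y0 <- bag$coords$y[i]
    ring <- list(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s),
                 c(x0, y0 + s), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(slide_id = bag$slide_id,
                           attention = attention[i],
                           attention_rank = as.integer(rk[i])))
  })
  doc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(doc)
}
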