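#' Construct a VillageSet
#'
#' @param ids unique village identifiers.
#' @param polygons list of 2-column (x, y) coordinate matrices in meters, one
#'   simple ring per village (first vertex need not be repeated).
#' @return a [VillageSet-class]; areas (km2) are computed from the rings.
#' @export
villageSet <- function(ids, polygons) {
  if (anyDuplicated(ids)) .dataError("duplicate village ids")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    n <- nrow(p)
    # drop a repeated closing vertex
    if (n > 3L && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    unname(p)
  })
  areas <- vapply(polygons, .polygonArea, numeric(1)) / 1e6
  new("VillageSet", ids = as.character(ids), polygons = polygons,
      areas = areas)
}

#' Read and write village polygons as GeoJSON
#'
#' Villages are exchanged as a GeoJSON FeatureCollection of Polygon features
#' carrying a \code{village_id} property (plus any extra columns supplied in
#' \code{properties}). Coordinates are in the shared projected CRS of the
#' study; no reprojection is attempted.
#'
#' @param path file path.
#' @return \code{readVillagesGeoJSON} returns a [VillageSet-class];
#'   \code{writeVillagesGeoJSON} returns \code{path} invisibly.
#' @export
readVillagesGeoJSON <- function(path) {
  if (!file.exists(path)) .configError("GeoJSON file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) .dataError("no features in %s", path)
  ids <- character(0)
  polys <- list()
  for (f in gj$features) {
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon"))
      .dataError("unsupported geometry type in %s", path)
    ring <- if (geom$type == "Polygon") geom$coordinates[[1]]
            else geom$coordinates[[1]][[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    id <- f$properties$village_id
    if (is.null(id)) .dataError("feature without village_id in %s", path)
    ids <- c(ids, as.character(id))
    polys[[length(polys) + 1L]] <- xy
  }
  villageSet(ids, polys)
}

#' @param villages a [VillageSet-class].
#' @param properties optional data.frame of per-village attributes to embed;
#'   matched to villages by a \code{village_id} column.
#' @rdname readVillagesGeoJSON
#' @export
writeVillagesGeoJSON <- function(villages, path, properties = NULL) {
  ids <- villages@ids
  if (!is.null(properties)) {
    if (is.null(properties$village_id))
      .dataError("'properties' must contain a village_id column")
    properties <- properties[match(ids, properties$village_id), , drop = FALSE]
  }
  feats <- lapply(seq_along(ids), function(i) {
    p <- villages@polygons[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    props <- list(village_id = ids[i],
                  area_km2 = round(villages@areas[i], 6))
    if (!is.null(properties)) {
      extra <- as.list(properties[i, setdiff(names(properties), "village_id"),
                                  drop = FALSE])
      props <- c(props, lapply(extra, function(v)
        if (is.factor(v)) as.character(v) else unname(v)))
    }
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read and write per-village mortality tables
#'
#' Long-format CSV with columns \code{village_id, period, deaths, population}.
#'
#' @param path CSV path.
#' @return a data.frame (\code{readMortalityCSV}) or \code{path} invisibly.
#' @export
readMortalityCSV <- function(path) {
  if (!file.exists(path)) .configError("mortality file not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("village_id", "period", "deaths", "population")
  if (!all(need %in% names(m)))
    .dataError("mortality CSV must have columns: %s",
               paste(need, collapse = ", "))
  if (any(m$deaths < 0) || any(m$population < 0))
    .dataError("negative deaths or population in %s", path)
  m$village_id <- as.character(m$village_id)
  m
}

#' @param mortality long-format mortality data.frame.
#' @rdname readMortalityCSV
#' @export
writeMortalityCSV <- function(mortality, path) {
  utils::write.csv(mortality, path, row.names = FALSE)
  invisible(path)
}
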