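#' Write rectangular zones (sub-basins, counties, fields) as GeoJSON polygons
#'
#' @param zones data.table/data.frame with one row per zone: an id column plus
#'   `xmin`, `xmax`, `ymin`, `ymax` rectangle bounds in projected meters. Any
#'   additional columns become feature properties.
#' @param path Output path.
#' @param id_col Name of the id column.
#' @param crs_label Stored in the file's top-level `crs_label` member.
#' @return `path`, invisibly.
#' @export
write_geojson_rects <- function(zones, path, id_col = "id",
                                crs_label = "local-projected-m") {
  zones <- as.data.frame(zones)
  req <- c(id_col, "xmin", "xmax", "ymin", "ymax")
  if (!all(req %in% names(zones)))
    stop("zones must have columns: ", paste(req, collapse = ", "))
  props <- setdiff(names(zones), c("xmin", "xmax", "ymin", "ymax"))
  features <- lapply(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    ring <- list(c(z$xmin, z$ymin), c(z$xmax, z$ymin), c(z$xmax, z$ymax),
                 c(z$xmin, z$ymax), c(z$xmin, z$ymin))
    list(type = "Feature",
         properties = as.list(z[props]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", crs_label = crs_label,
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read back rectangles written by [write_geojson_rects()]
#'
#' @param path GeoJSON path.
#' @return data.table of feature properties.
#' @export
read_geojson_rects <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    c(f$properties,
      list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys)))
  })
  rbindlist(lapply(rows, as.data.table), fill = TRUE)
}
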