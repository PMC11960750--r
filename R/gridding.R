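#' Square analysis grid specification
#'
#' Cells are half-open squares `[origin + i*cell, origin + (i+1)*cell)` on
#' each axis with 0-based indices `(ix, iy)`.
#'
#' @param origin_x,origin_y Lower-left corner in projected metres.
#' @param cell_size Cell edge length in metres (default 15).
#' @param nx,ny Number of cells along x and y.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 15, nx, ny) {
  stopifnot(cell_size > 0, nx >= 1, ny >= 1,
            nx == round(nx), ny == round(ny))
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, nx = as.integer(nx),
                 ny = as.integer(ny)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Build a grid covering a set of projected fixes
#'
#' The grid covers `[min - pad, max + pad]` on each axis with the minimal
#' number of cells, with the origin snapped so that the projected-space
#' origin `(0, 0)` falls on a cell corner.  Snapping makes grids
#' reproducible run-to-run regardless of which animal's data defined the
#' extent.
#'
#' @param fixes Data frame with projected `x`, `y` columns (or a numeric
#'   matrix/data.frame of coordinates).
#' @param cell_size Cell edge length in metres (default 15).
#' @param pad Margin in metres added on every side (default 0).
#' @return A [grid_spec()].
#' @export
make_grid <- function(fixes, cell_size = 15, pad = 0) {
  stopifnot(cell_size > 0, pad >= 0)
  x <- fixes$x; y <- fixes$y
  if (is.null(x) || length(x) == 0) stop("no fixes to grid", call. = FALSE)
  lo_x <- floor((min(x) - pad) / cell_size) * cell_size
  lo_y <- floor((min(y) - pad) / cell_size) * cell_size
  nx <- max(1L, ceiling(((max(x) + pad) - lo_x) / cell_size))
  ny <- max(1L, ceiling(((max(y) + pad) - lo_y) / cell_size))
  # a point exactly on the upper edge must stay in-bounds (half-open cells)
  if (lo_x + nx * cell_size <= max(x) + pad) nx <- nx + 1L
  if (lo_y + ny * cell_size <= max(y) + pad) ny <- ny + 1L
  grid_spec(lo_x, lo_y, cell_size, nx, ny)
}

#' Locate points in grid cells
#'
#' Half-open assignment: a point exactly on the boundary
#' `origin + i*cell_size` belongs to cell `i`.  Out-of-bounds points get
#' `NA` indices rather than an error; the caller decides.
#'
#' @param grid A [grid_spec()].
#' @param x,y Numeric vectors of projected coordinates (metres).
#' @return Data frame with 0-based integer columns `ix`, `iy` (`NA` when
#'   out of bounds).
#' @export
locate_cell <- function(grid, x, y) {
  ix <- floor((x - grid$origin_x) / grid$cell_size)
  iy <- floor((y - grid$origin_y) / grid$cell_size)
  oob <- ix < 0 | ix >= grid$nx | iy < 0 | iy >= grid$ny |
    !is.finite(ix) | !is.finite(iy)
  ix[oob] <- NA_integer_; iy[oob] <- NA_integer_
  data.frame(ix = as.integer(ix), iy = as.integer(iy))
}

#' Raster of values over a grid
#'
#' @param grid A [grid_spec()].
#' @param values `nx` by `ny` numeric matrix; `values[ix + 1, iy + 1]` is
#'   the value of 0-based cell `(ix, iy)`.  Defaults to all zeros.
#' @param units Free-text unit tag (`"seconds"`, `"activity counts"`,
#'   `"degC"`, `"probability"`, ...).
#' @return An object of class `ud_raster`.
#' @export
ud_raster <- function(grid, values = NULL, units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(values)) values <- matrix(0, grid$nx, grid$ny)
  values <- as.matrix(values)
  if (nrow(values) != grid$nx || ncol(values) != grid$ny)
    stop("values dimensions do not match the grid", call. = FALSE)
  structure(list(grid = grid, values = values, units = units),
            class = "ud_raster")
}

#' @export
print.ud_raster <- function(x, ...) {
  cat(sprintf("ud_raster [%s]: %d x %d cells, total %g\n",
              x$units, x$grid$nx, x$grid$ny, sum(x$values, na.rm = TRUE)))
  invisible(x)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Normalize a raster to a discrete probability distribution
#'
#' Divides every cell by the raster total so entries sum to 1; `NA` cells
#' (flagged empty/no-data) are treated as zero mass and excluded.
#'
#' @param r A `ud_raster` with non-negative values and positive total.
#' @return A raster of class `c("prob_raster", "ud_raster")` with
#'   `units = "probability"`.
#' @export
normalize_raster <- function(r) {
  stopifnot(inherits(r, "ud_raster"))
  v <- r$values
  v[is.na(v)] <- 0
  if (any(v < 0)) stop("negative mass cannot be normalized", call. = FALSE)
  tot <- sum(v)
  if (tot <= 0) stop("all-zero raster cannot be normalized", call. = FALSE)
  out <- ud_raster(r$grid, v / tot, units = "probability")
  class(out) <- c("prob_raster", class(out))
  out
}

.check_prob <- function(p) {
  if (!inherits(p, "prob_raster")) {
    v <- p$values
    v[is.na(v)] <- 0
    if (abs(sum(v) - 1) > 1e-9)
      stop("input is not a normalized probability raster", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a raster as CSV plus a JSON grid sidecar
#'
#' The canonical on-disk raster format is a headered CSV of
#' `(ix, iy, value)` triples for non-empty cells together with a JSON
#' sidecar (`<path>.grid.json`) holding the `grid_spec`, units and, if
#' given, the projection reference point.
#'
#' @param r A `ud_raster`.
#' @param path CSV output path.
#' @param ref Optional [ref_point()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, ref = NULL) {
  idx <- which(!is.na(r$values), arr.ind = TRUE)
  df <- data.frame(ix = idx[, 1] - 1L, iy = idx[, 2] - 1L,
                   value = r$values[idx])
  df <- df[order(df$ix, df$iy), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(grid = unclass(r$grid), units = r$units)
  if (!is.null(ref)) side$ref <- unclass(ref)
  jsonlite::write_json(side, paste0(path, ".grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @param empty_na Cells absent from the CSV are read back as `NA` when
#'   `TRUE` (no-data flag) or 0 when `FALSE`.
#' @export
read_raster <- function(path, empty_na = FALSE) {
  side <- jsonlite::read_json(paste0(path, ".grid.json"),
                              simplifyVector = TRUE)
  g <- grid_spec(side$grid$origin_x, side$grid$origin_y,
                 side$grid$cell_size, side$grid$nx, side$grid$ny)
  df <- read.csv(path)
  v <- matrix(if (empty_na) NA_real_ else 0, g$nx, g$ny)
  v[cbind(df$ix + 1L, df$iy + 1L)] <- df$value
  r <- ud_raster(g, v, units = side$units)
  if (identical(side$units, "probability")) class(r) <- c("prob_raster", class(r))
  r
}

.point_in_polygon <- function(px, py, poly_x, poly_y) {
  # even-odd rule; vertices given in order, polygon closed implicitly
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Region mask over a grid from labelled polygons
#'
#' Assigns each grid cell exactly one region label by testing the cell
#' centre against labelled polygons (first match wins, in file order);
#' cells in no polygon get `default_label`.  Polygons are supplied as a
#' GeoJSON FeatureCollection in projected metres with a `label` (or
#' `name`) property per feature.
#'
#' @param grid A [grid_spec()].
#' @param path Path to a GeoJSON polygon file, or a list of
#'   `list(label =, x =, y =)` polygons.
#' @param default_label Label for unclaimed cells.
#' @return An object of class `region_mask`: the grid plus an `nx` by `ny`
#'   character matrix `membership`.
#' @export
read_region_mask <- function(grid, path, default_label = "outside") {
  polys <- if (is.character(path)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(gj$features, function(f) {
      ring <- f$geometry$coordinates[[1]]
      list(label = f$properties$label %||% f$properties$name %||% "region",
           x = vapply(ring, function(p) as.numeric(p[[1]]), 0),
           y = vapply(ring, function(p) as.numeric(p[[2]]), 0))
    })
  } else path
  cx <- grid$origin_x + (seq_len(grid$nx) - 0.5) * grid$cell_size
  cy <- grid$origin_y + (seq_len(grid$ny) - 0.5) * grid$cell_size
  pts <- expand.grid(x = cx, y = cy)
  membership <- matrix(default_label, grid$nx, grid$ny)
  claimed <- matrix(FALSE, grid$nx, grid$ny)
  for (pg in polys) {
    hit <- matrix(.point_in_polygon(pts$x, pts$y, pg$x, pg$y),
                  grid$nx, grid$ny)
    take <- hit & !claimed
    membership[take] <- pg$label
    claimed <- claimed | hit
  }
  structure(list(grid = grid, membership = membership),
            class = "region_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an isopleth cell set as GeoJSON polygons
#'
#' Each included cell is emitted as one square polygon feature in
#' projected metres; the reference point, level and enclosed mass are
#' recorded in the feature properties.
#'
#' @param iso An isopleth result from [volume_isopleth()].
#' @param grid The [grid_spec()] the isopleth was computed on.
#' @param path Output path.
#' @param ref Optional [ref_point()] recorded in properties.
#' @return `path`, invisibly.
#' @export
write_isopleth_geojson <- function(iso, grid, path, ref = NULL) {
  cs <- grid$cell_size
  feats <- lapply(seq_len(nrow(iso$cells)), function(i) {
    x0 <- grid$origin_x + iso$cells$ix[i] * cs
    y0 <- grid$origin_y + iso$cells$iy[i] * cs
    ring <- list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                 c(x0, y0 + cs), c(x0, y0))
    props <- list(level = iso$level, mass = iso$mass)
    if (!is.null(ref)) { props$lat0 <- ref$lat0; props$lon0 <- ref$lon0 }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
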