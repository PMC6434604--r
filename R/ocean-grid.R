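#' Ocean/land raster grid for least-cost marine distances
#'
#' A rectangular grid of cells flagged water or land. Water cells are
#' connected to their 8 neighbours; edge weights are the distances between
#' cell centers (planar Euclidean for `lonlat = FALSE`, great-circle
#' otherwise). Any single-band gridded mask can be supplied as a matrix
#' (values `<= sea_level` are water), so ETOPO1-style bathymetry exported as
#' a plain matrix is accepted but never required.
#'
#' @param mask numeric or logical matrix; with logical input `TRUE` = water.
#' @param sea_level threshold for numeric masks (water iff `mask <= sea_level`).
#' @param cell_km cell size in km (planar grids).
#' @param lonlat treat coordinates as decimal degrees and use great-circle
#'   edge lengths.
#' @param lon,lat optional vectors of cell-center longitudes (per column)
#'   and latitudes (per row); required when `lonlat = TRUE`.
#' @return object of class `ocean_grid`.
#' @export
ocean_grid <- function(mask, sea_level = 0, cell_km = 1, lonlat = FALSE,
                       lon = NULL, lat = NULL) {
  water <- if (is.logical(mask)) mask else mask <= sea_level
  if (!any(water)) .stopf("grid has no water cells")
  nr <- nrow(water); nc <- ncol(water)
  if (lonlat) {
    if (is.null(lon) || is.null(lat)) .stopf("lonlat grids need lon and lat")
    stopifnot(length(lon) == nc, length(lat) == nr)
    x <- matrix(lon, nr, nc, byrow = TRUE)
    y <- matrix(lat, nr, nc)
  } else {
    x <- matrix((seq_len(nc) - 0.5) * cell_km, nr, nc, byrow = TRUE)
    y <- matrix((seq_len(nr) - 0.5) * cell_km, nr, nc)
  }
  structure(list(water = water, x = x, y = y, lonlat = lonlat,
                 cell_km = cell_km), class = "ocean_grid")
}

#' @export
print.ocean_grid <- function(x, ...) {
  cat(sprintf("ocean_grid: %d x %d cells, %d water (%s)\n",
              nrow(x$water), ncol(x$water), sum(x$water),
              if (x$lonlat) "lon/lat" else "planar km"))
  invisible(x)
}

#' Great-circle distance in km (haversine)
#' @param lon1,lat1,lon2,lat2 decimal degrees (vectorised).
#' @return distance in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to <- pi / 180
  dlat <- (lat2 - lat1) * to
  dlon <- (lon2 - lon1) * to
  a <- sin(dlat / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

.cell_dist <- function(grid, i1, i2) {
  if (grid$lonlat) great_circle_km(grid$x[i1], grid$y[i1], grid$x[i2], grid$y[i2])
  else sqrt((grid$x[i1] - grid$x[i2])^2 + (grid$y[i1] - grid$y[i2])^2)
}

# igraph over water cells, 8-neighbourhood, center-to-center edge weights
.grid_graph <- function(grid) {
  nr <- nrow(grid$water); nc <- ncol(grid$water)
  id <- matrix(seq_len(nr * nc), nr, nc)     # row-major cell numbering below
  wid <- which(grid$water)
  vmap <- rep(NA_integer_, nr * nc)
  vmap[wid] <- seq_along(wid)
  from <- integer(0); to <- integer(0)
  for (sh in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    dr <- sh[1]; dc <- sh[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- as.vector(id[r1, c1, drop = FALSE])
    b <- as.vector(id[r1 + dr, c1 + dc, drop = FALSE])
    ok <- grid$water[a] & grid$water[b]
    from <- c(from, a[ok]); to <- c(to, b[ok])
  }
  w <- .cell_dist(grid, from, to)
  g <- igraph::make_empty_graph(n = length(wid), directed = FALSE)
  g <- igraph::add_edges(g, rbind(vmap[from], vmap[to]))
  igraph::E(g)$weight <- w
  list(graph = g, vmap = vmap, wid = wid)
}

#' Snap a coordinate to the nearest water cell
#'
#' Nearest by center distance; ties broken by row-major cell order.
#'
#' @param grid ocean_grid.
#' @param x,y coordinate (lon/lat degrees for lon/lat grids, km otherwise).
#' @return linear cell index (row-major within the grid matrix).
#' @export
snap_to_water <- function(grid, x, y) {
  wid <- which(grid$water)
  ord <- order(((wid - 1) %% nrow(grid$water)) * ncol(grid$water) +
               (wid - 1) %/% nrow(grid$water))   # row-major scan order
  wid <- wid[ord]
  d <- if (grid$lonlat) great_circle_km(x, y, grid$x[wid], grid$y[wid])
       else sqrt((grid$x[wid] - x)^2 + (grid$y[wid] - y)^2)
  wid[which.min(d)]
}

#' Least-cost water distance between two points
#'
#' Dijkstra shortest path over water cells (8-neighbourhood). With
#' `waypoints`, the path is the concatenation of shortest legs
#' `src -> w1 -> ... -> dst`, e.g. to force routes to round the east side of
#' an island before heading west.
#'
#' @param grid ocean_grid.
#' @param src,dst length-2 coordinate vectors `c(x, y)` (or `c(lon, lat)`).
#' @param waypoints optional list of coordinate vectors visited in order.
#' @return distance in km (grid units for unit planar grids).
#' @export
least_cost_distance <- function(grid, src, dst, waypoints = NULL) {
  gg <- .grid_graph(grid)
  pts <- c(list(src), waypoints, list(dst))
  cells <- vapply(pts, function(p) snap_to_water(grid, p[1], p[2]), numeric(1))
  v <- gg$vmap[cells]
  total <- 0
  for (i in seq_len(length(v) - 1)) {
    d <- igraph::distances(gg$graph, v[i], v[i + 1])[1, 1]
    if (!is.finite(d)) .stopf("no water path between points %d and %d", i, i + 1)
    total <- total + d
  }
  total
}

#' Per-site distances from an origin site
#'
#' Computes, for every site, the least-cost water distance from the origin,
#' optionally forcing designated sites through an ordered set of waypoints
#' (the "modified" distance), plus the great-circle distance.
#'
#' @param grid ocean_grid (lon/lat or planar; coordinates must match).
#' @param sites data.frame with columns `pop`, `lat`, `lon` (or `y`, `x`
#'   for planar grids via `lat`/`lon` aliases).
#' @param origin population label of the origin site.
#' @param waypoint_sites character vector of site labels whose paths must
#'   pass through `waypoints`.
#' @param waypoints list of `c(lon, lat)` coordinates applied, in order, to
#'   `waypoint_sites`.
#' @return data.frame `pop`, `least_cost_km`, `modified_km`,
#'   `great_circle_km`; origin rows are 0.
#' @export
distance_table <- function(grid, sites, origin, waypoint_sites = character(0),
                           waypoints = NULL) {
  if (!origin %in% sites$pop) .stopf("origin %s not in sites", origin)
  o <- sites[sites$pop == origin, ]
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    if (s$pop == origin)
      return(data.frame(pop = s$pop, least_cost_km = 0, modified_km = 0,
                        great_circle_km = 0))
    lc <- least_cost_distance(grid, c(o$lon, o$lat), c(s$lon, s$lat))
    md <- if (s$pop %in% waypoint_sites && length(waypoints))
      least_cost_distance(grid, c(o$lon, o$lat), c(s$lon, s$lat),
                          waypoints = waypoints)
    else lc
    gc <- if (grid$lonlat) great_circle_km(o$lon, o$lat, s$lon, s$lat)
          else sqrt((o$lon - s$lon)^2 + (o$lat - s$lat)^2)
    data.frame(pop = s$pop, least_cost_km = lc, modified_km = md,
               great_circle_km = gc)
  }))
  rownames(out) <- NULL
  out
}

#' Regress a per-site diversity statistic on distance from the origin
#'
#' Ordinary least squares; the two-sided p-value is from the t statistic of
#' the slope with n - 2 degrees of freedom.
#'
#' @param values named numeric vector (names = site labels) or numeric
#'   vector aligned with `distances`.
#' @param distances data.frame from [distance_table()] (uses `modified_km`),
#'   or a numeric vector of distances.
#' @param distance_col column of `distances` to use when it is a data.frame.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
diversity_distance_regression <- function(values, distances,
                                          distance_col = "modified_km") {
  if (is.data.frame(distances)) {
    x <- distances[[distance_col]]
    if (!is.null(names(values))) values <- values[distances$pop]
  } else x <- as.numeric(distances)
  y <- as.numeric(values)
  if (length(x) != length(y)) .stopf("values and distances differ in length")
  if (length(x) < 3) .stopf("regression needs >= 3 sites")
  if (stats::var(x) == 0) .stopf("zero variance in distances")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p_value = 1,
                n = length(x)))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = unname(co["x", "Pr(>|t|)"]),
       n = length(x))
}
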