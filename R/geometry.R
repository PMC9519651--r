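#' Planar polygon utilities
#'
#' Polygons are simple rings: two-column matrices of vertex coordinates in
#' meters (open form; the closing edge back to the first vertex is implied).
#' A set of grazing sites is a list with elements `polygons` (list of rings),
#' `site_id` (character) and `group` (character, e.g. "north"/"south").
#'
#' @param polygons list of two-column vertex matrices.
#' @param site_id character vector of site identifiers.
#' @param group character vector assigning each site to a site group.
#' @return An object of class `site_set`.
#' @export
site_set <- function(polygons, site_id = NULL, group = NULL) {
  if (length(polygons) == 0L) stop("empty site list")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) < 2L || nrow(p) < 3L) stop("polygon must have >= 3 vertices")
    v <- p[, 1:2, drop = FALSE]
    if (!all(is.finite(v))) stop("polygon vertices must be finite")
    if (abs(polygon_area(v)) <= 0) stop("degenerate polygon (zero area)")
    v
  })
  structure(list(
    polygons = polygons,
    site_id = site_id %||% paste0("site", seq_along(polygons)),
    group = group %||% rep("all", length(polygons))
  ), class = "site_set")
}

#' Shoelace area of a polygon ring
#' @param poly two-column matrix of vertices.
#' @return area in square meters (always nonnegative).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Minimum convex polygon (convex hull) of relocations
#'
#' The grazing-site boundaries in the study design are delineated as the
#' minimum convex polygon of a collared animal's fixes.
#'
#' @param points two-column matrix or data.frame of x/y in meters.
#' @return two-column matrix of hull vertices in counter-clockwise order.
#' @export
mcp <- function(points) {
  pts <- unique(as.matrix(points[, 1:2, drop = FALSE]))
  if (nrow(pts) < 3L) stop("need >= 3 distinct points for a convex polygon")
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (polygon_area(hull) <= 0) stop("degenerate input: points are collinear")
  # chull returns clockwise order; reverse for counter-clockwise rings
  hull[rev(seq_len(nrow(hull))), , drop = FALSE]
}

# squared distance from points (n x 2) to one segment a-b, vectorized over points
.dist2_seg <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- pts[, 1] - (a[1] + t * ab[1])
  dy <- pts[, 2] - (a[2] + t * ab[2])
  dx^2 + dy^2
}

# distance from points to a polygon boundary
.dist_boundary <- function(pts, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d2 <- pmin(d2, .dist2_seg(pts, poly[i, ], poly[j, ]))
  }
  sqrt(d2)
}

# strict interior test via mgcv's in/out routine
.in_polygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1L, , drop = FALSE])
  mgcv::in.out(bnd, as.matrix(pts))
}

#' Minimum distance from points to the nearest grazing site
#'
#' Euclidean distance in meters to the closest site polygon; points inside a
#' polygon or on its boundary have distance 0. With several sites the minimum
#' over all sites is returned.
#'
#' @param points two-column matrix or data.frame of x/y in meters.
#' @param sites a `site_set` (or list of polygon matrices).
#' @return numeric vector of distances (m).
#' @export
distance_to_sites <- function(points, sites) {
  polys <- if (inherits(sites, "site_set")) sites$polygons else sites
  if (length(polys) == 0L) stop("need at least one site polygon")
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  d <- rep(Inf, nrow(pts))
  for (poly in polys) {
    db <- .dist_boundary(pts, poly)
    db[.in_polygon(pts, poly)] <- 0
    d <- pmin(d, db)
  }
  d
}

#' Binary inside-site indicator
#'
#' 1 if a point lies inside or on the boundary of any site polygon
#' (boundary points count as inside), else 0. This is the response of the
#' site-use model.
#'
#' @inheritParams distance_to_sites
#' @param tol boundary tolerance in meters.
#' @return integer vector of 0/1.
#' @export
point_in_sites <- function(points, sites, tol = 1e-9) {
  polys <- if (inherits(sites, "site_set")) sites$polygons else sites
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  inside <- rep(FALSE, nrow(pts))
  for (poly in polys) {
    inside <- inside | .in_polygon(pts, poly) | (.dist_boundary(pts, poly) <= tol)
  }
  as.integer(inside)
}

#' Uniform random points inside a polygon
#'
#' Rejection sampling from the bounding box.
#'
#' @param n number of points.
#' @param poly two-column vertex matrix.
#' @param seed integer seed.
#' @return n x 2 matrix of coordinates.
#' @export
sample_in_polygon <- function(n, poly, seed) {
  with_seed(seed, {
    out <- matrix(NA_real_, 0L, 2L)
    rx <- range(poly[, 1]); ry <- range(poly[, 2])
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 64L)
      cand <- cbind(stats::runif(m, rx[1], rx[2]), stats::runif(m, ry[1], ry[2]))
      keep <- .in_polygon(cand, poly)
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
}

#' Assign an animal to the grazing-site group inside its home range
#'
#' The treatment category of each fix refers to grazing activity at the
#' site(s) lying within that animal's home range. The group whose sites
#' intersect the home polygon is chosen; with overlap of several groups, the
#' larger intersection area wins (measured by grid integration).
#'
#' @param home_polygon two-column vertex matrix of the home range (or an
#'   `isopleth`; its first polygon ring is used).
#' @param sites a `site_set` with a `group` vector.
#' @param cell grid resolution (m) for the area integration.
#' @return the group label, or `NA_character_` (with a warning) when the home
#'   polygon overlaps no site.
#' @export
assign_site_group <- function(home_polygon, sites, cell = 25) {
  stopifnot(inherits(sites, "site_set"))
  if (inherits(home_polygon, "isopleth")) home_polygon <- home_polygon$polygons[[1L]]
  home_polygon <- as.matrix(home_polygon)
  rx <- range(home_polygon[, 1]); ry <- range(home_polygon[, 2])
  cell <- min(cell, (rx[2] - rx[1]) / 8, (ry[2] - ry[1]) / 8)
  gx <- seq(rx[1] + cell / 2, rx[2], by = cell)
  gy <- seq(ry[1] + cell / 2, ry[2], by = cell)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  in_home <- .in_polygon(grid, home_polygon)
  groups <- unique(sites$group)
  areas <- vapply(groups, function(g) {
    polys <- sites$polygons[sites$group == g]
    hit <- rep(FALSE, nrow(grid))
    for (p in polys) hit <- hit | .in_polygon(grid, p)
    sum(hit & in_home) * cell^2
  }, numeric(1))
  if (all(areas == 0)) {
    warning("home polygon intersects no site group; animal unassignable")
    return(NA_character_)
  }
  groups[which.max(areas)]
}

#' Write polygons as GeoJSON
#'
#' @param sites a `site_set` or list of polygon matrices.
#' @param path output path.
#' @param properties optional data.frame of per-polygon properties.
#' @export
write_geojson <- function(sites, path, properties = NULL) {
  polys <- if (inherits(sites, "site_set")) sites$polygons else sites
  if (inherits(sites, "site_set") && is.null(properties)) {
    properties <- data.frame(site_id = sites$site_id, group = sites$group,
                             stringsAsFactors = FALSE)
  }
  feats <- lapply(seq_along(polys), function(i) {
    ring <- rbind(polys[[i]], polys[[i]][1L, , drop = FALSE])
    list(
      type = "Feature",
      properties = if (is.null(properties)) structure(list(), names = character()) else as.list(properties[i, , drop = FALSE]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(k) ring[k, ])))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#' @param path GeoJSON file with Polygon features.
#' @return a `site_set`; `site_id`/`group` read from feature properties when present.
#' @export
read_geojson_sites <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    m[-nrow(m), , drop = FALSE]  # drop closing vertex
  })
  ids <- vapply(feats, function(f) as.character(f$properties$site_id %||% NA), character(1))
  grp <- vapply(feats, function(f) as.character(f$properties$group %||% NA), character(1))
  site_set(polys,
           site_id = if (all(is.na(ids))) NULL else ids,
           group = if (all(is.na(grp))) NULL else grp)
}
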