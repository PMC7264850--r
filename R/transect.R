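#' @importFrom grDevices contourLines
#' @importFrom stats predict median
NULL

EARTH_RADIUS_M <- 6371000

#' Project geographic coordinates to a local planar frame
#'
#' Local equirectangular projection about the centroid:
#' \eqn{x = R \Delta\lambda \cos\bar\phi}, \eqn{y = R \Delta\phi}
#' (radians, R = 6,371,000 m) -- adequate over the few-kilometer extents a
#' hybrid zone spans. Input already carrying planar \code{x}/\code{y}
#' columns passes through unchanged.
#'
#' @param coords data.frame with either \code{lon}/\code{lat} (degrees) or
#'   \code{x}/\code{y} (m) columns; other columns are preserved.
#' @return the same data.frame with planar \code{x}, \code{y} columns (m)
#'   and, for geographic input, the projection origin recorded in
#'   attributes \code{"origin"} (lon, lat) so the map is invertible.
#' @export
projectCoordinates <- function(coords) {
  geo <- all(c("lon", "lat") %in% names(coords))
  planar <- all(c("x", "y") %in% names(coords))
  if (geo && planar)
    stop("coordinates carry both geographic and planar columns; supply one")
  if (planar) return(coords)
  if (!geo) stop("need lon/lat or x/y columns")
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("latitudes must lie in [-90, 90] and longitudes in [-180, 180]")
  lon0 <- mean(coords$lon)
  lat0 <- mean(coords$lat)
  coords$x <- EARTH_RADIUS_M * (coords$lon - lon0) * pi / 180 *
    cos(lat0 * pi / 180)
  coords$y <- EARTH_RADIUS_M * (coords$lat - lat0) * pi / 180
  attr(coords, "origin") <- c(lon = lon0, lat = lat0)
  coords
}

#' Estimate the zone-center contour from hybrid-index values
#'
#' Interpolates the hybrid index over a regular grid with a thin-plate
#' regression spline and extracts the iso-contour at \code{level} by
#' marching squares, returning the longest connected polyline -- the
#' estimated center of the hybrid zone.
#'
#' @param x,y planar tree coordinates (m).
#' @param q hybrid-index values in [0, 1].
#' @param gridResolution grid spacing (m).
#' @param level iso-level to trace (default 0.5).
#' @param k basis dimension of the thin-plate spline (default
#'   \code{min(100, n - 1)}); larger follows the surface more closely.
#' @return a [ContourLine-class].
#' @export
estimateContour <- function(x, y, q, gridResolution, level = 0.5, k = NULL) {
  ok <- is.finite(x) & is.finite(y) & is.finite(q)
  x <- x[ok]; y <- y[ok]; q <- q[ok]
  if (length(x) < 10L) stop("need at least 10 trees with hybrid-index values")
  if (gridResolution <= 0) stop("gridResolution must be > 0")
  if (sum(q > level) < 1L || sum(q < level) < 1L)
    stop("no contour found: hybrid index does not cross the requested level")
  if (is.null(k)) k <- min(100L, length(x) - 1L)
  dat <- data.frame(x = x, y = y, q = q)
  fit <- mgcv::gam(q ~ s(x, y, bs = "tp", k = k), data = dat, method = "REML")
  gx <- seq(min(x), max(x), by = gridResolution)
  gy <- seq(min(y), max(y), by = gridResolution)
  if (length(gx) < 2L || length(gy) < 2L)
    stop("gridResolution too coarse for the sampled extent")
  surf <- matrix(predict(fit, expand.grid(x = gx, y = gy)),
                 nrow = length(gx))
  lines <- contourLines(gx, gy, surf, levels = level)
  if (!length(lines)) stop("no contour found: interpolated surface does not cross the level")
  lens <- vapply(lines, function(l) {
    sum(sqrt(diff(l$x)^2 + diff(l$y)^2))
  }, 0)
  best <- lines[[which.max(lens)]]
  new("ContourLine", vertices = cbind(x = best$x, y = best$y),
      gridResolution = gridResolution,
      interpolation = "thin-plate regression spline", level = level)
}

setMethod("contourVertices", "ContourLine", function(x) x@vertices)

setMethod("show", "ContourLine", function(object) {
  v <- object@vertices
  cat(sprintf("ContourLine at level %.3g: %d vertices, length %.1f m (%s, grid %.0f m)\n",
              object@level, nrow(v),
              sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)),
              object@interpolation, object@gridResolution))
  invisible(object)
})

# squared point-to-segment distances for a set of points against one segment
.segDist2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx * vx + vy * vy
  t <- if (L2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
       else rep(0, length(px))
  dx <- px - (ax + t * vx)
  dy <- py - (ay + t * vy)
  list(d2 = dx * dx + dy * dy, t = t)
}

# nearest-segment index and distance per point; also the side (sign of the
# cross product along the nearest segment)
.nearestOnPolyline <- function(px, py, verts) {
  n <- nrow(verts) - 1L
  best <- rep(Inf, length(px))
  seg <- integer(length(px))
  for (i in seq_len(n)) {
    r <- .segDist2(px, py, verts[i, 1], verts[i, 2],
                   verts[i + 1, 1], verts[i + 1, 2])
    upd <- r$d2 < best
    best[upd] <- r$d2[upd]
    seg[upd] <- i
  }
  cross <- numeric(length(px))
  for (i in unique(seg)) {
    idx <- seg == i
    cross[idx] <- (verts[i + 1, 1] - verts[i, 1]) * (py[idx] - verts[i, 2]) -
      (verts[i + 1, 2] - verts[i, 2]) * (px[idx] - verts[i, 1])
  }
  list(dist = sqrt(best), side = sign(cross))
}

#' Signed distance from trees to the zone-center contour
#'
#' The magnitude is the minimum Euclidean distance from each point to the
#' contour polyline; the sign is negative for points lying on the same side
#' as \code{negativeSideReference} (conventionally the centroid of the
#' western parental pool, so the western taxon gets negative distances).
#'
#' @param x,y planar point coordinates (m); vectors.
#' @param contour a [ContourLine-class] or a two-column vertex matrix.
#' @param negativeSideReference length-2 planar point defining the negative
#'   side.
#' @return numeric vector of signed distances (m).
#' @export
signedDistance <- function(x, y, contour, negativeSideReference) {
  verts <- if (is(contour, "ContourLine")) contour@vertices else as.matrix(contour)
  if (nrow(verts) < 2L) stop("degenerate contour: need at least 2 vertices")
  if (all(.segLengths(verts) == 0)) stop("degenerate zero-length contour")
  r <- .nearestOnPolyline(x, y, verts)
  ref <- .nearestOnPolyline(negativeSideReference[1], negativeSideReference[2],
                            verts)
  if (ref$side == 0) stop("negativeSideReference lies on the contour")
  s <- ifelse(r$side == 0, 0, ifelse(r$side == ref$side, -1, 1))
  s * r$dist
}

.segLengths <- function(verts) {
  sqrt(diff(verts[, 1])^2 + diff(verts[, 2])^2)
}

#' Group trees into transect bins
#'
#' Bin edges sit at multiples of \code{binWidth} from the minimum distance.
#' Bins holding fewer than \code{minPerBin} trees are collapsed iteratively:
#' the under-filled bin closest to distance zero merges with whichever
#' adjacent bin has its center nearer zero (ties go to the smaller
#' neighbor), until every bin satisfies the minimum. Each bin's distance is
#' the mean distance of its member trees.
#'
#' @param distance signed transect distances (m).
#' @param ids tree identifiers (default sequential).
#' @param binWidth bin spacing in meters (default 250).
#' @param minPerBin minimum trees per bin (default 3).
#' @return data.frame with one row per tree: \code{id}, \code{distance},
#'   \code{bin} (integer label ordered by distance); summarized per-bin
#'   table in attribute \code{"bins"} (\code{bin}, \code{meanDistance},
#'   \code{nTrees}).
#' @export
makeBins <- function(distance, ids = seq_along(distance), binWidth = 250,
                     minPerBin = 3L) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (minPerBin < 1L) stop("minPerBin must be >= 1")
  ok <- is.finite(distance)
  distance <- distance[ok]
  ids <- ids[ok]
  if (length(distance) < minPerBin)
    stop("fewer trees than minPerBin in total")
  d0 <- min(distance)
  edges <- seq(d0, max(distance) + binWidth, by = binWidth)
  grp <- findInterval(distance, edges, rightmost.closed = TRUE)
  # current partition as a list of index vectors, ordered along the transect
  parts <- split(seq_along(distance), grp)
  repeat {
    counts <- lengths(parts)
    centers <- vapply(parts, function(i) mean(distance[i]), 0)
    under <- which(counts < minPerBin)
    if (!length(under) || length(parts) == 1L) break
    u <- under[which.min(abs(centers[under]))]
    nb <- c(if (u > 1L) u - 1L, if (u < length(parts)) u + 1L)
    if (length(nb) == 2L) {
      da <- abs(centers[nb])
      nb <- if (da[1] < da[2]) nb[1]
            else if (da[2] < da[1]) nb[2]
            else nb[which.min(counts[nb])]
    }
    parts[[nb]] <- sort(c(parts[[nb]], parts[[u]]))
    parts[[u]] <- NULL
  }
  centers <- vapply(parts, function(i) mean(distance[i]), 0)
  ord <- order(centers)
  parts <- parts[ord]
  binOf <- integer(length(distance))
  for (b in seq_along(parts)) binOf[parts[[b]]] <- b
  out <- data.frame(id = ids, distance = distance, bin = binOf,
                    stringsAsFactors = FALSE)
  attr(out, "bins") <- data.frame(
    bin = seq_along(parts),
    meanDistance = vapply(parts, function(i) mean(distance[i]), 0),
    nTrees = lengths(parts)
  )
  out
}
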