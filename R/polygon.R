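# Polygon primitives: area, orientation, simplification, signed distance,
# simplicity check, IoU. Polygons are n x 2 matrices in µm, implicitly
# closed (first vertex not repeated).

#' Shoelace (signed) area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly n x 2 coordinate matrix, implicitly closed.
#' @return signed area.
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

# Reorient to counter-clockwise (interior on the left of the boundary walk).
orient_ccw <- function(poly) {
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

# Douglas-Peucker polyline simplification on the closed polygon; eps in µm.
simplify_polygon <- function(poly, eps) {
  if (eps <= 0 || nrow(poly) <= 4) return(poly)
  # split the ring at the two mutually most distant vertices, simplify both
  # open chains, and rejoin
  d0 <- (poly[, 1] - poly[1, 1])^2 + (poly[, 2] - poly[1, 2])^2
  a <- which.max(d0)
  p1 <- dp_chain(poly[1:a, , drop = FALSE], eps)
  p2 <- dp_chain(rbind(poly[a:nrow(poly), , drop = FALSE], poly[1, , drop = FALSE]), eps)
  out <- rbind(p1, p2[-c(1, nrow(p2)), , drop = FALSE])
  if (nrow(out) < 3) poly else out
}

# Douglas-Peucker on an open chain (keeps endpoints).
dp_chain <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    dx <- pts[j, 1] - pts[i, 1]; dy <- pts[j, 2] - pts[i, 2]
    L <- sqrt(dx^2 + dy^2)
    mid <- (i + 1):(j - 1)
    d <- if (L == 0) {
      sqrt((pts[mid, 1] - pts[i, 1])^2 + (pts[mid, 2] - pts[i, 2])^2)
    } else {
      abs(dx * (pts[i, 2] - pts[mid, 2]) - (pts[i, 1] - pts[mid, 1]) * dy) / L
    }
    k <- mid[which.max(d)]
    if (max(d) > eps) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# Minimum distance from points to the polygon boundary (unsigned).
point_boundary_distance <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nxt <- c(2:n, 1)
  x2 <- poly[nxt, 1]; y2 <- poly[nxt, 2]
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    dx <- x2[i] - x1[i]; dy <- y2[i] - y1[i]
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - x1[i]) * dx + (py - y1[i]) * dy) / L2))
    qx <- x1[i] + t * dx; qy <- y1[i] + t * dy
    d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
  }
  sqrt(d2)
}

#' Signed distance from points to a closed borderline
#'
#' Positive inside the polygon (tumor side), negative outside, zero on the
#' boundary.
#'
#' @param px,py point coordinates in µm.
#' @param poly n x 2 polygon matrix, implicitly closed.
#' @return numeric vector of signed distances.
#' @export
signed_distance <- function(px, py, poly) {
  d <- point_boundary_distance(px, py, poly)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  ifelse(d == 0, 0, ifelse(inside, d, -d))
}

# TRUE when no two non-adjacent edges intersect.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  a1 <- poly; a2 <- poly[nxt, , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]      # skip edges sharing a vertex
    if (!length(js)) next
    if (any(segments_intersect(a1[i, ], a2[i, ], a1[js, , drop = FALSE],
                               a2[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

# Vectorized proper/improper segment intersection of (p1,p2) vs rows of (q1,q2).
segments_intersect <- function(p1, p2, q1, q2) {
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p1[1], p1[2])
  d2 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p2[1], p2[2])
  d3 <- cross(p1[1], p1[2], p2[1], p2[2], q1[, 1], q1[, 2])
  d4 <- cross(p1[1], p1[2], p2[1], p2[2], q2[, 1], q2[, 2])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Intersection-over-union of two polygons by grid sampling
#'
#' @param poly_a,poly_b n x 2 polygon matrices, implicitly closed.
#' @param resolution_um sampling grid step in µm.
#' @return IoU in `[0, 1]`.
#' @export
polygon_iou <- function(poly_a, poly_b, resolution_um = 20) {
  xr <- range(poly_a[, 1], poly_b[, 1])
  yr <- range(poly_a[, 2], poly_b[, 2])
  gx <- seq(xr[1] + resolution_um / 2, xr[2], by = resolution_um)
  gy <- seq(yr[1] + resolution_um / 2, yr[2], by = resolution_um)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  in_a <- mgcv::in.out(rbind(poly_a, poly_a[1, ]), pts)
  in_b <- mgcv::in.out(rbind(poly_b, poly_b[1, ]), pts)
  u <- sum(in_a | in_b)
  if (u == 0) return(0)
  sum(in_a & in_b) / u
}
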