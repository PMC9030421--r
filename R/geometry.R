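# Internal planar geometry. Points are (x, y) with x = column index and
# y = row index of the source raster; pixel centres sit at integer
# coordinates. All routines are deterministic.

# Closed polyline length through vertices in order.
polyline_length <- function(x, y) {
  if (length(x) < 2) return(0)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

# Signed shoelace area; positive for counter-clockwise vertex order in the
# (x, y) frame as given. With y = image row (pointing down), positive
# therefore means clockwise on paper.
shoelace_signed <- function(x, y) {
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

shoelace_area <- function(x, y) abs(shoelace_signed(x, y))

# Convex hull as a counter-clockwise (paper orientation) vertex matrix of
# strict corners: chull() may keep vertices lying inside a hull edge, and a
# collinear run stalls the rotating-calipers advance, so those are pruned
# (perimeter, area and farthest pairs are unchanged by the pruning).
# Degenerate inputs (all collinear) return the hull chain as given by chull.
convex_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1) return(pts)
  if (nrow(pts) == 2) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  h <- nrow(hull)
  if (h >= 3) {
    prv <- c(h, seq_len(h - 1))
    nx <- c(2:h, 1)
    cross <- (hull[, 1] - hull[prv, 1]) * (hull[nx, 2] - hull[, 2]) -
      (hull[nx, 1] - hull[, 1]) * (hull[, 2] - hull[prv, 2])
    keep <- cross != 0
    if (any(keep)) hull <- hull[keep, , drop = FALSE]
  }
  # enforce counter-clockwise on paper: negative signed area in image coords
  if (nrow(hull) >= 3 && shoelace_signed(hull[, 1], hull[, 2]) > 0) {
    hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  }
  hull
}

# Maximum caliper distance (Feret diameter) of a convex polygon via rotating
# calipers over antipodal vertex pairs. Returns the distance and the two
# endpoints. `hull` must be a convex polygon vertex matrix (either
# orientation; orientation is normalised internally).
feret_calipers <- function(hull) {
  h <- nrow(hull)
  if (h == 1) {
    return(list(feret = 0, p = hull[1, ], q = hull[1, ]))
  }
  if (h == 2) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(list(feret = d, p = hull[1, ], q = hull[2, ]))
  }
  if (shoelace_signed(hull[, 1], hull[, 2]) > 0) {
    hull <- hull[rev(seq_len(h)), , drop = FALSE]
  }
  x <- hull[, 1]
  y <- hull[, 2]
  nxt <- function(i) if (i == h) 1L else i + 1L
  # twice the triangle area spanned by vertices a, b, c
  tri2 <- function(a, b, c) {
    abs((x[b] - x[a]) * (y[c] - y[a]) - (x[c] - x[a]) * (y[b] - y[a]))
  }
  d2 <- function(a, b) (x[a] - x[b])^2 + (y[a] - y[b])^2
  best <- 0
  bi <- 1L
  bj <- 1L
  consider <- function(a, b) {
    dd <- d2(a, b)
    if (dd > best) {
      best <<- dd
      bi <<- a
      bj <<- b
    }
  }
  j <- 2L
  guard <- 0L
  for (i in seq_len(h)) {
    i2 <- nxt(i)
    # advance the caliper while the support distance to edge (i, i2) grows
    while (tri2(i, i2, nxt(j)) > tri2(i, i2, j) && guard <= 4L * h) {
      j <- nxt(j)
      guard <- guard + 1L
    }
    consider(i, j)
    consider(i2, j)
    # handle parallel-edge ties
    if (tri2(i, i2, nxt(j)) == tri2(i, i2, j)) consider(i, nxt(j))
  }
  list(feret = sqrt(best), p = hull[bi, ], q = hull[bj, ])
}

# Caliper extent of `hull` vertices perpendicular to the direction p -> q.
breadth_perpendicular <- function(hull, p, q) {
  u <- q - p
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(0)
  v <- c(-u[2], u[1]) / nu
  proj <- hull[, 1] * v[1] + hull[, 2] * v[2]
  max(proj) - min(proj)
}

# --- minimal enclosing circle (Welzl's algorithm) ------------------------

circle_from2 <- function(p, q) {
  c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
}

circle_from3 <- function(p, q, r) {
  d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
  if (abs(d) < 1e-12) {
    # collinear: widest pair as diameter
    cands <- list(circle_from2(p, q), circle_from2(p, r), circle_from2(q, r))
    return(cands[[which.max(vapply(cands, function(z) z[3], 0))]])
  }
  p2 <- sum(p^2)
  q2 <- sum(q^2)
  r2 <- sum(r^2)
  ux <- (p2 * (q[2] - r[2]) + q2 * (r[2] - p[2]) + r2 * (p[2] - q[2])) / d
  uy <- (p2 * (r[1] - q[1]) + q2 * (p[1] - r[1]) + r2 * (q[1] - p[1])) / d
  c(ux, uy, sqrt((p[1] - ux)^2 + (p[2] - uy)^2))
}

circle_trivial <- function(R) {
  n <- nrow(R)
  if (n == 0) return(c(0, 0, -1))
  if (n == 1) return(c(R[1, ], 0))
  if (n == 2) return(circle_from2(R[1, ], R[2, ]))
  circle_from3(R[1, ], R[2, ], R[3, ])
}

in_circle <- function(circ, p, tol = 1e-10) {
  circ[3] >= 0 &&
    sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] + tol * (1 + circ[3])
}

welzl_rec <- function(P, R) {
  if (nrow(P) == 0 || nrow(R) == 3) return(circle_trivial(R))
  p <- P[1, ]
  D <- welzl_rec(P[-1, , drop = FALSE], R)
  if (in_circle(D, p)) return(D)
  welzl_rec(P[-1, , drop = FALSE], rbind(R, p))
}

# Minimal enclosing circle of a point set; returns c(cx, cy, radius).
# The input order is scrambled by a fixed pseudo-random key so that points
# in convex position (the common case here: hull vertices) do not trigger
# Welzl's worst case; the scramble is deterministic.
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 0) stop("empty point set")
  if (n > 2) {
    key <- sin(seq_len(n) * 12.9898 + 78.233) * 43758.5453
    pts <- pts[order(key - floor(key)), , drop = FALSE]
  }
  welzl_rec(pts, matrix(numeric(0), 0, 2))
}
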