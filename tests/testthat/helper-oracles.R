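# Independent oracles for the geometry and classification tests. These
# share no code with the package internals: rasterization is a direct
# inside test, boundaries come from a 4-neighbour background test plus
# angular sorting (convex shapes only), Feret is an exhaustive pairwise
# maximum, the minimal enclosing circle an exhaustive pair/triple search,
# and Wilks' lambda a direct determinant ratio.

# rasterize a continuous inside test on the integer lattice [-half, half]^2
oracle_rasterize <- function(inside, half) {
  xs <- -half:half
  g <- expand.grid(y = xs, x = xs)
  matrix(inside(g$x, g$y), nrow = length(xs))
}

oracle_disk <- function(r, half = ceiling(r) + 3) {
  oracle_rasterize(function(x, y) x^2 + y^2 <= r^2, half)
}

oracle_ellipse <- function(a, b, angle = 0, half = ceiling(a) + 3) {
  oracle_rasterize(function(x, y) {
    xr <- x * cos(angle) + y * sin(angle)
    yr <- -x * sin(angle) + y * cos(angle)
    (xr / a)^2 + (yr / b)^2 <= 1
  }, half)
}

oracle_rect <- function(w, h, angle = 0, half = ceiling(sqrt(w^2 + h^2) / 2) + 3) {
  oracle_rasterize(function(x, y) {
    xr <- x * cos(angle) + y * sin(angle)
    yr <- -x * sin(angle) + y * cos(angle)
    abs(xr) <= w / 2 & abs(yr) <= h / 2
  }, half)
}

# 0-based (row, col) foreground pixels having a background 4-neighbour
# (or lying on the matrix edge)
oracle_boundary4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  fg <- which(m, arr.ind = TRUE)
  i <- fg[, 1] + 1L; j <- fg[, 2] + 1L
  bnd <- !(pad[cbind(i - 1, j)] & pad[cbind(i + 1, j)] &
             pad[cbind(i, j - 1)] & pad[cbind(i, j + 1)])
  fg[bnd, , drop = FALSE] - 1L
}

# as above with an 8-neighbour background test
oracle_boundary8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  fg <- which(m, arr.ind = TRUE)
  i <- fg[, 1] + 1L; j <- fg[, 2] + 1L
  all8 <- pad[cbind(i - 1, j)] & pad[cbind(i + 1, j)] &
    pad[cbind(i, j - 1)] & pad[cbind(i, j + 1)] &
    pad[cbind(i - 1, j - 1)] & pad[cbind(i - 1, j + 1)] &
    pad[cbind(i + 1, j - 1)] & pad[cbind(i + 1, j + 1)]
  fg[!all8, , drop = FALSE] - 1L
}

# exhaustive maximum pairwise distance over a (row, col) point matrix
oracle_feret <- function(pts) {
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

# exhaustive minimal enclosing circle over all pair and triple candidates;
# pts is an (x, y) matrix with <= ~60 rows
oracle_mec_radius <- function(pts, tol = 1e-7) {
  n <- nrow(pts)
  if (n == 1) return(0)
  cand <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cand[[length(cand) + 1]] <- c((pts[i, ] + pts[j, ]) / 2,
                                    sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          p <- pts[i, ]; q <- pts[j, ]; r <- pts[k, ]
          d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
          if (abs(d) < 1e-12) next
          p2 <- sum(p^2); q2 <- sum(q^2); r2 <- sum(r^2)
          ux <- (p2 * (q[2] - r[2]) + q2 * (r[2] - p[2]) + r2 * (p[2] - q[2])) / d
          uy <- (p2 * (r[1] - q[1]) + q2 * (p[1] - r[1]) + r2 * (q[1] - p[1])) / d
          cand[[length(cand) + 1]] <- c(ux, uy, sqrt((p[1] - ux)^2 + (p[2] - uy)^2))
        }
      }
    }
  }
  C <- do.call(rbind, cand)
  dx <- outer(C[, 1], pts[, 1], "-")
  dy <- outer(C[, 2], pts[, 2], "-")
  maxd <- sqrt(apply(dx^2 + dy^2, 1, max))
  ok <- maxd <= C[, 3] + tol * (1 + C[, 3])
  min(C[ok, 3])
}

# all 26 descriptors of a convex digitized shape, measured independently:
# boundary by 4-neighbour test, polygon by angular sort around the pixel
# centroid, hull by chull, Feret by brute force, MBC by exhaustive search
oracle_features_convex <- function(m) {
  fg <- which(m, arr.ind = TRUE) - 1L
  cen <- colMeans(fg) # (row, col)
  bp <- oracle_boundary4(m)
  o <- order(atan2(bp[, 1] - cen[1], bp[, 2] - cen[2]))
  y <- bp[o, 1]; x <- bp[o, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  Area <- abs(sum(x * y2 - x2 * y)) / 2
  Perim <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  dcen <- sqrt((y - cen[1])^2 + (x - cen[2])^2)
  hi <- grDevices::chull(x, y)
  hx <- x[hi]; hy <- y[hi]
  hx2 <- c(hx[-1], hx[1]); hy2 <- c(hy[-1], hy[1])
  CHull <- sum(sqrt((hx2 - hx)^2 + (hy2 - hy)^2))
  CArea <- abs(sum(hx * hy2 - hx2 * hy)) / 2
  Feret <- oracle_feret(cbind(hy, hx))
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  u <- c(hx[ij[2]] - hx[ij[1]], hy[ij[2]] - hy[ij[1]])
  v <- c(-u[2], u[1]) / sqrt(sum(u^2))
  proj <- hx * v[1] + hy * v[2]
  Breadth <- max(proj) - min(proj)
  MBCRadius <- oracle_mec_radius(cbind(hx, hy))
  out <- list(
    Perim = Perim, Area = Area, Pixels = nrow(fg),
    MinR = min(dcen), MaxR = max(dcen), Feret = Feret, Breadth = Breadth,
    CHull = CHull, CArea = CArea, MBCRadius = MBCRadius
  )
  out$AspRatio <- Feret / Breadth
  out$Circ <- 4 * pi * Area / Perim^2
  out$Roundness <- 4 * Area / (pi * Feret^2)
  out$ArEquivD <- sqrt(4 / pi * Area)
  out$PerEquivD <- Area / pi
  out$EquivEllAr <- pi * Feret * Breadth / 4
  out$Compactness <- sqrt(4 / pi * Area) / Feret
  out$Solidity <- Area / CArea
  out$Concavity <- CArea - Area
  out$Convexity <- CHull / Perim
  out$Shape <- Perim^2 / Area
  out$RFactor <- CHull / (Feret * pi)
  out$ModRatio <- 2 * out$MinR / Feret
  out$Sphericity <- out$MinR / out$MaxR
  out$ArBBox <- Feret * Breadth
  out$Rectang <- Area / (Feret * Breadth)
  out
}

# Wilks' lambda of a feature subset by direct determinant ratio
oracle_wilks <- function(X, groups, S) {
  if (length(S) == 0) return(1)
  X <- X[, S, drop = FALSE]
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (g in unique(groups)) {
    W <- W + crossprod(scale(X[groups == g, , drop = FALSE], center = TRUE, scale = FALSE))
  }
  det(W) / det(Tm)
}

# best subset of size k by exhaustive Wilks minimisation
oracle_best_subset <- function(X, groups, k) {
  feats <- colnames(X)
  combs <- utils::combn(feats, k, simplify = FALSE)
  lams <- vapply(combs, function(S) oracle_wilks(X, groups, S), 0)
  combs[[which.min(lams)]]
}

# two-class Gaussian feature table: `informative` features shifted by
# delta / sqrt(informative) each (realized Mahalanobis separation ~ delta),
# the rest standard noise; 26 columns named as the descriptor panel
gauss_feature_table <- function(n_per_class = 100, delta = 6, informative = 3,
                                seed = 1) {
  stopifnot(informative <= length(seedmorph::seed_feature_names))
  withr::with_seed(seed, {
    p <- length(seedmorph::seed_feature_names)
    shift <- c(rep(delta / sqrt(informative), informative), rep(0, p - informative))
    XA <- matrix(rnorm(n_per_class * p), n_per_class, p)
    XB <- matrix(rnorm(n_per_class * p), n_per_class, p, byrow = FALSE)
    XB <- sweep(XB, 2, shift, "+")
    X <- rbind(XA, XB)
    colnames(X) <- seedmorph::seed_feature_names
    tab <- tibble::as_tibble(X)
    tab$specimen_id <- sprintf("s%03d", seq_len(2 * n_per_class))
    tab$class_label <- rep(c("A", "B"), each = n_per_class)
    tab[, c("specimen_id", "class_label", seedmorph::seed_feature_names)]
  })
}

# randomized mask suite shared by the property and acceptance tests
random_mask_suite <- function(n, seed = 42) {
  per <- ceiling(n / 4)
  specs <- dplyr::bind_rows(
    seedmorph::shape_class_spec("round", per, size_mean = 25, size_sd = 6,
                                aspect_mean = 0.85, aspect_sd = 0.08,
                                squareness_mean = 2, squareness_sd = 0.2,
                                boundary_noise = 0.02),
    seedmorph::shape_class_spec("elong", per, size_mean = 35, size_sd = 8,
                                aspect_mean = 0.45, aspect_sd = 0.06,
                                squareness_mean = 1.8, squareness_sd = 0.2,
                                boundary_noise = 0.04),
    seedmorph::shape_class_spec("blocky", per, size_mean = 30, size_sd = 6,
                                aspect_mean = 0.7, aspect_sd = 0.08,
                                squareness_mean = 3.5, squareness_sd = 0.5,
                                boundary_noise = 0.03),
    seedmorph::shape_class_spec("rough", per, size_mean = 20, size_sd = 4,
                                aspect_mean = 0.6, aspect_sd = 0.1,
                                squareness_mean = 2.2, squareness_sd = 0.3,
                                boundary_noise = 0.08)
  )
  pop <- seedmorph::sample_population(specs, seed = seed)
  pop[seq_len(min(n, nrow(pop))), , drop = FALSE]
}

# shared lazily-built fixtures (kept across test files within a run)
sm_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(sm_test_cache[[name]])) sm_test_cache[[name]] <- force(expr)
  sm_test_cache[[name]]
}
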