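# Synthetic seed-silhouette populations: labelled multi-class superellipse
# outlines with controlled shape statistics and analytic ground truth, so
# the whole pipeline is testable without physical seed collections.

#' Describe one synthetic shape class
#'
#' A class is a population of superellipse silhouettes
#' `|x/a|^m + |y/b|^m = 1` with truncated-normal parameter scatter and an
#' optional low-order radial Fourier perturbation of the boundary:
#' `r(theta) * (1 + sum_k c_k cos(k theta + phi_k))`, harmonics k = 2..5.
#'
#' @param name class label.
#' @param n number of specimens.
#' @param size_mean,size_sd semi-major axis `a` in px (truncated at 4 px).
#' @param aspect_mean,aspect_sd semi-axis ratio `b/a` in (0, 1].
#' @param squareness_mean,squareness_sd superellipse exponent `m` (2 =
#'   ellipse, larger = blockier; truncated to [1.2, 12]).
#' @param boundary_noise relative amplitude scale of the radial Fourier
#'   perturbation (0 = smooth superellipse).
#' @return a one-row tibble; rows from several calls can be bound together.
#' @export
shape_class_spec <- function(name, n, size_mean, size_sd = 0,
                             aspect_mean = 0.7, aspect_sd = 0,
                             squareness_mean = 2, squareness_sd = 0,
                             boundary_noise = 0) {
  if (n < 1) sm_abort("validation", "n must be >= 1")
  if (size_sd < 0 || aspect_sd < 0 || squareness_sd < 0 || boundary_noise < 0) {
    sm_abort("validation", "spread parameters must be >= 0")
  }
  if (aspect_mean <= 0 || aspect_mean > 1) {
    sm_abort("validation", "aspect_mean must be in (0, 1]")
  }
  if (size_mean < 4) {
    sm_abort("validation", "size_mean below 4 px implies < 3 px shapes")
  }
  tibble::tibble(
    name = name, n = as.integer(n),
    size_mean = size_mean, size_sd = size_sd,
    aspect_mean = aspect_mean, aspect_sd = aspect_sd,
    squareness_mean = squareness_mean, squareness_sd = squareness_sd,
    boundary_noise = boundary_noise
  )
}

#' Three example shape classes
#'
#' Loosely plum-stone-, watermelon-seed- and grape-pip-like populations at
#' 400 dpi scale: semi-major axes of about 11.4, 4.8 and 2.9 mm with
#' per-class aspect, blockiness and boundary-roughness settings.
#'
#' @return a 3-row spec tibble for [sample_population()].
#' @export
example_class_specs <- function() {
  dplyr::bind_rows(
    shape_class_spec("plum", n = 50, size_mean = 180, size_sd = 12,
                     aspect_mean = 0.72, aspect_sd = 0.04,
                     squareness_mean = 2.3, squareness_sd = 0.15,
                     boundary_noise = 0.02),
    shape_class_spec("watermelon", n = 50, size_mean = 75, size_sd = 6,
                     aspect_mean = 0.62, aspect_sd = 0.04,
                     squareness_mean = 2.0, squareness_sd = 0.1,
                     boundary_noise = 0.015),
    shape_class_spec("grape", n = 50, size_mean = 45, size_sd = 4,
                     aspect_mean = 0.55, aspect_sd = 0.05,
                     squareness_mean = 1.7, squareness_sd = 0.1,
                     boundary_noise = 0.03)
  )
}

# truncated-normal draws by inverse-CDF; sd = 0 collapses to the mean
# (clamped into the bounds)
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Radial extent of the (possibly perturbed, rotated) superellipse along
# polar angle theta.
superellipse_radius <- function(theta, a, b, m, rotation = 0,
                                amps = numeric(0), phases = numeric(0)) {
  t2 <- theta - rotation
  base <- (abs(cos(t2) / a)^m + abs(sin(t2) / b)^m)^(-1 / m)
  if (length(amps) > 0) {
    mod <- rep(1, length(theta))
    for (k in seq_along(amps)) {
      mod <- mod + amps[k] * cos((k + 1) * t2 + phases[k])
    }
    base <- base * pmax(mod, 0.05)
  }
  base
}

# Rasterize one silhouette to a tight logical matrix (pixel centre inside
# the boundary, closed inequality).
rasterize_silhouette <- function(a, b, m, rotation = 0, amps = numeric(0),
                                 phases = numeric(0)) {
  if (b < 1.5 || a < 1.5) {
    sm_abort("validation", "shape parameters imply a silhouette under 3 px")
  }
  half <- ceiling(a * (1 + sum(abs(amps))) + 2)
  xs <- -half:half
  cx <- matrix(xs, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  cy <- matrix(xs, 2 * half + 1, 2 * half + 1)
  rho <- sqrt(cx^2 + cy^2)
  theta <- atan2(cy, cx)
  rad <- superellipse_radius(theta, a, b, m, rotation, amps, phases)
  # closed inequality with a relative epsilon so pixels exactly on the
  # continuous boundary are included regardless of rounding direction
  mask <- rho <= rad * (1 + 1e-9) + 1e-9
  keep_r <- which(rowSums(mask) > 0)
  keep_c <- which(colSums(mask) > 0)
  if (length(keep_r) == 0 || max(rowSums(mask)) < 2) {
    sm_abort("validation", "shape parameters imply a silhouette under 3 px")
  }
  mask[min(keep_r):max(keep_r), min(keep_c):max(keep_c), drop = FALSE]
}

#' Sample a labelled synthetic seed population
#'
#' Draws per-specimen shape parameters from each class specification
#' (truncated normals), a uniform rotation and random Fourier boundary
#' phases, and rasterizes every silhouette to a binary mask at pixel-centre
#' sampling. Regeneration with the same seed is bit-identical; the calling
#' session's RNG state is left untouched.
#'
#' @param specs spec tibble ([shape_class_spec()] rows).
#' @param dpi nominal resolution recorded with the population.
#' @param seed integer RNG seed (required).
#' @return a `seed_population` tibble: `specimen_id`, `class_label`, `mask`
#'   list-column, and the generating truth (`a`, `b`, `aspect`,
#'   `squareness`, `rotation`, `amp2..amp5`, `phase2..phase5`); attributes
#'   `dpi` and `seed`.
#' @export
sample_population <- function(specs, dpi = 400, seed) {
  if (missing(seed)) sm_abort("validation", "sample_population requires a seed")
  if (nrow(specs) < 1) sm_abort("validation", "need at least one class spec")
  with_local_seed(seed, {
    out <- vector("list", nrow(specs))
    for (si in seq_len(nrow(specs))) {
      sp <- specs[si, ]
      n <- sp$n
      a <- rtruncnorm1(n, sp$size_mean, sp$size_sd, lo = 4)
      aspect <- rtruncnorm1(n, sp$aspect_mean, sp$aspect_sd, lo = 0.05, hi = 1)
      m <- rtruncnorm1(n, sp$squareness_mean, sp$squareness_sd, lo = 1.2, hi = 12)
      rot <- stats::runif(n, 0, pi)
      amps <- matrix(stats::rnorm(4 * n, 0, sp$boundary_noise / 2), n, 4)
      # keep the outline star-shaped and positive
      amps <- pmin(pmax(amps, -0.12), 0.12)
      phases <- matrix(stats::runif(4 * n, 0, 2 * pi), n, 4)
      masks <- vector("list", n)
      for (i in seq_len(n)) {
        masks[[i]] <- rasterize_silhouette(a[i], a[i] * aspect[i], m[i], rot[i],
                                           amps[i, ], phases[i, ])
      }
      out[[si]] <- tibble::tibble(
        specimen_id = sprintf("%s_%03d", sp$name, seq_len(n)),
        class_label = sp$name,
        mask = masks,
        a = a, b = a * aspect, aspect = aspect, squareness = m, rotation = rot,
        amp2 = amps[, 1], amp3 = amps[, 2], amp4 = amps[, 3], amp5 = amps[, 4],
        phase2 = phases[, 1], phase3 = phases[, 2], phase4 = phases[, 3],
        phase5 = phases[, 4]
      )
    }
    pop <- dplyr::bind_rows(out)
    attr(pop, "dpi") <- dpi
    attr(pop, "seed") <- seed
    class(pop) <- c("seed_population", class(pop))
    pop
  })
}

#' Render a population onto a synthetic scanner image
#'
#' Places the masks on a regular grid with at least `spacing` pixels
#' between bounding boxes, paints seed and background grey levels with a
#' small per-specimen jitter, adds mild Gaussian pixel noise, and returns
#' the image together with the placement truth. White background:
#' background about 245/255, seeds about 60/255; black background is the
#' inverse.
#'
#' @param population a `seed_population` (or any tibble with a `mask`
#'   list-column and `specimen_id`).
#' @param ncol,nrow grid shape; defaults to a near-square grid.
#' @param spacing minimum clearance between mask bounding boxes, px
#'   (must be >= 1).
#' @param background_mode `"white"` or `"black"`.
#' @param noise_sd Gaussian pixel-noise standard deviation on [0, 1].
#' @param jitter half-range of the per-specimen foreground level jitter on
#'   [0, 1].
#' @param seed RNG seed for the grey-level jitter and noise.
#' @return a list: `scan` (a [seed_scan()]), `placement` (tibble of
#'   specimen_id, offset_row, offset_col).
#' @export
render_scan <- function(population, ncol = NULL, nrow = NULL, spacing = 10,
                        background_mode = c("white", "black"),
                        noise_sd = 2 / 255, jitter = 6 / 255, seed = 1) {
  background_mode <- match.arg(background_mode)
  n <- length(population$mask)
  if (n == 0) sm_abort("validation", "empty population")
  if (spacing < 1) {
    sm_abort("validation", "spacing %g cannot guarantee non-overlapping placement", spacing)
  }
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  if (is.null(nrow)) nrow <- ceiling(n / ncol)
  if (nrow * ncol < n) {
    sm_abort("validation", "grid %d x %d cannot hold %d seeds", nrow, ncol, n)
  }
  hs <- vapply(population$mask, nrow, 0L)
  ws <- vapply(population$mask, ncol, 0L)
  cell_h <- max(hs) + spacing
  cell_w <- max(ws) + spacing
  H <- nrow * cell_h + spacing
  W <- ncol * cell_w + spacing
  bg <- if (background_mode == "white") 245 / 255 else 10 / 255
  fg <- if (background_mode == "white") 60 / 255 else 195 / 255
  with_local_seed(seed, {
    img <- matrix(bg, H, W)
    off_r <- integer(n)
    off_c <- integer(n)
    for (i in seq_len(n)) {
      gr <- (i - 1) %/% ncol
      gc <- (i - 1) %% ncol
      r0 <- spacing + gr * cell_h + (cell_h - spacing - hs[i]) %/% 2 + 1L
      c0 <- spacing + gc * cell_w + (cell_w - spacing - ws[i]) %/% 2 + 1L
      lev <- fg + stats::runif(1, -jitter, jitter)
      sub <- img[r0:(r0 + hs[i] - 1), c0:(c0 + ws[i] - 1)]
      sub[population$mask[[i]]] <- lev
      img[r0:(r0 + hs[i] - 1), c0:(c0 + ws[i] - 1)] <- sub
      off_r[i] <- r0 - 1L
      off_c[i] <- c0 - 1L
    }
    img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(
      scan = seed_scan(img, dpi = attr(population, "dpi") %||% 400,
                       background_mode = background_mode,
                       source_id = sprintf("synthetic_%s", background_mode)),
      placement = tibble::tibble(
        specimen_id = population$specimen_id %||% sprintf("specimen_%03d", seq_len(n)),
        offset_row = off_r, offset_col = off_c
      )
    )
  })
}

#' Analytic descriptor values for a noise-free superellipse
#'
#' Ground-truth `Area`, `Feret`, `Breadth`, `AspRatio`, `Roundness` and
#' `Rectang` for the continuous superellipse `|x/a|^m + |y/b|^m = 1`,
#' independent of the raster pipeline: the ellipse (`m = 2`) and rectangle
#' (`m = Inf`) limits use closed forms, intermediate exponents a dense
#' parametric quadrature of the boundary (shoelace area, caliper search on
#' the convex outline).
#'
#' @param a,b semi-axes (a >= b > 0).
#' @param squareness exponent `m >= 1` (Inf for the rectangle limit).
#' @param boundary_noise must be 0; the analytic oracle does not cover
#'   perturbed outlines.
#' @param n_quad quadrature points along the boundary.
#' @return one-row tibble of the six expected descriptor values.
#' @export
analytic_features <- function(a, b, squareness = 2, boundary_noise = 0,
                              n_quad = 8192) {
  if (boundary_noise != 0) {
    sm_abort("validation", "analytic_features supports only boundary_noise = 0")
  }
  if (a <= 0 || b <= 0 || b > a) sm_abort("validation", "need a >= b > 0")
  m <- squareness
  if (is.infinite(m)) {
    area <- 4 * a * b
    feret <- 2 * sqrt(a^2 + b^2)
    breadth <- 4 * a * b / sqrt(a^2 + b^2)
  } else if (m == 2) {
    area <- pi * a * b
    feret <- 2 * a
    breadth <- 2 * b
  } else {
    t <- seq(0, 2 * pi, length.out = n_quad + 1)[-(n_quad + 1)]
    x <- a * sign(cos(t)) * abs(cos(t))^(2 / m)
    y <- b * sign(sin(t)) * abs(sin(t))^(2 / m)
    area <- shoelace_area(x, y)
    hi <- grDevices::chull(x, y)
    hx <- x[hi]
    hy <- y[hi]
    d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
    feret <- sqrt(max(d2))
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    u <- c(hx[ij[2]] - hx[ij[1]], hy[ij[2]] - hy[ij[1]])
    v <- c(-u[2], u[1]) / sqrt(sum(u^2))
    proj <- hx * v[1] + hy * v[2]
    breadth <- max(proj) - min(proj)
  }
  tibble::tibble(
    Area = area, Feret = feret, Breadth = breadth,
    AspRatio = feret / breadth,
    Roundness = 4 * area / (pi * feret^2),
    Rectang = area / (feret * breadth)
  )
}
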