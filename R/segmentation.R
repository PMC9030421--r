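# Segmentation of flatbed-scanner seed images into per-specimen silhouettes.

#' Load a scanned seed image
#'
#' Reads a PNG/TIFF raster, converts colour images to grayscale by luminance,
#' and attaches the acquisition metadata (resolution, background polarity)
#' needed downstream.
#'
#' @param path path to a PNG or TIFF file.
#' @param dpi scan resolution in dots per inch; must be positive. Flatbed
#'   seed scans are typically acquired at 400 dpi.
#' @param background_mode `"white"` (seeds darker than the background) or
#'   `"black"` (seeds lighter).
#' @param source_id identifier recorded on every specimen cut from this scan;
#'   defaults to the file name without extension.
#' @return a `seed_scan` object: intensity matrix in `[0, 1]` (rows = image
#'   rows) plus `dpi`, `background_mode` and `source_id`.
#' @seealso [segment_seeds()]
#' @export
load_scan <- function(path, dpi = 400, background_mode = c("white", "black"),
                      source_id = NULL) {
  background_mode <- match.arg(background_mode)
  if (!is.numeric(dpi) || length(dpi) != 1 || !is.finite(dpi) || dpi <= 0) {
    sm_abort("validation", "dpi must be a single positive number, got %s", format(dpi))
  }
  if (!file.exists(path)) {
    sm_abort("io", "cannot read image: file does not exist: %s", path)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) sm_abort("io", "cannot decode image %s: %s", path, conditionMessage(e))
  )
  if (EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, "luminance")
  }
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2) px <- px[, , 1]
  px <- t(px) # EBImage stores x-major; we use rows = image rows
  px[px < 0] <- 0
  px[px > 1] <- 1
  if (nrow(px) < 2 || ncol(px) < 2) {
    sm_abort("validation", "image %s is smaller than 2 x 2 pixels", path)
  }
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  seed_scan(px, dpi = dpi, background_mode = background_mode, source_id = source_id)
}

#' Construct a seed scan from an intensity matrix
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`, rows = image rows.
#' @inheritParams load_scan
#' @return a `seed_scan` object.
#' @export
seed_scan <- function(pixels, dpi = 400, background_mode = c("white", "black"),
                      source_id = "scan") {
  background_mode <- match.arg(background_mode)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    sm_abort("validation", "a seed_scan needs at least 2 x 2 pixels")
  }
  if (dpi <= 0) sm_abort("validation", "dpi must be positive")
  structure(
    list(pixels = pixels, dpi = dpi, background_mode = background_mode,
         source_id = source_id),
    class = "seed_scan"
  )
}

#' @export
print.seed_scan <- function(x, ...) {
  cat(sprintf("<seed_scan '%s': %d x %d px, %g dpi, %s background>\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$dpi,
              x$background_mode))
  invisible(x)
}

# Merge 4-connected labels that touch diagonally, yielding the 8-connected
# labelling convention used for particle analysis (8-connected foreground,
# 4-connected background).
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1])
      b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Segment a scan into per-specimen seed masks
#'
#' Chooses a global threshold automatically (Otsu's bimodal-histogram
#' criterion), inverts polarity on white backgrounds so that foreground =
#' seed, labels 8-connected components, fills interior holes, and drops
#' components below `min_area_px` (scanner speckle) or touching the image
#' border (clipped specimens) when requested. Touching seeds are not split;
#' they come back as one merged mask.
#'
#' @param scan a `seed_scan` from [load_scan()] or [seed_scan()].
#' @param min_area_px minimum foreground pixel count for a component to be
#'   kept.
#' @param exclude_border drop components touching the image border?
#' @return a tibble with one row per specimen, ordered top-to-bottom then
#'   left-to-right by centroid: `specimen_id`, `source_id`, `area_px`,
#'   `offset_row`, `offset_col` (0-based origin of the cropped mask),
#'   `centroid_row`, `centroid_col`, and a `mask` list-column of logical
#'   matrices. The Otsu threshold is attached as attribute `threshold`.
#'   An empty (0-row) tibble with a warning if nothing survives filtering.
#' @export
segment_seeds <- function(scan, min_area_px = 100, exclude_border = FALSE) {
  stopifnot(inherits(scan, "seed_scan"))
  px <- scan$pixels
  thr <- EBImage::otsu(EBImage::Image(t(px)))
  fg <- if (scan$background_mode == "white") px < thr else px > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg))))
  lab <- t(lab)
  storage.mode(lab) <- "integer"
  if (max(lab) > 0) {
    lab <- merge_diagonal_labels(lab)
    lab <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(lab)))))
    storage.mode(lab) <- "integer"
  }
  k <- max(lab)
  rows <- list()
  if (k > 0) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    for (i in seq_len(k)) {
      idx <- which(lab == i, arr.ind = TRUE)
      if (nrow(idx) < min_area_px) next
      if (exclude_border && i %in% border_labels) next
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      m <- lab[r0:r1, c0:c1, drop = FALSE] == i
      rows[[length(rows) + 1]] <- list(
        area_px = nrow(idx),
        offset_row = r0 - 1L, offset_col = c0 - 1L,
        centroid_row = mean(idx[, 1]) - 1, centroid_col = mean(idx[, 2]) - 1,
        mask = m
      )
    }
  }
  if (length(rows) == 0) {
    warning(sprintf("no component survived filtering in scan '%s'", scan$source_id),
            call. = FALSE)
    out <- tibble::tibble(
      specimen_id = character(0), source_id = character(0),
      area_px = integer(0), offset_row = integer(0), offset_col = integer(0),
      centroid_row = numeric(0), centroid_col = numeric(0), mask = list()
    )
    attr(out, "threshold") <- thr
    attr(out, "dpi") <- scan$dpi
    return(out)
  }
  ord <- order(vapply(rows, `[[`, 0, "centroid_row"),
               vapply(rows, `[[`, 0, "centroid_col"))
  rows <- rows[ord]
  out <- tibble::tibble(
    specimen_id = sprintf("%s_%03d", scan$source_id, seq_along(rows)),
    source_id = scan$source_id,
    area_px = vapply(rows, `[[`, 0, "area_px"),
    offset_row = vapply(rows, `[[`, 0, "offset_row"),
    offset_col = vapply(rows, `[[`, 0, "offset_col"),
    centroid_row = vapply(rows, `[[`, 0, "centroid_row"),
    centroid_col = vapply(rows, `[[`, 0, "centroid_col"),
    mask = lapply(rows, `[[`, "mask")
  )
  attr(out, "threshold") <- thr
  attr(out, "dpi") <- scan$dpi
  sm_log("info", "scan '%s': threshold %.4f, %d specimen(s) kept",
         scan$source_id, thr, nrow(out))
  out
}

#' Write per-specimen masks and a provenance sidecar
#'
#' @param segments tibble from [segment_seeds()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_masks <- function(segments, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    sm_abort("io", "cannot create output directory %s", dir)
  }
  paths <- character(0)
  for (i in seq_len(nrow(segments))) {
    p <- file.path(dir, paste0(segments$specimen_id[i], ".png"))
    EBImage::writeImage(EBImage::Image(t(segments$mask[[i]] * 1)), p)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, "segments.json")
  jsonlite::write_json(
    list(
      source_id = unique(segments$source_id),
      dpi = attr(segments, "dpi"),
      threshold_value = attr(segments, "threshold"),
      specimen_ids = segments$specimen_id,
      offsets = as.data.frame(segments[, c("offset_row", "offset_col")])
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, sidecar))
}

# Moore neighbourhood offsets, clockwise from north (image coordinates,
# row index grows downwards).
.moore_dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
.moore_dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Trace the outer boundary of a seed mask
#'
#' Moore-neighbour tracing through foreground pixel centres with Jacob's
#' stopping criterion. The first vertex is the top-most, then left-most
#' boundary pixel; the polygon is returned closed (first vertex not
#' repeated) and oriented counter-clockwise on paper.
#'
#' @param mask logical matrix (a `mask` list-column element from
#'   [segment_seeds()] works directly).
#' @return an `n x 2` matrix of 0-based `(row, col)` pixel-centre
#'   coordinates, class `boundary_polygon`.
#' @export
trace_boundary <- function(mask) {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  nfg <- sum(mask)
  # boundary pixels under the 8-connected-foreground / 4-connected-background
  # duality: foreground with a background 4-neighbour (or image edge); this
  # is exactly the pixel set a Moore-neighbour contour walk visits
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad
  for (d in c(1L, 3L, 5L, 7L)) {
    sh <- pad[seq_len(nr) + 1 + .moore_dr[d], seq_len(nc) + 1 + .moore_dc[d], drop = FALSE]
    inner[2:(nr + 1), 2:(nc + 1)] <- inner[2:(nr + 1), 2:(nc + 1)] & sh
  }
  nbnd <- sum(pad[2:(nr + 1), 2:(nc + 1)] & !inner[2:(nr + 1), 2:(nc + 1)])
  if (nbnd < 3) {
    sm_abort("degenerate", "mask has fewer than 3 boundary pixels (%d)", nbnd)
  }
  # start: top-most then left-most foreground pixel (in padded coordinates)
  fg <- which(pad, arr.ind = TRUE)
  srow <- min(fg[, 1])
  scol <- min(fg[fg[, 1] == srow, 2])
  # backtrack starts at the pixel due north of the start (background)
  pr <- srow; pc <- scol
  bdir <- 1L # direction index pointing at the backtrack pixel
  maxit <- 4L * nfg + 16L
  verts_r <- integer(maxit); verts_c <- integer(maxit)
  # the walk is deterministic on states (pixel, backtrack direction); it
  # closes when a state repeats, and the recorded cycle is the boundary
  seen <- new.env(hash = TRUE, parent = emptyenv())
  step <- 0L
  cut_from <- 1L
  repeat {
    key <- sprintf("%d_%d_%d", pr, pc, bdir)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      cut_from <- prev
      break
    }
    step <- step + 1L
    if (step > maxit) sm_abort("degenerate", "boundary trace failed to close")
    seen[[key]] <- step
    verts_r[step] <- pr
    verts_c[step] <- pc
    # scan clockwise starting one step past the backtrack direction
    found <- FALSE
    d <- bdir
    for (s in 1:8) {
      d <- if (d == 8L) 1L else d + 1L
      rr <- pr + .moore_dr[d]; cc <- pc + .moore_dc[d]
      if (pad[rr, cc]) {
        # new backtrack: the previously scanned (background) neighbour,
        # expressed as a direction from the new pixel
        prevd <- if (d == 1L) 8L else d - 1L
        br <- pr + .moore_dr[prevd]; bc <- pc + .moore_dc[prevd]
        pr <- rr; pc <- cc
        bdir <- which(.moore_dr == (br - pr) & .moore_dc == (bc - pc))
        found <- TRUE
        break
      }
    }
    if (!found) sm_abort("degenerate", "isolated pixel encountered in trace")
  }
  # padded 1-based -> original 0-based coordinates
  poly <- cbind(row = verts_r[cut_from:step] - 2L,
                col = verts_c[cut_from:step] - 2L)
  # enforce counter-clockwise paper orientation, then rotate so the first
  # vertex is the top-most, then left-most boundary pixel
  if (nrow(poly) >= 3) {
    # CCW with y up = negative signed area in (col, row) image coordinates
    s <- shoelace_signed(poly[, 2], poly[, 1])
    if (s > 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  }
  top <- which(poly[, 1] == min(poly[, 1]))
  lead <- top[which.min(poly[top, 2])]
  if (lead > 1) {
    poly <- poly[c(lead:nrow(poly), 1:(lead - 1)), , drop = FALSE]
  }
  structure(poly, class = c("boundary_polygon", class(poly)))
}
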