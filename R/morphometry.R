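# The 26-descriptor morphometric panel computed on each seed silhouette.

#' Names of the 26 morphometric descriptors, in canonical column order
#'
#' Ten primary measures taken from the silhouette and its boundary polygon
#' (`Perim`, `Area`, `Pixels`, `MinR`, `MaxR`, `Feret`, `Breadth`, `CHull`,
#' `CArea`, `MBCRadius`) followed by sixteen derived descriptors.
#' @export
seed_feature_names <- c(
  "Perim", "Area", "Pixels", "MinR", "MaxR", "Feret", "Breadth", "CHull",
  "CArea", "MBCRadius", "AspRatio", "Circ", "Roundness", "ArEquivD",
  "PerEquivD", "EquivEllAr", "Compactness", "Solidity", "Concavity",
  "Convexity", "Shape", "RFactor", "ModRatio", "Sphericity", "ArBBox",
  "Rectang"
)

# descriptor dimension classes, used for px -> mm conversion
sm_length_features <- c("Perim", "MinR", "MaxR", "Feret", "Breadth", "CHull",
                        "MBCRadius", "ArEquivD")
sm_area_features <- c("Area", "CArea", "EquivEllAr", "Concavity", "ArBBox")

#' Primary boundary and region measures of one silhouette
#'
#' Measures the ten primary quantities of the descriptor panel: boundary
#' polygon perimeter and enclosed (shoelace) area, foreground pixel count,
#' the inscribed/enclosing radii about the pixel-mass centroid, the Feret
#' diameter (maximum caliper, via rotating calipers on the convex hull),
#' the breadth (caliper extent perpendicular to the Feret axis), the convex
#' hull perimeter and area, and the minimal-bounding-circle radius (Welzl).
#' All geometry is in pixel units on the pixel-centre lattice.
#'
#' @param mask logical matrix (foreground = seed), or a list with a `mask`
#'   element.
#' @param polygon optional precomputed [trace_boundary()] polygon.
#' @param specimen_id used in error messages.
#' @return a one-row tibble with columns `Perim`, `Area`, `Pixels`, `MinR`,
#'   `MaxR`, `Feret`, `Breadth`, `CHull`, `CArea`, `MBCRadius`.
#' @export
primary_measures <- function(mask, polygon = NULL, specimen_id = "specimen") {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  if (is.null(polygon)) polygon <- trace_boundary(mask)
  x <- polygon[, 2]
  y <- polygon[, 1]
  area <- shoelace_area(x, y)
  if (area <= 0) {
    sm_abort("degenerate", "zero-area boundary polygon for specimen '%s'", specimen_id)
  }
  perim <- polyline_length(x, y)
  fg <- which(mask > 0, arr.ind = TRUE)
  centroid <- c(mean(fg[, 2]) - 1, mean(fg[, 1]) - 1) # (x, y), 0-based
  dcent <- sqrt((x - centroid[1])^2 + (y - centroid[2])^2)
  hull <- convex_hull(x, y)
  fer <- feret_calipers(hull)
  breadth <- breadth_perpendicular(hull, fer$p, fer$q)
  mbc <- min_enclosing_circle(hull)
  tibble::tibble(
    Perim = perim,
    Area = area,
    Pixels = sum(mask > 0),
    MinR = min(dcent),
    MaxR = max(dcent),
    Feret = fer$feret,
    Breadth = breadth,
    CHull = polyline_length(hull[, 1], hull[, 2]),
    CArea = shoelace_area(hull[, 1], hull[, 2]),
    MBCRadius = mbc[3]
  )
}

#' Derived shape descriptors from the primary measures
#'
#' Applies the sixteen derived-descriptor formulas exactly as used in
#' seed-image particle analysis:
#' \describe{
#'   \item{AspRatio}{Feret / Breadth}
#'   \item{Circ}{4 pi Area / Perim^2}
#'   \item{Roundness}{4 Area / (pi Feret^2)}
#'   \item{ArEquivD}{sqrt((4 / pi) Area)}
#'   \item{PerEquivD}{Area / pi (see `perequivd_convention`)}
#'   \item{EquivEllAr}{pi Feret Breadth / 4}
#'   \item{Compactness}{sqrt((4 / pi) Area) / Feret}
#'   \item{Solidity}{Area / CArea}
#'   \item{Concavity}{CArea - Area}
#'   \item{Convexity}{CHull / Perim}
#'   \item{Shape}{Perim^2 / Area}
#'   \item{RFactor}{CHull / (Feret pi)}
#'   \item{ModRatio}{2 MinR / Feret}
#'   \item{Sphericity}{MinR / MaxR}
#'   \item{ArBBox}{Feret Breadth}
#'   \item{Rectang}{Area / ArBBox}
#' }
#'
#' `PerEquivD` follows the source descriptor table verbatim, which defines
#' the "perimeter equivalent diameter" as `Area / pi` — dimensionally an
#' area, and almost certainly a misprint of the conventional
#' `Perim / pi`. The default reproduces the printed formula; set
#' `perequivd_convention = "perimeter_over_pi"` for the conventional one.
#'
#' @param primary one-row data frame from [primary_measures()] (extra rows
#'   are processed row-wise).
#' @param perequivd_convention `"as_printed"` (`Area / pi`, default) or
#'   `"perimeter_over_pi"` (`Perim / pi`).
#' @return the input with the 16 derived columns appended, in canonical
#'   order.
#' @export
derived_measures <- function(primary,
                             perequivd_convention = c("as_printed", "perimeter_over_pi")) {
  perequivd_convention <- match.arg(perequivd_convention)
  need <- c("Perim", "Area", "Feret", "Breadth", "CArea", "MaxR")
  pv <- primary[need]
  if (any(!vapply(pv, is.numeric, TRUE)) || any(vapply(pv, function(z) any(!is.finite(z)), TRUE))) {
    sm_abort("degenerate", "primary measures contain non-finite values")
  }
  if (any(primary$Perim <= 0 | primary$Feret <= 0 | primary$Breadth <= 0 |
            primary$CArea <= 0 | primary$MaxR <= 0)) {
    sm_abort("degenerate", "degenerate primary measures (zero length or area)")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(primary),
    AspRatio = .data$Feret / .data$Breadth,
    Circ = 4 * pi * .data$Area / .data$Perim^2,
    Roundness = 4 * .data$Area / (pi * .data$Feret^2),
    ArEquivD = sqrt((4 / pi) * .data$Area),
    PerEquivD = if (perequivd_convention == "as_printed") .data$Area / pi else .data$Perim / pi,
    EquivEllAr = (pi * .data$Feret * .data$Breadth) / 4,
    Compactness = sqrt((4 / pi) * .data$Area) / .data$Feret,
    Solidity = .data$Area / .data$CArea,
    Concavity = .data$CArea - .data$Area,
    Convexity = .data$CHull / .data$Perim,
    Shape = .data$Perim^2 / .data$Area,
    RFactor = .data$CHull / (.data$Feret * pi),
    ModRatio = (2 * .data$MinR) / .data$Feret,
    Sphericity = .data$MinR / .data$MaxR,
    ArBBox = .data$Feret * .data$Breadth,
    Rectang = .data$Area / (.data$Feret * .data$Breadth)
  )
  dplyr::select(out, dplyr::any_of(c("specimen_id", "class_label")),
                dplyr::all_of(seed_feature_names))
}

#' Compute the full 26-descriptor feature table for a set of masks
#'
#' Runs boundary tracing, primary measurement and the derived formulas for
#' every mask. Degenerate specimens (e.g. one-pixel masks) are skipped with
#' a warning and listed in the `rejects` attribute; only if every specimen
#' is degenerate does the call fail.
#'
#' @param masks a tibble with a `mask` list-column (as returned by
#'   [segment_seeds()] or [sample_population()]), optionally with
#'   `specimen_id` and `class_label` columns; or a plain list of logical
#'   matrices.
#' @param units `"px"` (default) or `"mm"`. Lengths are scaled by
#'   `25.4 / dpi` and areas by its square; `Pixels` and all dimensionless
#'   ratios are unit-free and identical under either choice.
#' @param dpi resolution used for the mm conversion.
#' @param class_label optional single label or vector recycled across masks
#'   (overrides a `class_label` column). Use `"UNKNOWN"` for unlabelled
#'   cohorts.
#' @param perequivd_convention see [derived_measures()].
#' @return a tibble with `specimen_id`, `class_label` and the 26 feature
#'   columns in canonical order; attributes `units`, `dpi`,
#'   `perequivd_convention` and `rejects` (character vector of skipped
#'   specimen ids).
#' @export
extract_features <- function(masks, units = c("px", "mm"), dpi = 400,
                             class_label = NULL,
                             perequivd_convention = c("as_printed", "perimeter_over_pi")) {
  units <- match.arg(units)
  perequivd_convention <- match.arg(perequivd_convention)
  if (is.data.frame(masks)) {
    mask_list <- masks$mask
    ids <- if ("specimen_id" %in% names(masks)) masks$specimen_id else
      sprintf("specimen_%03d", seq_along(mask_list))
    labels <- if ("class_label" %in% names(masks)) masks$class_label else
      rep(NA_character_, length(mask_list))
  } else {
    mask_list <- masks
    ids <- sprintf("specimen_%03d", seq_along(mask_list))
    labels <- rep(NA_character_, length(mask_list))
  }
  if (length(mask_list) < 1) sm_abort("validation", "no masks supplied")
  if (!is.null(class_label)) labels <- rep_len(class_label, length(mask_list))
  rows <- vector("list", length(mask_list))
  rejects <- character(0)
  for (i in seq_along(mask_list)) {
    res <- tryCatch(
      primary_measures(mask_list[[i]], specimen_id = ids[i]),
      seedmorph_degenerate_error = function(e) e
    )
    if (inherits(res, "condition")) {
      rejects <- c(rejects, ids[i])
      next
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(specimen_id = ids[i], class_label = labels[i]), res
    )
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rejects) > 0) {
    warning(sprintf("%d degenerate specimen(s) rejected: %s",
                    length(rejects), paste(rejects, collapse = ", ")),
            call. = FALSE)
  }
  if (length(rows) == 0) {
    sm_abort("degenerate", "all %d specimens were rejected as degenerate",
             length(mask_list))
  }
  tab <- derived_measures(dplyr::bind_rows(rows), perequivd_convention)
  if (units == "mm") {
    s <- 25.4 / dpi
    len_cols <- sm_length_features
    area_cols <- sm_area_features
    if (perequivd_convention == "as_printed") {
      area_cols <- c(area_cols, "PerEquivD")
    } else {
      len_cols <- c(len_cols, "PerEquivD")
    }
    tab <- dplyr::mutate(
      tab,
      dplyr::across(dplyr::all_of(len_cols), ~ .x * s),
      dplyr::across(dplyr::all_of(area_cols), ~ .x * s^2)
    )
  }
  sm_log("info", "extracted %d feature row(s), %d reject(s)", nrow(tab), length(rejects))
  attr(tab, "units") <- units
  attr(tab, "dpi") <- dpi
  attr(tab, "perequivd_convention") <- perequivd_convention
  attr(tab, "rejects") <- rejects
  tab
}

#' Write / read a feature table as CSV with a units sidecar
#'
#' The CSV column contract is fixed: `specimen_id,class_label` followed by
#' the 26 descriptors in canonical order. Units and provenance go to a JSON
#' sidecar next to the CSV.
#'
#' @param table a feature table from [extract_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("specimen_id", "class_label", seed_feature_names)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    sm_abort("validation", "feature table lacks columns: %s",
             paste(missing, collapse = ", "))
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- as.data.frame(table[, cols])
  lines <- c(
    paste(cols, collapse = ","),
    vapply(seq_len(nrow(df)), function(i) {
      vals <- vapply(df[i, -(1:2)], function(v) sprintf("%.10g", v), "")
      paste(c(df$specimen_id[i], df$class_label[i], vals), collapse = ",")
    }, "")
  )
  writeLines(lines, path)
  jsonlite::write_json(
    list(units = attr(table, "units") %||% "px",
         dpi = attr(table, "dpi") %||% NA,
         perequivd_convention = attr(table, "perequivd_convention") %||% "as_printed",
         n_specimens = nrow(df),
         rejects = as.list(attr(table, "rejects") %||% character(0))),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) sm_abort("io", "feature table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("specimen_id", "class_label", seed_feature_names), names(df))
  if (length(missing) > 0) {
    sm_abort("validation", "feature CSV %s lacks columns: %s", path,
             paste(missing, collapse = ", "))
  }
  tab <- tibble::as_tibble(df)
  sidecar <- sub("\\.csv$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tab, "units") <- meta$units
    attr(tab, "dpi") <- meta$dpi
    attr(tab, "perequivd_convention") <- meta$perequivd_convention
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
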