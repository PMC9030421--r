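# Tidiers and autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a discriminant model into a long tibble of class means
#'
#' @param x a `seed_lda` model.
#' @param ... unused.
#' @return tibble with `class_label`, `feature`, `mean`.
#' @export
tidy.seed_lda <- function(x, ...) {
  tibble::as_tibble(x$class_means, rownames = "class_label") |>
    tidyr::pivot_longer(-"class_label", names_to = "feature", values_to = "mean")
}

#' One-row model summary
#'
#' @param x a `seed_lda` model.
#' @param ... unused.
#' @return tibble with `n`, `n_classes`, `n_features`, `features`,
#'   `log_det_cov`.
#' @export
glance.seed_lda <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_classes = length(x$class_labels),
    n_features = length(x$selected_features),
    features = paste(x$selected_features, collapse = ","),
    log_det_cov = as.numeric(determinant(x$pooled_within_covariance)$modulus)
  )
}

#' Tidy an allocation table into long form
#'
#' @param x a `seed_allocation`.
#' @param ... unused.
#' @return tibble with `row`, `n`, `predicted_class`, `percent`, `count`.
#' @export
tidy.seed_allocation <- function(x, ...) {
  long <- tibble::as_tibble(x$percentages, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "predicted_class", values_to = "percent")
  cnt <- tibble::as_tibble(x$counts, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "predicted_class", values_to = "count")
  dplyr::left_join(long, cnt, by = c("row", "predicted_class")) |>
    dplyr::left_join(tibble::tibble(row = names(x$n_per_row), n = as.integer(x$n_per_row)),
                     by = "row") |>
    dplyr::select("row", "n", "predicted_class", "percent", "count")
}

#' @rdname tidy.seed_allocation
#' @export
glance.seed_allocation <- function(x, ...) {
  tibble::tibble(
    n = sum(x$n_per_row),
    n_rows = nrow(x$percentages),
    overall_correct = x$overall_correct,
    row_type = x$row_type
  )
}

#' Tidy the stepwise trace
#'
#' @param x a `stepwise_selection`.
#' @param ... unused.
#' @return the step log tibble.
#' @export
tidy.stepwise_selection <- function(x, ...) x$log

#' Heatmap of an allocation table
#'
#' Rows are true classes (or the unknown cohort), columns predicted
#' classes; tiles show row percentages.
#'
#' @param object a `seed_allocation`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.seed_allocation <- function(object, ...) {
  df <- tidy.seed_allocation(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted_class, y = .data$row,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "predicted class", y = NULL, fill = "%") +
    ggplot2::theme_minimal()
}

#' Canonical discriminant score plot
#'
#' Projects specimens onto the first two canonical discriminant axes
#' (eigenvectors of `W^-1 B` over the model's selected features).
#'
#' @param object a `seed_lda` model.
#' @param data feature table to project (e.g. the training table).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.seed_lda <- function(object, data, ...) {
  X <- as.matrix(data[, object$selected_features, drop = FALSE])
  M <- object$class_means
  gm <- colMeans(M)
  B <- crossprod(sweep(M, 2, gm)) # between-class scatter of class means
  ev <- eigen(solve(object$pooled_within_covariance, B))
  V <- Re(ev$vectors[, 1:min(2, ncol(B)), drop = FALSE])
  S <- X %*% V
  df <- tibble::tibble(
    LD1 = S[, 1],
    LD2 = if (ncol(S) > 1) S[, 2] else 0,
    class_label = data$class_label %||% NA_character_
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                   colour = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "class") +
    ggplot2::theme_minimal()
}

#' Silhouette gallery of a synthetic population
#'
#' @param object a `seed_population`.
#' @param max_per_class silhouettes drawn per class.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.seed_population <- function(object, max_per_class = 8, ...) {
  df <- object |>
    dplyr::group_by(.data$class_label) |>
    dplyr::slice_head(n = max_per_class) |>
    dplyr::ungroup()
  pts <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
    b <- trace_boundary(df$mask[[i]])
    tibble::tibble(specimen_id = df$specimen_id[i],
                   class_label = df$class_label[i],
                   x = b[, 2], y = -b[, 1])
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$specimen_id)) +
    ggplot2::geom_polygon(fill = "grey30", colour = NA) +
    ggplot2::facet_wrap(~ specimen_id, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
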