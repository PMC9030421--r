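# Stepwise linear discriminant analysis with Wilks'-lambda partial-F
# selection, leave-one-out / k-fold cross-validation, and allocation of an
# UNKNOWN specimen group to the reference classes.

#' Control parameters for stepwise discriminant selection
#'
#' The three classical controls of stepwise LDA: a variable enters when its
#' partial F-to-enter reaches `f_to_enter` and its within-group tolerance
#' (1 - R^2 against the already-included variables) is at least `tolerance`;
#' an included variable leaves when its partial F-to-remove falls below
#' `f_to_remove`. Defaults are the conventional thresholds of classical
#' statistics packages.
#'
#' @param f_to_enter minimum partial F for entry (default 3.84).
#' @param f_to_remove maximum partial F for removal (default 2.71; must be
#'   below `f_to_enter`).
#' @param tolerance collinearity guard in (0, 1) (default 0.001).
#' @param max_steps hard cap on enter/remove steps.
#' @param priors `"equal"` (default) or `"proportional"` class priors for
#'   the downstream classifier.
#' @return a `stepwise_config` list.
#' @export
stepwise_config <- function(f_to_enter = 3.84, f_to_remove = 2.71,
                            tolerance = 0.001, max_steps = 100,
                            priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  if (tolerance <= 0 || tolerance >= 1) {
    sm_abort("validation", "tolerance must be in (0, 1)")
  }
  if (f_to_enter < 0 || f_to_remove < 0 || f_to_remove >= f_to_enter) {
    sm_abort("validation", "need 0 <= f_to_remove < f_to_enter")
  }
  structure(list(f_to_enter = f_to_enter, f_to_remove = f_to_remove,
                 tolerance = tolerance, max_steps = max_steps, priors = priors),
            class = "stepwise_config")
}

# Labelled (non-UNKNOWN) subset of a feature table.
sm_labelled <- function(table) {
  lab <- table$class_label
  keep <- !is.na(lab) & lab != "UNKNOWN"
  table[keep, , drop = FALSE]
}

sm_feature_cols <- function(table) {
  intersect(seed_feature_names, names(table))
}

# Within-group (W) and total (T) sums-of-squares-and-cross-products matrices.
sm_sscp <- function(X, groups) {
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  for (g in unique(groups)) {
    Xi <- X[groups == g, , drop = FALSE]
    W <- W + crossprod(scale(Xi, center = TRUE, scale = FALSE))
  }
  list(W = W, T = Tm)
}

# Wilks' lambda of a feature subset: det(W_SS) / det(T_SS); 1 for the
# empty set. Uses log-determinants for stability.
sm_wilks <- function(sscp, S) {
  if (length(S) == 0) return(1)
  ldW <- determinant(sscp$W[S, S, drop = FALSE], logarithm = TRUE)
  ldT <- determinant(sscp$T[S, S, drop = FALSE], logarithm = TRUE)
  if (ldW$sign <= 0 || ldT$sign <= 0) return(NA_real_)
  exp(as.numeric(ldW$modulus) - as.numeric(ldT$modulus))
}

# Within-group tolerance of candidate j given included set S:
# 1 - R^2 of j regressed on S in the pooled within-group metric.
sm_tolerance <- function(sscp, j, S) {
  W <- sscp$W
  if (W[j, j] <= 0) return(0)
  if (length(S) == 0) return(1)
  WSS <- W[S, S, drop = FALSE]
  WSj <- W[S, j]
  r2 <- tryCatch(drop(crossprod(WSj, solve(WSS, WSj))) / W[j, j],
                 error = function(e) 1)
  max(0, min(1, 1 - r2))
}

#' Stepwise feature selection by Wilks' lambda
#'
#' Classical forward-stepwise discriminant selection: at each step every
#' excluded descriptor's partial F-to-enter (given the current set) is
#' computed from the ratio of Wilks' lambdas, the best candidate passing
#' `f_to_enter` and the tolerance guard enters, and any included descriptor
#' whose partial F-to-remove drops below `f_to_remove` is removed. Rows
#' labelled `UNKNOWN` (or `NA`) are excluded from selection.
#'
#' @param table a feature table with `class_label` and the 26 descriptor
#'   columns (see [extract_features()]).
#' @param config a [stepwise_config()].
#' @return a `stepwise_selection` object: `selected` (ordered character
#'   vector), `log` (tibble with one row per enter/remove step: step,
#'   action, feature, F, wilks, tolerance), `wilks` (final lambda),
#'   `config`, `n`, `classes`.
#' @export
stepwise_select <- function(table, config = stepwise_config()) {
  stopifnot(inherits(config, "stepwise_config"))
  lab <- sm_labelled(table)
  feats <- sm_feature_cols(lab)
  if (length(feats) == 0) sm_abort("validation", "no descriptor columns found")
  groups <- lab$class_label
  tabn <- table(groups)
  if (length(tabn) < 2 || any(tabn < 2)) {
    sm_abort("validation",
             "need >= 2 classes with >= 2 specimens each (got: %s)",
             paste(sprintf("%s=%d", names(tabn), tabn), collapse = ", "))
  }
  X <- as.matrix(lab[, feats])
  n <- nrow(X)
  g <- length(tabn)
  sscp <- sm_sscp(X, groups)
  included <- character(0)
  log_rows <- list()
  lambda_S <- 1
  steps <- 0
  seen_sets <- character(0)
  partial_f <- function(lambda_ratio, p_other) {
    # lambda_ratio = Lambda(larger set) / Lambda(smaller set)
    (1 - lambda_ratio) / lambda_ratio * (n - g - p_other) / (g - 1)
  }
  repeat {
    steps <- steps + 1
    if (steps > config$max_steps) break
    sig <- paste(sort(included), collapse = "|")
    if (sig %in% seen_sets && length(included) > 0) break
    seen_sets <- c(seen_sets, sig)
    # ---- entry phase
    p <- length(included)
    cands <- setdiff(feats, included)
    entered <- FALSE
    if (length(cands) > 0 && n - g - p > 0) {
      Fs <- rep(NA_real_, length(cands))
      tols <- rep(NA_real_, length(cands))
      lams <- rep(NA_real_, length(cands))
      for (ci in seq_along(cands)) {
        j <- cands[ci]
        tol <- sm_tolerance(sscp, j, included)
        tols[ci] <- tol
        if (tol < config$tolerance) next
        lam <- sm_wilks(sscp, c(included, j))
        if (!is.finite(lam) || lam <= 0) next
        lams[ci] <- lam
        Fs[ci] <- partial_f(lam / lambda_S, p)
      }
      if (any(is.finite(Fs)) && max(Fs, na.rm = TRUE) >= config$f_to_enter) {
        best <- which.max(Fs)
        included <- c(included, cands[best])
        lambda_S <- lams[best]
        log_rows[[length(log_rows) + 1]] <- tibble::tibble(
          step = length(log_rows) + 1L, action = "enter",
          feature = cands[best], F = Fs[best], wilks = lambda_S,
          tolerance = tols[best]
        )
        entered <- TRUE
      }
    }
    if (!entered && length(included) == 0) {
      sm_abort("model",
               paste("no descriptor reaches f_to_enter = %.3g at step 1;",
                     "lower the threshold or inspect the data"),
               config$f_to_enter)
    }
    # ---- removal phase
    removed_any <- FALSE
    repeat {
      p <- length(included)
      if (p < 2) break
      Fr <- vapply(included, function(j) {
        lam_wo <- sm_wilks(sscp, setdiff(included, j))
        if (!is.finite(lam_wo) || lam_wo <= 0) return(Inf)
        partial_f(lambda_S / lam_wo, p - 1)
      }, 0)
      if (min(Fr) < config$f_to_remove) {
        worst <- names(which.min(Fr))
        included <- setdiff(included, worst)
        lambda_S <- sm_wilks(sscp, included)
        log_rows[[length(log_rows) + 1]] <- tibble::tibble(
          step = length(log_rows) + 1L, action = "remove",
          feature = worst, F = min(Fr), wilks = lambda_S,
          tolerance = NA_real_
        )
        removed_any <- TRUE
      } else break
    }
    if (!entered && !removed_any) break
  }
  structure(
    list(selected = included,
         log = if (length(log_rows) > 0) dplyr::bind_rows(log_rows) else
           tibble::tibble(step = integer(0), action = character(0),
                          feature = character(0), F = numeric(0),
                          wilks = numeric(0), tolerance = numeric(0)),
         wilks = lambda_S, config = config, n = n,
         classes = sort(names(tabn))),
    class = "stepwise_selection"
  )
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("<stepwise_selection: %d feature(s), Wilks' lambda = %.4g>\n",
              length(x$selected), x$wilks))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a linear discriminant model on selected descriptors
#'
#' Gaussian linear discriminant with a pooled within-class covariance:
#' class means, pooled covariance (SSCP / (n - g)) and priors are stored;
#' classification uses the linear scores
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log p_k`.
#'
#' @param table feature table; rows labelled `UNKNOWN`/`NA` are ignored.
#' @param selected non-empty character vector of descriptor names (e.g.
#'   `stepwise_select(...)$selected`).
#' @param priors `"equal"` or `"proportional"`.
#' @param units optional unit tag carried for validation against unknown
#'   cohorts (defaults to the table's `units` attribute).
#' @return a `seed_lda` model object.
#' @export
fit_lda <- function(table, selected, priors = c("equal", "proportional"),
                    units = NULL) {
  priors <- match.arg(priors)
  if (inherits(selected, "stepwise_selection")) selected <- selected$selected
  if (length(selected) == 0) sm_abort("validation", "empty feature selection")
  missing <- setdiff(selected, names(table))
  if (length(missing) > 0) {
    sm_abort("validation", "table lacks selected columns: %s",
             paste(missing, collapse = ", "))
  }
  lab <- sm_labelled(table)
  groups <- lab$class_label
  classes <- sort(unique(groups))
  nk <- table(factor(groups, levels = classes))
  if (length(classes) < 2 || any(nk < 2)) {
    sm_abort("validation", "need >= 2 classes with >= 2 specimens each")
  }
  X <- as.matrix(lab[, selected, drop = FALSE])
  n <- nrow(X)
  g <- length(classes)
  means <- do.call(rbind, lapply(classes, function(k) colMeans(X[groups == k, , drop = FALSE])))
  rownames(means) <- classes
  W <- matrix(0, ncol(X), ncol(X), dimnames = list(selected, selected))
  for (k in classes) {
    W <- W + crossprod(scale(X[groups == k, , drop = FALSE], center = TRUE, scale = FALSE))
  }
  cov <- W / (n - g)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    bad <- selected[diag(cov) <= .Machine$double.eps * max(diag(cov), 1)]
    sm_abort("model",
             "pooled within-class covariance is singular on {%s}%s",
             paste(selected, collapse = ", "),
             if (length(bad) > 0) sprintf(" (zero variance: %s)", paste(bad, collapse = ", ")) else "")
  }
  pk <- if (priors == "equal") rep(1 / g, g) else as.numeric(nk) / n
  names(pk) <- classes
  structure(
    list(selected_features = selected, class_labels = classes,
         class_means = means, pooled_within_covariance = cov,
         priors = pk, n_per_class = stats::setNames(as.integer(nk), classes),
         n = n, units = units %||% (attr(table, "units") %||% NA_character_)),
    class = "seed_lda"
  )
}

#' @export
print.seed_lda <- function(x, ...) {
  cat(sprintf("<seed_lda: %d classes, %d feature(s): %s>\n",
              length(x$class_labels), length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  invisible(x)
}

#' Predict classes and posteriors from a seed_lda model
#'
#' @param object a `seed_lda` model.
#' @param newdata data frame containing the model's selected feature
#'   columns.
#' @param ... unused.
#' @return a tibble with `specimen_id` (if present in `newdata`),
#'   `.pred_class`, and one posterior column per class (named
#'   `.post_<class>`). Ties in the argmax are broken towards the
#'   lexicographically first class label and flagged via a message.
#' @export
predict.seed_lda <- function(object, newdata, ...) {
  missing <- setdiff(object$selected_features, names(newdata))
  if (length(missing) > 0) {
    sm_abort("validation", "newdata lacks model features: %s",
             paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[, object$selected_features, drop = FALSE])
  Sinv <- solve(object$pooled_within_covariance)
  M <- object$class_means
  A <- Sinv %*% t(M)                       # p x g
  const <- -0.5 * colSums(t(M) * A) + log(object$priors)
  scores <- sweep(X %*% A, 2, const, "+")  # n x g, classes in sorted order
  mx <- apply(scores, 1, max)
  post <- exp(sweep(scores, 1, mx))
  post <- post / rowSums(post)
  colnames(post) <- object$class_labels
  idx <- apply(post, 1, which.max)
  ties <- apply(post, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  if (any(ties)) {
    sm_log("info", "%d posterior tie(s) broken towards the first class label",
           sum(ties))
  }
  out <- tibble::tibble(.pred_class = object$class_labels[idx])
  if ("specimen_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble::tibble(specimen_id = newdata$specimen_id), out)
  }
  postdf <- tibble::as_tibble(as.data.frame(post))
  names(postdf) <- paste0(".post_", object$class_labels)
  dplyr::bind_cols(out, postdf)
}

# Largest-remainder rounding of a percentage vector to one decimal so that
# the row totals exactly 100.0.
round_percent_row <- function(p) {
  if (all(!is.finite(p)) || sum(p) == 0) return(round(p, 1))
  p <- p / sum(p) * 100
  f <- floor(p * 10)
  rem <- p * 10 - f
  short <- 1000L - as.integer(round(sum(f)))
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    f[add] <- f[add] + 1
  }
  f / 10
}

sm_allocation <- function(counts, row_type, overall_correct = NA_real_) {
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  perc <- t(apply(counts, 1, round_percent_row))
  dimnames(perc) <- dimnames(counts)
  structure(
    list(counts = counts, percentages = perc,
         n_per_row = rowSums(counts), overall_correct = overall_correct,
         row_type = row_type),
    class = "seed_allocation"
  )
}

#' @export
print.seed_allocation <- function(x, ...) {
  df <- as.data.frame(x$percentages)
  df$Total <- sprintf("%.1f", rowSums(x$percentages))
  df <- cbind(n = x$n_per_row, df)
  print(df)
  if (is.finite(x$overall_correct)) {
    cat(sprintf("Overall correct: %.1f%%\n", x$overall_correct))
  }
  invisible(x)
}

#' Cross-validated classification of a labelled feature table
#'
#' Feature selection is performed once on the full labelled table (the
#' classical, source-faithful variant; set `honest = TRUE` to re-run
#' selection inside every fold), then each held-out specimen is classified
#' by a model refit without it. Leave-one-out refits use exact mean /
#' pooled-SSCP downdates, so LOO is deterministic and seed-free.
#'
#' When no descriptor passes `f_to_enter`, cross-validation falls back to
#' prior-only classification (every specimen assigned the prior-argmax
#' class, ties towards the first label) rather than failing, so chance-level
#' data yields a chance-level table.
#'
#' @param table labelled feature table (rows labelled `UNKNOWN` are
#'   ignored).
#' @param config a [stepwise_config()].
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param seed RNG seed for fold assignment (`"kfold"` only).
#' @param honest re-run stepwise selection inside each training fold.
#' @return a `seed_allocation` with one labelled row per true class, the
#'   held-out confusion expressed as row percentages, per-row counts, and
#'   `overall_correct` (count-weighted diagonal percentage). The selection
#'   used is attached as attribute `selection`.
#' @export
cross_validate <- function(table, config = stepwise_config(),
                           scheme = c("loo", "kfold"), k = 10, seed = NULL,
                           honest = FALSE) {
  scheme <- match.arg(scheme)
  lab <- sm_labelled(table)
  groups <- lab$class_label
  classes <- sort(unique(groups))
  singletons <- names(which(table(groups) < 2))
  if (length(singletons) > 0) {
    warning(sprintf("class(es) with a single specimen skipped in CV: %s",
                    paste(singletons, collapse = ", ")), call. = FALSE)
    lab <- lab[!groups %in% singletons, , drop = FALSE]
    groups <- lab$class_label
    classes <- sort(unique(groups))
  }
  sel <- tryCatch(stepwise_select(lab, config),
                  seedmorph_model_error = function(e) NULL)
  n <- nrow(lab)
  folds <- if (scheme == "loo") {
    seq_len(n)
  } else {
    if (is.null(seed)) sm_abort("validation", "kfold requires a seed")
    with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  }
  pred <- character(n)
  if (is.null(sel) && !honest) {
    sm_log("warn", "no descriptor passed f_to_enter; prior-only fallback")
    pk <- if (config$priors == "equal") rep(1, length(classes)) else
      as.numeric(table(factor(groups, levels = classes)))
    pred <- rep(classes[which.max(pk)], n)
  } else if (honest) {
    for (f in sort(unique(folds))) {
      test <- folds == f
      train <- lab[!test, , drop = FALSE]
      sel_f <- tryCatch(stepwise_select(train, config),
                        seedmorph_model_error = function(e) NULL)
      if (is.null(sel_f)) {
        pred[test] <- classes[1]
        next
      }
      m <- fit_lda(train, sel_f$selected, priors = config$priors)
      pred[test] <- predict(m, lab[test, , drop = FALSE])$.pred_class
    }
  } else if (scheme == "loo") {
    pred <- loo_predict_downdate(lab, sel$selected, config$priors)
  } else {
    for (f in sort(unique(folds))) {
      test <- folds == f
      m <- fit_lda(lab[!test, , drop = FALSE], sel$selected, priors = config$priors)
      pred[test] <- predict(m, lab[test, , drop = FALSE])$.pred_class
    }
  }
  counts <- as.matrix(table(factor(groups, levels = classes),
                            factor(pred, levels = classes)))
  overall <- 100 * sum(diag(counts)) / sum(counts)
  out <- sm_allocation(counts, row_type = "labelled", overall_correct = overall)
  attr(out, "selection") <- sel
  attr(out, "scheme") <- scheme
  out
}

# Exact leave-one-out predictions via mean / pooled-SSCP downdating.
loo_predict_downdate <- function(lab, selected, priors) {
  groups <- lab$class_label
  classes <- sort(unique(groups))
  g <- length(classes)
  X <- as.matrix(lab[, selected, drop = FALSE])
  n <- nrow(X)
  nk <- stats::setNames(as.numeric(table(factor(groups, levels = classes))), classes)
  sums <- rowsum(X, groups)               # g x p, rows in sorted class order
  means <- sums / nk[rownames(sums)]
  W <- matrix(0, ncol(X), ncol(X))
  for (kk in classes) {
    W <- W + crossprod(scale(X[groups == kk, , drop = FALSE], center = TRUE, scale = FALSE))
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    ki <- groups[i]
    x <- X[i, ]
    nki <- nk[ki]
    mki <- means[ki, ]
    d <- x - mki
    W_i <- W - (nki / (nki - 1)) * tcrossprod(d)
    means_i <- means
    means_i[ki, ] <- (sums[ki, ] - x) / (nki - 1)
    cov_i <- W_i / (n - 1 - g)
    Sinv <- tryCatch(solve(cov_i), error = function(e) NULL)
    if (is.null(Sinv)) {
      sm_abort("model", "pooled covariance singular in LOO fold %d", i)
    }
    pk <- if (priors == "equal") rep(1 / g, g) else {
      nn <- nk
      nn[ki] <- nn[ki] - 1
      nn / (n - 1)
    }
    A <- Sinv %*% t(means_i)
    const <- -0.5 * colSums(t(means_i) * A) + log(pk)
    sc <- drop(x %*% A) + const
    pred[i] <- classes[which.max(sc)]
  }
  pred
}

#' Allocate an unknown specimen group to the reference classes
#'
#' Classifies every `UNKNOWN` row with a fitted model and summarises the
#' cohort as a single allocation row of per-class percentages (one decimal,
#' largest-remainder rounding so the row totals 100.0), alongside the full
#' per-specimen posterior table.
#'
#' @param model a [fit_lda()] model.
#' @param unknowns feature-table rows to allocate (any `class_label`).
#' @param label row label for the cohort.
#' @return a `seed_allocation` (row_type `"unknown"`) with attribute
#'   `posteriors`: the per-specimen prediction tibble.
#' @export
allocate_unknowns <- function(model, unknowns, label = "Unknown samples") {
  stopifnot(inherits(model, "seed_lda"))
  if (nrow(unknowns) == 0) sm_abort("validation", "no unknown specimens supplied")
  mu <- model$units
  uu <- attr(unknowns, "units")
  if (!is.null(uu) && !is.na(mu) && !identical(uu, mu)) {
    sm_abort("validation", "unit mismatch: model in '%s', unknowns in '%s'", mu, uu)
  }
  pr <- predict(model, unknowns)
  counts <- matrix(as.numeric(table(factor(pr$.pred_class, levels = model$class_labels))),
                   nrow = 1, dimnames = list(label, model$class_labels))
  out <- sm_allocation(counts, row_type = "unknown")
  attr(out, "posteriors") <- pr
  out
}

#' Write allocation tables and the stepwise trace to disk
#'
#' One CSV per table (row label, n, per-class percentages, `Total`, plus an
#' `overall` line when available), and optionally a JSON log of the
#' stepwise selection trace. Output is byte-deterministic for fixed input.
#'
#' @param tables a named list of `seed_allocation` objects (a bare
#'   `seed_allocation` is wrapped as `list(allocation = x)`).
#' @param path output directory.
#' @param step_log optional `stepwise_selection` whose trace is written to
#'   `step_log.json`.
#' @return invisibly, the paths written (none, with a warning, for an empty
#'   table list).
#' @export
write_report <- function(tables, path, step_log = NULL) {
  if (inherits(tables, "seed_allocation")) tables <- list(allocation = tables)
  if (length(tables) == 0) {
    warning("no allocation tables to write", call. = FALSE)
    return(invisible(character(0)))
  }
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    sm_abort("io", "cannot create report directory %s", path)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(inherits(tab, "seed_allocation"))
    f <- file.path(path, paste0(nm, ".csv"))
    classes <- colnames(tab$percentages)
    lines <- paste(c("row", "n", classes, "Total"), collapse = ",")
    for (i in seq_len(nrow(tab$percentages))) {
      p <- tab$percentages[i, ]
      lines <- c(lines, paste(c(rownames(tab$percentages)[i], tab$n_per_row[i],
                                sprintf("%.1f", p), sprintf("%.1f", sum(p))),
                              collapse = ","))
    }
    if (is.finite(tab$overall_correct)) {
      lines <- c(lines, sprintf("overall,%d,%s%.1f", sum(tab$n_per_row),
                                paste(rep("", length(classes) + 1), collapse = ","),
                                tab$overall_correct))
    }
    writeLines(lines, f)
    paths <- c(paths, f)
  }
  if (!is.null(step_log)) {
    f <- file.path(path, "step_log.json")
    jsonlite::write_json(
      list(selected = step_log$selected, wilks = step_log$wilks,
           config = unclass(step_log$config),
           log = as.data.frame(step_log$log)),
      f, auto_unbox = TRUE, digits = NA, na = "null"
    )
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Serialize / restore a discriminant model as JSON
#'
#' @param model a `seed_lda` model.
#' @param path JSON file path.
#' @return `path` invisibly; `read_discriminant_json()` returns the model.
#' @export
write_discriminant_json <- function(model, path) {
  stopifnot(inherits(model, "seed_lda"))
  jsonlite::write_json(
    list(selected_features = model$selected_features,
         class_labels = model$class_labels,
         class_means = apply(model$class_means, 1, as.list),
         pooled_within_covariance = model$pooled_within_covariance,
         priors = as.list(model$priors),
         n_per_class = as.list(model$n_per_class),
         units = model$units),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor", na = "null"
  )
  invisible(path)
}

#' @rdname write_discriminant_json
#' @export
read_discriminant_json <- function(path) {
  if (!file.exists(path)) sm_abort("io", "model file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(j$selected_features)
  means <- do.call(rbind, lapply(j$class_means, unlist))
  colnames(means) <- j$selected_features
  cov <- matrix(unlist(j$pooled_within_covariance), p, p, byrow = TRUE,
                dimnames = list(j$selected_features, j$selected_features))
  structure(
    list(selected_features = j$selected_features,
         class_labels = j$class_labels, class_means = means,
         pooled_within_covariance = cov,
         priors = unlist(j$priors),
         n_per_class = unlist(j$n_per_class),
         n = sum(unlist(j$n_per_class)),
         units = if (is.null(j$units)) NA_character_ else j$units),
    class = "seed_lda"
  )
}

# Run code with a temporarily-set RNG seed, restoring the previous state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
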