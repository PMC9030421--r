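# End-to-end pipeline: (simulate | scans | feature CSVs) -> 26-descriptor
# feature tables -> stepwise LDA -> cross-validation and unknown-group
# allocation, with full provenance.

#' Build a resolved pipeline configuration
#'
#' @param out_dir directory all artifacts are written to.
#' @param mode `"simulate"` (synthetic population; default), `"features"`
#'   (precomputed feature CSVs) or `"images"` (scan files).
#' @param seed single RNG seed governing every stochastic stage.
#' @param specs simulate mode: class-spec tibble ([shape_class_spec()]) or
#'   path to a specs JSON; defaults to [example_class_specs()].
#' @param unknown_class simulate mode: class whose distribution the unknown
#'   cohort is drawn from (default: first spec).
#' @param n_unknown simulate mode: unknown cohort size.
#' @param train_features,unknown_features features mode: CSV paths
#'   (`unknown_features` optional).
#' @param images images mode: data frame with columns `path`,
#'   `class_label`; rows labelled `UNKNOWN` form the unknown cohort.
#' @param dpi,units,background_mode,min_area_px,exclude_border image /
#'   measurement settings (see [load_scan()], [segment_seeds()],
#'   [extract_features()]).
#' @param f_to_enter,f_to_remove,tolerance,priors stepwise LDA controls
#'   (see [stepwise_config()]).
#' @param cv `"loo"` or `"kfold"`; `k` folds for the latter;
#'   `honest_cv` re-runs selection per fold.
#' @param log_level see [seedmorph_log_level()].
#' @return a `seedmorph_config` list.
#' @export
pipeline_config <- function(out_dir, mode = c("simulate", "features", "images"),
                            seed = 7, specs = NULL, unknown_class = NULL,
                            n_unknown = 20, train_features = NULL,
                            unknown_features = NULL, images = NULL,
                            dpi = 400, units = "px",
                            background_mode = "white", min_area_px = 100,
                            exclude_border = FALSE, f_to_enter = 3.84,
                            f_to_remove = 2.71, tolerance = 0.001,
                            priors = "equal", cv = "loo", k = 10,
                            honest_cv = FALSE, log_level = "info") {
  mode <- match.arg(mode)
  structure(
    list(out_dir = out_dir, mode = mode, seed = seed, specs = specs,
         unknown_class = unknown_class, n_unknown = n_unknown,
         train_features = train_features, unknown_features = unknown_features,
         images = images, dpi = dpi, units = units,
         background_mode = background_mode, min_area_px = min_area_px,
         exclude_border = exclude_border, f_to_enter = f_to_enter,
         f_to_remove = f_to_remove, tolerance = tolerance, priors = priors,
         cv = cv, k = k, honest_cv = honest_cv, log_level = log_level),
    class = "seedmorph_config"
  )
}

#' Read / write class-spec JSON files
#'
#' The JSON schema is a list of objects with the [shape_class_spec()]
#' fields; an example ships at
#' `system.file("extdata", "example_class_specs.json", package = "seedmorph")`.
#'
#' @param path JSON file path.
#' @return a spec tibble.
#' @export
read_class_specs <- function(path) {
  if (!file.exists(path)) sm_abort("io", "spec file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dplyr::bind_rows(lapply(seq_len(nrow(j)), function(i) {
    do.call(shape_class_spec, as.list(j[i, ]))
  }))
}

#' @rdname read_class_specs
#' @param specs a spec tibble.
#' @export
write_class_specs <- function(specs, path) {
  jsonlite::write_json(specs, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes input resolution (simulation, segmentation of scans, or CSV
#' load), feature extraction, stepwise LDA with cross-validation, unknown
#' allocation when an unknown cohort exists, and writes every artifact plus
#' a resolved-config provenance JSON into `config$out_dir`.
#'
#' Typed pipeline failures are caught and reported through the returned
#' status instead of an R error: 0 success, 2 validation, 3 I/O,
#' 4 degenerate data, 5 model failure.
#'
#' @param config a [pipeline_config()].
#' @return a list with `status`, `artifacts` (paths), and on success
#'   `results`: `features`, `selection`, `model`, `cv` and (optionally)
#'   `allocation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "seedmorph_config"))
  old <- seedmorph_log_level(config$log_level)
  on.exit(options(seedmorph.log_level = old))
  res <- tryCatch(
    run_pipeline_impl(config),
    seedmorph_error = function(e) {
      sm_log("warn", "pipeline failed (status %d): %s",
             e$status %||% 1L, conditionMessage(e))
      list(status = as.integer(e$status %||% 1L), error = conditionMessage(e),
           artifacts = character(0))
    }
  )
  res
}

run_pipeline_impl <- function(config) {
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    sm_abort("io", "cannot create output directory %s", out_dir)
  }
  artifacts <- character(0)
  if (config$mode == "simulate") {
    specs <- config$specs
    if (is.null(specs)) specs <- example_class_specs()
    if (is.character(specs)) specs <- read_class_specs(specs)
    pop <- sample_population(specs, dpi = config$dpi, seed = config$seed)
    sm_log("info", "simulated %d specimens in %d classes", nrow(pop), nrow(specs))
    train <- extract_features(pop, units = config$units, dpi = config$dpi)
    ucl <- config$unknown_class %||% specs$name[1]
    uspec <- specs[specs$name == ucl, ]
    if (nrow(uspec) == 0) sm_abort("validation", "unknown_class '%s' not in specs", ucl)
    uspec$n <- as.integer(config$n_unknown)
    upop <- sample_population(uspec, dpi = config$dpi, seed = config$seed + 1L)
    unknown <- extract_features(upop, units = config$units, dpi = config$dpi,
                                class_label = "UNKNOWN")
    truth_path <- file.path(out_dir, "truth.csv")
    utils::write.csv(as.data.frame(dplyr::select(pop, -"mask")), truth_path,
                     row.names = FALSE)
    artifacts <- c(artifacts, truth_path)
  } else if (config$mode == "features") {
    if (is.null(config$train_features)) {
      sm_abort("validation", "mode 'features' requires train_features")
    }
    train <- read_feature_table(config$train_features)
    unknown <- if (!is.null(config$unknown_features)) {
      read_feature_table(config$unknown_features)
    } else NULL
  } else { # images
    imgs <- config$images
    if (is.null(imgs) || !all(c("path", "class_label") %in% names(imgs))) {
      sm_abort("validation", "mode 'images' requires images$path and images$class_label")
    }
    feats <- lapply(seq_len(nrow(imgs)), function(i) {
      scan <- load_scan(imgs$path[i], dpi = config$dpi,
                        background_mode = config$background_mode)
      segs <- segment_seeds(scan, min_area_px = config$min_area_px,
                            exclude_border = config$exclude_border)
      if (nrow(segs) == 0) return(NULL)
      extract_features(segs, units = config$units, dpi = config$dpi,
                       class_label = imgs$class_label[i])
    })
    feats <- feats[!vapply(feats, is.null, TRUE)]
    if (length(feats) == 0) sm_abort("degenerate", "no specimens found in any scan")
    all_feats <- dplyr::bind_rows(feats)
    train <- all_feats[all_feats$class_label != "UNKNOWN", , drop = FALSE]
    unknown <- all_feats[all_feats$class_label == "UNKNOWN", , drop = FALSE]
    if (nrow(unknown) == 0) unknown <- NULL
    attr(train, "units") <- config$units
    if (!is.null(unknown)) attr(unknown, "units") <- config$units
  }
  fpath <- file.path(out_dir, "features_train.csv")
  write_feature_table(train, fpath)
  artifacts <- c(artifacts, fpath)
  if (!is.null(unknown) && nrow(unknown) > 0) {
    upath <- file.path(out_dir, "features_unknown.csv")
    write_feature_table(unknown, upath)
    artifacts <- c(artifacts, upath)
  }
  cfg <- stepwise_config(f_to_enter = config$f_to_enter,
                         f_to_remove = config$f_to_remove,
                         tolerance = config$tolerance,
                         priors = config$priors)
  sel <- stepwise_select(train, cfg)
  sm_log("info", "stepwise selected %d feature(s): %s", length(sel$selected),
         paste(sel$selected, collapse = ", "))
  model <- fit_lda(train, sel$selected, priors = config$priors,
                   units = config$units)
  cv <- cross_validate(train, cfg, scheme = config$cv, k = config$k,
                       seed = config$seed, honest = config$honest_cv)
  tables <- list(cross_validation = cv)
  allocation <- NULL
  if (!is.null(unknown) && nrow(unknown) > 0) {
    allocation <- allocate_unknowns(model, unknown)
    tables$unknown_allocation <- allocation
  }
  artifacts <- c(artifacts, write_report(tables, out_dir, step_log = sel))
  mpath <- file.path(out_dir, "model.json")
  write_discriminant_json(model, mpath)
  artifacts <- c(artifacts, mpath)
  prov <- file.path(out_dir, "resolved_config.json")
  cfg_out <- unclass(config)
  cfg_out$images <- NULL
  cfg_out$specs <- if (is.data.frame(config$specs)) "inline" else config$specs
  jsonlite::write_json(
    list(package = "seedmorph",
         version = as.character(utils::packageVersion("seedmorph")),
         config = cfg_out,
         counts = list(
           n_train = nrow(train),
           n_unknown = if (is.null(unknown)) 0L else nrow(unknown),
           n_rejects = length(attr(train, "rejects") %||% character(0)),
           n_selected = length(sel$selected),
           cv_folds = if (config$cv == "loo") nrow(sm_labelled(train)) else config$k
         )),
    prov, auto_unbox = TRUE, digits = NA, null = "null"
  )
  artifacts <- c(artifacts, prov)
  sm_log("info", "pipeline complete: %d artifact(s) in %s", length(artifacts), out_dir)
  list(status = 0L, artifacts = artifacts,
       results = list(features = train, unknown = unknown, selection = sel,
                      model = model, cv = cv, allocation = allocation))
}
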