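# Stepwise Wilks-lambda selection, LDA fit/predict, cross-validation,
# unknown allocation and report layout.

# feature table with a single informative descriptor (Feret), the other
# 25 pure noise
single_signal_table <- function(n_per_class = 50, delta = 5, seed = 3) {
  withr::with_seed(seed, {
    p <- length(seed_feature_names)
    X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
    colnames(X) <- seed_feature_names
    X[(n_per_class + 1):(2 * n_per_class), "Feret"] <-
      X[(n_per_class + 1):(2 * n_per_class), "Feret"] + delta
    tab <- tibble::as_tibble(X)
    tab$specimen_id <- sprintf("s%03d", seq_len(2 * n_per_class))
    tab$class_label <- rep(c("A", "B"), each = n_per_class)
    tab
  })
}

test_that("stepwise enters the single informative descriptor first", {
  tab <- single_signal_table()
  sel <- stepwise_select(tab, stepwise_config())
  expect_equal(sel$log$feature[1], "Feret")
  expect_true("Feret" %in% sel$selected)
  # step-1 choice agrees with an exhaustive single-feature F ranking
  lab <- tab[tab$class_label != "UNKNOWN", ]
  X <- as.matrix(lab[, seed_feature_names])
  lams <- vapply(seed_feature_names, function(f) oracle_wilks(X, lab$class_label, f), 0)
  expect_equal(names(which.min(lams)), "Feret")
  # and the logged F matches the one-way ANOVA F for that feature
  aovF <- summary(stats::aov(X[, "Feret"] ~ factor(lab$class_label)))[[1]]$`F value`[1]
  expect_equal(sel$log$F[1], aovF, tolerance = 1e-8)
})

test_that("exact collinearity is blocked by the tolerance rule", {
  tab <- single_signal_table()
  tab$Breadth <- tab$Feret # duplicated column
  sel <- stepwise_select(tab, stepwise_config())
  expect_lte(sum(c("Feret", "Breadth") %in% sel$selected), 1)
})

test_that("an unreachable entry threshold raises the empty-model error", {
  tab <- single_signal_table()
  expect_error(stepwise_select(tab, stepwise_config(f_to_enter = 1e9, f_to_remove = 1)),
               class = "seedmorph_model_error")
})

test_that("stepwise requires a legal design", {
  tab <- single_signal_table(n_per_class = 5)
  tab$class_label <- "A"
  expect_error(stepwise_select(tab), class = "seedmorph_validation_error")
  expect_error(stepwise_config(f_to_enter = 2, f_to_remove = 3),
               class = "seedmorph_validation_error")
  expect_error(stepwise_config(tolerance = 0), class = "seedmorph_validation_error")
})

test_that("stepwise matches exhaustive best-subset search on small unique-path instances", {
  n_agree <- 0
  n_run <- 0
  for (rep in 1:12) {
    inst <- withr::with_seed(100 + rep, {
      g <- sample(2:3, 1)
      p <- sample(3:6, 1)
      n <- 20 * g
      mu <- matrix(rnorm(g * p, 0, 0.9), g, p)
      X <- matrix(rnorm(n * p), n, p)
      groups <- rep(letters[1:g], each = 20)
      for (k in 1:g) X[groups == letters[k], ] <-
          sweep(X[groups == letters[k], ], 2, mu[k, ], "+")
      colnames(X) <- seed_feature_names[1:p]
      tab <- tibble::as_tibble(X)
      tab$specimen_id <- as.character(seq_len(n))
      tab$class_label <- groups
      tab
    })
    sel <- tryCatch(stepwise_select(inst, stepwise_config(f_to_enter = 3, f_to_remove = 2)),
                    seedmorph_model_error = function(e) NULL)
    if (is.null(sel) || length(sel$selected) == 0) next
    n_run <- n_run + 1
    X <- as.matrix(inst[, setdiff(names(inst), c("specimen_id", "class_label"))])
    best <- oracle_best_subset(X, inst$class_label, length(sel$selected))
    if (setequal(sel$selected, best)) n_agree <- n_agree + 1
  }
  expect_gte(n_run, 8)
  expect_equal(n_agree, n_run)
})

test_that("the 1-D two-class discriminant has the midpoint boundary and logistic posterior", {
  # sample means exactly 0 and 4, pooled within-class variance exactly 1
  e <- 1 / sqrt(2)
  tab <- tibble::tibble(
    specimen_id = as.character(1:4),
    class_label = c("A", "A", "B", "B"),
    Feret = c(-e, e, 4 - e, 4 + e)
  )
  m <- fit_lda(tab, "Feret", priors = "equal")
  expect_equal(unname(m$class_means[, 1]), c(0, 4))
  expect_equal(unname(m$pooled_within_covariance[1, 1]), 1)
  pr <- predict(m, tibble::tibble(Feret = c(1.99, 2.01, 0)))
  expect_equal(pr$.pred_class, c("A", "B", "A"))
  expect_equal(pr$.post_A[3], 1 / (1 + exp(-8)), tolerance = 1e-12)
  # posteriors always sum to 1
  expect_equal(pr$.post_A + pr$.post_B, rep(1, 3), tolerance = 1e-12)
})

test_that("singular pooled covariance is reported as a collinearity error", {
  tab <- tibble::tibble(
    specimen_id = as.character(1:4),
    class_label = c("A", "A", "B", "B"),
    Feret = c(1, 1, 3, 3),   # zero within-class variance in both classes
    Breadth = c(1, 2, 3, 4)
  )
  expect_error(fit_lda(tab, c("Feret", "Breadth")), class = "seedmorph_model_error")
  # perfectly collinear pair
  tab2 <- single_signal_table(n_per_class = 10)
  tab2$Breadth <- 2 * tab2$Feret
  expect_error(fit_lda(tab2, c("Feret", "Breadth")), class = "seedmorph_model_error")
})

test_that("fit and predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  tab <- gauss_feature_table(n_per_class = 40, delta = 3, informative = 4, seed = 9)
  sel <- c("Perim", "Area", "Pixels", "MinR", "MaxR")
  m <- fit_lda(tab, sel, priors = "equal")
  pr <- predict(m, tab)
  ref <- MASS::lda(as.matrix(tab[, sel]), grouping = tab$class_label,
                   prior = c(0.5, 0.5))
  rp <- predict(ref, as.matrix(tab[, sel]))
  expect_equal(pr$.pred_class, as.character(rp$class))
  expect_equal(unname(as.matrix(pr[, c(".post_A", ".post_B")])),
               unname(rp$posterior), tolerance = 1e-8)
})

test_that("LOO on well-separated classes is near-perfect and reproducible", {
  tab <- gauss_feature_table(n_per_class = 50, delta = 8, informative = 3, seed = 21)
  cv1 <- cross_validate(tab, stepwise_config())
  cv2 <- cross_validate(tab, stepwise_config())
  expect_identical(cv1$counts, cv2$counts)
  expect_identical(cv1$overall_correct, cv2$overall_correct)
  expect_gte(cv1$overall_correct, 95)
  # row percentages total 100.0 after rounding
  expect_true(all(abs(rowSums(cv1$percentages) - 100) <= 0.1))
})

test_that("point-mass classes cross-validate at exactly 100 percent", {
  tab <- tibble::tibble(
    specimen_id = as.character(1:12),
    class_label = rep(c("A", "B"), each = 6),
    Feret = c(rep(c(10, 10.01, 9.99), 2), rep(c(20, 20.01, 19.99), 2)),
    Area = rep(c(5, 50), each = 6)
  )
  cv <- cross_validate(tab, stepwise_config(f_to_enter = 1, f_to_remove = 0.5))
  expect_equal(cv$overall_correct, 100)
})

test_that("indistinguishable classes fall back to a chance-level table", {
  tab <- gauss_feature_table(n_per_class = 30, delta = 0, informative = 0, seed = 4)
  # with an unreachable entry threshold the fallback is prior-only
  cv <- suppressMessages(
    cross_validate(tab, stepwise_config(f_to_enter = 1e9, f_to_remove = 1))
  )
  expect_equal(cv$overall_correct, 50)
})

test_that("classification is invariant to affine descriptor rescaling", {
  tab <- gauss_feature_table(n_per_class = 40, delta = 4, informative = 3, seed = 13)
  scales <- withr::with_seed(5, runif(length(seed_feature_names), 0.1, 30))
  shifts <- withr::with_seed(6, runif(length(seed_feature_names), -5, 5))
  tab2 <- tab
  for (i in seq_along(seed_feature_names)) {
    f <- seed_feature_names[i]
    tab2[[f]] <- tab[[f]] * scales[i] + shifts[i]
  }
  cfg <- stepwise_config()
  sel1 <- stepwise_select(tab, cfg)
  sel2 <- stepwise_select(tab2, cfg)
  expect_equal(sel1$selected, sel2$selected)
  m1 <- fit_lda(tab, sel1$selected)
  m2 <- fit_lda(tab2, sel2$selected)
  expect_equal(predict(m1, tab)$.pred_class, predict(m2, tab2)$.pred_class)
  cv1 <- cross_validate(tab, cfg)
  cv2 <- cross_validate(tab2, cfg)
  expect_identical(cv1$counts, cv2$counts)
})

test_that("kfold CV is reproducible under a fixed seed and honest CV runs", {
  tab <- gauss_feature_table(n_per_class = 30, delta = 5, informative = 2, seed = 17)
  k1 <- cross_validate(tab, stepwise_config(), scheme = "kfold", k = 5, seed = 11)
  k2 <- cross_validate(tab, stepwise_config(), scheme = "kfold", k = 5, seed = 11)
  expect_identical(k1$counts, k2$counts)
  expect_error(cross_validate(tab, stepwise_config(), scheme = "kfold"),
               class = "seedmorph_validation_error")
  h <- cross_validate(tab, stepwise_config(), scheme = "kfold", k = 5, seed = 11,
                      honest = TRUE)
  expect_gte(h$overall_correct, 90)
})

test_that("unknown cohorts allocate to the generating class", {
  tab <- gauss_feature_table(n_per_class = 60, delta = 6, informative = 3, seed = 31)
  sel <- stepwise_select(tab, stepwise_config())
  m <- fit_lda(tab, sel$selected)
  # a specimen exactly at a class mean gets that class with top posterior
  mean_row <- tibble::as_tibble(as.list(m$class_means["B", ]))
  pr <- predict(m, mean_row)
  expect_equal(pr$.pred_class, "B")
  expect_gt(pr$.post_B, pr$.post_A)
  # a cohort drawn around class B's mean goes overwhelmingly to B
  unk <- withr::with_seed(8, {
    U <- gauss_feature_table(n_per_class = 35, delta = 6, informative = 3, seed = 8)
    u <- U[U$class_label == "B", ]
    u$class_label <- "UNKNOWN"
    u
  })
  alloc <- allocate_unknowns(m, unk)
  expect_gte(alloc$percentages[1, "B"], 80)
  expect_equal(sum(alloc$percentages[1, ]), 100, tolerance = 0.05)
  post <- attr(alloc, "posteriors")
  expect_equal(nrow(post), 35)
  expect_equal(unname(rowSums(as.matrix(post[, c(".post_A", ".post_B")]))),
               rep(1, 35), tolerance = 1e-9)
})

test_that("unit mismatch between model and unknowns is a validation error", {
  tab <- gauss_feature_table(n_per_class = 20, delta = 5, informative = 2, seed = 41)
  attr(tab, "units") <- "px"
  m <- fit_lda(tab, c("Perim", "Area"), units = "px")
  unk <- tab[1:5, ]
  unk$class_label <- "UNKNOWN"
  attr(unk, "units") <- "mm"
  expect_error(allocate_unknowns(m, unk), class = "seedmorph_validation_error")
  expect_error(allocate_unknowns(m, tab[0, ]), class = "seedmorph_validation_error")
})

test_that("report CSVs have the allocation-table layout and are byte-stable", {
  tab <- gauss_feature_table(n_per_class = 25, delta = 5, informative = 3, seed = 51)
  cfg <- stepwise_config()
  sel <- stepwise_select(tab, cfg)
  m <- fit_lda(tab, sel$selected)
  cv <- cross_validate(tab, cfg)
  unk <- tab[tab$class_label == "B", ][1:10, ]
  unk$class_label <- "UNKNOWN"
  alloc <- allocate_unknowns(m, unk)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report(list(cv = cv, unknown = alloc), d1, step_log = sel)
  p2 <- write_report(list(cv = cv, unknown = alloc), d2, step_log = sel)
  cvl <- readLines(file.path(d1, "cv.csv"))
  expect_equal(length(cvl), 1 + 2 + 1) # header, 2 class rows, overall line
  expect_match(cvl[1], "^row,n,")
  expect_match(cvl[length(cvl)], "^overall,")
  ul <- readLines(file.path(d1, "unknown.csv"))
  expect_match(ul[2], ",100\\.0$")
  for (f in basename(p1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_warning(write_report(list(), d1), "no allocation tables")
})

test_that("discriminant models survive a JSON round-trip", {
  tab <- gauss_feature_table(n_per_class = 20, delta = 5, informative = 2, seed = 61)
  m <- fit_lda(tab, c("Perim", "Area", "Feret"), units = "px")
  f <- withr::local_tempfile(fileext = ".json")
  write_discriminant_json(m, f)
  m2 <- read_discriminant_json(f)
  expect_equal(m2$class_means, m$class_means, tolerance = 1e-12)
  expect_equal(m2$pooled_within_covariance, m$pooled_within_covariance,
               tolerance = 1e-12)
  expect_equal(predict(m2, tab)$.pred_class, predict(m, tab)$.pred_class)
})

test_that("tidiers and autoplots expose the fitted objects", {
  tab <- gauss_feature_table(n_per_class = 20, delta = 5, informative = 2, seed = 71)
  cfg <- stepwise_config()
  sel <- stepwise_select(tab, cfg)
  m <- fit_lda(tab, sel$selected)
  cv <- cross_validate(tab, cfg)
  td <- tidy(m)
  expect_true(all(c("class_label", "feature", "mean") %in% names(td)))
  expect_equal(nrow(td), 2 * length(m$selected_features))
  g <- glance(m)
  expect_equal(g$n_classes, 2)
  ta <- tidy(cv)
  expect_equal(sum(ta$count), sum(cv$counts))
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(m, tab), "ggplot")
  expect_equal(tidy(sel), sel$log)
})
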