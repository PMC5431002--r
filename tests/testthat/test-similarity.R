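test_that("normalization z-scores columns and survives degenerate features", {
  set.seed(1)
  m <- matrix(rnorm(10 * 44, mean = 5, sd = 3), 10, 44,
              dimnames = list(NULL, feature_names()))
  m[, 7] <- 2.5                       # constant column
  norm <- normalize_features(m)
  expect_false(anyNA(norm$z))
  expect_equal(unname(colMeans(norm$z)), rep(0, 44), tolerance = 1e-12)
  sds <- apply(norm$z, 2, sd)
  expect_equal(unname(sds[-7]), rep(1, 43), tolerance = 1e-12)
  expect_equal(unname(norm$z[, 7]), rep(0, 10))
  expect_equal(unname(norm$sds[7]), 1)
  # re-applying the stored constants reproduces the matrix exactly
  z2 <- sweep(sweep(m, 2, norm$means), 2, norm$sds, "/")
  z2[, 7] <- 0
  expect_equal(z2, norm$z)
  expect_error(normalize_features(m[1, , drop = FALSE]), "at least 2")
})

test_that("PCA recovers an embedded line and keeps the basis orthonormal", {
  t_vals <- c(-2, -0.5, 0.3, 1.1, 2.6)
  m <- matrix(0, length(t_vals), 44)
  m[, 3] <- t_vals
  m[, 9] <- 2 * t_vals
  pca <- fit_pca(m)
  v1 <- pca$basis[, 1]
  expect_equal(abs(v1[c(3, 9)]), c(1, 2) / sqrt(5), tolerance = 1e-10)
  expect_equal(sum(abs(v1[-c(3, 9)])), 0, tolerance = 1e-10)
  expect_gt(v1[9], 0)                    # sign rule: largest loading positive
  expect_equal(pca$explained[1], 1, tolerance = 1e-10)
  expect_equal(pca$explained[2], 0, tolerance = 1e-10)
  expect_equal(crossprod(pca$basis), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_pca(matrix(0, 5, 3)), "rank 0")
})

test_that("PCA explained shares are near-equal for an isotropic cloud", {
  set.seed(8)
  m <- matrix(rnorm(3000 * 44), 3000, 44)
  pca <- fit_pca(m)
  # finite-sample top eigenvalues sit slightly above 1/p (Marchenko-Pastur)
  expect_equal(pca$explained[1], 1 / 44, tolerance = 0.3)
  expect_equal(pca$explained[2], 1 / 44, tolerance = 0.3)
})

test_that("one-class SVM honours the nu bound and rejects far points", {
  set.seed(12)
  train <- matrix(rnorm(400), 200, 2)
  m <- fit_ocsvm(train)
  frac_out <- mean(ocsvm_decision(m, train) < 0)
  expect_lte(frac_out, 0.05 + 2 / sqrt(200))
  expect_lt(ocsvm_decision(m, c(1e4, 1e4)), 0)
  expect_warning(deg <- fit_ocsvm(matrix(1, 5, 2)), "degenerate")
  expect_true(all(ocsvm_decision(deg, matrix(rnorm(10), 5, 2)) >= 0))
})

test_that("one-class decision region is connected and contains the origin", {
  set.seed(13)
  m <- fit_ocsvm(matrix(rnorm(100), 50, 2))
  gx <- seq(-4, 4, length.out = 55)
  inside <- matrix(ocsvm_decision(m, as.matrix(expand.grid(gx, gx))) >= 0,
                   55, 55)
  expect_true(inside[28, 28])           # origin
  # flood fill from the origin must reach every inside cell
  lab <- matrix(FALSE, 55, 55)
  stack <- list(c(28, 28))
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- p[1]; j <- p[2]
    if (i < 1 || i > 55 || j < 1 || j > 55 || lab[i, j] || !inside[i, j]) next
    lab[i, j] <- TRUE
    stack <- c(stack, list(c(i + 1, j), c(i - 1, j), c(i, j + 1),
                           c(i, j - 1)))
  }
  expect_identical(sum(lab), sum(inside))
})

test_that("the per-animal pipeline classifies stored-order-invariantly", {
  ft <- random_feature_table(3, 8, 2)
  a1 <- ft[ft$animal_id == "a01", ]
  model <- fit_animal_model(a1)
  own <- classify_seizures(model, a1[, feature_names()])
  expect_gte(mean(own[a1$label == "spontaneous"]), 1 - 0.05 - 2 / sqrt(8))
  # permuting the row order of the query never changes per-row results
  perm <- sample(nrow(ft))
  r1 <- classify_seizures(model, ft[, feature_names()])
  r2 <- classify_seizures(model, ft[perm, feature_names()])
  expect_identical(r2, r1[perm])
  # a distant animal's cluster is rejected
  a3 <- ft[ft$animal_id == "a03", feature_names()]
  expect_lte(mean(classify_seizures(model, a3)), 0.5)
})

test_that("similarity report pools permutations and matches printed-count arithmetic", {
  ft <- random_feature_table(3, n_spont = 6, n_induced = 2)
  models <- lapply(split(ft, ft$animal_id), fit_animal_model)
  rep <- suppressWarnings(similarity_report(models, ft))
  tab <- rep$table
  own_sp <- tab[tab$group == "spontaneous" & tab$comparison == "own", ]
  oth_sp <- tab[tab$group == "spontaneous" & tab$comparison == "other", ]
  expect_equal(own_sp$n, 18)            # 3 animals x 6 own spontaneous
  expect_equal(oth_sp$n, 36)            # sum_j sum_{i != j} n_i
  oth_kcl <- tab[tab$group == "kcl_reuniens" & tab$comparison == "other", ]
  expect_equal(oth_kcl$n, 12)
  expect_equal(own_sp$p, 1)             # gold standard against itself
  expect_equal(tab$uncertainty, sqrt(tab$k) / tab$n)
  expect_identical(nrow(rep$per_seizure), 3L * nrow(ft))
  # the p column is proportion_test against the own-spontaneous proportion
  kcl_own <- tab[tab$group == "kcl_reuniens" & tab$comparison == "own", ]
  expect_equal(kcl_own$p,
               proportion_test(own_sp$k, own_sp$n, kcl_own$k, kcl_own$n)$p)
})

test_that("nearly identical seizures classify as similar at about 1 - nu", {
  ft <- random_feature_table(2, n_spont = 30, spread = 1e-4, seed = 77)
  a1 <- ft[ft$animal_id == "a01", ]
  model <- suppressWarnings(fit_animal_model(a1))
  own <- classify_seizures(model, a1[, feature_names()])
  expect_gte(mean(own), 1 - 0.05 - 2 / sqrt(30))
})

test_that("seizure selection keeps two induced and ten consecutive spontaneous", {
  meta <- data.frame(
    animal_id = "a1",
    label = c(rep("spontaneous", 14), rep("kcl_reuniens", 3), "kainic_acid"),
    time_h = c(-30, -20, -10, -5, -4, 1, 2, 3, 7, 8, 9, 10, 11, 12,
               0.5, 1.0, 1.5, 20),
    stringsAsFactors = FALSE)
  meta$seizure_id <- seq_len(nrow(meta))
  sel <- select_seizures(meta)
  sp <- sel[sel$label == "spontaneous", ]
  # seizures inside (-3 h, 6 h) around the experiment are ineligible
  expect_false(any(sp$time_h > -3 & sp$time_h < 6))
  expect_lte(nrow(sp), 10)
  expect_identical(nrow(sel[sel$label == "kcl_reuniens", ]), 2L)
  expect_identical(nrow(sel[sel$label == "kainic_acid", ]), 1L)
})
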