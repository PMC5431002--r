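#' Z-score a feature matrix using an animal's own seizures
#'
#' Column-wise z-scores using the mean and (sample) standard deviation of
#' the supplied seizures.  Zero-variance columns are set to 0 and their SD
#' recorded as 1, so the stored constants can be re-applied to new data
#' without producing NaN.
#'
#' @param features numeric matrix or data.frame of feature rows (one row per
#'   seizure, 44 columns in [feature_names()] order); at least 2 rows.
#' @return list with `z` (matrix), `means`, `sds`.
#' @export
normalize_features <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 2)
    stop("need at least 2 seizures to normalize", call. = FALSE)
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  sds[degenerate] <- 1
  z <- sweep(sweep(m, 2, means), 2, sds, "/")
  z[, degenerate] <- 0
  list(z = z, means = means, sds = sds)
}

#' First two principal components of a z-scored feature matrix
#'
#' Eigen-decomposition of the sample covariance of the (already z-scored)
#' matrix, i.e. correlation-matrix PCA of the raw features.  Components are
#' returned in descending eigenvalue order with a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param z z-scored matrix from [normalize_features()], >= 2 rows.
#' @param n_components number of components to keep (default 2).
#' @return list with `basis` (columns are orthonormal loading vectors) and
#'   `explained` (explained-variance shares).
#' @export
fit_pca <- function(z, n_components = 2) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need at least 2 rows for PCA", call. = FALSE)
  zc <- sweep(z, 2, colMeans(z))
  cv <- crossprod(zc) / (nrow(z) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  if (all(eig$values <= 1e-12))
    stop("feature matrix has rank 0; PCA undefined", call. = FALSE)
  k <- min(n_components, ncol(z))
  basis <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  total <- sum(pmax(eig$values, 0))
  list(basis = basis, explained = pmax(eig$values[seq_len(k)], 0) / total)
}

#' Fit a one-class SVM to the spontaneous-seizure cloud
#'
#' The nu formulation of the one-class SVM with a radial-basis kernel
#' `K(x, z) = exp(-||x - z||^2 / s^2)`: the study's "outlier fraction"
#' maps to `nu` (default 0.05, so at most ~5% of training points fall
#' outside the learned support), and the "kernel scale" to `s` (default
#' 50).  A point is "similar" when the decision function
#' `f(x) = sum_i alpha_i K(x, sv_i) - rho` is non-negative.  Fitting is
#' delegated to the libsvm solver in e1071 (KKT tolerance 1e-6).
#'
#' @param train numeric matrix of training points (rows), typically the
#'   first two principal-component scores of the spontaneous seizures;
#'   >= 2 rows.
#' @param nu training outlier fraction bound (default 0.05).
#' @param kernel_scale RBF scale `s` (default 50).
#' @return An object of class `ocsvm`.
#' @export
fit_ocsvm <- function(train, nu = 0.05, kernel_scale = 50) {
  train <- as.matrix(train)
  if (nrow(train) < 2)
    stop("need at least 2 training points", call. = FALSE)
  if (max(apply(train, 2, function(col) diff(range(col)))) < 1e-12) {
    warning("all training points identical; one-class boundary is ",
            "degenerate, every point will be classified as similar",
            call. = FALSE)
    return(structure(list(fit = NULL, nu = nu, kernel_scale = kernel_scale,
                          dim = ncol(train)), class = "ocsvm"))
  }
  fit <- tryCatch(
    e1071::svm(train, y = NULL, type = "one-classification",
               kernel = "radial", gamma = 1 / kernel_scale^2, nu = nu,
               scale = FALSE, tolerance = 1e-6),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("degenerate training set; one-class fit collapsed, ",
            "all points will be classified as similar", call. = FALSE)
    return(structure(list(fit = NULL, nu = nu, kernel_scale = kernel_scale,
                          dim = ncol(train)), class = "ocsvm"))
  }
  structure(list(fit = fit, nu = nu, kernel_scale = kernel_scale,
                 dim = ncol(train)), class = "ocsvm")
}

#' Decision values of a one-class SVM
#'
#' @param model an [fit_ocsvm()] result.
#' @param points numeric matrix of points (rows).
#' @return Numeric decision values `f(x)`; `f >= 0` means "similar".
#' @export
ocsvm_decision <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = model$dim)
  if (is.null(model$fit)) return(rep(0, nrow(points)))
  pr <- stats::predict(model$fit, points, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

#' @export
print.ocsvm <- function(x, ...) {
  nsv <- if (is.null(x$fit)) 0L else nrow(x$fit$SV)
  cat(sprintf("<ocsvm> nu = %g, kernel scale = %g, %d support vector(s)\n",
              x$nu, x$kernel_scale, nsv))
  invisible(x)
}

#' Fit one animal's seizure-similarity model
#'
#' Chains the per-animal pipeline: z-score the features using that animal's
#' seizures (by default all of them, spontaneous and induced alike), project
#' onto the first two principal components, and fit a one-class SVM to the
#' spontaneous seizures only.
#'
#' @param features data.frame for one animal with columns `animal_id`,
#'   `label` and the 44 canonical feature columns ([feature_table()] rows).
#' @param normalize_on `"all"` (default) to compute normalization and PCA
#'   constants from all of the animal's seizures, or `"spontaneous"` to use
#'   only the spontaneous ones.
#' @param nu,kernel_scale one-class SVM parameters, see [fit_ocsvm()].
#' @param n_components number of principal components (default 2).
#' @return An object of class `animal_model`.
#' @export
fit_animal_model <- function(features, normalize_on = c("all", "spontaneous"),
                             nu = 0.05, kernel_scale = 50, n_components = 2) {
  normalize_on <- match.arg(normalize_on)
  stopifnot(length(unique(features$animal_id)) == 1)
  fn <- feature_names()
  spont <- features$label == "spontaneous"
  if (sum(spont) < 2)
    stop("need at least 2 spontaneous seizures to fit a model", call. = FALSE)
  base <- if (normalize_on == "all") features else features[spont, ]
  norm <- normalize_features(base[, fn])
  pca <- fit_pca(norm$z, n_components)
  z_spont <- sweep(sweep(as.matrix(features[spont, fn]), 2, norm$means),
                   2, norm$sds, "/")
  pc_spont <- z_spont %*% pca$basis
  structure(
    list(animal_id = features$animal_id[1], means = norm$means,
         sds = norm$sds, basis = pca$basis, explained = pca$explained,
         ocsvm = fit_ocsvm(pc_spont, nu, kernel_scale),
         n_spontaneous = sum(spont)),
    class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  cat(sprintf(
    "<animal_model> animal %s: %d spontaneous seizures, PC1+PC2 explain %.0f%%\n",
    x$animal_id, x$n_spontaneous, 100 * sum(x$explained)))
  invisible(x)
}

#' Project feature rows into an animal model's component space
#'
#' @param model an [fit_animal_model()] result.
#' @param features numeric matrix/data.frame of 44-feature rows (or a single
#'   named vector).
#' @return Matrix of principal-component scores.
#' @export
project_features <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  m <- as.matrix(as.data.frame(features)[, names(model$means)])
  z <- sweep(sweep(m, 2, model$means), 2, model$sds, "/")
  z %*% model$basis
}

#' Classify seizures as similar to an animal's spontaneous seizures
#'
#' Applies the animal's stored normalization constants and PCA basis, then
#' the trained one-class decision function.  Works for the animal's own
#' seizures and for other animals' seizures alike.
#'
#' @param model an [fit_animal_model()] result.
#' @param features 44-feature rows (matrix, data.frame or single named
#'   vector).
#' @return Logical vector: `TRUE` where the seizure falls inside the
#'   spontaneous-seizure support.
#' @export
classify_seizures <- function(model, features) {
  ocsvm_decision(model$ocsvm, project_features(model, features)) >= 0
}

#' Similarity report across groups and animals
#'
#' For every seizure group (spontaneous, KCl-reuniens, kainic acid,
#' electrical) tabulates the proportion classified as similar to (A) the
#' same animal's spontaneous seizures and (B) other animals' spontaneous
#' seizures, pooling all cross-animal permutations (each seizure is
#' evaluated against every other animal's model).  Proportions carry
#' Poisson uncertainties `sqrt(k)/n` and are compared with the
#' own-spontaneous gold standard by [proportion_test()].
#'
#' @param models named list of [fit_animal_model()] objects (names are
#'   animal ids).
#' @param features [feature_table()] data.frame for all seizures of all
#'   animals.
#' @return An object of class `similarity_report`: list with `table`
#'   (group x comparison summary) and `per_seizure` (one row per
#'   seizure-model evaluation).
#' @export
similarity_report <- function(models, features) {
  if (!length(models)) stop("no animal models supplied", call. = FALSE)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "animal_id")
  evals <- list()
  for (mid in names(models)) {
    sim <- classify_seizures(models[[mid]], features[, feature_names()])
    evals[[mid]] <- data.frame(
      model_animal = mid, animal_id = features$animal_id,
      seizure_id = features$seizure_id, label = features$label,
      own = features$animal_id == mid, similar = sim,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, evals)
  rownames(per) <- NULL

  groups <- c("spontaneous", "kcl_reuniens", "kainic_acid", "electrical")
  gold <- per[per$label == "spontaneous" & per$own, ]
  k0 <- sum(gold$similar); n0 <- nrow(gold)
  rows <- list()
  for (g in groups) {
    for (comp in c("own", "other")) {
      sel <- per$label == g & (if (comp == "own") per$own else !per$own)
      n <- sum(sel)
      if (n == 0) {
        warning(sprintf("no %s/%s seizure evaluations; group omitted",
                        g, comp), call. = FALSE)
        next
      }
      k <- sum(per$similar[sel])
      pt <- proportion_test(k0, n0, k, n)
      rows[[paste(g, comp)]] <- data.frame(
        group = g, comparison = comp, k = k, n = n,
        proportion = k / n, uncertainty = sqrt(k) / n,
        chi2 = pt$chi2, p = pt$p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, per_seizure = per),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  tab <- x$table
  tab$proportion <- sprintf("%.2f+/-%.2f", tab$proportion, tab$uncertainty)
  print(tab[, c("group", "comparison", "proportion", "n", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Select seizures for the similarity analysis
#'
#' Applies the study's selection rule to a feature/metadata table: per
#' animal, the first two KCl-induced seizures and up to ten consecutive
#' spontaneous seizures, the latter restricted (when a `time_h` column of
#' seizure times relative to the experiment is present) to seizures at
#' least 3 h before or 6 h after the experiment.
#'
#' @param features data.frame with `animal_id`, `label` and optionally
#'   `time_h`; row order is the recording order.
#' @param max_spontaneous,max_induced selection caps (defaults 10 and 2).
#' @return The selected subset of `features`, original row order.
#' @export
select_seizures <- function(features, max_spontaneous = 10, max_induced = 2) {
  keep <- logical(nrow(features))
  for (a in unique(features$animal_id)) {
    idx <- which(features$animal_id == a)
    lab <- features$label[idx]
    eligible <- rep(TRUE, length(idx))
    if ("time_h" %in% names(features)) {
      t <- features$time_h[idx]
      eligible <- lab != "spontaneous" | is.na(t) | t <= -3 | t >= 6
    }
    sp <- idx[lab == "spontaneous" & eligible]
    ind <- idx[lab == "kcl_reuniens"]
    keep[utils::head(sp, max_spontaneous)] <- TRUE
    keep[utils::head(ind, max_induced)] <- TRUE
    keep[idx[!(lab %in% c("spontaneous", "kcl_reuniens"))]] <- TRUE
  }
  features[keep, , drop = FALSE]
}
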