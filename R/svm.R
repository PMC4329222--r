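# RBF-kernel support vector machine on feature pairs.
#
# The Gaussian kernel is parameterized by the width sigma,
# K(a, b) = exp(-||a - b||^2 / sigma^2), and the soft-margin penalty C is
# the box constraint of the dual. The quadratic program is delegated to
# libsvm via e1071 (whose gamma equals 1/sigma^2); the decision function is
# recomputed here from the support vectors, dual coefficients and bias with
# the package's own kernel, so predictions depend only on stored model
# fields. Features are z-standardized with training statistics before
# fitting: the sigma grid {4, 32} is only meaningful on a common scale.

#' RBF kernel value
#'
#' `K(a, b) = exp(-||a - b||^2 / sigma^2)`; equals 1 at zero distance and
#' `exp(-1)` when `||a - b|| = sigma`.
#'
#' @param a,b Numeric vectors of equal length.
#' @param sigma Kernel width (> 0).
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(a, b, sigma) {
  if (length(a) != length(b)) stopf("kernel inputs must have equal length")
  if (!is.finite(sigma) || sigma <= 0) stopf("`sigma` must be > 0")
  exp(-sum((a - b)^2) / sigma^2)
}

# Cross-kernel matrix between row sets X (n x d) and Y (m x d).
.rbf_cross <- function(X, Y, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / sigma^2)
}

.standardize_fit <- function(X) {
  center <- colMeans(X)
  # population (1/n) standard deviation: invariant under duplicating the
  # training set, unlike the n-1 sample estimator
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale,
       z = sweep(sweep(X, 2, center), 2, scale, `/`))
}

.standardize_apply <- function(std, X) {
  sweep(sweep(X, 2, std$center), 2, std$scale, `/`)
}

# Fit a binary soft-margin RBF SVM on (already standardized) data and
# capture the dual solution. Orientation is fixed so positive decision
# scores mean class 1.
.svm_fit <- function(z, y, cost, sigma) {
  if (length(unique(y)) < 2L) stopf("both classes must be present to train")
  fit <- e1071::svm(x = z, y = factor(y, levels = c(0L, 1L)),
                    scale = FALSE, kernel = "radial",
                    gamma = 1 / sigma^2, cost = cost, tolerance = 1e-6,
                    fitted = FALSE)
  # libsvm orients decision values toward the class it encounters first in
  # the training data (fit$labels[1]); fix the sign so that positive scores
  # always mean class 1
  orient <- if (fit$levels[fit$labels[1]] == "1") 1 else -1
  list(sv = unname(as.matrix(fit$SV)), coefs = as.vector(fit$coefs),
       rho = fit$rho, sigma = sigma, cost = cost, orient = orient)
}

.svm_score <- function(model, z) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  K <- .rbf_cross(z, model$sv, model$sigma)
  model$orient * (as.vector(K %*% model$coefs) - model$rho)
}

#' SVM training configuration
#'
#' @param cost_grid Soft-margin penalties searched; default
#'   `{1, 1e1, 1e2, 1e3, 1e4}`.
#' @param sigma_grid RBF widths searched; default `{4, 32}`.
#' @param folds Stratified CV folds for grid selection (default 5).
#' @param seed Fold-assignment seed.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(cost_grid = c(1, 1e1, 1e2, 1e3, 1e4),
                       sigma_grid = c(4, 32), folds = 5L, seed = 1L) {
  if (any(cost_grid <= 0) || any(sigma_grid <= 0)) {
    stopf("all costs and sigmas must be > 0")
  }
  structure(list(cost_grid = as.double(cost_grid),
                 sigma_grid = as.double(sigma_grid),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "svm_config")
}

#' Train the RBF-SVM on a (pair of) feature columns
#'
#' Z-standardizes the features with training statistics, selects `(C,
#' sigma)` on the configured grid by stratified k-fold cross-validated
#' accuracy (ties prefer the smaller `C`, then the smaller `sigma`), and
#' refits on all training data at the chosen point.
#'
#' @param fm A [feature_matrix] (typically restricted to a feature pair).
#' @param config An [svm_config].
#' @return Object of class `cadx_svm`: feature names, standardization
#'   parameters, support vectors, dual coefficients, bias, chosen
#'   `(cost, sigma)` and the CV grid table.
#' @export
svm_train <- function(fm, config = svm_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "svm_config"))
  X <- fm$x; y <- fm$labels
  if (length(unique(y)) < 2L) stopf("both classes must be present to train")
  fold_id <- .stratified_folds(y, config$folds, config$seed)
  grid <- expand.grid(cost = config$cost_grid, sigma = config$sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  fold_split <- lapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    std <- .standardize_fit(X[tr, , drop = FALSE])
    list(ztr = std$z, zte = .standardize_apply(std, X[!tr, , drop = FALSE]),
         ytr = y[tr], yte = y[!tr])
  })
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (fs in fold_split) {
      fit <- .svm_fit(fs$ztr, fs$ytr, grid$cost[g], grid$sigma[g])
      pred <- .svm_score(fit, fs$zte) > 0
      correct <- correct + sum(pred == fs$yte)
    }
    grid$cv_accuracy[g] <- correct / length(y)
  }
  ord <- order(-grid$cv_accuracy, grid$cost, grid$sigma)
  best <- grid[ord[1], ]
  std <- .standardize_fit(X)
  fit <- .svm_fit(std$z, y, best$cost, best$sigma)
  structure(list(features = colnames(X), center = std$center,
                 scale = std$scale, fit = fit,
                 cost = best$cost, sigma = best$sigma,
                 cv_accuracy = best$cv_accuracy, cv_grid = grid,
                 n_train = length(y)),
            class = "cadx_svm")
}

#' @export
print.cadx_svm <- function(x, ...) {
  cat(sprintf(
    "<cadx_svm> features (%s), C=%g, sigma=%g, %d SV, CV accuracy %.1f%%\n",
    paste(x$features, collapse = ", "), x$cost, x$sigma,
    nrow(x$fit$sv), 100 * x$cv_accuracy))
  invisible(x)
}

# Internal: scores for a raw (unstandardized) feature matrix.
.model_scores <- function(model, X) {
  z <- .standardize_apply(list(center = model$center, scale = model$scale), X)
  .svm_score(model$fit, z)
}

#' Classify one slice descriptor
#'
#' @param model A [svm_train()ed][svm_train] `cadx_svm`.
#' @param features Named numeric vector (or 1-row matrix) containing at
#'   least the model's feature names.
#' @return List with `label` (0/1; 1 = nodule) and `score` (signed decision
#'   value, positive = nodule).
#' @export
predict_slice <- function(model, features) {
  stopifnot(inherits(model, "cadx_svm"))
  if (is.matrix(features)) features <- features[1, ]
  missing <- setdiff(model$features, names(features))
  if (length(missing) > 0L) {
    stopf("missing feature(s): %s", paste(missing, collapse = ", "))
  }
  s <- .model_scores(model, matrix(as.double(features[model$features]),
                                   nrow = 1))
  list(label = as.integer(s > 0), score = s)
}

#' Classify a whole scan from its slice descriptors
#'
#' Slice decisions are aggregated with a logical OR: the scan is marked
#' cancerous iff at least one slice is.
#'
#' @param model A `cadx_svm`.
#' @param features Numeric matrix, one row per slice, columns containing the
#'   model's feature names.
#' @return List with `scan_label` (0/1), `slice_labels`, `scores`.
#' @export
predict_scan <- function(model, features) {
  stopifnot(inherits(model, "cadx_svm"))
  features <- as.matrix(features)
  if (nrow(features) < 1L) stopf("need >= 1 slice")
  missing <- setdiff(model$features, colnames(features))
  if (length(missing) > 0L) {
    stopf("missing feature(s): %s", paste(missing, collapse = ", "))
  }
  s <- .model_scores(model, features[, model$features, drop = FALSE])
  labels <- as.integer(s > 0)
  list(scan_label = as.integer(any(labels == 1L)), slice_labels = labels,
       scores = s)
}

#' Serialize / restore a trained SVM as JSON
#'
#' Persists every field the decision function needs (feature names,
#' standardization parameters, support vectors, dual coefficients, bias,
#' chosen hyperparameters).
#'
#' @param model A `cadx_svm`.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `cadx_svm` (read).
#' @export
svm_to_json <- function(model, path) {
  stopifnot(inherits(model, "cadx_svm"))
  obj <- list(features = model$features, center = unname(model$center),
              scale = unname(model$scale), sv = model$fit$sv,
              coefs = model$fit$coefs, rho = model$fit$rho,
              orient = model$fit$orient, cost = model$cost,
              sigma = model$sigma, cv_accuracy = model$cv_accuracy,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname svm_to_json
#' @export
svm_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = o$features,
                 center = stats::setNames(o$center, o$features),
                 scale = stats::setNames(o$scale, o$features),
                 fit = list(sv = matrix(as.double(as.matrix(o$sv)),
                                        ncol = length(o$features)),
                            coefs = o$coefs, rho = o$rho, sigma = o$sigma,
                            cost = o$cost, orient = o$orient),
                 cost = o$cost, sigma = o$sigma,
                 cv_accuracy = o$cv_accuracy, n_train = o$n_train),
            class = "cadx_svm")
}
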