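#' Ridge-penalized logistic regression by Newton iteration.
#'
#' Minimizes  -sum_i [y_i log p_i + (1-y_i) log(1-p_i)] + lambda/2 * ||w||^2
#' over standardized predictors, intercept unpenalized. Fully deterministic:
#' zero start, full Newton steps with step halving on objective increase,
#' convergence when the max coefficient update falls below `tol`.
#' @param z standardized design matrix (no intercept column)
#' @param y 0/1 response
#' @noRd
ridge_logistic_irls <- function(z, y, lambda = 1.0, tol = 1e-6, max_iter = 100) {
  n <- nrow(z)
  p <- ncol(z)
  beta <- numeric(p + 1)                       # (intercept, w)
  zi <- cbind(1, z)
  pen_mask <- c(0, rep(1, p))
  objective <- function(b) {
    eta <- drop(zi %*% b)
    # log(1 + exp(eta)) - y*eta, numerically stable
    ll <- sum(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
    ll + lambda / 2 * sum((b * pen_mask)^2)
  }
  obj <- objective(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(zi %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(zi, mu - y)) + lambda * pen_mask * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    hess <- crossprod(zi * w, zi) + lambda * diag(pen_mask)
    delta <- solve(hess, grad)
    step <- 1
    repeat {
      cand <- beta - step * delta
      obj_cand <- objective(cand)
      if (obj_cand <= obj + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    moved <- max(abs(step * delta))
    beta <- cand
    obj <- obj_cand
    if (moved < tol) { converged <- TRUE; break }
  }
  list(intercept = beta[1], w = beta[-1], converged = converged,
       n_iter = iter, objective = obj)
}

#' Fit the per-sample logistic refit model
#'
#' The model retrained de novo for each test sample: an L2-regularized
#' (ridge) logistic regression on a given ordered feature list, fit on
#' discovery data. Features are standardized to zero mean / unit variance
#' using training statistics; the penalty (strength `lambda`, intercept
#' unpenalized) is applied on the standardized scale. Coefficients on the
#' original log10 scale are recoverable through the stored standardization
#' and reported by [tidy()]. The fit is a deterministic function of its
#' inputs.
#'
#' @param train A complete log10-state [quant_matrix()] — apply the
#'   completeness filter and one-time KNN imputation (or restrict to
#'   complete cases) first; missing values here are an error.
#' @param labels Binary class labels; the second factor level is scored as
#'   the positive class.
#' @param features Ordered protein list, a subset of `train`'s proteins.
#' @param lambda Ridge penalty strength (default 1.0).
#' @param min_features Refuse to fit with fewer usable features (default 3);
#'   features constant in training are dropped with a warning.
#' @param tol,max_iter Newton convergence controls.
#' @return An object of class `sslr_fit` with [predict()], [tidy()] and
#'   [glance()] methods.
#' @export
fit_single_sample_model <- function(train, labels, features, lambda = 1.0,
                                    min_features = 3, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(train, "quant_matrix"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) abort("fit_single_sample_model() needs exactly two classes.")
  if (length(labels) != nrow(train$values)) abort("One label per sample required.")
  missing_feat <- setdiff(features, colnames(train$values))
  if (length(missing_feat) > 0) {
    abort(paste0("Features absent from training matrix: ",
                 paste(head(missing_feat, 5), collapse = ", ")))
  }
  x <- train$values[, features, drop = FALSE]
  if (anyNA(x)) {
    abort("Training values on the requested features contain missing entries; impute the training matrix (one-time) or restrict to complete cases first.")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Dropping features constant in training: ",
                paste(features[sds == 0], collapse = ", ")))
    features <- features[sds > 0]
    x <- x[, features, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (length(features) < min_features) {
    abort(paste0("Only ", length(features), " usable features; at least ",
                 min_features, " required."),
          class = "adaptms_insufficient_features")
  }
  ctr <- colMeans(x)
  z <- scale(x, center = ctr, scale = sds)
  y <- as.numeric(labels == levels(labels)[2])
  fit <- ridge_logistic_irls(z, y, lambda = lambda, tol = tol, max_iter = max_iter)
  structure(list(
    features = features, center = ctr, scale = sds,
    intercept = fit$intercept, w = fit$w, lambda = lambda,
    classes = levels(labels), converged = fit$converged,
    n_iter = fit$n_iter, n_train = nrow(x)
  ), class = "sslr_fit")
}

#' @export
print.sslr_fit <- function(x, ...) {
  cat(sprintf("<sslr_fit> ridge logistic (%s vs %s), %d features, lambda = %g\n",
              x$classes[2], x$classes[1], length(x$features), x$lambda))
  invisible(x)
}

#' Score new observations with a per-sample refit model
#'
#' @param object An `sslr_fit`.
#' @param newdata Named numeric vector of log10 intensities, or a matrix with
#'   the model's features as columns; values must be observed (no NA).
#' @param ... Ignored.
#' @return Probability of the positive (second) class, one per observation.
#' @export
predict.sslr_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  if (!all(object$features %in% colnames(newdata))) {
    abort("`newdata` must provide every model feature.")
  }
  x <- newdata[, object$features, drop = FALSE]
  if (anyNA(x)) abort("Missing values in `newdata`; the refit model scores observed values only.")
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  drop(stats::plogis(object$intercept + z %*% object$w))
}

#' @describeIn fit_single_sample_model coefficients per feature, on both the
#'   standardized and the original log10 scale.
#' @param x An `sslr_fit`.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.sslr_fit <- function(x, ...) {
  beta_orig <- x$w / x$scale
  tibble::tibble(
    term = c("(Intercept)", x$features),
    estimate = c(x$intercept - sum(x$w * x$center / x$scale), unname(beta_orig)),
    estimate_std = c(x$intercept, unname(x$w))
  )
}

#' @describeIn fit_single_sample_model one-row fit summary.
#' @exportS3Method generics::glance
glance.sslr_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features), n_train = x$n_train,
    lambda = x$lambda, converged = x$converged, n_iter = x$n_iter
  )
}
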