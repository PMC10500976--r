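#' Principal component analysis of a feature series
#'
#' Mean-subtracted singular value decomposition: the principal components
#' are the right-singular vectors, candidate linear collective variables.
#' Angular columns are recentred about their circular mean and mapped to
#' `(-pi, pi]` before the SVD, so a cluster of angles straddling the
#' periodic boundary is not torn apart; PCA itself then treats them as
#' plain reals. Component signs follow the deterministic convention that
#' the largest-magnitude loading is positive. By default mixed-unit
#' features are not standardized; set `scale = TRUE` to z-score them.
#'
#' @param features feature tibble or numeric matrix (>= 2 rows).
#' @param scale z-score columns before the SVD (default `FALSE`).
#' @return object of class `pca_model`: `mean` (post-recentring column
#'   means), `rotation` (d x d orthonormal PC columns), `singular_values`
#'   (descending), `circular_shift` (per-column circular means removed),
#'   `scale`, `names`, `n`.
#' @export
pca_fit <- function(features, scale = FALSE) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(X) < 2) abort("PCA needs at least 2 frames.")
  ang <- if (is.matrix(features)) rep(FALSE, ncol(X)) else unname(angular_mask(features))
  shift <- numeric(ncol(X))
  for (j in which(ang)) {
    cm <- atan2(mean(sin(X[, j])), mean(cos(X[, j])))
    d <- (X[, j] - cm) %% (2 * pi)
    X[, j] <- ifelse(d > pi, d - 2 * pi, d)
    shift[j] <- cm
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sdv <- rep(1, ncol(X))
  if (scale) {
    sdv <- apply(Xc, 2, sd)
    if (any(sdv == 0)) abort("cannot standardize a constant column.")
    Xc <- sweep(Xc, 2, sdv, "/")
  }
  sv <- svd(Xc)
  if (max(sv$d) <= 1e-12 * nrow(X)) warn("constant data: all singular values are 0.")
  V <- apply(sv$v, 2, function(v) if (v[which.max(abs(v))] < 0) -v else v)
  V <- matrix(V, ncol = ncol(X))
  cn <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  rownames(V) <- cn
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(list(mean = stats::setNames(mu, cn), rotation = V,
                 singular_values = sv$d, circular_shift = shift,
                 is_angular = ang, scale = sdv, scaled = scale,
                 names = cn, n = nrow(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> d=", length(x$names), " n=", x$n, "\n  singular values: ",
      paste(sprintf("%.3g", head(x$singular_values, 6)), collapse = " "),
      if (length(x$singular_values) > 6) " ..." else "", "\n", sep = "")
  invisible(x)
}

pca_prepare <- function(model, X) {
  for (j in which(model$is_angular)) {
    d <- (X[, j] - model$circular_shift[j]) %% (2 * pi)
    X[, j] <- ifelse(d > pi, d - 2 * pi, d)
  }
  Xc <- sweep(X, 2, model$mean)
  if (model$scaled) Xc <- sweep(Xc, 2, model$scale, "/")
  Xc
}

#' Principal-component coefficients of each frame
#'
#' Projects the (recentred) feature rows onto principal component `j`
#' (or all components when `j` is `NULL`).
#'
#' @param features feature tibble or matrix compatible with the model.
#' @param model a [pca_fit()] model.
#' @param j PC index, or `NULL` for all.
#' @return numeric vector (single `j`) or tibble `frame`, `PC1`, ...
#' @export
pc_coefficients <- function(features, model, j = NULL) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (ncol(X) != length(model$names)) abort("feature dimension differs from the model.")
  Xc <- pca_prepare(model, X)
  if (!is.null(j)) {
    if (j < 1 || j > ncol(model$rotation)) abort("PC index out of range.")
    return(as.numeric(Xc %*% model$rotation[, j]))
  }
  S <- Xc %*% model$rotation
  colnames(S) <- colnames(model$rotation)
  dplyr::bind_cols(tibble::tibble(frame = seq_len(nrow(S))),
                   tibble::as_tibble(as.data.frame(S)))
}

#' @rdname pca_fit
#' @param x a `pca_model`.
#' @param ... unused.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  tb <- tibble::as_tibble(as.data.frame(x$rotation))
  dplyr::bind_cols(tibble::tibble(feature = x$names), tb) |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
}

#' @rdname pca_fit
#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  s2 <- x$singular_values^2
  tibble::tibble(n = x$n, d = length(x$names),
                 var_explained_pc1 = if (sum(s2) > 0) s2[1] / sum(s2) else NA_real_,
                 sigma_1 = x$singular_values[1])
}

#' Pearson correlation of two scalar series
#'
#' `cov(C, D) / (sd(C) sd(D))`; errors on zero variance rather than
#' returning `NA`, since a constant candidate CV carries no signal.
#'
#' @param c_series,d_series numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(c_series, d_series) {
  if (length(c_series) != length(d_series)) abort("series differ in length.")
  if (length(c_series) < 2) abort("need at least 2 observations.")
  if (sd(c_series) == 0 || sd(d_series) == 0) {
    abort("correlation undefined for a zero-variance series.")
  }
  cor(c_series, d_series)
}

#' Correlate candidate collective variables with diffusion coordinates
#'
#' Computes `|rho|` between every candidate CV column and every diffusion
#' coordinate, and ranks candidates by their best correlation (ties broken
#' by declaration order). Because only magnitudes enter, the ranking is
#' invariant to eigenvector sign flips of the diffusion map. Zero-variance
#' CVs are reported as `NA` with a warning.
#'
#' @param cvs data frame of candidate CV series (a `frame` column is
#'   ignored), e.g. internal coordinates joined with PC coefficients.
#' @param dcs data frame of diffusion coordinates (`frame` ignored), e.g.
#'   `tidy(diffusion_map(...))`.
#' @return tibble of class `cv_correlation`: one row per CV with one
#'   `abs_cor_<DC>` column per DC, `best_dc`, `best_abs_cor`, `rank`.
#' @export
correlation_table <- function(cvs, dcs) {
  cv_m <- as.matrix(cvs[, setdiff(names(cvs), c("frame", "energy", "run")),
                        drop = FALSE])
  dc_m <- as.matrix(dcs[, setdiff(names(dcs), "frame"), drop = FALSE])
  if (nrow(cv_m) != nrow(dc_m)) abort("CV and DC series differ in length.")
  res <- matrix(NA_real_, ncol(cv_m), ncol(dc_m),
                dimnames = list(colnames(cv_m), colnames(dc_m)))
  bad <- character()
  for (i in seq_len(ncol(cv_m))) {
    if (sd(cv_m[, i]) == 0) { bad <- c(bad, colnames(cv_m)[i]); next }
    for (j in seq_len(ncol(dc_m))) {
      res[i, j] <- abs(pearson_correlation(cv_m[, i], dc_m[, j]))
    }
  }
  if (length(bad)) {
    warn(paste0("zero-variance CVs reported as NA: ",
                paste(bad, collapse = ", ")))
  }
  out <- tibble::as_tibble(as.data.frame(res))
  names(out) <- paste0("abs_cor_", names(out))
  out <- dplyr::bind_cols(tibble::tibble(cv = rownames(res)), out)
  best <- apply(res, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  best_dc <- colnames(res)[apply(res, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })]
  out$best_dc <- best_dc
  out$best_abs_cor <- best
  # stable ranking: declaration order breaks ties
  ord <- order(-ifelse(is.na(best), -Inf, best), seq_along(best))
  out$rank <- match(seq_along(best), ord)
  class(out) <- c("cv_correlation", class(out))
  out
}

#' @rdname correlation_table
#' @param x a `cv_correlation`.
#' @param ... unused.
#' @method tidy cv_correlation
#' @export
tidy.cv_correlation <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::starts_with("abs_cor_"),
                      names_to = "dc", names_prefix = "abs_cor_",
                      values_to = "abs_cor")
}

#' @rdname correlation_table
#' @param object a `cv_correlation`.
#' @method autoplot cv_correlation
#' @export
autoplot.cv_correlation <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$dc, .data$cv, fill = .data$abs_cor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = "|Pearson correlation| of CVs with DCs",
                  x = NULL, y = NULL, fill = "|rho|")
}

#' Compare normalized singular-value decay of two sample sets
#'
#' Divides each set's singular values by its largest, so the leading value
#' is 1 in both; a faster decay signals samples concentrated along a
#' lower-dimensional path (e.g. a minimum-energy path) rather than
#' spread through a basin.
#'
#' @param x_a,x_b feature tibbles or matrices.
#' @param names labels for the two sets.
#' @return tibble `set`, `index`, `sigma`, `sigma_norm`.
#' @export
singular_value_decay <- function(x_a, x_b, names = c("a", "b")) {
  one <- function(X, nm) {
    m <- pca_fit(X)
    s <- m$singular_values
    if (s[1] <= 0) abort("zero leading singular value.")
    tibble::tibble(set = nm, index = seq_along(s), sigma = s,
                   sigma_norm = s / s[1])
  }
  dplyr::bind_rows(one(x_a, names[1]), one(x_b, names[2]))
}
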