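#' Assign snapshots to reactant/product basins by reference proximity
#'
#' A snapshot belongs to basin A (reactant) when its wrapped feature
#' distance to the reactant reference is at most `cutoff`, likewise for
#' basin B (product); a snapshot within both cutoffs is resolved to the
#' nearer reference. A and B are therefore disjoint by construction.
#'
#' @param features feature tibble or matrix.
#' @param reactant_ref,product_ref reference feature vectors.
#' @param cutoff positive distance threshold.
#' @return list of class `basin_spec` with integer index sets `A`, `B`,
#'   the references, and `cutoff`.
#' @export
define_basins <- function(features, reactant_ref, product_ref, cutoff) {
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  X <- if (is.matrix(features)) features else feature_matrix(features)
  ang <- if (is.matrix(features)) rep(FALSE, ncol(X)) else unname(angular_mask(features))
  da <- feature_distance_matrix(X, matrix(as.numeric(reactant_ref), 1),
                                is_angular = ang)[, 1]
  db <- feature_distance_matrix(X, matrix(as.numeric(product_ref), 1),
                                is_angular = ang)[, 1]
  A <- which(da <= cutoff & da <= db)
  B <- which(db <= cutoff & db < da)
  if (length(A) == 0L || length(B) == 0L) {
    abort(paste0("empty basin (", length(A), " reactant / ", length(B),
                 " product frames); increase `cutoff`."))
  }
  if (length(A) + length(B) >= nrow(X)) {
    abort("basins cover every snapshot; decrease `cutoff`.")
  }
  structure(list(A = A, B = B, reactant_ref = reactant_ref,
                 product_ref = product_ref, cutoff = cutoff),
            class = "basin_spec")
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Solve the discrete committor boundary-value problem
#'
#' On the sampled graph of a diffusion map, the committor `q` satisfies
#' the generator equation `(L q)_i = 0` for every interior snapshot with
#' boundary rows clamped at `q = 0` on A and `q = 1` on B. With `P` the
#' transition matrix this is the linear system
#' `sum_j (P - I)_{ij} q_j = 0` over the complement indices, solved
#' directly (dense). For a connected kernel graph the discrete maximum
#' principle keeps interior values strictly inside (0, 1).
#'
#' @param model a `diffusion_map` (spectrum not required).
#' @param basins a [define_basins()] result, or `NULL` when `A`/`B` given.
#' @param A,B optional explicit index sets (used when `basins` is `NULL`).
#' @return object of class `committor_solution`: tibble-backed list with
#'   `q` (per-snapshot values), `basins`, `residual` (max interior
#'   |L q|), `interior` indices.
#' @export
solve_committor <- function(model, basins = NULL, A = NULL, B = NULL) {
  if (!is.null(basins)) { A <- basins$A; B <- basins$B }
  n <- model$n
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0L || length(B) == 0L) abort("A and B must be non-empty.")
  if (length(intersect(A, B))) abort("A and B must be disjoint.")
  Cc <- setdiff(seq_len(n), union(A, B))
  if (length(Cc) == 0L) abort("no interior snapshots between A and B.")
  P <- model$transition_matrix
  # connectivity of the kernel graph: every component must touch A or B
  thr <- .Machine$double.eps * n
  adj <- model$kernel > thr * max(model$kernel)
  comp <- graph_components(adj)
  bad <- setdiff(unique(comp[Cc]), unique(comp[c(A, B)]))
  if (length(bad)) {
    abort(paste0("kernel graph is disconnected: component(s) ",
                 paste(bad, collapse = ", "),
                 " contain interior snapshots but no basin members."))
  }
  Lm <- P
  diag(Lm) <- diag(Lm) - 1
  q <- numeric(n)
  q[B] <- 1
  rhs <- -rowSums(Lm[Cc, B, drop = FALSE])
  q[Cc] <- solve(Lm[Cc, Cc, drop = FALSE], rhs)
  residual <- max(abs(Lm[Cc, , drop = FALSE] %*% q))
  structure(list(
    q = q,
    frame = model$frame,
    basins = list(A = A, B = B),
    interior = Cc,
    residual = residual
  ), class = "committor_solution")
}

#' @export
print.committor_solution <- function(x, ...) {
  cat("<committor_solution> n=", length(x$q),
      " |A|=", length(x$basins$A), " |B|=", length(x$basins$B),
      sprintf(" residual=%.2e\n", x$residual), sep = "")
  invisible(x)
}

#' @rdname solve_committor
#' @param x a `committor_solution`.
#' @param ... unused.
#' @method tidy committor_solution
#' @export
tidy.committor_solution <- function(x, ...) {
  lab <- rep("interior", length(x$q))
  lab[x$basins$A] <- "A"
  lab[x$basins$B] <- "B"
  tibble::tibble(frame = x$frame, q = x$q, basin = lab)
}

#' @rdname solve_committor
#' @method glance committor_solution
#' @export
glance.committor_solution <- function(x, ...) {
  tibble::tibble(n = length(x$q), n_a = length(x$basins$A),
                 n_b = length(x$basins$B), n_interior = length(x$interior),
                 residual = x$residual,
                 q_min_interior = min(x$q[x$interior]),
                 q_max_interior = max(x$q[x$interior]))
}

#' @rdname solve_committor
#' @param object a `committor_solution`.
#' @method autoplot committor_solution
#' @export
autoplot.committor_solution <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$frame, .data$q, colour = .data$basin)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(title = "Committor per snapshot", y = "q")
}

#' Snapshots on an isocommittor band
#'
#' The `q = 0.5` isocommittor defines the transition region; this returns
#' all snapshot indices with `|q - level| <= tol` (possibly none).
#'
#' @param solution a `committor_solution` (or bare numeric `q`).
#' @param level committor level (default 0.5).
#' @param tol half-width of the band.
#' @return integer snapshot indices.
#' @export
isocommittor_band <- function(solution, level = 0.5, tol = 0.05) {
  q <- if (inherits(solution, "committor_solution")) solution$q else as.numeric(solution)
  which(abs(q - level) <= tol)
}

#' Error of a committor solution against an oracle
#'
#' Interior-point RMSE and maximum absolute error against reference
#' committor values on the same snapshots (e.g. the closed-form quadrature
#' committor or a shooting estimate).
#'
#' @param solution a `committor_solution`.
#' @param oracle_q numeric vector of reference values, one per snapshot.
#' @return tibble `rmse`, `max_error`, `n_interior`.
#' @export
committor_validation <- function(solution, oracle_q) {
  if (length(oracle_q) != length(solution$q)) {
    abort("oracle and solution differ in length.")
  }
  i <- solution$interior
  err <- solution$q[i] - oracle_q[i]
  tibble::tibble(rmse = sqrt(mean(err^2)), max_error = max(abs(err)),
                 n_interior = length(i))
}

#' Select snapshots whose other coordinates match a reference
#'
#' For 2-D committor or free-energy views one plots two CVs while holding
#' the remaining coordinates near their transition-state values; this
#' utility returns the snapshots within a per-coordinate tolerance of the
#' reference on every non-excluded coordinate (wrapped for angles).
#'
#' @param features feature tibble.
#' @param reference full-dimensional reference feature vector.
#' @param tol per-coordinate tolerance (scalar or one per coordinate).
#' @param exclude names (or indices) of the plotted coordinates, exempt
#'   from the restriction.
#' @return integer vector of snapshot indices.
#' @export
select_near_reference <- function(features, reference, tol, exclude = NULL) {
  X <- feature_matrix(features)
  ang <- unname(angular_mask(features))
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) abort("reference dimension mismatch.")
  tol <- rep_len(tol, ncol(X))
  if (any(tol <= 0)) abort("`tol` must be positive.")
  keep_dims <- seq_len(ncol(X))
  if (!is.null(exclude)) {
    idx <- if (is.character(exclude)) match(exclude, colnames(X)) else as.integer(exclude)
    if (anyNA(idx)) abort("unknown coordinate in `exclude`.")
    keep_dims <- setdiff(keep_dims, idx)
  }
  ok <- rep(TRUE, nrow(X))
  for (j in keep_dims) {
    d <- if (ang[j]) wrap_angle_difference(X[, j], reference[j])
         else abs(X[, j] - reference[j])
    ok <- ok & d <= tol[j]
  }
  which(ok)
}
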