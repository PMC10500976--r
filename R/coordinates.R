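#' Define an internal-coordinate topology
#'
#' Lists which bonds, angles and dihedrals to compute from a Cartesian
#' trajectory. Atom indices are 1-based. Each entry gets a label; defaults
#' are built from the indices (`b1-2`, `a1-2-3`, `d1-2-3-4`).
#'
#' @param bonds list of length-2 integer vectors (or 2-column matrix).
#' @param angles list of length-3 integer vectors (or 3-column matrix).
#' @param dihedrals list of length-4 integer vectors (or 4-column matrix).
#' @param names optional character labels, one per coordinate, ordered
#'   bonds, then angles, then dihedrals.
#' @return A tibble of class `ic_topology` with columns `type`, `i`, `j`,
#'   `k`, `l` (`NA` where unused) and `name`.
#' @examples
#' ic_topology(bonds = list(c(1, 2), c(1, 3)), angles = list(c(2, 1, 3)))
#' @export
ic_topology <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                        names = NULL) {
  as_rows <- function(x, len) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x <- asplit(x, 1)
    lapply(x, function(v) {
      v <- as.integer(v)
      if (length(v) != len || anyNA(v)) {
        abort(paste0("each entry must hold ", len, " atom indices."))
      }
      if (anyDuplicated(v)) abort("atom indices within one coordinate must be distinct.")
      v
    })
  }
  b <- as_rows(bonds, 2L); a <- as_rows(angles, 3L); d <- as_rows(dihedrals, 4L)
  pad <- function(v) c(v, rep(NA_integer_, 4L - length(v)))
  rows <- c(b, a, d)
  if (length(rows) == 0L) abort("topology is empty.")
  key <- vapply(rows, function(v) paste(v, collapse = "-"), character(1))
  if (anyDuplicated(key)) abort("duplicate coordinate definitions in topology.")
  m <- t(vapply(rows, pad, integer(4)))
  type <- rep(c("bond", "angle", "dihedral"), c(length(b), length(a), length(d)))
  lab <- if (!is.null(names)) {
    if (length(names) != length(rows)) abort("`names` must label every coordinate.")
    as.character(names)
  } else {
    paste0(substr(type, 1, 1),
           vapply(rows, function(v) paste(v, collapse = "-"), character(1)))
  }
  out <- tibble::tibble(type = type, i = m[, 1], j = m[, 2], k = m[, 3],
                        l = m[, 4], name = lab)
  class(out) <- c("ic_topology", class(out))
  out
}

#' Read an internal-coordinate topology from a YAML file
#'
#' The file lists 0-based atom indices under keys `bonds`, `angles`,
#' `dihedrals` (each a sequence of index sequences) and optionally `names`.
#'
#' @param path YAML file path.
#' @return An `ic_topology` tibble (1-based indices).
#' @export
read_ic_topology <- function(path) {
  y <- yaml::read_yaml(path)
  shift <- function(x) if (is.null(x)) NULL else lapply(x, function(v) as.integer(v) + 1L)
  ic_topology(bonds = shift(y$bonds), angles = shift(y$angles),
              dihedrals = shift(y$dihedrals), names = y$names)
}

vec_angle <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  acos(max(-1, min(1, sum(u * v) / (cu * cv))))
}

dihedral_angle <- function(p1, p2, p3, p4) {
  # IUPAC sign convention, range (-pi, pi]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

#' Compute internal coordinates along a trajectory
#'
#' Bond lengths are Euclidean distances (Angstrom); bond angles and
#' dihedrals are in radians. Dihedrals follow the IUPAC sign convention in
#' `(-pi, pi]`, the angular storage convention used throughout the package.
#'
#' @param traj trajectory tibble ([trajectory_tbl()]).
#' @param topo an [ic_topology()].
#' @param degenerate what to do when a collinear triple/quadruple makes an
#'   angle or dihedral undefined: `"error"` (default, names the frame and
#'   coordinate) or `"nan"` (emit `NaN` and warn once, so callers may drop
#'   the frame downstream).
#' @return A feature tibble: column `frame` plus one column per internal
#'   coordinate, with attribute `is_angular` (named logical) marking the
#'   angle/dihedral columns, and class `feature_tbl`.
#' @export
compute_internal_coordinates <- function(traj, topo,
                                         degenerate = c("error", "nan")) {
  degenerate <- match.arg(degenerate)
  na <- n_atoms(traj)
  idx <- as.matrix(topo[, c("i", "j", "k", "l")])
  if (any(idx < 1L | idx > na, na.rm = TRUE)) {
    abort("topology refers to atom indices outside the trajectory.")
  }
  frames <- sort(unique(traj$frame))
  vals <- matrix(NA_real_, length(frames), nrow(topo))
  warned <- FALSE
  for (fi in seq_along(frames)) {
    co <- frame_coords(traj, frames[fi])
    for (ci in seq_len(nrow(topo))) {
      tp <- topo$type[ci]
      v <- if (tp == "bond") {
        sqrt(sum((co[topo$i[ci], ] - co[topo$j[ci], ])^2))
      } else if (tp == "angle") {
        u <- co[topo$i[ci], ] - co[topo$j[ci], ]
        w <- co[topo$k[ci], ] - co[topo$j[ci], ]
        s <- sum((u / sqrt(sum(u^2)) + w / sqrt(sum(w^2)))^2)
        if (s < 1e-16 || sum(u^2) < 1e-20 || sum(w^2) < 1e-20) NA_real_
        else vec_angle(u, w)
      } else {
        dihedral_angle(co[topo$i[ci], ], co[topo$j[ci], ],
                       co[topo$k[ci], ], co[topo$l[ci], ])
      }
      if (is.na(v)) {
        if (degenerate == "error") {
          abort(paste0("degenerate ", tp, " '", topo$name[ci],
                       "' (collinear atoms) in frame ", frames[fi], "."))
        }
        if (!warned) {
          warn("degenerate internal coordinates emitted as NaN.")
          warned <- TRUE
        }
        v <- NaN
      }
      vals[fi, ci] <- v
    }
  }
  colnames(vals) <- topo$name
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble::tibble(frame = frames), out)
  ang <- topo$type != "bond"
  names(ang) <- topo$name
  new_feature_tbl(out, ang)
}

new_feature_tbl <- function(tbl, is_angular) {
  attr(tbl, "is_angular") <- is_angular
  class(tbl) <- unique(c("feature_tbl", class(tbl)))
  tbl
}

#' Construct a feature tibble from a numeric matrix
#'
#' @param values numeric matrix (rows = frames) or data frame.
#' @param is_angular logical mask per column (radians, convention
#'   `(-pi, pi]`); default all `FALSE`.
#' @param names optional column names.
#' @return a `feature_tbl` (column `frame` plus one column per feature).
#' @export
feature_tbl <- function(values, is_angular = NULL, names = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- names %||% paste0("f", seq_len(ncol(values)))
  }
  if (!is.null(names)) colnames(values) <- names
  ang <- is_angular %||% rep(FALSE, ncol(values))
  if (length(ang) != ncol(values)) abort("`is_angular` must mask every column.")
  names(ang) <- colnames(values)
  tbl <- dplyr::bind_cols(tibble::tibble(frame = seq_len(nrow(values))),
                          tibble::as_tibble(as.data.frame(values)))
  new_feature_tbl(tbl, ang)
}

#' Feature matrix and angular mask of a feature tibble
#'
#' The columns `frame`, `energy` and `run` are bookkeeping, not features,
#' and are excluded.
#'
#' @param features a `feature_tbl` (or any data frame whose non-metadata
#'   numeric columns are the features).
#' @return `feature_matrix()`: numeric matrix; `angular_mask()`: named
#'   logical vector (falls back to all-`FALSE` when the attribute is absent).
#' @export
feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("frame", "energy", "run"))
  as.matrix(features[, cols, drop = FALSE])
}

#' @rdname feature_matrix
#' @export
angular_mask <- function(features) {
  cols <- setdiff(names(features), c("frame", "energy", "run"))
  ang <- attr(features, "is_angular")
  if (is.null(ang)) {
    ang <- rep(FALSE, length(cols)); names(ang) <- cols
  }
  out <- ang[cols]
  out[is.na(out)] <- FALSE
  names(out) <- cols
  out
}

#' Minimal angular separation of two angles
#'
#' Angles that straddle the periodic boundary must not inflate feature
#' distances: the difference of `pi/6` and `2*pi - pi/6` is `pi/3`, not
#' `2*pi - pi/3`. Inputs are reduced mod `2*pi` first; the result is the
#' minimal absolute separation on the circle, in `[0, pi]`.
#'
#' @param theta1,theta2 angles in radians (vectorized).
#' @return separation in radians, in `[0, pi]`.
#' @examples
#' wrap_angle_difference(pi / 6, 2 * pi - pi / 6) # pi/3
#' @export
wrap_angle_difference <- function(theta1, theta2) {
  if (any(!is.finite(theta1)) || any(!is.finite(theta2))) {
    abort("angles must be finite.")
  }
  d <- abs(theta1 - theta2) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Euclidean feature distance with angular wrapping
#'
#' The L2 norm of component differences where angular components use
#' [wrap_angle_difference()].
#'
#' @param a,b numeric feature vectors of equal length.
#' @param is_angular logical mask (recycled `FALSE` when `NULL`).
#' @return non-negative scalar.
#' @export
feature_distance <- function(a, b, is_angular = NULL) {
  if (length(a) != length(b)) abort("feature vectors differ in length.")
  ang <- is_angular %||% rep(FALSE, length(a))
  d <- ifelse(ang, wrap_angle_difference(a, b), a - b)
  sqrt(sum(d^2))
}

#' All pairwise feature distances
#'
#' Computes the `n x n` matrix of wrapped Euclidean distances between the
#' rows of a feature tibble (or between its rows and those of `other`).
#'
#' @param features feature tibble or numeric matrix.
#' @param other optional second feature set; default `features`.
#' @param is_angular optional mask overriding the tibble attribute.
#' @return distance matrix.
#' @export
feature_distance_matrix <- function(features, other = NULL, is_angular = NULL) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  ang <- is_angular %||%
    (if (is.matrix(features)) rep(FALSE, ncol(X)) else unname(angular_mask(features)))
  Y <- if (is.null(other)) X else if (is.matrix(other)) other else feature_matrix(other)
  if (ncol(Y) != ncol(X)) abort("feature dimensions differ.")
  d2 <- matrix(0, nrow(X), nrow(Y))
  for (j in seq_len(ncol(X))) {
    dj <- outer(X[, j], Y[, j], "-")
    if (ang[j]) {
      dj <- abs(dj) %% (2 * pi)
      dj <- pmin(dj, 2 * pi - dj)
    }
    d2 <- d2 + dj^2
  }
  sqrt(d2)
}

kabsch_rotation <- function(P, Q) {
  # optimal rotation R (applied as row-vectors P %*% R) mapping centred P
  # onto centred Q; the det guard excludes improper reflections
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose a trajectory onto a reference frame (Kabsch)
#'
#' Rigidly rotates and translates every frame to minimise its RMSD to the
#' reference, using the Kabsch SVD solution. With fewer than 3 atoms (or a
#' collinear reference) the rotation is ill-posed; a warning is emitted and
#' only the translational fit is applied.
#'
#' @param traj trajectory tibble.
#' @param reference `n_atoms x 3` coordinate matrix (e.g. [frame_coords()]).
#' @return A list with `trajectory` (aligned trajectory tibble) and `rmsd`
#'   (tibble `frame`, `rmsd` in Angstrom).
#' @export
kabsch_align <- function(traj, reference) {
  na <- n_atoms(traj)
  if (nrow(reference) != na) abort("reference must match the trajectory's atom count.")
  refc <- scale(reference, scale = FALSE)
  ref_centre <- attr(refc, "scaled:center")
  sv_ref <- svd(refc)$d
  ill <- na < 3 || sum(sv_ref > 1e-10 * max(sv_ref, 1e-30)) < 2
  if (ill) warn("alignment ill-posed (< 3 non-collinear atoms); translation-only fit.")
  frames <- sort(unique(traj$frame))
  out_frames <- vector("list", length(frames))
  rmsd <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    co <- frame_coords(traj, frames[fi])
    cc <- scale(co, scale = FALSE)
    A <- if (ill) cc else cc %*% kabsch_rotation(cc, refc)
    A <- sweep(A, 2, ref_centre, "+")
    rmsd[fi] <- sqrt(mean(rowSums((A - reference)^2)))
    out_frames[[fi]] <- unname(A)
  }
  en <- frame_energies(traj)
  el <- frame_coords(traj, frames[1])
  aligned <- trajectory_tbl(out_frames, rownames(el), energies = en,
                            dt = attr(traj, "dt"),
                            temperature = attr(traj, "temperature"))
  list(trajectory = aligned, rmsd = tibble::tibble(frame = frames, rmsd = rmsd))
}

#' Smooth coordination number of an atom
#'
#' Counts near-equilibrium neighbours of a centre atom with a Fermi-Dirac
#' switching function: `CN = sum_j 1 / (1 + exp(kappa * (r_j - r0_j)))`.
#' Each term tends to 1 when the neighbour sits well inside its equilibrium
#' distance and to 0 when far outside, so the sum is bounded by the number
#' of neighbours and non-increasing in every `r_j`.
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param center centre atom index.
#' @param neighbors integer vector of neighbour atom indices.
#' @param r0 equilibrium distances (Angstrom), one per neighbour (recycled).
#' @param kappa switch steepness in 1/Angstrom (default 10).
#' @return scalar coordination number in `[0, length(neighbors)]`.
#' @export
coordination_number <- function(frame, center, neighbors, r0, kappa = 10) {
  if (center %in% neighbors) abort("centre atom listed among its own neighbours.")
  if (any(r0 <= 0)) abort("`r0` must be positive.")
  if (kappa <= 0) abort("`kappa` must be positive.")
  r0 <- rep_len(r0, length(neighbors))
  rj <- sqrt(rowSums((frame[neighbors, , drop = FALSE] -
                        matrix(frame[center, ], length(neighbors), 3,
                               byrow = TRUE))^2))
  sum(1 / (1 + exp(kappa * (rj - r0))))
}
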