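#' Assemble a Cartesian trajectory tibble
#'
#' A trajectory is stored in long ("tidy") form: one row per atom per frame,
#' with Cartesian coordinates in Angstrom and, when available, the potential
#' energy of the frame repeated on each of its atom rows. All downstream
#' functions accept this layout.
#'
#' @param frames list of `n_atoms x 3` coordinate matrices (Angstrom), all
#'   with the same atom count and ordering.
#' @param elements character vector of element symbols, one per atom.
#' @param energies optional numeric vector of per-frame potential energies
#'   (kept in the unit of the source data and echoed unchanged in outputs).
#' @param dt,temperature optional metadata: time step (fs) and temperature (K).
#' @return A tibble of class `md_trajectory` with columns `frame`, `atom`,
#'   `element`, `x`, `y`, `z` and (if given) `energy`.
#' @examples
#' tr <- trajectory_tbl(
#'   frames = list(rbind(c(0, 0, 0), c(1, 0, 0))),
#'   elements = c("O", "H"), energies = -1.5
#' )
#' n_frames(tr)
#' @export
trajectory_tbl <- function(frames, elements, energies = NULL,
                           dt = NULL, temperature = NULL) {
  if (!is.list(frames) || length(frames) == 0L) {
    abort("`frames` must be a non-empty list of coordinate matrices.")
  }
  na <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == na && ncol(f) == 3,
               logical(1))
  if (!all(ok)) abort("all frames must be matrices sharing n_atoms x 3 shape.")
  if (length(elements) != na) abort("`elements` must have one entry per atom.")
  if (!is.null(energies) && length(energies) != length(frames)) {
    abort("`energies` must have one entry per frame.")
  }
  nf <- length(frames)
  xyz <- do.call(rbind, frames)
  out <- tibble::tibble(
    frame = rep(seq_len(nf), each = na),
    atom = rep(seq_len(na), times = nf),
    element = rep(as.character(elements), times = nf),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  if (!is.null(energies)) out$energy <- rep(as.numeric(energies), each = na)
  attr(out, "dt") <- dt
  attr(out, "temperature") <- temperature
  class(out) <- c("md_trajectory", class(out))
  out
}

#' Number of frames / atoms in a trajectory tibble
#' @param traj trajectory tibble (see [trajectory_tbl()]).
#' @return integer count.
#' @export
n_frames <- function(traj) length(unique(traj$frame))

#' @rdname n_frames
#' @export
n_atoms <- function(traj) length(unique(traj$atom))

#' Extract one frame as a coordinate matrix
#' @param traj trajectory tibble.
#' @param i frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  fr <- traj[traj$frame == i, , drop = FALSE]
  if (nrow(fr) == 0L) abort(paste0("frame ", i, " not present in trajectory."))
  fr <- fr[order(fr$atom), , drop = FALSE]
  m <- as.matrix(fr[, c("x", "y", "z")])
  rownames(m) <- fr$element
  m
}

#' Per-frame energies of a trajectory tibble
#' @param traj trajectory tibble.
#' @return numeric vector (one value per frame) or `NULL` when absent.
#' @export
frame_energies <- function(traj) {
  if (!"energy" %in% names(traj)) return(NULL)
  e <- traj[!duplicated(traj$frame), , drop = FALSE]
  e <- e[order(e$frame), ]
  e$energy
}

#' Read an (extended-)XYZ trajectory
#'
#' Reads concatenated XYZ frames. A per-frame energy is parsed from the
#' comment line when it carries a `key=value` token named `energy`
#' (extended-XYZ convention); plain XYZ comment lines are ignored.
#'
#' @param path file path.
#' @return trajectory tibble (see [trajectory_tbl()]).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  i <- 1L
  frames <- list(); energies <- numeric(); elements <- NULL
  any_energy <- FALSE
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) abort(paste0("malformed XYZ: expected atom count at line ", i))
    comment <- lines[i + 1L]
    en <- NA_real_
    m <- regmatches(comment, regexec("(^|\\s)energy=([-+0-9.eE]+)", comment))[[1]]
    if (length(m) == 3L) { en <- as.numeric(m[3]); any_energy <- TRUE }
    block <- lines[(i + 2L):(i + 1L + na)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    energies <- c(energies, en)
    i <- i + 2L + na
  }
  trajectory_tbl(frames, elements,
                 energies = if (any_energy) energies else NULL)
}

#' Write an extended-XYZ trajectory
#'
#' Writes one XYZ block per frame; when the trajectory carries energies the
#' comment line is `energy=<value>`.
#'
#' @param traj trajectory tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  na <- n_atoms(traj)
  en <- frame_energies(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in sort(unique(traj$frame))) {
    co <- frame_coords(traj, i)
    writeLines(as.character(na), con)
    writeLines(if (is.null(en)) "" else sprintf("energy=%.10g", en[i]), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       rownames(co), co[, 1], co[, 2], co[, 3]), con)
  }
  invisible(path)
}
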