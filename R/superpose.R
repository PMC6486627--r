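# Weighted least-squares rigid superposition (Kabsch) and decomposition of
# the fitted transform into rotation angle, axis and point displacement.
# The transform convention throughout is x_b = R %*% x_a + t.

#' Pair atoms present in both of two atom sets
#'
#' Atoms are matched on (residue number, insertion code, atom name); with
#' `mode = "by-alignment"` residue numbers of `a` are first mapped through an
#' equivalence table, which is how residues of one protein are matched to the
#' corresponding residues of a homolog.
#'
#' @param a,b Atom tibbles (e.g. from [select_atoms()]).
#' @param mode `"by-residue-number"` or `"by-alignment"`.
#' @param equivalence For `"by-alignment"`: tibble with columns `resno_a`,
#'   `resno_b` mapping author numbers of `a` onto `b`.
#' @return List with `xyz_a`, `xyz_b` (n x 3 matrices in a deterministic
#'   order) and `keys` (tibble of matched residue number / atom name).
#' @export
pair_common_atoms <- function(a, b, mode = c("by-residue-number", "by-alignment"),
                              equivalence = NULL) {
  mode <- match.arg(mode)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty atom set")
  resno_a <- a$resno
  if (mode == "by-alignment") {
    if (is.null(equivalence)) stop("by-alignment mode needs an equivalence table")
    idx <- match(a$resno, equivalence$resno_a)
    resno_a <- equivalence$resno_b[idx]
  }
  key_a <- paste(resno_a, a$ins, a$atom, sep = "|")
  key_b <- paste(b$resno, b$ins, b$atom, sep = "|")
  common <- intersect(key_a, key_b)
  if (length(common) < 3) {
    stop("fewer than 3 atom pairs in common (", length(common), ")")
  }
  common <- sort(common)
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  list(
    xyz_a = cbind(x = a$x[ia], y = a$y[ia], z = a$z[ia]),
    xyz_b = cbind(x = b$x[ib], y = b$y[ib], z = b$z[ib]),
    keys = tibble::tibble(
      resno_a = a$resno[ia], resno_b = b$resno[ib],
      atom = a$atom[ia]
    )
  )
}

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising the weighted
#' sum of squared distances `sum(w * |R a + t - b|^2)` by singular value
#' decomposition of the weighted covariance matrix; a reflection in the SVD
#' solution is corrected by flipping the sign of the smallest singular
#' direction, so the result is always a genuine rotation (det = +1).
#'
#' @param pairs Pairing from [pair_common_atoms()], or a list with `xyz_a`,
#'   `xyz_b` n x 3 matrices.
#' @param weights Optional per-pair weights (e.g. atomic masses); default
#'   uniform.
#' @return Object of class `kabsch_fit`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom, root of the weighted mean
#'   squared post-fit distance), `n_pairs`, and `pairing` keys when present.
#' @export
kabsch_fit <- function(pairs, weights = NULL) {
  A <- pairs$xyz_a
  B <- pairs$xyz_b
  n <- nrow(A)
  if (is.null(n) || n < 3 || !identical(dim(A), dim(B))) {
    stop("need >= 3 coordinate pairs of equal dimension")
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))
  w <- w / sum(w)
  ca <- colSums(A * w)
  cb <- colSums(B * w)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # degenerate (collinear) configurations have a rank-deficient covariance
  # and no unique rotation; refuse rather than return an arbitrary one
  if (qr(sweep(A0, 1, sqrt(w), `*`))$rank < 2) {
    stop("degenerate (collinear) atom configuration; superposition undefined")
  }
  H <- t(A0 * w) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  resid <- B - (A %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE))
  rmsd <- sqrt(sum(w * rowSums(resid^2)))
  structure(
    list(rotation = R, translation = t_vec, rmsd = rmsd, n_pairs = n,
         pairing = pairs$keys %||% NULL),
    class = "kabsch_fit"
  )
}

#' Apply a rigid transform to coordinates or an atom table
#'
#' @param transform A `kabsch_fit` or list with `rotation` and `translation`.
#' @param x n x 3 coordinate matrix, or an atom tibble with `x`, `y`, `z`.
#' @return Object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  R <- transform$rotation
  t_vec <- transform$translation
  if (is.matrix(x)) {
    return(x %*% t(R) + matrix(t_vec, nrow(x), 3, byrow = TRUE))
  }
  xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(R) +
    matrix(t_vec, nrow(x), 3, byrow = TRUE)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

#' Center of mass of an atom set
#'
#' @param atoms Atom tibble.
#' @param weighting `"uniform"` (plain coordinate mean) or `"atomic-mass"`
#'   (standard atomic weights by element; unknown elements fall back to
#'   carbon).
#' @return Length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(atoms, weighting = c("uniform", "atomic-mass")) {
  weighting <- match.arg(weighting)
  if (nrow(atoms) == 0) stop("empty atom set")
  w <- if (weighting == "uniform") rep(1, nrow(atoms)) else {
    m <- ATOMIC_MASS[atoms$element]
    m[is.na(m)] <- ATOMIC_MASS[["C"]]
    m
  }
  as.numeric(colSums(cbind(atoms$x, atoms$y, atoms$z) * w) / sum(w))
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; `axis` is normalised internally.
#'
#' @param angle_deg Rotation angle in degrees.
#' @param axis Length-3 axis vector.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(angle_deg, axis) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Decompose a rigid transform into angle, axis and point displacement
#'
#' The rotation angle comes from the matrix trace
#' (`cos(theta) = (tr(R) - 1) / 2`, reported in `[0, 180]` degrees), the axis
#' from the antisymmetric part (eigenvector for eigenvalue 1 when the angle
#' is near 180 degrees), and the point displacement is the distance a named
#' reference point (typically a domain center of mass) moves under the full
#' transform.
#'
#' @param transform A `kabsch_fit` or list with `rotation`, `translation`.
#' @param reference_point Length-3 point whose displacement is reported.
#' @return Object of class `transform_decomposition`: list with `angle_deg`
#'   in `[0, 180]`, unit `axis`, and `displacement` (Angstrom).
#' @export
decompose_transform <- function(transform, reference_point = c(0, 0, 0)) {
  R <- transform$rotation
  t_vec <- transform$translation %||% c(0, 0, 0)
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(R %*% t(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("not a proper rotation matrix")
  }
  ct <- (sum(diag(R)) - 1) / 2
  angle <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) > 1e-8) {
    axis <- v / sqrt(sum(v^2))
  } else if (angle < 90) {
    axis <- c(0, 0, 1)  # identity: axis undefined, return a fixed convention
  } else {
    # angle ~ 180: axis from the symmetric part, sign irrelevant
    ev <- eigen(R, symmetric = FALSE)
    k <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, k])
    axis <- axis / sqrt(sum(axis^2))
  }
  p <- as.numeric(reference_point)
  disp <- sqrt(sum((as.numeric(R %*% p) + t_vec - p)^2))
  structure(
    list(angle_deg = angle, axis = axis, displacement = disp),
    class = "transform_decomposition"
  )
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("Kabsch superposition: %d pairs, rmsd %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' @export
print.transform_decomposition <- function(x, ...) {
  cat(sprintf("rotation %.3f deg about (%.3f, %.3f, %.3f); reference point moves %.3f A\n",
              x$angle_deg, x$axis[1], x$axis[2], x$axis[3], x$displacement))
  invisible(x)
}

#' @rdname tidy_helicore
#' @export
tidy.transform_decomposition <- function(x, ...) {
  tibble::tibble(
    angle_deg = x$angle_deg,
    axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
    displacement_A = x$displacement
  )
}

#' @rdname tidy_helicore
#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, rmsd = x$rmsd)
}
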