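# Independent oracles and shared fixture builders. These deliberately use
# plain loops / direct arithmetic, not the package's code paths.

# direct weighted mean: sum(m_i x_i) / sum(m_i)
oracle_com <- function(atoms, masses) {
  acc <- c(0, 0, 0); tot <- 0
  for (i in seq_len(nrow(atoms))) {
    acc <- acc + masses[i] * c(atoms$x[i], atoms$y[i], atoms$z[i])
    tot <- tot + masses[i]
  }
  acc / tot
}

# RMS of post-fit pair distances, recomputed from scratch
oracle_rmsd <- function(R, t_vec, A, B) {
  ss <- 0
  for (i in seq_len(nrow(A))) {
    d <- as.numeric(R %*% A[i, ]) + t_vec - B[i, ]
    ss <- ss + sum(d^2)
  }
  sqrt(ss / nrow(A))
}

# distance-only all-pairs polar-atom scan (fixtures used with it carry no
# covalent antecedents, so the angle criterion is vacuous)
oracle_polar_pairs <- function(sel_a, sel_b, dist_max) {
  n <- 0
  for (i in seq_len(nrow(sel_a))) {
    if (!sel_a$element[i] %in% c("N", "O", "S")) next
    for (j in seq_len(nrow(sel_b))) {
      if (!sel_b$element[j] %in% c("N", "O", "S")) next
      d <- sqrt((sel_a$x[i] - sel_b$x[j])^2 + (sel_a$y[i] - sel_b$y[j])^2 +
                  (sel_a$z[i] - sel_b$z[j])^2)
      if (d <= dist_max && d > 0.5) n <- n + 1
    }
  }
  n
}

# a cloud of isolated polar atoms (no two atoms of one residue within
# covalent range, so no antecedents exist)
make_polar_cloud <- function(n, chain, seed, resname = "GLY", atom = "O",
                             element = "O", polymer = "protein") {
  withr::with_seed(seed, {
    xyz <- matrix(stats::runif(n * 3, 0, 15), n, 3)
    new_structure(tibble::tibble(
      chain = chain, resno = seq_len(n), ins = "", resname = resname,
      atom = atom, altloc = "", element = element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      polymer = polymer
    ))
  })
}

# full-coverage CA-only synthetic chain over an author-number interval
make_ca_chain <- function(from, to, chain = "A", seed = 1) {
  n <- to - from + 1
  withr::with_seed(seed, {
    xyz <- matrix(stats::runif(n * 3, -20, 20), n, 3)
    new_structure(tibble::tibble(
      chain = chain, resno = seq(from, to), ins = "", resname = "ALA",
      atom = "CA", altloc = "", element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      polymer = "protein"
    ))
  })
}

# three stacked rings forming a His-Pro-Phe column (triad-like geometry)
make_triad_structure <- function(gap = 3.5, spread = FALSE) {
  hexagon <- function(z, r = 1.4, n = 6) {
    ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    cbind(r * cos(ang), r * sin(ang), z)
  }
  dx <- if (spread) 10 else 0
  his <- hexagon(0, n = 5)
  pro <- hexagon(gap, n = 5); pro[, 1] <- pro[, 1] + dx
  phe <- hexagon(2 * gap, n = 6); phe[, 1] <- phe[, 1] + 2 * dx
  rows <- dplyr::bind_rows(
    tibble::tibble(resno = 1128L, resname = "HIS",
                   atom = c("CG", "ND1", "CD2", "CE1", "NE2"),
                   element = c("C", "N", "C", "C", "N"),
                   x = his[, 1], y = his[, 2], z = his[, 3]),
    tibble::tibble(resno = 1129L, resname = "PRO",
                   atom = c("N", "CA", "CB", "CG", "CD"),
                   element = c("N", "C", "C", "C", "C"),
                   x = pro[, 1], y = pro[, 2], z = pro[, 3]),
    tibble::tibble(resno = 1134L, resname = "PHE",
                   atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                   element = "C",
                   x = phe[, 1], y = phe[, 2], z = phe[, 3])
  )
  new_structure(tibble::as_tibble(cbind(
    tibble::tibble(chain = "A"), rows[, c("resno")],
    tibble::tibble(ins = ""), rows[, c("resname", "atom")],
    tibble::tibble(altloc = ""), rows[, c("element", "x", "y", "z")],
    tibble::tibble(occ = 1, b = 0, polymer = "protein")
  )))
}
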