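# Deterministic fixture generators with recorded ground truth. Every
# generator takes an explicit seed, restores the caller's RNG state, and
# returns the true parameters next to the data so tests and the acceptance
# script can measure recovery without any external input.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

atomset <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                    atom = "CA", resname = "GLY", element = "C") {
  tibble::tibble(
    chain = chain, resno = as.integer(resno), ins = "", resname = resname,
    atom = atom, altloc = "", element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, b = 0, polymer = polymer_class(resname)
  )
}

#' Generate a rigid coordinate pair with known transform
#'
#' Draws a well-spread random point cloud A and builds
#' `B = R A + t + noise` with the requested rotation and translation, so a
#' superposition method can be checked against the exact generating
#' transform.
#'
#' @param n_atoms Number of atoms (>= 4).
#' @param angle_deg,axis,translation Generating rotation (degrees, axis
#'   vector) and translation (Angstrom).
#' @param noise_sigma Isotropic Gaussian coordinate noise added to B, A.
#' @param seed RNG seed.
#' @return List `a`, `b` (atom tibbles), and `truth` (list with `rotation`,
#'   `translation`, `angle_deg`, `axis`).
#' @export
gen_rigid_pair <- function(n_atoms = 50, angle_deg = 0, axis = c(0, 0, 1),
                           translation = c(0, 0, 0), noise_sigma = 0, seed = 1) {
  stopifnot(n_atoms >= 4)
  with_seed(seed, {
    repeat {
      A <- matrix(stats::runif(n_atoms * 3, -10, 10), n_atoms, 3)
      if (qr(sweep(A, 2, colMeans(A)))$rank == 3) break
    }
    R <- rotation_matrix(angle_deg, axis)
    B <- A %*% t(R) + matrix(translation, n_atoms, 3, byrow = TRUE)
    if (noise_sigma > 0) {
      B <- B + matrix(stats::rnorm(n_atoms * 3, 0, noise_sigma), n_atoms, 3)
    }
    list(
      a = atomset(A), b = atomset(B),
      truth = list(rotation = R, translation = translation,
                   angle_deg = angle_deg, axis = axis / sqrt(sum(axis^2)))
    )
  })
}

#' Generate a two-lobe structure with known lobe-COM separation
#'
#' Builds two random CA-only lobes whose centers of mass (both uniform and
#' mass-weighted, all atoms being carbon) sit exactly `com_separation`
#' Angstrom apart, numbered inside the RecA1 (557-733) and RecA2 (734-909)
#' intervals, so the center-of-mass distance protocol can be verified
#' against the generating separation.
#'
#' @param lobe_sizes Length-2 integer vector of residues per lobe.
#' @param com_separation True separation, Angstrom (> 0).
#' @param seed RNG seed.
#' @return List `structure` (a `helicore_structure`), `domains` (definition
#'   tibble for chain A), and `truth` (list with `com_separation`).
#' @export
gen_two_lobe_structure <- function(lobe_sizes = c(80, 80), com_separation = 30,
                                   seed = 1) {
  stopifnot(com_separation > 0, all(lobe_sizes >= 4),
            lobe_sizes[1] <= 177, lobe_sizes[2] <= 176)
  with_seed(seed, {
    mk_lobe <- function(n, center) {
      repeat {
        p <- matrix(stats::rnorm(n * 3, 0, 4), n, 3)
        if (qr(sweep(p, 2, colMeans(p)))$rank == 3) break
      }
      sweep(p, 2, colMeans(p)) + matrix(center, n, 3, byrow = TRUE)
    }
    l1 <- mk_lobe(lobe_sizes[1], c(0, 0, 0))
    l2 <- mk_lobe(lobe_sizes[2], c(com_separation, 0, 0))
    atoms <- dplyr::bind_rows(
      atomset(l1, resno = seq(557, length.out = lobe_sizes[1])),
      atomset(l2, resno = seq(734, length.out = lobe_sizes[2]))
    )
    list(
      structure = new_structure(atoms, id = sprintf("twolobe_%g", com_separation)),
      domains = domain_definitions(
        c("RecA1", "RecA2"), "A",
        c(557L, 734L), c(556L + lobe_sizes[1], 733L + lobe_sizes[2])
      ),
      truth = list(com_separation = com_separation)
    )
  })
}

#' Apply a random rigid motion to a structure
#'
#' @param structure A `helicore_structure` or atom tibble.
#' @param seed RNG seed.
#' @return The structure under a uniformly random rotation plus a random
#'   translation; the transform is attached as attribute `transform`.
#' @export
random_rigid_motion <- function(structure, seed = 1) {
  with_seed(seed, {
    axis <- stats::rnorm(3)
    R <- rotation_matrix(stats::runif(1, 0, 360), axis)
    t_vec <- stats::runif(3, -30, 30)
    out <- apply_transform(list(rotation = R, translation = t_vec), structure)
    attr(out, "transform") <- list(rotation = R, translation = t_vec)
    out
  })
}

#' Generate an idealized stacked single-stranded RNA
#'
#' Builds a poly-U single strand as a stack of flat six-membered base rings
#' on a common axis (consecutive ring centroids `rise` Angstrom apart,
#' rotated by `twist` degrees) with a minimal covalently connected
#' sugar-phosphate backbone, so 5'->3' ordering by connectivity and
#' base-stack detection can be verified by construction. With
#' `unstack_after = k`, nucleotides `k+1 ... n` are rigidly displaced
#' sideways, breaking exactly the (k, k+1) stacking step and splitting the
#' strand into runs of k and n-k.
#'
#' @param n Number of nucleotides (>= 2).
#' @param rise Stacking rise, Angstrom (default 3.4).
#' @param twist Helical twist per step, degrees (default 33).
#' @param unstack_after Optional 5'->3' index after which the strand is
#'   displaced out of stacking range.
#' @param chain RNA chain id (default `"R"`).
#' @return List `structure` and `truth` (list with `runs`, `max_stack`).
#' @export
gen_stacked_rna <- function(n, rise = 3.4, twist = 33, unstack_after = NULL,
                            chain = "R") {
  stopifnot(n >= 2)
  ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ring_elem <- c("N", "C", "N", "C", "C", "C")
  rows <- list()
  for (i in seq_len(n)) {
    th0 <- (i - 1) * twist * pi / 180
    z <- (i - 1) * rise
    # base ring centered on the axis
    ring_ang <- th0 + seq(0, 2 * pi, length.out = 7)[1:6]
    ring <- cbind(1.4 * cos(ring_ang), 1.4 * sin(ring_ang), z)
    # minimal backbone at radius 8: P, C1' (glycosidic anchor), O3'
    p_ang <- th0
    p <- c(8 * cos(p_ang), 8 * sin(p_ang), z - 1.0)
    c1 <- c(5 * cos(p_ang), 5 * sin(p_ang), z)
    # O3' placed adjacent to the NEXT nucleotide's phosphate
    p_next_ang <- th0 + twist * pi / 180
    p_next <- c(8 * cos(p_next_ang), 8 * sin(p_next_ang), z + rise - 1.0)
    o3 <- p_next - c(0, 0, 1.6)
    xyz <- rbind(ring, p, c1, o3)
    rows[[i]] <- tibble::tibble(
      chain = chain, resno = i, ins = "", resname = "U",
      atom = c(ring_names, "P", "C1'", "O3'"), altloc = "",
      element = c(ring_elem, "P", "C", "O"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      polymer = "RNA"
    )
  }
  atoms <- dplyr::bind_rows(rows)
  if (!is.null(unstack_after)) {
    stopifnot(unstack_after >= 1, unstack_after < n)
    shift <- atoms$resno > unstack_after
    atoms$x[shift] <- atoms$x[shift] + 12
  }
  truth_runs <- if (is.null(unstack_after)) n else c(unstack_after, n - unstack_after)
  list(
    structure = new_structure(atoms, id = sprintf("rna%d", n)),
    truth = list(runs = truth_runs, max_stack = max(truth_runs))
  )
}

#' Generate a donor-acceptor hydrogen-bond geometry fixture
#'
#' A glycine backbone nitrogen (with its CA antecedent) facing a uridine
#' phosphate oxygen at a chosen donor-acceptor distance and
#' antecedent-donor-acceptor angle, for verifying the hydrogen-bond
#' criteria against constructed geometry.
#'
#' @param distance N...O distance, Angstrom.
#' @param angle CA-N-O angle, degrees.
#' @return A `helicore_structure` with one protein and one RNA residue.
#' @export
gen_hbond_geometry <- function(distance = 3.0, angle = 160) {
  ca <- c(0, 0, 0)
  nn <- c(1.47, 0, 0)
  th <- angle * pi / 180
  # acceptor in the xy-plane at the requested angle from the CA-N bond
  o <- nn + distance * c(-cos(th), sin(th), 0)
  p <- o + c(0, 1.5, 0)
  atoms <- tibble::tibble(
    chain = c("A", "A", "R", "R"), resno = c(1L, 1L, 1L, 1L), ins = "",
    resname = c("GLY", "GLY", "U", "U"),
    atom = c("CA", "N", "OP1", "P"), altloc = "",
    element = c("C", "N", "O", "P"),
    x = c(ca[1], nn[1], o[1], p[1]), y = c(ca[2], nn[2], o[2], p[2]),
    z = c(ca[3], nn[3], o[3], p[3]), occ = 1, b = 0,
    polymer = c("protein", "protein", "RNA", "RNA")
  )
  new_structure(atoms, id = "hbond_fixture")
}

#' Generate a two-ring geometry fixture
#'
#' Two idealized six-membered rings (a phenylalanine-like protein ring and
#' a uridine base) at a chosen interplanar angle and centroid displacement,
#' for verifying ring-interaction classification.
#'
#' @param interplanar_angle Angle between ring planes, degrees.
#' @param displacement Length-3 vector from ring-1 centroid to ring-2
#'   centroid, Angstrom.
#' @return A `helicore_structure` with one PHE and one U residue.
#' @export
gen_ring_geometry <- function(interplanar_angle = 0, displacement = c(0, 0, 3.5)) {
  hex <- function() {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  }
  r1 <- hex()
  r2 <- hex() %*% t(rotation_matrix(interplanar_angle, c(1, 0, 0)))
  r2 <- sweep(r2, 2, -as.numeric(displacement))
  phe_atoms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  u_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6")
  atoms <- tibble::tibble(
    chain = rep(c("A", "R"), each = 6), resno = 1L, ins = "",
    resname = rep(c("PHE", "U"), each = 6),
    atom = c(phe_atoms, u_atoms), altloc = "",
    element = c(rep("C", 6), "N", "C", "N", "C", "C", "C"),
    x = c(r1[, 1], r2[, 1]), y = c(r1[, 2], r2[, 2]), z = c(r1[, 3], r2[, 3]),
    occ = 1, b = 0, polymer = rep(c("protein", "RNA"), each = 6)
  )
  new_structure(atoms, id = "ring_fixture")
}

#' Generate a peptide backbone with exact (phi, psi) dihedrals
#'
#' Chains N-CA-C atoms with ideal bond lengths/angles and the requested
#' backbone dihedrals (omega fixed at 180 degrees), so helicity assessment
#' can be verified against canonical alpha-helical or extended values.
#'
#' @param n Number of residues.
#' @param phi,psi Backbone dihedrals, degrees (recycled).
#' @param chain Chain id.
#' @return A `helicore_structure` of polyalanine backbone (N, CA, C).
#' @export
gen_helix_dihedrals <- function(n = 10, phi = -57, psi = -47, chain = "A") {
  phi <- rep(phi, length.out = n)
  psi <- rep(psi, length.out = n)
  # NeRF-style sequential placement
  place <- function(a, b, c, L, theta_deg, chi_deg) {
    theta <- theta_deg * pi / 180; chi <- -chi_deg * pi / 180
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2], nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    d2 <- c(-L * cos(theta), L * sin(theta) * cos(chi), L * sin(theta) * sin(chi))
    c + cbind(bc, m, nrm) %*% d2
  }
  coords <- list()
  # seed atoms of residue 1
  Np <- c(0, 0, 0); CAp <- c(1.458, 0, 0)
  Cp <- as.numeric(place(c(-1, 1, 0), Np, CAp, 1.525, 111, psi[1] * 0 + 120))
  coords[[1]] <- rbind(N = Np, CA = CAp, C = Cp)
  for (i in seq_len(n - 1)) {
    prev <- coords[[i]]
    Nn <- as.numeric(place(prev["N", ], prev["CA", ], prev["C", ], 1.329, 116.2, psi[i]))
    CAn <- as.numeric(place(prev["CA", ], prev["C", ], Nn, 1.458, 121.7, 180))
    Cn <- as.numeric(place(prev["C", ], Nn, CAn, 1.525, 111, phi[i + 1]))
    coords[[i + 1]] <- rbind(N = Nn, CA = CAn, C = Cn)
  }
  atoms <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    m <- coords[[i]]
    tibble::tibble(
      chain = chain, resno = i, ins = "", resname = "ALA",
      atom = c("N", "CA", "C"), altloc = "", element = c("N", "C", "C"),
      x = m[, 1], y = m[, 2], z = m[, 3], occ = 1, b = 0, polymer = "protein"
    )
  }))
  new_structure(atoms, id = "backbone_fixture")
}

#' Simulate a Michaelis-Menten kinetics dataset
#'
#' Velocities from the rate law at the given substrate grid plus Gaussian
#' noise scaled to the maximal velocity; the substrate grid defaults to a
#' two-fold dilution series over the 0-2 mM range typical of NADH-coupled
#' ATPase assays, with triplicate points.
#'
#' @param kcat,km_mM,e_uM True parameters.
#' @param s_grid Substrate concentrations, mM.
#' @param reps Replicates per concentration.
#' @param noise_sigma_frac Noise SD as a fraction of `Vmax = kcat * e_uM`.
#' @param seed RNG seed.
#' @return List `data` (tibble `s_mM`, `v0`, `e_uM`, `rep`) and `truth`.
#' @export
gen_mm_data <- function(kcat = 2, km_mM = 0.1, e_uM = 0.4,
                        s_grid = c(0, 0.0156, 0.0313, 0.0625, 0.125, 0.25,
                                   0.5, 1, 2),
                        reps = 3, noise_sigma_frac = 0.02, seed = 1) {
  stopifnot(kcat > 0, km_mM > 0, e_uM > 0)
  with_seed(seed, {
    grid <- tidyr::expand_grid(s_mM = s_grid, rep = seq_len(reps))
    vmax <- kcat * e_uM
    v <- mm_velocity(grid$s_mM, kcat, km_mM, e_uM)
    if (noise_sigma_frac > 0) {
      v <- v + stats::rnorm(nrow(grid), 0, noise_sigma_frac * vmax)
    }
    list(
      data = tibble::tibble(s_mM = grid$s_mM, v0 = v, e_uM = e_uM,
                            rep = grid$rep),
      truth = list(kcat = kcat, km_mM = km_mM, e_uM = e_uM)
    )
  })
}

#' Simulate a fluorescence-polarization titration
#'
#' Fraction bound from the exact quadratic isotherm on a two-fold protein
#' dilution series (default up to 70 uM, the range used to titrate a 6 nM
#' labeled RNA), mapped to raw polarization between the given plateaus,
#' plus Gaussian noise.
#'
#' @param kd_uM True dissociation constant, uM.
#' @param lt_nM Labeled ligand concentration, nM.
#' @param rt_grid Protein concentrations, uM.
#' @param reps Replicates per concentration.
#' @param noise_sigma Gaussian noise SD on fraction bound (scaled by the
#'   plateau span for raw polarization).
#' @param p_free,p_bound Plateau polarizations of the free and bound label.
#' @param seed RNG seed.
#' @return List `data` (tibble `rt_uM`, `polarization`, `fb`, `rep`) and
#'   `truth`.
#' @export
gen_fp_data <- function(kd_uM = 2, lt_nM = 6,
                        rt_grid = c(0, 70 / 2^(11:0)),
                        reps = 3, noise_sigma = 0.02,
                        p_free = 50, p_bound = 250, seed = 1) {
  stopifnot(kd_uM > 0, lt_nM > 0)
  with_seed(seed, {
    grid <- tidyr::expand_grid(rt_uM = rt_grid, rep = seq_len(reps))
    fb <- fp_fraction_bound(grid$rt_uM, kd_uM, lt_nM / 1000)
    if (noise_sigma > 0) fb <- fb + stats::rnorm(nrow(grid), 0, noise_sigma)
    pol <- p_free + (p_bound - p_free) * fb
    list(
      data = tibble::tibble(rt_uM = grid$rt_uM, polarization = pol, fb = fb,
                            rep = grid$rep),
      truth = list(kd_uM = kd_uM, lt_nM = lt_nM, p_free = p_free,
                   p_bound = p_bound)
    )
  })
}

#' Simulate an NADH-coupled absorbance trace
#'
#' First-order consumption curve `A(t) = A_end + (A0 - A_end) exp(-k t)`
#' observed over its early phase, with the true initial rate recorded in
#' uM/s.
#'
#' @param rate_uM_s True initial ATPase velocity.
#' @param a0 Starting absorbance.
#' @param epsilon_nadh,pathlength Beer-Lambert constants.
#' @param frac_consumed Fraction of total NADH consumed over the trace
#'   (kept small so the observed window is near-linear).
#' @param n_points Number of time points.
#' @param noise_sigma Gaussian absorbance noise SD.
#' @param seed RNG seed.
#' @return List `trace` (tibble `time`, `a340`) and `truth`.
#' @export
gen_nadh_trace <- function(rate_uM_s = 1, a0 = 0.8,
                           epsilon_nadh = EPSILON_NADH_340, pathlength = 1,
                           frac_consumed = 0.15, n_points = 120,
                           noise_sigma = 0, seed = 1) {
  stopifnot(rate_uM_s > 0, a0 > 0, frac_consumed > 0, frac_consumed < 1)
  with_seed(seed, {
    slope0 <- rate_uM_s * epsilon_nadh * pathlength * 1e-6  # A/s
    k <- slope0 / a0
    t_end <- -log(1 - frac_consumed) / k
    tt <- seq(0, t_end, length.out = n_points)
    a <- a0 * exp(-k * tt)
    if (noise_sigma > 0) a <- a + stats::rnorm(n_points, 0, noise_sigma)
    list(trace = tibble::tibble(time = tt, a340 = a),
         truth = list(rate_uM_s = rate_uM_s))
  })
}
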