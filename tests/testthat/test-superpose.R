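test_that("atom pairing matches keys present on both sides", {
  a <- make_ca_chain(1, 10, seed = 1)
  b <- make_ca_chain(1, 10, seed = 2)
  p <- pair_common_atoms(a, b)
  expect_equal(nrow(p$xyz_a), 10)

  a_gapped <- new_structure(a[!a$resno %in% c(5, 7), ])
  expect_equal(nrow(pair_common_atoms(a_gapped, b)$xyz_a), 8)

  # random deletions on both sides: count equals set intersection
  withr::with_seed(10, {
    for (k in 1:5) {
      keep_a <- sort(sample(1:40, 25)); keep_b <- sort(sample(1:40, 25))
      base_a <- make_ca_chain(1, 40, seed = k)
      base_b <- make_ca_chain(1, 40, seed = k + 100)
      pa <- new_structure(base_a[base_a$resno %in% keep_a, ])
      pb <- new_structure(base_b[base_b$resno %in% keep_b, ])
      expect_equal(nrow(pair_common_atoms(pa, pb)$xyz_a),
                   length(intersect(keep_a, keep_b)))
    }
  })
  expect_error(pair_common_atoms(a[0, ], b), "empty")
  expect_error(pair_common_atoms(new_structure(a[a$resno <= 2, ]), b),
               "fewer than 3")
})

test_that("alignment-mode pairing maps residues through an equivalence table", {
  a <- make_ca_chain(101, 110, seed = 3)
  b <- make_ca_chain(501, 510, seed = 4)
  eq <- tibble::tibble(resno_a = 101:110, resno_b = 501:510)
  p <- pair_common_atoms(a, b, mode = "by-alignment", equivalence = eq)
  expect_equal(nrow(p$xyz_a), 10)
  expect_equal(p$keys$resno_b, p$keys$resno_a + 400L)
})

test_that("superposing identical coordinates gives zero rmsd and zero rotation", {
  a <- make_ca_chain(1, 20, seed = 5)
  f <- kabsch_fit(pair_common_atoms(a, a))
  expect_lt(f$rmsd, 1e-12)
  dec <- decompose_transform(f)
  expect_lt(dec$angle_deg, 1e-6)
  expect_lt(dec$displacement, 1e-9)
})

test_that("the generating transform is recovered exactly from noiseless pairs", {
  p <- gen_rigid_pair(50, angle_deg = 19, axis = c(0, 0, 1),
                      translation = c(1, 2, 3), seed = 2)
  f <- kabsch_fit(pair_common_atoms(p$a, p$b))
  expect_lt(max(abs(f$rotation - p$truth$rotation)), 1e-9)
  expect_lt(max(abs(f$translation - c(1, 2, 3))), 1e-6)
  dec <- decompose_transform(f)
  expect_equal(dec$angle_deg, 19, tolerance = 1e-6)
  expect_equal(abs(sum(dec$axis * c(0, 0, 1))), 1, tolerance = 1e-9)
})

test_that("reported rmsd equals an independently recomputed residual RMS", {
  p <- gen_rigid_pair(60, angle_deg = 25, axis = c(1, 1, 0),
                      translation = c(-2, 0.5, 4), noise_sigma = 0.2, seed = 7)
  pr <- pair_common_atoms(p$a, p$b)
  f <- kabsch_fit(pr)
  expect_gt(f$rmsd, 0.05)
  expect_equal(f$rmsd, oracle_rmsd(f$rotation, f$translation, pr$xyz_a, pr$xyz_b),
               tolerance = 1e-9)
  # fitted rmsd never exceeds the unfitted pair distances
  raw <- sqrt(mean(rowSums((pr$xyz_a - pr$xyz_b)^2)))
  expect_lte(f$rmsd, raw)
})

test_that("degenerate collinear configurations are refused, not reflected", {
  line <- tibble::tibble(
    chain = "A", resno = 1:5, ins = "", resname = "GLY", atom = "CA",
    altloc = "", element = "C", x = as.numeric(1:5), y = 0, z = 0,
    occ = 1, b = 0, polymer = "protein"
  )
  expect_error(kabsch_fit(pair_common_atoms(line, line)), "degenerate|collinear")
})

test_that("center of mass matches the explicit weighted-mean loop", {
  one <- tibble::tibble(chain = "A", resno = 1L, ins = "", resname = "GLY",
                        atom = "CA", altloc = "", element = "C",
                        x = 1, y = 2, z = 3, occ = 1, b = 0, polymer = "protein")
  expect_equal(center_of_mass(one), c(1, 2, 3))
  two <- dplyr::bind_rows(one, dplyr::mutate(one, resno = 2L, x = 2, y = 0, z = 0))
  two$x <- c(0, 2); two$y <- c(0, 0); two$z <- c(0, 0)
  expect_equal(center_of_mass(two), c(1, 0, 0))

  withr::with_seed(21, {
    elements <- sample(c("C", "N", "O", "P", "S"), 50, replace = TRUE)
    cloud <- tibble::tibble(
      chain = "A", resno = 1:50, ins = "", resname = "GLY", atom = "X",
      altloc = "", element = elements,
      x = stats::rnorm(50), y = stats::rnorm(50), z = stats::rnorm(50),
      occ = 1, b = 0, polymer = "protein"
    )
    masses <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)[elements]
    expect_equal(center_of_mass(cloud, "atomic-mass"),
                 oracle_com(cloud, masses), tolerance = 1e-12)
  })
  expect_error(center_of_mass(one[0, ]), "empty")
})

test_that("decompose/recompose is the identity on rotation matrices", {
  withr::with_seed(31, {
    for (k in 1:20) {
      ang <- stats::runif(1, 0.5, 179.5)
      ax <- stats::rnorm(3)
      R <- rotation_matrix(ang, ax)
      dec <- decompose_transform(list(rotation = R, translation = c(0, 0, 0)))
      expect_equal(dec$angle_deg, ang, tolerance = 1e-6)
      R2 <- rotation_matrix(dec$angle_deg, dec$axis)
      expect_lt(max(abs(R2 - R)), 1e-6)
    }
  })
})

test_that("a rotation about an axis through the reference point leaves it in place", {
  dec <- decompose_transform(list(rotation = rotation_matrix(19, c(0, 0, 1)),
                                  translation = c(0, 0, 0)),
                             reference_point = c(0, 0, 0))
  expect_equal(dec$angle_deg, 19, tolerance = 1e-9)
  expect_lt(dec$displacement, 1e-12)
  # the same rotation about an off-axis point displaces it
  p <- c(5, 0, 0)
  dec2 <- decompose_transform(list(rotation = rotation_matrix(19, c(0, 0, 1)),
                                   translation = c(0, 0, 0)),
                              reference_point = p)
  expect_equal(dec2$displacement, 2 * 5 * sin(19 / 2 * pi / 180),
               tolerance = 1e-9)
  expect_error(decompose_transform(list(rotation = diag(c(1, 1, -1)),
                                        translation = c(0, 0, 0))),
               "proper rotation")
})

test_that("rmsd, angle and displacement are invariant under global rigid motion", {
  p <- gen_rigid_pair(40, angle_deg = 33, axis = c(1, 2, 3),
                      translation = c(4, -1, 2), noise_sigma = 0.1, seed = 13)
  f0 <- kabsch_fit(pair_common_atoms(p$a, p$b))
  d0 <- decompose_transform(f0, reference_point = center_of_mass(p$a))
  for (k in 1:5) {
    a2 <- random_rigid_motion(p$a, seed = 100 + k)
    b2 <- random_rigid_motion(p$b, seed = 100 + k)
    f2 <- kabsch_fit(pair_common_atoms(a2, b2))
    d2 <- decompose_transform(f2, reference_point = center_of_mass(a2))
    expect_equal(f2$rmsd, f0$rmsd, tolerance = 1e-9)
    expect_equal(d2$angle_deg, d0$angle_deg, tolerance = 1e-6)
    expect_equal(d2$displacement, d0$displacement, tolerance = 1e-6)
  }
})

test_that("mass weighting shifts the fit toward heavy atoms", {
  # two atoms displaced, one heavy: weighted fit must favour the heavy one
  A <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5, 5, 5))
  B <- A; B[1, ] <- B[1, ] + c(0, 0, 1)
  pairs <- list(xyz_a = A, xyz_b = B)
  f_uni <- kabsch_fit(pairs)
  f_w <- kabsch_fit(pairs, weights = c(100, 1, 1, 1))
  # weighted fit leaves smaller residual on the heavy atom
  r_uni <- sqrt(sum((as.numeric(f_uni$rotation %*% A[1, ]) + f_uni$translation - B[1, ])^2))
  r_w <- sqrt(sum((as.numeric(f_w$rotation %*% A[1, ]) + f_w$translation - B[1, ])^2))
  expect_lt(r_w, r_uni)
})
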