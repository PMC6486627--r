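test_that("the protocol on a structure against itself gives the direct COM distance", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 1)
  s <- tl$structure
  r <- com_distance_protocol(s, s, "A", "A", tl$domains, tl$domains)
  d1 <- ct_direct <- sqrt(sum((
    center_of_mass(select_atoms(s, "A", c(557, 636))) -
      center_of_mass(select_atoms(s, "A", c(734, 813))))^2))
  expect_equal(r$d_com, 30, tolerance = 1e-9)
  expect_lt(r$rmsd_RecA1, 1e-12)
  expect_lt(r$rmsd_RecA2, 1e-12)
  expect_equal(r$state, "open")
})

test_that("the generating lobe separation is recovered from a re-oriented target", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 3)
  tgt <- random_rigid_motion(tl$structure, seed = 4)
  r <- com_distance_protocol(tgt, tl$structure, "A", "A", tl$domains, tl$domains)
  expect_equal(r$d_com, 30, tolerance = 1e-6)
})

test_that("d_com is invariant under rigid motion of the target", {
  tl <- gen_two_lobe_structure(com_separation = 28.2, seed = 6)
  # a gapped target (different modeled set) still measures the reference set
  gapped <- new_structure(tl$structure[tl$structure$resno %% 7 != 0, ],
                          "gapped")
  r0 <- com_distance_protocol(gapped, tl$structure, "A", "A",
                              tl$domains, tl$domains)
  for (k in 1:5) {
    moved <- random_rigid_motion(gapped, seed = 50 + k)
    r <- com_distance_protocol(moved, tl$structure, "A", "A",
                               tl$domains, tl$domains)
    expect_equal(r$d_com, r0$d_com, tolerance = 1e-8)
  }
})

test_that("open/closed classification follows the threshold with the boundary open", {
  expect_equal(classify_state(27.5), "closed")
  expect_equal(classify_state(31.7), "open")
  expect_equal(classify_state(29.5), "open")  # boundary assigned to open
  expect_error(classify_state(-1))
  # monotone: increasing d_com never flips open -> closed
  d <- seq(20, 40, by = 0.1)
  states <- classify_state(d)
  expect_false(any(states == "closed" & dplyr::lag(states, default = "closed") == "open"))
})

test_that("two-lobe fixtures at nucleotide-bound and RNA-complex separations classify correctly", {
  closed <- gen_two_lobe_structure(com_separation = 27.5, seed = 8)
  open <- gen_two_lobe_structure(com_separation = 31.7, seed = 9)
  rc <- com_distance_protocol(closed$structure, closed$structure, "A", "A",
                              closed$domains, closed$domains)
  ro <- com_distance_protocol(open$structure, open$structure, "A", "A",
                              open$domains, open$domains)
  expect_equal(rc$state, "closed")
  expect_equal(ro$state, "open")
  tiny <- gen_two_lobe_structure(com_separation = 1e-3, seed = 10)
  rt <- com_distance_protocol(tiny$structure, tiny$structure, "A", "A",
                              tiny$domains, tiny$domains)
  expect_equal(rt$state, "closed")
  expect_gt(rt$d_com, 0)
})

test_that("swapping reference and target changes d_com only at the residual scale", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 12)
  # perturb the target slightly so the two directions are not trivially equal
  pert <- tl$structure
  withr::with_seed(13, {
    pert$x <- pert$x + stats::rnorm(nrow(pert), 0, 0.1)
    pert$y <- pert$y + stats::rnorm(nrow(pert), 0, 0.1)
    pert$z <- pert$z + stats::rnorm(nrow(pert), 0, 0.1)
  })
  pert <- new_structure(pert, "pert")
  r_ab <- com_distance_protocol(pert, tl$structure, "A", "A",
                                tl$domains, tl$domains)
  r_ba <- com_distance_protocol(tl$structure, pert, "A", "A",
                                tl$domains, tl$domains)
  expect_lt(abs(r_ab$d_com - r_ba$d_com),
            max(r_ab$rmsd_RecA1, r_ab$rmsd_RecA2))
})

test_that("a high-rmsd superposition warns but still returns", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 14)
  mangled <- tl$structure
  withr::with_seed(15, {
    mangled$x <- mangled$x + stats::rnorm(nrow(mangled), 0, 8)
  })
  mangled <- new_structure(mangled, "mangled")
  w <- testthat::capture_warnings(
    r <- com_distance_protocol(mangled, tl$structure, "A", "A",
                               tl$domains, tl$domains)
  )
  expect_match(w, "sanity ceiling", all = TRUE)
  expect_gte(length(w), 1)
  expect_true(is.finite(r$d_com))
})

test_that("domain shift recovers a pure mobile-lobe translation", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 16)
  a <- tl$structure
  b <- a
  mob <- b$resno >= 734
  b$x[mob] <- b$x[mob] + 4.0
  b <- new_structure(b, "shifted")
  dec <- domain_shift(a, b, "A", "A", tl$domains, tl$domains)
  expect_equal(dec$displacement, 4.0, tolerance = 1e-6)
  expect_lt(dec$angle_deg, 1e-6)
  # self comparison: no shift
  dec0 <- domain_shift(a, a, "A", "A", tl$domains, tl$domains)
  expect_lt(dec0$displacement, 1e-9)
  expect_lt(dec0$angle_deg, 1e-6)
})

test_that("domain shift sees through a global motion of one state", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 17)
  a <- tl$structure
  b <- a
  mob <- b$resno >= 734
  b$y[mob] <- b$y[mob] + 5.8
  b <- new_structure(random_rigid_motion(b, seed = 18), "shifted_moved")
  dec <- domain_shift(a, b, "A", "A", tl$domains, tl$domains)
  expect_equal(dec$displacement, 5.8, tolerance = 1e-6)
})

test_that("RNA-frame residue displacement reports the planted rigid shift", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 20)
  a <- tl$structure
  b <- a
  mob <- b$resno >= 734
  b$z[mob] <- b$z[mob] + 3.0
  b <- new_structure(b, "reca2_shifted")
  track <- c(750L, 770L, 790L, 810L)  # inside the fixture's RecA2 lobe
  disp <- modeled_rna_displacement(a, b, "A", "A", residues = track,
                                   domains_a = tl$domains, domains_b = tl$domains)
  expect_equal(nrow(disp), 4)
  expect_true(all(disp$modeled))
  expect_equal(disp$displacement_A, rep(3.0, 4), tolerance = 1e-6)
  # identical structures: all displacements zero
  disp0 <- modeled_rna_displacement(a, a, "A", "A", residues = track,
                                    domains_a = tl$domains, domains_b = tl$domains)
  expect_equal(disp0$displacement_A, rep(0, 4), tolerance = 1e-9)
})

test_that("unmodeled tracked residues are flagged, not dropped", {
  tl <- gen_two_lobe_structure(com_separation = 30, seed = 22)
  a <- tl$structure
  b <- new_structure(a[a$resno != 800, ], "missing_800")
  disp <- modeled_rna_displacement(a, b, "A", "A", residues = c(790L, 800L),
                                   domains_a = tl$domains, domains_b = tl$domains)
  expect_equal(disp$modeled, c(TRUE, FALSE))
  expect_true(is.na(disp$displacement_A[2]))
})
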