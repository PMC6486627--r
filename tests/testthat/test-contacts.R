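test_that("a constructed N-H...O=P geometry is detected and classified by moiety", {
  s <- gen_hbond_geometry(distance = 3.0, angle = 160)
  hb <- hydrogen_bonds(s, s[s$polymer == "protein", ], s[s$polymer == "RNA", ])
  expect_equal(nrow(hb), 1)
  expect_equal(hb$kind, "hbond")
  expect_equal(hb$moiety, "phosphate")
  expect_equal(hb$distance, 3.0, tolerance = 1e-9)
  expect_equal(hb$angle, 160, tolerance = 1e-6)

  far <- gen_hbond_geometry(distance = 4.2, angle = 160)
  expect_equal(nrow(hydrogen_bonds(far, far[far$polymer == "protein", ],
                                   far[far$polymer == "RNA", ])), 0)
})

test_that("donor directionality rejects geometries with both antecedents misaligned", {
  # donor N (antecedent CA) and acceptor O (antecedent C) both bent < 90 deg
  mk <- function(ca_pos) new_structure(tibble::tibble(
    chain = c("A", "A", "B", "B"), resno = c(1L, 1L, 2L, 2L), ins = "",
    resname = c("GLY", "GLY", "GLY", "GLY"),
    atom = c("CA", "N", "C", "O"), altloc = "",
    element = c("C", "N", "C", "O"),
    x = c(ca_pos[1], 0, 2.5, 3), y = c(ca_pos[2], 0, -1.15, 0),
    z = 0, occ = 1, b = 0, polymer = "protein"
  ))
  bent <- mk(c(0.5, -1.38))   # CA-N-O angle ~70 deg; C-O-N ~66 deg
  hb_bent <- hydrogen_bonds(bent, bent[bent$chain == "A", ],
                            bent[bent$chain == "B", ])
  expect_equal(nrow(hb_bent), 0)
  straight <- mk(c(-1.47, 0))  # CA-N-O angle 180 deg
  hb_straight <- hydrogen_bonds(straight, straight[straight$chain == "A", ],
                                straight[straight$chain == "B", ])
  expect_equal(nrow(hb_straight), 1)
})

test_that("pair detection equals a brute-force all-pairs scan on antecedent-free clouds", {
  for (k in 1:4) {
    a <- make_polar_cloud(30, "A", seed = k, atom = "O", element = "O")
    b <- make_polar_cloud(30, "B", seed = k + 50, resname = "U", atom = "OP1",
                          element = "O", polymer = "RNA")
    s <- new_structure(dplyr::bind_rows(a, b))
    for (cutoff in c(3.0, 3.5, 4.5)) {
      hb <- hydrogen_bonds(s, s[s$chain == "A", ], s[s$chain == "B", ],
                           hbond_criteria(dist_max = cutoff))
      expect_equal(nrow(hb), oracle_polar_pairs(a, b, cutoff))
    }
  }
})

test_that("tightening the distance cutoff never adds contacts", {
  a <- make_polar_cloud(40, "A", seed = 31)
  b <- make_polar_cloud(40, "B", seed = 32, resname = "U", atom = "OP2",
                        element = "O", polymer = "RNA")
  s <- new_structure(dplyr::bind_rows(a, b))
  cutoffs <- seq(2.5, 5, by = 0.5)
  counts <- vapply(cutoffs, function(cc) {
    nrow(hydrogen_bonds(s, s[s$chain == "A", ], s[s$chain == "B", ],
                        hbond_criteria(dist_max = cc)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("contact lists are invariant under global rigid motion", {
  a <- make_polar_cloud(25, "A", seed = 41)
  b <- make_polar_cloud(25, "B", seed = 42, resname = "U", atom = "OP1",
                        element = "O", polymer = "RNA")
  s <- new_structure(dplyr::bind_rows(a, b))
  hb0 <- hydrogen_bonds(s, s[s$chain == "A", ], s[s$chain == "B", ])
  for (k in 1:3) {
    sm <- new_structure(random_rigid_motion(s, seed = 60 + k), "moved")
    hbm <- hydrogen_bonds(sm, sm[sm$chain == "A", ], sm[sm$chain == "B", ])
    expect_equal(nrow(hbm), nrow(hb0))
    expect_equal(hbm[order(hbm$resno_a, hbm$resno_b), c("resno_a", "resno_b")],
                 hb0[order(hb0$resno_a, hb0$resno_b), c("resno_a", "resno_b")])
    expect_equal(sort(hbm$distance), sort(hb0$distance), tolerance = 1e-9)
  }
})

test_that("backbone-contact residue counting collapses bonds to distinct residues", {
  # plant exactly two protein residues h-bonding the RNA backbone
  prot <- tibble::tibble(
    chain = "A", resno = c(700L, 700L, 710L), ins = "",
    resname = "SER", atom = c("OG", "N", "OG"), altloc = "",
    element = c("O", "N", "O"),
    x = c(0, 0.5, 10), y = c(0, 1.2, 0), z = 0,
    occ = 1, b = 0, polymer = "protein"
  )
  rna <- tibble::tibble(
    chain = "R", resno = c(1L, 2L), ins = "", resname = "U",
    atom = "OP1", altloc = "", element = "O",
    x = c(2.8, 12.8), y = 0, z = 0, occ = 1, b = 0, polymer = "RNA"
  )
  s <- new_structure(dplyr::bind_rows(prot, rna))
  dom <- tibble::tibble(name = "RecA1", chain = "A", start = 557L, end = 733L)
  n <- count_backbone_contact_residues(s, "A", dom, "R")
  expect_equal(as.integer(n), 2)
  expect_equal(attr(n, "residues"), c(700L, 710L))
  expect_error(count_backbone_contact_residues(s, "A", dom, "Z"), "RNA")
})

test_that("ring geometries classify as parallel-displaced, edge-to-face, cation-pi", {
  pd <- ring_interactions(gen_ring_geometry(0, c(1.0, 0, 3.3)))
  expect_equal(pd$kind, "pi-pi-parallel-displaced")
  ef <- ring_interactions(gen_ring_geometry(80, c(0, 0, 5.0)))
  expect_equal(ef$kind, "pi-pi-edge-to-face")
  expect_equal(ef$angle, 80, tolerance = 1e-6)
  none <- ring_interactions(gen_ring_geometry(0, c(0, 0, 8)))
  expect_equal(nrow(none), 0)

  # arginine guanidinium nitrogen over a uridine ring
  ringfix <- gen_ring_geometry(0, c(0, 0, 20))  # move the PHE far away
  arg <- tibble::tibble(
    chain = "A", resno = 1012L, ins = "", resname = "ARG",
    atom = c("NE", "NH1", "NH2"), altloc = "", element = "N",
    x = c(0, 1.1, -1.1), y = 0, z = c(4.0, 4.8, 4.8),
    occ = 1, b = 0, polymer = "protein"
  )
  u_ring <- ringfix[ringfix$resname == "U", ]
  u_ring$x <- u_ring$x; u_ring$z <- u_ring$z - 20  # back at origin
  s <- new_structure(dplyr::bind_rows(u_ring, arg))
  cp <- ring_interactions(s)
  expect_true("cation-pi" %in% cp$kind)
  cp_row <- cp[cp$kind == "cation-pi", ]
  expect_equal(cp_row$resname_a, "ARG")
  expect_equal(cp_row$moiety, "base")
  expect_equal(cp_row$distance, 4.0, tolerance = 1e-6)
})

test_that("a stacked His-Pro-Phe column is detected as a stacking triad", {
  expect_true(has_stacking_triad(make_triad_structure(gap = 3.5), "A"))
  expect_false(has_stacking_triad(make_triad_structure(gap = 3.5, spread = TRUE), "A"))
})

test_that("ideal stacked n-mers give max_stack = n for n in 2..12", {
  for (n in 2:12) {
    st <- stack_segments(gen_stacked_rna(n)$structure, "R")
    expect_equal(st$max_stack, n)
    expect_equal(nrow(st$runs), 1)
  }
})

test_that("an unstacking break splits the strand into the generated runs", {
  g <- gen_stacked_rna(9, unstack_after = 5)
  st <- stack_segments(g$structure, "R")
  expect_equal(st$runs$length, c(5L, 4L))
  expect_equal(st$max_stack, 5)
  g2 <- gen_stacked_rna(9, unstack_after = 4)
  expect_equal(stack_segments(g2$structure, "R")$runs$length, c(4L, 5L))
  expect_error(stack_segments(gen_stacked_rna(2)$structure, "Z"), "no RNA")
})

test_that("5'->3' ordering comes from connectivity, not author numbering", {
  g <- gen_stacked_rna(6)
  s <- g$structure
  # renumber: author numbers reversed; connectivity unchanged
  s$resno <- 7L - s$resno
  s <- new_structure(s, "renumbered")
  st <- stack_segments(s, "R")
  expect_equal(st$max_stack, 6)
  # 5' terminus (no phosphate predecessor) is the old nucleotide 1 = new 6
  expect_equal(st$nucleotides$resno[1], 6L)
})

test_that("protein atoms intercalating at a stack break are reported as the interrupting element", {
  g <- gen_stacked_rna(9, unstack_after = 5)
  s <- g$structure
  # place a beta-hairpin-like residue between the centroids of nt 5 and 6
  c5 <- colMeans(as.matrix(s[s$resno == 5 & s$atom %in%
                               c("N1", "C2", "N3", "C4", "C5", "C6"),
                             c("x", "y", "z")]))
  c6 <- colMeans(as.matrix(s[s$resno == 6 & s$atom %in%
                               c("N1", "C2", "N3", "C4", "C5", "C6"),
                             c("x", "y", "z")]))
  mid <- (c5 + c6) / 2
  hairpin <- tibble::tibble(
    chain = "A", resno = 853L, ins = "", resname = "LYS", atom = "CA",
    altloc = "", element = "C", x = mid[1], y = mid[2], z = mid[3],
    occ = 1, b = 0, polymer = "protein"
  )
  s2 <- new_structure(dplyr::bind_rows(s, hairpin))
  st <- stack_segments(s2, "R")
  expect_equal(st$runs$length, c(5L, 4L))
  expect_true(853L %in% st$interruptions$resno)
})

test_that("canonical backbone dihedrals assess as helical or distorted", {
  h <- motif_helicity(gen_helix_dihedrals(10, -57, -47), "A", c(1, 10))
  expect_equal(h$fraction_helical, 1.0)
  expect_equal(h$label, "helical")
  mid <- h$residues[!is.na(h$residues$phi) & !is.na(h$residues$psi), ]
  expect_equal(mid$phi, rep(-57, nrow(mid)), tolerance = 1e-3)
  expect_equal(mid$psi, rep(-47, nrow(mid)), tolerance = 1e-3)

  e <- motif_helicity(gen_helix_dihedrals(10, -120, 120), "A", c(1, 10))
  expect_equal(e$fraction_helical, 0)
  expect_equal(e$label, "distorted")
  expect_error(motif_helicity(gen_helix_dihedrals(10), "A", c(1, 3)), ">= 4")
})

test_that("chain breaks make the spanning dihedrals non-assessable", {
  s <- gen_helix_dihedrals(10, -57, -47)
  s2 <- new_structure(s[s$resno != 5, ], "broken")
  h <- motif_helicity(s2, "A", c(1, 10))
  r <- h$residues
  expect_true(is.na(r$phi[r$resno == 5]))
  expect_true(is.na(r$psi[r$resno == 4]))   # needs N of residue 5
  expect_true(is.na(r$phi[r$resno == 6]))   # needs C of residue 5
  # remaining residues still helical
  expect_equal(h$label, "helical")
})

test_that("a partially distorted motif drops below the helical label threshold", {
  phis <- c(rep(-57, 5), rep(-120, 5))
  psis <- c(rep(-47, 5), rep(120, 5))
  s <- gen_helix_dihedrals(10, phis, psis)
  h <- motif_helicity(s, "A", c(1, 10))
  expect_lt(h$fraction_helical, 0.8)
  expect_equal(h$label, "distorted")
})
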