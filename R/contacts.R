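# Protein-RNA interaction fingerprinting: hydrogen bonds classified by RNA
# moiety, pi-pi and cation-pi ring interactions, base-stack segmentation of
# the bound ssRNA, and backbone-dihedral helicity of sequence motifs.
# All geometry is heavy-atom only; criteria objects expose every cutoff.

#' Hydrogen-bond detection criteria
#'
#' Heavy-atom criteria suitable for 2-3.5 A crystal structures where
#' hydrogens are not modeled: donor-acceptor distance cutoff plus, where a
#' covalent antecedent of the donor can be identified, a minimum
#' antecedent-donor-acceptor angle.
#'
#' @param dist_max Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_min Minimum antecedent-donor-acceptor angle, degrees.
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_max = 3.5, angle_min = 90) {
  stopifnot(dist_max > 0, angle_min >= 0, angle_min <= 180)
  structure(list(dist_max = dist_max, angle_min = angle_min),
            class = "hbond_criteria")
}

#' Ring-interaction and base-stacking criteria
#'
#' @param centroid_max Ring-centroid distance cutoff for base stacking, A.
#' @param angle_max Maximum interplanar angle for stacking, degrees.
#' @param offset_max Maximum lateral centroid offset from the ring normal, A.
#' @param pi_centroid_max Centroid cutoff for generic pi-pi contacts
#'   (edge-to-face geometries sit further apart than stacks), A.
#' @param ef_split Interplanar angle separating parallel-displaced from
#'   edge-to-face pi-pi geometry, degrees.
#' @param cation_pi_max Charged-nitrogen to ring-centroid cutoff, A.
#' @return List of class `stack_criteria`.
#' @export
stack_criteria <- function(centroid_max = 4.5, angle_max = 30, offset_max = 2.0,
                           pi_centroid_max = 5.5, ef_split = 50,
                           cation_pi_max = 6.0) {
  structure(list(centroid_max = centroid_max, angle_max = angle_max,
                 offset_max = offset_max, pi_centroid_max = pi_centroid_max,
                 ef_split = ef_split, cation_pi_max = cation_pi_max),
            class = "stack_criteria")
}

# RNA moiety from atom name
RNA_PHOSPHATE <- c("P", "OP1", "OP2", "OP3", "O5'", "O3'")
RNA_RIBOSE <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'")

#' @export
rna_moiety <- function(atom) {
  dplyr::case_when(
    atom %in% RNA_PHOSPHATE ~ "phosphate",
    atom %in% RNA_RIBOSE ~ "ribose",
    TRUE ~ "base"
  )
}

vdist <- function(p, q) sqrt(sum((p - q)^2))

angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Covalent antecedents of a polar heavy atom: heavy atoms of the same
# residue within covalent range (bonded neighbours stand in for the
# unresolved hydrogens when checking donor directionality).
antecedents <- function(structure, row) {
  same <- structure[structure$chain == row$chain &
                      structure$resno == row$resno &
                      structure$ins == row$ins, , drop = FALSE]
  d <- sqrt((same$x - row$x)^2 + (same$y - row$y)^2 + (same$z - row$z)^2)
  same[d > 0.1 & d < 1.8, , drop = FALSE]
}

#' Detect hydrogen bonds between two atom selections
#'
#' Scans all polar-heavy-atom pairs (N, O, S on either side) across the two
#' selections; a pair is reported when the heavy-atom distance is within the
#' cutoff and, wherever a covalent antecedent is identifiable, at least one
#' antecedent-donor-acceptor angle meets the minimum in either donor
#' direction (the search is symmetric in donor/acceptor roles). RNA atoms
#' are classified into phosphate / ribose / base moieties.
#'
#' @param structure A `helicore_structure` (used to find covalent
#'   antecedents).
#' @param sel_a,sel_b Atom tibbles (subsets of `structure`), e.g. a protein
#'   domain and an RNA chain.
#' @param criteria An [hbond_criteria()] object.
#' @return `ContactRecord` tibble: `kind`, protein-side and partner-side
#'   chain / residue / atom descriptors, `moiety` (for RNA partners),
#'   `distance`, `angle` (best antecedent angle, `NA` when no antecedent
#'   exists). Zero rows is a valid result.
#' @export
hydrogen_bonds <- function(structure, sel_a, sel_b, criteria = hbond_criteria()) {
  pa <- sel_a[sel_a$element %in% c("N", "O", "S"), , drop = FALSE]
  pb <- sel_b[sel_b$element %in% c("N", "O", "S"), , drop = FALSE]
  out <- list()
  if (nrow(pa) == 0 || nrow(pb) == 0) return(empty_contacts())
  for (i in seq_len(nrow(pa))) {
    ai <- pa[i, ]
    d <- sqrt((pb$x - ai$x)^2 + (pb$y - ai$y)^2 + (pb$z - ai$z)^2)
    hits <- which(d <= criteria$dist_max & d > 0.5)
    for (j in hits) {
      bj <- pb[j, ]
      ok <- FALSE; best_ang <- NA_real_
      for (side in list(list(don = ai, acc = bj), list(don = bj, acc = ai))) {
        ante <- antecedents(structure, side$don)
        if (nrow(ante) == 0) { ok <- TRUE; next }
        angs <- vapply(seq_len(nrow(ante)), function(k) {
          angle_deg(c(ante$x[k], ante$y[k], ante$z[k]),
                    c(side$don$x, side$don$y, side$don$z),
                    c(side$acc$x, side$acc$y, side$acc$z))
        }, numeric(1))
        if (max(angs) >= criteria$angle_min) {
          ok <- TRUE
          best_ang <- max(best_ang, max(angs), na.rm = TRUE)
        }
      }
      if (ok) {
        out[[length(out) + 1]] <- tibble::tibble(
          kind = "hbond",
          chain_a = ai$chain, resno_a = ai$resno, resname_a = ai$resname,
          atom_a = ai$atom,
          chain_b = bj$chain, resno_b = bj$resno, resname_b = bj$resname,
          atom_b = bj$atom,
          moiety = if (bj$polymer == "RNA") rna_moiety(bj$atom)
                   else if (ai$polymer == "RNA") rna_moiety(ai$atom)
                   else NA_character_,
          distance = d[j], angle = best_ang
        )
      }
    }
  }
  if (length(out) == 0) return(empty_contacts())
  dplyr::bind_rows(out)
}

empty_contacts <- function() {
  tibble::tibble(
    kind = character(), chain_a = character(), resno_a = integer(),
    resname_a = character(), atom_a = character(), chain_b = character(),
    resno_b = integer(), resname_b = character(), atom_b = character(),
    moiety = character(), distance = numeric(), angle = numeric()
  )
}

#' Count domain residues hydrogen-bonding to the RNA backbone
#'
#' Distinct protein residues within a domain that make at least one
#' hydrogen bond to a phosphate or ribose moiety of the given RNA chain.
#' This is the per-domain grip on the sugar-phosphate backbone that decides
#' which RecA-like domain keeps hold of the RNA through the catalytic cycle.
#'
#' @param structure A `helicore_structure` containing protein and RNA.
#' @param chain Protein chain id.
#' @param domain One-row domain definition (or `name`,`start`,`end` tibble
#'   row).
#' @param rna_chain RNA chain id.
#' @param criteria [hbond_criteria()].
#' @return Integer count of distinct contacting residues, with attribute
#'   `residues` (their author numbers).
#' @export
count_backbone_contact_residues <- function(structure, chain, domain, rna_chain,
                                            criteria = hbond_criteria()) {
  dom_atoms <- select_atoms(structure, chain, c(domain$start, domain$end),
                            "all-heavy")
  rna_atoms <- structure[structure$chain == rna_chain &
                           structure$polymer == "RNA", , drop = FALSE]
  if (nrow(rna_atoms) == 0) stop("no RNA atoms on chain ", rna_chain)
  hb <- hydrogen_bonds(structure, dom_atoms, rna_atoms, criteria)
  hb <- hb[!is.na(hb$moiety) & hb$moiety %in% c("phosphate", "ribose"), ,
           drop = FALSE]
  res <- sort(unique(hb$resno_a))
  n <- length(res)
  attr(n, "residues") <- res
  n
}

# ---- ring geometry ------------------------------------------------------

# Ring atom tables. Purine bases use the six-membered ring for stacking
# geometry (one convention throughout); the proline ring is included so
# CH-pi stacking such as a His-Pro-Phe triad is detectable.
RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PRO = c("N", "CA", "CB", "CG", "CD"),
  A = c("N1", "C2", "N3", "C4", "C5", "C6"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

CATION_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")

# Centroid and unit normal of a ring from its atom coordinates (SVD plane
# fit; robust to slight non-planarity).
ring_plane <- function(xyz) {
  centroid <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, centroid))
  normal <- sv$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

# All defined rings in a structure: one row per ring with list-columns for
# centroid and normal. Requires >= 4 modeled ring atoms.
find_rings <- function(structure) {
  keys <- unique(structure[, c("chain", "resno", "ins", "resname", "polymer")])
  rings <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    defn <- RING_ATOMS[[k$resname]]
    if (is.null(defn)) next
    at <- structure[structure$chain == k$chain & structure$resno == k$resno &
                      structure$ins == k$ins & structure$atom %in% defn, ,
                    drop = FALSE]
    if (nrow(at) < 4) next
    pl <- ring_plane(as.matrix(at[, c("x", "y", "z")]))
    rings[[length(rings) + 1]] <- tibble::tibble(
      chain = k$chain, resno = k$resno, ins = k$ins, resname = k$resname,
      polymer = k$polymer,
      cx = pl$centroid[1], cy = pl$centroid[2], cz = pl$centroid[3],
      nx = pl$normal[1], ny = pl$normal[2], nz = pl$normal[3]
    )
  }
  if (length(rings) == 0) return(NULL)
  dplyr::bind_rows(rings)
}

interplanar_angle <- function(n1, n2) {
  a <- acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
  a
}

# Lateral offset of centroid 2 from the normal axis of ring 1 (and vice
# versa); the smaller of the two is used, as stacking only requires one
# ring to sit over the other.
centroid_offset <- function(c1, n1, c2, n2) {
  d <- c2 - c1
  off1 <- sqrt(max(0, sum(d^2) - sum(d * n1)^2))
  off2 <- sqrt(max(0, sum(d^2) - sum(d * n2)^2))
  min(off1, off2)
}

#' Detect pi-pi and cation-pi ring interactions
#'
#' Every pair of defined rings (aromatic side chains, the proline ring,
#' nucleobase six-membered rings) whose centroids fall within the pi-pi
#' cutoff is reported, classified as parallel-displaced or edge-to-face by
#' the interplanar angle. Charged side-chain nitrogens (Arg guanidinium,
#' Lys ammonium) within the cation-pi cutoff of a ring centroid are
#' reported as cation-pi contacts.
#'
#' @param structure A `helicore_structure`.
#' @param criteria A [stack_criteria()] object.
#' @return `ContactRecord` tibble with `kind` in
#'   `c("pi-pi-parallel-displaced", "pi-pi-edge-to-face", "cation-pi")`,
#'   the two residues, `distance` (centroid-centroid or N-centroid) and
#'   `angle` (interplanar, `NA` for cation-pi).
#' @export
ring_interactions <- function(structure, criteria = stack_criteria()) {
  rings <- find_rings(structure)
  out <- list()
  if (!is.null(rings) && nrow(rings) > 1) {
    for (i in seq_len(nrow(rings) - 1)) {
      for (j in seq((i + 1), nrow(rings))) {
        ri <- rings[i, ]; rj <- rings[j, ]
        if (ri$chain == rj$chain && ri$resno == rj$resno && ri$ins == rj$ins) next
        c1 <- c(ri$cx, ri$cy, ri$cz); c2 <- c(rj$cx, rj$cy, rj$cz)
        d <- vdist(c1, c2)
        if (d > criteria$pi_centroid_max) next
        ang <- interplanar_angle(c(ri$nx, ri$ny, ri$nz), c(rj$nx, rj$ny, rj$nz))
        kind <- if (ang < criteria$ef_split) "pi-pi-parallel-displaced"
                else "pi-pi-edge-to-face"
        out[[length(out) + 1]] <- tibble::tibble(
          kind = kind,
          chain_a = ri$chain, resno_a = ri$resno, resname_a = ri$resname,
          atom_a = "ring",
          chain_b = rj$chain, resno_b = rj$resno, resname_b = rj$resname,
          atom_b = "ring",
          moiety = if (rj$polymer == "RNA" || ri$polymer == "RNA") "base"
                   else NA_character_,
          distance = d, angle = ang
        )
      }
    }
  }
  # cation-pi
  cat_at <- structure[
    (structure$resname == "ARG" & structure$atom %in% CATION_ATOMS$ARG) |
      (structure$resname == "LYS" & structure$atom %in% CATION_ATOMS$LYS), ,
    drop = FALSE]
  if (!is.null(rings) && nrow(cat_at) > 0) {
    for (i in seq_len(nrow(cat_at))) {
      ai <- cat_at[i, ]
      for (j in seq_len(nrow(rings))) {
        rj <- rings[j, ]
        if (ai$chain == rj$chain && ai$resno == rj$resno) next
        d <- vdist(c(ai$x, ai$y, ai$z), c(rj$cx, rj$cy, rj$cz))
        if (d <= criteria$cation_pi_max) {
          out[[length(out) + 1]] <- tibble::tibble(
            kind = "cation-pi",
            chain_a = ai$chain, resno_a = ai$resno, resname_a = ai$resname,
            atom_a = ai$atom,
            chain_b = rj$chain, resno_b = rj$resno, resname_b = rj$resname,
            atom_b = "ring",
            moiety = if (rj$polymer == "RNA") "base" else NA_character_,
            distance = d, angle = NA_real_
          )
        }
      }
    }
  }
  if (length(out) == 0) return(empty_contacts())
  # deduplicate cation-pi per residue pair (keep closest nitrogen)
  dplyr::bind_rows(out) |>
    dplyr::group_by(.data$kind, .data$chain_a, .data$resno_a,
                    .data$chain_b, .data$resno_b) |>
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Is the His-Pro-Phe stacking triad present?
#'
#' Checks that the histidine ring stacks on the proline ring and the proline
#' ring on the phenylalanine ring (a mutual stacking chain), given the three
#' residue numbers on one chain.
#'
#' @param structure A `helicore_structure`.
#' @param chain Protein chain.
#' @param residues Length-3 integer vector (His, Pro, Phe author numbers).
#' @param criteria [stack_criteria()].
#' @return Logical scalar.
#' @export
has_stacking_triad <- function(structure, chain, residues = c(1128L, 1129L, 1134L),
                               criteria = stack_criteria()) {
  sub <- structure[structure$chain == chain &
                     structure$resno %in% residues, , drop = FALSE]
  ri <- ring_interactions(new_structure(sub, structure_id(structure)), criteria)
  pp <- ri[ri$kind %in% c("pi-pi-parallel-displaced", "pi-pi-edge-to-face"), ]
  link <- function(r1, r2) any((pp$resno_a == r1 & pp$resno_b == r2) |
                                 (pp$resno_a == r2 & pp$resno_b == r1))
  link(residues[1], residues[2]) && link(residues[2], residues[3])
}

# ---- RNA stack segmentation --------------------------------------------

# 5'->3' nucleotide order from chain connectivity: nucleotide j follows i
# when O3'(i) is covalently bonded to P(j). Fragments (broken connectivity)
# are concatenated in author-number order.
rna_chain_order <- function(structure, rna_chain) {
  nt <- unique(structure[structure$chain == rna_chain &
                           structure$polymer == "RNA",
                         c("chain", "resno", "ins", "resname")])
  if (nrow(nt) < 1) stop("no RNA nucleotides on chain ", rna_chain)
  nt <- dplyr::arrange(nt, .data$resno, .data$ins)
  get_atom <- function(resno, ins, name) {
    a <- structure[structure$chain == rna_chain & structure$resno == resno &
                     structure$ins == ins & structure$atom == name, ,
                   drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    c(a$x[1], a$y[1], a$z[1])
  }
  n <- nrow(nt)
  succ <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    o3 <- get_atom(nt$resno[i], nt$ins[i], "O3'")
    if (is.null(o3)) next
    for (j in seq_len(n)) {
      if (i == j) next
      p <- get_atom(nt$resno[j], nt$ins[j], "P")
      if (!is.null(p) && vdist(o3, p) < 2.0) { succ[i] <- j; break }
    }
  }
  has_pred <- seq_len(n) %in% succ
  starts <- which(!has_pred)
  order_idx <- integer(0)
  for (s in starts[order(nt$resno[starts])]) {
    i <- s
    while (!is.na(i) && !(i %in% order_idx)) {
      order_idx <- c(order_idx, i)
      i <- succ[i]
    }
  }
  order_idx <- c(order_idx, setdiff(seq_len(n), order_idx))
  nt[order_idx, , drop = FALSE]
}

#' Segment the bound RNA into base-stacked runs
#'
#' Orders the nucleotides 5' to 3' from backbone connectivity, marks each
#' consecutive pair as stacked when its base-ring geometry (centroid
#' distance, interplanar angle, lateral offset) meets the criteria, and
#' assembles maximal stacked runs. For each break between adjacent
#' non-stacked nucleotides, protein residues whose atoms intercalate
#' between the two base centroids are reported as the interrupting element
#' (in the helicase this is the RecA2 beta-hairpin bounding the stack).
#'
#' @param structure A `helicore_structure`.
#' @param rna_chain RNA chain id.
#' @param criteria [stack_criteria()].
#' @return Object of class `stack_report`: list with `nucleotides` (ordered
#'   tibble with 5'->3' `index`), `runs` (tibble `start`, `end`, `length`
#'   in 5'->3' indices), `max_stack`, and `interruptions` (tibble of break
#'   position and intercalating protein residues).
#' @export
stack_segments <- function(structure, rna_chain, criteria = stack_criteria()) {
  nt <- rna_chain_order(structure, rna_chain)
  if (nrow(nt) < 2) stop("need >= 2 nucleotides")
  nt$index <- seq_len(nrow(nt))
  planes <- vector("list", nrow(nt))
  for (i in seq_len(nrow(nt))) {
    at <- structure[structure$chain == rna_chain & structure$resno == nt$resno[i] &
                      structure$ins == nt$ins[i] &
                      structure$atom %in% RING_ATOMS[[nt$resname[i]]], ,
                    drop = FALSE]
    planes[[i]] <- if (nrow(at) >= 4)
      ring_plane(as.matrix(at[, c("x", "y", "z")])) else NULL
  }
  n <- nrow(nt)
  stacked <- rep(FALSE, n - 1)
  for (i in seq_len(n - 1)) {
    p1 <- planes[[i]]; p2 <- planes[[i + 1]]
    if (is.null(p1) || is.null(p2)) next
    d <- vdist(p1$centroid, p2$centroid)
    ang <- interplanar_angle(p1$normal, p2$normal)
    off <- centroid_offset(p1$centroid, p1$normal, p2$centroid, p2$normal)
    stacked[i] <- d <= criteria$centroid_max && ang <= criteria$angle_max &&
      off <= criteria$offset_max
  }
  runs <- list(); start <- 1
  for (i in seq_len(n - 1)) {
    if (!stacked[i]) {
      runs[[length(runs) + 1]] <- c(start, i)
      start <- i + 1
    }
  }
  runs[[length(runs) + 1]] <- c(start, n)
  runs <- dplyr::bind_rows(lapply(runs, function(r) {
    tibble::tibble(start = r[1], end = r[2], length = r[2] - r[1] + 1L)
  }))
  inter <- list()
  prot <- structure[structure$polymer == "protein", , drop = FALSE]
  if (nrow(prot) > 0) {
    for (i in which(!stacked)) {
      p1 <- planes[[i]]; p2 <- planes[[i + 1]]
      if (is.null(p1) || is.null(p2)) next
      mid <- (p1$centroid + p2$centroid) / 2
      gap <- vdist(p1$centroid, p2$centroid)
      d <- sqrt((prot$x - mid[1])^2 + (prot$y - mid[2])^2 + (prot$z - mid[3])^2)
      near <- prot[d <= pmax(gap, 5), , drop = FALSE]
      if (nrow(near) > 0) {
        inter[[length(inter) + 1]] <- tibble::tibble(
          break_after_index = i,
          chain = near$chain, resno = near$resno, resname = near$resname
        ) |> dplyr::distinct()
      }
    }
  }
  interruptions <- if (length(inter) > 0) dplyr::bind_rows(inter) else
    tibble::tibble(break_after_index = integer(), chain = character(),
                   resno = integer(), resname = character())
  structure(
    list(nucleotides = nt, runs = runs,
         max_stack = max(runs$length), interruptions = interruptions,
         criteria = criteria),
    class = "stack_report"
  )
}

#' @export
print.stack_report <- function(x, ...) {
  cat(sprintf("RNA stack report: %d nucleotides, max stack %d\n",
              nrow(x$nucleotides), x$max_stack))
  cat("runs:", paste(x$runs$length, collapse = ", "), "\n")
  invisible(x)
}

# ---- backbone dihedrals / helicity -------------------------------------

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Alpha-helical (phi, psi) window; brackets the canonical (-57, -47).
HELICAL_PHI <- c(-100, -30)
HELICAL_PSI <- c(-80, -5)

#' Backbone-dihedral helicity of a residue range
#'
#' Computes phi/psi for each residue of the range from N/CA/C backbone
#' atoms, marks a residue helical when both angles fall inside the
#' alpha-helical window (phi in \[-100, -30\], psi in \[-80, -5\] degrees),
#' and labels the range `"helical"` when at least 80\% of assessable
#' residues are helical, `"distorted"` otherwise. Dihedrals spanning a
#' chain break (peptide C-N distance > 2 A) are skipped and counted as
#' non-assessable.
#'
#' @param structure A `helicore_structure`.
#' @param chain Chain id.
#' @param range Length-2 inclusive author-numbered interval (>= 4 residues).
#' @param helical_min Fraction of helical residues required for the
#'   `"helical"` label (default 0.8).
#' @return Object of class `helicity_report`: list with `residues` (tibble
#'   `resno`, `phi`, `psi`, `helical`), `fraction_helical`, `label`.
#' @export
motif_helicity <- function(structure, chain, range, helical_min = 0.8) {
  range <- as.integer(range)
  if (range[2] - range[1] + 1 < 4) stop("need >= 4 consecutive residues")
  bb <- structure[structure$chain == chain & structure$polymer == "protein" &
                    structure$atom %in% c("N", "CA", "C"), , drop = FALSE]
  get <- function(resno, name) {
    a <- bb[bb$resno == resno & bb$atom == name, , drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    c(a$x[1], a$y[1], a$z[1])
  }
  rows <- list()
  for (r in seq(range[1], range[2])) {
    Cm <- get(r - 1, "C"); N <- get(r, "N"); CA <- get(r, "CA")
    Cc <- get(r, "C"); Np <- get(r + 1, "N")
    phi <- psi <- NA_real_
    if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(Cc) &&
        vdist(Cm, N) < 2.0) {
      phi <- dihedral_deg(Cm, N, CA, Cc)
    }
    if (!is.null(N) && !is.null(CA) && !is.null(Cc) && !is.null(Np) &&
        vdist(Cc, Np) < 2.0) {
      psi <- dihedral_deg(N, CA, Cc, Np)
    }
    helical <- if (is.na(phi) || is.na(psi)) NA else
      phi >= HELICAL_PHI[1] && phi <= HELICAL_PHI[2] &&
      psi >= HELICAL_PSI[1] && psi <= HELICAL_PSI[2]
    rows[[length(rows) + 1]] <- tibble::tibble(resno = r, phi = phi, psi = psi,
                                               helical = helical)
  }
  res <- dplyr::bind_rows(rows)
  assessable <- sum(!is.na(res$helical))
  frac <- if (assessable == 0) NA_real_ else
    sum(res$helical, na.rm = TRUE) / assessable
  structure(
    list(residues = res, fraction_helical = frac,
         label = if (!is.na(frac) && frac >= helical_min) "helical" else "distorted"),
    class = "helicity_report"
  )
}

#' @export
print.helicity_report <- function(x, ...) {
  cat(sprintf("helicity: fraction %.2f -> %s\n", x$fraction_helical, x$label))
  invisible(x)
}
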