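# Open/closed classification of the helicase core via the center-of-mass
# distance protocol: the RecA1 and RecA2 domains of a reference RNA complex
# are superposed individually onto the corresponding domains of each
# catalytic state, and the distance between the centers of mass of the two
# transplanted reference domains is the conformational coordinate. Computing
# both COMs over the *reference's* atoms guarantees the distance is always
# measured over the same atom set, regardless of which residues happen to be
# modeled in the target.

#' Open/closed threshold for the RecA1-RecA2 center-of-mass distance
#'
#' Nucleotide-bound helicase cores sit near 27.3-27.7 A, nucleotide-free
#' ones near 31 A and above; the default cut of 29.5 A is the midpoint of
#' that gap.
#' @export
HELICORE_DCOM_THRESHOLD <- 29.5

#' Classify a helicase core as open or closed from its COM distance
#'
#' @param d_com RecA1-RecA2 center-of-mass distance, Angstrom (> 0).
#' @param threshold Boundary in Angstrom; distances at or above it are
#'   `"open"`, below it `"closed"`.
#' @return `"closed"` or `"open"` (vectorised).
#' @export
classify_state <- function(d_com, threshold = HELICORE_DCOM_THRESHOLD) {
  stopifnot(all(d_com > 0))
  ifelse(d_com < threshold, "closed", "open")
}

#' Center-of-mass distance protocol for one target chain
#'
#' For each of RecA1 and RecA2: pair the common atoms of the reference
#' domain and the target domain, least-squares fit the reference onto the
#' target, transform the full reference domain, and take its center of mass.
#' The reported `d_com` is the distance between the two transplanted
#' reference-domain centers.
#'
#' @param target,reference `helicore_structure` objects.
#' @param target_chain,reference_chain Chain ids analysed.
#' @param target_domains,reference_domains Domain-definition tibbles
#'   containing `RecA1` and `RecA2` rows ([ct_prp22_domains()] by default
#'   for the reference).
#' @param equivalence Optional residue-equivalence table (`resno_a` =
#'   reference numbering, `resno_b` = target numbering) for cross-protein
#'   comparisons.
#' @param atom_filter Atom subset used for pairing and COM (default
#'   `"CA-only"`).
#' @param weighting COM weighting, `"uniform"` or `"atomic-mass"`.
#' @param threshold Open/closed boundary passed to [classify_state()].
#' @param rmsd_warn Sanity ceiling (Angstrom): a per-domain fit RMSD above
#'   it triggers a warning but the result is still returned.
#' @return One-row `ConformationReport` tibble: `target_id`, `chain`,
#'   `reference_id`, `d_com`, `state`, per-domain `rmsd_*` and `n_pairs_*`.
#' @export
com_distance_protocol <- function(target, reference,
                                  target_chain, reference_chain,
                                  target_domains = ct_prp22_domains(target_chain),
                                  reference_domains = ct_prp22_domains(reference_chain),
                                  equivalence = NULL,
                                  atom_filter = "CA-only",
                                  weighting = "uniform",
                                  threshold = HELICORE_DCOM_THRESHOLD,
                                  rmsd_warn = 5) {
  coms <- list(); rmsds <- c(); npairs <- c()
  for (dom in c("RecA1", "RecA2")) {
    rrow <- reference_domains[reference_domains$name == dom, , drop = FALSE]
    trow <- target_domains[target_domains$name == dom, , drop = FALSE]
    if (nrow(rrow) != 1 || nrow(trow) != 1) {
      stop("both structures need a single ", dom, " definition")
    }
    ref_sel <- select_atoms(reference, reference_chain,
                            c(rrow$start, rrow$end), atom_filter)
    tgt_sel <- select_atoms(target, target_chain,
                            c(trow$start, trow$end), atom_filter)
    pairs <- pair_common_atoms(
      ref_sel, tgt_sel,
      mode = if (is.null(equivalence)) "by-residue-number" else "by-alignment",
      equivalence = equivalence
    )
    fit <- kabsch_fit(pairs)
    if (fit$rmsd > rmsd_warn) {
      warning(sprintf("%s superposition rmsd %.2f A exceeds sanity ceiling %.1f A",
                      dom, fit$rmsd, rmsd_warn))
    }
    moved <- apply_transform(fit, ref_sel)
    coms[[dom]] <- center_of_mass(moved, weighting)
    rmsds[dom] <- fit$rmsd
    npairs[dom] <- fit$n_pairs
  }
  d_com <- sqrt(sum((coms$RecA1 - coms$RecA2)^2))
  tibble::tibble(
    target_id = structure_id(target), chain = target_chain,
    reference_id = structure_id(reference),
    d_com = d_com, state = classify_state(d_com, threshold),
    rmsd_RecA1 = rmsds[["RecA1"]], rmsd_RecA2 = rmsds[["RecA2"]],
    n_pairs_RecA1 = npairs[["RecA1"]], n_pairs_RecA2 = npairs[["RecA2"]]
  )
}

#' Rigid-body shift of a mobile domain between two catalytic states
#'
#' Superposes the anchor domain (default RecA1) of state `a` onto state `b`,
#' then fits the anchor-aligned mobile domain (default RecA2) of `a` onto
#' the mobile domain of `b`; the residual transform, decomposed at the
#' mobile domain's center of mass, gives the inter-state rotation angle and
#' COM displacement of the mobile domain.
#'
#' @param state_a,state_b `helicore_structure` objects.
#' @param chain_a,chain_b Chains analysed.
#' @param domains_a,domains_b Domain definitions for each structure.
#' @param anchor,mobile Domain names (defaults `"RecA1"`, `"RecA2"`).
#' @param equivalence Optional residue map (`resno_a` in `a` numbering,
#'   `resno_b` in `b` numbering) for cross-protein comparisons.
#' @param atom_filter Atom subset for both fits.
#' @return `transform_decomposition` (angle in degrees, axis, displacement
#'   of the mobile COM in Angstrom) with extra fields `anchor_rmsd`,
#'   `mobile_rmsd`, `n_pairs_anchor`, `n_pairs_mobile`.
#' @export
domain_shift <- function(state_a, state_b, chain_a, chain_b,
                         domains_a = ct_prp22_domains(chain_a),
                         domains_b = ct_prp22_domains(chain_b),
                         anchor = "RecA1", mobile = "RecA2",
                         equivalence = NULL, atom_filter = "CA-only") {
  mode <- if (is.null(equivalence)) "by-residue-number" else "by-alignment"
  get_dom <- function(s, ch, doms, name) {
    row <- doms[doms$name == name, , drop = FALSE]
    if (nrow(row) != 1) stop("missing domain definition: ", name)
    select_atoms(s, ch, c(row$start, row$end), atom_filter)
  }
  anc_a <- get_dom(state_a, chain_a, domains_a, anchor)
  anc_b <- get_dom(state_b, chain_b, domains_b, anchor)
  anchor_fit <- kabsch_fit(pair_common_atoms(anc_a, anc_b, mode, equivalence))

  mob_a <- get_dom(state_a, chain_a, domains_a, mobile)
  mob_b <- get_dom(state_b, chain_b, domains_b, mobile)
  mob_a_aligned <- apply_transform(anchor_fit, mob_a)
  mob_pairs <- pair_common_atoms(mob_a_aligned, mob_b, mode, equivalence)
  mobile_fit <- kabsch_fit(mob_pairs)
  dec <- decompose_transform(mobile_fit,
                             reference_point = center_of_mass(mob_a_aligned))
  dec$anchor_rmsd <- anchor_fit$rmsd
  dec$mobile_rmsd <- mobile_fit$rmsd
  dec$n_pairs_anchor <- anchor_fit$n_pairs
  dec$n_pairs_mobile <- mobile_fit$n_pairs
  dec
}

#' Displacement of RNA-contacting residues between two states
#'
#' Models the frame of state `b` into state `a` by superposing the anchor
#' (RecA1) domains, then reports how far the representative atom (CA) of
#' each listed residue moves between the two anchor-aligned frames. This is
#' the geometry behind transplanting the ssRNA of a nucleotide-bound complex
#' into another catalytic state and asking which RNA-contacting residues can
#' no longer reach it.
#'
#' @inheritParams domain_shift
#' @param residues Integer vector of author residue numbers (state-`a`
#'   numbering) to track, e.g. the conserved RecA2 RNA-contact residues.
#' @return Tibble `resno`, `resname`, `displacement_A`, `modeled`;
#'   unmodeled residues are flagged, not dropped.
#' @export
modeled_rna_displacement <- function(state_a, state_b, chain_a, chain_b,
                                     residues,
                                     domains_a = ct_prp22_domains(chain_a),
                                     domains_b = ct_prp22_domains(chain_b),
                                     anchor = "RecA1",
                                     equivalence = NULL,
                                     atom_filter = "CA-only") {
  mode <- if (is.null(equivalence)) "by-residue-number" else "by-alignment"
  arow <- domains_a[domains_a$name == anchor, , drop = FALSE]
  brow <- domains_b[domains_b$name == anchor, , drop = FALSE]
  anc_a <- select_atoms(state_a, chain_a, c(arow$start, arow$end), atom_filter)
  anc_b <- select_atoms(state_b, chain_b, c(brow$start, brow$end), atom_filter)
  fit_ab <- kabsch_fit(pair_common_atoms(anc_a, anc_b, mode, equivalence))
  inv <- list(rotation = t(fit_ab$rotation),
              translation = as.numeric(-t(fit_ab$rotation) %*% fit_ab$translation))
  b_aligned <- apply_transform(inv, state_b[state_b$chain == chain_b, ])
  map_b <- if (mode == "by-alignment") {
    function(r) equivalence$resno_b[match(r, equivalence$resno_a)]
  } else identity
  purrr::map_dfr(residues, function(r) {
    ca_a <- state_a[state_a$chain == chain_a & state_a$resno == r &
                      state_a$atom == "CA", , drop = FALSE]
    rb <- map_b(r)
    ca_b <- b_aligned[!is.na(rb) & b_aligned$resno == rb &
                        b_aligned$atom == "CA", , drop = FALSE]
    if (nrow(ca_a) < 1 || nrow(ca_b) < 1) {
      return(tibble::tibble(resno = r, resname = NA_character_,
                            displacement_A = NA_real_, modeled = FALSE))
    }
    tibble::tibble(
      resno = r, resname = ca_a$resname[1],
      displacement_A = sqrt((ca_a$x[1] - ca_b$x[1])^2 +
                              (ca_a$y[1] - ca_b$y[1])^2 +
                              (ca_a$z[1] - ca_b$z[1])^2),
      modeled = TRUE
    )
  })
}
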