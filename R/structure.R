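# Atomic data model: a structure is a tibble of heavy atoms, one row per atom,
# carrying author chain/residue numbering so that residue-level annotations
# (domains, motifs) can be expressed the way crystallographers write them.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)
STANDARD_RNA <- c("A", "C", "G", "U")

# Monoisotopic-free standard atomic weights for mass-weighted centers of mass.
ATOMIC_MASS <- c(
  "H" = 1.008, "C" = 12.011, "N" = 14.007, "O" = 15.999, "P" = 30.974,
  "S" = 32.06, "SE" = 78.971, "MG" = 24.305, "K" = 39.098, "NA" = 22.990,
  "ZN" = 65.38, "CL" = 35.45, "F" = 18.998, "BE" = 9.012, "FE" = 55.845,
  "MN" = 54.938
)

#' Classify a residue name as protein, RNA or other
#'
#' Standard amino acids (plus MSE/SEC/PYL) map to `"protein"`, the four
#' ribonucleotides to `"RNA"`, everything else (waters, ions, ligands) to
#' `"other"`.
#'
#' @param resname Character vector of residue names (e.g. `"ALA"`, `"U"`).
#' @return Character vector of the same length with values
#'   `"protein"`, `"RNA"` or `"other"`.
#' @export
polymer_class <- function(resname) {
  dplyr::case_when(
    toupper(resname) %in% STANDARD_AA ~ "protein",
    toupper(resname) %in% STANDARD_RNA ~ "RNA",
    TRUE ~ "other"
  )
}

atom_tbl_columns <- c(
  "chain", "resno", "ins", "resname", "atom", "altloc", "element",
  "x", "y", "z", "occ", "b", "polymer"
)

#' Construct a structure from an atom table
#'
#' Low-level constructor validating the atom-table contract (finite
#' coordinates, required columns). Mostly used by fixture generators and
#' when assembling structures in code.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `ins`, `resname`,
#'   `atom`, `altloc`, `element`, `x`, `y`, `z`, `occ`, `b`, `polymer`.
#' @param id Structure identifier.
#' @return A `helicore_structure` tibble.
#' @export
new_structure <- function(atoms, id = "unknown") {
  atoms <- tibble::as_tibble(atoms)
  missing <- setdiff(atom_tbl_columns, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  out <- atoms[, atom_tbl_columns]
  attr(out, "id") <- id
  class(out) <- c("helicore_structure", class(tibble::tibble()))
  out
}

#' @export
structure_id <- function(structure) attr(structure, "id") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a macromolecular coordinate file into a tidy atom table
#'
#' Parses legacy PDB or mmCIF (dispatch on file extension, overridable) via
#' the readers in \pkg{bio3d} and returns one row per heavy atom with author
#' chain id, author residue number, insertion code, residue name, atom name,
#' element, coordinates in Angstrom, occupancy and isotropic B-factor.
#'
#' Policy applied on ingestion:
#' \itemize{
#'   \item hydrogens and zero-occupancy atoms are dropped (they carry no
#'     reliable geometric signal at the resolutions this package targets);
#'   \item where alternate locations exist, the highest-occupancy conformer
#'     is kept, ties broken alphabetically by alt-loc identifier;
#'   \item waters and ions are retained but flagged `polymer = "other"`.
#' }
#'
#' @param source Path to a `.pdb`/`.ent` or `.cif` file.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"cif"`.
#' @param id Structure identifier; defaults to the file stem.
#' @return A `helicore_structure`: a tibble of atoms (columns `chain`,
#'   `resno`, `ins`, `resname`, `atom`, `altloc`, `element`, `x`, `y`, `z`,
#'   `occ`, `b`, `polymer`) with the id stored as an attribute.
#' @export
read_structure <- function(source, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("file not found: ", source)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(source, rm.alt = FALSE)
      else bio3d::read.pdb(source, rm.alt = FALSE)
    ),
    error = function(e) {
      stop("could not parse ", format, " file '", source, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty model in ", source)
  atoms <- tibble::tibble(
    chain   = as.character(at$chain),
    resno   = as.integer(at$resno),
    ins     = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = trimws(as.character(at$resid)),
    atom    = trimws(as.character(at$elety)),
    altloc  = ifelse(is.na(at$alt), "", as.character(at$alt)),
    element = toupper(trimws(ifelse(is.na(at$elesy), "", as.character(at$elesy)))),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b   = ifelse(is.na(at$b), 0, at$b)
  )
  atoms$chain[is.na(atoms$chain)] <- ""
  # element fallback from the atom name when the element column is absent
  blank <- atoms$element == ""
  atoms$element[blank] <- gsub("[^A-Z]", "", substr(toupper(atoms$atom[blank]), 1, 1))
  atoms <- atoms[!(atoms$element %in% c("H", "D")) & atoms$occ > 0, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms with positive occupancy in ", source)
  atoms <- resolve_altloc(atoms)
  atoms$polymer <- polymer_class(atoms$resname)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, atoms$altloc)
  if (anyDuplicated(key)) {
    stop("duplicate atom keys after alt-loc resolution in ", source)
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(source))
  new_structure(atoms, id = id)
}

# Keep the highest-occupancy conformer per (chain, resno, ins, atom);
# ties broken alphabetically by alt-loc id.
resolve_altloc <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$ins, .data$atom)
}

#' Write a structure as a legacy PDB file
#'
#' Fixed-width ATOM records, coordinates at 3 decimals. Used chiefly by the
#' fixture generators so parsing tests exercise the real reader.
#'
#' @param structure A `helicore_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure
  name4 <- ifelse(nchar(a$atom) < 4 & nchar(a$element) == 1,
                  sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
  rec <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$polymer == "other", "HETATM", "ATOM"),
    seq_len(nrow(a)) %% 100000L, name4,
    substr(paste0(a$altloc, " "), 1, 1), a$resname,
    substr(paste0(a$chain, " "), 1, 1), a$resno,
    substr(paste0(a$ins, " "), 1, 1),
    a$x, a$y, a$z, a$occ, a$b, a$element
  )
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Write a structure as a minimal mmCIF file
#'
#' Emits a single `atom_site` loop with both label and author numbering so
#' the standard readers recover the same atom table that went in.
#'
#' @inheritParams write_structure_pdb
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(structure, path) {
  a <- structure
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure_id(structure))),
    "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  q <- function(v, blank = ".") ifelse(v == "" | is.na(v), blank, v)
  rows <- sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(a$polymer == "other", "HETATM", "ATOM"),
    seq_len(nrow(a)), q(a$element, "C"), a$atom, q(a$altloc),
    a$resname, q(a$chain, "A"), a$resno, q(a$ins, "?"),
    a$x, a$y, a$z, a$occ, a$b, a$resno, a$resname, q(a$chain, "A"), a$atom
  )
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Select atoms of a domain from a structure
#'
#' @param structure A `helicore_structure`.
#' @param chain Chain identifier.
#' @param range Length-2 integer vector, inclusive author-numbered residue
#'   interval. `NULL` selects the whole chain.
#' @param atom_filter `"CA-only"` (alpha carbons; C1' for RNA residues),
#'   `"backbone"` (protein N/CA/C/O; RNA sugar-phosphate backbone) or
#'   `"all-heavy"`.
#' @return Tibble of atoms sorted by residue number then atom name, with an
#'   attribute `gaps` listing residue numbers in `range` that have no modeled
#'   atom.
#' @export
select_atoms <- function(structure, chain, range = NULL,
                         atom_filter = c("CA-only", "backbone", "all-heavy")) {
  atom_filter <- match.arg(atom_filter)
  if (!chain %in% unique(structure$chain)) {
    stop("chain '", chain, "' not present in structure ", structure_id(structure))
  }
  sel <- structure[structure$chain == chain, , drop = FALSE]
  if (!is.null(range)) {
    range <- as.integer(range)
    sel <- sel[sel$resno >= range[1] & sel$resno <= range[2], , drop = FALSE]
  }
  sel <- apply_atom_filter(sel, atom_filter)
  if (nrow(sel) == 0) {
    stop("empty selection for chain ", chain,
         if (!is.null(range)) paste0(" range ", range[1], "-", range[2]))
  }
  sel <- dplyr::arrange(sel, .data$resno, .data$ins, .data$atom)
  gaps <- integer(0)
  if (!is.null(range)) {
    gaps <- setdiff(seq(range[1], range[2]), unique(sel$resno))
  }
  attr(sel, "gaps") <- gaps
  sel
}

apply_atom_filter <- function(atoms, atom_filter) {
  switch(
    atom_filter,
    "CA-only" = atoms[(atoms$polymer == "protein" & atoms$atom == "CA") |
                        (atoms$polymer == "RNA" & atoms$atom == "C1'"), ,
                      drop = FALSE],
    "backbone" = atoms[(atoms$polymer == "protein" &
                          atoms$atom %in% c("N", "CA", "C", "O")) |
                         (atoms$polymer == "RNA" &
                            atoms$atom %in% c("P", "OP1", "OP2", "O5'", "C5'",
                                              "C4'", "C3'", "O3'")), ,
                       drop = FALSE],
    "all-heavy" = atoms
  )
}

#' Count modeled residues in an author-numbered interval
#'
#' A residue counts as resolved when at least one heavy atom is modeled.
#' Crystallographic models routinely omit disordered stretches, so this
#' count is reported against the interval length (and optionally against an
#' externally supplied denominator, since published per-domain residue
#' totals do not always equal the annotated interval length).
#'
#' @inheritParams select_atoms
#' @param range Length-2 inclusive residue interval.
#' @return Integer count of resolved residues, with attributes
#'   `interval_length` and `gaps`.
#' @export
resolved_residue_count <- function(structure, chain, range) {
  if (!chain %in% unique(structure$chain)) {
    stop("chain '", chain, "' not present in structure ", structure_id(structure))
  }
  range <- as.integer(range)
  stopifnot(length(range) == 2, range[2] >= range[1])
  sel <- structure[structure$chain == chain &
                     structure$resno >= range[1] &
                     structure$resno <= range[2], , drop = FALSE]
  n <- length(unique(paste(sel$resno, sel$ins)))
  attr(n, "interval_length") <- range[2] - range[1] + 1L
  attr(n, "gaps") <- setdiff(seq(range[1], range[2]), unique(sel$resno))
  n
}
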