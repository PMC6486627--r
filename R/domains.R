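# Domain and motif annotation for DEAH-box ATPases, expressed in author
# residue numbering. Defaults cover ctPrp22; further proteins are added via
# the plain-text config (inst/extdata/domains.tsv).

DOMAIN_ORDER <- c("Nterm", "RecA1", "RecA2", "WH", "HB", "OB")

#' Domain definitions for the ctPrp22 helicase core and C-terminal domains
#'
#' Author-numbered inclusive intervals: the truncated N-terminal stub
#' (549-556), RecA1 (557-733), RecA2 (734-909), winged-helix (910-977),
#' helix-bundle (978-1091) and OB fold (1092-1175).
#'
#' @param chain Chain identifier the definitions apply to (default `"A"`).
#' @return Tibble with columns `name`, `chain`, `start`, `end`.
#' @export
ct_prp22_domains <- function(chain = "A") {
  domain_definitions(
    name  = c("Nterm", "RecA1", "RecA2", "WH", "HB", "OB"),
    chain = chain,
    start = c(549L, 557L, 734L, 910L, 978L, 1092L),
    end   = c(556L, 733L, 909L, 977L, 1091L, 1175L)
  )
}

#' Construct a validated domain-definition table
#'
#' @param name Domain names from
#'   `c("Nterm", "RecA1", "RecA2", "WH", "HB", "OB")`.
#' @param chain Chain id (recycled).
#' @param start,end Inclusive author-numbered interval bounds.
#' @return Tibble `name`, `chain`, `start`, `end`; intervals on one chain
#'   must be non-overlapping and the core/C-terminal domains in sequence
#'   order (RecA1 < RecA2 < WH < HB < OB).
#' @export
domain_definitions <- function(name, chain, start, end) {
  d <- tibble::tibble(
    name = as.character(name), chain = as.character(chain),
    start = as.integer(start), end = as.integer(end)
  )
  bad <- setdiff(d$name, DOMAIN_ORDER)
  if (length(bad) > 0) stop("unknown domain name(s): ", paste(bad, collapse = ", "))
  if (any(d$end < d$start)) stop("domain interval with end < start")
  for (ch in unique(d$chain)) {
    dd <- d[d$chain == ch, , drop = FALSE]
    dd <- dd[order(dd$start), , drop = FALSE]
    if (nrow(dd) > 1 && any(dd$start[-1] <= dd$end[-nrow(dd)])) {
      stop("overlapping domain intervals on chain ", ch)
    }
    core <- dd[dd$name %in% c("RecA1", "RecA2", "WH", "HB", "OB"), , drop = FALSE]
    ord <- match(core$name, c("RecA1", "RecA2", "WH", "HB", "OB"))
    if (is.unsorted(ord[order(core$start)])) {
      stop("domains out of sequence order on chain ", ch)
    }
  }
  d
}

#' Read domain definitions from the package's TSV config format
#'
#' Columns: `structure_id`, `chain`, `domain`, `start`, `end`. A chain value
#' of `*` applies to every chain of the structure and is expanded by
#' [domains_for()].
#'
#' @param path TSV file; default is the config shipped with the package.
#' @return Tibble of raw config rows.
#' @export
read_domain_config <- function(path = system.file("extdata", "domains.tsv",
                                                  package = "helicore")) {
  cfg <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("structure_id", "chain", "domain", "start", "end") %in%
                  names(cfg)))
  tibble::as_tibble(cfg)
}

#' Resolve configured domain definitions for one structure chain
#'
#' @param config Tibble from [read_domain_config()].
#' @param structure_id Structure identifier to look up.
#' @param chain Chain the definitions should be bound to.
#' @return A domain-definition tibble (see [domain_definitions()]).
#' @export
domains_for <- function(config, structure_id, chain) {
  rows <- config[config$structure_id == structure_id &
                   (config$chain == "*" | config$chain == chain), , drop = FALSE]
  if (nrow(rows) == 0) stop("no domain config for ", structure_id)
  domain_definitions(rows$domain, chain, rows$start, rows$end)
}

#' Motif and functional-residue annotation for ctPrp22
#'
#' Conserved-sequence-motif and structural-element residues discussed for
#' the ctPrp22 RNA complex: R612 (motif Ia), R639 (hook-turn), T654 (motif
#' Ib), S806 (hook-loop), T831 and S837 (motif V), K853 (beta-hairpin),
#' Q1073 (HB domain), the OB-fold stacking triad H1128/P1129/F1134, and
#' R1012 (HB, cation-pi partner of the 5' bases).
#'
#' @return Tibble `motif`, `resno`, `resname`.
#' @export
ct_prp22_motifs <- function() {
  tibble::tribble(
    ~motif,           ~resno, ~resname,
    "Ia",              612L,  "ARG",
    "hook-turn",       639L,  "ARG",
    "Ib",              654L,  "THR",
    "hook-loop",       806L,  "SER",
    "V",               831L,  "THR",
    "V",               837L,  "SER",
    "beta-hairpin",    853L,  "LYS",
    "HB",             1073L,  "GLN",
    "cation-pi",      1012L,  "ARG",
    "stacking-triad", 1128L,  "HIS",
    "stacking-triad", 1129L,  "PRO",
    "stacking-triad", 1134L,  "PHE"
  )
}

#' The motif V interval of ctPrp22
#'
#' Short RecA2 element around T831/S837 whose backbone conformation switches
#' between helical (nucleotide-free, ADP) and distorted (ATP-bound).
#'
#' @return Length-2 integer residue interval.
#' @export
ct_prp22_motif_v_range <- function() c(828L, 840L)

#' Check annotated residues against a structure
#'
#' @param structure A `helicore_structure`.
#' @param motifs Tibble as returned by [ct_prp22_motifs()].
#' @param chain Chain to check.
#' @return `motifs` with logical column `modeled` (FALSE marks residues
#'   absent from the model, e.g. disordered stretches).
#' @export
annotate_motifs <- function(structure, motifs, chain = "A") {
  present <- unique(structure$resno[structure$chain == chain])
  dplyr::mutate(motifs, modeled = .data$resno %in% present)
}
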