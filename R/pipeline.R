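# Orchestration: run the whole conformational-state analysis over a
# manifest of structures with ligand-state labels, producing the
# conformation table, pairwise domain-shift matrix, per-complex contact and
# stack tables, and a JSON-able summary.

LIGAND_STATES <- c("ATP-analog", "ADP", "apo", "RNA-only", "ATP-analog+RNA")

#' Build an analysis manifest
#'
#' One row per structure chain to analyse. Exactly one row must be flagged
#' as the reference (by convention the RNA-bound complex, whose domains the
#' COM protocol transplants).
#'
#' @param id Entry identifiers.
#' @param source File paths (PDB/mmCIF), or `NA` when `structure` objects
#'   are supplied.
#' @param chain Protein chain to analyse.
#' @param state_label Ligand state, one of `"ATP-analog"`, `"ADP"`,
#'   `"apo"`, `"RNA-only"`, `"ATP-analog+RNA"`.
#' @param reference Logical; exactly one `TRUE`.
#' @param rna_chain RNA chain id or `NA` for RNA-free entries.
#' @param structure Optional list-column of pre-read `helicore_structure`
#'   objects (takes precedence over `source`).
#' @return Validated manifest tibble.
#' @export
analysis_manifest <- function(id, source = NA_character_, chain = "A",
                              state_label, reference = FALSE,
                              rna_chain = NA_character_, structure = NULL) {
  m <- tibble::tibble(
    id = as.character(id), source = source, chain = chain,
    state_label = state_label, reference = reference, rna_chain = rna_chain
  )
  if (!is.null(structure)) m$structure <- structure
  if (nrow(m) == 0) stop("empty manifest")
  if (sum(m$reference) != 1) stop("manifest must flag exactly one reference entry")
  bad <- setdiff(m$state_label, LIGAND_STATES)
  if (length(bad) > 0) {
    stop("unknown ligand-state label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(LIGAND_STATES, collapse = ", "), ")")
  }
  if (anyDuplicated(m$id)) stop("duplicate manifest ids")
  m
}

#' Run the full conformational-state analysis over a manifest
#'
#' For every entry: the center-of-mass distance protocol against the
#' reference entry (open/closed classification), pairwise RecA2 domain
#' shifts between all entries, and for entries carrying RNA the
#' hydrogen-bond contact table and base-stack report. Failures of single
#' entries are collected, not fatal; the run continues and the summary
#' lists them.
#'
#' @param manifest Tibble from [analysis_manifest()].
#' @param domains Function mapping a chain id to a domain-definition tibble
#'   (default [ct_prp22_domains()]); or a named list of such tibbles keyed
#'   by entry id.
#' @param hbond [hbond_criteria()] used for contact tables.
#' @param stack [stack_criteria()] used for stack reports.
#' @param threshold Open/closed COM-distance boundary, Angstrom.
#' @param out_dir Optional directory; when given, `conformation.csv`,
#'   `shifts.csv`, `contacts.csv`, `stacks.csv` and `summary.json` are
#'   written there.
#' @return Object of class `helicore_analysis`: list with tibbles
#'   `conformation`, `shifts`, `contacts`, `stacks`, plus `summary` (config
#'   echo, entry status, failures).
#' @export
run_analysis <- function(manifest,
                         domains = ct_prp22_domains,
                         hbond = hbond_criteria(),
                         stack = stack_criteria(),
                         threshold = HELICORE_DCOM_THRESHOLD,
                         out_dir = NULL) {
  if (nrow(manifest) == 0) stop("empty manifest")
  if (sum(manifest$reference) != 1) {
    stop("manifest must flag exactly one reference entry")
  }
  get_domains <- function(entry) {
    if (is.function(domains)) domains(entry$chain) else domains[[entry$id]]
  }
  structures <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    structures[[entry$id]] <- tryCatch({
      if ("structure" %in% names(manifest) && !is.null(entry$structure[[1]])) {
        entry$structure[[1]]
      } else {
        read_structure(entry$source, id = entry$id)
      }
    }, error = function(e) {
      failures[[entry$id]] <<- conditionMessage(e)
      NULL
    })
  }
  ok <- manifest[manifest$id %in% names(Filter(Negate(is.null), structures)), ]
  ref_entry <- ok[ok$reference, ]
  if (nrow(ref_entry) != 1) stop("reference entry failed to load")
  ref_struct <- structures[[ref_entry$id]]

  conf <- list()
  for (i in seq_len(nrow(ok))) {
    entry <- ok[i, ]
    row <- tryCatch(
      com_distance_protocol(
        structures[[entry$id]], ref_struct,
        target_chain = entry$chain, reference_chain = ref_entry$chain,
        target_domains = get_domains(entry),
        reference_domains = get_domains(ref_entry),
        threshold = threshold
      ) |> dplyr::mutate(id = entry$id, state_label = entry$state_label,
                         .before = 1),
      error = function(e) {
        failures[[entry$id]] <<- conditionMessage(e); NULL
      }
    )
    conf[[length(conf) + 1]] <- row
  }
  conformation <- dplyr::bind_rows(conf)

  shifts <- list()
  ids <- ok$id
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq((i + 1), length(ids))) {
        ea <- ok[ok$id == ids[i], ]; eb <- ok[ok$id == ids[j], ]
        dec <- tryCatch(
          domain_shift(structures[[ea$id]], structures[[eb$id]],
                       ea$chain, eb$chain,
                       domains_a = get_domains(ea), domains_b = get_domains(eb)),
          error = function(e) NULL
        )
        if (!is.null(dec)) {
          shifts[[length(shifts) + 1]] <- tibble::tibble(
            id_a = ea$id, id_b = eb$id,
            state_a = ea$state_label, state_b = eb$state_label,
            angle_deg = dec$angle_deg, displacement_A = dec$displacement,
            anchor_rmsd = dec$anchor_rmsd, mobile_rmsd = dec$mobile_rmsd
          )
        }
      }
    }
  }
  shifts <- if (length(shifts) > 0) dplyr::bind_rows(shifts) else
    tibble::tibble(id_a = character(), id_b = character(),
                   state_a = character(), state_b = character(),
                   angle_deg = numeric(), displacement_A = numeric(),
                   anchor_rmsd = numeric(), mobile_rmsd = numeric())

  contacts <- list(); stacks <- list()
  rna_entries <- ok[!is.na(ok$rna_chain), ]
  for (i in seq_len(nrow(rna_entries))) {
    entry <- rna_entries[i, ]
    s <- structures[[entry$id]]
    tryCatch({
      prot <- s[s$chain == entry$chain & s$polymer == "protein", ]
      rna <- s[s$chain == entry$rna_chain & s$polymer == "RNA", ]
      hb <- hydrogen_bonds(s, prot, rna, hbond)
      if (nrow(hb) > 0) {
        contacts[[length(contacts) + 1]] <- dplyr::mutate(hb, id = entry$id,
                                                          .before = 1)
      }
      sr <- stack_segments(s, entry$rna_chain, stack)
      stacks[[length(stacks) + 1]] <- tibble::tibble(
        id = entry$id, n_nucleotides = nrow(sr$nucleotides),
        max_stack = sr$max_stack,
        runs = paste(sr$runs$length, collapse = "+")
      )
    }, error = function(e) { failures[[entry$id]] <<- conditionMessage(e) })
  }
  contacts <- if (length(contacts) > 0) dplyr::bind_rows(contacts) else
    dplyr::mutate(empty_contacts(), id = character(), .before = 1)
  stacks <- if (length(stacks) > 0) dplyr::bind_rows(stacks) else
    tibble::tibble(id = character(), n_nucleotides = integer(),
                   max_stack = integer(), runs = character())

  summary <- list(
    reference = ref_entry$id,
    n_entries = nrow(manifest),
    n_analyzed = nrow(conformation),
    threshold_A = threshold,
    hbond_criteria = unclass(hbond),
    stack_criteria = unclass(stack),
    failures = if (length(failures) > 0) failures else setNames(list(), character(0))
  )
  result <- structure(
    list(conformation = conformation, shifts = shifts, contacts = contacts,
         stacks = stacks, summary = summary),
    class = "helicore_analysis"
  )
  if (!is.null(out_dir)) write_analysis(result, out_dir)
  result
}

#' Write an analysis bundle to disk
#'
#' Deterministic CSV tables (`conformation.csv`, `shifts.csv`,
#' `contacts.csv`, `stacks.csv`) plus `summary.json` echoing every numeric
#' criterion used, so reported numbers are self-describing.
#'
#' @param result A `helicore_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$conformation, file.path(out_dir, "conformation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$shifts, file.path(out_dir, "shifts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$contacts, file.path(out_dir, "contacts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$stacks, file.path(out_dir, "stacks.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.helicore_analysis <- function(x, ...) {
  cat("helicore analysis:", x$summary$n_analyzed, "of", x$summary$n_entries,
      "entries analyzed (reference:", x$summary$reference, ")\n")
  print(x$conformation[, c("id", "state_label", "d_com", "state")])
  invisible(x)
}
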