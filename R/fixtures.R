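# Packaged transcriptions of the published characterization tables:
# the 26-disease response-cluster panel, the IVIg direct-target profile,
# the indirect-target list (annotation only, never scored), and the
# published relationship-score grid kept for side-by-side comparison.

ivignet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ivignet", mustWork = TRUE)
  path
}

#' The 26-disease IVIg response panel
#'
#' Transcription of the published characterization of 26 autoimmune and
#' inflammatory diseases: response cluster (7 DB, 6 PB, 9 MPB, 4 UPB),
#' pathophysiological processes with immune-system group codes, and the number
#' of curated effector proteins per disease. The full effector lists are not
#' redistributed, so the `effectors` column is empty; use
#' [generate_disease_panel()] for panels with explicit effector sets.
#'
#' @return A disease tibble (see [read_disease_table()]).
#' @examples
#' panel <- ivig_disease_panel()
#' table(panel$cluster)
#' @export
ivig_disease_panel <- function() {
  read_disease_table(ivignet_extdata("disease_panel_table1.tsv"))
}

#' IVIg direct protein targets
#'
#' The direct-target profile of IVIg: proteins directly bound, blocked or
#' activated by the drug, grouped by immune-related function, with the
#' direction of the effect (`activate`, `inhibit`, or `both` where the
#' literature reports dual arrows). The single published "HLA class I and II
#' (includes 21 proteins)" entry is expanded into 21 explicit identifiers (the
#' five HLA proteins named in the published score grid first, then
#' placeholders `HLA_06`..`HLA_21`), because the scoring engine operates on
#' explicit protein identifiers.
#'
#' @return A tibble with columns `uniprot`, `protein_name`, `gene`,
#'   `functional_group`, `effect`.
#' @export
ivig_direct_targets <- function() {
  readr::read_tsv(ivignet_extdata("ivig_direct_targets_table2.tsv"),
                  col_types = "ccccc", progress = FALSE)
}

#' IVIg indirect targets (annotation only)
#'
#' Proteins modulated downstream of the direct targets. They are not part of
#' the drug's target set for mechanistic scoring (`scorable` is `FALSE` for
#' every row) and are shipped for annotation and display only.
#'
#' @return A tibble with columns `uniprot`, `protein_name`, `gene`, `effect`,
#'   `scorable`.
#' @export
ivig_indirect_targets <- function() {
  readr::read_tsv(ivignet_extdata("ivig_indirect_targets_table3.tsv"),
                  col_types = "ccccl", progress = FALSE)
}

#' Published target-disease relationship scores (comparison fixture)
#'
#' The published grid of neural-network relationship scores between individual
#' IVIg targets and the seven definitely-beneficial diseases, with the
#' published category glyphs (`+++` strong, `++` medium-strong, `+` medium,
#' `-` low). These numbers were produced with a proprietary protein network
#' and training corpus; the package ships them for comparison and display,
#' never as something its own models are fit to.
#'
#' @return A tibble with columns `target`, `uniprot`, `functional_group`,
#'   `disease`, `glyph`, `score_pct`.
#' @export
ivig_published_scores <- function() {
  readr::read_tsv(ivignet_extdata("published_scores_table4.tsv"),
                  col_types = "cccccd", progress = FALSE)
}

#' Build a drug profile from a target table
#'
#' Collapses a target table (e.g. [ivig_direct_targets()]) into the one-row
#' drug-profile shape used by the scoring engine.
#'
#' @param targets Tibble with at least a `gene` column, optionally `effect`
#'   and `functional_group`.
#' @param drug_id Identifier for the drug; default `"IVIG"`.
#' @return A one-row tibble with `drug_id`, `targets` (list-column tibble of
#'   `protein`, `effect`, `functional_group`) and `n_targets`.
#' @export
as_drug_profile <- function(targets, drug_id = "IVIG") {
  stopifnot(is.data.frame(targets), "gene" %in% names(targets))
  tt <- tibble::tibble(
    protein = normalize_protein(targets$gene),
    effect = if ("effect" %in% names(targets)) targets$effect else NA_character_,
    functional_group = if ("functional_group" %in% names(targets))
      targets$functional_group else NA_character_
  )
  tt <- dplyr::distinct(tt, .data$protein, .keep_all = TRUE)
  if (nrow(tt) == 0) abort_validation("drug profile has no targets")
  tibble::tibble(drug_id = drug_id, targets = list(tt), n_targets = nrow(tt))
}

#' Write the packaged fixture bundle to a directory
#'
#' Copies the packaged transcriptions (disease panel, direct-target profile,
#' indirect-target list, published score grid) into `dir` so external tools
#' can consume them.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_fixture_bundle <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("disease_panel_table1.tsv", "ivig_direct_targets_table2.tsv",
             "ivig_indirect_targets_table3.tsv", "published_scores_table4.tsv")
  out <- file.path(dir, files)
  ok <- file.copy(purrr::map_chr(files, ivignet_extdata), out, overwrite = TRUE)
  stopifnot(all(ok))
  invisible(out)
}
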