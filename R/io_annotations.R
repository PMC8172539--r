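#' Read cell and gene annotation tables
#'
#' Cell annotations carry, per cell: `cell_id`, `class` (one of
#' `glutamatergic`, `GABAergic`, `non-neuronal`; matched case-insensitively),
#' `cluster` (free-text cluster label such as `"L4/5 IT"`), `reporter_positive`
#' (logical; fluorescence-reporter pull) and `region`. Gene annotations carry
#' `gene_id`, `is_gpcr`, `coupling` (one of `Gi`, `Gq`, `Gs`, `other`,
#' `unknown`) and `is_sensory`. Unrecognised coupling values are mapped through
#' `coupling_aliases` when possible, otherwise stored as `"unknown"` with a
#' warning.
#'
#' @param cells_path Path to the cell annotation CSV/TSV (header required).
#' @param genes_path Path to the gene annotation CSV/TSV (header required).
#' @param coupling_aliases Named character vector mapping vendor coupling
#'   strings to the closed vocabulary, e.g. `c("Gi/Go" = "Gi")`.
#' @return A list with tibbles `cells` and `genes`.
#' @export
read_annotations <- function(cells_path, genes_path,
                             coupling_aliases = c("Gi/Go" = "Gi", "Gi/o" = "Gi",
                                                  "Gq/11" = "Gq", "Gq/G11" = "Gq",
                                                  "Gs/olf" = "Gs")) {
  cells <- .read_table_auto(cells_path)
  genes <- .read_table_auto(genes_path)
  .require_cols(cells, c("cell_id", "class", "cluster", "reporter_positive"),
                cells_path)
  .require_cols(genes, c("gene_id", "is_gpcr", "coupling"), genes_path)
  if (!"region" %in% names(cells)) cells$region <- NA_character_
  if (!"is_sensory" %in% names(genes)) genes$is_sensory <- FALSE

  cells <- cells %>%
    mutate(
      cell_id = as.character(.data$cell_id),
      class = .normalise_class(.data$class),
      cluster = as.character(.data$cluster),
      reporter_positive = as.logical(.data$reporter_positive)
    )
  genes <- genes %>%
    mutate(
      gene_id = as.character(.data$gene_id),
      is_gpcr = as.logical(.data$is_gpcr),
      is_sensory = as.logical(.data$is_sensory),
      coupling = .normalise_coupling(.data$coupling, coupling_aliases)
    )
  list(cells = as_tibble(cells), genes = as_tibble(genes))
}

.read_table_auto <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::read_delim(path, delim = delim, comment = "#", show_col_types = FALSE)
}

.require_cols <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort(sprintf("'%s' lacks required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "impulscreen_format_error")
  }
}

.cell_classes <- c("glutamatergic", "GABAergic", "non-neuronal")

.normalise_class <- function(x) {
  idx <- match(tolower(x), tolower(.cell_classes))
  if (anyNA(idx)) {
    abort(paste0("unknown cell class value(s): ",
                 paste(unique(x[is.na(idx)]), collapse = ", ")),
          class = "impulscreen_validation_error")
  }
  .cell_classes[idx]
}

.coupling_levels <- c("Gi", "Gq", "Gs", "other", "unknown")

.normalise_coupling <- function(x, aliases = character()) {
  x <- as.character(x)
  hit <- match(x, names(aliases))
  x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  bad <- !x %in% .coupling_levels & !is.na(x)
  if (any(bad)) {
    warn(paste0("unrecognised coupling value(s) mapped to 'unknown': ",
                paste(unique(x[bad]), collapse = ", ")))
    x[bad] <- "unknown"
  }
  x[is.na(x)] <- "unknown"
  x
}

#' Check that an annotation table covers a dataset's cells
#'
#' @param ds An [expression_dataset()].
#' @param cells Cell annotation tibble.
#' @return Invisibly `TRUE`; aborts listing missing cell ids otherwise.
#' @export
validate_annotation_coverage <- function(ds, cells) {
  missing <- setdiff(ds$cell_ids, cells$cell_id)
  if (length(missing)) {
    abort(paste0("cells present in matrix but absent from annotation: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10) else ""),
          class = "impulscreen_validation_error")
  }
  invisible(TRUE)
}

#' Write cell/gene annotation tables
#'
#' @param tbl Annotation tibble.
#' @param path Output CSV path.
#' @param config_hash Optional hash stamped into the comment header.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(tbl, path, config_hash = NULL) {
  .write_commented_table(tbl, path, config_hash, delim = ",")
}

.write_commented_table <- function(tbl, path, config_hash = NULL, delim = "\t") {
  con <- file(path, "w")
  writeLines(paste0("#", .header_comment(config_hash)), con)
  close(con)
  readr::write_delim(tbl, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}
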