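#' Hash a configuration object
#'
#' Canonical serialisation (deparsed R structure) hashed with MD5; used to
#' stamp every output file of a pipeline run so bundles can be verified.
#'
#' @param config Any R object (typically a named list of run settings).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end discovery demonstration
#'
#' Generates a synthetic expression dataset with one planted Gi-coupled GPCR
#' marker, runs the full 2 x 3 comparison grid and the candidate ranking,
#' then simulates a two-group behavioural cohort (a Gi-like group whose drug
#' condition reduces the premature hazard, and a control group) and runs the
#' within-subject challenge statistics. All outputs are written to `out_dir`
#' as commented TSV/CSV/MTX files stamped with the run's configuration hash.
#'
#' Stage seeds are derived deterministically from the global seed, so any
#' stage can be re-run in isolation and re-running the whole demo reproduces
#' every numeric output exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param n_genes Number of genes in the demo dataset (demo-scale default
#'   2000; the generator itself defaults to 20000).
#' @param cluster_scale Multiplier on the default cluster roster sizes
#'   (default 0.25 for a quick demo).
#' @param n_subjects Subjects per cohort group (default 12).
#' @param gi_hazard_multiplier Drug multiplier on the premature hazard in the
#'   Gi-like group (default 0.3).
#' @return Invisibly, a list with `screen` (the [screen_grid()]),
#'   `candidates`, `challenge` (the [challenge_table()] result), `truth`, and
#'   `paths`.
#' @export
run_discovery_demo <- function(out_dir, seed = 1, n_genes = 2000,
                               cluster_scale = 0.25, n_subjects = 12,
                               gi_hazard_multiplier = 0.3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(seed = seed, n_genes = n_genes, cluster_scale = cluster_scale,
                 n_subjects = n_subjects,
                 gi_hazard_multiplier = gi_hazard_multiplier)
  hash <- config_hash(config)

  roster <- default_cluster_roster()
  roster$n_cells <- pmax(20L, as.integer(round(roster$n_cells * cluster_scale)))
  roster$n_reporter <- pmin(roster$n_cells,
                            as.integer(round(roster$n_reporter * cluster_scale)))
  expr_cfg <- expression_sim_config(
    clusters = roster, n_genes = n_genes, seed = derive_seed(seed, "expression")
  )
  sim <- make_expression_dataset(expr_cfg)

  grid <- screen_grid(sim$dataset, sim$cells)
  candidates <- rank_candidates(grid, sim$genes, coupling_filter = "Gi")

  gi_agent <- agent_params(drug_multipliers = list(
    cno = list(premature_hazard = gi_hazard_multiplier)
  ))
  ctrl_agent <- agent_params(drug_multipliers = list(
    cno = list(premature_hazard = 1)
  ))
  cohort_cfg <- cohort_sim_config(
    groups = list(gi = list(n = n_subjects, agent = gi_agent),
                  ctrl = list(n = n_subjects, agent = ctrl_agent)),
    spec = "fiti9", seed = derive_seed(seed, "cohort")
  )
  cohort <- make_cohort(cohort_cfg)
  metrics <- cohort_metrics(cohort)
  challenge <- challenge_table(metrics)

  paths <- list(
    matrix = file.path(out_dir, "expression.mtx"),
    genes = file.path(out_dir, "genes.txt"),
    cells_index = file.path(out_dir, "cells.txt"),
    cell_annot = file.path(out_dir, "cell_annotation.csv"),
    gene_annot = file.path(out_dir, "gene_annotation.csv"),
    truth_expr = file.path(out_dir, "truth_planted_markers.tsv"),
    screen = file.path(out_dir, "screen_report.tsv"),
    candidates = file.path(out_dir, "candidate_table.tsv"),
    metrics = file.path(out_dir, "cohort_metrics.tsv"),
    challenge = file.path(out_dir, "challenge_tests.tsv"),
    correlations = file.path(out_dir, "challenge_correlations.tsv"),
    truth_cohort = file.path(out_dir, "truth_cohort_subjects.tsv")
  )
  write_expression(sim$dataset, paths$matrix, paths$genes, paths$cells_index,
                   config_hash = hash)
  write_annotation(sim$cells, paths$cell_annot, config_hash = hash)
  write_annotation(sim$genes, paths$gene_annot, config_hash = hash)
  .write_commented_table(sim$truth, paths$truth_expr, hash)
  write_screen_report(grid$records, paths$screen, config_hash = hash)
  .write_commented_table(as_tibble(candidates), paths$candidates, hash)
  .write_commented_table(metrics, paths$metrics, hash)
  .write_commented_table(challenge$tests, paths$challenge, hash)
  .write_commented_table(challenge$correlations, paths$correlations, hash)
  .write_commented_table(cohort$truth, paths$truth_cohort, hash)

  invisible(list(screen = grid, candidates = candidates, challenge = challenge,
                 truth = sim$truth, config = config, hash = hash,
                 paths = paths))
}

#' Verify the configuration-hash consistency of an output bundle
#'
#' Checks that every commented text file in a directory carries the same
#' configuration hash in its header.
#'
#' @param dir Bundle directory.
#' @return Invisibly `TRUE` if consistent; aborts listing mismatched files
#'   otherwise.
#' @export
verify_bundle <- function(dir) {
  files <- list.files(dir, full.names = TRUE,
                      pattern = "\\.(tsv|csv|mtx|txt)$")
  hashes <- purrr::map_chr(files, function(f) {
    lines <- readLines(f, n = 3L)
    hit <- grep("config=", lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(".*config=([0-9a-f]+).*", "\\1", hit[1])
  })
  seen <- unique(hashes[!is.na(hashes)])
  if (length(seen) > 1) {
    abort(paste0("mismatched config hashes in bundle: ",
                 paste(basename(files[!is.na(hashes)]), collapse = ", ")),
          class = "impulscreen_validation_error")
  }
  invisible(TRUE)
}
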