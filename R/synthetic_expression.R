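#' Default cluster roster for the synthetic cortical dataset
#'
#' Emulates the composition of a ~5190-cell anterior cingulate single-cell
#' dataset: glutamatergic clusters across layers (including the L4/5 IT
#' target class, 1238 cells), GABAergic interneuron clusters, and
#' non-neuronal cells. The reporter-positive pull (676 cells) overlaps the
#' L4/5 IT cluster in 502 cells, with the remainder spread over other deep
#' glutamatergic clusters.
#'
#' @return Tibble with columns `cluster`, `class`, `n_cells`, `n_reporter`,
#'   `is_target`.
#' @export
default_cluster_roster <- function() {
  tibble(
    cluster = c("L2/3 IT", "L4/5 IT", "L5 PT", "L6 IT", "L6 CT", "L6b",
                "Pvalb", "Sst", "Vip", "Lamp5",
                "Astro", "Oligo", "Micro"),
    class = c(rep("glutamatergic", 6), rep("GABAergic", 4),
              rep("non-neuronal", 3)),
    n_cells = c(900L, 1238L, 238L, 500L, 400L, 200L,
                450L, 400L, 350L, 214L, 150L, 100L, 50L),
    n_reporter = c(0L, 502L, 120L, 0L, 0L, 54L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    is_target = c(FALSE, TRUE, rep(FALSE, 11))
  )
}

#' Configure a synthetic expression dataset
#'
#' Defines the generative model for a planted-marker CPM dataset: a cluster
#' roster (cells, classes, reporter overlap), a log-normal per-gene baseline
#' mean with detection-linked Bernoulli dropout, a GPCR gene panel, and a list
#' of planted markers with known fold-change and detection fractions in the
#' target vs contrast cells.
#'
#' @param clusters Cluster roster tibble (see [default_cluster_roster()]).
#' @param n_genes Total number of genes (default 20000).
#' @param n_gpcr Number of GPCR-annotated genes (default 402, of which
#'   `n_sensory` are flagged as sensory receptors).
#' @param n_sensory Number of sensory GPCRs (default 3).
#' @param planted Tibble of planted markers with columns `coupling`, `fold`,
#'   `pct_t`, `pct_c` and `base_cpm` (contrast-set mean CPM). Default: one
#'   Gi-coupled marker at 10-fold, detected in 90% of target and 5% of
#'   contrast cells.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean CPM.
#' @param value_sdlog Log-normal scale of detected expression values.
#' @param detection_k Half-saturation constant linking mean CPM to detection
#'   probability (`d = m / (m + k)`, jittered on the logit scale).
#' @param seed Integer seed; the generator is a pure function of config +
#'   seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(clusters = default_cluster_roster(),
                                  n_genes = 20000L,
                                  n_gpcr = 402L,
                                  n_sensory = 3L,
                                  planted = tibble(
                                    coupling = "Gi", fold = 10,
                                    pct_t = 0.9, pct_c = 0.05, base_cpm = 3
                                  ),
                                  baseline_meanlog = 0.5,
                                  baseline_sdlog = 1.2,
                                  value_sdlog = 0.7,
                                  detection_k = 3,
                                  seed = 1L) {
  stopifnot(all(clusters$n_cells > 0),
            all(clusters$n_reporter <= clusters$n_cells),
            n_gpcr <= n_genes, nrow(planted) <= n_gpcr)
  if (nrow(planted)) {
    if (any(planted$fold <= 0)) {
      abort("planted folds must be > 0", class = "impulscreen_configuration_error")
    }
    if (any(planted$pct_t <= 0 | planted$pct_t > 1 |
            planted$pct_c < 0 | planted$pct_c > 1)) {
      abort("planted detection fractions must lie in (0, 1]",
            class = "impulscreen_configuration_error")
    }
    # conditional mean per detected cell must stay a valid CPM value
    if (any(planted$fold * planted$base_cpm / planted$pct_t <= 0)) {
      abort("infeasible fold/pct combination",
            class = "impulscreen_configuration_error")
    }
  }
  structure(
    list(clusters = clusters, n_genes = as.integer(n_genes),
         n_gpcr = as.integer(n_gpcr), n_sensory = as.integer(n_sensory),
         planted = planted, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, value_sdlog = value_sdlog,
         detection_k = detection_k, seed = as.integer(seed)),
    class = "expression_sim_config"
  )
}

#' Generate a synthetic planted-marker expression dataset
#'
#' Draws a sparse genes-by-cells CPM matrix under the configured model:
#' per-gene baseline mean CPM is log-normal; each gene is detected in a cell
#' with a probability tied to its mean expression (Bernoulli dropout), and
#' detected values are log-normal with the conditional mean chosen so the
#' unconditional per-cell mean matches the gene's baseline. Planted markers
#' override this in the target population (cells of target clusters plus all
#' reporter-positive cells): detection at `pct_t` with conditional mean
#' `fold * base_cpm / pct_t`, against `pct_c` and `base_cpm / pct_c`
#' elsewhere, so the target/contrast mean-CPM ratio is `fold` in expectation.
#'
#' @param cfg An [expression_sim_config()].
#' @return A list with `dataset` ([expression_dataset()]), `cells` and
#'   `genes` annotation tibbles, and `truth` (planted-marker ground truth).
#' @export
make_expression_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  withr::with_seed(cfg$seed, .make_expression_impl(cfg))
}

.make_expression_impl <- function(cfg) {
  roster <- cfg$clusters
  n_cells <- sum(roster$n_cells)
  cells <- tibble(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    class = rep(roster$class, roster$n_cells),
    cluster = rep(roster$cluster, roster$n_cells),
    reporter_positive = FALSE,
    region = "ACA"
  )
  for (r in seq_len(nrow(roster))) {
    if (roster$n_reporter[r] > 0) {
      in_cl <- which(cells$cluster == roster$cluster[r])
      cells$reporter_positive[sample(in_cl, roster$n_reporter[r])] <- TRUE
    }
  }
  target_cells <- which(cells$cluster %in% roster$cluster[roster$is_target] |
                          cells$reporter_positive)
  other_cells <- setdiff(seq_len(n_cells), target_cells)

  n_genes <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  gpcr_idx <- sort(sample.int(n_genes, cfg$n_gpcr))
  gene_ids[gpcr_idx] <- sprintf("gpcr%03d", seq_len(cfg$n_gpcr))
  n_planted <- nrow(cfg$planted)
  planted_idx <- if (n_planted) sort(sample(gpcr_idx, n_planted)) else integer(0)

  # background model
  m_g <- rlnorm(n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  d_g <- plogis(qlogis(pmin(0.99, pmax(0.01, m_g / (m_g + cfg$detection_k)))) +
                  rnorm(n_genes, 0, 0.4))
  d_g <- pmin(0.99, pmax(0.005, d_g))

  s <- cfg$value_sdlog
  cond_meanlog <- log(m_g / d_g) - s^2 / 2

  i_list <- vector("list", n_genes)
  x_list <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (g %in% planted_idx) {
      p <- cfg$planted[match(g, planted_idx), ]
      det_t <- target_cells[runif(length(target_cells)) < p$pct_t]
      det_c <- other_cells[runif(length(other_cells)) < p$pct_c]
      ml_t <- log(p$fold * p$base_cpm / p$pct_t) - s^2 / 2
      ml_c <- log(p$base_cpm / max(p$pct_c, 1e-6)) - s^2 / 2
      i_list[[g]] <- c(det_t, det_c)
      x_list[[g]] <- c(rlnorm(length(det_t), ml_t, s),
                       rlnorm(length(det_c), ml_c, s))
    } else {
      n_det <- rbinom(1L, n_cells, d_g[g])
      if (n_det == 0) next
      det <- sample.int(n_cells, n_det)
      i_list[[g]] <- det
      x_list[[g]] <- rlnorm(n_det, cond_meanlog[g], s)
    }
  }
  lens <- lengths(i_list)
  mat <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n_genes), lens),
    j = unlist(i_list, use.names = FALSE),
    x = unlist(x_list, use.names = FALSE),
    dims = c(n_genes, n_cells)
  )
  ds <- expression_dataset(mat, gene_ids, cells$cell_id)

  coupling <- rep(NA_character_, n_genes)
  coupling[gpcr_idx] <- sample(.coupling_levels, cfg$n_gpcr, replace = TRUE,
                               prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
  coupling[planted_idx] <- cfg$planted$coupling
  sensory_pool <- setdiff(gpcr_idx, planted_idx)
  sensory_idx <- if (cfg$n_sensory) sample(sensory_pool, cfg$n_sensory) else integer(0)
  genes <- tibble(
    gene_id = gene_ids,
    is_gpcr = seq_len(n_genes) %in% gpcr_idx,
    coupling = ifelse(is.na(coupling), "unknown", coupling),
    is_sensory = seq_len(n_genes) %in% sensory_idx
  )

  truth <- if (n_planted) {
    tibble(gene = gene_ids[planted_idx],
           coupling = cfg$planted$coupling, fold = cfg$planted$fold,
           pct_t = cfg$planted$pct_t, pct_c = cfg$planted$pct_c,
           base_cpm = cfg$planted$base_cpm)
  } else {
    tibble(gene = character(), coupling = character(), fold = numeric(),
           pct_t = numeric(), pct_c = numeric(), base_cpm = numeric())
  }

  list(dataset = ds, cells = cells, genes = genes, truth = truth)
}
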