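# shared fixtures and independent oracles

# hand-sized expression dataset: 4 genes x 6 cells
tiny_dataset <- function() {
  m <- rbind(
    c(10, 12, 11, 0, 1, 0),    # up in first three cells
    c(0, 0, 0, 0, 0, 0),       # silent
    c(5, 5, 5, 5, 5, 5),       # constant
    c(0.5, 2, 1, 3, 0, 4)      # mixed
  )
  expression_dataset(m, paste0("g", 1:4), paste0("c", 1:6))
}

tiny_cells <- function() {
  tibble::tibble(
    cell_id = c(paste0("t", 1:4), paste0("g", 1:3), paste0("n", 1:2)),
    class = c(rep("glutamatergic", 4), rep("GABAergic", 3),
              rep("non-neuronal", 2)),
    cluster = c(rep("L4/5 IT", 4), rep("Pvalb", 3), rep("Astro", 2)),
    reporter_positive = c(rep(TRUE, 4), rep(FALSE, 5)),
    region = "ACA"
  )
}

# exhaustive-permutation two-sided rank-sum p; independent of the
# implementation (enumerates the U null distribution by brute force)
ranksum_enum_p <- function(x, y) {
  n_t <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n_t)]) - n_t * (n_t + 1) / 2
  combs <- utils::combn(length(vals), n_t)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n_t * (n_t + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# one-gene dataset wrapper so wilcoxon_de can be called on plain vectors
wilcox_p_vec <- function(x, y, ...) {
  m <- matrix(c(x, y), nrow = 1)
  ds <- expression_dataset(m, "g", paste0("c", seq_along(c(x, y))))
  unname(wilcoxon_de(ds, paste0("c", seq_along(x)),
                     paste0("c", length(x) + seq_along(y)), ...))
}

# small cluster roster for screen-scale tests: two balanced sets
null_roster <- function(n_t = 200L, n_c = 200L) {
  tibble::tibble(
    cluster = c("L4/5 IT", "Pvalb"),
    class = c("glutamatergic", "GABAergic"),
    n_cells = c(n_t, n_c),
    n_reporter = c(n_t, 0L),
    is_target = c(TRUE, FALSE)
  )
}

# compact roster for planted-marker recovery runs (>= 100 cells per set)
recovery_roster <- function() {
  tibble::tibble(
    cluster = c("L2/3 IT", "L4/5 IT", "L6 IT", "Pvalb", "Sst", "Astro"),
    class = c("glutamatergic", "glutamatergic", "glutamatergic",
              "GABAergic", "GABAergic", "non-neuronal"),
    n_cells = c(60L, 150L, 60L, 70L, 50L, 40L),
    n_reporter = c(0L, 100L, 0L, 0L, 0L, 0L),
    is_target = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

no_planted <- function() {
  tibble::tibble(coupling = character(), fold = numeric(), pct_t = numeric(),
                 pct_c = numeric(), base_cpm = numeric())
}

random_agent <- function() {
  agent_params(
    premature_hazard = runif(1, 0, 0.3),
    p_detect = runif(1, 0.5, 1),
    p_omit_given_detect = runif(1, 0, 0.5),
    accuracy_given_response = runif(1, 0.3, 1),
    response_latency_meanlog = runif(1, log(0.4), log(1.5)),
    response_latency_sdlog = runif(1, 0.2, 0.6),
    reward_latency_meanlog = runif(1, log(0.6), log(2)),
    reward_latency_sdlog = runif(1, 0.2, 0.6),
    p_perseverate = runif(1, 0, 0.5)
  )
}
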