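# Shared fixture builders and independent brute-force oracles.

# Small long-format DE table from per-gene (L, q) triples over (CT, DT, CD).
toy_de <- function(gene_id, l_ct, l_dt, l_cd, q_ct, q_dt, q_cd, alpha = 0.05) {
  n <- length(gene_id)
  l <- c(rep_len(l_ct, n), rep_len(l_dt, n), rep_len(l_cd, n))
  q <- c(rep_len(q_ct, n), rep_len(q_dt, n), rep_len(q_cd, n))
  tibble::tibble(
    gene_id = rep(gene_id, 3),
    contrast = rep(c("CT", "DT", "CD"), each = n),
    log2fc = l,
    se = 0.1,
    pvalue = q,
    qvalue = q,
    significant = q < alpha & l != 0,
    direction = ifelse(q >= alpha | l == 0, "none",
                       ifelse(l > 0, "up", "down"))
  )
}

# Random toy DE table with n genes; qvalues drawn to mix significant and not.
random_de <- function(n, seed) {
  withr::with_seed(seed, {
    toy_de(
      gene_id = sprintf("g%03d", seq_len(n)),
      l_ct = round(runif(n, -3, 3), 2),
      l_dt = round(runif(n, -3, 3), 2),
      l_cd = round(runif(n, -3, 3), 2),
      q_ct = round(runif(n), 3),
      q_dt = round(runif(n), 3),
      q_cd = round(runif(n), 3)
    )
  })
}

# Hand-enumerated mode lookup for all 26 non-null sign patterns: an oracle
# written directly from the mode definitions, independent of
# classify_pattern() / profile_templates().
oracle_mode_table <- function() {
  pat <- function(s1, s2, s3, mode) data.frame(s_ct = s1, s_dt = s2, s_cd = s3, mode = mode)
  rbind(
    pat(1, 1, 1, "similar"), pat(-1, -1, -1, "similar"),
    pat(1, -1, 1, "prioritized"), pat(1, -1, -1, "prioritized"),
    pat(-1, 1, 1, "prioritized"), pat(-1, 1, -1, "prioritized"),
    pat(1, 0, 0, "canceled"), pat(-1, 0, 0, "canceled"),
    pat(0, 1, 0, "canceled"), pat(0, -1, 0, "canceled"),
    pat(1, 1, 0, "canceled"), pat(-1, -1, 0, "canceled"),
    pat(1, -1, 0, "canceled"), pat(-1, 1, 0, "canceled"),
    pat(1, 0, 1, "independent"), pat(-1, 0, -1, "independent"),
    pat(0, 1, 1, "independent"), pat(0, -1, -1, "independent"),
    pat(1, 1, -1, "combinatorial"), pat(-1, -1, 1, "combinatorial"),
    pat(1, 0, -1, "combinatorial"), pat(-1, 0, 1, "combinatorial"),
    pat(0, 1, -1, "combinatorial"), pat(0, -1, 1, "combinatorial"),
    pat(0, 0, 1, "combinatorial"), pat(0, 0, -1, "combinatorial")
  )
}

# Brute-force disjoint Venn cells by direct membership enumeration.
oracle_venn <- function(ct, dt, cd) {
  universe <- unique(c(ct, dt, cd))
  key <- vapply(universe, function(g) {
    paste0(as.integer(g %in% ct), as.integer(g %in% dt), as.integer(g %in% cd))
  }, character(1))
  c(
    CT_only = sum(key == "100"), DT_only = sum(key == "010"),
    CD_only = sum(key == "001"), CT_DT = sum(key == "110"),
    CT_CD = sum(key == "101"), DT_CD = sum(key == "011"),
    CT_DT_CD = sum(key == "111")
  )
}

# Random gene sets over a small universe.
random_sets <- function(seed, universe_size = 60) {
  withr::with_seed(seed, {
    universe <- sprintf("u%02d", seq_len(universe_size))
    lapply(1:3, function(i) sample(universe, sample.int(50, 1)))
  })
}

# Simulated dataset under the default study conditions.
sim_dataset <- function(n_genes, seed, ...) {
  cfg <- sim_config(n_genes = n_genes, rng_seed = seed, ...)
  truth <- build_truth(cfg)
  list(config = cfg, truth = truth, design = sim_design(cfg),
       counts = simulate_counts(truth, config = cfg))
}
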