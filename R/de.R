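#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes
#' expressed in every sample, of the ratio of the gene's count in that sample
#' to its geometric mean across samples.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @return Tibble with columns `sample_id`, `size_factor` (all positive).
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", a = 10L, b = 40L)
#' estimate_size_factors(counts) # factors 1/2 and 2 (geometric mean 20)
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  m <- count_matrix(counts)
  expressed <- rowSums(m > 0) == ncol(m)
  if (!any(expressed)) {
    abort(paste("no gene has nonzero counts in every sample; median-of-ratios",
                "normalization is undefined. Filter samples or supply size factors."),
          class = "stressmodes_normalization_error")
  }
  logm <- log(m[expressed, , drop = FALSE])
  logref <- rowMeans(logm)
  factors <- apply(logm - logref, 2, function(x) exp(median(x)))
  tibble::tibble(sample_id = colnames(m), size_factor = unname(factors))
}

# Internal: matrix of counts / size factors, samples matched by name
normalize_counts <- function(m, factors) {
  sf <- setNames(factors$size_factor, factors$sample_id)
  sweep(m, 2, sf[colnames(m)], "/")
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene negative-binomial dispersion under `var = mu + phi * mu^2`,
#' estimated from normalized counts as the replicate-weighted average over
#' conditions of `(var - mean) / mean^2`, truncated below at `floor`.
#' A deliberately simple estimator with no sharing of information across
#' genes: adequate for ranking and Wald testing on simulated data, noisy at
#' few replicates.
#'
#' @param counts Counts tibble.
#' @param design Design tibble; every condition used must have >= 2 replicates.
#' @param factors Size factors from [estimate_size_factors()] (computed if
#'   omitted).
#' @param floor Lower truncation for the estimate. Default 1e-8.
#' @return Tibble with columns `gene_id`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, design, factors = NULL, floor = 1e-8) {
  validate_counts(counts)
  if (is.null(factors)) factors <- estimate_size_factors(counts)
  m <- count_matrix(counts)
  design <- design[design$sample_id %in% colnames(m), ]
  check_replicates(design, unique(design$condition))
  y <- normalize_counts(m[, design$sample_id, drop = FALSE], factors)
  phi_num <- rep(0, nrow(y))
  wsum <- 0
  for (cond in unique(design$condition)) {
    cols <- design$sample_id[design$condition == cond]
    yc <- y[, cols, drop = FALSE]
    mu_c <- rowMeans(yc)
    v_c <- apply(yc, 1, var)
    w <- length(cols) - 1
    phi_c <- ifelse(mu_c > 0, (v_c - mu_c) / mu_c^2, 0)
    phi_num <- phi_num + w * phi_c
    wsum <- wsum + w
  }
  tibble::tibble(
    gene_id = rownames(y),
    dispersion = pmax(floor, phi_num / wsum)
  )
}

#' Wald test of one treatment against control
#'
#' Computes, for every gene, the log2 fold change of normalized group means
#' (with a pseudo-count), a delta-method standard error under the
#' negative-binomial variance model, a two-sided Wald p-value, and
#' Benjamini-Hochberg adjusted p-values across genes within the contrast.
#' Genes are flagged significant at adjusted p below `alpha` with direction
#' `up`/`down` by the sign of the fold change; non-significant genes have
#' direction `none`. Genes with zero counts in both groups get `log2fc = 0`,
#' `pvalue = 1`.
#'
#' @param counts Counts tibble.
#' @param design Design tibble containing CK and the treatment, each with
#'   >= 2 replicates.
#' @param treatment One of `"CT"`, `"DT"`, `"CD"`.
#' @param alpha Significance threshold on adjusted p. Default 0.05.
#' @param pseudo_count Added to both group means before the log ratio.
#'   Default 0.5.
#' @param factors,dispersions Optional precomputed normalization factors and
#'   dispersions (computed from the data if omitted).
#' @param dispersion_floor Passed to [estimate_dispersion()].
#' @return Tibble of class `stress_de` with columns `gene_id`, `contrast`,
#'   `base_mean`, `log2fc`, `se`, `pvalue`, `qvalue`, `significant`,
#'   `direction`.
#' @export
test_contrast <- function(counts, design, treatment, alpha = 0.05,
                          pseudo_count = 0.5, factors = NULL,
                          dispersions = NULL, dispersion_floor = 1e-8) {
  if (identical(treatment, "CK")) {
    abort("treatment must differ from the control condition CK",
          class = "stressmodes_contract_error")
  }
  if (!treatment %in% .treatments) {
    abort(sprintf("unknown treatment '%s'", treatment),
          class = "stressmodes_contract_error")
  }
  validate_counts(counts)
  sub <- design[design$condition %in% c("CK", treatment), ]
  check_replicates(sub, c("CK", treatment))
  if (is.null(factors)) factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, design, factors, floor = dispersion_floor)
  }
  m <- count_matrix(counts)
  y <- normalize_counts(m[, sub$sample_id, drop = FALSE], factors)
  ck_cols <- sub$sample_id[sub$condition == "CK"]
  tr_cols <- sub$sample_id[sub$condition == treatment]
  m_ck <- rowMeans(y[, ck_cols, drop = FALSE])
  m_tr <- rowMeans(y[, tr_cols, drop = FALSE])
  phi <- dispersions$dispersion[match(rownames(y), dispersions$gene_id)]
  sf <- setNames(factors$size_factor, factors$sample_id)

  # Var of a normalized group mean under var(K) = mu + phi mu^2 with
  # K_j ~ NB(mean s_j * m), so var(K_j / s_j) = m / s_j + phi m^2.
  group_var <- function(mu, cols) {
    sapply(seq_along(mu), function(g) {
      sum(mu[g] / sf[cols] + phi[g] * mu[g]^2) / length(cols)^2
    })
  }
  v_ck <- group_var(m_ck, ck_cols)
  v_tr <- group_var(m_tr, tr_cols)
  c0 <- pseudo_count
  log2fc <- log2((m_tr + c0) / (m_ck + c0))
  se <- sqrt(v_tr / (m_tr + c0)^2 + v_ck / (m_ck + c0)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pnorm(-abs(z))
  dead <- m_ck == 0 & m_tr == 0
  log2fc[dead] <- 0
  pvalue[dead] <- 1
  se[dead] <- NA_real_
  qvalue <- adjust_bh(pvalue)
  significant <- qvalue < alpha
  direction <- ifelse(!significant | log2fc == 0, "none",
                      ifelse(log2fc > 0, "up", "down"))
  significant <- significant & direction != "none"
  tibble::new_tibble(
    tibble::tibble(
      gene_id = rownames(y),
      contrast = treatment,
      base_mean = unname((m_ck + m_tr) / 2),
      log2fc = unname(log2fc),
      se = unname(se),
      pvalue = unname(pvalue),
      qvalue = unname(qvalue),
      significant = unname(significant),
      direction = unname(direction)
    ),
    class = "stress_de"
  )
}

#' Differential expression for every treatment in the design
#'
#' Runs [test_contrast()] for each treatment condition present (CT, DT, CD,
#' each against CK) with shared size factors and dispersions, and stacks the
#' per-contrast tables.
#'
#' @inheritParams test_contrast
#' @return Tibble of class `stress_de` (long format, `contrast` column).
#' @examples
#' cfg <- sim_config(n_genes = 100, rng_seed = 42)
#' truth <- build_truth(cfg)
#' counts <- simulate_counts(truth, config = cfg)
#' de <- run_de(counts, sim_design(cfg))
#' dplyr::count(de, contrast, significant)
#' @export
run_de <- function(counts, design, alpha = 0.05, pseudo_count = 0.5,
                   dispersion_floor = 1e-8) {
  validate_design(design, counts)
  factors <- estimate_size_factors(counts)
  dispersions <- estimate_dispersion(counts, design, factors,
                                     floor = dispersion_floor)
  treatments <- intersect(.treatments, unique(design$condition))
  res <- purrr::map(treatments, function(tr) {
    test_contrast(counts, design, tr, alpha = alpha,
                  pseudo_count = pseudo_count, factors = factors,
                  dispersions = dispersions)
  })
  tibble::new_tibble(dplyr::bind_rows(res), class = "stress_de")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the adjusted value for the i-th smallest p is
#' `min over j >= i of p_(j) * m / j`, clipped to 1, returned in input order.
#' Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must be finite and in [0, 1]",
          class = "stressmodes_validation_error")
  }
  p.adjust(p, method = "BH")
}
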