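#' Simulation configuration
#'
#' Parameters for the negative-binomial count simulator with planted
#' transcriptional response modes. The defaults mirror the design of the
#' combined cold/drought study this package targets: four conditions
#' (CK/CT/DT/CD) with three biological replicates each, and mode fractions
#' matching the response-mode composition reported there (26% similar,
#' 36% independent, 28% canceled, 10% combinatorial, 0% prioritized).
#' Any remainder after the mode fractions becomes null genes with no
#' planted effect.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_replicates Replicates per condition (>= 2). Default 3.
#' @param mode_fractions Named numeric vector over
#'   `similar`, `independent`, `combinatorial`, `canceled`, `prioritized`;
#'   entries in \[0, 1\] summing to at most 1.
#' @param effect_size Planted absolute log2 fold change |L| for non-null
#'   responses. Default 2.
#' @param l_jitter_sd Standard deviation of optional Gaussian jitter added to
#'   planted |L| (sign-preserving, magnitude floored at 0.1). Default 0 (off).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of the baseline mean
#'   distribution. Defaults `log(100)` and 1.
#' @param dispersion Constant NB dispersion phi in `var = mu + phi * mu^2`
#'   (>= 0; 0 gives Poisson sampling). Default 0.1.
#' @param depth_range `NULL` for unit sequencing-depth factors (default), or
#'   a length-2 positive range from which per-sample depth factors are drawn
#'   log-uniformly, e.g. `c(0.5, 2)`.
#' @param rng_seed Integer seed. Default 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L,
                       n_replicates = 3L,
                       mode_fractions = c(similar = 0.26, independent = 0.36,
                                          combinatorial = 0.10, canceled = 0.28,
                                          prioritized = 0),
                       effect_size = 2,
                       l_jitter_sd = 0,
                       mu_meanlog = log(100),
                       mu_sdlog = 1,
                       dispersion = 0.1,
                       depth_range = NULL,
                       rng_seed = 1L) {
  if (n_genes < 1) abort("n_genes must be >= 1", class = "stressmodes_config_error")
  if (n_replicates < 2) abort("n_replicates must be >= 2", class = "stressmodes_config_error")
  fr <- setNames(rep(0, length(.modes)), .modes)
  unknown <- setdiff(names(mode_fractions), .modes)
  if (length(unknown) > 0) {
    abort(sprintf("unknown mode(s) in mode_fractions: %s", paste(unknown, collapse = ", ")),
          class = "stressmodes_config_error")
  }
  fr[names(mode_fractions)] <- mode_fractions
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12) {
    abort("mode_fractions must lie in [0, 1] and sum to at most 1",
          class = "stressmodes_config_error")
  }
  if (dispersion < 0) abort("dispersion must be >= 0", class = "stressmodes_config_error")
  if (effect_size <= 0) abort("effect_size must be > 0", class = "stressmodes_config_error")
  if (!is.null(depth_range) &&
      (length(depth_range) != 2 || any(depth_range <= 0) || depth_range[1] > depth_range[2])) {
    abort("depth_range must be NULL or an increasing positive length-2 range",
          class = "stressmodes_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_replicates = as.integer(n_replicates),
      mode_fractions = fr,
      effect_size = effect_size,
      l_jitter_sd = l_jitter_sd,
      mu_meanlog = mu_meanlog,
      mu_sdlog = mu_sdlog,
      dispersion = dispersion,
      depth_range = depth_range,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

# Largest-remainder apportionment of n_genes across mode fractions.
# Quotas are fraction * n; each mode gets floor(quota), and leftover units go
# to the largest fractional remainders (ties by mode order), so that totals
# match round-off-free and exact quotas (e.g. 0.26 * 5000) stay exact.
apportion_modes <- function(fractions, n_genes) {
  quota <- fractions * n_genes
  counts <- floor(quota + 1e-9)
  leftover <- round(sum(quota)) - sum(counts)
  if (leftover > 0) {
    rem <- quota - counts
    take <- order(rem, decreasing = TRUE)[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Build a planted ground-truth table
#'
#' Assigns each gene a transcriptional response mode (or `null`), a sign
#' pattern over (CT, DT, CD) drawn uniformly from the profiles belonging to
#' that mode, planted log2 fold changes consistent with the pattern, a
#' log-normal baseline mean and a dispersion. Per-mode gene counts follow the
#' configured fractions with a largest-remainder correction so they total
#' `n_genes` exactly. Deterministic given `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return Tibble of class `stress_truth` with columns `gene_id`, `mode`,
#'   `s_ct`, `s_dt`, `s_cd`, `l_ct`, `l_dt`, `l_cd`, `mu`, `dispersion`.
#' @examples
#' truth <- build_truth(sim_config(n_genes = 20, rng_seed = 7))
#' dplyr::count(truth, mode)
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- profile_templates()
  n <- config$n_genes
  counts <- apportion_modes(config$mode_fractions, n)
  mode_vec <- c(rep(names(config$mode_fractions), counts),
                rep("null", n - sum(counts)))
  withr::with_seed(config$rng_seed, {
    patt <- matrix(0L, n, 3)
    for (m in .modes) {
      idx <- which(mode_vec == m)
      if (length(idx) == 0) next
      pool <- templates[templates$meta_mode == m, c("s_ct", "s_dt", "s_cd")]
      pick <- sample.int(nrow(pool), length(idx), replace = TRUE)
      patt[idx, ] <- as.matrix(pool)[pick, , drop = FALSE]
    }
    lfc <- patt * config$effect_size
    if (config$l_jitter_sd > 0) {
      jit <- matrix(rnorm(3 * n, 0, config$l_jitter_sd), n, 3)
      mag <- pmax(abs(lfc + jit * (patt != 0)), 0.1)
      lfc <- patt * mag
    }
    mu <- rlnorm(n, config$mu_meanlog, config$mu_sdlog)
    tibble::new_tibble(
      tibble::tibble(
        gene_id = sprintf("gene_%05d", seq_len(n)),
        mode = mode_vec,
        s_ct = patt[, 1], s_dt = patt[, 2], s_cd = patt[, 3],
        l_ct = lfc[, 1], l_dt = lfc[, 2], l_cd = lfc[, 3],
        mu = mu,
        dispersion = config$dispersion
      ),
      class = "stress_truth"
    )
  })
}

#' Build the default 4-condition design for a simulation
#'
#' @param config A [sim_config()].
#' @return Design tibble with `n_replicates` samples per condition, named
#'   `<condition>_<replicate>`.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble::tibble(
    sample_id = paste0(rep(.conditions, each = config$n_replicates), "_",
                       rep(seq_len(config$n_replicates), length(.conditions))),
    condition = rep(.conditions, each = config$n_replicates)
  )
}

#' Simulate a count matrix from planted truth
#'
#' Draws counts for gene g in a sample of condition X from a negative
#' binomial with mean `mu_g * 2^L_gX * depth_j` and variance
#' `mean + phi * mean^2` (`L = 0` for CK and null responses; `phi = 0` falls
#' back to Poisson). Deterministic given the configuration seed.
#'
#' @param truth Truth tibble from [build_truth()].
#' @param design Design tibble (defaults to [sim_design()] of `config`).
#' @param config The [sim_config()] used to build `truth`.
#' @return Counts tibble (`gene_id` + one integer column per sample) with the
#'   per-sample depth factors attached as attribute `depth_factors`.
#' @export
simulate_counts <- function(truth, design = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion < 0) {
    abort("dispersion must be >= 0", class = "stressmodes_config_error")
  }
  if (is.null(design)) design <- sim_design(config)
  validate_design(design)
  n <- nrow(truth)
  lfc <- cbind(CK = 0, CT = truth$l_ct, DT = truth$l_dt, CD = truth$l_cd)
  withr::with_seed(config$rng_seed + 1L, {
    depth <- if (is.null(config$depth_range)) {
      rep(1, nrow(design))
    } else {
      exp(runif(nrow(design), log(config$depth_range[1]), log(config$depth_range[2])))
    }
    names(depth) <- design$sample_id
    phi <- truth$dispersion
    if (any(phi < 0)) {
      abort("dispersion must be >= 0", class = "stressmodes_config_error")
    }
    pois <- phi == 0
    out <- matrix(0L, n, nrow(design))
    for (j in seq_len(nrow(design))) {
      mu_j <- truth$mu * 2^lfc[, design$condition[j]] * depth[j]
      col <- numeric(n)
      if (any(pois)) col[pois] <- rpois(sum(pois), mu_j[pois])
      if (any(!pois)) {
        col[!pois] <- rnbinom(sum(!pois), mu = mu_j[!pois], size = 1 / phi[!pois])
      }
      out[, j] <- col
    }
    counts <- tibble::as_tibble(setNames(as.data.frame(out), design$sample_id))
    counts <- dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id), counts)
    attr(counts, "depth_factors") <- depth
    counts
  })
}
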