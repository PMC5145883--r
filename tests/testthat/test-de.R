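test_that("median-of-ratios size factors match closed forms", {
  # identical samples -> all factors 1
  same <- tibble::tibble(gene_id = c("g1", "g2"), a = c(10L, 4L), b = c(10L, 4L))
  expect_equal(estimate_size_factors(same)$size_factor, c(1, 1))

  # B = 2 x A for every gene -> factors (1/sqrt(2), sqrt(2))
  doubled <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            a = c(10L, 50L, 3L), b = c(20L, 100L, 6L))
  expect_equal(estimate_size_factors(doubled)$size_factor,
               c(1 / sqrt(2), sqrt(2)))

  # single gene (10, 40): geometric mean 20 -> (1/2, 2)
  single <- tibble::tibble(gene_id = "g1", a = 10L, b = 40L)
  expect_equal(estimate_size_factors(single)$size_factor, c(0.5, 2))

  # no gene expressed in every sample -> normalization error
  holed <- tibble::tibble(gene_id = c("g1", "g2"), a = c(0L, 5L), b = c(5L, 0L))
  expect_error(estimate_size_factors(holed),
               class = "stressmodes_normalization_error")
})

test_that("dispersion estimates are calibrated on simulated data", {
  design50 <- sim_design(sim_config(n_genes = 1, n_replicates = 50))

  # Poisson counts -> phi near 0
  d <- sim_dataset(300, seed = 11, n_replicates = 50, dispersion = 0,
                   mode_fractions = c(similar = 0))
  disp <- estimate_dispersion(d$counts, d$design)
  expect_gt(mean(disp$dispersion < 0.02), 0.95)

  # NB at phi = 0.1 -> estimates concentrate in [0.05, 0.2]
  d <- sim_dataset(300, seed = 12, n_replicates = 50, dispersion = 0.1,
                   mode_fractions = c(similar = 0))
  disp <- estimate_dispersion(d$counts, d$design)
  expect_gt(mean(disp$dispersion >= 0.05 & disp$dispersion <= 0.2), 0.9)

  # constant counts within conditions -> floor
  const <- tibble::tibble(gene_id = "g1",
                          CK_1 = 10L, CK_2 = 10L, CT_1 = 10L, CT_2 = 10L)
  des <- tibble::tibble(sample_id = names(const)[-1],
                        condition = c("CK", "CK", "CT", "CT"))
  expect_equal(estimate_dispersion(const, des)$dispersion, 1e-8)

  # a condition with a single replicate errors, naming it
  bad <- tibble::tibble(sample_id = c("a", "b", "c"),
                        condition = c("CK", "CK", "CT"))
  cts <- tibble::tibble(gene_id = "g1", a = 1L, b = 2L, c = 3L)
  expect_error(estimate_dispersion(cts, bad), "CT")
})

test_that("Wald contrast rejects contract violations and degenerate genes", {
  d <- sim_dataset(50, seed = 13)
  expect_error(test_contrast(d$counts, d$design, "CK"),
               class = "stressmodes_contract_error")

  zero <- d$counts
  zero[1, -1] <- 0L
  de <- test_contrast(zero, d$design, "CT")
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$pvalue[1], 1)
  expect_false(de$significant[1])
  expect_equal(de$direction[1], "none")
})

test_that("null p-values are approximately uniform at many replicates", {
  d <- sim_dataset(300, seed = 13, n_replicates = 50, dispersion = 0.1,
                   mode_fractions = c(similar = 0))
  de <- test_contrast(d$counts, d$design, "CT")
  expect_lt(max(abs(de$log2fc)), 0.5)
  expect_gt(stats::ks.test(de$pvalue, "punif")$p.value, 0.01)
})

test_that("planted fold changes are recovered at 3 replicates", {
  # 1000 genes at |L| = 2 (500 up, 500 down) among 1500 nulls, mu = 100
  cfg <- sim_config(n_genes = 2500, n_replicates = 3, dispersion = 0.1,
                    mode_fractions = c(similar = 0), rng_seed = 14)
  truth <- build_truth(cfg)
  truth$mu <- rep(100, 2500)
  truth$l_ct[1:500] <- 2; truth$s_ct[1:500] <- 1L
  truth$l_ct[501:1000] <- -2; truth$s_ct[501:1000] <- -1L
  de <- test_contrast(simulate_counts(truth, config = cfg), sim_design(cfg), "CT")
  planted <- de[1:1000, ]
  hit <- planted$significant & abs(planted$log2fc) >= 1 & abs(planted$log2fc) <= 3
  expect_gte(mean(hit), 0.95)
})

test_that("significance calls are invariant to sample depth rescaling", {
  d <- sim_dataset(500, seed = 15)
  de1 <- run_de(d$counts, d$design)
  scaled <- d$counts
  scaled$CT_1 <- scaled$CT_1 * 3L
  de2 <- run_de(scaled, d$design)
  expect_gte(mean(de1$significant == de2$significant), 0.99)
  sf <- estimate_size_factors(scaled)
  expect_gt(sf$size_factor[sf$sample_id == "CT_1"],
            max(sf$size_factor[sf$sample_id != "CT_1"]))
})

test_that("BH adjustment follows the step-up rule and preserves p-value order", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.05), 0.05)
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "stressmodes_validation_error")

  withr::with_seed(21, {
    for (i in 1:10) {
      p <- runif(50)
      q <- adjust_bh(p)
      expect_true(all(diff(q[order(p)]) >= -1e-12))
      expect_true(all(q >= p & q <= 1))
    }
  })
})

test_that("fold changes agree with DESeq2 on a planted dataset", {
  d <- sim_dataset(200, seed = 31)
  sub <- d$design[d$design$condition %in% c("CK", "CT"), ]
  m <- as.matrix(d$counts[, sub$sample_id])
  storage.mode(m) <- "integer"
  rownames(m) <- d$counts$gene_id
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(condition = factor(sub$condition, levels = c("CK", "CT"))),
    ~condition
  )
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  mine <- test_contrast(d$counts[, c("gene_id", sub$sample_id)], sub, "CT")
  both <- is.finite(res$log2FoldChange) & is.finite(mine$log2fc)
  expect_gt(cor(res$log2FoldChange[both], mine$log2fc[both]), 0.9)
})
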