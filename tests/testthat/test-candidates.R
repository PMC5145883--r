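test_that("co-up-regulated genes require significance and positive L in all contrasts", {
  de <- toy_de(c("g1", "g2", "g3", "g4"),
               l_ct = c(1, 1, -1, 1), l_dt = c(2, 2, 1, 2), l_cd = c(1, 1, 1, 1),
               q_ct = c(0.01, 0.01, 0.01, 0.2), q_dt = c(0.01, 0.01, 0.01, 0.01),
               q_cd = c(0.01, 0.2, 0.01, 0.01))
  expect_equal(co_upregulated(de), "g1")

  none <- toy_de("g1", -1, 1, 1, 0.01, 0.01, 0.01)
  expect_equal(co_upregulated(none), character())

  # brute-force triple filter on random toys
  for (seed in 1:100) {
    d <- random_de(20, seed = 300 + seed)
    got <- co_upregulated(d)
    wide <- tidyr::pivot_wider(d[, c("gene_id", "contrast", "log2fc", "qvalue")],
                               names_from = contrast,
                               values_from = c(log2fc, qvalue))
    want <- sort(wide$gene_id[
      wide$qvalue_CT < 0.05 & wide$log2fc_CT > 0 &
        wide$qvalue_DT < 0.05 & wide$log2fc_DT > 0 &
        wide$qvalue_CD < 0.05 & wide$log2fc_CD > 0
    ])
    expect_equal(got, want)
  }
})

test_that("enhancement filter keeps genes stronger in CD than both single stresses", {
  de <- toy_de(c("g1", "g2"),
               l_ct = c(1, 1), l_dt = c(1, 2), l_cd = c(2, 1.5),
               q_ct = 0.01, q_dt = 0.01, q_cd = 0.01)
  res <- enhanced_in_combined(de, c("g1", "g2"), margin = 0)
  expect_true(res$retained[res$gene_id == "g1"])   # (1,1,2): above both
  expect_false(res$retained[res$gene_id == "g2"])  # (1,2,1.5): not above DT
  expect_equal(res$enh_over_ct, c(1, 0.5))

  # brute-force agreement at margin 0.5, and margin monotonicity
  for (seed in 1:100) {
    d <- random_de(15, seed = 400 + seed)
    genes <- unique(d$gene_id)
    res05 <- enhanced_in_combined(d, genes, margin = 0.5)
    wide <- tidyr::pivot_wider(d[, c("gene_id", "contrast", "log2fc")],
                               names_from = contrast, values_from = log2fc)
    wide <- wide[match(genes, wide$gene_id), ]
    want <- wide$CD - wide$CT > 0.5 & wide$CD - wide$DT > 0.5
    expect_equal(res05$retained, want)

    res0 <- enhanced_in_combined(d, genes, margin = 0)
    expect_true(all(res05$retained <= res0$retained))
  }

  expect_error(enhanced_in_combined(de, "nope"),
               class = "stressmodes_contract_error")
  expect_error(enhanced_in_combined(de, "g1", margin = -0.1),
               class = "stressmodes_config_error")
})

test_that("subgrouping is deterministic, ordered by combined-stress strength", {
  # two well-separated planted clusters
  cand <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    l_ct = c(rep(1, 10), rep(4, 10)) + rep(c(-0.1, 0.1), 10),
    l_dt = c(rep(1, 10), rep(4, 10)) + rep(c(0.05, -0.05), 10),
    l_cd = c(rep(2, 10), rep(8, 10)) + rep(c(-0.1, 0.1), 10),
    enh_over_ct = 1, enh_over_dt = 1, retained = TRUE
  )
  sub <- cluster_subgroups(cand, k = 2)
  expect_equal(sub$subgroup, c(rep(2L, 10), rep(1L, 10)))  # group 1 = high CD
  means <- tapply(sub$l_cd, sub$subgroup, mean)
  expect_true(all(diff(means) < 0))

  # identical input -> identical labels
  expect_identical(cluster_subgroups(cand, k = 2), sub)

  one <- cluster_subgroups(cand, k = 1)
  expect_true(all(one$subgroup == 1L))

  expect_error(cluster_subgroups(cand[1:2, ], k = 3),
               class = "stressmodes_contract_error")
})

test_that("annotation coverage counts genes without annotation entries", {
  retained <- tibble::tibble(gene_id = c("g1", "g2", "g3"))
  ann <- tibble::tibble(gene_id = c("g1", "g2"),
                        annotation = c("kinase", ""), effect = NA_character_)
  cov <- annotation_coverage(retained, ann)
  expect_equal(cov$n_unannotated, 2L)  # g2 empty, g3 absent
  expect_equal(cov$percent_unannotated, round_half_up(200 / 3, 1))

  full <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         annotation = c("a", "b", "c"), effect = NA_character_)
  expect_equal(annotation_coverage(retained, full)$percent_unannotated, 0)

  expect_equal(annotation_coverage(retained, NULL)$n_unannotated, 3L)
  expect_error(annotation_coverage(retained[0, ], ann),
               class = "stressmodes_empty_error")

  # brute-force agreement on random toys
  for (seed in 1:50) {
    withr::with_seed(500 + seed, {
      genes <- sprintf("g%02d", sample.int(40, sample(5:20, 1)))
      annotated <- sample(sprintf("g%02d", 1:40), 15)
    })
    ann <- tibble::tibble(gene_id = annotated, annotation = "x",
                          effect = NA_character_)
    cov <- annotation_coverage(tibble::tibble(gene_id = genes), ann)
    expect_equal(cov$n_unannotated, sum(!unique(genes) %in% annotated))
  }
})

test_that("mode-and-effect selection partitions genes by effect label", {
  de <- toy_de(c("g1", "g2", "g3", "g4"),
               l_ct = c(2, 2, 2, 0), l_dt = c(2, 2, 2, 0), l_cd = c(2, 2, 2, 2),
               q_ct = c(0.01, 0.01, 0.01, 0.9), q_dt = c(0.01, 0.01, 0.01, 0.9),
               q_cd = c(0.01, 0.01, 0.01, 0.01))
  asn <- assign_profiles(de)
  similar_profile <- asn$profile_id[1]
  effects <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            annotation = NA_character_,
                            effect = c("promote", "promote", "delay"))
  sel <- select_by_modes_and_effect(asn, similar_profile, effects)
  expect_equal(sum(sel$effect == "promote"), 2L)
  expect_equal(sum(sel$effect == "delay"), 1L)
  expect_false("g4" %in% sel$gene_id)  # different profile

  expect_equal(nrow(select_by_modes_and_effect(asn, integer(), effects)), 0L)
  unlab <- select_by_modes_and_effect(asn, similar_profile, NULL)
  expect_true(all(unlab$effect == "unlabeled"))
  expect_error(select_by_modes_and_effect(asn, 99L, effects),
               class = "stressmodes_validation_error")
})
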