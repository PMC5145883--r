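test_that("profile templates partition the 26 non-null sign patterns", {
  templates <- profile_templates()
  expect_equal(nrow(templates), 26L)
  expect_equal(anyDuplicated(templates$profile_id), 0L)
  key <- paste(templates$s_ct, templates$s_dt, templates$s_cd)
  expect_equal(anyDuplicated(key), 0L)
  expect_false("0 0 0" %in% key)
  counts <- table(templates$meta_mode)
  expect_equal(counts[["similar"]], 2L)
  expect_equal(counts[["prioritized"]], 4L)
  expect_equal(counts[["canceled"]], 8L)
  expect_equal(counts[["independent"]], 4L)
  expect_equal(counts[["combinatorial"]], 8L)
})

test_that("template modes match the hand-enumerated rule table", {
  templates <- profile_templates()
  oracle <- oracle_mode_table()
  merged <- merge(templates, oracle, by = c("s_ct", "s_dt", "s_cd"))
  expect_equal(nrow(merged), 26L)
  expect_equal(merged$meta_mode, merged$mode)
})

test_that("representative patterns classify as documented", {
  expect_equal(classify_pattern(1L, 1L, 1L), "similar")
  expect_equal(classify_pattern(0L, 1L, 0L), "canceled")
  expect_equal(classify_pattern(1L, -1L, 1L), "prioritized")
  expect_equal(classify_pattern(0L, 1L, 1L), "independent")
  expect_equal(classify_pattern(1L, 1L, -1L), "combinatorial")
  expect_equal(classify_pattern(0L, 0L, 1L), "combinatorial")
  expect_equal(classify_pattern(0L, 0L, 0L), "unassigned")
})

test_that("discretization gates the fold-change sign on significance", {
  expect_equal(discretize(c(2, 2, 2), c(0.01, 0.01, 0.01)), c(1L, 1L, 1L))
  expect_equal(discretize(c(-1, 3, 0.1), c(0.01, 0.2, 0.8)), c(-1L, 0L, 0L))
  expect_equal(discretize(c(5, -5, 2), c(0.5, 0.9, 0.051)), c(0L, 0L, 0L))
  expect_error(discretize(c(1, 2), c(0.1, 0.1)),
               class = "stressmodes_contract_error")
})

test_that("profile assignment matches per-gene rule application", {
  de <- random_de(200, seed = 8)
  asn <- assign_profiles(de, alpha = 0.05)
  # independent oracle: discretize each gene by hand, look the pattern up in
  # the hand-enumerated table
  oracle <- oracle_mode_table()
  wide <- tidyr::pivot_wider(de[, c("gene_id", "contrast", "log2fc", "qvalue")],
                             names_from = contrast,
                             values_from = c(log2fc, qvalue))
  for (i in seq_len(nrow(wide))) {
    s <- sign(c(wide$log2fc_CT[i], wide$log2fc_DT[i], wide$log2fc_CD[i])) *
      (c(wide$qvalue_CT[i], wide$qvalue_DT[i], wide$qvalue_CD[i]) < 0.05)
    hit <- oracle[oracle$s_ct == s[1] & oracle$s_dt == s[2] & oracle$s_cd == s[3], ]
    expected <- if (nrow(hit) == 0) "unassigned" else hit$mode
    expect_equal(asn$meta_mode[asn$gene_id == wide$gene_id[i]], expected)
  }
  # all-null genes are unassigned and carry no profile
  expect_true(all(is.na(asn$profile_id[asn$meta_mode == "unassigned"])))
})

test_that("correlation-based assignment agrees with discrete on clean patterns", {
  de <- toy_de(c("g1", "g2", "g3"),
               l_ct = c(2, -2, 0.05), l_dt = c(2, 2, 0.02), l_cd = c(2, -2, 2),
               q_ct = c(0.01, 0.01, 0.9), q_dt = c(0.01, 0.01, 0.9),
               q_cd = c(0.01, 0.01, 0.01))
  disc <- assign_profiles(de, method = "discrete")
  corr <- assign_profiles(de, method = "correlation")
  expect_equal(disc$meta_mode[1:2], corr$meta_mode[1:2])
  # g3: tiny single-stress L, CD-dominated vector -> CD-only template
  expect_equal(corr$meta_mode[3], "combinatorial")
})

test_that("top-N selection matches brute-force ranking and set union", {
  de <- random_de(30, seed = 9)
  warns <- capture_warnings(all_genes <- select_top_n(de, 1000))
  expect_length(warns, 3)  # one saturation warning per contrast
  expect_match(warns, "taking all", all = TRUE)
  expect_setequal(all_genes, unique(de$gene_id))

  for (seed in 1:10) {
    d <- random_de(25, seed = 100 + seed)
    n <- 7
    got <- select_top_n(d, n)
    manual <- unique(unlist(lapply(split(d, d$contrast), function(tbl) {
      tbl <- tbl[order(tbl$qvalue, -abs(tbl$log2fc), tbl$gene_id), ]
      tbl$gene_id[seq_len(n)]
    })))
    expect_setequal(got, manual)
  }

  # disjoint top lists union to 3n
  de3 <- toy_de(sprintf("g%02d", 1:9),
                l_ct = c(rep(2, 3), rep(0.1, 6)),
                l_dt = c(rep(0.1, 3), rep(2, 3), rep(0.1, 3)),
                l_cd = c(rep(0.1, 6), rep(2, 3)),
                q_ct = c(rep(0.001, 3), rep(0.8, 6)),
                q_dt = c(rep(0.8, 3), rep(0.001, 3), rep(0.8, 3)),
                q_cd = c(rep(0.8, 6), rep(0.001, 3)))
  expect_length(select_top_n(de3, 3), 9L)
})

test_that("mode summaries count assigned genes and the unpredictable aggregate", {
  de <- toy_de(c("g1", "g2", "g3", "g4"),
               l_ct = c(2, 2, 1, 0), l_dt = c(2, 0, -1, 0), l_cd = c(2, 0, 1, 0),
               q_ct = c(0.01, 0.01, 0.01, 0.9), q_dt = c(0.01, 0.9, 0.01, 0.9),
               q_cd = c(0.01, 0.9, 0.01, 0.9))
  summ <- summarize_modes(assign_profiles(de))
  get <- function(m) summ$count[summ$meta_mode == m]
  expect_equal(get("similar"), 1L)       # g1 (+,+,+)
  expect_equal(get("canceled"), 1L)      # g2 (+,0,0)
  expect_equal(get("prioritized"), 1L)   # g3 (+,-,+)
  expect_equal(get("unpredictable"), get("canceled") + get("prioritized") +
                 get("combinatorial"))
  assigned <- summ[summ$meta_mode != "unpredictable", ]
  expect_equal(sum(assigned$fraction), 1)

  all_sim <- toy_de("g1", 2, 2, 2, 0.01, 0.01, 0.01)
  s <- summarize_modes(assign_profiles(all_sim))
  expect_equal(s$fraction[s$meta_mode == "similar"], 1)

  none <- toy_de("g1", 2, 2, 2, 0.9, 0.9, 0.9)
  expect_error(summarize_modes(assign_profiles(none)),
               class = "stressmodes_empty_error")
})

test_that("stability check degenerates correctly for a single N", {
  de <- random_de(100, seed = 10)
  st <- stability_check(de, n_list = 40)
  expect_equal(st$max_deviation, 0)
  expect_equal(unique(st$fractions$top_n), 40L)
  expect_error(stability_check(de, integer()), class = "stressmodes_contract_error")
})
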