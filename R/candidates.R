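#' Genes up-regulated in all three stress contrasts
#'
#' @param de Long DE table covering CT, DT and CD.
#' @return Sorted character vector of genes significant with positive log2
#'   fold change in every contrast.
#' @export
co_upregulated <- function(de) {
  up <- de |>
    dplyr::filter(.data$significant, .data$log2fc > 0) |>
    dplyr::distinct(.data$gene_id, .data$contrast) |>
    dplyr::count(.data$gene_id)
  sort(up$gene_id[up$n == 3])
}

#' Filter candidates enhanced under combined stress
#'
#' Keeps genes whose combined-stress log2 fold change exceeds both
#' single-stress fold changes by more than `margin` log2 units — i.e. genes
#' whose induction is stronger under the stress combination than under either
#' stress alone.
#'
#' @param de Long DE table covering CT, DT and CD.
#' @param candidates Character vector of gene identifiers (typically from
#'   [co_upregulated()]).
#' @param margin Non-negative log2-unit enhancement margin. Default 0
#'   (strict inequality).
#' @return Tibble with columns `gene_id`, `l_ct`, `l_dt`, `l_cd`,
#'   `enh_over_ct` (`l_cd - l_ct`), `enh_over_dt` (`l_cd - l_dt`) and
#'   `retained` (logical).
#' @export
enhanced_in_combined <- function(de, candidates, margin = 0) {
  if (margin < 0) abort("margin must be >= 0", class = "stressmodes_config_error")
  wide <- de_wide(de)
  missing <- setdiff(candidates, wide$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("candidate gene(s) missing fold changes: %s",
                  paste(head(missing, 3), collapse = ", ")),
          class = "stressmodes_contract_error")
  }
  wide <- wide[match(candidates, wide$gene_id), ]
  tibble::tibble(
    gene_id = wide$gene_id,
    l_ct = wide$log2fc_CT,
    l_dt = wide$log2fc_DT,
    l_cd = wide$log2fc_CD,
    enh_over_ct = wide$log2fc_CD - wide$log2fc_CT,
    enh_over_dt = wide$log2fc_CD - wide$log2fc_DT
  ) |>
    dplyr::mutate(retained = .data$enh_over_ct > margin & .data$enh_over_dt > margin)
}

#' Subgroup retained candidates by their fold-change profile
#'
#' Agglomerative hierarchical clustering (Euclidean distance on the
#' (`l_ct`, `l_dt`, `l_cd`) vectors, average linkage) cut into `k` clusters.
#' Clusters are relabeled 1..k by descending mean `l_cd`, so subgroup 1 has
#' the strongest combined-stress induction.
#'
#' @param retained Tibble from [enhanced_in_combined()], already filtered to
#'   retained genes (rows with `retained == FALSE` are dropped with a
#'   warning).
#' @param k Number of subgroups (>= 1, at most the number of genes).
#' @return The input tibble with an integer `subgroup` column.
#' @export
cluster_subgroups <- function(retained, k = 3L) {
  if ("retained" %in% names(retained) && !all(retained$retained)) {
    warn("dropping non-retained rows before subgrouping")
    retained <- retained[retained$retained, ]
  }
  if (k < 1) abort("k must be >= 1", class = "stressmodes_config_error")
  if (nrow(retained) < k) {
    abort(sprintf("only %d retained gene(s) for k = %d subgroups; choose a smaller k",
                  nrow(retained), k),
          class = "stressmodes_contract_error")
  }
  m <- as.matrix(retained[, c("l_ct", "l_dt", "l_cd")])
  cl <- if (k == 1 || nrow(retained) == 1) {
    rep(1L, nrow(retained))
  } else {
    cutree(hclust(dist(m), method = "average"), k = k)
  }
  means <- tapply(retained$l_cd, cl, mean)
  relabel <- setNames(seq_along(means), names(sort(means, decreasing = TRUE)))
  dplyr::mutate(retained, subgroup = as.integer(relabel[as.character(cl)]))
}

#' Annotation coverage of a candidate set
#'
#' Counts retained candidates lacking any annotation entry (absent from the
#' table, or an empty/`NA` annotation field).
#'
#' @param retained Tibble with a `gene_id` column (non-empty).
#' @param annotations Annotation tibble (see [read_annotation()]); `NULL`
#'   means no gene is annotated.
#' @return Tibble with one row: `n_genes`, `n_unannotated`,
#'   `percent_unannotated` (one decimal, half away from zero).
#' @export
annotation_coverage <- function(retained, annotations = NULL) {
  genes <- unique(retained$gene_id)
  if (length(genes) == 0) {
    abort("retained candidate set is empty; coverage undefined",
          class = "stressmodes_empty_error")
  }
  annotated <- if (is.null(annotations)) character() else {
    ann <- annotations[!is.na(annotations$annotation) & annotations$annotation != "", ]
    ann$gene_id
  }
  n_un <- sum(!genes %in% annotated)
  tibble::tibble(
    n_genes = length(genes),
    n_unannotated = as.integer(n_un),
    percent_unannotated = round_half_up(100 * n_un / length(genes), 1)
  )
}

#' Select genes by expression profile and senescence effect
#'
#' Filters profile assignments to a caller-supplied set of profile
#' identifiers (e.g. the profiles whose combined-stress behaviour is of
#' interest) and partitions the selected genes by their annotated effect on
#' senescence (`promote`, `delay`, or `unlabeled` when no effect is
#' recorded).
#'
#' @param assignments Assignment table from [assign_profiles()].
#' @param profile_ids Integer vector of profile identifiers (validated
#'   against [profile_templates()]).
#' @param effects Annotation tibble with `gene_id` and `effect` columns, or
#'   `NULL` (all genes unlabeled).
#' @return Tibble with columns `gene_id`, `profile_id`, `meta_mode`,
#'   `effect` (`promote`/`delay`/`unlabeled`).
#' @export
select_by_modes_and_effect <- function(assignments, profile_ids, effects = NULL) {
  valid <- profile_templates()$profile_id
  bad <- setdiff(profile_ids, valid)
  if (length(bad) > 0) {
    abort(sprintf("unknown profile id(s): %s", paste(bad, collapse = ", ")),
          class = "stressmodes_validation_error")
  }
  sel <- assignments[!is.na(assignments$profile_id) &
                       assignments$profile_id %in% profile_ids,
                     c("gene_id", "profile_id", "meta_mode")]
  eff <- rep("unlabeled", nrow(sel))
  if (!is.null(effects) && nrow(effects) > 0) {
    hit <- match(sel$gene_id, effects$gene_id)
    lab <- effects$effect[hit]
    eff[!is.na(lab)] <- lab[!is.na(lab)]
  }
  dplyr::mutate(sel, effect = eff)
}
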