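#' Run the full combined-stress analysis pipeline
#'
#' Orchestrates the stages end to end: (optionally) simulate counts with
#' planted response modes, test each treatment against control, assign
#' expression profiles and summarize response modes on the union of top-N
#' most significant genes, check mode stability across several N, decompose
#' DEG sets into Venn cells with overlap statistics, compute the cumulative
#' fold-change contribution of each single stress in CD, and select
#' candidates with enhanced expression under combined stress. All randomness
#' flows from `config$rng_seed`; identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param counts Counts tibble, or `NULL` when simulating.
#' @param design Design tibble, or `NULL` when simulating.
#' @param config A [pipeline_config()].
#' @param sim A [sim_config()] to simulate inputs (its seed is overridden by
#'   `config$rng_seed` so one seed governs the run); `NULL` to use `counts` +
#'   `design`.
#' @param annotations Optional annotation tibble (see [read_annotation()]).
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV plus a `report.json` whose numbers are all re-derivable
#'   from those tables.
#' @return A list of class `stress_run` with elements `config`, `truth`
#'   (when simulated), `de`, `assignments`, `mode_summary`, `stability`,
#'   `venn`, `overlap`, `contribution`, `candidates`, `subgroups`,
#'   `coverage`, `report`.
#' @examples
#' run <- run_pipeline(sim = sim_config(n_genes = 300),
#'                     config = pipeline_config(top_n_list = c(50, 100),
#'                                              rng_seed = 11))
#' glance(run)
#' @export
run_pipeline <- function(counts = NULL, design = NULL,
                         config = pipeline_config(), sim = NULL,
                         annotations = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "stress_config"))
  truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$rng_seed <- config$rng_seed
    truth <- build_truth(sim)
    design <- sim_design(sim)
    counts <- simulate_counts(truth, design, sim)
  }
  if (is.null(counts) || is.null(design)) {
    abort("supply counts and design, or a sim_config", class = "stressmodes_contract_error")
  }
  validate_counts(counts)
  validate_design(design, counts)

  de <- run_de(counts, design, alpha = config$alpha,
               pseudo_count = config$pseudo_count,
               dispersion_floor = config$dispersion_floor)

  head_n <- min(config$top_n_list)
  head_genes <- select_top_n(de, head_n)
  assignments <- assign_profiles(de, alpha = config$alpha, genes = head_genes,
                                 method = config$assignment_method)
  mode_summary <- summarize_modes(assignments)
  stability <- stability_check(de, config$top_n_list, alpha = config$alpha,
                               method = config$assignment_method)

  venn <- deg_venn(de)
  overlap <- overlap_statistics(venn)
  contribution <- contribution_stats(de, config$contribution_n)

  co_up <- co_upregulated(de)
  candidates <- enhanced_in_combined(de, co_up, margin = config$enhancement_margin)
  retained <- candidates[candidates$retained, ]
  subgroups <- if (nrow(retained) >= config$subgroup_k) {
    cluster_subgroups(retained, k = config$subgroup_k)
  } else {
    warn(sprintf("%d retained candidate(s) < k = %d; skipping subgrouping",
                 nrow(retained), config$subgroup_k))
    NULL
  }
  coverage <- if (nrow(retained) > 0) {
    annotation_coverage(retained, annotations)
  } else NULL

  report <- list(
    config = unclass(config),
    n_genes = nrow(counts),
    n_samples = nrow(design),
    simulated = !is.null(truth),
    deg_counts = as.list(setNames(
      purrr::map_int(.treatments, function(tr) {
        sum(de$significant[de$contrast == tr])
      }), .treatments)),
    top_n_union = length(head_genes),
    n_assigned = sum(assignments$meta_mode != "unassigned"),
    mode_fractions = as.list(setNames(mode_summary$fraction, mode_summary$meta_mode)),
    stability_max_deviation = stability$max_deviation,
    overlap = purrr::pmap(overlap, function(statistic, count, denominator, digits, percent) {
      list(count = count, denominator = denominator, percent = percent)
    }) |> setNames(overlap$statistic),
    contribution = as.list(setNames(contribution$absolute, contribution$stress)),
    n_co_upregulated = length(co_up),
    n_retained = nrow(retained)
  )

  run <- structure(
    list(config = config, truth = truth, counts = counts, design = design,
         de = de, assignments = assignments, mode_summary = mode_summary,
         stability = stability, venn = venn, overlap = overlap,
         contribution = contribution, candidates = candidates,
         subgroups = subgroups, coverage = coverage, report = report),
    class = "stress_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Write every stage table plus the derived JSON report.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)
  write_result_table(run$counts, out("counts.tsv"))
  write_result_table(run$design, out("design.tsv"))
  if (!is.null(run$truth)) write_result_table(run$truth, out("truth.tsv"))
  for (tr in unique(run$de$contrast)) {
    write_result_table(run$de[run$de$contrast == tr, ],
                       out(sprintf("de_%s.tsv", tr)))
  }
  write_result_table(run$assignments, out("modes.tsv"))
  write_result_table(run$mode_summary, out("mode_summary.tsv"))
  write_result_table(run$stability$fractions, out("stability.tsv"))
  write_result_table(run$venn, out("venn.tsv"))
  write_result_table(run$overlap, out("overlap.tsv"))
  write_result_table(run$contribution, out("contribution.tsv"))
  write_result_table(run$candidates, out("candidates.tsv"))
  if (!is.null(run$subgroups)) write_result_table(run$subgroups, out("subgroups.tsv"))
  if (!is.null(run$coverage)) write_result_table(run$coverage, out("coverage.tsv"))
  report <- run$report
  report$manifest <- sort(setdiff(list.files(out_dir), "report.json"))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.stress_run <- function(x, ...) {
  cat("<stress_run>\n")
  cat(sprintf("  %d genes x %d samples%s\n", x$report$n_genes, x$report$n_samples,
              if (x$report$simulated) " (simulated)" else ""))
  degs <- unlist(x$report$deg_counts)
  cat(sprintf("  DEGs: %s\n",
              paste(sprintf("%s %d", names(degs), degs), collapse = ", ")))
  cat(sprintf("  assigned genes: %d; mode stability max deviation: %.3f\n",
              x$report$n_assigned, x$report$stability_max_deviation))
  cat(sprintf("  co-up-regulated: %d; retained candidates: %d\n",
              x$report$n_co_upregulated, x$report$n_retained))
  invisible(x)
}

#' Tidy one table of a pipeline run
#'
#' @param x A `stress_run` from [run_pipeline()].
#' @param table Which result to return: `"de"`, `"modes"` (per-gene
#'   assignments), `"mode_summary"`, `"stability"`, `"venn"`, `"overlap"`,
#'   `"contribution"`, or `"candidates"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stress_run
#' @export
tidy.stress_run <- function(x, table = c("de", "modes", "mode_summary",
                                         "stability", "venn", "overlap",
                                         "contribution", "candidates"), ...) {
  table <- match.arg(table)
  switch(table,
    de = tibble::as_tibble(x$de),
    modes = x$assignments,
    mode_summary = x$mode_summary,
    stability = x$stability$fractions,
    venn = x$venn,
    overlap = x$overlap,
    contribution = x$contribution,
    candidates = x$candidates
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `stress_run` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble with DEG counts per contrast, the assigned-gene
#'   count, the unpredictable-mode fraction, stability deviation, and
#'   candidate counts.
#' @method glance stress_run
#' @export
glance.stress_run <- function(x, ...) {
  unpred <- x$mode_summary$fraction[x$mode_summary$meta_mode == "unpredictable"]
  tibble::tibble(
    n_genes = x$report$n_genes,
    deg_ct = x$report$deg_counts$CT,
    deg_dt = x$report$deg_counts$DT,
    deg_cd = x$report$deg_counts$CD,
    n_assigned = x$report$n_assigned,
    unpredictable_fraction = unpred,
    stability_max_deviation = x$report$stability_max_deviation,
    n_co_upregulated = x$report$n_co_upregulated,
    n_retained = x$report$n_retained
  )
}
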