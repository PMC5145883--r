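#' Read a count matrix and its sample design
#'
#' Reads a genes-by-samples count table (TSV, first column gene identifiers,
#' header row of sample identifiers) together with a two-column design table
#' (`sample_id`, `condition`). Conditions use the four-state vocabulary
#' `CK` (control), `CT` (cold), `DT` (drought), `CD` (combined); alternative
#' labels can be mapped via `condition_aliases`.
#'
#' @param path Path to the counts TSV.
#' @param design_path Path to the design TSV.
#' @param condition_aliases Optional named character vector mapping labels
#'   found in the design file to the canonical `CK`/`CT`/`DT`/`CD` vocabulary,
#'   e.g. `c(control = "CK")`.
#' @return A list with elements `counts` (tibble: `gene_id` plus one integer
#'   column per sample, gene order as in the file) and `design` (tibble:
#'   `sample_id`, `condition`).
#' @examples
#' counts <- tibble::tibble(
#'   gene_id = c("g1", "g2"),
#'   s1 = c(5L, 0L), s2 = c(7L, 1L), s3 = c(6L, 2L), s4 = c(9L, 0L)
#' )
#' design <- tibble::tibble(
#'   sample_id = c("s1", "s2", "s3", "s4"),
#'   condition = c("CK", "CK", "CT", "CT")
#' )
#' cf <- tempfile(fileext = ".tsv"); df <- tempfile(fileext = ".tsv")
#' write_result_table(counts, cf); write_result_table(design, df)
#' dat <- read_counts(cf, df)
#' dat$counts
#' @export
read_counts <- function(path, design_path, condition_aliases = NULL) {
  for (p in c(path, design_path)) {
    if (!file.exists(p)) {
      abort(sprintf("file not found: %s", p), class = "stressmodes_io_error")
    }
  }
  counts <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                    show_col_types = FALSE),
    error = function(e) {
      abort(sprintf("failed to parse counts TSV '%s': %s", path, conditionMessage(e)),
            class = "stressmodes_parse_error")
    }
  )
  prob <- readr::problems(counts)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed counts TSV '%s' at line %d: %s",
                  path, prob$row[1], prob$expected[1]),
          class = "stressmodes_parse_error")
  }
  names(counts)[1] <- "gene_id"
  counts$gene_id <- as.character(counts$gene_id)
  design <- tryCatch(
    readr::read_tsv(design_path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) {
      abort(sprintf("failed to parse design TSV '%s': %s", design_path, conditionMessage(e)),
            class = "stressmodes_parse_error")
    }
  )
  if (ncol(design) < 2) {
    abort("design file must have two columns: sample_id, condition",
          class = "stressmodes_parse_error")
  }
  names(design)[1:2] <- c("sample_id", "condition")
  design <- tibble::as_tibble(design[, 1:2])
  if (!is.null(condition_aliases)) {
    hit <- design$condition %in% names(condition_aliases)
    design$condition[hit] <- unname(condition_aliases[design$condition[hit]])
  }
  validate_counts(counts)
  validate_design(design, counts)
  list(counts = counts, design = design)
}

#' Validate a count table
#'
#' Checks that a counts tibble has unique gene and sample identifiers and
#' finite, non-negative, integer-valued entries.
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @return The input, invisibly; aborts with a validation error otherwise.
#' @export
validate_counts <- function(counts) {
  if (!"gene_id" %in% names(counts)) {
    abort("counts must contain a 'gene_id' column", class = "stressmodes_validation_error")
  }
  if (anyDuplicated(counts$gene_id)) {
    dup <- counts$gene_id[duplicated(counts$gene_id)][1]
    abort(sprintf("duplicate gene identifier: %s", dup),
          class = "stressmodes_validation_error")
  }
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) == 0) {
    abort("counts contain no sample columns", class = "stressmodes_validation_error")
  }
  if (anyDuplicated(samples)) {
    abort("duplicate sample identifiers in counts header",
          class = "stressmodes_validation_error")
  }
  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("sample '%s' has non-numeric counts", s),
            class = "stressmodes_validation_error")
    }
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort(sprintf("invalid count for gene '%s', sample '%s': %s (must be a finite non-negative integer)",
                    counts$gene_id[bad[1]], s, format(v[bad[1]])),
            class = "stressmodes_validation_error")
    }
  }
  invisible(counts)
}

#' Validate a sample design
#'
#' Checks that every sample in the counts appears exactly once in the design,
#' that condition labels are drawn from `CK`/`CT`/`DT`/`CD`, and that the
#' control plus at least one treatment each have two or more replicates.
#'
#' @param design Tibble with `sample_id` and `condition` columns.
#' @param counts Optional counts tibble to cross-check samples against.
#' @return The design, invisibly; aborts with a validation error otherwise.
#' @export
validate_design <- function(design, counts = NULL) {
  if (!all(c("sample_id", "condition") %in% names(design))) {
    abort("design must contain 'sample_id' and 'condition' columns",
          class = "stressmodes_validation_error")
  }
  if (anyDuplicated(design$sample_id)) {
    abort("duplicate sample identifiers in design", class = "stressmodes_validation_error")
  }
  unknown <- setdiff(unique(design$condition), .conditions)
  if (length(unknown) > 0) {
    abort(sprintf("unknown condition label(s): %s (expected %s)",
                  paste(unknown, collapse = ", "), paste(.conditions, collapse = ", ")),
          class = "stressmodes_validation_error")
  }
  if (!is.null(counts)) {
    samples <- setdiff(names(counts), "gene_id")
    missing <- setdiff(samples, design$sample_id)
    if (length(missing) > 0) {
      abort(sprintf("sample(s) present in counts but absent from design: %s",
                    paste(missing, collapse = ", ")),
            class = "stressmodes_validation_error")
    }
  }
  check_replicates(design, "CK")
  present_treatments <- intersect(.treatments, unique(design$condition))
  if (length(present_treatments) == 0) {
    abort("design contains no treatment condition (CT, DT or CD)",
          class = "stressmodes_validation_error")
  }
  check_replicates(design, present_treatments)
  invisible(design)
}

#' Read a gene annotation table
#'
#' Reads a TSV with columns `gene_id`, optional `annotation` (free text) and
#' optional `effect` (one of `promote`, `delay`). Genes absent from the table
#' are treated as unannotated by downstream functions, mirroring studies in
#' which a sizeable fraction of candidates has no database hit.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with columns `gene_id`, `annotation`, `effect` (missing
#'   input columns are filled with `NA`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "stressmodes_io_error")
  }
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!"gene_id" %in% names(ann)) names(ann)[1] <- "gene_id"
  if (!"annotation" %in% names(ann)) ann$annotation <- NA_character_
  if (!"effect" %in% names(ann)) ann$effect <- NA_character_
  bad <- setdiff(unique(ann$effect[!is.na(ann$effect)]), c("promote", "delay"))
  if (length(bad) > 0) {
    abort(sprintf("unknown effect label(s): %s (expected promote/delay)",
                  paste(bad, collapse = ", ")),
          class = "stressmodes_validation_error")
  }
  if (anyDuplicated(ann$gene_id)) {
    abort("duplicate gene identifiers in annotation table",
          class = "stressmodes_validation_error")
  }
  dplyr::select(ann, "gene_id", "annotation", "effect")
}

#' Write a result table as TSV
#'
#' Writes any tabular result as UTF-8, tab-separated text with a header row
#' and `.` as the decimal mark. Floats are written with enough precision that
#' re-reading reproduces them to at least six significant digits.
#'
#' @param records Data frame or tibble (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(records, path) {
  if (is.null(records)) {
    abort("records must not be NULL", class = "stressmodes_validation_error")
  }
  tryCatch(
    readr::write_tsv(tibble::as_tibble(records), path, progress = FALSE),
    error = function(e) {
      abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
            class = "stressmodes_io_error")
    }
  )
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "stressmodes_io_error")
  }
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full analysis. Defaults follow the
#' conventions of the underlying study design: DEGs are genes with
#' BH-adjusted p below `alpha`; response-mode stability is examined over the
#' union of top-`top_n_list` most significant genes per contrast; the
#' cumulative fold-change contribution uses the `contribution_n` most
#' significant single-stress responders; candidates must exceed both
#' single-stress log2 fold changes by more than `enhancement_margin` and are
#' split into `subgroup_k` subgroups.
#'
#' @param alpha Adjusted-p significance threshold, in (0, 1). Default 0.05.
#' @param top_n_list Integer vector of top-N sizes for the stability
#'   analysis. Default `c(500, 1000, 2000)`.
#' @param contribution_n Top-N size for the cumulative contribution
#'   statistic. Default 1000.
#' @param enhancement_margin Non-negative log2-unit margin for the
#'   enhanced-in-combined filter. Default 0.
#' @param subgroup_k Number of candidate subgroups. Default 3.
#' @param pseudo_count Pseudo-count added to normalized group means before
#'   taking log2 fold changes. Default 0.5.
#' @param dispersion_floor Lower bound for per-gene dispersion estimates.
#'   Default 1e-8.
#' @param assignment_method Profile assignment method, `"discrete"`
#'   (significance-gated sign pattern, default) or `"correlation"`
#'   (cosine similarity of the fold-change vector to each template).
#' @param rng_seed Integer seed governing all randomness. Default 1.
#' @return A list of class `stress_config`.
#' @export
pipeline_config <- function(alpha = 0.05,
                            top_n_list = c(500L, 1000L, 2000L),
                            contribution_n = 1000L,
                            enhancement_margin = 0,
                            subgroup_k = 3L,
                            pseudo_count = 0.5,
                            dispersion_floor = 1e-8,
                            assignment_method = c("discrete", "correlation"),
                            rng_seed = 1L) {
  assignment_method <- match.arg(assignment_method)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a single number in (0, 1)", class = "stressmodes_config_error")
  }
  if (length(top_n_list) < 1 || any(top_n_list < 1)) {
    abort("top_n_list values must be >= 1", class = "stressmodes_config_error")
  }
  if (contribution_n < 1) {
    abort("contribution_n must be >= 1", class = "stressmodes_config_error")
  }
  if (enhancement_margin < 0) {
    abort("enhancement_margin must be >= 0", class = "stressmodes_config_error")
  }
  if (subgroup_k < 1) {
    abort("subgroup_k must be >= 1", class = "stressmodes_config_error")
  }
  structure(
    list(
      alpha = alpha,
      top_n_list = as.integer(sort(top_n_list)),
      contribution_n = as.integer(contribution_n),
      enhancement_margin = enhancement_margin,
      subgroup_k = as.integer(subgroup_k),
      pseudo_count = pseudo_count,
      dispersion_floor = dispersion_floor,
      assignment_method = assignment_method,
      rng_seed = as.integer(rng_seed)
    ),
    class = "stress_config"
  )
}
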