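#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when reporting percentages (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(12.75, 1) # 12.8
#' round_half_up(0.5, 0)   # 1
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Internal: counts tibble -> integer matrix with gene rownames
count_matrix <- function(counts) {
  genes <- counts$gene_id
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

# Internal: stop unless all conditions in the design have >= n replicates
check_replicates <- function(design, conditions, n = 2) {
  tab <- table(design$condition)
  for (cond in conditions) {
    k <- if (cond %in% names(tab)) tab[[cond]] else 0L
    if (k < n) {
      abort(
        sprintf("condition '%s' has %d sample(s); at least %d replicates are required", cond, k, n),
        class = "stressmodes_design_error"
      )
    }
  }
  invisible(design)
}
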