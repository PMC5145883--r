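#' Predefined expression-profile templates
#'
#' Enumerates all 26 non-null sign patterns over the three contrasts
#' (CT, DT, CD) and labels each with one of five transcriptional response
#' modes. The rules are applied in order, so each pattern gets exactly one
#' mode:
#'
#' 1. **similar** — the same non-zero response in CT, DT and CD;
#' 2. **prioritized** — opposing responses to CT and DT, with a (necessarily
#'    one-sided) non-zero response to CD;
#' 3. **canceled** — a response to CT and/or DT that returns to control
#'    level under CD (CD sign 0);
#' 4. **independent** — a response to exactly one single stress, echoed with
#'    the same sign in CD;
#' 5. **combinatorial** — everything else: agreeing single-stress responses
#'    altered under CD, single-stress responses reversed under CD, and
#'    CD-only responses.
#'
#' Profile identifiers follow a fixed canonical enumeration (signs ordered
#' +1, 0, -1; CD varying fastest, then DT, then CT) and are not claimed to
#' match any published profile numbering.
#'
#' @return Tibble with columns `profile_id` (1..26), `s_ct`, `s_dt`, `s_cd`
#'   and `meta_mode`.
#' @examples
#' templates <- profile_templates()
#' dplyr::count(templates, meta_mode)
#' @export
profile_templates <- function() {
  signs <- c(1L, 0L, -1L)
  grid <- expand.grid(s_cd = signs, s_dt = signs, s_ct = signs,
                      KEEP.OUT.ATTRS = FALSE)[, c("s_ct", "s_dt", "s_cd")]
  grid <- grid[!(grid$s_ct == 0 & grid$s_dt == 0 & grid$s_cd == 0), ]
  out <- tibble::as_tibble(grid)
  out$profile_id <- seq_len(nrow(out))
  out$meta_mode <- mapply(classify_pattern, out$s_ct, out$s_dt, out$s_cd)
  dplyr::select(out, "profile_id", "s_ct", "s_dt", "s_cd", "meta_mode")
}

#' Classify one sign pattern into a response mode
#'
#' The rule set behind [profile_templates()], applied to a single
#' (CT, DT, CD) sign triple. The all-zero pattern returns `"unassigned"`.
#'
#' @param s_ct,s_dt,s_cd Signs in `{-1, 0, 1}`.
#' @return One of `"similar"`, `"prioritized"`, `"canceled"`,
#'   `"independent"`, `"combinatorial"`, `"unassigned"`.
#' @export
classify_pattern <- function(s_ct, s_dt, s_cd) {
  stopifnot(all(c(s_ct, s_dt, s_cd) %in% c(-1L, 0L, 1L)))
  if (s_ct == 0 && s_dt == 0 && s_cd == 0) return("unassigned")
  if (s_ct == s_dt && s_dt == s_cd && s_cd != 0) return("similar")
  if (s_ct == -s_dt && s_ct != 0 && s_cd != 0) return("prioritized")
  if ((s_ct != 0 || s_dt != 0) && s_cd == 0) return("canceled")
  one_single <- xor(s_ct != 0, s_dt != 0)
  if (one_single && s_cd == (s_ct + s_dt)) return("independent")
  "combinatorial"
}

#' Discretize one gene's differential-expression triple
#'
#' Significance-gated sign: the pattern entry for a contrast is the sign of
#' the log2 fold change when the adjusted p-value is below `alpha`, else 0.
#'
#' @param log2fc,qvalue Length-3 numeric vectors ordered (CT, DT, CD).
#' @param alpha Significance threshold.
#' @return Integer vector of signs, length 3.
#' @export
discretize <- function(log2fc, qvalue, alpha = 0.05) {
  if (length(log2fc) != 3 || length(qvalue) != 3) {
    abort("discretize expects log2fc and qvalue triples (CT, DT, CD)",
          class = "stressmodes_contract_error")
  }
  as.integer(sign(log2fc) * (qvalue < alpha))
}

# Internal: long DE table -> wide per-gene tibble with l_*, q_* columns.
# Errors if any gene lacks one of the three contrasts.
de_wide <- function(de) {
  need <- .treatments
  have <- unique(de$contrast)
  if (!all(need %in% have)) {
    abort(sprintf("profile assignment needs all three contrasts (missing: %s)",
                  paste(setdiff(need, have), collapse = ", ")),
          class = "stressmodes_contract_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(de, "gene_id", "contrast", "log2fc", "qvalue"),
    names_from = "contrast", values_from = c("log2fc", "qvalue")
  )
  incomplete <- wide$gene_id[!stats::complete.cases(
    wide[, c("qvalue_CT", "qvalue_DT", "qvalue_CD")])]
  if (length(incomplete) > 0) {
    abort(sprintf("gene(s) missing a contrast: %s",
                  paste(head(incomplete, 3), collapse = ", ")),
          class = "stressmodes_contract_error")
  }
  wide
}

#' Assign genes to expression profiles and response modes
#'
#' With the default `method = "discrete"`, each gene's (CT, DT, CD) pattern is
#' the significance-gated sign of its log2 fold changes ([discretize()]); the
#' pattern indexes a unique profile from [profile_templates()]. Genes with an
#' all-zero pattern get `meta_mode = "unassigned"` and `profile_id = NA`.
#' With `method = "correlation"` (sensitivity analysis), genes with at least
#' one significant contrast are assigned to the template whose sign vector
#' has the highest cosine similarity to the gene's log2 fold-change vector
#' (ties broken by lowest `profile_id`).
#'
#' @param de Long DE table from [run_de()] covering the CT, DT and CD
#'   contrasts.
#' @param alpha Significance threshold on adjusted p. Default 0.05.
#' @param genes Optional gene subset (e.g. from [select_top_n()]).
#' @param method `"discrete"` (default) or `"correlation"`.
#' @return Tibble with columns `gene_id`, `s_ct`, `s_dt`, `s_cd`,
#'   `profile_id`, `meta_mode`, plus the `log2fc_*` and `qvalue_*` values
#'   used.
#' @export
assign_profiles <- function(de, alpha = 0.05, genes = NULL,
                            method = c("discrete", "correlation")) {
  method <- match.arg(method)
  wide <- de_wide(de)
  if (!is.null(genes)) wide <- wide[wide$gene_id %in% genes, ]
  templates <- profile_templates()
  lmat <- as.matrix(wide[, c("log2fc_CT", "log2fc_DT", "log2fc_CD")])
  qmat <- as.matrix(wide[, c("qvalue_CT", "qvalue_DT", "qvalue_CD")])
  smat <- matrix(as.integer(sign(lmat) * (qmat < alpha)), nrow(wide), 3)

  if (method == "discrete") {
    key <- paste(smat[, 1], smat[, 2], smat[, 3])
    tkey <- paste(templates$s_ct, templates$s_dt, templates$s_cd)
    idx <- match(key, tkey)
    profile_id <- templates$profile_id[idx]
    meta_mode <- dplyr::coalesce(templates$meta_mode[idx], "unassigned")
    s <- smat
  } else {
    tmat <- as.matrix(templates[, c("s_ct", "s_dt", "s_cd")])
    # cosine similarity of each gene's L vector against each template
    tnorm <- sqrt(rowSums(tmat^2))
    lnorm <- sqrt(rowSums(lmat^2))
    sim <- (lmat %*% t(tmat)) / outer(pmax(lnorm, 1e-12), tnorm)
    best <- apply(sim, 1, which.max)
    any_sig <- rowSums(qmat < alpha) > 0
    profile_id <- ifelse(any_sig, templates$profile_id[best], NA_integer_)
    meta_mode <- ifelse(any_sig, templates$meta_mode[best], "unassigned")
    s <- tmat[best, , drop = FALSE]
    s[!any_sig, ] <- 0L
  }
  tibble::tibble(
    gene_id = wide$gene_id,
    s_ct = s[, 1], s_dt = s[, 2], s_cd = s[, 3],
    profile_id = profile_id,
    meta_mode = meta_mode,
    log2fc_CT = lmat[, 1], log2fc_DT = lmat[, 2], log2fc_CD = lmat[, 3],
    qvalue_CT = qmat[, 1], qvalue_DT = qmat[, 2], qvalue_CD = qmat[, 3]
  )
}

#' Union of the top-N most significant genes per contrast
#'
#' For each contrast in `de`, ranks genes by adjusted p ascending, ties by
#' larger |log2 fold change|, then by gene identifier, takes the first `n`,
#' and returns the union across contrasts. Requesting more genes than a
#' contrast has triggers a warning and takes all.
#'
#' @param de Long DE table.
#' @param n Number of genes per contrast (>= 1).
#' @return Character vector of gene identifiers (sorted).
#' @export
select_top_n <- function(de, n) {
  if (n < 1) abort("n must be >= 1", class = "stressmodes_contract_error")
  picks <- de |>
    dplyr::group_by(.data$contrast) |>
    dplyr::arrange(.data$qvalue, dplyr::desc(abs(.data$log2fc)), .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::group_map(function(tbl, key) {
      if (n > nrow(tbl)) {
        warn(sprintf("top-N %d exceeds the %d genes available in contrast %s; taking all",
                     n, nrow(tbl), key$contrast[[1]]))
      }
      tbl$gene_id[seq_len(min(n, nrow(tbl)))]
    })
  sort(unique(unlist(picks)))
}

#' Summarize response-mode composition
#'
#' Counts and fractions of assigned genes per mode, over the five modes, plus
#' an `unpredictable` aggregate combining the prioritized, combinatorial and
#' canceled modes (the response patterns a single-stress experiment cannot
#' predict).
#'
#' @param assignments Assignment table from [assign_profiles()].
#' @return Tibble with columns `meta_mode`, `count`, `fraction`; the last row
#'   is the `unpredictable` aggregate (its fraction relative to the same
#'   assigned-gene denominator).
#' @export
summarize_modes <- function(assignments) {
  assigned <- assignments[assignments$meta_mode != "unassigned", ]
  if (nrow(assigned) == 0) {
    abort("no gene has a non-null pattern; cannot summarize modes",
          class = "stressmodes_empty_error")
  }
  counts <- table(factor(assigned$meta_mode, levels = .modes))
  total <- sum(counts)
  out <- tibble::tibble(
    meta_mode = names(counts),
    count = as.integer(counts),
    fraction = as.integer(counts) / total
  )
  unpred <- sum(out$count[out$meta_mode %in% c("prioritized", "combinatorial", "canceled")])
  dplyr::bind_rows(out, tibble::tibble(
    meta_mode = "unpredictable", count = unpred, fraction = unpred / total
  ))
}

#' Stability of mode fractions across top-N gene sets
#'
#' Recomputes the mode summary on the union of top-N genes per contrast for
#' each N in `n_list`, and reports the largest absolute difference in any
#' mode's fraction between any two N values.
#'
#' @param de Long DE table.
#' @param n_list Integer vector of top-N sizes (e.g. `c(500, 1000, 2000)`).
#' @param alpha Significance threshold.
#' @param method Assignment method, see [assign_profiles()].
#' @return List with `fractions` (tibble: `top_n`, `meta_mode`, `count`,
#'   `fraction`) and `max_deviation` (single number; 0 when `n_list` has one
#'   element).
#' @export
stability_check <- function(de, n_list = c(500L, 1000L, 2000L), alpha = 0.05,
                            method = "discrete") {
  if (length(n_list) < 1) {
    abort("n_list must be non-empty", class = "stressmodes_contract_error")
  }
  tabs <- purrr::map(n_list, function(n) {
    genes <- select_top_n(de, n)
    summ <- summarize_modes(assign_profiles(de, alpha = alpha, genes = genes,
                                            method = method))
    dplyr::mutate(summ, top_n = as.integer(n), .before = 1)
  })
  fractions <- dplyr::bind_rows(tabs)
  dev <- fractions |>
    dplyr::filter(.data$meta_mode %in% .modes) |>
    dplyr::group_by(.data$meta_mode) |>
    dplyr::summarise(spread = max(.data$fraction) - min(.data$fraction))
  list(fractions = fractions, max_deviation = max(dev$spread))
}
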