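.venn_regions <- c("CT_only", "DT_only", "CD_only",
                   "CT_DT", "CT_CD", "DT_CD", "CT_DT_CD")

#' Disjoint three-set Venn cell counts
#'
#' Exact counts of the seven disjoint regions formed by the CT, DT and CD
#' DEG sets (pairwise regions exclude the triple intersection).
#'
#' @param ct,dt,cd Character vectors of gene identifiers (duplicates are
#'   ignored; empty sets allowed).
#' @return Tibble with columns `region`
#'   (`CT_only`, `DT_only`, `CD_only`, `CT_DT`, `CT_CD`, `DT_CD`,
#'   `CT_DT_CD`) and `count`; cell counts always sum to the union size.
#' @examples
#' venn_counts(c("a", "b"), c("b", "c"), c("b", "d"))
#' @export
venn_counts <- function(ct, dt, cd) {
  ct <- unique(as.character(ct)); dt <- unique(as.character(dt))
  cd <- unique(as.character(cd))
  universe <- union(union(ct, dt), cd)
  in_ct <- universe %in% ct
  in_dt <- universe %in% dt
  in_cd <- universe %in% cd
  tibble::tibble(
    region = .venn_regions,
    count = c(
      sum(in_ct & !in_dt & !in_cd),
      sum(!in_ct & in_dt & !in_cd),
      sum(!in_ct & !in_dt & in_cd),
      sum(in_ct & in_dt & !in_cd),
      sum(in_ct & !in_dt & in_cd),
      sum(!in_ct & in_dt & in_cd),
      sum(in_ct & in_dt & in_cd)
    )
  )
}

#' Direction-stratified Venn decomposition of DEG sets
#'
#' Builds the significant gene set of each contrast (all DEGs, up-regulated
#' only, down-regulated only) and computes the disjoint Venn cells for each
#' stratum.
#'
#' @param de Long DE table from [run_de()] with CT, DT and CD contrasts.
#' @return Tibble with columns `direction` (`all`, `up`, `down`), `region`,
#'   `count`.
#' @export
deg_venn <- function(de) {
  sets <- function(dir) {
    keep <- if (dir == "all") de$significant else de$significant & de$direction == dir
    split(de$gene_id[keep], de$contrast[keep])
  }
  purrr::map_dfr(c("all", "up", "down"), function(dir) {
    s <- sets(dir)
    v <- venn_counts(s$CT %||% character(), s$DT %||% character(),
                     s$CD %||% character())
    dplyr::mutate(v, direction = dir, .before = 1)
  })
}

#' Overlap statistics from a Venn decomposition
#'
#' Derives the summary percentages used to compare single and combined
#' stress responses:
#'
#' * `triple_overlap` — genes differential in all three contrasts, as a
#'   percentage of the DEG union;
#' * `cd_unique` — combined-stress-only DEGs, as a percentage of the CD
#'   total;
#' * `single_in_cd` — genes responding to CT or DT that also respond to CD,
#'   as a percentage of the DEG union;
#' * `induced_in_cd` — among genes up-regulated by at least one single
#'   stress, those also up-regulated under CD (percentage of that set);
#' * `repressed_in_cd` — the down-regulated counterpart.
#'
#' Percentages are rounded half away from zero to the precision conventional
#' for each statistic (one decimal for the first three, integer for the
#' directional two), recorded in the `digits` column.
#'
#' @param venn Direction-stratified cell table from [deg_venn()] (columns
#'   `direction`, `region`, `count`).
#' @return Tibble with columns `statistic`, `count`, `denominator`,
#'   `percent`, `digits`.
#' @export
overlap_statistics <- function(venn) {
  cell <- function(dir, region) {
    x <- venn$count[venn$direction == dir & venn$region == region]
    if (length(x) != 1) {
      abort(sprintf("venn table lacks region '%s' for direction '%s'", region, dir),
            class = "stressmodes_contract_error")
    }
    x
  }
  dir_stats <- function(dir) {
    cells <- setNames(purrr::map_int(.venn_regions, function(r) as.integer(cell(dir, r))),
                      .venn_regions)
    list(
      union = sum(cells),
      triple = cells[["CT_DT_CD"]],
      cd_total = sum(cells[c("CD_only", "CT_CD", "DT_CD", "CT_DT_CD")]),
      cd_only = cells[["CD_only"]],
      single_union = sum(cells) - cells[["CD_only"]],
      single_and_cd = sum(cells[c("CT_CD", "DT_CD", "CT_DT_CD")])
    )
  }
  a <- dir_stats("all"); u <- dir_stats("up"); d <- dir_stats("down")
  pct <- function(num, den, digits) {
    if (den == 0) {
      abort("percentage undefined: empty denominator set",
            class = "stressmodes_empty_error")
    }
    round_half_up(100 * num / den, digits)
  }
  tibble::tibble(
    statistic = c("triple_overlap", "cd_unique", "single_in_cd",
                  "induced_in_cd", "repressed_in_cd"),
    count = c(a$triple, a$cd_only, a$single_and_cd, u$single_and_cd, d$single_and_cd),
    denominator = c(a$union, a$cd_total, a$union, u$single_union, d$single_union),
    digits = c(1L, 1L, 1L, 0L, 0L),
    percent = c(
      pct(a$triple, a$union, 1),
      pct(a$cd_only, a$cd_total, 1),
      pct(a$single_and_cd, a$union, 1),
      pct(u$single_and_cd, u$single_union, 0),
      pct(d$single_and_cd, d$single_union, 0)
    )
  )
}

#' Cumulative fold-change contribution of a gene list in the combined stress
#'
#' Sums the absolute log2 fold changes that the listed genes exhibit in the
#' CD contrast (the primary statistic; the signed sum is reported alongside).
#' Genes absent from the CD results contribute zero and are reported.
#'
#' @param genes Character vector of gene identifiers (typically the top-N
#'   most significant responders to one single stress).
#' @param de_cd DE table restricted to, or containing, the CD contrast.
#' @return Tibble with one row: `n_genes`, `n_missing`, `absolute`, `signed`.
#' @examples
#' de_cd <- tibble::tibble(gene_id = c("a", "b", "c"), contrast = "CD",
#'                         log2fc = c(1, -2, 3))
#' cumulative_contribution(c("a", "b", "c"), de_cd) # absolute 6, signed 2
#' @export
cumulative_contribution <- function(genes, de_cd) {
  de_cd <- de_cd[de_cd$contrast == "CD", ]
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    warn("empty gene list; contribution is 0")
    return(tibble::tibble(n_genes = 0L, n_missing = 0L, absolute = 0, signed = 0))
  }
  l <- de_cd$log2fc[match(genes, de_cd$gene_id)]
  missing <- sum(is.na(l))
  if (missing > 0) {
    inform(sprintf("%d gene(s) absent from the CD results contribute 0", missing))
    l[is.na(l)] <- 0
  }
  tibble::tibble(
    n_genes = length(genes),
    n_missing = as.integer(missing),
    absolute = sum(abs(l)),
    signed = sum(l)
  )
}

#' Single-stress contribution statistics
#'
#' For each single stress (CT, DT), selects the `n` most significant genes in
#' that contrast (adjusted p ascending, ties by |log2 fold change| then gene
#' id) and computes their cumulative fold-change contribution in CD.
#'
#' @param de Long DE table covering CT, DT and CD.
#' @param n Number of top genes per single stress. Default 1000.
#' @return Tibble with columns `stress`, `n_genes`, `n_missing`, `absolute`,
#'   `signed`.
#' @export
contribution_stats <- function(de, n = 1000L) {
  purrr::map_dfr(c("CT", "DT"), function(stress) {
    top <- select_top_n(de[de$contrast == stress, ], n)
    dplyr::mutate(cumulative_contribution(top, de), stress = stress, .before = 1)
  })
}
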