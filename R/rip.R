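#' RIP enrichment of features between pull-down conditions
#'
#' Contrasts immunoprecipitated libraries of two conditions (e.g. disease
#' IP vs. control IP; an IP-vs-input contrast works the same way by passing
#' the input libraries as controls). Counts are normalized by
#' median-of-ratios size factors across all libraries, the fold change is
#' the ratio of normalized group means, and a pooled-variance t-test gives
#' the per-feature P value. A feature is called *bound* when it is
#' significantly enriched (P below threshold and fold change above 1).
#'
#' @param counts Data frame with columns `feature`, optionally `gene`
#'   (feature-to-gene map), plus one count column per library.
#' @param case_ids,ctrl_ids Library column names of the two sides (at
#'   least 2 each).
#' @param normalize Apply size-factor normalization (default `TRUE`).
#' @param p_max Significance threshold for the bound call (default 0.05).
#' @param pseudocount Added to both group means when either is zero.
#' @param adjust Benjamini-Hochberg correction (default off: raw P).
#' @return A tibble sorted by fold change descending: `feature`, `gene`,
#'   `fold_change`, `t_statistic`, `p_value`, `bound`.
#' @export
rip_enrich <- function(counts, case_ids, ctrl_ids, normalize = TRUE,
                       p_max = 0.05, pseudocount = 0.5, adjust = FALSE) {
  if (!"feature" %in% names(counts)) {
    stop("RIP count table needs a 'feature' column", call. = FALSE)
  }
  gene <- if ("gene" %in% names(counts)) counts$gene else counts$feature
  num <- counts[, c(case_ids, ctrl_ids), drop = FALSE]
  keep <- rowSums(!is.na(num)) == ncol(num)
  if (any(!keep)) {
    warning(sum(!keep), " feature(s) missing counts on one side, skipped")
  }
  tab <- dplyr::bind_cols(
    tibble::tibble(gene = counts$feature),
    num
  )[keep, , drop = FALSE]
  gene <- gene[keep]
  if (normalize) {
    tab <- normalize_counts(tab)
  }
  de <- de_ttest(tab, case_ids, ctrl_ids,
    pseudocount = pseudocount,
    p_max = p_max, adjust = adjust
  )
  tibble::tibble(
    feature = de$gene,
    gene = gene,
    fold_change = de$fold_change,
    t_statistic = de$t_statistic,
    p_value = de$p_value,
    bound = !is.na(de$p_value) & de$p_value < p_max & de$fold_change > 1
  ) |>
    dplyr::arrange(dplyr::desc(fold_change))
}

#' Genes both bound in RIP and differentially spliced
#'
#' Intersects, at the gene level, the features enriched in the pull-down
#' with the exonic parts showing significant PSI changes: a gene counts as
#' bound when any of its features is bound, and as spliced when any of its
#' parts is significant. The intersection is the bound-and-differentially-
#' spliced target set; a per-chromosome tally is emitted when part
#' coordinates are supplied.
#'
#' @param rip_records Output of [rip_enrich()].
#' @param dpsi_records Output of [delta_psi_test()].
#' @param p_max Significance threshold applied to the splicing P values
#'   (the bound flag in `rip_records` already encodes its own threshold).
#' @param parts Optional exonic-part tibble (for chromosome assignment).
#' @return A list with `genes` (sorted character vector), `counts` tibble
#'   (bound, spliced, intersection sizes) and `per_chromosome` (tibble or
#'   `NULL`).
#' @export
bound_and_spliced <- function(rip_records, dpsi_records, p_max = 0.05,
                              parts = NULL) {
  bound_genes <- unique(rip_records$gene[rip_records$bound])
  spliced_genes <- unique(dpsi_records$gene_id[
    !is.na(dpsi_records$p_value) & dpsi_records$p_value < p_max
  ])
  if (length(intersect(
    unique(rip_records$gene),
    unique(dpsi_records$gene_id)
  )) == 0L) {
    stop("no shared gene ids between RIP and splicing tables", call. = FALSE)
  }
  genes <- sort(intersect(bound_genes, spliced_genes))
  per_chrom <- NULL
  if (!is.null(parts)) {
    per_chrom <- parts |>
      dplyr::distinct(gene_id, contig) |>
      dplyr::filter(gene_id %in% genes) |>
      dplyr::count(contig, name = "n_genes") |>
      dplyr::arrange(contig)
  }
  list(
    genes = genes,
    counts = tibble::tibble(
      set = c("bound", "spliced", "bound_and_spliced"),
      n = c(length(bound_genes), length(spliced_genes), length(genes))
    ),
    per_chromosome = per_chrom
  )
}
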