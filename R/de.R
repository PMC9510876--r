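#' Median-of-ratios size factors
#'
#' Computes one scaling constant per library so that counts become
#' comparable across sequencing depths: each sample's factor is the median,
#' over genes detected in every sample, of that sample's count divided by
#' the gene's geometric mean across samples. Dividing a sample's counts by
#' its factor yields normalized counts.
#'
#' @param counts Data frame with a `gene` column and one non-negative
#'   integer column per sample.
#' @return A tibble with columns `sample` and `size_factor`.
#' @examples
#' cnt <- tibble::tibble(gene = c("g1", "g2", "g3"), A = c(2, 4, 6), B = c(4, 8, 12))
#' size_factors(cnt) # factors 0.707 and 1.414
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) {
    stop(
      "no gene has positive counts in all samples; ",
      "consider a pseudo-reference (add a pseudocount before calling)",
      call. = FALSE
    )
  }
  logm <- log(m[ok, , drop = FALSE])
  geo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - geo)))
  tibble::tibble(sample = colnames(m), size_factor = as.numeric(sf))
}

#' Normalize counts by size factors
#'
#' @param counts Count data frame (see [size_factors()]).
#' @param factors Output of [size_factors()]; computed from `counts` when
#'   omitted.
#' @return A tibble of the same shape with each sample divided by its
#'   factor.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  m <- count_matrix(counts)
  sf <- setNames(factors$size_factor, factors$sample)[colnames(m)]
  if (anyNA(sf)) stop("size factor missing for some samples", call. = FALSE)
  norm <- sweep(m, 2, sf, "/")
  dplyr::bind_cols(
    tibble::tibble(gene = counts$gene),
    tibble::as_tibble(norm)
  )
}

#' Per-gene differential expression by Student's t-test
#'
#' Tests each gene between two groups of samples with a pooled-variance
#' two-sample t-test on normalized counts (Welch's correction available via
#' `welch = TRUE`). The fold change is the ratio of group means; when a
#' group mean is zero a pseudocount is added to both means so the ratio
#' stays finite and positive.
#'
#' Genes with zero variance in both groups and unequal means cannot be
#' tested: their P value is `NA` and they are flagged (`zero_variance`),
#' which excludes them from candidate calls. Identical constant groups are
#' reported as fold change 1, P = 1.
#'
#' @param norm_counts Data frame with `gene` plus one numeric column per
#'   sample (normalized counts; see [normalize_counts()]).
#' @param case_ids,ctrl_ids Column names of the two groups (at least 2
#'   samples each).
#' @param pseudocount Added to both group means when either is zero
#'   (default 0.5).
#' @param p_max Significance threshold used for the `direction` call
#'   (default 0.05).
#' @param welch Use Welch's unequal-variance t instead of the pooled test.
#' @param adjust Apply Benjamini-Hochberg correction to the reported
#'   `p_value` (default `FALSE`: raw P values, as screening at P < 0.05
#'   without correction).
#' @return A tibble with one row per gene: `mean_case`, `mean_ctrl`,
#'   `fold_change` (case/control), `log2_fold_change`, `t_statistic`,
#'   `p_value`, `direction` (`up`/`down`/`ns`), `zero_variance`.
#' @export
de_ttest <- function(norm_counts, case_ids, ctrl_ids, pseudocount = 0.5,
                     p_max = 0.05, welch = FALSE, adjust = FALSE) {
  m <- count_matrix(norm_counts, integer_only = FALSE)
  for (ids in list(case_ids, ctrl_ids)) {
    absent <- setdiff(ids, colnames(m))
    if (length(absent) > 0L) {
      stop("sample(s) not in table: ", paste(absent, collapse = ", "),
        call. = FALSE
      )
    }
    if (length(ids) < 2L) stop("need >= 2 samples per group", call. = FALSE)
  }
  case <- m[, case_ids, drop = FALSE]
  ctrl <- m[, ctrl_ids, drop = FALSE]

  res <- purrr::map(seq_len(nrow(m)), function(i) {
    two_group_t(case[i, ], ctrl[i, ], welch = welch)
  }) |> purrr::list_rbind()

  mean_case <- unname(rowMeans(case))
  mean_ctrl <- unname(rowMeans(ctrl))
  pc <- ifelse(mean_case == 0 | mean_ctrl == 0, pseudocount, 0)
  fc <- (mean_case + pc) / (mean_ctrl + pc)

  p <- res$p_value
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    gene = norm_counts$gene,
    mean_case = mean_case,
    mean_ctrl = mean_ctrl,
    fold_change = fc,
    log2_fold_change = log2(fc),
    t_statistic = res$t_statistic,
    p_value = p,
    direction = dplyr::case_when(
      is.na(p) | p >= p_max ~ "ns",
      fc > 1 ~ "up",
      .default = "down"
    ),
    zero_variance = res$zero_variance
  )
}

two_group_t <- function(x, y, welch = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(
        t_statistic = 0, p_value = 1, zero_variance = TRUE
      ))
    }
    return(tibble::tibble(
      t_statistic = NA_real_, p_value = NA_real_, zero_variance = TRUE
    ))
  }
  tt <- t.test(x, y, var.equal = !welch)
  tibble::tibble(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    zero_variance = FALSE
  )
}

#' Nominate screen candidates from enrichment and regulation
#'
#' Combines heart-specificity scores with differential-expression results:
#' a gene is a candidate when it is both heart-enriched (`hss >= hss_min`)
#' and significantly regulated in disease (`p_value < p_max`). This is the
#' two-axis screen that surfaces tissue-enriched, disease-regulated
#' RNA-binding proteins.
#'
#' @param hss_scores Output of [compute_hss()].
#' @param de Output of [de_ttest()].
#' @param hss_min Minimum heart-specificity score (default 3).
#' @param p_max Maximum raw P value (default 0.05).
#' @return A tibble sorted by P value then absolute log2 fold change, with
#'   flags `enriched`, `regulated` and the combined `verdict`. The counts
#'   of up- and down-regulated candidates are attached as attribute
#'   `regulated_counts`.
#' @export
nominate_candidates <- function(hss_scores, de, hss_min = 3, p_max = 0.05) {
  joined <- dplyr::inner_join(
    dplyr::select(hss_scores, gene, hss),
    de,
    by = "gene"
  )
  if (nrow(joined) == 0L) {
    stop(
      "no shared gene ids between HSS and DE tables; unmatched: ",
      paste(head(
        c(setdiff(hss_scores$gene, de$gene), setdiff(de$gene, hss_scores$gene)),
        10
      ), collapse = ", "),
      call. = FALSE
    )
  }
  out <- joined |>
    dplyr::mutate(
      enriched = hss >= hss_min,
      regulated = !is.na(p_value) & p_value < p_max & !zero_variance,
      verdict = enriched & regulated
    ) |>
    dplyr::arrange(p_value, dplyr::desc(abs(log2_fold_change)))
  attr(out, "regulated_counts") <- c(
    up = sum(out$verdict & out$direction == "up"),
    down = sum(out$verdict & out$direction == "down")
  )
  out
}

#' Relative expression by the 2^-dCt method
#'
#' qPCR quantification relative to a reference gene: one cycle difference
#' doubles the template amount, so relative expression is
#' `2^-(Ct_target - Ct_reference)`.
#'
#' @param ct_target,ct_reference Threshold cycles (vectorized).
#' @return Relative expression, same length as the inputs.
#' @examples
#' delta_ct(25, 20) # 0.03125
#' @export
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference))
  2^-(ct_target - ct_reference)
}

count_matrix <- function(counts, integer_only = TRUE) {
  if (!"gene" %in% names(counts)) {
    stop("count table needs a 'gene' column", call. = FALSE)
  }
  m <- as.matrix(counts[, setdiff(names(counts), "gene"), drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  if (integer_only && any(m != round(m))) {
    stop("counts must be integers", call. = FALSE)
  }
  rownames(m) <- counts$gene
  m
}
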