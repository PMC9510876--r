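#' Correlate per-exon expression with a splicing factor's expression
#'
#' For every exonic part of a gene, computes the correlation across samples
#' between the part's expression and the expression of a candidate
#' splicing factor. Along-gene profiles of these coefficients localize the
#' region a factor acts on (e.g. elevated coefficients over the exons
#' encoding titin's PEVK spring region).
#'
#' @param part_expr Data frame with columns `part_id` (optionally
#'   `gene_id`, `part_index`) plus one numeric column per sample.
#' @param factor_expr Either a named numeric vector (names = samples) or a
#'   data frame with columns `sample` and `expression`.
#' @param transform `"log2"` (log2(x+1), default) or `"identity"`, applied
#'   to both variables before correlating.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble with one row per part: `part_id`, `r` (`NA` when the
#'   part has zero variance), `n_samples`.
#' @export
exon_factor_correlation <- function(part_expr, factor_expr,
                                    transform = c("log2", "identity"),
                                    method = c("pearson", "spearman")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (is.data.frame(factor_expr)) {
    factor_expr <- setNames(factor_expr$expression, factor_expr$sample)
  }
  samples <- setdiff(names(part_expr), c("part_id", "gene_id", "part_index"))
  shared <- intersect(samples, names(factor_expr))
  if (length(shared) < 3L) {
    stop(
      "need >= 3 shared samples; in parts only: ",
      paste(setdiff(samples, names(factor_expr)), collapse = ", "),
      "; in factor only: ",
      paste(setdiff(names(factor_expr), samples), collapse = ", "),
      call. = FALSE
    )
  }
  tf <- if (transform == "log2") function(x) log2(x + 1) else identity
  f <- tf(as.numeric(factor_expr[shared]))
  m <- tf(as.matrix(part_expr[, shared, drop = FALSE]))
  r <- apply(m, 1, function(x) {
    if (stats::sd(x) == 0 || stats::sd(f) == 0) {
      return(NA_real_)
    }
    cor(x, f, method = method)
  })
  out <- tibble::tibble(
    part_id = part_expr$part_id,
    r = as.numeric(r),
    n_samples = length(shared)
  )
  for (col in c("gene_id", "part_index")) {
    if (col %in% names(part_expr)) out[[col]] <- part_expr[[col]]
  }
  dplyr::relocate(out, dplyr::any_of(c("gene_id", "part_id", "part_index")))
}

#' Compare two correlation profiles over a region
#'
#' Summarizes the profiles of two candidate factors over a part-index
#' region of the same gene (mean and maximum coefficient, the part
#' attaining the maximum) and reports the difference of region means; a
#' factor that regulates the region shows systematically higher
#' coefficients there than an unrelated factor.
#'
#' @param profile_a,profile_b Outputs of [exon_factor_correlation()] on the
#'   same part grid.
#' @param region Integer vector of part indices (e.g. `131:133`).
#' @return A tibble with one row per profile (`mean_r`, `max_r`,
#'   `argmax_part`); the difference of region means is attached as
#'   attribute `difference`.
#' @export
compare_factor_profiles <- function(profile_a, profile_b, region) {
  if (length(region) == 0L) stop("empty region", call. = FALSE)
  if (!identical(profile_a$part_id, profile_b$part_id)) {
    stop("profiles are not on the same part grid", call. = FALSE)
  }
  if (!"part_index" %in% names(profile_a)) {
    stop("profiles need a part_index column for region selection",
      call. = FALSE
    )
  }
  if (!all(region %in% profile_a$part_index)) {
    stop("region outside the part range of the profiles", call. = FALSE)
  }
  summarize_one <- function(p, label) {
    d <- p[p$part_index %in% region & !is.na(p$r), , drop = FALSE]
    tibble::tibble(
      profile = label,
      mean_r = mean(d$r),
      max_r = max(d$r),
      argmax_part = d$part_id[which.max(d$r)]
    )
  }
  out <- dplyr::bind_rows(
    summarize_one(profile_a, "a"),
    summarize_one(profile_b, "b")
  )
  attr(out, "difference") <- out$mean_r[1] - out$mean_r[2]
  out
}
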