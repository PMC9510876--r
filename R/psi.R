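#' Percent spliced in (PSI) per exonic part and sample
#'
#' Quantifies inclusion of each exonic part from two evidence streams:
#' reads assigned to the part itself (`part_counts`) plus junction reads
#' that splice into or out of the part's boundaries count as *inclusion*;
#' junction reads whose intron covers the whole part (a splice event that
#' removes it, including the spliced form of a retained intron) count as
#' *exclusion*. PSI is inclusion over total evidence.
#'
#' In the default length-normalized mode, inclusion evidence is divided by
#' the number of read start positions consistent with the part
#' (`part length + read_length - 1`) and exclusion by the junction-spanning
#' positions (`read_length - 1`), so parts of different lengths are
#' comparable. `mode = "raw"` skips the normalization, appropriate when the
#' inputs are event-level informative-read counts rather than positional
#' coverage.
#'
#' @param parts Exonic-part tibble from [flatten_annotation()].
#' @param junctions Junction tibble from [read_junctions()] (with a
#'   `sample` column), or row-bound tibbles of several samples.
#' @param part_counts Tibble with columns `part_id`, `sample`, `count`:
#'   reads assigned to each part.
#' @param read_length Read length used for normalization (default 100).
#' @param mode `"normalized"` (default) or `"raw"`.
#' @return A tibble with one row per part x sample: `part_id`, `gene_id`,
#'   `part_index`, `sample`, `inclusion`, `exclusion` (raw counts),
#'   `inc_norm`, `exc_norm`, `psi` (`NA` when the part has no evidence in
#'   that sample).
#' @export
compute_psi <- function(parts, junctions, part_counts, read_length = 100,
                        mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if (mode == "normalized" && read_length <= 1) {
    stop("read_length must be > 1 in normalized mode", call. = FALSE)
  }
  samples <- sort(unique(c(part_counts$sample, junctions$sample)))
  unknown <- setdiff(unique(junctions$contig), unique(parts$contig))
  if (length(unknown) > 0L) {
    warning(
      "junction contig(s) absent from parts, skipped: ",
      paste(unknown, collapse = ", ")
    )
    junctions <- junctions[!junctions$contig %in% unknown, , drop = FALSE]
  }

  grid <- tidyr::expand_grid(
    parts |> dplyr::select(part_id, gene_id, part_index, contig, start, end),
    sample = samples
  )

  cov <- part_counts |>
    dplyr::group_by(part_id, sample) |>
    dplyr::summarise(cov = sum(count), .groups = "drop")

  # junction evidence per part: cross parts with junctions on the same
  # contig, then classify by interval arithmetic
  jev <- dplyr::inner_join(
    parts |> dplyr::select(part_id,
      contig,
      p_start = start, p_end = end
    ),
    junctions |> dplyr::select(contig,
      j_start = start, j_end = end,
      sample, count
    ),
    by = "contig", relationship = "many-to-many"
  )
  exc <- jev |>
    dplyr::filter(.data$j_start <= .data$p_start & .data$j_end >= .data$p_end) |>
    dplyr::group_by(part_id, sample) |>
    dplyr::summarise(exc = sum(count), .groups = "drop")
  inc_j <- jev |>
    dplyr::filter(.data$j_end == .data$p_start | .data$j_start == .data$p_end) |>
    dplyr::group_by(part_id, sample) |>
    dplyr::summarise(inc_j = sum(count), .groups = "drop")

  out <- grid |>
    dplyr::left_join(cov, by = c("part_id", "sample")) |>
    dplyr::left_join(exc, by = c("part_id", "sample")) |>
    dplyr::left_join(inc_j, by = c("part_id", "sample")) |>
    dplyr::mutate(
      inclusion = dplyr::coalesce(cov, 0) + dplyr::coalesce(inc_j, 0),
      exclusion = dplyr::coalesce(exc, 0),
      inc_norm = if (mode == "normalized") {
        inclusion / (end - start + read_length - 1)
      } else {
        inclusion
      },
      exc_norm = if (mode == "normalized") {
        exclusion / (read_length - 1)
      } else {
        exclusion
      },
      psi = dplyr::if_else(inc_norm + exc_norm > 0,
        inc_norm / (inc_norm + exc_norm), NA_real_
      )
    ) |>
    dplyr::select(
      part_id, gene_id, part_index, sample,
      inclusion, exclusion, inc_norm, exc_norm, psi
    ) |>
    dplyr::arrange(gene_id, part_index, sample)
  out
}

#' Test PSI differences between two conditions
#'
#' For each exonic part with enough defined PSI values in both groups, the
#' per-sample PSI values are compared with a pooled-variance two-sample
#' t-test; delta PSI is the difference of group means (case minus control).
#' Undefined PSI values (no evidence) are dropped pairwise; parts falling
#' below `min_defined` defined values in either group are skipped with a
#' reason.
#'
#' @param psi_records Output of [compute_psi()].
#' @param case_ids,ctrl_ids Sample ids of the two groups.
#' @param min_defined Minimum defined PSI values required per group
#'   (default: every sample of the group).
#' @param p_max Significance threshold recorded in the `significant` flag.
#' @param adjust Benjamini-Hochberg correction of P values (default off:
#'   raw P).
#' @return A tibble sorted by gene then part: `mean_psi_case`,
#'   `mean_psi_ctrl`, `delta_psi`, `t_statistic`, `p_value`,
#'   `significant`, `skipped`, `skip_reason`.
#' @export
delta_psi_test <- function(psi_records, case_ids, ctrl_ids,
                           min_defined = NULL, p_max = 0.05, adjust = FALSE) {
  if (is.null(min_defined)) {
    min_case <- length(case_ids)
    min_ctrl <- length(ctrl_ids)
  } else {
    min_case <- min_ctrl <- min_defined
  }
  out <- psi_records |>
    dplyr::filter(sample %in% c(case_ids, ctrl_ids)) |>
    dplyr::group_by(part_id, gene_id, part_index) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      x <- d$psi[d$sample %in% case_ids & !is.na(d$psi)]
      y <- d$psi[d$sample %in% ctrl_ids & !is.na(d$psi)]
      base <- tibble::tibble(
        part_id = d$part_id[1], gene_id = d$gene_id[1],
        part_index = d$part_index[1],
        n_case = length(x), n_ctrl = length(y),
        mean_psi_case = if (length(x)) mean(x) else NA_real_,
        mean_psi_ctrl = if (length(y)) mean(y) else NA_real_
      )
      if (length(x) < max(2L, min_case) || length(y) < max(2L, min_ctrl)) {
        return(dplyr::mutate(base,
          delta_psi = NA_real_, t_statistic = NA_real_, p_value = NA_real_,
          skipped = TRUE, skip_reason = "too few defined PSI values"
        ))
      }
      tt <- two_group_t(x, y)
      dplyr::mutate(base,
        delta_psi = mean(x) - mean(y),
        t_statistic = tt$t_statistic, p_value = tt$p_value,
        skipped = FALSE, skip_reason = NA_character_
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(gene_id, part_index)
  if (adjust) {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$significant <- !is.na(out$p_value) & out$p_value < p_max
  out
}

#' Splice-product ratios and retention index
#'
#' Summarizes a three-band splice assay (largest product retaining the
#' introns, middle and small spliced products) into the ratios of the large
#' product to each smaller one and a retention PSI, the large product's
#' share of all products.
#'
#' @param large,middle,small Non-negative product quantities (vectorized).
#' @return A tibble with `ratio_large_middle`, `ratio_large_small`,
#'   `retention_psi` and an `undefined` flag for all-zero inputs.
#' @examples
#' retention_index(100, 20, 5) # ratios 5 and 20, retention 0.8
#' @export
retention_index <- function(large, middle, small) {
  stopifnot(all(large >= 0), all(middle >= 0), all(small >= 0))
  total <- large + middle + small
  tibble::tibble(
    ratio_large_middle = ifelse(middle > 0, large / middle,
      ifelse(large > 0, Inf, NA_real_)
    ),
    ratio_large_small = ifelse(small > 0, large / small,
      ifelse(large > 0, Inf, NA_real_)
    ),
    retention_psi = ifelse(total > 0, large / total, NA_real_),
    undefined = total == 0
  )
}

#' Overlap of two differentially spliced gene sets
#'
#' @param set_a,set_b Character vectors of gene ids (e.g. genes spliced in
#'   disease vs. genes spliced after factor overexpression).
#' @return A list with `intersection`, `only_a`, `only_b` and a `counts`
#'   tibble.
#' @export
spliced_set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  both <- sort(intersect(set_a, set_b))
  list(
    intersection = both,
    only_a = sort(setdiff(set_a, set_b)),
    only_b = sort(setdiff(set_b, set_a)),
    counts = tibble::tibble(
      set = c("a", "b", "intersection", "only_a", "only_b"),
      n = c(
        length(set_a), length(set_b), length(both),
        length(setdiff(set_a, set_b)), length(setdiff(set_b, set_a))
      )
    )
  )
}
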