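#' Simulate a complete screen fixture with planted ground truth
#'
#' Bundles every input of the end-to-end screen into one object: a
#' multi-tissue expression matrix with one heart-enriched, disease-
#' regulated factor gene (plus enriched-but-unregulated decoys, the
#' pattern of constitutively heart-restricted splicing factors), a
#' two-condition gene count matrix, per-part and junction counts with a
#' set of genes spliced differentially in disease, one intron-retention
#' event with the largest planted PSI shift, and RIP libraries in which
#' exactly the differentially spliced genes are enriched — so the
#' bound-and-spliced intersection has a known answer.
#'
#' @param seed Integer seed governing all draws.
#' @param n_genes Genes in the expression screen (default 500).
#' @param n_case,n_ctrl Samples per condition (default 4 and 4).
#' @param factor_gene Identifier of the planted splicing factor.
#' @param factor_hss,factor_fc Planted heart-enrichment factor and
#'   disease fold change of the factor gene (defaults 8 and 2).
#' @param n_enriched_decoys Heart-enriched but unregulated genes
#'   (default 10).
#' @param n_spliced,n_splice_null Differentially spliced genes and
#'   unchanged genes in the splicing assay (defaults 25 and 15).
#' @param delta_psi Planted PSI shift of the spliced cassettes
#'   (default 0.3); the retained intron gets `retention_delta`
#'   (default 0.5).
#' @param retention_delta PSI shift of the intron-retention event.
#' @param splice_depth Expected informative reads per part per sample.
#' @param rip_factor Binding-enrichment factor of spliced genes in the
#'   case IP libraries (default 8).
#' @param n_ip_case,n_ip_ctrl RIP libraries per side (defaults 3 and 4).
#' @param gene_mean Expected count of an average gene in the DE matrix.
#' @return A named list (`expression`, `counts`, `samples`, `splice`,
#'   `rip`, `truth`) accepted by [run_screen()].
#' @export
simulate_screen_data <- function(seed = 1, n_genes = 500, n_case = 4,
                                 n_ctrl = 4, factor_gene = "gene_0001",
                                 factor_hss = 8, factor_fc = 2,
                                 n_enriched_decoys = 10, n_spliced = 25,
                                 n_splice_null = 15, delta_psi = 0.3,
                                 retention_delta = 0.5, splice_depth = 500,
                                 rip_factor = 8, n_ip_case = 3, n_ip_ctrl = 4,
                                 gene_mean = 200) {
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  stopifnot(factor_gene %in% genes)
  decoys <- setdiff(genes, factor_gene)[seq_len(n_enriched_decoys)]

  tissue <- simulate_tissue_matrix(
    n_genes,
    enriched = tibble::tibble(
      gene = c(factor_gene, decoys),
      factor = factor_hss,
      alt_factor = factor_hss
    ),
    noise_sd = 0.2, seed = seed
  )

  # two-condition gene counts: Poisson around a log-normal base mean,
  # library depths varied to exercise normalization, the factor gene
  # up-regulated in cases
  samples <- tibble::tibble(
    sample = c(sprintf("case_%d", seq_len(n_case)), sprintf("ctrl_%d", seq_len(n_ctrl))),
    condition = rep(c("case", "ctrl"), c(n_case, n_ctrl))
  )
  counts <- withr::with_seed(seed + 1L, {
    base <- exp(rnorm(n_genes, log(gene_mean), 0.6))
    depth <- runif(nrow(samples), 0.7, 1.3)
    mu <- outer(base, depth)
    mu[genes == factor_gene, samples$condition == "case"] <-
      mu[genes == factor_gene, samples$condition == "case"] * factor_fc
    m <- matrix(rpois(length(mu), mu), nrow = n_genes)
    colnames(m) <- samples$sample
    dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
  })

  # splicing assay over a subset of the gene universe; the last spliced
  # gene is built as an intron-retention cassette
  splice_genes <- setdiff(genes, c(factor_gene, decoys))
  splice_genes <- splice_genes[seq_len(n_spliced + n_splice_null)]
  spliced <- splice_genes[seq_len(n_spliced)]
  retention_gene <- spliced[n_spliced]
  annotation <- simulate_annotation(
    gene_ids = splice_genes,
    retention_genes = match(retention_gene, splice_genes)
  )
  parts <- flatten_annotation(annotation)
  alt <- parts[parts$is_alternative, c("gene_id", "part_id")]
  events <- tibble::tibble(
    part_id = alt$part_id[match(spliced, alt$gene_id)],
    psi_ctrl = ifelse(spliced == retention_gene, 0.3, 0.5),
    delta_psi = ifelse(spliced == retention_gene, retention_delta, delta_psi)
  )
  splice <- simulate_splice_counts(
    annotation = annotation, n_case = n_case, n_ctrl = n_ctrl,
    depth_per_event = splice_depth, events = events, seed = seed + 2L
  )

  # RIP libraries quantify the whole gene universe; enrichment is planted
  # for the differentially spliced genes, so the unchanged majority keeps
  # median-of-ratios normalization well-posed
  rip <- simulate_rip_counts(
    feature_ids = genes,
    bound = tibble::tibble(feature = spliced, factor = rip_factor),
    n_ip_case = n_ip_case, n_ip_ctrl = n_ip_ctrl,
    mean_count = 200, library_sizes = 1, seed = seed + 3L
  )

  list(
    expression = tissue$expression,
    counts = counts,
    samples = samples,
    splice = splice,
    rip = rip,
    truth = list(
      factor_gene = factor_gene, enriched_decoys = decoys,
      spliced_genes = spliced, retention_part = events$part_id[n_spliced],
      tissue = tissue$truth, splice = splice$truth, rip = rip$truth,
      seed = seed
    )
  )
}

#' Run the full splicing-factor screen
#'
#' Executes the screen end to end: heart-specificity scoring, size-factor
#' normalization and differential expression, candidate nomination
#' (enriched AND regulated), PSI quantification and delta-PSI testing,
#' RIP enrichment, the bound-and-spliced gene intersection, and an
#' along-gene correlation profile of the top candidate against the gene
#' with the strongest splicing shift.
#'
#' @param data A named list as produced by [simulate_screen_data()]:
#'   `expression` (genes x tissues), `counts` (genes x samples),
#'   `samples` (sample/condition), `splice` (list: `parts`,
#'   `part_counts`, `junctions`, `samples`, `read_length`) and `rip`
#'   (list: `counts`, `samples`).
#' @param heart Heart tissue label.
#' @param hss_min Heart-specificity threshold (default 3).
#' @param p_max Significance threshold shared by all stages (default 0.05).
#' @param psi_mode `"raw"` (event-level counts, default) or
#'   `"normalized"`.
#' @param epsilon HSS pseudocount.
#' @param correlate_gene Factor gene for the correlation profile
#'   (default: the top nominated candidate).
#' @return An object of class `cardio_screen`: a list of result tibbles
#'   (`hss`, `size_factors`, `de`, `candidates`, `psi`, `delta_psi`,
#'   `rip`, `bound_spliced`, `correlation`) plus the run `params`. Use
#'   [tidy()], [glance()], `autoplot()` or [write_screen_outputs()].
#' @export
run_screen <- function(data, heart = "heart_left_ventricle", hss_min = 3,
                       p_max = 0.05, psi_mode = c("raw", "normalized"),
                       epsilon = 0.01, correlate_gene = NULL) {
  psi_mode <- match.arg(psi_mode)
  required <- c("expression", "counts", "samples", "splice", "rip")
  missing_in <- setdiff(required, names(data))
  if (length(missing_in) > 0L) {
    stop("screen input lacks component(s): ",
      paste(missing_in, collapse = ", "),
      call. = FALSE
    )
  }

  hss_scores <- compute_hss(data$expression,
    heart = heart,
    epsilon = epsilon, threshold = hss_min
  )

  sf <- size_factors(data$counts)
  norm <- normalize_counts(data$counts, sf)
  case_ids <- data$samples$sample[data$samples$condition == "case"]
  ctrl_ids <- data$samples$sample[data$samples$condition == "ctrl"]
  de <- de_ttest(norm, case_ids, ctrl_ids, p_max = p_max)
  candidates <- nominate_candidates(hss_scores, de,
    hss_min = hss_min,
    p_max = p_max
  )
  if (!any(candidates$verdict)) {
    warning("no gene passes both the enrichment and regulation filters")
  }

  sp <- data$splice
  psi <- compute_psi(sp$parts, sp$junctions, sp$part_counts,
    read_length = sp$read_length, mode = psi_mode
  )
  sp_case <- sp$samples$sample[sp$samples$condition == "case"]
  sp_ctrl <- sp$samples$sample[sp$samples$condition == "ctrl"]
  dpsi <- delta_psi_test(psi, sp_case, sp_ctrl, p_max = p_max)

  rip_case <- data$rip$samples$sample[data$rip$samples$side == "case"]
  rip_ctrl <- data$rip$samples$sample[data$rip$samples$side == "ctrl"]
  rip <- rip_enrich(data$rip$counts, rip_case, rip_ctrl, p_max = p_max)
  bs <- bound_and_spliced(rip, dpsi, p_max = p_max, parts = sp$parts)

  # correlation profile: top candidate vs. the gene with the strongest
  # splicing shift
  correlation <- NULL
  factor_gene <- correlate_gene
  if (is.null(factor_gene) && any(candidates$verdict)) {
    factor_gene <- candidates$gene[candidates$verdict][1]
  }
  tested <- dpsi[!is.na(dpsi$delta_psi), , drop = FALSE]
  if (!is.null(factor_gene) && factor_gene %in% norm$gene &&
    nrow(tested) > 0L) {
    target_gene <- tested$gene_id[which.max(abs(tested$delta_psi))]
    shared <- intersect(
      unique(sp$part_counts$sample),
      setdiff(names(norm), "gene")
    )
    if (length(shared) >= 3L) {
      part_expr <- sp$part_counts |>
        dplyr::inner_join(
          sp$parts[sp$parts$gene_id == target_gene, c("part_id", "gene_id", "part_index")],
          by = "part_id"
        ) |>
        tidyr::pivot_wider(names_from = sample, values_from = count)
      factor_expr <- setNames(
        as.numeric(norm[norm$gene == factor_gene, shared]),
        shared
      )
      correlation <- exon_factor_correlation(part_expr, factor_expr)
      attr(correlation, "factor_gene") <- factor_gene
      attr(correlation, "target_gene") <- target_gene
    }
  }

  structure(
    list(
      hss = hss_scores, size_factors = sf, de = de,
      candidates = candidates, psi = psi, delta_psi = dpsi, rip = rip,
      bound_spliced = bs, correlation = correlation,
      params = list(
        heart = heart, hss_min = hss_min, p_max = p_max,
        psi_mode = psi_mode, epsilon = epsilon
      )
    ),
    class = "cardio_screen"
  )
}

#' @export
print.cardio_screen <- function(x, ...) {
  cand <- x$candidates[x$candidates$verdict, , drop = FALSE]
  cat("<cardio_screen>\n")
  cat(sprintf(
    "  %d genes scored for heart specificity (%d with HSS >= %g)\n",
    nrow(x$hss), sum(x$hss$passes_enrichment), x$params$hss_min
  ))
  cat(sprintf(
    "  %d genes tested for differential expression; %d candidates (%d up, %d down)\n",
    nrow(x$de), nrow(cand),
    sum(cand$direction == "up"), sum(cand$direction == "down")
  ))
  if (nrow(cand) > 0L) {
    cat(sprintf(
      "  top candidate: %s (HSS %.2f, fold change %.2f, P %.2g)\n",
      cand$gene[1], cand$hss[1], cand$fold_change[1], cand$p_value[1]
    ))
  }
  cat(sprintf(
    "  %d exonic parts tested for delta PSI; %d significant\n",
    sum(!x$delta_psi$skipped), sum(x$delta_psi$significant, na.rm = TRUE)
  ))
  cat(sprintf(
    "  %d bound-and-differentially-spliced genes\n",
    length(x$bound_spliced$genes)
  ))
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `cardio_screen` object.
#' @param ... Unused.
#' @return The candidate table (one row per gene: HSS, fold change, P
#'   value, screen flags) as a tibble.
#' @export
tidy.cardio_screen <- function(x, ...) {
  tibble::as_tibble(x$candidates)
}

#' One-row summary of a screen result
#'
#' @param x A `cardio_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with the headline counts of every stage.
#' @export
glance.cardio_screen <- function(x, ...) {
  cand <- x$candidates[x$candidates$verdict, , drop = FALSE]
  tibble::tibble(
    n_genes = nrow(x$hss),
    n_enriched = sum(x$hss$passes_enrichment),
    n_candidates = nrow(cand),
    top_candidate = if (nrow(cand) > 0L) cand$gene[1] else NA_character_,
    n_parts_tested = sum(!x$delta_psi$skipped),
    n_spliced_parts = sum(x$delta_psi$significant, na.rm = TRUE),
    n_bound = sum(x$rip$bound),
    n_bound_spliced = length(x$bound_spliced$genes)
  )
}

#' Write every screen result table to a directory
#'
#' Emits one TSV per stage, each with a commented provenance header
#' (package version, thresholds), plus a `manifest.tsv` of run
#' parameters.
#'
#' @param screen A `cardio_screen` object.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (the screen itself is
#'   deterministic given its inputs).
#' @return `dir`, invisibly.
#' @export
write_screen_outputs <- function(screen, dir, seed = NA) {
  stopifnot(inherits(screen, "cardio_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- c(screen$params, list(seed = seed))
  tabs <- list(
    hss = screen$hss, size_factors = screen$size_factors, de = screen$de,
    candidates = screen$candidates, psi = screen$psi,
    delta_psi = screen$delta_psi, rip = screen$rip,
    bound_spliced_counts = screen$bound_spliced$counts
  )
  if (!is.null(screen$bound_spliced$per_chromosome)) {
    tabs$bound_spliced_per_chromosome <- screen$bound_spliced$per_chromosome
  }
  tabs$bound_spliced_genes <- tibble::tibble(gene = screen$bound_spliced$genes)
  if (!is.null(screen$correlation)) {
    tabs$correlation <- screen$correlation
  }
  for (nm in names(tabs)) {
    write_result_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")), manifest)
  }
  write_result_tsv(
    tibble::tibble(
      key = names(manifest),
      value = vapply(manifest, function(v) paste(format(v), collapse = ","), character(1))
    ),
    file.path(dir, "manifest.tsv")
  )
  invisible(dir)
}
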