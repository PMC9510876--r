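#' A 53-tissue panel of labels
#'
#' Tissue labels emulating a GTEx-like multi-tissue panel: 53 tissues
#' including left ventricle (the heart reference) and atrial appendage
#' (the validation reference).
#'
#' @return A character vector of length 53.
#' @export
gtex_like_tissues <- function() {
  c(
    "heart_left_ventricle", "heart_atrial_appendage",
    "adipose_subcutaneous", "adipose_visceral", "adrenal_gland",
    "artery_aorta", "artery_coronary", "artery_tibial", "bladder",
    "brain_amygdala", "brain_cerebellum", "brain_cortex",
    "brain_hippocampus", "brain_hypothalamus", "brain_striatum",
    "brain_substantia_nigra", "breast", "cells_fibroblasts",
    "cells_lymphocytes", "cervix_ectocervix", "cervix_endocervix",
    "colon_sigmoid", "colon_transverse", "esophagus_gej",
    "esophagus_mucosa", "esophagus_muscularis", "fallopian_tube",
    "kidney_cortex", "liver", "lung", "minor_salivary_gland",
    "muscle_skeletal", "nerve_tibial", "ovary", "pancreas", "pituitary",
    "prostate", "skin_not_sun_exposed", "skin_sun_exposed",
    "small_intestine", "spleen", "stomach", "testis", "thyroid",
    "uterus", "vagina", "whole_blood", "brain_spinal_cord",
    "brain_frontal_cortex", "brain_anterior_cingulate",
    "brain_caudate", "brain_nucleus_accumbens", "brain_putamen"
  )
}

#' Simulate a multi-tissue expression matrix with planted heart enrichment
#'
#' Background expression of each gene is log-normal
#' (`exp(rnorm(baseline_log_mean, baseline_log_sd))`), shared across
#' tissues up to multiplicative log-normal noise of standard deviation
#' `noise_sd`. Genes listed in `enriched` have their heart value multiplied
#' by the given enrichment factor (and, optionally, the alternative heart
#' tissue by `alt_factor`), so their expected heart-specificity score
#' equals the factor under uniform background.
#'
#' @param n_genes Number of genes (ids `gene_0001`...).
#' @param tissues Tissue labels (default [gtex_like_tissues()]).
#' @param heart Heart label (must be one of `tissues`).
#' @param baseline_log_mean,baseline_log_sd Log-scale background
#'   parameters (defaults log(5) and 1, an RPKM-like spread).
#' @param enriched Tibble with columns `gene`, `factor` (> 1) and
#'   optionally `alt_factor`; `NULL` plants nothing.
#' @param alt_heart Label receiving `alt_factor` (default atrial
#'   appendage).
#' @param noise_sd Log-scale noise standard deviation (0 = noise-free).
#' @param seed Integer seed; identical configuration and seed reproduce
#'   the matrix exactly.
#' @return A list with `expression` (tibble: `gene` + tissue columns) and
#'   `truth` (list: `planted` tibble, `heart`, `seed`).
#' @export
simulate_tissue_matrix <- function(n_genes, tissues = gtex_like_tissues(),
                                   heart = "heart_left_ventricle",
                                   baseline_log_mean = log(5),
                                   baseline_log_sd = 1,
                                   enriched = NULL,
                                   alt_heart = "heart_atrial_appendage",
                                   noise_sd = 0.2, seed = 1) {
  stopifnot(n_genes >= 1, noise_sd >= 0, baseline_log_sd >= 0)
  if (sum(tissues == heart) != 1L) {
    stop("exactly one tissue must carry the heart label", call. = FALSE)
  }
  if (anyDuplicated(tissues)) stop("duplicate tissue labels", call. = FALSE)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  if (is.null(enriched)) {
    enriched <- tibble::tibble(gene = character(), factor = numeric())
  }
  if (anyDuplicated(enriched$gene)) {
    stop("duplicate gene ids in the planted set", call. = FALSE)
  }
  if (!all(enriched$gene %in% genes)) {
    stop("planted gene id outside gene_0001..gene_",
      sprintf("%04d", n_genes),
      call. = FALSE
    )
  }
  if (any(enriched$factor <= 0)) {
    stop("enrichment factors must be > 0", call. = FALSE)
  }
  withr::with_seed(seed, {
    baseline <- exp(rnorm(n_genes, baseline_log_mean, baseline_log_sd))
    x <- baseline * exp(matrix(
      rnorm(n_genes * length(tissues), 0, noise_sd),
      nrow = n_genes
    ))
    colnames(x) <- tissues
    idx <- match(enriched$gene, genes)
    x[idx, heart] <- x[idx, heart] * enriched$factor
    if ("alt_factor" %in% names(enriched) && alt_heart %in% tissues) {
      x[idx, alt_heart] <- x[idx, alt_heart] * enriched$alt_factor
    }
  })
  list(
    expression = dplyr::bind_cols(
      tibble::tibble(gene = genes),
      tibble::as_tibble(x)
    ),
    truth = list(planted = enriched, heart = heart, seed = seed)
  )
}

#' Simulate a multi-gene annotation of skipped-exon / retained-intron cassettes
#'
#' Each simulated gene carries three exons and two isoforms. For the
#' default `"cassette"` genes, one isoform includes the middle exon and
#' one skips it, so flattening yields an alternative middle part whose
#' exclusion evidence is the exon-skipping junction. For `"retention"`
#' genes, one isoform retains the first intron as exonic sequence, so the
#' intron itself becomes the alternative part and the spliced junction
#' coincides with it — the intron-retention geometry.
#'
#' @param n_genes Number of genes (one contig per gene).
#' @param retention_genes Indices into the gene list of genes built as
#'   intron-retention cassettes (default none).
#' @param gene_ids Optional explicit gene identifiers (default
#'   `gene_0001`...).
#' @param exon_width,intron_width Widths in bp (defaults 150 and 300).
#' @param strand Strand assigned to all genes.
#' @return An exon tibble suitable for [flatten_annotation()].
#' @export
simulate_annotation <- function(n_genes = length(gene_ids),
                                retention_genes = integer(0),
                                gene_ids = sprintf("gene_%04d", seq_len(n_genes)),
                                exon_width = 150, intron_width = 300,
                                strand = "+") {
  purrr::map(seq_len(n_genes), function(i) {
    g <- gene_ids[i]
    e1 <- c(0, exon_width)
    e2 <- e1[2] + intron_width + c(0, exon_width)
    e3 <- e2[2] + intron_width + c(0, exon_width)
    contig <- paste0("chr_", g)
    if (i %in% retention_genes) {
      # isoform A splices the first intron out; isoform B retains it
      tibble::tibble(
        gene_id = g,
        transcript_id = c(rep(paste0(g, ":tA"), 3), rep(paste0(g, ":tB"), 2)),
        contig = contig, strand = strand,
        start = c(e1[1], e2[1], e3[1], e1[1], e3[1]),
        end = c(e1[2], e2[2], e3[2], e2[2], e3[2])
      )
    } else {
      tibble::tibble(
        gene_id = g,
        transcript_id = c(rep(paste0(g, ":tA"), 3), rep(paste0(g, ":tB"), 2)),
        contig = contig, strand = strand,
        start = c(e1[1], e2[1], e3[1], e1[1], e3[1]),
        end = c(e1[2], e2[2], e3[2], e1[2], e3[2])
      )
    }
  }) |> purrr::list_rbind()
}

#' Simulate exonic-part and junction counts with planted splicing changes
#'
#' Generates per-sample counting evidence for the alternative part of each
#' simulated gene: the number of informative reads is Poisson
#' (`depth_per_event`), split binomially into inclusion reads (assigned to
#' the part) and exclusion reads (assigned to the junction that removes
#' the part) according to the sample's PSI. Optional extra-binomial
#' variability (`dispersion`) draws each sample's PSI from a beta
#' distribution around the condition mean. Constitutive parts receive
#' Poisson coverage with no exclusion evidence.
#'
#' Planted events override the background PSI (drawn uniformly on
#' `background_psi`) with `psi_ctrl` in controls and
#' `psi_ctrl + delta_psi` in cases.
#'
#' @param annotation Exon tibble (default
#'   `simulate_annotation(n_genes, ...)`).
#' @param n_genes Used when `annotation` is `NULL`.
#' @param retention_genes Passed to [simulate_annotation()].
#' @param n_case,n_ctrl Samples per condition (ids `case_1`..., `ctrl_1`...).
#' @param depth_per_event Expected informative reads per part per sample.
#' @param events Tibble with columns `part_id`, `psi_ctrl`, `delta_psi`;
#'   part ids must exist after flattening and `psi_ctrl + delta_psi` must
#'   stay in `[0, 1]`.
#' @param background_psi Range (length 2) of control PSI for unplanted
#'   alternative parts.
#' @param dispersion Non-negative; 0 gives pure binomial sampling.
#' @param read_length Read length recorded for downstream normalization.
#' @param seed Integer seed.
#' @return A list: `annotation`, `parts` (flattened), `part_counts`
#'   (`part_id`, `sample`, `count`), `junctions` (with `sample` and
#'   `count`), `samples` (tibble: `sample`, `condition`), `read_length`
#'   and `truth` (list with the per-part PSI table and the seed).
#' @export
simulate_splice_counts <- function(annotation = NULL, n_genes = 20,
                                   retention_genes = integer(0),
                                   n_case = 4, n_ctrl = 4,
                                   depth_per_event = 100, events = NULL,
                                   background_psi = c(0.2, 0.9),
                                   dispersion = 0, read_length = 100,
                                   seed = 1) {
  stopifnot(depth_per_event > 0, n_case >= 1, n_ctrl >= 1, dispersion >= 0)
  if (is.null(annotation)) {
    annotation <- simulate_annotation(n_genes, retention_genes = retention_genes)
  }
  parts <- flatten_annotation(annotation)
  alt <- parts[parts$is_alternative, , drop = FALSE]
  if (is.null(events)) {
    events <- tibble::tibble(
      part_id = character(), psi_ctrl = numeric(), delta_psi = numeric()
    )
  }
  bad <- setdiff(events$part_id, alt$part_id)
  if (length(bad) > 0L) {
    stop("planted part id(s) not derivable from the annotation: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(events$psi_ctrl < 0 | events$psi_ctrl > 1 |
    events$psi_ctrl + events$delta_psi < 0 |
    events$psi_ctrl + events$delta_psi > 1)) {
    stop("psi_ctrl and psi_ctrl + delta_psi must lie in [0, 1]",
      call. = FALSE
    )
  }
  samples <- tibble::tibble(
    sample = c(sprintf("case_%d", seq_len(n_case)), sprintf("ctrl_%d", seq_len(n_ctrl))),
    condition = rep(c("case", "ctrl"), c(n_case, n_ctrl))
  )
  withr::with_seed(seed, {
    psi_tab <- alt |>
      dplyr::select(part_id, gene_id, contig, start, end) |>
      dplyr::mutate(
        psi_ctrl = runif(dplyr::n(), background_psi[1], background_psi[2]),
        delta_psi = 0
      )
    m <- match(events$part_id, psi_tab$part_id)
    psi_tab$psi_ctrl[m] <- events$psi_ctrl
    psi_tab$delta_psi[m] <- events$delta_psi
    psi_tab$psi_case <- psi_tab$psi_ctrl + psi_tab$delta_psi

    # the junction that removes each alternative part spans from the end of
    # the preceding part to the start of the following part (cassette), or
    # the part's own boundaries (retained intron)
    exclusion_intron <- purrr::pmap(psi_tab, function(part_id, gene_id, ...) {
      p <- parts[parts$gene_id == gene_id, , drop = FALSE]
      i <- which(p$part_id == part_id)
      if (i > 1L && i < nrow(p)) {
        c(p$end[i - 1L], p$start[i + 1L])
      } else {
        c(p$start[i], p$end[i]) # retained intron abutting its neighbours
      }
    })
    # retained-intron parts abut their neighbours: the spliced junction is
    # the part itself
    ir <- purrr::map_lgl(seq_len(nrow(psi_tab)), function(k) {
      p <- parts[parts$gene_id == psi_tab$gene_id[k], , drop = FALSE]
      i <- which(p$part_id == psi_tab$part_id[k])
      i > 1L && i < nrow(p) &&
        p$end[i - 1L] == p$start[i] && p$start[i + 1L] == p$end[i]
    })
    exclusion_intron[ir] <- purrr::map(which(ir), function(k) {
      c(psi_tab$start[k], psi_tab$end[k])
    })

    draws <- tidyr::expand_grid(
      k = seq_len(nrow(psi_tab)),
      sample = samples$sample
    ) |>
      dplyr::mutate(
        condition = samples$condition[match(sample, samples$sample)],
        part_id = psi_tab$part_id[k],
        psi_true = dplyr::if_else(condition == "case",
          psi_tab$psi_case[k], psi_tab$psi_ctrl[k]
        ),
        n_informative = rpois(dplyr::n(), depth_per_event)
      )
    psi_draw <- if (dispersion > 0) {
      conc <- 1 / dispersion
      p <- draws$psi_true
      ifelse(p %in% c(0, 1), p, rbeta(nrow(draws), p * conc, (1 - p) * conc))
    } else {
      draws$psi_true
    }
    draws$inclusion <- rbinom(nrow(draws), draws$n_informative, psi_draw)
    draws$exclusion <- draws$n_informative - draws$inclusion

    const <- parts[!parts$is_alternative, , drop = FALSE]
    const_counts <- tidyr::expand_grid(
      part_id = const$part_id, sample = samples$sample
    ) |>
      dplyr::mutate(count = rpois(dplyr::n(), depth_per_event))
  })
  part_counts <- dplyr::bind_rows(
    dplyr::select(draws, part_id, sample, count = inclusion),
    const_counts
  ) |> dplyr::arrange(part_id, sample)
  junctions <- draws |>
    dplyr::mutate(
      contig = psi_tab$contig[k],
      start = purrr::map_int(k, ~ as.integer(exclusion_intron[[.x]][1])),
      end = purrr::map_int(k, ~ as.integer(exclusion_intron[[.x]][2])),
      strand = "+"
    ) |>
    dplyr::select(contig, start, end, strand, sample, count = exclusion)
  list(
    annotation = annotation,
    parts = parts,
    part_counts = part_counts,
    junctions = junctions,
    samples = samples,
    read_length = read_length,
    truth = list(
      events = dplyr::select(
        psi_tab, part_id, gene_id, psi_ctrl, psi_case, delta_psi
      ),
      seed = seed
    )
  )
}

#' Simulate RIP pull-down counts with planted binding enrichment
#'
#' Each feature's base abundance is log-normal; library counts are Poisson
#' with mean `library size x abundance`, and bound features have the
#' case-IP mean multiplied by their enrichment factor. Unbound features
#' are equal in expectation on both sides.
#'
#' @param n_features Number of features (ids `feat_0001`...).
#' @param bound Tibble with columns `feature` and `factor` (> 0); `NULL`
#'   plants nothing.
#' @param n_ip_case,n_ip_ctrl Libraries per side (>= 2 for testing).
#' @param library_sizes Positive relative depths, one per library
#'   (case libraries first; recycled scalar allowed).
#' @param mean_count Expected count of an average feature at depth 1.
#' @param abundance_log_sd Log-scale spread of feature abundances.
#' @param seed Integer seed.
#' @param feature_ids Optional explicit feature identifiers (default
#'   `feat_0001`...).
#' @return A list with `counts` (tibble: `feature`, `gene`, one column per
#'   library), `samples` (tibble: `sample`, `side`) and `truth`.
#' @export
simulate_rip_counts <- function(n_features = length(feature_ids), bound = NULL,
                                n_ip_case = 3, n_ip_ctrl = 4,
                                library_sizes = 1, mean_count = 100,
                                abundance_log_sd = 0.5, seed = 1,
                                feature_ids = sprintf("feat_%04d", seq_len(n_features))) {
  if (missing(feature_ids) && missing(n_features)) n_features <- 200
  stopifnot(n_features >= 1, mean_count > 0)
  n_lib <- n_ip_case + n_ip_ctrl
  library_sizes <- rep_len(library_sizes, n_lib)
  if (any(library_sizes <= 0)) {
    stop("library sizes must be > 0", call. = FALSE)
  }
  feats <- feature_ids
  if (is.null(bound)) {
    bound <- tibble::tibble(feature = character(), factor = numeric())
  }
  if (!all(bound$feature %in% feats)) {
    stop("planted feature id outside the feature set", call. = FALSE)
  }
  if (any(bound$factor <= 0)) {
    stop("enrichment factors must be > 0", call. = FALSE)
  }
  libs <- c(
    sprintf("ip_case_%d", seq_len(n_ip_case)),
    sprintf("ip_ctrl_%d", seq_len(n_ip_ctrl))
  )
  side <- rep(c("case", "ctrl"), c(n_ip_case, n_ip_ctrl))
  withr::with_seed(seed, {
    abundance <- exp(rnorm(n_features, 0, abundance_log_sd))
    enr <- rep(1, n_features)
    enr[match(bound$feature, feats)] <- bound$factor
    mu <- outer(abundance * mean_count, library_sizes)
    mu[, side == "case"] <- mu[, side == "case"] * enr
    counts <- matrix(rpois(length(mu), mu), nrow = n_features)
  })
  colnames(counts) <- libs
  list(
    counts = dplyr::bind_cols(
      tibble::tibble(feature = feats, gene = feats),
      tibble::as_tibble(counts)
    ),
    samples = tibble::tibble(sample = libs, side = side),
    truth = list(planted = bound, seed = seed)
  )
}

#' Simulate a sequence with UWAA motifs planted at known positions
#'
#' The background is drawn uniformly over A/C/G/U and then cleaned by
#' rejection: any accidental UWAA occurrence outside the planted positions
#' has one of its background bases replaced by C or G (which cannot occur
#' in a match), so the scan recovers exactly the planted positions.
#'
#' @param length Sequence length (>= 4 when motifs are planted).
#' @param planted_positions 0-based start positions, pairwise at least 4
#'   apart and within bounds.
#' @param seed Integer seed.
#' @param w Middle base of each planted motif: `"A"`, `"U"` or `"random"`.
#' @return A list with `sequence` (RNA alphabet) and `truth` (positions,
#'   motifs, seed).
#' @export
simulate_motif_sequence <- function(length, planted_positions = integer(0),
                                    seed = 1, w = "random") {
  planted_positions <- sort(as.integer(planted_positions))
  if (any(planted_positions < 0 | planted_positions + 4 > length)) {
    stop("planted position out of bounds", call. = FALSE)
  }
  if (any(diff(planted_positions) < 4)) {
    stop("planted positions overlap (must be >= 4 apart)", call. = FALSE)
  }
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
    motif_pos <- unlist(lapply(planted_positions, function(p) p + 1:4))
    motifs <- vapply(planted_positions, function(p) {
      mid <- switch(w,
        random = sample(c("A", "U"), 1),
        w
      )
      paste0("U", mid, "AA")
    }, character(1))
    for (i in seq_along(planted_positions)) {
      chars[planted_positions[i] + 1:4] <- strsplit(motifs[i], "")[[1]]
    }
    repeat {
      hits <- scan_uwaa(paste(chars, collapse = ""))$position
      stray <- setdiff(hits, planted_positions)
      if (length(stray) == 0L) break
      for (p in stray) {
        window <- p + 1:4
        bg <- setdiff(window, motif_pos)
        # a stray hit always touches a background base (planted motifs are
        # >= 4 apart, so no window is fully planted)
        chars[bg[1]] <- sample(c("C", "G"), 1)
      }
    }
  })
  list(
    sequence = paste(chars, collapse = ""),
    truth = list(positions = planted_positions, motifs = motifs, seed = seed)
  )
}
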