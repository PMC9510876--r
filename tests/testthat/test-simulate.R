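test_that("noise-free tissue simulation is exact", {
  sim <- simulate_tissue_matrix(
    3,
    tissues = c("heart_left_ventricle", "t1", "t2"),
    baseline_log_mean = 0, baseline_log_sd = 0,
    enriched = tibble::tibble(gene = "gene_0002", factor = 10),
    noise_sd = 0, seed = 1
  )
  m <- sim$expression
  expect_equal(m$heart_left_ventricle, c(1, 10, 1))
  expect_equal(m$t1, c(1, 1, 1))
  expect_equal(m$t2, c(1, 1, 1))
  expect_equal(sim$truth$planted$gene, "gene_0002")
})

test_that("every generator is reproducible from its seed", {
  expect_identical(
    simulate_tissue_matrix(30, seed = 5)$expression,
    simulate_tissue_matrix(30, seed = 5)$expression
  )
  a <- simulate_splice_counts(n_genes = 4, seed = 5)
  b <- simulate_splice_counts(n_genes = 4, seed = 5)
  expect_identical(a$part_counts, b$part_counts)
  expect_identical(a$junctions, b$junctions)
  expect_false(identical(
    a$part_counts,
    simulate_splice_counts(n_genes = 4, seed = 6)$part_counts
  ))
})

test_that("tissue simulation validates its configuration", {
  expect_error(
    simulate_tissue_matrix(5, tissues = c("a", "b")),
    "heart label"
  )
  expect_error(
    simulate_tissue_matrix(
      5,
      enriched = tibble::tibble(gene = c("gene_0001", "gene_0001"), factor = 2)
    ),
    "duplicate"
  )
  expect_error(
    simulate_tissue_matrix(
      5,
      enriched = tibble::tibble(gene = "gene_0009", factor = 2)
    ),
    "outside"
  )
  expect_error(
    simulate_tissue_matrix(
      5,
      enriched = tibble::tibble(gene = "gene_0001", factor = -1)
    ),
    "> 0"
  )
  expect_length(gtex_like_tissues(), 53)
})

test_that("splice counts conserve informative reads between inclusion and exclusion", {
  sim <- simulate_splice_counts(
    n_genes = 3, depth_per_event = 50,
    events = tibble::tibble(
      part_id = "gene_0001:002", psi_ctrl = 1, delta_psi = 0
    ),
    seed = 7
  )
  # psi = 1 means no exclusion reads at the planted part in any sample
  j <- sim$junctions |>
    dplyr::filter(contig == "chr_gene_0001")
  expect_true(all(j$count == 0))
  # inclusion + exclusion totals are Poisson around the configured depth
  inc <- sim$part_counts |>
    dplyr::filter(part_id == "gene_0002:002") |>
    dplyr::arrange(sample)
  exc <- sim$junctions |>
    dplyr::filter(contig == "chr_gene_0002") |>
    dplyr::arrange(sample)
  totals <- inc$count + exc$count
  expect_gt(mean(totals), 35)
  expect_lt(mean(totals), 65)
})

test_that("planted splice events appear in both data and truth", {
  ev <- tibble::tibble(
    part_id = c("gene_0001:002", "gene_0002:002"),
    psi_ctrl = c(0.5, 0.2), delta_psi = c(0.3, 0)
  )
  sim <- simulate_splice_counts(n_genes = 4, events = ev, seed = 9)
  expect_true(all(ev$part_id %in% sim$truth$events$part_id))
  expect_true(all(ev$part_id %in% sim$part_counts$part_id))
  tr <- sim$truth$events[match(ev$part_id, sim$truth$events$part_id), ]
  expect_equal(tr$psi_ctrl, ev$psi_ctrl)
  expect_equal(tr$delta_psi, ev$delta_psi)

  expect_error(
    simulate_splice_counts(
      n_genes = 2,
      events = tibble::tibble(part_id = "nope:001", psi_ctrl = 0.5, delta_psi = 0)
    ),
    "not derivable"
  )
  expect_error(
    simulate_splice_counts(
      n_genes = 2,
      events = tibble::tibble(part_id = "gene_0001:002", psi_ctrl = 0.9, delta_psi = 0.3)
    ),
    "\\[0, 1\\]"
  )
})

test_that("retention cassettes make the intron an alternative part", {
  ann <- simulate_annotation(n_genes = 2, retention_genes = 2)
  parts <- flatten_annotation(ann)
  ir <- parts[parts$gene_id == "gene_0002", ]
  # the retained intron abuts its flanking parts
  expect_equal(ir$start[2], ir$end[1])
  expect_equal(ir$end[2], ir$start[3])
  expect_true(ir$is_alternative[2])
  # and its spliced junction coincides with the part, counting as exclusion
  sim <- simulate_splice_counts(
    annotation = ann,
    events = tibble::tibble(
      part_id = ir$part_id[2], psi_ctrl = 0.3, delta_psi = 0.4
    ),
    depth_per_event = 2000, seed = 3
  )
  psi <- compute_psi(sim$parts, sim$junctions, sim$part_counts, mode = "raw")
  got <- psi |>
    dplyr::filter(part_id == ir$part_id[2], sample == "case_1")
  expect_equal(got$psi, 0.7, tolerance = 0.1)
})

test_that("null RIP features are unenriched and planted ones recorded", {
  sim <- simulate_rip_counts(n_features = 400, mean_count = 300, seed = 15)
  r <- rip_enrich(
    sim$counts,
    sim$samples$sample[sim$samples$side == "case"],
    sim$samples$sample[sim$samples$side == "ctrl"]
  )
  expect_equal(median(r$fold_change), 1, tolerance = 0.05)
  expect_equal(nrow(sim$truth$planted), 0)

  planted <- simulate_rip_counts(
    n_features = 10,
    bound = tibble::tibble(feature = "feat_0004", factor = 6), seed = 15
  )
  expect_equal(planted$truth$planted$feature, "feat_0004")
  expect_true("feat_0004" %in% planted$counts$feature)
  expect_error(
    simulate_rip_counts(n_features = 5, library_sizes = 0),
    "> 0"
  )
})
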