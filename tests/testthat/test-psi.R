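write_lines <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("junction dialects are converted to 0-based half-open introns", {
  bed <- write_lines("chr2\t100\t200\tJ1\t15\t+", ".bed")
  j <- read_junctions(bed, "bed", sample = "s1")
  expect_equal(j$start, 100L)
  expect_equal(j$end, 200L)
  expect_equal(j$count, 15L)
  expect_equal(j$strand, "+")

  sj <- write_lines("chr2\t101\t200\t1\t1\t1\t15\t0\t50", ".tab")
  k <- read_junctions(sj, "sj", sample = "s1")
  expect_equal(k[c("contig", "start", "end", "strand", "count")],
    j[c("contig", "start", "end", "strand", "count")],
    ignore_attr = TRUE
  )
  # strand code 0 is unstranded, 2 is minus
  expect_equal(
    read_junctions(write_lines("chr1\t11\t20\t0\t0\t0\t3\t0\t10", ".tab"), "sj")$strand,
    "*"
  )
  expect_equal(
    read_junctions(write_lines("chr1\t11\t20\t2\t0\t0\t3\t0\t10", ".tab"), "sj")$strand,
    "-"
  )

  empty <- write_lines(character(0), ".bed")
  expect_equal(nrow(read_junctions(empty, "bed")), 0)
  expect_error(
    read_junctions(write_lines("chr1\t200\t100\tJ\t5\t+", ".bed"), "bed"),
    "start >= end"
  )
})

test_that("junction round trip is lossless in both dialects", {
  sim <- simulate_splice_counts(n_genes = 3, seed = 5)
  j <- sim$junctions[sim$junctions$sample == "case_1", ]
  for (dialect in c("bed", "sj")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_junctions(j, path, dialect)
    back <- read_junctions(path, dialect, sample = "case_1")
    expect_equal(
      back[c("contig", "start", "end", "strand", "sample", "count")],
      j[c("contig", "start", "end", "strand", "sample", "count")],
      ignore_attr = TRUE
    )
  }
})

simple_part <- function(len = 100) {
  tibble::tibble(
    gene_id = "g", part_id = "g:001", part_index = 1L, contig = "chr1",
    start = 1000L, end = 1000L + len, strand = "+",
    transcripts = "t1", n_transcripts = 1L, is_alternative = TRUE
  )
}

test_that("PSI is inclusion over total evidence", {
  parts <- simple_part()
  junc <- tibble::tibble(
    contig = "chr1", start = 900L, end = 1200L, strand = "+",
    sample = "s1", count = 10L
  )
  cov <- tibble::tibble(part_id = "g:001", sample = "s1", count = 30L)
  raw <- compute_psi(parts, junc, cov, mode = "raw")
  expect_equal(raw$psi, 0.75)
  expect_equal(raw$inclusion, 30)
  expect_equal(raw$exclusion, 10)

  no_exc <- compute_psi(parts, junc[0, ], cov, mode = "raw")
  expect_equal(no_exc$psi, 1)

  no_any <- compute_psi(parts, junc[0, ], cov[0, ], mode = "raw")
  expect_equal(nrow(no_any), 0)
})

test_that("length normalization uses the stated placement counts", {
  parts <- simple_part(len = 100)
  junc <- tibble::tibble(
    contig = "chr1", start = 900L, end = 1200L, strand = "+",
    sample = "s1", count = 49L
  )
  cov <- tibble::tibble(part_id = "g:001", sample = "s1", count = 149L)
  psi <- compute_psi(parts, junc, cov, read_length = 50, mode = "normalized")
  expect_equal(psi$inc_norm, 1) # 149 / (100 + 50 - 1)
  expect_equal(psi$exc_norm, 1) # 49 / (50 - 1)
  expect_equal(psi$psi, 0.5)
  expect_error(
    compute_psi(parts, junc, cov, read_length = 1, mode = "normalized"),
    "read_length"
  )
})

test_that("junction evidence is classified by interval arithmetic", {
  parts <- simple_part() # [1000, 1100)
  junc <- tibble::tibble(
    contig = "chr1",
    start = c(900L, 1000L, 900L, 1100L, 950L),
    end = c(1200L, 1100L, 1000L, 1300L, 1050L),
    strand = "+", sample = "s1",
    count = c(7L, 11L, 13L, 17L, 19L)
  )
  cov <- tibble::tibble(part_id = "g:001", sample = "s1", count = 0L)
  got <- compute_psi(parts, junc, cov, mode = "raw")
  # containing [900,1200) and coinciding [1000,1100) exclude; abutting
  # [900,1000) and [1100,1300) include; the straddling [950,1050) is neither
  expect_equal(got$exclusion, 7 + 11)
  expect_equal(got$inclusion, 13 + 17)

  # independent brute-force classification of the same records
  brute_exc <- sum(junc$count[junc$start <= 1000 & junc$end >= 1100])
  brute_inc <- sum(junc$count[junc$end == 1000 | junc$start == 1100])
  expect_equal(got$exclusion, brute_exc)
  expect_equal(got$inclusion, brute_inc)

  off <- dplyr::mutate(junc, contig = "chrX")
  expect_warning(compute_psi(parts, off, cov, mode = "raw"), "skipped")
})

test_that("PSI is bounded and monotone in the evidence", {
  parts <- simple_part()
  withr::with_seed(31, {
    for (i in 1:25) {
      inc <- rpois(1, 50)
      exc <- rpois(1, 50)
      cov <- tibble::tibble(part_id = "g:001", sample = "s1", count = inc)
      junc <- tibble::tibble(
        contig = "chr1", start = 900L, end = 1200L, strand = "+",
        sample = "s1", count = exc
      )
      p0 <- compute_psi(parts, junc, cov, mode = "raw")$psi
      if (!is.na(p0)) {
        expect_gte(p0, 0)
        expect_lte(p0, 1)
      }
      p_more_exc <- compute_psi(
        parts, dplyr::mutate(junc, count = count + 5L), cov,
        mode = "raw"
      )$psi
      p_more_inc <- compute_psi(
        parts, junc, dplyr::mutate(cov, count = count + 5L),
        mode = "raw"
      )$psi
      expect_lte(p_more_exc, max(p0, 0, na.rm = TRUE) + 1e-12)
      expect_gte(p_more_inc, min(p0, 1, na.rm = TRUE) - 1e-12)
    }
  })
})

test_that("PSI is unchanged by a consistent strand flip", {
  sim_p <- simulate_splice_counts(n_genes = 4, seed = 12)
  ann_m <- simulate_annotation(n_genes = 4, strand = "-")
  sim_m <- simulate_splice_counts(annotation = ann_m, seed = 12)
  psi_p <- compute_psi(sim_p$parts, sim_p$junctions, sim_p$part_counts, mode = "raw")
  psi_m <- compute_psi(
    sim_m$parts, dplyr::mutate(sim_m$junctions, strand = "-"),
    sim_m$part_counts,
    mode = "raw"
  )
  expect_equal(psi_m$psi, psi_p$psi)
})

test_that("pooled PSI recovers the planted inclusion level", {
  sim <- simulate_splice_counts(
    n_genes = 2, depth_per_event = 10000,
    events = tibble::tibble(
      part_id = "gene_0001:002", psi_ctrl = 0.5, delta_psi = 0
    ),
    seed = 19
  )
  psi <- compute_psi(sim$parts, sim$junctions, sim$part_counts, mode = "raw")
  pooled <- psi |>
    dplyr::filter(part_id == "gene_0001:002") |>
    dplyr::summarise(psi = sum(inclusion) / sum(inclusion + exclusion))
  expect_equal(pooled$psi, 0.5, tolerance = 0.04) # binomial SE ~ 0.005
})

test_that("delta-PSI testing flags planted events and skips sparse parts", {
  sim <- simulate_splice_counts(
    n_genes = 6, depth_per_event = 1000,
    events = tibble::tibble(
      part_id = "gene_0002:002", psi_ctrl = 0.4, delta_psi = 0.3
    ),
    seed = 29
  )
  psi <- compute_psi(sim$parts, sim$junctions, sim$part_counts, mode = "raw")
  case_ids <- sim$samples$sample[sim$samples$condition == "case"]
  ctrl_ids <- sim$samples$sample[sim$samples$condition == "ctrl"]
  dpsi <- delta_psi_test(psi, case_ids, ctrl_ids)
  hit <- dpsi[dpsi$part_id == "gene_0002:002", ]
  expect_lt(hit$p_value, 0.05)
  expect_equal(hit$delta_psi, 0.3, tolerance = 0.15)
  # results are sorted by gene then part
  expect_equal(dpsi$gene_id, sort(dpsi$gene_id))

  # identical PSI vectors: no change, P = 1
  flat <- tidyr::expand_grid(
    part_id = "g:001", gene_id = "g", part_index = 1L,
    sample = c(case_ids, ctrl_ids)
  ) |>
    dplyr::mutate(
      inclusion = 5, exclusion = 5, inc_norm = 5, exc_norm = 5,
      psi = rep(c(0.2, 0.5, 0.9, 0.4), 2)
    )
  d0 <- delta_psi_test(flat, case_ids, ctrl_ids)
  expect_equal(d0$delta_psi, 0)
  expect_equal(d0$p_value, 1)

  # undefined PSI values push a part below the defined minimum
  sparse <- dplyr::mutate(flat, psi = ifelse(sample == "case_1", NA, psi))
  ds <- delta_psi_test(sparse, case_ids, ctrl_ids)
  expect_true(ds$skipped)
  ds2 <- delta_psi_test(sparse, case_ids, ctrl_ids, min_defined = 2)
  expect_false(ds2$skipped)
})

test_that("splice ratios and the retention index follow their definitions", {
  r <- retention_index(c(50, 0, 100, 0), c(25, 10, 20, 0), c(25, 10, 5, 0))
  expect_equal(r$ratio_large_middle, c(2, 0, 5, NA))
  expect_equal(r$ratio_large_small, c(2, 0, 20, NA))
  expect_equal(r$retention_psi, c(0.5, 0, 0.8, NA))
  expect_equal(r$undefined, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("spliced-set overlap is plain set algebra", {
  ov <- spliced_set_overlap(c("TTN", "MYL2", "TPM1"), c("TTN", "RYR2"))
  expect_equal(ov$intersection, "TTN")
  expect_setequal(ov$only_a, c("MYL2", "TPM1"))
  expect_equal(ov$only_b, "RYR2")
  expect_equal(ov$counts$n[ov$counts$set == "intersection"], 1)
  same <- spliced_set_overlap(c("a", "b"), c("b", "a"))
  expect_setequal(same$intersection, c("a", "b"))
  expect_equal(spliced_set_overlap("a", "b")$intersection, character(0))
})
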