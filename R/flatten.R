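#' Flatten transcript models into disjoint exonic parts
#'
#' Overlapping transcripts of a gene are segmented into maximal intervals
#' supported by a constant set of transcripts ("exonic parts"), the counting
#' bin used by exon-level splicing analyses. Boundaries are placed at every
#' exon start and end of every transcript; adjacent intervals are merged only
#' when they are contiguous and carry an identical supporting-transcript set.
#'
#' A part is flagged alternative when its supporting set is a proper subset
#' of the gene's transcripts, i.e. at least one isoform skips it.
#'
#' @param exons A data frame of exons with columns `gene_id`,
#'   `transcript_id`, `contig`, `strand`, `start`, `end`. Coordinates are
#'   0-based half-open (as returned by [read_gtf()]).
#' @return A tibble of exonic parts with columns `gene_id`, `part_id`
#'   (`gene:NNN`, zero-padded, ascending along the genome), `part_index`,
#'   `contig`, `start`, `end`, `strand`, `transcripts` (supporting ids
#'   joined with `+`), `n_transcripts` and `is_alternative`.
#' @examples
#' ex <- tibble::tibble(
#'   gene_id = "g1", transcript_id = c("t1", "t1", "t2", "t2"),
#'   contig = "chr1", strand = "+",
#'   start = c(0, 200, 0, 250), end = c(100, 300, 100, 300)
#' )
#' flatten_annotation(ex)
#' @export
flatten_annotation <- function(exons) {
  exons <- validate_exons(exons)
  exons |>
    dplyr::group_by(gene_id) |>
    dplyr::group_split() |>
    purrr::map(flatten_gene) |>
    purrr::list_rbind() |>
    dplyr::arrange(contig, start)
}

#' Flatten the transcripts of a single gene
#'
#' @param exons Exon data frame for one gene (see [flatten_annotation()]).
#' @return A tibble of exonic parts for that gene.
#' @export
flatten_gene <- function(exons) {
  exons <- validate_exons(exons)
  if (dplyr::n_distinct(exons$gene_id) != 1L) {
    stop("flatten_gene() expects exons of exactly one gene", call. = FALSE)
  }
  if (dplyr::n_distinct(exons$contig) != 1L) {
    stop("gene '", exons$gene_id[1], "' spans multiple contigs", call. = FALSE)
  }
  if (dplyr::n_distinct(exons$strand) != 1L) {
    stop("gene '", exons$gene_id[1], "' mixes strands", call. = FALSE)
  }
  gene <- exons$gene_id[1]
  all_tx <- sort(unique(exons$transcript_id))

  # boundary sweep: every exon start/end is a candidate breakpoint
  bp <- sort(unique(c(exons$start, exons$end)))
  seg_start <- bp[-length(bp)]
  seg_end <- bp[-1]

  support <- purrr::map2(seg_start, seg_end, function(s, e) {
    sort(unique(exons$transcript_id[exons$start <= s & exons$end >= e]))
  })
  keep <- lengths(support) > 0L
  seg_start <- seg_start[keep]
  seg_end <- seg_end[keep]
  support <- support[keep]
  if (length(seg_start) == 0L) {
    return(empty_parts())
  }

  # merge maximal runs: contiguous segments with identical support
  sup_key <- purrr::map_chr(support, paste, collapse = "+")
  new_run <- c(TRUE, sup_key[-1] != sup_key[-length(sup_key)] |
    seg_start[-1] != seg_end[-length(seg_end)])
  run_id <- cumsum(new_run)

  parts <- tibble::tibble(
    start = as.integer(tapply(seg_start, run_id, min)),
    end = as.integer(tapply(seg_end, run_id, max)),
    transcripts = as.character(tapply(sup_key, run_id, function(x) x[1]))
  )
  parts |>
    dplyr::filter(end > start) |>
    dplyr::arrange(start) |>
    dplyr::mutate(
      gene_id = gene,
      part_index = dplyr::row_number(),
      part_id = sprintf("%s:%03d", gene, part_index),
      contig = exons$contig[1],
      strand = exons$strand[1],
      n_transcripts = lengths(strsplit(transcripts, "+", fixed = TRUE)),
      is_alternative = n_transcripts < length(all_tx)
    ) |>
    dplyr::select(
      gene_id, part_id, part_index, contig, start, end, strand,
      transcripts, n_transcripts, is_alternative
    )
}

empty_parts <- function() {
  tibble::tibble(
    gene_id = character(), part_id = character(), part_index = integer(),
    contig = character(), start = integer(), end = integer(),
    strand = character(), transcripts = character(),
    n_transcripts = integer(), is_alternative = logical()
  )
}

validate_exons <- function(exons) {
  required <- c("gene_id", "transcript_id", "contig", "strand", "start", "end")
  missing <- setdiff(required, names(exons))
  if (length(missing) > 0L) {
    stop("exon table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(exons$end <= exons$start)) {
    stop("exon with end <= start (0-based half-open coordinates expected)",
      call. = FALSE
    )
  }
  bad <- !exons$strand %in% c("+", "-", "*")
  if (any(bad)) {
    stop("unknown strand symbol '", exons$strand[which(bad)[1]], "'",
      call. = FALSE
    )
  }
  ov <- exons |>
    dplyr::group_by(transcript_id) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = dplyr::n() > 1 && any(start[-1] < end[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(ov$overlap)) {
    stop("transcript '", ov$transcript_id[which(ov$overlap)[1]],
      "' has overlapping exons",
      call. = FALSE
    )
  }
  tibble::as_tibble(exons) |> dplyr::arrange(gene_id, transcript_id, start)
}
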