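#' Read exon models from a GTF file
#'
#' Imports the `exon` features of a GTF annotation and converts the 1-based
#' inclusive GTF coordinates to the 0-based half-open convention used
#' internally (matching BED arithmetic).
#'
#' @param path Path to a GTF file.
#' @return A tibble of exons with columns `gene_id`, `transcript_id`,
#'   `contig`, `strand`, `start`, `end`, sorted by gene, transcript and
#'   start. An annotation without exon features yields an empty tibble.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) {
    return(validate_exons(tibble::tibble(
      gene_id = character(), transcript_id = character(),
      contig = character(), strand = character(),
      start = integer(), end = integer()
    )[0, ]))
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    idx <- if (is.null(gr$transcript_id)) 1L else which(is.na(gr$transcript_id))[1]
    stop("exon feature ", idx, " lacks a transcript_id attribute", call. = FALSE)
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("exon feature lacks a gene_id attribute", call. = FALSE)
  }
  tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L, # GTF is 1-based inclusive
    end = GenomicRanges::end(gr)
  ) |>
    validate_exons()
}

#' Write exon models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exon intervals are
#' emitted as 1-based inclusive GTF `exon` features.
#'
#' @param exons Exon tibble (see [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  exons <- validate_exons(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = exons$contig,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand
  )
  gr$type <- "exon"
  gr$source <- "cardiosplice"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read splice junctions
#'
#' Parses a junction file into intron intervals with read counts. Two
#' dialects are supported: `"bed"` (BED6 with a 0-based half-open intron
#' interval and the read count in the score column, the regtools-style
#' output) and `"sj"` (STAR `SJ.out.tab`: 1-based inclusive intron
#' coordinates, strand coded 0/1/2, unique read count in column 7).
#'
#' @param path Path to the junction file.
#' @param dialect `"bed"` or `"sj"`.
#' @param sample Sample identifier attached to every record.
#' @return A tibble with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `sample`, `count`.
#' @export
read_junctions <- function(path, dialect = c("bed", "sj"), sample = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(tibble::tibble(
      contig = character(), start = integer(), end = integer(),
      strand = character(), sample = character(), count = integer()
    ))
  }
  if (dialect == "bed") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bed"),
      error = function(e) {
        stop("malformed BED (intron start >= end?): ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    out <- tibble::tibble(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      sample = sample,
      count = as.integer(gr$score)
    )
  } else {
    cols <- readr::read_tsv(path,
      col_names = c(
        "contig", "first_base", "last_base", "strand_code",
        "motif_code", "annotated", "unique_reads", "multi_reads",
        "max_overhang"
      ),
      col_types = readr::cols(contig = "c", .default = "i"),
      progress = FALSE
    )
    out <- tibble::tibble(
      contig = cols$contig,
      start = cols$first_base - 1L, # SJ tab is 1-based inclusive
      end = cols$last_base,
      strand = c("*", "+", "-")[cols$strand_code + 1L],
      sample = sample,
      count = cols$unique_reads
    )
  }
  bad <- which(out$start >= out$end)
  if (length(bad) > 0L) {
    stop("junction line ", bad[1], ": intron start >= end", call. = FALSE)
  }
  bad <- which(is.na(out$count) | out$count < 0L)
  if (length(bad) > 0L) {
    stop("junction line ", bad[1], ": negative or missing read count",
      call. = FALSE
    )
  }
  out
}

#' Write splice junctions
#'
#' @param junctions Junction tibble (see [read_junctions()]); one sample.
#' @param path Output path.
#' @param dialect `"bed"` (BED6, score = count) or `"sj"` (STAR-style tab).
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path, dialect = c("bed", "sj")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    bed <- tibble::tibble(
      contig = junctions$contig,
      start = junctions$start,
      end = junctions$end,
      name = sprintf("J%05d", seq_len(nrow(junctions))),
      score = junctions$count,
      strand = junctions$strand
    )
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  } else {
    sj <- tibble::tibble(
      contig = junctions$contig,
      first_base = junctions$start + 1L,
      last_base = junctions$end,
      strand_code = match(junctions$strand, c("*", "+", "-")) - 1L,
      motif_code = 0L, annotated = 0L,
      unique_reads = junctions$count, multi_reads = 0L, max_overhang = 50L
    )
    readr::write_tsv(sj, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Write a result table with a commented provenance header
#'
#' Result TSVs carry `#`-prefixed header lines recording the package
#' version and any run parameters (seed, thresholds), so every output file
#' states how it was produced.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param manifest Named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, manifest = list()) {
  manifest <- c(
    list(tool = paste0(
      "cardiosplice ",
      as.character(utils::packageVersion("cardiosplice"))
    )),
    manifest
  )
  hdr <- sprintf("# %s: %s", names(manifest), vapply(manifest, function(v) {
    paste(format(v, digits = 10), collapse = ",")
  }, character(1)))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble; the parsed header is attached as attribute `manifest`.
#' @export
read_result_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  x <- readr::read_tsv(I(lines[setdiff(seq_along(lines), hdr)]),
    col_types = readr::cols(), progress = FALSE
  )
  man <- sub("^# *", "", lines[hdr])
  attr(x, "manifest") <- setNames(
    sub("^[^:]+: *", "", man),
    sub(":.*$", "", man)
  )
  x
}
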