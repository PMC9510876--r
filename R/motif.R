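#' Scan a sequence for UWAA motifs
#'
#' Finds every (possibly overlapping) occurrence of the STAR-family
#' binding motif UWAA — U, A-or-U, A, A — in a nucleotide sequence. The
#' scan is case-insensitive, T is read as U (DNA input allowed), and N
#' never matches. Positions are 0-based.
#'
#' @param sequence A single nucleotide string over A/C/G/T/U/N.
#' @param regions Optional region annotation: a data frame with columns
#'   `start`, `end` (0-based half-open) and `label` (e.g. exon/intron
#'   names). Regions must not overlap. A hit is assigned to the region
#'   containing its start position, or `"unknown"`.
#' @param id Sequence identifier carried into the output.
#' @return A tibble with columns `sequence_id`, `position` (0-based start),
#'   `motif` (the matched 4-mer, in U alphabet) and `region`.
#' @examples
#' scan_uwaa("CUAAAC") # one hit at position 1
#' scan_uwaa("UUAAA") # overlapping hits at 0 and 1
#' @export
scan_uwaa <- function(sequence, regions = NULL, id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  bad <- stringr::str_locate(s, "[^ACGTUN]")[1]
  if (!is.na(bad)) {
    stop("invalid symbol '", substr(sequence, bad, bad),
      "' at position ", bad - 1L, " (0-based)",
      call. = FALSE
    )
  }
  s <- gsub("T", "U", s, fixed = TRUE)
  starts <- unname(stringr::str_locate_all(s, "(?=U[AU]AA)")[[1]][, "start"])
  hits <- tibble::tibble(
    sequence_id = rep(id, length(starts)),
    position = as.integer(starts) - 1L,
    motif = if (length(starts)) substring(s, starts, starts + 3L) else character(0)
  )
  hits$region <- assign_regions(hits$position, regions)
  hits
}

assign_regions <- function(positions, regions) {
  if (is.null(regions)) {
    return(rep("unknown", length(positions)))
  }
  regions <- dplyr::arrange(regions, start)
  if (any(regions$end <= regions$start)) {
    stop("region with end <= start", call. = FALSE)
  }
  if (nrow(regions) > 1L &&
    any(regions$start[-1] < regions$end[-nrow(regions)])) {
    stop("overlapping region definitions", call. = FALSE)
  }
  vapply(positions, function(p) {
    i <- which(regions$start <= p & p < regions$end)
    if (length(i) == 0L) "unknown" else regions$label[i]
  }, character(1))
}

#' Count motif hits per annotated region
#'
#' @param hits Output of [scan_uwaa()].
#' @param regions Region annotation (see [scan_uwaa()]); every label is
#'   reported, including zero-hit regions.
#' @return A tibble with columns `label` and `n_hits`.
#' @export
motif_occurrence_by_region <- function(hits, regions) {
  hits$region <- assign_regions(hits$position, regions)
  counts <- table(factor(hits$region, levels = unique(regions$label)))
  tibble::tibble(
    label = names(counts),
    n_hits = as.integer(counts)
  )
}

#' Ablate UWAA motifs by point mutation
#'
#' Designs motif-killing mutations for minigene constructs: at each
#' selected hit the two invariant adenosines (motif positions 3-4) are
#' replaced by C and G. Because neither C nor G can occur anywhere in a
#' UWAA match, the substitution can never create a new motif; the full
#' sequence is nevertheless rescanned and the result verified.
#'
#' @param sequence Nucleotide string (see [scan_uwaa()]).
#' @param positions 0-based start positions of the hits to mutate (a
#'   subset of the scan's positions).
#' @param scheme Two replacement characters for motif positions 3-4
#'   (default `c("C", "G")`).
#' @return A list with `sequence` (mutated, in the input's alphabet),
#'   `report` (tibble: position, before, after), and `hits_remaining`
#'   (rescan of the mutated sequence).
#' @export
mutate_motifs <- function(sequence, positions, scheme = c("C", "G")) {
  hits <- scan_uwaa(sequence)
  unknown <- setdiff(positions, hits$position)
  if (length(unknown) > 0L) {
    stop("no UWAA hit at position(s) ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!scheme %in% c("C", "G"))) {
    stop("mutation scheme must use C/G (any other base can re-create a motif)",
      call. = FALSE
    )
  }
  chars <- strsplit(sequence, "")[[1]]
  report <- purrr::map(sort(positions), function(p) {
    before <- toupper(paste(chars[(p + 1):(p + 4)], collapse = ""))
    chars[p + 3] <<- scheme[1]
    chars[p + 4] <<- scheme[2]
    tibble::tibble(
      position = p, before = gsub("T", "U", before, fixed = TRUE),
      after = toupper(paste(chars[(p + 1):(p + 4)], collapse = ""))
    )
  }) |> purrr::list_rbind()
  mutated <- paste(chars, collapse = "")
  remaining <- scan_uwaa(mutated)
  new_hits <- setdiff(remaining$position, hits$position)
  if (length(new_hits) > 0L) {
    stop("mutation created new motif(s) at ", paste(new_hits, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(positions %in% remaining$position)) {
    stop("mutation failed to ablate all selected motifs", call. = FALSE)
  }
  list(sequence = mutated, report = report, hits_remaining = remaining)
}
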