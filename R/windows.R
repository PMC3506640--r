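# Sliding-window diversity profile: the median nearest-neighbour percent
# identity in fixed-length windows along a target, computed from a
# multiple alignment. Conserved regions show up as plateaus at or near
# 100%, uniformly diverse targets as a flat profile below it.

# Split gapped sequences into a character matrix (rows = sequences).
alignment_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("alignment sequences must have equal length", call. = FALSE)
  }
  do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
}

# A sequence "covers" a set of alignment columns when its first and last
# non-gap positions bracket them; internal gaps (deletions) still count
# as covered.
coverage_flags <- function(mat, cols) {
  is_base <- mat != "-" & mat != "."
  first <- apply(is_base, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  last <- apply(is_base, 1, function(z) {
    if (any(z)) tail(which(z), 1) else NA_integer_
  })
  !is.na(first) & first <= min(cols) & last >= max(cols)
}

#' Nearest-neighbour percent identity within a window
#'
#' Percent identity of one sequence to its closest neighbour (the maximum
#' pairwise identity) over a set of alignment columns. Identity is
#' matches over alignment columns; any column where the two sequences are
#' not the same unambiguous base (including gap columns) counts as a
#' mismatch. Neighbours must cover the window and, when genome labels are
#' supplied, come from a different genome (paralogs of the same genome
#' are not their own neighbours).
#'
#' @param alignment Gapped sequences (named character vector, tibble with
#'   `id`/`sequence`, or DNAStringSet).
#' @param index Index (or id) of the focal sequence.
#' @param cols Integer vector of alignment columns forming the window.
#' @param genomes Optional character vector (one per sequence) of genome
#'   labels used to exclude same-genome neighbours.
#' @return Percent identity in `[0, 100]`, or `NA` when no eligible
#'   neighbour covers the window.
#' @export
nearest_neighbor_identity <- function(alignment, index, cols,
                                      genomes = NULL) {
  seqs <- as_named_seqs(alignment)
  mat <- alignment_matrix(seqs)
  if (is.character(index)) index <- match(index, names(seqs))
  stopifnot(!is.na(index), index >= 1, index <= nrow(mat))
  covered <- coverage_flags(mat, cols)
  if (!covered[index]) {
    stop("focal sequence does not cover the window", call. = FALSE)
  }
  if (is.null(genomes)) genomes <- names(seqs)
  eligible <- which(covered & seq_len(nrow(mat)) != index &
                      genomes != genomes[index])
  if (length(eligible) == 0) return(NA_real_)
  focal <- mat[index, cols]
  acgt <- c("A", "C", "G", "T")
  ids <- vapply(eligible, function(j) {
    other <- mat[j, cols]
    100 * sum(focal == other & focal %in% acgt) / length(cols)
  }, numeric(1))
  max(ids)
}

#' Sliding-window nearest-neighbour diversity profile
#'
#' Slides a fixed-length window (in reference coordinates) along a
#' multiple alignment and reports, per window, the median over sequences
#' of each sequence's nearest-neighbour percent identity. Windows are
#' emitted only when at least `coverage` of the sequences cover them
#' fully, so ragged ends do not distort the profile.
#'
#' @param alignment Gapped sequences of equal length.
#' @param manifest Optional tibble with `id` and `genome_id` columns used
#'   to exclude same-genome paralogs as neighbours.
#' @param window Window length in reference bases (default 120).
#' @param coverage Minimum fraction of sequences that must cover a window
#'   for it to be emitted (default 0.95).
#' @param step Step between window starts, in reference bases.
#' @param reference Id of the reference sequence on whose degapped
#'   coordinates windows are laid out; default is the longest sequence.
#' @return A tibble of class `window_profile`: `midpoint` (1-based
#'   reference coordinate), `median_identity`, `n_included` (sequences
#'   contributing to the median), `n_covering`.
#' @export
window_profile <- function(alignment, manifest = NULL, window = 120,
                           coverage = 0.95, step = 1, reference = NULL) {
  seqs <- as_named_seqs(alignment)
  if (length(seqs) == 0) stop("empty alignment", call. = FALSE)
  mat <- alignment_matrix(seqs)
  n <- nrow(mat)
  genomes <- names(seqs)
  if (!is.null(manifest)) {
    stopifnot(all(c("id", "genome_id") %in% names(manifest)))
    hit <- match(names(seqs), manifest$id)
    genomes <- ifelse(is.na(hit), names(seqs), manifest$genome_id[hit])
  }
  if (is.null(reference)) {
    reference <- names(seqs)[which.max(nchar(degap(seqs)))]
  }
  ridx <- match(reference, names(seqs))
  stopifnot(!is.na(ridx))
  ref_cols <- which(mat[ridx, ] != "-" & mat[ridx, ] != ".")
  Lref <- length(ref_cols)
  if (window > Lref) {
    stop("window (", window, ") longer than the reference (", Lref, " bp)",
         call. = FALSE)
  }
  is_base <- mat != "-" & mat != "."
  firsts <- apply(is_base, 1, function(z) which(z)[1])
  lasts <- apply(is_base, 1, function(z) tail(which(z), 1))
  acgt <- c("A", "C", "G", "T")

  starts <- seq(1L, Lref - window + 1L, by = step)
  rows <- lapply(starts, function(s) {
    cols <- ref_cols[s]:ref_cols[s + window - 1L]
    covered <- firsts <= cols[1] & lasts >= cols[length(cols)]
    if (sum(covered) < coverage * n) return(NULL)
    cov_idx <- which(covered)
    sub <- mat[cov_idx, cols, drop = FALSE]
    vals <- vapply(seq_along(cov_idx), function(r) {
      others <- which(genomes[cov_idx] != genomes[cov_idx[r]])
      if (length(others) == 0) return(NA_real_)
      focal <- sub[r, ]
      max(vapply(others, function(o) {
        100 * sum(focal == sub[o, ] & focal %in% acgt) / length(cols)
      }, numeric(1)))
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NULL)
    tibble::tibble(
      midpoint = s + (window - 1) / 2,
      median_identity = median(vals),
      n_included = length(vals),
      n_covering = length(cov_idx)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      midpoint = numeric(), median_identity = numeric(),
      n_included = integer(), n_covering = integer()
    )
  }
  attr(out, "window") <- window
  attr(out, "reference") <- reference
  class(out) <- c("window_profile", class(out))
  out
}
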