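# Barcode region delineation: locate the annealing sites of a primer
# pair in each sequence of an alignment and extract the inter-primer
# (amplicon interior) region. The barcode region excludes the primer
# footprints themselves, consistent with post-assembly primer trimming.

#' Delineate a barcode region from a primer pair
#'
#' For each sequence of an alignment (gaps are tolerated and removed
#' before matching), finds the forward-primer annealing site and the
#' reverse-primer site (the reverse primer is given 5'->3' on the
#' antisense strand, so its sense-strand footprint is its reverse
#' complement), then extracts the degapped subsequence strictly between
#' the two footprints. Sequences missing either site are reported and
#' skipped. When several sites qualify, the pair with the fewest total
#' mismatches (then the leftmost forward site and the rightmost
#' compatible reverse site) is used and the ambiguity is reported in the
#' `n_sites_f`/`n_sites_r` columns for review.
#'
#' @param alignment Sequences: named character vector, tibble with
#'   `id`/`sequence` columns, or DNAStringSet. May be gapped or ungapped.
#' @param primer_pair One-row tibble with `forward` and `reverse` columns
#'   (see [primer_table()] / [get_primer_pair()]).
#' @param max_mismatches Per-primer mismatch tolerance.
#' @return A tibble with one row per input sequence: `id`, `status`
#'   (`"ok"`, `"missing_forward"`, `"missing_reverse"`), `start`, `end`
#'   (1-based inclusive interior coordinates on the degapped sequence),
#'   `n_mismatch_f`, `n_mismatch_r`, `n_sites_f`, `n_sites_r`, and the
#'   extracted gap-free `sequence` (NA when skipped).
#' @export
delineate_region <- function(alignment, primer_pair, max_mismatches = 3) {
  seqs <- as_named_seqs(alignment)
  if (length(seqs) < 2) {
    stop("need at least 2 sequences to delineate a region", call. = FALSE)
  }
  fwd <- primer_pair$forward[1]
  rev_footprint <- revcomp(primer_pair$reverse[1])

  one <- function(id, s) {
    s0 <- degap(s)
    sf <- match_primer(s0, fwd, max_mismatches)
    sf <- sf[sf$strand == "+", , drop = FALSE]
    sr <- match_primer(s0, rev_footprint, max_mismatches)
    sr <- sr[sr$strand == "+", , drop = FALSE]
    base <- tibble::tibble(
      id = id, status = "ok",
      start = NA_integer_, end = NA_integer_,
      n_mismatch_f = NA_integer_, n_mismatch_r = NA_integer_,
      n_sites_f = nrow(sf), n_sites_r = nrow(sr),
      sequence = NA_character_
    )
    if (nrow(sf) == 0) {
      base$status <- "missing_forward"
      return(base)
    }
    if (nrow(sr) == 0) {
      base$status <- "missing_reverse"
      return(base)
    }
    # best compatible pair: fewest total mismatches, then leftmost
    # forward, then rightmost reverse
    grid <- tidyr::expand_grid(f = seq_len(nrow(sf)), r = seq_len(nrow(sr)))
    grid$f_end <- sf$end[grid$f]
    grid$r_start <- sr$start[grid$r]
    grid <- grid[grid$r_start > grid$f_end + 1L, , drop = FALSE]
    if (nrow(grid) == 0) {
      base$status <- "missing_reverse"
      return(base)
    }
    grid$mm <- sf$mismatches[grid$f] + sr$mismatches[grid$r]
    grid <- grid[order(grid$mm, sf$start[grid$f], -grid$r_start), ,
                 drop = FALSE]
    f <- grid$f[1]
    r <- grid$r[1]
    base$start <- sf$end[f] + 1L
    base$end <- sr$start[r] - 1L
    base$n_mismatch_f <- sf$mismatches[f]
    base$n_mismatch_r <- sr$mismatches[r]
    base$sequence <- substr(s0, base$start, base$end)
    base
  }

  out <- purrr::map2(names(seqs), unname(seqs), one) |> dplyr::bind_rows()
  if (all(out$status != "ok")) {
    message(
      "no sequence contained both primer annealing sites (max_mismatches = ",
      max_mismatches, ")"
    )
  }
  out
}
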