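# R-facing wrappers around the compiled semiglobal (free end-gap)
# aligner, plus a star-alignment fallback for fixture-scale multiple
# alignments of extracted barcode regions.

#' Best overlap between two sequences
#'
#' Maximal-scoring semiglobal (free end-gap) alignment of `b` against `a`
#' over both orientations of `b`. Percent identity is computed over the
#' aligned overlap columns with internal gaps counted as mismatches; end
#' overhangs are not part of the overlap.
#'
#' @param a,b Nucleotide sequences (single strings).
#' @return A one-row tibble: `length` (overlap columns), `identity`
#'   (percent), `orientation` (`"forward"`/`"reverse"`), `offset`
#'   (start of the overlap on `b` minus start on `a`, 0-based), `score`,
#'   and the 1-based overlap spans `a_start`, `a_end`, `b_start`, `b_end`
#'   (`b` coordinates refer to the aligned orientation).
#' @export
#' @examples
#' best_overlap("ACGTACGTACGT", "GTACGTACGTTT")
best_overlap <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  r <- cpp_best_overlap(toupper(a), toupper(b), band = -1L)
  if (!isTRUE(r$ok)) {
    return(tibble::tibble(
      length = 0L, identity = NA_real_, orientation = NA_character_,
      offset = NA_integer_, score = NA_integer_,
      a_start = NA_integer_, a_end = NA_integer_,
      b_start = NA_integer_, b_end = NA_integer_
    ))
  }
  tibble::tibble(
    length = r$length,
    identity = r$identity,
    orientation = if (isTRUE(r$reverse)) "reverse" else "forward",
    offset = (r$b_start - 1L) - (r$a_start - 1L),
    score = r$score,
    a_start = r$a_start, a_end = r$a_end,
    b_start = r$b_start, b_end = r$b_end
  )
}

#' Percent identity between two sequences
#'
#' Convenience wrapper around [best_overlap()] returning only the percent
#' identity of the best overlap alignment.
#'
#' @param a,b Nucleotide sequences.
#' @return Percent identity (scalar), or `NA` when the sequences share no
#'   alignable overlap.
#' @export
pairwise_identity <- function(a, b) {
  best_overlap(a, b)$identity
}

#' Star multiple alignment around a centre sequence
#'
#' Fixture-scale fallback aligner: every sequence is aligned pairwise
#' (semiglobal) to a centre sequence (default: the longest) and the
#' pairwise gaps are merged into common columns, "once a gap, always a
#' gap". Intended for small panels of homologous barcode regions; a
#' dedicated multiple aligner should be preferred at scale.
#'
#' @param x Sequences (named character vector, tibble with
#'   `id`/`sequence`, or DNAStringSet).
#' @param center Optional id of the centre sequence.
#' @return Named character vector of gapped sequences of equal length.
#' @export
star_align <- function(x, center = NULL) {
  seqs <- toupper(as_named_seqs(x))
  if (length(seqs) < 2) return(seqs)
  if (is.null(center)) {
    center <- names(seqs)[which.max(nchar(seqs))]
  }
  stopifnot(center %in% names(seqs))
  cseq <- seqs[[center]]
  Lc <- nchar(cseq)
  others <- setdiff(names(seqs), center)

  # For each pairwise alignment record, per centre position p (0..Lc),
  # the number of partner characters inserted before centre position p+1.
  aligned <- list()
  ins <- matrix(0L, nrow = length(others), ncol = Lc + 1L,
                dimnames = list(others, NULL))
  paths <- list()
  for (id in others) {
    r <- cpp_overlap_path(cseq, seqs[[id]])
    if (!isTRUE(r$ok)) {
      stop("star_align: no alignable overlap between '", center,
           "' and '", id, "'", call. = FALSE)
    }
    paths[[id]] <- r
    # characters of the partner before the overlap insert before centre
    # position a_start
    ins[id, r$a_start] <- ins[id, r$a_start] + (r$b_start - 1L)
    p <- r$a_start - 1L  # centre chars consumed so far
    run <- 0L
    for (step in r$path) {
      if (step == 3L) {
        run <- run + 1L
      } else {
        if (run > 0L) {
          ins[id, p + 1L] <- ins[id, p + 1L] + run
          run <- 0L
        }
        p <- p + 1L
      }
    }
    if (run > 0L) ins[id, p + 1L] <- ins[id, p + 1L] + run
    # partner tail after the overlap inserts after the last centre char
    ins[id, Lc + 1L] <- ins[id, Lc + 1L] + (nchar(seqs[[id]]) - r$b_end)
  }
  max_ins <- apply(ins, 2, max)

  build_row <- function(chars_fun) {
    out <- character(0)
    for (p in 0:Lc) {
      out <- c(out, chars_fun(p))
    }
    paste(out, collapse = "")
  }

  # centre row
  rows <- list()
  rows[[center]] <- build_row(function(p) {
    pre <- strrep("-", max_ins[p + 1L])
    ch <- if (p < Lc) substr(cseq, p + 1L, p + 1L) else ""
    paste0(pre, ch)
  })

  for (id in others) {
    r <- paths[[id]]
    s <- seqs[[id]]
    # reconstruct partner chars per slot: before centre position p+1
    # (insertion block), then the char aligned to centre position p+1
    ins_here <- integer(Lc + 1L)
    match_char <- rep("-", Lc)
    ins_chars <- vector("list", Lc + 1L)
    for (k in 0:Lc) ins_chars[[k + 1L]] <- character(0)
    bpos <- 1L
    take <- function(n) {
      out <- substr(s, bpos, bpos + n - 1L)
      bpos <<- bpos + n
      out
    }
    if (r$b_start > 1L) {
      ins_chars[[r$a_start]] <- strsplit(take(r$b_start - 1L), "")[[1]]
    }
    p <- r$a_start - 1L
    run <- character(0)
    for (step in r$path) {
      if (step == 3L) {
        run <- c(run, take(1L))
      } else {
        if (length(run) > 0L) {
          ins_chars[[p + 1L]] <- c(ins_chars[[p + 1L]], run)
          run <- character(0)
        }
        p <- p + 1L
        match_char[p] <- if (step == 1L) take(1L) else "-"
      }
    }
    if (length(run) > 0L) ins_chars[[p + 1L]] <- c(ins_chars[[p + 1L]], run)
    if (r$b_end < nchar(s)) {
      bpos <- r$b_end + 1L
      ins_chars[[Lc + 1L]] <- strsplit(
        substr(s, bpos, nchar(s)), ""
      )[[1]]
    }
    ins_here <- vapply(ins_chars, length, integer(1))

    rows[[id]] <- build_row(function(pp) {
      block <- ins_chars[[pp + 1L]]
      pad <- strrep("-", max_ins[pp + 1L] - ins_here[pp + 1L])
      ch <- if (pp < Lc) match_char[pp + 1L] else ""
      paste0(paste(block, collapse = ""), pad, ch)
    })
  }
  unlist(rows)[names(seqs)]
}
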