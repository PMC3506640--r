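# Sequence utilities shared across the package: IUPAC-aware matching,
# reverse complement, degapping, and coercion between the tabular
# representation used throughout (tibbles with id/sequence columns) and
# Biostrings objects at IO boundaries.

# Bitmask encoding of IUPAC nucleotide codes; two codes are compatible
# when their masks intersect. Inosine (I) pairs with any base and is
# treated like N.
.iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, I = 15L
)

.seq_bits <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bits <- unname(.iupac_bits[chars])
  bits[is.na(bits)] <- 0L
  bits
}

#' Reverse complement of IUPAC nucleotide sequences
#'
#' Vectorised reverse complement honouring the full IUPAC degeneracy code.
#' Inosine (I) complements to N (it pairs with any base). Gap characters
#' (`-`) are preserved.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTRY")
revcomp <- function(x) {
  flipped <- chartr(
    "ACGTUacgtuRYSWKMBDHVNIryswkmbdhvni",
    "TGCAAtgcaaYRSWMKVHDBNNyrswmkvhdbnn",
    x
  )
  vapply(
    strsplit(flipped, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

#' Remove alignment gaps from sequences
#'
#' @param x Character vector of (possibly gapped) sequences.
#' @param gap Characters treated as gaps.
#' @return Character vector with gap characters removed.
#' @export
degap <- function(x, gap = c("-", ".")) {
  gsub(paste0("[", paste(gap, collapse = ""), "]"), "", x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Coerce the accepted sequence inputs (named character vector, tibble
# with id/sequence columns, or a Biostrings XStringSet) to a named
# character vector.
as_named_seqs <- function(x, id_col = "id", seq_col = "sequence") {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (is.data.frame(x)) {
    if (!all(c(id_col, seq_col) %in% names(x))) {
      stop("expected columns '", id_col, "' and '", seq_col, "'",
           call. = FALSE)
    }
    return(setNames(as.character(x[[seq_col]]), as.character(x[[id_col]])))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret sequences of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' tabular form used throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(x), sequence = as.character(x))
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector or tibble with `id`/`sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- as_named_seqs(x)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Locate degenerate-primer annealing sites
#'
#' Scans a sequence for IUPAC-degeneracy-aware Hamming matches to a primer
#' on both strands. Inosine in the primer matches any base. Gap characters
#' in the sequence are skipped during matching, and reported coordinates
#' refer to the degapped sequence (1-based inclusive).
#'
#' @param sequence A single nucleotide sequence (gapped or ungapped).
#' @param primer Primer sequence, 5'->3', IUPAC codes and inosine allowed.
#' @param max_mismatches Maximum number of mismatching positions allowed.
#' @return A tibble with columns `start`, `end`, `strand` (`+` when the
#'   primer matches the given sequence as written, `-` when its reverse
#'   complement matches) and `mismatches`, best site first. Zero rows when
#'   no site qualifies.
#' @export
#' @examples
#' match_primer("TTTAGAGTTTGATCCTGGCTCAGTTT", "AGAGTTTGATCCTGGCTCAG")
match_primer <- function(sequence, primer, max_mismatches = 3) {
  stopifnot(length(sequence) == 1, length(primer) == 1)
  if (nchar(primer) < 10) {
    stop("primer must be at least 10 nt long", call. = FALSE)
  }
  seq0 <- degap(sequence)
  sb <- .seq_bits(seq0)
  scan_one <- function(pat, strand) {
    pb <- .seq_bits(pat)
    m <- length(pb)
    L <- length(sb)
    if (L < m) return(NULL)
    n_start <- L - m + 1L
    mism <- integer(n_start)
    for (k in seq_len(m)) {
      mism <- mism + as.integer(bitwAnd(pb[k], sb[k:(k + n_start - 1L)]) == 0L)
    }
    hit <- which(mism <= max_mismatches)
    if (length(hit) == 0) return(NULL)
    tibble::tibble(
      start = hit, end = hit + m - 1L,
      strand = strand, mismatches = mism[hit]
    )
  }
  out <- dplyr::bind_rows(
    scan_one(primer, "+"),
    scan_one(revcomp(primer), "-")
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(
      start = integer(), end = integer(),
      strand = character(), mismatches = integer()
    ))
  }
  dplyr::arrange(out, .data$mismatches, .data$start, .data$strand)
}
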