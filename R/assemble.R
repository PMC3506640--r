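# Greedy overlap-consensus assembly of barcode amplicon reads into OTUs.
# The assembler repeatedly merges the read/contig pair with the best
# qualifying overlap (identity >= mi and overlap length >= ml; globally
# best-first by identity, then overlap length, then lexicographic ids)
# and recomputes the majority-vote consensus after every merge.
# Single-read contigs are reported as singletons, not OTUs.

#' Assemble amplicon reads into OTUs
#'
#' @param reads Reads: a `read_set` from [simulate_reads()], a tibble
#'   with `read_id`/`sequence` columns, or a named character vector.
#' @param ml Minimum overlap length (nucleotides) to merge.
#' @param mi Minimum overlap identity (percent) to merge.
#' @param exhaustive When `TRUE`, every pair is aligned with a full
#'   dynamic program; when `FALSE`, candidate pairs come from a shared
#'   k-mer prescreen and alignments are banded around the voted diagonal.
#'   Default: exhaustive for up to 150 reads.
#' @param k,min_kmer_votes,band Prescreen parameters: k-mer size, minimum
#'   shared k-mers on a diagonal for a pair to be considered, and
#'   half-width of the alignment band.
#' @return An object of class `otu_assembly`: list with `otus` (tibble
#'   `otu_id`, `n_members`, `length`, `consensus`, `coverage`
#'   list-column), `membership` (tibble `read_id`, `otu_id`, where
#'   unmerged reads carry `"singleton"`), `params` and `n_reads`.
#' @export
#' @examples
#' reads <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGT")
#' assemble(reads, ml = 10, mi = 95)
assemble <- function(reads, ml = 100, mi = 92, exhaustive = NULL,
                     k = 12, min_kmer_votes = 3, band = 16) {
  seqs <- if (inherits(reads, "read_set")) {
    setNames(reads$reads$sequence, reads$reads$read_id)
  } else {
    as_named_seqs(reads, id_col = "read_id", seq_col = "sequence")
  }
  stopifnot(ml >= 1, mi > 0, mi <= 100)
  if (anyDuplicated(names(seqs))) {
    stop("read ids must be unique", call. = FALSE)
  }
  ord <- order(names(seqs), method = "radix")
  seqs <- seqs[ord]
  if (is.null(exhaustive)) exhaustive <- length(seqs) <= 150

  res <- cpp_assemble(
    toupper(unname(seqs)), ml = as.integer(ml), mi = as.numeric(mi),
    exhaustive = exhaustive, k = as.integer(k), band = as.integer(band),
    vote_min = as.integer(min_kmer_votes)
  )
  n_otus <- length(res$consensus)
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))
  membership <- tibble::tibble(
    read_id = names(seqs),
    otu_id = ifelse(is.na(res$membership), "singleton",
                    otu_ids[res$membership])
  )
  otus <- tibble::tibble(
    otu_id = otu_ids,
    n_members = as.integer(table(factor(res$membership,
                                        levels = seq_len(n_otus)))),
    length = nchar(res$consensus),
    consensus = as.character(res$consensus),
    coverage = res$coverage
  )
  structure(
    list(
      otus = otus,
      membership = membership,
      params = list(ml = ml, mi = mi),
      n_reads = length(seqs)
    ),
    class = "otu_assembly"
  )
}

#' @export
print.otu_assembly <- function(x, ...) {
  n_single <- sum(x$membership$otu_id == "singleton")
  cat("<otu_assembly> ml = ", x$params$ml, ", mi = ", x$params$mi, ": ",
      nrow(x$otus), " OTUs from ", x$n_reads, " reads (",
      n_single, " singletons, ",
      sprintf("%.1f", 100 * n_single / x$n_reads), "%)\n", sep = "")
  invisible(x)
}

#' @describeIn assemble Per-read membership table.
#' @param x An `otu_assembly`.
#' @param ... Unused.
#' @export
tidy.otu_assembly <- function(x, ...) {
  x$membership
}

#' @describeIn assemble One-row assembly summary.
#' @export
glance.otu_assembly <- function(x, ...) {
  n_single <- sum(x$membership$otu_id == "singleton")
  tibble::tibble(
    n_reads = x$n_reads,
    n_otus = nrow(x$otus),
    n_singletons = n_single,
    pct_singletons = 100 * n_single / x$n_reads,
    ml = x$params$ml,
    mi = x$params$mi
  )
}

#' Write assembly outputs
#'
#' Writes the OTU consensus sequences as FASTA and the read membership
#' table as TSV.
#'
#' @param assembly An `otu_assembly`.
#' @param consensus_fasta,membership_tsv Output paths (`NULL` to skip).
#' @return `assembly`, invisibly.
#' @export
write_assembly <- function(assembly, consensus_fasta = NULL,
                           membership_tsv = NULL) {
  if (!is.null(consensus_fasta)) {
    write_fasta(
      setNames(assembly$otus$consensus, assembly$otus$otu_id),
      consensus_fasta
    )
  }
  if (!is.null(membership_tsv)) {
    readr::write_tsv(assembly$membership, membership_tsv)
  }
  invisible(assembly)
}
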