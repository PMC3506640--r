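# Built-in definitions of the barcode regions and the broad-range PCR
# primer pairs that delineate them.

#' Built-in barcode regions and their PCR primer pairs
#'
#' Established broad-range primer pairs delineating the candidate barcode
#' regions: four multi-variable-region 16S rRNA amplicons, the short
#' V6-alternate amplicon, and the cpn60 universal target (UT, the region
#' corresponding to nucleotides 274-828 of the *E. coli* 60 kDa chaperonin
#' gene, amplified by the degenerate primers H279/H280). Reverse primers
#' are given 5'->3' on the antisense strand, as usual; `ref_start` and
#' `ref_end` are the 1-based inclusive coordinates of the amplified region
#' on the *E. coli* reference numbering of each gene.
#'
#' @return A tibble with one row per region: `gene`, `region`,
#'   `ref_start`, `ref_end`, `name_f`, `forward`, `name_r`, `reverse`.
#' @export
#' @examples
#' primer_table()
primer_table <- function() {
  tibble::tribble(
    ~gene,       ~region,        ~ref_start, ~ref_end, ~name_f, ~forward,                       ~name_r, ~reverse,
    "16S rRNA",  "V1-V3",        27L,  534L,  "27F",   "AGAGTTTGATCCTGGCTCAG",         "534R",  "ATTACCGCGGCTGCTGG",
    "16S rRNA",  "V2-V4",        101L, 806L,  "101F",  "AGYGGCGIACGGGTGAGTAA",         "806R",  "GGACTACARGGTATCTAAT",
    "16S rRNA",  "V3-V5",        357L, 926L,  "357F",  "CCTACGGGAGGCAGCAG",            "926R",  "CCGTCAATTCMTTTRAGT",
    "16S rRNA",  "V6",           907L, 1073L, "907F",  "AAACTCAAAKGAATTGACGG",         "1073R", "ACGAGCTGACGACARCCATG",
    "16S rRNA",  "V6-alternate", 985L, 1078L, "L-V6",  "CAACGCGARGAACCTTACC",          "R-V6",  "ACAACACGAGCTGACGAC",
    "cpn60",     "UT",           274L, 828L,  "H279",  "GAIIIIGCIGGIGAYGGIACIACIAC",   "H280",  "YKIYKITCICCRAAICCIGGIGCYTT"
  )
}

#' Look up one primer pair by region label
#'
#' @param region Region label, e.g. `"UT"` or `"V1-V3"`.
#' @return A one-row tibble from [primer_table()].
#' @export
get_primer_pair <- function(region) {
  tab <- primer_table()
  row <- tab[tab$region == region, ]
  if (nrow(row) != 1) {
    stop("unknown region '", region, "'; available: ",
         paste(tab$region, collapse = ", "), call. = FALSE)
  }
  row
}

# Replace degenerate IUPAC positions (and inosine) in a primer by
# concrete bases, sampling uniformly among the compatible bases. Used to
# synthesise the primer-derived ends of simulated amplicons.
concretize_primer <- function(primer) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  out <- vapply(chars, function(c) {
    bits <- .iupac_bits[[c]]
    if (is.null(bits)) stop("bad primer character '", c, "'", call. = FALSE)
    allowed <- bases[bitwAnd(bits, c(1L, 2L, 4L, 8L)) != 0L]
    if (length(allowed) == 1) allowed else sample(allowed, 1)
  }, character(1))
  paste(out, collapse = "")
}
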