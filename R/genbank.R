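# Minimal GenBank flat-file support: enough of the format to carry
# annotated marker genes (rRNA and CDS features with gene/product
# qualifiers and simple or complemented spans) in and out of the package.
# Records are represented as plain lists so that the synthetic genome
# generator and the parser share one structure.

new_genome_record <- function(genome_id, taxon_id, sequence, features) {
  structure(
    list(
      genome_id = genome_id,
      taxon_id = taxon_id,
      sequence = sequence,
      features = features
    ),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id,
      " (taxon ", if (nzchar(x$taxon_id)) x$taxon_id else "?",
      "), ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Parse GenBank flat files
#'
#' Reads one or more GenBank flat files (or literal text) into genome
#' records: the replicon sequence plus a feature table of rRNA and CDS
#' annotations with their gene/product qualifiers. Feature locations of
#' the forms `a..b` and `complement(a..b)` are supported (partial-end
#' markers `<`/`>` are tolerated); `join(...)` locations are skipped with
#' a warning. Coordinates are 1-based inclusive as in the format.
#'
#' @param path Character vector of file paths (each may hold several
#'   LOCUS entries).
#' @param text Literal GenBank text (used instead of `path`).
#' @return A list of genome records, each with fields `genome_id`,
#'   `taxon_id` (empty string, with a warning, when the source feature
#'   carries no taxon db_xref), `sequence` and a `features` tibble with
#'   columns `type`, `start`, `end`, `strand`, `gene`, `product`.
#' @export
read_genbank <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    lines <- unlist(lapply(path, readLines), use.names = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) {
    stop("malformed GenBank input: no LOCUS line found", call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    records[[r]] <- parse_one_locus(lines[starts[r]:ends[r]], starts[r])
  }
  records
}

# Parse one LOCUS..// block. `offset` is the 1-based line number of the
# LOCUS line in the original input, for error messages.
parse_one_locus <- function(lines, offset) {
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(locus_fields) < 2) {
    stop("malformed GenBank record at line ", offset,
         ": unparsable LOCUS line", call. = FALSE)
  }
  genome_id <- locus_fields[2]

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(origin_start) == 0) {
    stop("malformed GenBank record '", genome_id,
         "' at line ", offset, ": no ORIGIN section", call. = FALSE)
  }
  origin_start <- origin_start[1]

  # --- sequence ---
  seq_lines <- lines[(origin_start + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) {
    stop("malformed GenBank record '", genome_id,
         "': empty ORIGIN sequence", call. = FALSE)
  }

  # --- features ---
  feats <- list()
  taxon_id <- ""
  if (length(feat_start) > 0 && feat_start[1] + 1L < origin_start) {
    block <- lines[(feat_start[1] + 1L):(origin_start - 1L)]
    block_offsets <- offset + feat_start[1] + seq_along(block) - 1L
    key_idx <- grep("^ {5}\\S", block)
    for (f in seq_along(key_idx)) {
      from <- key_idx[f]
      to <- if (f < length(key_idx)) key_idx[f + 1L] - 1L else length(block)
      chunk <- block[from:to]
      header <- trimws(chunk[1])
      parts <- strsplit(header, "\\s+")[[1]]
      type <- parts[1]
      loc <- paste(parts[-1], collapse = "")
      # location may continue on lines before the first qualifier
      qual_idx <- grep("^\\s+/", chunk)
      loc_extra <- if (length(qual_idx) > 0 && qual_idx[1] > 2) {
        2:(qual_idx[1] - 1L)
      } else if (length(qual_idx) == 0 && length(chunk) > 1) {
        2:length(chunk)
      } else {
        integer()
      }
      if (length(loc_extra) > 0) {
        loc <- paste0(loc, paste(trimws(chunk[loc_extra]), collapse = ""))
      }
      quals <- parse_qualifiers(chunk[grep("^\\s+/", chunk)])

      if (grepl("^join|^order|^complement\\(join", loc)) {
        warning("skipping feature with compound location '", loc,
                "' in record ", genome_id, call. = FALSE)
        next
      }
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      span <- gsub("^complement\\(|\\)$|[<>]", "", loc)
      coords <- strsplit(span, "..", fixed = TRUE)[[1]]
      coords_ok <- length(coords) %in% c(1L, 2L) &&
        all(grepl("^[0-9]+$", coords))
      if (!coords_ok) {
        stop("malformed GenBank record '", genome_id, "' at line ",
             block_offsets[from], ": unparsable location '", loc, "'",
             call. = FALSE)
      }
      start <- as.integer(coords[1])
      end <- as.integer(coords[length(coords)])
      if (start > end || end > nchar(sequence)) {
        stop("malformed GenBank record '", genome_id, "' at line ",
             block_offsets[from], ": location ", loc,
             " outside the ", nchar(sequence), " bp sequence",
             call. = FALSE)
      }
      if (type == "source") {
        xref <- quals[names(quals) == "db_xref"]
        tax <- grep("^taxon:", xref, value = TRUE)
        if (length(tax) > 0) taxon_id <- unname(sub("^taxon:", "", tax[1]))
        next
      }
      feats[[length(feats) + 1L]] <- tibble::tibble(
        type = type, start = start, end = end, strand = strand,
        gene = if ("gene" %in% names(quals)) quals[["gene"]] else NA_character_,
        product = if ("product" %in% names(quals)) {
          quals[["product"]]
        } else {
          NA_character_
        }
      )
    }
  }
  features <- if (length(feats) > 0) {
    dplyr::bind_rows(feats)
  } else {
    tibble::tibble(
      type = character(), start = integer(), end = integer(),
      strand = character(), gene = character(), product = character()
    )
  }
  if (!nzchar(taxon_id)) {
    warning("record '", genome_id, "' has no taxon db_xref; taxon_id left empty",
            call. = FALSE)
  }
  new_genome_record(genome_id, taxon_id, sequence, features)
}

parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(character())
  txt <- trimws(lines)
  # continuation lines (no leading /) glued to the previous qualifier
  is_q <- grepl("^/", txt)
  grp <- cumsum(is_q)
  merged <- vapply(
    split(txt, grp),
    function(x) paste(x, collapse = " "),
    character(1)
  )
  merged <- merged[grepl("^/", merged)]
  keys <- sub("^/([A-Za-z_0-9]+).*$", "\\1", merged)
  vals <- ifelse(
    grepl("=", merged, fixed = TRUE),
    sub('^/[A-Za-z_0-9]+="?(.*?)"?$', "\\1", merged),
    ""
  )
  setNames(vals, keys)
}

#' Write genome records as GenBank flat files
#'
#' Emits the subset of the GenBank format that [read_genbank()] consumes:
#' LOCUS, a source feature carrying the taxon db_xref, rRNA/CDS features
#' with gene/product qualifiers, and the ORIGIN sequence.
#'
#' @param records A genome record or list of them.
#' @param path Output path; when `NULL` the text is returned invisibly
#'   instead of written.
#' @return The GenBank text, invisibly.
#' @export
write_genbank <- function(records, path = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  blocks <- vapply(records, format_one_locus, character(1))
  text <- paste(blocks, collapse = "\n")
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}

format_one_locus <- function(rec) {
  L <- nchar(rec$sequence)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   BCT", rec$genome_id, L),
    sprintf("DEFINITION  %s, synthetic genome fixture.", rec$genome_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    sprintf("                     /organism=\"synthetic bacterium %s\"",
            rec$genome_id),
    if (nzchar(rec$taxon_id)) {
      sprintf("                     /db_xref=\"taxon:%s\"", rec$taxon_id)
    }
  )
  if (nrow(rec$features) > 0) {
    for (i in seq_len(nrow(rec$features))) {
      f <- rec$features[i, ]
      loc <- if (f$strand == "-") {
        sprintf("complement(%d..%d)", f$start, f$end)
      } else {
        sprintf("%d..%d", f$start, f$end)
      }
      out <- c(out, sprintf("     %-15s %s", f$type, loc))
      if (!is.na(f$gene)) {
        out <- c(out, sprintf("                     /gene=\"%s\"", f$gene))
      }
      if (!is.na(f$product)) {
        out <- c(out, sprintf("                     /product=\"%s\"", f$product))
      }
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(rec$sequence, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  paste(c(out, "//"), collapse = "\n")
}

#' Default annotation keyword sets for marker extraction
#'
#' Bacterial genome annotations name the 60 kDa chaperonin gene
#' inconsistently, so cpn60 extraction relies on a list of keywords; 16S
#' rRNA genes are recognised by "16S" in rRNA feature names. Matching is
#' case-insensitive on whole tokens (so "groEL" matches "groEL chaperonin"
#' but not "groES"). The sets are deliberately user-extensible.
#'
#' @param gene `"16S"` or `"cpn60"`.
#' @return Character vector of match terms.
#' @export
default_keywords <- function(gene = c("16S", "cpn60")) {
  gene <- match.arg(gene)
  switch(gene,
    "16S" = c("16S"),
    "cpn60" = c(
      "cpn60", "cpn 60", "groEL", "groL", "hsp60",
      "60 kDa chaperonin", "chaperonin 60", "chaperonin GroEL",
      "heat shock protein 60"
    )
  )
}

#' Read a taxonomy table
#'
#' @param path Path to a 3-column TSV (`taxon_id`, `species`, `lineage`),
#'   headerless or with that header.
#' @return A tibble with columns `taxon_id`, `species`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^taxon_id\\t", first)
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("taxon_id", "species", "lineage"),
    col_types = readr::cols(.default = readr::col_character()),
    skip = 0
  )
  names(tab)[1:3] <- c("taxon_id", "species", "lineage")
  tab
}

# Case-insensitive whole-token match of any keyword in any of the given
# annotation strings. Tokens are maximal alphanumeric runs, so "groEL"
# does not hit "groES" or "groESL".
keyword_hit <- function(strings, keywords) {
  strings <- strings[!is.na(strings)]
  if (length(strings) == 0) return(FALSE)
  for (kw in keywords) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw)
    pat <- paste0("(?i)(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
    if (any(grepl(pat, strings, perl = TRUE))) return(TRUE)
  }
  FALSE
}

#' Extract annotated marker gene copies from genome records
#'
#' Pulls every annotated copy of a marker gene (16S rRNA from rRNA
#' features, cpn60 from CDS features) whose gene or product annotation
#' contains one of the keywords, reverse-complementing minus-strand
#' features so that all copies are reported on the gene's sense strand.
#' All paralogs are kept; `copy_index` numbers them by position within
#' each genome.
#'
#' @param records A genome record or list of them (see [read_genbank()]).
#' @param gene `"16S"` or `"cpn60"`.
#' @param taxonomy Optional taxonomy tibble ([read_taxonomy()]); species
#'   falls back to `"unknown"` when the record's taxon is absent.
#' @param keywords Match terms; defaults to [default_keywords()].
#' @return A tibble with columns `genome_id`, `species`, `taxon_id`,
#'   `gene`, `copy_index`, `sequence` (ungapped, sense strand).
#' @export
extract_markers <- function(records, gene = c("16S", "cpn60"),
                            taxonomy = NULL,
                            keywords = default_keywords(gene)) {
  gene <- match.arg(gene)
  if (inherits(records, "genome_record")) records <- list(records)
  stopifnot(length(keywords) > 0)
  want_type <- if (gene == "16S") "rRNA" else "CDS"

  rows <- lapply(records, function(rec) {
    f <- rec$features
    f <- f[f$type == want_type, , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    hits <- vapply(
      seq_len(nrow(f)),
      function(i) keyword_hit(c(f$gene[i], f$product[i]), keywords),
      logical(1)
    )
    f <- f[hits, , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    f <- f[order(f$start), , drop = FALSE]
    seqs <- substr(rep(rec$sequence, nrow(f)), f$start, f$end)
    seqs[f$strand == "-"] <- revcomp(seqs[f$strand == "-"])
    species <- "unknown"
    if (!is.null(taxonomy) && nzchar(rec$taxon_id)) {
      hit <- taxonomy$species[taxonomy$taxon_id == rec$taxon_id]
      if (length(hit) > 0) species <- hit[1]
    }
    tibble::tibble(
      genome_id = rec$genome_id,
      species = species,
      taxon_id = rec$taxon_id,
      gene = gene,
      copy_index = seq_len(nrow(f)),
      sequence = seqs
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      genome_id = character(), species = character(),
      taxon_id = character(), gene = character(),
      copy_index = integer(), sequence = character()
    )
  }
  out
}

#' Write a marker FASTA plus manifest
#'
#' FASTA headers follow `genome_id|gene|copy_index|species`; the manifest
#' TSV carries the same fields plus sequence length.
#'
#' @param markers Marker tibble from [extract_markers()].
#' @param fasta,manifest Output paths (`NULL` to skip either).
#' @return `markers`, invisibly.
#' @export
write_markers <- function(markers, fasta = NULL, manifest = NULL) {
  ids <- paste(markers$genome_id, markers$gene, markers$copy_index,
               markers$species, sep = "|")
  if (!is.null(fasta)) {
    write_fasta(setNames(markers$sequence, ids), fasta)
  }
  if (!is.null(manifest)) {
    readr::write_tsv(
      dplyr::mutate(markers, id = ids, length = nchar(markers$sequence),
                    sequence = NULL),
      manifest
    )
  }
  invisible(markers)
}
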