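# Readers, writers and validators for every file format the pipeline
# touches: CDS and protein FASTA (via Biostrings), aligned FASTA, domain /
# expression / tRNA-copy TSV tables, and dot-bracket structure files.

#' Validate a coding sequence
#'
#' A CDS is valid when it begins with ATG, ends with a canonical stop codon
#' (TGA, TAA or TAG), has a length that is a multiple of three, and (by
#' default) contains no internal in-frame stop codon. The first failed rule
#' is reported as a reason code.
#'
#' @param sequence a single non-empty nucleotide string (ACGTN alphabet).
#' @param check_internal_stops logical; treat internal in-frame stops as
#'   invalidating (default `TRUE`).
#' @return list with `valid` (logical) and `reason` (`"ok"`, `"no-start"`,
#'   `"no-stop"`, `"length-not-multiple-of-3"`, `"internal-stop"`,
#'   `"bad-alphabet"`).
#' @examples
#' validate_cds("ATGAAATGA")$valid       # TRUE
#' validate_cds("ATGAAA")$reason         # "no-stop"
#' @export
validate_cds <- function(sequence, check_internal_stops = TRUE) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("akashi_empty_sequence: sequence must be a non-empty string")
  sequence <- toupper(sequence)
  fail <- function(reason) list(valid = FALSE, reason = reason)
  if (grepl("[^ACGTN]", sequence)) return(fail("bad-alphabet"))
  if (nchar(sequence) %% 3L != 0L) return(fail("length-not-multiple-of-3"))
  if (substr(sequence, 1L, 3L) != "ATG") return(fail("no-start"))
  last <- substr(sequence, nchar(sequence) - 2L, nchar(sequence))
  if (!last %in% STOP_CODONS) return(fail("no-stop"))
  if (check_internal_stops && nchar(sequence) > 3L) {
    codons <- split_codons(substr(sequence, 1L, nchar(sequence) - 3L))
    if (any(codons %in% STOP_CODONS)) return(fail("internal-stop"))
  }
  list(valid = TRUE, reason = "ok")
}

# Split an in-frame nucleotide string into its codons.
split_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(sequence, starts, pmin(starts + 2L, n))
}

#' Read coding sequences from FASTA
#'
#' Reads a (possibly multi-record) FASTA of CDS. Records failing
#' [validate_cds()] are retained but flagged so callers can exclude them
#' downstream. Identifiers are taken as the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path FASTA file path.
#' @param species optional species tag attached to every record.
#' @param check_internal_stops passed to [validate_cds()].
#' @return data.frame with columns `gene_id`, `sequence`, `species`,
#'   `valid`, `reason`.
#' @export
read_cds_fasta <- function(path, species = NA_character_,
                           check_internal_stops = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA: ", path)
    return(data.frame(gene_id = character(0), sequence = character(0),
                      species = character(0), valid = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("akashi_duplicate_id: duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  verdicts <- lapply(seqs, validate_cds,
                     check_internal_stops = check_internal_stops)
  data.frame(
    gene_id = ids, sequence = unname(seqs), species = species,
    valid = vapply(verdicts, `[[`, logical(1), "valid"),
    reason = vapply(verdicts, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
}

#' Write coding sequences to FASTA
#'
#' @param cds data.frame as returned by [read_cds_fasta()], or a named
#'   character vector of sequences.
#' @param path output file path.
#' @export
write_cds_fasta <- function(cds, path) {
  if (is.data.frame(cds)) {
    seqs <- cds$sequence
    names(seqs) <- cds$gene_id
  } else seqs <- cds
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a protein alignment from aligned FASTA
#'
#' @param path aligned FASTA with 2 or more equal-length records; gaps as
#'   `-`.
#' @return named character vector of aligned sequences.
#' @export
read_protein_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 2L)
    stop("akashi_alignment_too_small: need >= 2 aligned sequences")
  if (length(unique(Biostrings::width(set))) != 1L)
    stop("akashi_unequal_alignment: aligned sequences differ in length")
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write an alignment to aligned FASTA
#' @param aln named character vector of equal-length aligned sequences.
#' @param path output file path.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln), path)
  invisible(path)
}

#' Pairwise alignment identity
#'
#' Percentage of identical amino-acid columns between two aligned
#' sequences. The denominator is, by default, the columns where neither
#' sequence has a gap; `denominator = "columns"` uses the full alignment
#' length instead.
#'
#' @param a,b aligned sequences of equal length (gaps as `-`).
#' @param denominator `"gapfree"` (default) or `"columns"`.
#' @return identity in percent (0-100); `NaN` when no gap-free column
#'   exists.
#' @export
alignment_identity <- function(a, b, denominator = c("gapfree", "columns")) {
  denominator <- match.arg(denominator)
  if (nchar(a) != nchar(b))
    stop("akashi_unequal_alignment: sequences differ in length")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  gapfree <- ca != "-" & cb != "-"
  same <- sum(ca == cb & gapfree)
  denom <- if (denominator == "gapfree") sum(gapfree) else length(ca)
  100 * same / denom
}

#' Filter ortholog alignments by minimum identity
#'
#' Retains alignments whose minimum pairwise identity across all sequence
#' pairs exceeds `min_identity` percent.
#'
#' @param alignments list of named character vectors (each an alignment of
#'   2 or 3 sequences).
#' @param min_identity identity threshold in percent (default 60; the
#'   alignment is retained when identity is strictly greater).
#' @param denominator passed to [alignment_identity()].
#' @return the retained subset of `alignments`.
#' @export
filter_ortholog_pairs <- function(alignments, min_identity = 60,
                                  denominator = "gapfree") {
  keep <- vapply(alignments, function(aln) {
    prs <- utils::combn(length(aln), 2L)
    ids <- apply(prs, 2L, function(ij)
      alignment_identity(aln[[ij[1]]], aln[[ij[2]]], denominator))
    min(ids) > min_identity
  }, logical(1))
  alignments[keep]
}

#' Read a protein-domain coordinate table
#'
#' Tab-separated columns `gene_id`, `domain_id`, `start`, `end` in 1-based
#' inclusive protein coordinates.
#'
#' @param path TSV file path.
#' @return data.frame with those columns.
#' @export
read_domain_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "domain_id", "start", "end")
  if (!all(needed %in% names(d)))
    stop("akashi_bad_domain_table: need columns ",
         paste(needed, collapse = ", "))
  if (any(d$start < 1L) || any(d$end < d$start))
    stop("akashi_bad_domain_table: require 1 <= start <= end")
  d[needed]
}

#' Read a gene-by-experiment expression table
#'
#' Tab-separated long format with columns `gene_id`, `experiment`,
#' `value`. Missing values (NA) are allowed and are distinct from zero.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `experiment`, `value`.
#' @export
read_expression_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "experiment", "value")
  if (!all(needed %in% names(d)))
    stop("akashi_bad_expression_table: need columns ",
         paste(needed, collapse = ", "))
  if (any(d$value < 0, na.rm = TRUE))
    stop("akashi_bad_expression_table: negative expression value")
  d[needed]
}

#' Read a tRNA gene copy-number table
#'
#' Tab-separated columns `codon`, `copies`: cognate tRNA gene copies per
#' sense codon (as produced by genomic tRNA scans).
#'
#' @param path TSV file path.
#' @return named integer vector of copy counts keyed by codon.
#' @export
read_trna_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "copies") %in% names(d)))
    stop("akashi_bad_trna_table: need columns codon, copies")
  if (any(d$copies < 0))
    stop("akashi_negative_copies: tRNA copy counts must be >= 0")
  counts <- as.integer(d$copies)
  names(counts) <- toupper(chartr("U", "T", d$codon))
  counts
}

#' Read a dot-bracket secondary-structure file
#'
#' Format: per record, an id line (`>gene`), the sequence line, the
#' dot-bracket line, and optionally a line of comma-separated per-base
#' pairing probabilities in [0, 1]. Bracket balance and length agreement
#' are checked.
#'
#' @param path structure file path.
#' @return named list per gene with elements `sequence`, `structure`,
#'   `pair_prob` (numeric vector or `NULL`).
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  idx <- grep("^>", lines)
  if (length(idx) == 0L) stop("akashi_bad_structure_file: no records")
  ends <- c(idx[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(idx)) {
    block <- lines[(idx[k] + 1L):ends[k]]
    if (length(block) < 2L)
      stop("akashi_bad_structure_file: record needs sequence + structure")
    gene <- sub("^>\\s*", "", lines[idx[k]])
    gene <- sub("\\s.*$", "", gene)
    seqline <- block[1]
    struct <- block[2]
    if (nchar(struct) != nchar(seqline))
      stop("akashi_bad_structure_file: structure length mismatch for ", gene)
    if (!is_balanced_dotbracket(struct))
      stop("akashi_bad_structure_file: unbalanced brackets for ", gene)
    prob <- NULL
    if (length(block) >= 3L) {
      prob <- as.numeric(strsplit(block[3], ",")[[1]])
      if (length(prob) != nchar(seqline) || any(is.na(prob)) ||
          any(prob < 0 | prob > 1))
        stop("akashi_bad_structure_file: bad probability line for ", gene)
    }
    out[[gene]] <- list(sequence = seqline, structure = struct,
                        pair_prob = prob)
  }
  out
}

#' Write a dot-bracket secondary-structure file
#' @param structures named list as returned by [read_structure_file()].
#' @param path output file path.
#' @export
write_structure_file <- function(structures, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (gene in names(structures)) {
    s <- structures[[gene]]
    writeLines(c(paste0(">", gene), s$sequence, s$structure), con)
    if (!is.null(s$pair_prob))
      writeLines(paste(formatC(s$pair_prob, format = "g"), collapse = ","),
                 con)
  }
  invisible(path)
}

is_balanced_dotbracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  all(depth >= 0L) && depth[length(depth)] == 0L
}

# Simple TSV writer used by all exporters.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
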