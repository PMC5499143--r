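# Standard nuclear genetic code tables and codon-family bookkeeping.
# Every other module looks codons up here; the tables are built once at load
# from Biostrings::GENETIC_CODE.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.build_code_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- chartr("U", "T", names(gc))
  aa <- unname(gc)
  names(aa) <- codons
  sense <- aa[aa != "*"]
  fam <- split(names(sense), unname(sense))
  fam <- lapply(fam, sort)
  list(codon_to_aa = aa, sense = sense, families = fam)
}

.CODE <- .build_code_tables()

# Sixfold amino acids optionally split into their 2- and 4-codon blocks
# (Leu TTR/CTN, Ser AGY/TCN, Arg AGR/CGN).
.SPLIT6 <- list(
  "L2" = c("TTA", "TTG"), "L4" = c("CTA", "CTC", "CTG", "CTT"),
  "S2" = c("AGC", "AGT"), "S4" = c("TCA", "TCC", "TCG", "TCT"),
  "R2" = c("AGA", "AGG"), "R4" = c("CGA", "CGC", "CGG", "CGT")
)

#' Standard genetic code table
#'
#' Returns the codon-to-amino-acid map, synonymous families and per-family
#' degeneracy for the standard nuclear genetic code. Sixfold-degenerate
#' amino acids (Leu, Ser, Arg) are by default kept as single synonymous
#' families of six codons; `split_sixfold = TRUE` splits each into its
#' two- and four-codon blocks for sensitivity analyses.
#'
#' @param split_sixfold logical; split Leu/Ser/Arg into 2+4 subfamilies.
#' @return A list with elements `codon_to_aa` (named character, 64 codons,
#'   stops as `"*"`), `families` (named list of codon vectors, keyed by
#'   amino-acid letter or subfamily tag), `degeneracy` (named integer per
#'   family), and `family_of` (named character mapping each sense codon to
#'   its family key).
#' @examples
#' ct <- codon_table()
#' ct$degeneracy[["L"]]  # 6
#' @export
codon_table <- function(split_sixfold = FALSE) {
  fam <- .CODE$families
  if (split_sixfold) {
    fam <- fam[setdiff(names(fam), c("L", "S", "R"))]
    fam <- c(fam, .SPLIT6)
    fam <- fam[order(names(fam))]
  }
  family_of <- rep(names(fam), lengths(fam))
  names(family_of) <- unlist(fam, use.names = FALSE)
  list(
    codon_to_aa = .CODE$codon_to_aa,
    families = fam,
    degeneracy = vapply(fam, length, integer(1)),
    family_of = family_of
  )
}

#' Test whether codons are sense codons of the standard code
#'
#' @param codon character vector of 3-letter uppercase codons.
#' @return logical vector; `FALSE` for stop codons and anything that is not
#'   an ACGT triplet (including codons containing N or IUPAC ambiguity
#'   codes, which are excluded from all counts rather than guessed).
#' @export
is_sense_codon <- function(codon) {
  !is.na(codon) & codon %in% names(.CODE$sense)
}

#' Translate codons to amino acids
#'
#' Vectorised lookup in the standard code. Non-ACGT triplets translate to
#' `NA`; stops translate to `"*"`.
#'
#' @param codons character vector of codons (DNA alphabet).
#' @return character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  unname(.CODE$codon_to_aa[codons])
}

#' Synonymous peers of a codon
#'
#' All codons encoding the same amino acid as `codon`, excluding `codon`
#' itself, in lexicographic order. Single-codon families (ATG, TGG) have no
#' peers.
#'
#' @param codon a single sense codon.
#' @param split_sixfold logical; treat the 2- and 4-codon blocks of Leu,
#'   Ser and Arg as separate families.
#' @return character vector of peer codons (possibly empty).
#' @examples
#' synonymous_peers("TTC")  # "TTT"
#' synonymous_peers("TGG")  # character(0)
#' @export
synonymous_peers <- function(codon, split_sixfold = FALSE) {
  if (length(codon) != 1L || is.na(codon) || !grepl("^[ACGT]{3}$", codon))
    stop("akashi_bad_codon: not an ACGT triplet: ", codon)
  if (codon %in% STOP_CODONS)
    stop("akashi_stop_codon: stop codon has no synonymous family: ", codon)
  ct <- codon_table(split_sixfold)
  fam <- ct$families[[ct$family_of[[codon]]]]
  setdiff(fam, codon)
}

# Third base of each codon in a character vector.
third_base <- function(codons) substr(codons, 3L, 3L)

# Sense codons belonging to families of degeneracy >= 2 (the codons for
# which an enrichment odds ratio is defined): 59 under the unsplit code.
degenerate_sense_codons <- function(split_sixfold = FALSE) {
  ct <- codon_table(split_sixfold)
  unlist(ct$families[ct$degeneracy >= 2L], use.names = FALSE)
}
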