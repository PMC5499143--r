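# Codon alignments back-translated from protein alignments, per-site
# evolutionary classification (pairwise, phylogeny-based with outgroup,
# optimality-tied), and site-level annotation with protein-domain,
# stem/loop and transcript-third flags.
#
# The central container is the "site table": one row per alignment column
# with columns
#   gene, column, prot_pos (ungapped position in the principal protein,
#   NA at principal gaps), codon (principal), codon_sister, state
#   (conserved/variable/excluded), lineage, and - after annotation -
#   in_domain, struct_class, third.

GAP_CODON <- "---"

#' Build a codon alignment from a protein alignment and CDS
#'
#' Back-translates each aligned protein onto its coding sequence. Every
#' CDS (stop codon removed) must translate exactly to its ungapped
#' protein; a mismatch is reported with the gene and first offending
#' position. Gap columns carry the marker `"---"`.
#'
#' @param protein_alignment named character vector of equal-length aligned
#'   protein sequences (2 or 3 records; gaps as `-`).
#' @param cds named character vector of coding sequences (same names),
#'   each a valid CDS including the stop codon.
#' @param roles character vector assigning roles to records, by position:
#'   defaults to `c("principal", "sister", "outgroup")[seq_along()]`.
#' @return object of class `codon_alignment`: list with `codons` and `aa`
#'   (role-by-column character matrices), `gene_ids` (named by role) and
#'   `n_col`.
#' @export
build_codon_alignment <- function(protein_alignment, cds, roles = NULL) {
  n <- length(protein_alignment)
  if (n < 2L || n > 3L)
    stop("akashi_alignment_too_small: need 2 or 3 sequences")
  if (is.null(roles)) roles <- c("principal", "sister", "outgroup")[seq_len(n)]
  ids <- names(protein_alignment)
  if (!all(ids %in% names(cds)))
    stop("akashi_missing_cds: no CDS for ",
         paste(setdiff(ids, names(cds)), collapse = ", "))
  n_col <- unique(nchar(protein_alignment))
  if (length(n_col) != 1L)
    stop("akashi_unequal_alignment: aligned sequences differ in length")
  codon_mat <- matrix(GAP_CODON, nrow = n, ncol = n_col,
                      dimnames = list(roles, NULL))
  aa_mat <- matrix("-", nrow = n, ncol = n_col, dimnames = list(roles, NULL))
  for (k in seq_len(n)) {
    aln_chars <- strsplit(protein_alignment[[k]], "")[[1]]
    seq <- toupper(cds[[ids[k]]])
    body <- substr(seq, 1L, nchar(seq) - 3L)       # strip stop codon
    codons <- split_codons(body)
    trans <- translate_codons(codons)
    prot <- aln_chars[aln_chars != "-"]
    if (length(prot) != length(codons))
      stop("akashi_translation_mismatch: gene ", ids[k],
           ": CDS has ", length(codons), " codons but protein has ",
           length(prot), " residues")
    bad <- which(trans != prot)
    if (length(bad))
      stop("akashi_translation_mismatch: gene ", ids[k],
           ": CDS codon ", bad[1], " (", codons[bad[1]],
           ") translates to ", trans[bad[1]], ", protein has ",
           prot[bad[1]])
    nongap <- which(aln_chars != "-")
    codon_mat[k, nongap] <- codons
    aa_mat[k, ] <- aln_chars
  }
  structure(list(codons = codon_mat, aa = aa_mat,
                 gene_ids = stats::setNames(ids, roles), n_col = n_col),
            class = "codon_alignment")
}

# Skeleton site table shared by the classifiers.
.site_frame <- function(aln) {
  principal_gap <- aln$aa["principal", ] == "-"
  prot_pos <- rep(NA_integer_, aln$n_col)
  prot_pos[!principal_gap] <- seq_len(sum(!principal_gap))
  data.frame(
    gene = unname(aln$gene_ids[["principal"]]),
    column = seq_len(aln$n_col),
    prot_pos = prot_pos,
    codon = aln$codons["principal", ],
    codon_sister = aln$codons[if ("sister" %in% rownames(aln$codons))
      "sister" else 2L, ],
    stringsAsFactors = FALSE
  )
}

#' Classify sites of a two-species codon alignment
#'
#' A column is conserved when both amino acids are present and identical,
#' variable when both are present and different, and excluded when either
#' sequence has a gap or either codon contains an ambiguous base.
#'
#' @param aln a 2-species [build_codon_alignment()] result.
#' @return a site table (see package overview) with `state` in
#'   `conserved`/`variable`/`excluded` and `lineage` = `"none"`.
#' @export
classify_pairwise <- function(aln) {
  sites <- .site_frame(aln)
  a1 <- aln$aa[1L, ]; a2 <- aln$aa[2L, ]
  ok <- a1 != "-" & a2 != "-" & .codons_clean(aln$codons[1L, ]) &
    .codons_clean(aln$codons[2L, ])
  sites$state <- ifelse(!ok, "excluded",
                        ifelse(a1 == a2, "conserved", "variable"))
  sites$lineage <- "none"
  sites
}

.ACGT_TRIPLETS <- as.vector(outer(outer(BASES, BASES, paste0), BASES,
                                  paste0))

.codons_clean <- function(codons) {
  codons %in% c(GAP_CODON, .ACGT_TRIPLETS)
}

#' Classify sites of a three-species alignment by lineage of change
#'
#' For the fixed rooted topology ((principal, sister), outgroup), each
#' column is assigned by single-column parsimony: all three identical is
#' conserved; principal = outgroup differing from sister is variable with
#' the change on the sister branch (the only variable class used
#' downstream); sister = outgroup differing from principal places the
#' change on the principal branch (excluded); principal = sister differing
#' from outgroup cannot be resolved between the outgroup branch and the
#' internal branch (excluded); three distinct amino acids are ambiguous
#' (excluded); columns with gaps or ambiguous bases are excluded.
#'
#' @param aln a 3-species [build_codon_alignment()] result with roles
#'   principal, sister, outgroup.
#' @return a site table with `state` and `lineage` in
#'   `sister`/`principal`/`outgroup-or-ancestral`/`ambiguous`/`none`.
#' @export
classify_phylogeny <- function(aln) {
  if (!all(c("principal", "sister", "outgroup") %in% rownames(aln$aa)))
    stop("akashi_missing_outgroup: need principal, sister and outgroup")
  sites <- .site_frame(aln)
  p <- aln$aa["principal", ]; s <- aln$aa["sister", ]; o <- aln$aa["outgroup", ]
  ok <- p != "-" & s != "-" & o != "-" &
    .codons_clean(aln$codons["principal", ]) &
    .codons_clean(aln$codons["sister", ]) &
    .codons_clean(aln$codons["outgroup", ])
  state <- rep("excluded", aln$n_col)
  lineage <- rep("none", aln$n_col)
  cons <- ok & p == s & s == o
  vsis <- ok & p == o & p != s
  vpri <- ok & s == o & s != p
  vout <- ok & p == s & p != o
  vamb <- ok & p != s & s != o & p != o
  state[cons] <- "conserved"
  state[vsis] <- "variable";  lineage[vsis] <- "sister"
  lineage[vpri] <- "principal"
  lineage[vout] <- "outgroup-or-ancestral"
  lineage[vamb] <- "ambiguous"
  sites$state <- state
  sites$lineage <- lineage
  sites
}

#' Optimality-tied filter for variable codon pairs
#'
#' Retains a variable site only when the two codons (i) share the same
#' third (silent) base, (ii) belong to families with the same favored
#' third base, and (iii), when the codons differ at both the first and
#' second positions, every intermediate codon on both substitution
#' orderings is a sense codon whose family has that same favored base
#' (the third base is unchanged along such pathways by construction).
#' Identical codons pass vacuously.
#'
#' @param codon_a,codon_b equal-length character vectors of sense codons
#'   observed at variable sites (principal and partner codon).
#' @param favored_base named character vector mapping family keys (see
#'   [codon_table()]) to the favored third base; `NA` marks families
#'   without one.
#' @param split_sixfold passed to [codon_table()].
#' @return data.frame with `keep` (logical) and `reason` (`"ok"`,
#'   `"silent-base-changed"`, `"no-favored-base"`,
#'   `"favored-base-differs"`, `"pathway-through-stop"`,
#'   `"pathway-favored-base-differs"`).
#' @export
optimality_tied_filter <- function(codon_a, codon_b, favored_base,
                                   split_sixfold = FALSE) {
  stopifnot(length(codon_a) == length(codon_b))
  ct <- codon_table(split_sixfold)
  fav_of <- function(codon) {
    fam <- ct$family_of[codon]
    ifelse(is.na(fam), NA_character_, unname(favored_base[fam]))
  }
  n <- length(codon_a)
  keep <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    a <- codon_a[i]; b <- codon_b[i]
    if (!is_sense_codon(a) || !is_sense_codon(b))
      stop("akashi_bad_codon: not a sense codon: ",
           paste(a, b, collapse = "/"))
    if (a == b) { keep[i] <- TRUE; reason[i] <- "ok"; next }
    if (substr(a, 3, 3) != substr(b, 3, 3)) {
      reason[i] <- "silent-base-changed"; next
    }
    fa <- fav_of(a); fb <- fav_of(b)
    if (is.na(fa) || is.na(fb)) { reason[i] <- "no-favored-base"; next }
    if (fa != fb) { reason[i] <- "favored-base-differs"; next }
    diff_pos <- which(c(substr(a, 1, 1) != substr(b, 1, 1),
                        substr(a, 2, 2) != substr(b, 2, 2)))
    if (length(diff_pos) == 2L) {
      inter <- c(paste0(substr(b, 1, 1), substr(a, 2, 2), substr(a, 3, 3)),
                 paste0(substr(a, 1, 1), substr(b, 2, 2), substr(a, 3, 3)))
      if (any(inter %in% STOP_CODONS)) {
        reason[i] <- "pathway-through-stop"; next
      }
      fi <- fav_of(inter)
      if (any(is.na(fi)) || any(fi != fa)) {
        reason[i] <- "pathway-favored-base-differs"; next
      }
    }
    keep[i] <- TRUE; reason[i] <- "ok"
  }
  data.frame(keep = keep, reason = reason, stringsAsFactors = FALSE)
}

#' Apply the optimality-tied filter to a site table
#'
#' Variable sites failing [optimality_tied_filter()] are demoted to
#' excluded; the drop reason is recorded in a `tied_reason` column.
#'
#' @param sites a site table from a classifier.
#' @param favored_base named favored-third-base map (see
#'   [optimality_tied_filter()]).
#' @param split_sixfold passed down.
#' @return the site table with updated `state` and a `tied_reason` column.
#' @export
apply_optimality_filter <- function(sites, favored_base,
                                    split_sixfold = FALSE) {
  sites$tied_reason <- NA_character_
  idx <- which(sites$state == "variable")
  if (length(idx)) {
    res <- optimality_tied_filter(sites$codon[idx], sites$codon_sister[idx],
                                  favored_base, split_sixfold)
    sites$tied_reason[idx] <- res$reason
    sites$state[idx[!res$keep]] <- "excluded"
  }
  sites
}

#' Flag sites inside protein domains
#'
#' @param sites a site table.
#' @param domains data.frame as from [read_domain_table()] (rows for other
#'   genes are ignored).
#' @param protein_length length of the principal protein; defaults to the
#'   largest `prot_pos` in `sites`.
#' @return the site table with a logical `in_domain` column (gap columns
#'   stay `FALSE`).
#' @export
annotate_domain <- function(sites, domains,
                            protein_length = max(sites$prot_pos,
                                                 na.rm = TRUE)) {
  d <- domains[domains$gene_id == sites$gene[1], , drop = FALSE]
  if (nrow(d) && any(d$end > protein_length | d$start < 1L))
    stop("akashi_domain_out_of_range: coordinates exceed protein length")
  flag <- rep(FALSE, nrow(sites))
  for (j in seq_len(nrow(d))) {
    flag <- flag | (!is.na(sites$prot_pos) &
                      sites$prot_pos >= d$start[j] &
                      sites$prot_pos <= d$end[j])
  }
  sites$in_domain <- flag
  sites
}

# Merge possibly-overlapping domain intervals into a disjoint region mask.
merge_intervals <- function(start, end) {
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (j in seq_along(start)[-1]) {
    if (start[j] <= me + 1L) me <- max(me, end[j])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[j]; me <- end[j] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Classify codon third bases as stem (S) or loop (L)
#'
#' Codon i is an S-codon when its third base (structure position
#' `cds_offset + 3*i`) is paired in the dot-bracket and, when pairing
#' probabilities are available, its probability is at least
#' `strong_threshold`; all other codons are L-codons. Gap columns stay
#' `"unknown"`.
#'
#' @param sites a site table.
#' @param structure list with `structure` (dot-bracket string) and
#'   optional `pair_prob`, as from [read_structure_file()].
#' @param strong_threshold strong-pairing probability cutoff (default
#'   0.9).
#' @param cds_offset 0-based offset of the CDS within the structure string
#'   (for mature mRNA with a 5' UTR); default 0 (CDS coordinates).
#' @return the site table with a `struct_class` column in
#'   `"S"`/`"L"`/`"unknown"`.
#' @export
annotate_structure <- function(sites, structure, strong_threshold = 0.9,
                               cds_offset = 0L) {
  n_codons <- max(sites$prot_pos, na.rm = TRUE)
  need <- cds_offset + 3L * n_codons
  if (nchar(structure$structure) < need)
    stop("akashi_structure_too_short: structure has ",
         nchar(structure$structure), " bases, need ", need)
  ch <- strsplit(structure$structure, "")[[1]]
  cls <- rep("unknown", nrow(sites))
  idx <- which(!is.na(sites$prot_pos))
  pos3 <- cds_offset + 3L * sites$prot_pos[idx]
  paired <- ch[pos3] %in% c("(", ")")
  if (!is.null(structure$pair_prob))
    paired <- paired & structure$pair_prob[pos3] >= strong_threshold
  cls[idx] <- ifelse(paired, "S", "L")
  sites$struct_class <- cls
  sites
}

#' Assign transcript thirds to sites
#'
#' Splits the principal CDS into three contiguous blocks of
#' `floor(L/3)` codons with the remainder in the last block, and labels
#' each site 1, 2 or 3 by its ungapped codon index.
#'
#' @param sites a site table.
#' @param n_codons principal CDS length in codons (stop excluded);
#'   defaults to the largest `prot_pos`.
#' @return the site table with an integer `third` column (NA at gaps).
#' @export
assign_thirds <- function(sites, n_codons = max(sites$prot_pos,
                                                na.rm = TRUE)) {
  block <- n_codons %/% 3L
  if (block == 0L)
    warning("CDS shorter than 3 codons; all sites assigned to third 3")
  third <- rep(NA_integer_, nrow(sites))
  idx <- which(!is.na(sites$prot_pos))
  p <- sites$prot_pos[idx]
  third[idx] <- ifelse(p <= block, 1L, ifelse(p <= 2L * block, 2L, 3L))
  sites$third <- third
  sites
}

#' Export site classifications as a TSV pseudoalignment
#'
#' One row per aligned column with the gene, column index, state, lineage
#' and any annotation flags present.
#'
#' @param sites a site table or a list of site tables (rbind-ed).
#' @param path output TSV path.
#' @export
export_site_classification <- function(sites, path) {
  if (!is.data.frame(sites)) sites <- do.call(rbind, sites)
  write_tsv(sites, path)
}
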