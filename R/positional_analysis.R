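# Variation of the accuracy signal and of Fop along the transcript:
# adjacent windows of five amino acids pooled across genes into
# per-window superalignments and supersequences.

#' Pool sites into adjacent positional windows
#'
#' Splits each gene's sites into adjacent windows of `window` amino acids
#' by the ungapped codon index of the principal species (gap columns are
#' skipped and do not shift window boundaries). A gene contributes a
#' window only when it is long enough to fill it completely; trailing
#' incomplete windows are dropped.
#'
#' @param sites a site table or rbind of site tables (columns `gene`,
#'   `prot_pos`, `codon`, `state`).
#' @param window window length in amino acids (default 5).
#' @return list of site-table subsets, one per window index (named by
#'   index); empty list for empty input.
#' @export
build_window_pools <- function(sites, window = 5L) {
  if (nrow(sites) == 0L) return(list())
  sites <- sites[!is.na(sites$prot_pos), , drop = FALSE]
  win <- (sites$prot_pos - 1L) %/% window + 1L
  gene_len <- tapply(sites$prot_pos, sites$gene, max)
  n_complete <- as.integer(gene_len[sites$gene]) %/% window
  keep <- win <= n_complete
  sites <- sites[keep, , drop = FALSE]
  win <- win[keep]
  if (nrow(sites) == 0L) return(list())
  split(sites, win)
}

#' Per-window Akashi odds ratio and Fop profile
#'
#' For each window pool, runs the Akashi test on the pooled sites (strata
#' are genes within the window) and computes Fop on the window
#' supersequence (all principal codons of the pool). Windows without an
#' informative stratum get an undefined OR.
#'
#' @param pools list from [build_window_pools()].
#' @param optimal_codons character vector or `optimal_codon_set`.
#' @param window window length in amino acids used to build the pools
#'   (for the reported start-codon coordinate).
#' @param split_sixfold passed down.
#' @return data.frame with `window`, `start_codon`, `or`, `chisq`, `p`,
#'   `fop`, `n_genes`, `n_codons`.
#' @export
positional_profiles <- function(pools, optimal_codons, window = 5L,
                                split_sixfold = FALSE) {
  if (inherits(optimal_codons, "optimal_codon_set"))
    optimal_codons <- optimal_codons$optimal_codons
  rows <- lapply(names(pools), function(w) {
    pool <- pools[[w]]
    res <- tryCatch(
      akashi_test(pool, optimal_codons, split_sixfold = split_sixfold),
      error = function(e) NULL)
    wi <- as.integer(w)
    data.frame(
      window = wi,
      start_codon = (wi - 1L) * window + 1L,
      or = if (is.null(res)) NA_real_ else res$or,
      chisq = if (is.null(res)) NA_real_ else res$chisq,
      p = if (is.null(res)) NA_real_ else res$p,
      fop = fop(pool$codon[pool$codon != GAP_CODON], optimal_codons,
                split_sixfold),
      n_genes = length(unique(pool$gene)),
      n_codons = sum(pool$codon != GAP_CODON),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$window), , drop = FALSE]
}
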