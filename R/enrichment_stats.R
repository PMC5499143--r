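# Statistical core: per-gene 2x2 strata, Mantel-Haenszel pooled odds
# ratios with significance, codon enrichment scans over all degenerate
# sense codons, optimal-codon identification from expression contrast,
# the Akashi test, tRNA-RSCU and correlation utilities.

#' Build per-gene 2x2 contingency strata for a focal codon
#'
#' For each gene, counts occurrences of the focal codon and of its
#' synonymous peers in two site classes A and B. The counts form the 2x2
#' table (a = focal in A, b = peers in A, c = focal in B, d = peers in B).
#' Genes containing no codon of the focal family are omitted. A stratum is
#' informative when both row sums and both column sums are positive.
#'
#' @param gene character vector of gene ids, one per counted codon site.
#' @param codon character vector of codons at those sites.
#' @param class character vector with values `"A"`, `"B"` or `NA` (sites
#'   with `NA` are dropped).
#' @param focal the focal codon (must belong to a family of degeneracy
#'   >= 2).
#' @param split_sixfold passed to [codon_table()].
#' @return data.frame with columns `gene`, `a`, `b`, `c`, `d`,
#'   `informative`.
#' @export
build_strata <- function(gene, codon, class, focal, split_sixfold = FALSE) {
  peers <- synonymous_peers(focal, split_sixfold)
  if (length(peers) == 0L)
    stop("akashi_no_peers: focal codon ", focal,
         " belongs to a single-codon family")
  keep <- !is.na(class) & codon %in% c(focal, peers)
  gene <- gene[keep]; codon <- codon[keep]; class <- class[keep]
  if (length(gene) == 0L)
    return(data.frame(gene = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      informative = logical(0), stringsAsFactors = FALSE))
  is_focal <- codon == focal
  g <- factor(gene, levels = unique(gene))
  a <- tapply(is_focal & class == "A", g, sum)
  b <- tapply(!is_focal & class == "A", g, sum)
  cc <- tapply(is_focal & class == "B", g, sum)
  d <- tapply(!is_focal & class == "B", g, sum)
  out <- data.frame(gene = levels(g), a = as.integer(a), b = as.integer(b),
                    c = as.integer(cc), d = as.integer(d),
                    stringsAsFactors = FALSE)
  out$informative <- with(out, (a + b) > 0 & (c + d) > 0 &
                            (a + c) > 0 & (b + d) > 0)
  out
}

#' Mantel-Haenszel pooled odds ratio over 2x2 strata
#'
#' Computes the Mantel-Haenszel common odds ratio
#' `OR = sum(a*d/N) / sum(b*c/N)` and the Mantel-Haenszel chi-square
#' statistic with continuity correction (two-sided). When a pooled
#' numerator or denominator sum is exactly zero the odds ratio is
#' undefined (`NA`) unless `continuity = TRUE`, in which case 0.5 is added
#' to every cell of every informative stratum and the result flagged.
#'
#' @param strata data.frame with integer columns `a`, `b`, `c`, `d` (one
#'   row per stratum), e.g. from [build_strata()].
#' @param correct logical; apply the 0.5 continuity correction to the
#'   chi-square statistic (default `TRUE`).
#' @param continuity logical; force a finite odds-ratio estimate when a
#'   pooled sum is zero (default `FALSE`).
#' @return object of class `enrichment_result`: list with `or`, `chisq`,
#'   `p`, `n_strata` (informative strata), `continuity_used`.
#' @examples
#' mantel_haenszel(data.frame(a = c(10, 8), b = c(5, 2),
#'                            c = c(5, 4), d = c(10, 6)))$or  # ~4.649
#' @export
mantel_haenszel <- function(strata, correct = TRUE, continuity = FALSE) {
  a <- as.numeric(strata$a); b <- as.numeric(strata$b)
  cc <- as.numeric(strata$c); d <- as.numeric(strata$d)
  N <- a + b + cc + d
  informative <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  if (!any(informative))
    stop("akashi_no_informative_strata: all strata have a zero margin")
  num <- sum((a * d / N)[N > 0])
  den <- sum((b * cc / N)[N > 0])
  continuity_used <- FALSE
  if ((num == 0 || den == 0) && continuity) {
    a2 <- a[informative] + 0.5; b2 <- b[informative] + 0.5
    c2 <- cc[informative] + 0.5; d2 <- d[informative] + 0.5
    N2 <- a2 + b2 + c2 + d2
    num <- sum(a2 * d2 / N2); den <- sum(b2 * c2 / N2)
    continuity_used <- TRUE
  }
  or <- if (den == 0) NA_real_ else num / den
  # chi-square over strata with N >= 2 (variance needs N - 1 > 0)
  use <- N >= 2
  A <- sum(a[use])
  E <- sum(((a + b) * (a + cc) / N)[use])
  V <- sum(((a + b) * (cc + d) * (a + cc) * (b + d) /
              (N^2 * (N - 1)))[use])
  if (V > 0) {
    delta <- abs(A - E)
    # Yates correction only when it cannot overshoot past zero
    yates <- if (correct && delta >= 0.5) 0.5 else 0
    chisq <- (delta - yates)^2 / V
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  structure(list(or = or, chisq = chisq, p = p,
                 n_strata = sum(informative),
                 continuity_used = continuity_used),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Mantel-Haenszel pooled odds ratio\n")
  cat(sprintf("  OR = %.4f, chi-square = %.3f, p = %.4g (%d informative strata)\n",
              x$or, x$chisq, x$p, x$n_strata))
  invisible(x)
}

#' Codon enrichment scan over all degenerate sense codons
#'
#' Runs [build_strata()] + [mantel_haenszel()] for every sense codon in a
#' family of degeneracy >= 2 (59 codons under the unsplit standard code).
#' The orientation is: OR > 1 means the focal codon is relatively enriched
#' in class A.
#'
#' @inheritParams build_strata
#' @param correct passed to [mantel_haenszel()].
#' @return data.frame with one row per focal codon: `codon`, `family`,
#'   `or`, `chisq`, `p`, `n_strata`.
#' @export
codon_enrichment_scan <- function(gene, codon, class, split_sixfold = FALSE,
                                  correct = TRUE) {
  ct <- codon_table(split_sixfold)
  focals <- degenerate_sense_codons(split_sixfold)
  rows <- lapply(focals, function(f) {
    st <- build_strata(gene, codon, class, f, split_sixfold)
    st <- st[st$informative, , drop = FALSE]
    if (nrow(st) == 0L)
      return(data.frame(codon = f, family = unname(ct$family_of[f]),
                        or = NA_real_, chisq = NA_real_, p = NA_real_,
                        n_strata = 0L, stringsAsFactors = FALSE))
    r <- mantel_haenszel(st, correct = correct)
    data.frame(codon = f, family = unname(ct$family_of[f]), or = r$or,
               chisq = r$chisq, p = r$p, n_strata = r$n_strata,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average codon odds ratios over several comparisons
#'
#' Arithmetic mean of the per-comparison odds ratios for each codon
#' (undefined ORs skipped and counted), plus the per-comparison mean
#' absolute deviation from the neutral value 1 as a dispersion summary.
#'
#' @param scans named list of [codon_enrichment_scan()] results, one per
#'   comparison.
#' @param log_scale logical; average on the log scale (geometric mean)
#'   instead of the natural scale (default `FALSE`).
#' @return list with `per_codon` (data.frame `codon`, `mean_or`, `sd_or`,
#'   `n_used`, `n_skipped`) and `deviation` (data.frame `comparison`,
#'   `mean_abs_dev`).
#' @export
average_over_comparisons <- function(scans, log_scale = FALSE) {
  codons <- scans[[1]]$codon
  mat <- vapply(scans, function(s) s$or[match(codons, s$codon)],
                numeric(length(codons)))
  mat <- matrix(mat, nrow = length(codons),
                dimnames = list(codons, names(scans)))
  agg <- if (log_scale) function(v) exp(mean(log(v))) else mean
  per_codon <- data.frame(
    codon = codons,
    mean_or = apply(mat, 1L, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) agg(v) else NA_real_
    }),
    sd_or = apply(mat, 1L, function(v) stats::sd(v[is.finite(v)])),
    n_used = apply(mat, 1L, function(v) sum(is.finite(v))),
    n_skipped = apply(mat, 1L, function(v) sum(!is.finite(v))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  deviation <- data.frame(
    comparison = colnames(mat),
    mean_abs_dev = apply(mat, 2L, function(v)
      mean(abs(v[is.finite(v)] - 1))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(per_codon = per_codon, deviation = deviation)
}

# Codon counts of a set of CDS (stop codons and ambiguous codons
# excluded), as a named integer vector over the 61 sense codons.
count_codons <- function(sequences) {
  codons <- unlist(lapply(sequences, function(s) {
    cs <- split_codons(toupper(s))
    cs[length(cs)] <- NA  # stop codon
    cs
  }), use.names = FALSE)
  codons <- codons[!is.na(codons) & is_sense_codon(codons)]
  tab <- table(factor(codons, levels = names(.CODE$sense)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Identify optimal codons from an expression contrast
#'
#' Genes are scored by the mean of log10(expression) over the experiments
#' in which they are expressed (value > `expressed_min`); unexpressed
#' genes are dropped. The top and bottom `quantile` of ranked genes form
#' the high- and low-expression sets. For every degenerate sense codon a
#' pooled 2x2 table (focal vs synonymous peers, high vs low set) is
#' tested by chi-square; codons with OR > 1 and p < `alpha` are optimal.
#' When a cell is zero the odds ratio uses a 0.5 addition to every cell
#' (flagged). The favored third base of each family is the unique third
#' base of its optimal codons (`NA` when the family has none, or when its
#' optimal codons disagree).
#'
#' @param cds data.frame from [read_cds_fasta()] (invalid records are
#'   ignored).
#' @param expression data.frame from [read_expression_table()].
#' @param quantile fraction of ranked genes in each expression set
#'   (default 0.20).
#' @param alpha per-codon significance level (default 0.05, two-sided; no
#'   multiple-testing correction unless `p_adjust = "BH"`).
#' @param expressed_min expression threshold defining "expressed"
#'   (default 100, exclusive).
#' @param min_genes minimum number of ranked genes required (default 10).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param split_sixfold passed to [codon_table()].
#' @return object of class `optimal_codon_set`: list with `table`
#'   (per-codon counts, `or`, `p`, `optimal`, `haldane` flag),
#'   `optimal_codons`, `favored_base` (named by family), `high_genes`,
#'   `low_genes`, `alpha`.
#' @export
identify_optimal_codons <- function(cds, expression, quantile = 0.20,
                                    alpha = 0.05, expressed_min = 100,
                                    min_genes = 10, p_adjust = "none",
                                    split_sixfold = FALSE) {
  cds <- cds[cds$valid, , drop = FALSE]
  expr <- expression[!is.na(expression$value) &
                       expression$value > expressed_min, , drop = FALSE]
  mean_log <- tapply(log10(expr$value), expr$gene_id, mean)
  genes <- intersect(cds$gene_id, names(mean_log))
  if (length(genes) < min_genes)
    stop("akashi_too_few_genes: only ", length(genes),
         " ranked genes (need ", min_genes, ")")
  score <- mean_log[genes]
  # rank descending; ties broken by stable gene-id order
  o <- order(-score, genes)
  n_set <- max(1L, floor(quantile * length(genes)))
  high <- genes[o[seq_len(n_set)]]
  low <- genes[rev(o)[seq_len(n_set)]]
  seq_of <- stats::setNames(cds$sequence, cds$gene_id)
  high_counts <- count_codons(seq_of[high])
  low_counts <- count_codons(seq_of[low])
  ct <- codon_table(split_sixfold)
  focals <- degenerate_sense_codons(split_sixfold)
  rows <- lapply(focals, function(f) {
    fam <- ct$families[[ct$family_of[[f]]]]
    peers <- setdiff(fam, f)
    a <- high_counts[[f]]; b <- sum(high_counts[peers])
    cc <- low_counts[[f]]; d <- sum(low_counts[peers])
    haldane <- any(c(a, b, cc, d) == 0)
    or <- if (haldane) (a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5))
          else a * d / (b * cc)
    p <- if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
      NA_real_
    else suppressWarnings(stats::chisq.test(
      matrix(c(a, b, cc, d), 2, byrow = TRUE), correct = FALSE)$p.value)
    data.frame(codon = f, family = unname(ct$family_of[f]),
               count_high = a, count_low = cc, or = or, p = p,
               haldane = haldane, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  p_use <- if (identical(p_adjust, "BH"))
    stats::p.adjust(tab$p, "BH") else tab$p
  tab$optimal <- !is.na(p_use) & tab$or > 1 & p_use < alpha
  structure(list(table = tab, optimal_codons = tab$codon[tab$optimal],
                 favored_base = favored_base_map(tab$codon[tab$optimal],
                                                 split_sixfold),
                 high_genes = high, low_genes = low, alpha = alpha),
            class = "optimal_codon_set")
}

#' Favored third base per synonymous family
#'
#' @param optimal_codons character vector of optimal codons.
#' @param split_sixfold passed to [codon_table()].
#' @return named character vector over all families of degeneracy >= 2;
#'   the unique third base of the family's optimal codons, or `NA` when
#'   the family has no optimal codon or its optimal codons disagree.
#' @export
favored_base_map <- function(optimal_codons, split_sixfold = FALSE) {
  ct <- codon_table(split_sixfold)
  fams <- names(ct$degeneracy)[ct$degeneracy >= 2L]
  out <- stats::setNames(rep(NA_character_, length(fams)), fams)
  for (f in fams) {
    opt <- intersect(optimal_codons, ct$families[[f]])
    tb <- unique(third_base(opt))
    if (length(tb) == 1L) out[[f]] <- tb
  }
  out
}

#' The Akashi test: optimal-codon usage at conserved vs variable sites
#'
#' Per gene, counts optimal and nonoptimal codons (restricted to families
#' containing at least one optimal codon) at conserved and variable sites,
#' and pools the per-gene 2x2 tables with [mantel_haenszel()]. OR > 1
#' means optimal codons are preferentially used at conserved sites.
#'
#' @param sites a site table (or rbind of site tables) with columns
#'   `gene`, `codon`, `state`.
#' @param optimal_codons character vector of optimal codons, or an
#'   `optimal_codon_set`.
#' @param mask optional logical vector over rows of `sites` restricting
#'   the test (e.g. domain-only or stem-only sites).
#' @param split_sixfold passed to [codon_table()].
#' @param correct passed to [mantel_haenszel()].
#' @return an `enrichment_result` (see [mantel_haenszel()]), with the
#'   per-gene strata attached as attribute `"strata"`.
#' @export
akashi_test <- function(sites, optimal_codons, mask = NULL,
                        split_sixfold = FALSE, correct = TRUE) {
  if (inherits(optimal_codons, "optimal_codon_set"))
    optimal_codons <- optimal_codons$optimal_codons
  if (length(optimal_codons) == 0L)
    stop("akashi_empty_optimal_set: no optimal codons")
  if (!is.null(mask)) {
    sites <- sites[mask, , drop = FALSE]
    if (nrow(sites) == 0L)
      stop("akashi_empty_mask: no sites left after masking")
  }
  ct <- codon_table(split_sixfold)
  opt_fams <- unique(ct$family_of[intersect(optimal_codons,
                                            names(ct$family_of))])
  counted_fams <- opt_fams[ct$degeneracy[opt_fams] >= 2L]
  m <- match(sites$codon, names(ct$family_of))
  fam <- unname(ct$family_of)[m]
  keep <- (sites$state == "conserved" | sites$state == "variable") &
    !is.na(m) & fam %in% counted_fams
  s <- list(gene = sites$gene[keep], codon = sites$codon[keep],
            state = sites$state[keep])
  s <- as.data.frame(s, stringsAsFactors = FALSE)
  if (nrow(s) == 0L)
    stop("akashi_empty_mask: no countable sites")
  is_opt <- s$codon %in% optimal_codons
  is_cons <- s$state == "conserved"
  g <- factor(s$gene, levels = unique(s$gene))
  counts <- rowsum(cbind(a = is_opt & is_cons, b = !is_opt & is_cons,
                         c = is_opt & !is_cons, d = !is_opt & !is_cons) + 0L,
                   g)
  strata <- data.frame(
    gene = rownames(counts),
    a = as.integer(counts[, "a"]), b = as.integer(counts[, "b"]),
    c = as.integer(counts[, "c"]), d = as.integer(counts[, "d"]),
    stringsAsFactors = FALSE
  )
  strata$informative <- with(strata, (a + b) > 0 & (c + d) > 0 &
                               (a + c) > 0 & (b + d) > 0)
  res <- mantel_haenszel(strata[strata$informative, , drop = FALSE],
                         correct = correct)
  attr(res, "strata") <- strata
  res
}

#' tRNA-RSCU from tRNA gene copy counts
#'
#' Normalises tRNA gene copy numbers analogously to the relative
#' synonymous codon usage: `RSCU_i = n * copies_i / sum(family copies)`,
#' with `n` the degeneracy of the codon's family. Within each family with
#' a positive copy total the values sum to `n`; families with zero total
#' get `NA` and are flagged.
#'
#' @param copies named non-negative integer vector, codon -> cognate tRNA
#'   gene copies (missing sense codons count as 0).
#' @param split_sixfold passed to [codon_table()].
#' @return data.frame with `codon`, `family`, `copies`, `rscu`,
#'   `defined`.
#' @export
trna_rscu <- function(copies, split_sixfold = FALSE) {
  if (any(copies < 0)) stop("akashi_negative_copies: counts must be >= 0")
  ct <- codon_table(split_sixfold)
  codons <- names(ct$family_of)
  full <- stats::setNames(rep(0, length(codons)), codons)
  hit <- intersect(names(copies), codons)
  full[hit] <- copies[hit]
  fam <- ct$family_of[codons]
  fam_tot <- tapply(full, fam, sum)[fam]
  n <- ct$degeneracy[fam]
  rscu <- ifelse(fam_tot > 0, n * full / fam_tot, NA_real_)
  data.frame(codon = codons, family = unname(fam),
             copies = unname(full), rscu = unname(rscu),
             defined = unname(fam_tot > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation with optional permutation p-value
#'
#' Pearson or Spearman correlation of two paired series (entries with
#' `NA` in either series are dropped pairwise), with the analytic p-value
#' and, when `permutations > 0`, an empirical p-value from random label
#' permutations of `y`. When `groups` is supplied (a grouping factor of
#' equal-sized blocks, e.g. species), the permutation instead reassigns
#' the whole per-group subvectors of `y` among groups, preserving the
#' within-group correlation structure.
#'
#' @param x,y equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param permutations number of permutation replicates (0 = analytic p
#'   only). Uses the current RNG state; seed with [set.seed()].
#' @param groups optional grouping vector for structured permutation.
#' @return list with `estimate`, `p_analytic`, `p_perm` (`NA` when no
#'   permutations), `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      permutations = 0, groups = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(groups)) groups <- groups[ok]
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("akashi_too_few_pairs: need >= 3 complete pairs")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  r_obs <- unname(ht$estimate)
  p_perm <- NA_real_
  if (permutations > 0) {
    r_perm <- numeric(permutations)
    if (is.null(groups)) {
      for (i in seq_len(permutations))
        r_perm[i] <- stats::cor(x, sample(y), method = method)
    } else {
      gl <- split(seq_along(y), groups)
      sizes <- lengths(gl)
      if (length(unique(sizes)) != 1L)
        stop("akashi_unequal_groups: structured permutation needs ",
             "equal-sized groups")
      for (i in seq_len(permutations)) {
        perm <- sample(length(gl))
        y2 <- y
        for (k in seq_along(gl)) y2[gl[[k]]] <- y[gl[[perm[k]]]]
        r_perm[i] <- stats::cor(x, y2, method = method)
      }
    }
    p_perm <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (permutations + 1)
  }
  list(estimate = r_obs, p_analytic = ht$p.value, p_perm = p_perm,
       n = length(x), method = method)
}
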