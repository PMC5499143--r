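# Nucleotide-composition and codon-usage summary statistics: GC/GC3,
# sliding windows across domain boundaries, Wright's effective number of
# codons, Fop, and the high/low-GC gene split.

#' GC content of a nucleotide sequence
#'
#' Fraction of G+C bases. N bases are excluded from both numerator and
#' denominator.
#'
#' @param sequence non-empty nucleotide string.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("akashi_empty_sequence: need a non-empty sequence")
  ch <- strsplit(toupper(sequence), "")[[1]]
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) return(NaN)
  sum(ch %in% c("G", "C")) / length(ch)
}

#' GC content at third codon positions
#'
#' Fraction of G+C among the third bases of each codon of an in-frame
#' sequence. The sequence is used as given; strip the stop codon first
#' when it should not contribute (per-gene metrics in this package do).
#'
#' @param cds in-frame nucleotide string (length a multiple of 3).
#' @return fraction in [0, 1].
#' @export
gc3_content <- function(cds) {
  if (length(cds) != 1L || is.na(cds) || nchar(cds) == 0L)
    stop("akashi_empty_sequence: need a non-empty sequence")
  if (nchar(cds) %% 3L != 0L)
    stop("akashi_not_in_frame: length must be a multiple of 3")
  thirds <- strsplit(toupper(cds), "")[[1]][seq(3L, nchar(cds), by = 3L)]
  thirds <- thirds[thirds != "N"]
  if (length(thirds) == 0L) return(NaN)
  sum(thirds %in% c("G", "C")) / length(thirds)
}

#' Sliding-window GC and GC3 series
#'
#' Windows of `size` bases advanced by `step` bases (defaults 9 and 3,
#' matching a 3-amino-acid window stepped by one codon). GC is computed
#' over all bases in each window; GC3 over the third-codon-position bases
#' of the parent reading frame falling inside the window. Windows that
#' would run past the end are discarded.
#'
#' @param sequence in-frame nucleotide string.
#' @param size window size in bases (default 9).
#' @param step step in bases (default 3).
#' @return data.frame with `window`, `start` (1-based), `gc`, `gc3`;
#'   empty (with a warning) when the sequence is shorter than `size`.
#' @export
sliding_window_series <- function(sequence, size = 9L, step = 3L) {
  n <- nchar(sequence)
  if (n < size) {
    warning("sequence shorter than window size; empty series")
    return(data.frame(window = integer(0), start = integer(0),
                      gc = numeric(0), gc3 = numeric(0)))
  }
  ch <- strsplit(toupper(sequence), "")[[1]]
  is_gc <- ch %in% c("G", "C")
  is_n <- ch == "N"
  third_pos <- seq_len(n) %% 3L == 0L
  starts <- seq.int(1L, n - size + 1L, by = step)
  gc <- gc3 <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + size - 1L)
    use <- idx[!is_n[idx]]
    gc[k] <- sum(is_gc[use]) / length(use)
    t3 <- use[third_pos[use]]
    gc3[k] <- if (length(t3)) sum(is_gc[t3]) / length(t3) else NaN
  }
  data.frame(window = seq_along(starts), start = starts, gc = gc, gc3 = gc3)
}

#' Extract domain and flanking regions for composition analysis
#'
#' For each (merged) domain interval of at least `region_len` amino acids:
#' the first and last `region_len` codons of the domain (label
#' `"domain"`), and the `region_len`-codon flank immediately 5' and 3' of
#' the domain (label `"nondomain"`). Flanks that run off the protein are
#' rejected as too short; flanks overlapping another domain are rejected
#' as containing a domain. Domains shorter than `region_len` are rejected.
#'
#' @param cds coding sequence of the gene, including the stop codon.
#' @param domains data.frame with `start`, `end` (1-based inclusive
#'   protein coordinates) for this gene, e.g. the matching rows of
#'   [read_domain_table()].
#' @param region_len region length in codons (default 100).
#' @return list with `regions` (data.frame `region_type`, `label`,
#'   `start`, `end`, `sequence` - the nucleotide substring) and
#'   `rejected` (data.frame `region_type`, `start`, `end`, `reason`).
#' @export
extract_domain_regions <- function(cds, domains, region_len = 100L) {
  n_codons <- nchar(cds) %/% 3L - 1L   # stop codon excluded
  merged <- merge_intervals(domains$start, domains$end)
  regions <- list(); rejected <- list()
  add_region <- function(type, label, s, e) {
    nt <- substr(cds, 3L * (s - 1L) + 1L, 3L * e)
    regions[[length(regions) + 1L]] <<- data.frame(
      region_type = type, label = label, start = s, end = e,
      sequence = nt, stringsAsFactors = FALSE)
  }
  add_reject <- function(type, s, e, reason) {
    rejected[[length(rejected) + 1L]] <<- data.frame(
      region_type = type, start = s, end = e, reason = reason,
      stringsAsFactors = FALSE)
  }
  overlaps_domain <- function(s, e)
    any(merged$start <= e & merged$end >= s)
  for (j in seq_len(nrow(merged))) {
    ds <- merged$start[j]; de <- merged$end[j]
    if (de - ds + 1L < region_len) {
      add_reject("domain-5p", ds, de, "too-short")
      add_reject("domain-3p", ds, de, "too-short")
    } else {
      add_region("domain-5p", "domain", ds, ds + region_len - 1L)
      add_region("domain-3p", "domain", de - region_len + 1L, de)
    }
    fs <- ds - region_len; fe <- ds - 1L
    if (fs < 1L) add_reject("flank-5p", max(1L, fs), fe, "too-short")
    else if (overlaps_domain(fs, fe))
      add_reject("flank-5p", fs, fe, "contains-domain")
    else add_region("flank-5p", "nondomain", fs, fe)
    fs <- de + 1L; fe <- de + region_len
    if (fe > n_codons) add_reject("flank-3p", fs, min(fe, n_codons),
                                  "too-short")
    else if (overlaps_domain(fs, fe))
      add_reject("flank-3p", fs, fe, "contains-domain")
    else add_region("flank-3p", "nondomain", fs, fe)
  }
  list(
    regions = if (length(regions)) do.call(rbind, regions) else
      data.frame(region_type = character(0), label = character(0),
                 start = integer(0), end = integer(0),
                 sequence = character(0), stringsAsFactors = FALSE),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(region_type = character(0), start = integer(0),
                 end = integer(0), reason = character(0),
                 stringsAsFactors = FALSE)
  )
}

#' Compare composition between domain and nondomain regions
#'
#' Two-sided unpaired Wilcoxon rank-sum test of per-window values, with
#' the mean difference reported as domain minus nondomain in percentage
#' points.
#'
#' @param domain_values,nondomain_values numeric vectors of per-window
#'   fractions (e.g. GC3) in [0, 1].
#' @return list with `delta` (percentage points, domain - nondomain),
#'   `p` (Wilcoxon), `n_domain`, `n_nondomain`.
#' @export
compare_regions <- function(domain_values, nondomain_values) {
  if (length(domain_values) == 0L || length(nondomain_values) == 0L)
    stop("akashi_empty_group: both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(domain_values,
                                            nondomain_values))
  list(delta = 100 * (mean(domain_values) - mean(nondomain_values)),
       p = wt$p.value,
       n_domain = length(domain_values),
       n_nondomain = length(nondomain_values))
}

# Wright's degeneracy groups for the standard code (Met and Trp
# contribute the constant 2).
.ENC_GROUPS <- list(`2` = c("F", "Y", "H", "Q", "N", "K", "D", "E", "C"),
                    `3` = "I",
                    `4` = c("V", "P", "T", "A", "G"),
                    `6` = c("L", "S", "R"))

#' Effective number of codons (Wright's ENC)
#'
#' Wright's estimator: per synonymous family with at least two observed
#' codons, the homozygosity `F = (n * sum(p^2) - 1) / (n - 1)` with `n`
#' the family's codon count; the ENC is
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with each `Fk` the mean over estimated
#' families of that degeneracy. When no threefold family (Ile) can be
#' estimated, `F3` is imputed as `(F2 + F4) / 2`; when any other
#' degeneracy group has no estimate the statistic is undefined (`NA`).
#' Values are clamped to [20, 61].
#'
#' @param cds coding sequence (stop codon, if present as final triplet,
#'   is excluded) or a character vector of codons.
#' @return ENC in [20, 61], or `NA` when undefined.
#' @export
enc <- function(cds) {
  codons <- if (length(cds) == 1L && nchar(cds[1]) > 3L)
    split_codons(toupper(cds)) else toupper(cds)
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  codons <- codons[is_sense_codon(codons)]
  aa <- translate_codons(codons)
  f_hat <- function(counts) {
    n <- sum(counts)
    if (n < 2L) return(NA_real_)
    p <- counts / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  ct <- codon_table()
  group_mean <- vapply(.ENC_GROUPS, function(fams) {
    fs <- vapply(fams, function(f) {
      obs <- table(factor(codons[aa == f], levels = ct$families[[f]]))
      f_hat(as.integer(obs))
    }, numeric(1))
    fs <- fs[!is.na(fs) & fs > 0]
    if (length(fs)) mean(fs) else NA_real_
  }, numeric(1))
  if (is.na(group_mean[["3"]]) && !is.na(group_mean[["2"]]) &&
      !is.na(group_mean[["4"]]))
    group_mean[["3"]] <- (group_mean[["2"]] + group_mean[["4"]]) / 2
  if (any(is.na(group_mean))) return(NA_real_)
  nc <- 2 + 9 / group_mean[["2"]] + 1 / group_mean[["3"]] +
    5 / group_mean[["4"]] + 3 / group_mean[["6"]]
  min(61, max(20, nc))
}

#' Fraction of optimal codons (Fop)
#'
#' Count of optimal codons divided by the count of codons belonging to
#' families containing at least one optimal codon. Stop and ambiguous
#' codons are excluded.
#'
#' @param cds coding sequence or character vector of codons.
#' @param optimal_codons character vector of optimal codons, or an
#'   `optimal_codon_set`.
#' @param split_sixfold passed to [codon_table()].
#' @return fraction in [0, 1]; `NA` (with attribute) when no codon of an
#'   optimal-containing family is present.
#' @export
fop <- function(cds, optimal_codons, split_sixfold = FALSE) {
  if (inherits(optimal_codons, "optimal_codon_set"))
    optimal_codons <- optimal_codons$optimal_codons
  if (length(optimal_codons) == 0L)
    stop("akashi_empty_optimal_set: no optimal codons")
  codons <- if (length(cds) == 1L && nchar(cds[1]) > 3L)
    split_codons(toupper(cds)) else toupper(cds)
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  codons <- codons[is_sense_codon(codons)]
  ct <- codon_table(split_sixfold)
  opt_fams <- unique(ct$family_of[intersect(optimal_codons,
                                            names(ct$family_of))])
  in_fam <- ct$family_of[codons] %in% opt_fams
  if (!any(in_fam)) return(NA_real_)
  sum(codons[in_fam] %in% optimal_codons) / sum(in_fam)
}

#' Split coding sequences into high-GC and low-GC classes
#'
#' Partition by whole-CDS GC content with the boundary (default 60%)
#' inclusive to the high-GC class, the bimodality characteristic of grass
#' genomes.
#'
#' @param cds data.frame from [read_cds_fasta()].
#' @param threshold GC fraction boundary (default 0.60).
#' @return list with data.frames `hgc` and `lgc`; each gains a `gc`
#'   column.
#' @export
split_hgc_lgc <- function(cds, threshold = 0.60) {
  if (nrow(cds) == 0L) return(list(hgc = cds, lgc = cds))
  gc <- vapply(cds$sequence, gc_content, numeric(1), USE.NAMES = FALSE)
  cds$gc <- gc
  list(hgc = cds[gc >= threshold, , drop = FALSE],
       lgc = cds[gc < threshold, , drop = FALSE])
}
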