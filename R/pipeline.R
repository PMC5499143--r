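# End-to-end orchestration: turn an input bundle (simulated in memory or
# read from disk) into site tables, Akashi summaries, codon scans,
# composition tables and a positional profile.

#' Read an analysis bundle from a directory
#'
#' Expects the layout written by [write_bundle()]: `cds_<role>.fasta`,
#' `alignments/<gene>.fasta`, and optional `domains.tsv`,
#' `structure.txt`, `expression.tsv`, `trna.tsv`.
#'
#' @param dir bundle directory.
#' @return list with the same shape as [simulate_bundle()] output
#'   (without `truth`).
#' @export
read_bundle <- function(dir) {
  roles <- c("principal", "sister", "outgroup")
  cds <- list()
  for (r in roles) {
    f <- file.path(dir, paste0("cds_", r, ".fasta"))
    if (file.exists(f)) {
      d <- read_cds_fasta(f, species = r)
      cds[[r]] <- stats::setNames(d$sequence, d$gene_id)
    }
  }
  if (is.null(cds$principal))
    stop("akashi_missing_input: no cds_principal.fasta in ", dir)
  adir <- file.path(dir, "alignments")
  files <- sort(list.files(adir, pattern = "\\.fasta$",
                           full.names = TRUE))
  alignments <- lapply(files, read_protein_alignment)
  names(alignments) <- sub("\\.fasta$", "", basename(files))
  opt_file <- function(name, reader) {
    f <- file.path(dir, name)
    if (file.exists(f)) reader(f) else NULL
  }
  list(cds = cds, alignments = alignments,
       domains = opt_file("domains.tsv", read_domain_table),
       structure = opt_file("structure.txt", read_structure_file),
       expression = opt_file("expression.tsv", read_expression_table),
       trna = opt_file("trna.tsv", read_trna_table))
}

#' Build annotated site tables for every gene of a bundle
#'
#' Back-translates each alignment, classifies sites (pairwise or
#' phylogeny-based), optionally applies the optimality-tied filter, and
#' attaches domain, stem/loop and transcript-third annotations when the
#' bundle provides them.
#'
#' @param bundle list as from [simulate_bundle()] or [read_bundle()].
#' @param mode `"pairwise"` (original test) or `"phylogeny"`
#'   (sister-lineage changes only; requires trio alignments).
#' @param favored_base optional favored-base map; when supplied the
#'   optimality-tied filter is applied to variable sites.
#' @param strong_threshold strong-pairing cutoff for S-codons.
#' @return one site table covering all genes (rbind of per-gene tables).
#' @export
classify_bundle <- function(bundle, mode = c("pairwise", "phylogeny"),
                            favored_base = NULL, strong_threshold = 0.9) {
  mode <- match.arg(mode)
  cds_all <- unlist(unname(bundle$cds))
  missing <- vapply(bundle$alignments, function(a)
    !all(names(a) %in% names(cds_all)), logical(1))
  if (any(missing))
    stop("akashi_cross_reference: alignments without CDS: ",
         paste(utils::head(names(bundle$alignments)[missing], 10),
               collapse = ", "))
  per_gene <- lapply(names(bundle$alignments), function(g) {
    aln_seqs <- bundle$alignments[[g]]
    if (mode == "pairwise" && length(aln_seqs) > 2L)
      aln_seqs <- aln_seqs[1:2]
    aln <- build_codon_alignment(aln_seqs, cds_all)
    sites <- if (mode == "pairwise") classify_pairwise(aln) else
      classify_phylogeny(aln)
    if (!is.null(favored_base))
      sites <- apply_optimality_filter(sites, favored_base)
    if (!is.null(bundle$domains))
      sites <- annotate_domain(sites, bundle$domains)
    if (!is.null(bundle$structure) && !is.null(bundle$structure[[g]]))
      sites <- annotate_structure(sites, bundle$structure[[g]],
                                  strong_threshold = strong_threshold)
    assign_thirds(sites)
  })
  rbind_fast(per_gene)
}

# Column-wise rbind of identically shaped data.frames (much faster than
# do.call(rbind, ...) for many small tables).
rbind_fast <- function(dfs) {
  cols <- names(dfs[[1]])
  out <- lapply(cols, function(cn)
    unlist(lapply(dfs, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  do.call(data.frame, c(out, list(stringsAsFactors = FALSE)))
}

#' Run the full translational-accuracy analysis
#'
#' Classifies sites, runs the Akashi test overall and within each
#' requested stratum, scans per-codon enrichment at conserved vs variable
#' sites, computes per-gene composition metrics, and profiles the signal
#' along the transcript.
#'
#' @param bundle list as from [simulate_bundle()] or [read_bundle()].
#' @param mode passed to [classify_bundle()].
#' @param optimal_codons optimal codons (character vector or
#'   `optimal_codon_set`); when `NULL` and the bundle has expression
#'   data, they are identified with [identify_optimal_codons()].
#' @param tied logical; apply the optimality-tied variable-site filter
#'   (requires an optimal set to derive favored bases from).
#' @param strong_threshold,alpha,quantile,expressed_min thresholds
#'   (defaults 0.9, 0.05, 0.20, 100).
#' @param window positional window in amino acids (default 5).
#' @return list of class `akashi_report`: `sites`, `akashi` (data.frame
#'   of pooled ORs per stratum), `codon_scan`, `optimal_set`,
#'   `composition`, `positional`, `site_counts`.
#' @export
run_pipeline <- function(bundle, mode = c("pairwise", "phylogeny"),
                         optimal_codons = NULL, tied = FALSE,
                         strong_threshold = 0.9, alpha = 0.05,
                         quantile = 0.20, expressed_min = 100,
                         window = 5L) {
  mode <- match.arg(mode)
  optimal_set <- NULL
  if (is.null(optimal_codons)) {
    if (is.null(bundle$expression))
      stop("akashi_missing_input: need optimal_codons or expression data")
    cds_df <- data.frame(gene_id = names(bundle$cds$principal),
                         sequence = unname(bundle$cds$principal),
                         valid = TRUE, stringsAsFactors = FALSE)
    optimal_set <- identify_optimal_codons(cds_df, bundle$expression,
                                           quantile = quantile,
                                           alpha = alpha,
                                           expressed_min = expressed_min)
    optimal_codons <- optimal_set$optimal_codons
  } else if (inherits(optimal_codons, "optimal_codon_set")) {
    optimal_set <- optimal_codons
    optimal_codons <- optimal_set$optimal_codons
  }
  favored <- if (tied) favored_base_map(optimal_codons) else NULL
  sites <- classify_bundle(bundle, mode, favored_base = favored,
                           strong_threshold = strong_threshold)
  run_stratum <- function(mask, name) {
    res <- tryCatch(akashi_test(sites, optimal_codons, mask = mask),
                    error = function(e) NULL)
    data.frame(stratum = name,
               or = if (is.null(res)) NA_real_ else res$or,
               chisq = if (is.null(res)) NA_real_ else res$chisq,
               p = if (is.null(res)) NA_real_ else res$p,
               n_strata = if (is.null(res)) 0L else res$n_strata,
               stringsAsFactors = FALSE)
  }
  strata_defs <- list(all = NULL)
  if (!is.null(sites$in_domain)) {
    strata_defs$domains <- sites$in_domain
    strata_defs$nondomains <- !sites$in_domain
  }
  if (!is.null(sites$struct_class)) {
    strata_defs$stems <- sites$struct_class == "S"
    strata_defs$loops <- sites$struct_class == "L"
  }
  for (k in 1:3)
    strata_defs[[paste0("third", k)]] <- !is.na(sites$third) &
      sites$third == k
  akashi <- do.call(rbind, lapply(names(strata_defs), function(nm)
    run_stratum(strata_defs[[nm]], nm)))
  class_ab <- ifelse(sites$state == "conserved", "A",
                     ifelse(sites$state == "variable", "B", NA))
  scan <- codon_enrichment_scan(sites$gene, sites$codon, class_ab)
  comp <- do.call(rbind, lapply(names(bundle$cds$principal), function(g) {
    s <- bundle$cds$principal[[g]]
    body <- substr(s, 1, nchar(s) - 3L)
    data.frame(gene = g, gc = gc_content(s), gc3 = gc3_content(body),
               enc = enc(s), fop = fop(s, optimal_codons),
               gc_class = if (gc_content(s) >= 0.60) "HGC" else "LGC",
               stringsAsFactors = FALSE)
  }))
  pools <- build_window_pools(sites, window = window)
  positional <- positional_profiles(pools, optimal_codons,
                                    window = window)
  site_counts <- as.list(table(sites$state))
  site_counts$total <- nrow(sites)
  structure(list(sites = sites, akashi = akashi, codon_scan = scan,
                 optimal_set = optimal_set, composition = comp,
                 positional = positional, site_counts = site_counts,
                 mode = mode),
            class = "akashi_report")
}

#' @export
print.akashi_report <- function(x, ...) {
  cat("Akashi translational-accuracy report (", x$mode, " mode)\n",
      sep = "")
  cat(sprintf("  %d genes, %d aligned columns (%s conserved, %s variable)\n",
              length(unique(x$sites$gene)), x$site_counts$total,
              x$site_counts$conserved %||% 0,
              x$site_counts$variable %||% 0))
  cat("  Pooled odds ratios by stratum:\n")
  print(x$akashi, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as TSV files
#'
#' @param report an `akashi_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$akashi, file.path(dir, "akashi_summary.tsv"))
  write_tsv(report$codon_scan, file.path(dir, "codon_odds_ratios.tsv"))
  write_tsv(report$composition, file.path(dir, "composition.tsv"))
  write_tsv(report$positional, file.path(dir, "positional_profile.tsv"))
  export_site_classification(report$sites,
                             file.path(dir, "site_classification.tsv"))
  if (!is.null(report$optimal_set))
    write_tsv(report$optimal_set$table,
              file.path(dir, "optimal_codons.tsv"))
  invisible(dir)
}
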