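# Synthetic ortholog trios with known injected effect structure: codon
# choice biased by site conservation, domain GC3 shifts, stem/loop
# annotations, expression tied to Fop, and tRNA copies tied to the
# designated optimal set. Every emitted file uses the formats the readers
# in this package consume, and the generating parameters are echoed in a
# truth object so recovery can be checked end to end.

# Amino acids of the 18 degenerate families of the standard code.
.DEGENERATE_AA <- sort(c("F", "Y", "H", "Q", "N", "K", "D", "E", "C",
                         "I", "V", "P", "T", "A", "G", "L", "S", "R"))

#' Simulation configuration
#'
#' Parameters of the ortholog-trio generator. The designated optimal
#' codon of each degenerate family is, by default, the lexicographically
#' first codon ending in C (else G), emulating the GC3-rich optimal
#' codons typical of plant genomes.
#'
#' @param seed integer seed; fully determines the bundle.
#' @param n_genes number of ortholog trios.
#' @param len_range integer c(min, max) internal CDS length in codons
#'   (start and stop codons are added on top).
#' @param f_c fraction of sites designated conserved.
#' @param p_c,p_v probability that the principal species uses the
#'   family's optimal codon at conserved / variable sites. The implied
#'   generative Akashi odds ratio is `(p_c/(1-p_c)) / (p_v/(1-p_v))`.
#' @param p_sub_sister,p_sub_principal,p_sub_outgroup probability of a
#'   nonsynonymous substitution on each branch at a designated variable
#'   site.
#' @param optimal_codons named character vector family -> optimal codon;
#'   `NULL` for the default GC3-rich set.
#' @param domain_fraction fraction of each gene covered by its (single,
#'   contiguous) protein domain; 0 disables domains.
#' @param delta_dom additive shift of third-base GC content at domain
#'   sites, in GC3 fraction units (e.g. 0.05 = +5 points).
#' @param stem_fraction approximate fraction of CDS bases paired in the
#'   emitted secondary structure.
#' @param strong_pair_prob probability that a paired base gets a pairing
#'   probability above 0.9 (an S-codon third base).
#' @param expr_mu,expr_beta,expr_sigma,n_experiments log10-expression
#'   model: per experiment, `log10(value) ~ Normal(mu + beta * Fop,
#'   sigma)`.
#' @param trio logical; emit a third (outgroup) species.
#' @param change_point optional codon index after which the conserved-site
#'   optimality probability drops to `p_c_after` (positional-gradient
#'   injection); `NULL` for a stationary profile.
#' @param p_c_after conserved-site optimal-codon probability after
#'   `change_point` (defaults to `p_v`, i.e. no enrichment).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 500L,
                              len_range = c(300L, 300L), f_c = 0.5,
                              p_c = 0.7, p_v = 0.5,
                              p_sub_sister = 1, p_sub_principal = 0,
                              p_sub_outgroup = 0,
                              optimal_codons = NULL,
                              domain_fraction = 0.3, delta_dom = 0,
                              stem_fraction = 0.4,
                              strong_pair_prob = 0.95,
                              expr_mu = 3, expr_beta = 8,
                              expr_sigma = 0.3, n_experiments = 5L,
                              trio = TRUE,
                              change_point = NULL, p_c_after = p_v) {
  if (is.null(optimal_codons)) optimal_codons <- default_optimal_codons()
  probs <- c(f_c = f_c, p_c = p_c, p_v = p_v,
             p_sub_sister = p_sub_sister,
             p_sub_principal = p_sub_principal,
             p_sub_outgroup = p_sub_outgroup,
             domain_fraction = domain_fraction,
             stem_fraction = stem_fraction,
             strong_pair_prob = strong_pair_prob, p_c_after = p_c_after)
  if (any(probs < 0 | probs > 1))
    stop("akashi_bad_config: probabilities must lie in [0, 1]")
  if (len_range[1] < 1L || len_range[2] < len_range[1])
    stop("akashi_bad_config: need 1 <= len_min <= len_max")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    len_range = as.integer(len_range), f_c = f_c, p_c = p_c, p_v = p_v,
    p_sub_sister = p_sub_sister, p_sub_principal = p_sub_principal,
    p_sub_outgroup = p_sub_outgroup, optimal_codons = optimal_codons,
    domain_fraction = domain_fraction, delta_dom = delta_dom,
    stem_fraction = stem_fraction, strong_pair_prob = strong_pair_prob,
    expr_mu = expr_mu, expr_beta = expr_beta, expr_sigma = expr_sigma,
    n_experiments = as.integer(n_experiments), trio = trio,
    change_point = change_point, p_c_after = p_c_after
  ), class = "simulation_config")
}

#' Default GC3-rich optimal-codon designation
#'
#' One optimal codon per degenerate family: the lexicographically first
#' family codon ending in C, else in G.
#'
#' @return named character vector, family (amino-acid letter) -> codon.
#' @export
default_optimal_codons <- function() {
  ct <- codon_table()
  fams <- .DEGENERATE_AA
  vapply(fams, function(f) {
    cods <- ct$families[[f]]
    pick <- cods[third_base(cods) == "C"]
    if (!length(pick)) pick <- cods[third_base(cods) == "G"]
    pick[1]
  }, character(1))
}

# Per-family sampling tables used by the generator.
.family_tables <- function(optimal_codons) {
  ct <- codon_table()
  fams <- .DEGENERATE_AA
  opt <- unname(optimal_codons[fams])
  nonopt <- lapply(fams, function(f)
    setdiff(ct$families[[f]], optimal_codons[[f]]))
  gc_cods <- lapply(fams, function(f) {
    cods <- ct$families[[f]]
    cods[third_base(cods) %in% c("G", "C")]
  })
  pad <- function(lst) {
    m <- max(lengths(lst))
    t(vapply(lst, function(v) c(v, rep(NA_character_, m - length(v))),
             character(m)))
  }
  list(fams = fams, opt = opt,
       opt_gc = third_base(opt) %in% c("G", "C"),
       nonopt_mat = pad(nonopt), n_nonopt = lengths(nonopt),
       gc_mat = pad(gc_cods), n_gc = lengths(gc_cods))
}

# Analytic P(third base is G/C) for a site drawn with optimality
# probability p, averaged over a uniform ancestral family.
.baseline_gc3 <- function(tabs, p) {
  mean(p * tabs$opt_gc + (1 - p) * tabs$n_nonopt_gc_frac)
}

# Draw one codon per site: optimal with probability p, else a uniform
# nonoptimal peer. fam_idx indexes tabs$fams.
.draw_codons <- function(tabs, fam_idx, p) {
  n <- length(fam_idx)
  use_opt <- stats::runif(n) < p
  codons <- tabs$opt[fam_idx]
  nn <- tabs$n_nonopt[fam_idx]
  k <- floor(stats::runif(n) * nn) + 1L
  codons[!use_opt] <- tabs$nonopt_mat[cbind(fam_idx, k)][!use_opt]
  codons
}

# Balanced dot-bracket of given length with ~stem_fraction paired bases:
# hairpin units (6 paired arms, 4-base loop) separated by dot spacers.
.make_structure <- function(len, stem_fraction) {
  if (stem_fraction <= 0) return(strrep(".", len))
  unit <- paste0(strrep("(", 6), "....", strrep(")", 6))
  spacer <- max(0L, round(12 / stem_fraction - 16))
  block <- paste0(unit, strrep(".", spacer))
  n_block <- len %/% nchar(block)
  out <- strrep(block, n_block)
  paste0(out, strrep(".", len - nchar(out)))
}

#' Simulate a synthetic ortholog bundle
#'
#' Generates `n_genes` ortholog pairs or trios plus companion annotation
#' files with a known effect structure (see [simulation_config()]).
#' Per gene: a conservation mask is drawn, ancestral amino acids are
#' drawn uniformly over the 18 degenerate families, the principal codon's
#' optimality is drawn with `p_c` or `p_v` (domain sites additionally
#' tilted towards third-base G/C by `delta_dom`), the sequence is copied
#' to sister and outgroup, and nonsynonymous substitutions are applied
#' per branch at variable sites. A start codon and stop codon are added.
#' Each gene has its own pseudo-random stream keyed by (seed, gene
#' index), so extending `n_genes` does not perturb earlier genes.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, the bundle is written as
#'   `cds_<role>.fasta`, `alignments/<gene>.fasta`, `domains.tsv`,
#'   `structure.txt`, `expression.tsv`, `trna.tsv` and `config.txt`.
#' @param components character subset of
#'   `c("domains", "structure", "expression", "trna")` to generate; the
#'   core sequences are always generated.
#' @return list with `cds` (named vectors per role), `proteins`,
#'   `alignments` (per-gene named aligned vectors), `domains`,
#'   `structure`, `expression`, `trna`, and `truth` (a
#'   `simulation_truth`: config echo, expected Akashi OR, designated
#'   optimal codons and favored bases, per-gene conservation masks).
#' @export
simulate_bundle <- function(config, dir = NULL,
                            components = c("domains", "structure",
                                           "expression", "trna")) {
  stopifnot(inherits(config, "simulation_config"))
  tabs <- .family_tables(config$optimal_codons)
  tabs$n_nonopt_gc_frac <- vapply(seq_along(tabs$fams), function(i) {
    nn <- tabs$nonopt_mat[i, seq_len(tabs$n_nonopt[i])]
    mean(third_base(nn) %in% c("G", "C"))
  }, numeric(1))
  roles <- if (config$trio) c("principal", "sister", "outgroup") else
    c("principal", "sister")
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  cds <- lapply(roles, function(r) character(config$n_genes))
  names(cds) <- roles
  proteins <- cds
  alignments <- vector("list", config$n_genes)
  names(alignments) <- gene_ids
  domains <- vector("list", config$n_genes)
  structures <- vector("list", config$n_genes)
  fops <- numeric(config$n_genes)
  conserved_masks <- vector("list", config$n_genes)
  n_fam <- length(tabs$fams)
  for (g in seq_len(config$n_genes)) {
    set.seed((config$seed * 48271L + g) %% 2147483629L)
    L <- if (config$len_range[1] == config$len_range[2])
      config$len_range[1] else
        sample(config$len_range[1]:config$len_range[2], 1L)
    cons <- stats::runif(L) < config$f_c
    conserved_masks[[g]] <- cons
    anc_fam <- sample.int(n_fam, L, replace = TRUE)
    # per-site optimality probability, with optional positional gradient
    p_site <- ifelse(cons, config$p_c, config$p_v)
    if (!is.null(config$change_point)) {
      late <- seq_len(L) > config$change_point
      p_site[late & cons] <- config$p_c_after
    }
    principal_fam <- anc_fam
    if (config$p_sub_principal > 0) {
      sub <- !cons & stats::runif(L) < config$p_sub_principal
      principal_fam[sub] <- .other_family(anc_fam[sub], n_fam)
    }
    p_codon <- .draw_codons(tabs, principal_fam, p_site)
    dom_mask <- rep(FALSE, L)
    if ("domains" %in% components && config$domain_fraction > 0) {
      dom_len <- max(1L, round(config$domain_fraction * L))
      dom_start <- sample.int(L - dom_len + 1L, 1L)
      dom_mask[dom_start:(dom_start + dom_len - 1L)] <- TRUE
      if (config$delta_dom > 0) {
        # exact third-base GC tilt: replace AT-ending codons with a
        # uniform GC-ending family codon at rate delta / (1 - g)
        for (class_p in unique(p_site)) {
          g0 <- .baseline_gc3(tabs, class_p)
          r <- min(1, config$delta_dom / (1 - g0))
          idx <- which(dom_mask & p_site == class_p &
                         !(third_base(p_codon) %in% c("G", "C")))
          flip <- idx[stats::runif(length(idx)) < r]
          if (length(flip)) {
            kk <- floor(stats::runif(length(flip)) *
                          tabs$n_gc[principal_fam[flip]]) + 1L
            p_codon[flip] <- tabs$gc_mat[cbind(principal_fam[flip], kk)]
          }
        }
      }
      # domain coordinates in protein space (leading Met is position 1)
      domains[[g]] <- data.frame(
        gene_id = gene_ids[g], domain_id = paste0("DOM_", gene_ids[g]),
        start = dom_start + 1L, end = dom_start + dom_len,
        stringsAsFactors = FALSE)
    }
    sister_fam <- anc_fam
    sub_s <- !cons & stats::runif(L) < config$p_sub_sister
    sister_fam[sub_s] <- .other_family(anc_fam[sub_s], n_fam)
    s_codon <- p_codon
    changed_s <- sister_fam != principal_fam
    s_codon[changed_s] <- .draw_codons(tabs, sister_fam[changed_s],
                                       config$p_v)
    out_fam <- anc_fam
    if (config$trio && config$p_sub_outgroup > 0) {
      sub_o <- !cons & stats::runif(L) < config$p_sub_outgroup
      out_fam[sub_o] <- .other_family(anc_fam[sub_o], n_fam)
    }
    o_codon <- p_codon
    changed_o <- out_fam != principal_fam
    o_codon[changed_o] <- .draw_codons(tabs, out_fam[changed_o],
                                       config$p_v)
    mk_cds <- function(codons) paste0("ATG",
                                      paste(codons, collapse = ""), "TAA")
    mk_prot <- function(fam) paste0("M",
                                    paste(tabs$fams[fam], collapse = ""))
    cds$principal[g] <- mk_cds(p_codon)
    cds$sister[g] <- mk_cds(s_codon)
    proteins$principal[g] <- mk_prot(principal_fam)
    proteins$sister[g] <- mk_prot(sister_fam)
    aln <- c(proteins$principal[g], proteins$sister[g])
    names(aln) <- c(gene_ids[g], paste0(gene_ids[g], "|sister"))
    if (config$trio) {
      cds$outgroup[g] <- mk_cds(o_codon)
      proteins$outgroup[g] <- mk_prot(out_fam)
      aln <- c(aln, stats::setNames(proteins$outgroup[g],
                                    paste0(gene_ids[g], "|outgroup")))
    }
    alignments[[g]] <- aln
    if ("structure" %in% components) {
      nt_len <- nchar(cds$principal[g])
      struct <- .make_structure(nt_len, config$stem_fraction)
      ch <- strsplit(struct, "")[[1]]
      paired <- ch %in% c("(", ")")
      prob <- stats::runif(nt_len, 0, 0.1)
      strong <- paired & stats::runif(nt_len) < config$strong_pair_prob
      prob[strong] <- stats::runif(sum(strong), 0.9, 1)
      prob[paired & !strong] <- stats::runif(sum(paired & !strong),
                                             0.2, 0.9)
      structures[[g]] <- list(sequence = cds$principal[g],
                              structure = struct,
                              pair_prob = round(prob, 4))
    }
    fops[g] <- fop(p_codon, unname(config$optimal_codons))
  }
  for (r in roles) {
    suffix <- if (r == "principal") "" else paste0("|", r)
    names(cds[[r]]) <- paste0(gene_ids, suffix)
    names(proteins[[r]]) <- paste0(gene_ids, suffix)
  }
  names(structures) <- gene_ids
  domains <- if (length(domains) && "domains" %in% components)
    do.call(rbind, domains[!vapply(domains, is.null, logical(1))]) else NULL
  expression <- NULL
  if ("expression" %in% components) {
    set.seed((config$seed * 48271L) %% 2147483629L)
    expression <- do.call(rbind, lapply(seq_len(config$n_genes),
                                        function(g) {
      lg <- stats::rnorm(config$n_experiments,
                         config$expr_mu + config$expr_beta * fops[g],
                         config$expr_sigma)
      data.frame(gene_id = gene_ids[g],
                 experiment = paste0("exp", seq_len(config$n_experiments)),
                 value = round(10^lg, 3), stringsAsFactors = FALSE)
    }))
  }
  trna <- NULL
  if ("trna" %in% components) {
    set.seed((config$seed * 48271L + 2147483L) %% 2147483629L)
    sense <- names(.CODE$sense)
    trna <- 1L + stats::rpois(length(sense), 1) +
      3L * (sense %in% config$optimal_codons)
    names(trna) <- sense
  }
  truth <- structure(list(
    config = config,
    expected_or = (config$p_c / (1 - config$p_c)) /
      (config$p_v / (1 - config$p_v)),
    optimal_codons = unname(config$optimal_codons),
    favored_base = favored_base_map(unname(config$optimal_codons)),
    conserved_masks = stats::setNames(conserved_masks, gene_ids),
    realized_f_c = mean(unlist(conserved_masks))
  ), class = "simulation_truth")
  bundle <- list(cds = cds, proteins = proteins, alignments = alignments,
                 domains = domains,
                 structure = if ("structure" %in% components)
                   structures else NULL,
                 expression = expression, trna = trna, truth = truth)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

# A uniformly drawn family different from the current one.
.other_family <- function(fam_idx, n_fam) {
  if (!length(fam_idx)) return(integer(0))
  shift <- floor(stats::runif(length(fam_idx)) * (n_fam - 1L)) + 1L
  (fam_idx + shift - 1L) %% n_fam + 1L
}

#' Write a simulated bundle to disk
#'
#' @param bundle result of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in names(bundle$cds))
    write_cds_fasta(bundle$cds[[r]], file.path(dir,
                                               paste0("cds_", r, ".fasta")))
  adir <- file.path(dir, "alignments")
  dir.create(adir, showWarnings = FALSE)
  for (g in names(bundle$alignments))
    write_alignment_fasta(bundle$alignments[[g]],
                          file.path(adir, paste0(g, ".fasta")))
  if (!is.null(bundle$domains))
    write_tsv(bundle$domains, file.path(dir, "domains.tsv"))
  if (!is.null(bundle$structure))
    write_structure_file(bundle$structure, file.path(dir, "structure.txt"))
  if (!is.null(bundle$expression))
    write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  if (!is.null(bundle$trna))
    write_tsv(data.frame(codon = names(bundle$trna),
                         copies = unname(bundle$trna)),
              file.path(dir, "trna.tsv"))
  cfg <- bundle$truth$config
  scalar <- vapply(cfg, function(v)
    is.atomic(v) && length(v) <= 2L, logical(1))
  lines <- vapply(names(cfg)[scalar], function(k)
    paste0(k, "\t", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Compare pipeline estimates against simulation truth
#'
#' @param truth a `simulation_truth` from [simulate_bundle()].
#' @param results data.frame with columns `contrast`, `or` (estimated
#'   pooled odds ratios, e.g. from repeated [akashi_test()] runs).
#' @return data.frame with per-contrast expected OR, estimated OR, bias
#'   (estimate - expected), and sign agreement with the injected effect.
#' @export
truth_report <- function(truth, results) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!all(c("contrast", "or") %in% names(results)))
    stop("akashi_bad_results: need columns contrast, or")
  data.frame(
    contrast = results$contrast,
    expected_or = truth$expected_or,
    estimated_or = results$or,
    bias = results$or - truth$expected_or,
    sign_agrees = (results$or > 1) == (truth$expected_or > 1),
    stringsAsFactors = FALSE
  )
}
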