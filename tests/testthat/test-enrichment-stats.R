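test_that("build_strata counts focal and peer codons per gene", {
  gene <- rep("g1", 7)
  codon <- c("AAA", "AAA", "AAG", "AAA", "AAG", "AAG", "AAG")
  class <- c("A", "A", "A", "B", "B", "B", "B")
  st <- build_strata(gene, codon, class, "AAA")
  expect_equal(st[1, c("a", "b", "c", "d")],
               data.frame(a = 2L, b = 1L, c = 1L, d = 3L),
               ignore_attr = TRUE)
  expect_true(st$informative)
  # gene without any Lys codon is omitted
  st <- build_strata(c(gene, "g2"), c(codon, "GGG"), c(class, "A"), "AAA")
  expect_equal(st$gene, "g1")
  # all class-B sites absent: flagged non-informative
  st <- build_strata(gene[1:3], codon[1:3], class[1:3], "AAA")
  expect_false(st$informative)
  expect_error(build_strata("g", "ATG", "A", "ATG"), "akashi_no_peers")
})

test_that("Mantel-Haenszel reproduces the hand-evaluated pooled OR", {
  st <- data.frame(a = c(10, 8), b = c(5, 2), c = c(5, 4), d = c(10, 6))
  r <- mantel_haenszel(st)
  hand <- (10 * 10 / 30 + 8 * 6 / 20) / (5 * 5 / 30 + 2 * 4 / 20)
  expect_equal(r$or, hand, tolerance = 1e-12)
  expect_equal(round(r$or, 3), 4.649)
})

test_that("single-stratum MH equals the cross-product ratio", {
  expect_equal(mantel_haenszel(data.frame(a = 2, b = 2, c = 2, d = 2))$or, 1)
  expect_equal(mantel_haenszel(data.frame(a = 6, b = 2, c = 3, d = 4))$or,
               6 * 4 / (2 * 3))
})

test_that("MH is invariant to stratum order and all-zero padding", {
  set.seed(5)
  st <- random_strata(5)
  r1 <- mantel_haenszel(st)
  r2 <- mantel_haenszel(st[rev(seq_len(nrow(st))), ])
  expect_equal(r1$or, r2$or)
  expect_equal(r1$chisq, r2$chisq)
  r3 <- mantel_haenszel(rbind(st, data.frame(a = 0, b = 0, c = 0, d = 0)))
  expect_equal(r1$or, r3$or)
  expect_equal(r1$chisq, r3$chisq)
})

test_that("MH matches the independent reference on random stratum sets", {
  set.seed(99)
  for (i in 1:100) {
    st <- random_strata(sample(2:5, 1))
    got <- mantel_haenszel(st)
    want <- mh_reference(st)
    if (is.finite(want$or))
      expect_equal(got$or, want$or, tolerance = 1e-12)
    else  # reference reports Inf for a zero denominator; we report NA
      expect_true(is.na(got$or))
    expect_equal(got$chisq, want$chisq, tolerance = 1e-12)
  }
})

test_that("MH handles zero pooled sums as undefined unless continuity", {
  st <- data.frame(a = 3, b = 0, c = 2, d = 0)  # d = 0 => denominator 0
  expect_error(mantel_haenszel(st), "akashi_no_informative_strata")
  st <- data.frame(a = c(3, 0), b = c(1, 2), c = c(2, 1), d = c(0, 4))
  st2 <- st; st2$d[2] <- 0; st2$b[1] <- 0
  # denominator = sum(b*c/N): make it zero via b=0, c=0 pattern
  stz <- data.frame(a = 3, b = 0, c = 0, d = 4)
  r <- mantel_haenszel(stz)
  expect_true(is.na(r$or))
  r <- mantel_haenszel(stz, continuity = TRUE)
  expect_true(is.finite(r$or))
  expect_true(r$continuity_used)
})

test_that("codon scan covers 59 focal codons and is antisymmetric", {
  set.seed(3)
  n <- 400
  gene <- rep(c("g1", "g2"), each = n / 2)
  codon <- sample(akashi:::degenerate_sense_codons(), n, TRUE)
  class <- sample(c("A", "B"), n, TRUE)
  scan <- codon_enrichment_scan(gene, codon, class)
  expect_equal(nrow(scan), 59L)
  swapped <- codon_enrichment_scan(gene, codon,
                                   ifelse(class == "A", "B", "A"))
  ok <- is.finite(scan$or) & is.finite(swapped$or) & scan$or > 0
  expect_true(sum(ok) > 10)
  expect_equal(swapped$or[ok], 1 / scan$or[ok], tolerance = 1e-12)
  expect_equal(swapped$p[ok], scan$p[ok], tolerance = 1e-12)
})

test_that("uniform synonymous usage gives odds ratios of 1", {
  # both classes use each family's codons in identical proportion
  gene <- rep("g1", 8)
  codon <- rep(c("AAA", "AAG"), 4)
  class <- rep(c("A", "B"), each = 4)
  scan <- codon_enrichment_scan(gene, codon, class)
  defined <- scan[is.finite(scan$or), ]
  expect_true(all(defined$or == 1))
})

test_that("averaging over comparisons skips undefined odds ratios", {
  mk <- function(ors) data.frame(codon = c("AAA", "AAG"), or = ors)
  out <- average_over_comparisons(list(c1 = mk(c(1.2, 2)),
                                       c2 = mk(c(0.8, NA))))
  expect_equal(out$per_codon$mean_or, c(1.0, 2.0))
  expect_equal(out$per_codon$n_skipped, c(0L, 1L))
  expect_equal(out$deviation$mean_abs_dev, c(mean(c(.2, 1)), .2))
  single <- average_over_comparisons(list(c1 = mk(c(1.5, 0.5))))
  expect_equal(single$per_codon$mean_or, c(1.5, 0.5))
})

test_that("optimal codons are identified from the expression contrast", {
  # 20 genes; strongly expressed genes use AAG, weak use AAA
  n <- 20
  ids <- sprintf("g%02d", 1:n)
  strong <- 1:4; weak <- 17:20
  seqs <- vapply(1:n, function(i) {
    codon <- if (i %in% strong) "AAG" else if (i %in% weak) "AAA"
             else sample(c("AAA", "AAG"), 1)
    paste0("ATG", strrep(codon, 30), "TAA")
  }, character(1))
  cds <- data.frame(gene_id = ids, sequence = seqs, valid = TRUE,
                    stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = ids, experiment = "e1",
                     value = 10^seq(6, 3, length.out = n))
  set.seed(1)
  opt <- identify_optimal_codons(cds, expr, quantile = 0.2)
  expect_true("AAG" %in% opt$optimal_codons)
  expect_false("AAA" %in% opt$optimal_codons)
  expect_equal(unname(opt$favored_base["K"]), "G")
  expect_equal(length(opt$high_genes), 4L)
  # unexpressed genes (never > 100) are excluded from ranking
  expr2 <- expr; expr2$value[expr2$gene_id == "g01"] <- 50
  opt2 <- identify_optimal_codons(cds, expr2, quantile = 0.2)
  expect_false("g01" %in% c(opt2$high_genes, opt2$low_genes))
  expect_error(identify_optimal_codons(cds[1:3, ], expr, min_genes = 10),
               "akashi_too_few_genes")
})

test_that("identical usage in both expression sets yields no optimal codon", {
  n <- 20
  ids <- sprintf("g%02d", 1:n)
  seqs <- rep(paste0("ATG", strrep("AAGAAA", 15), "TAA"), n)
  cds <- data.frame(gene_id = ids, sequence = seqs, valid = TRUE)
  expr <- data.frame(gene_id = ids, experiment = "e1",
                     value = 10^seq(6, 3, length.out = n))
  opt <- identify_optimal_codons(cds, expr, quantile = 0.2)
  expect_length(opt$optimal_codons, 0L)
})

test_that("favored-base map requires agreement within a family", {
  fb <- favored_base_map(c("AAG", "GCC"))
  expect_equal(unname(fb["K"]), "G")
  expect_equal(unname(fb["A"]), "C")
  expect_true(is.na(fb["F"]))
  # disagreeing optimal codons leave the family without a favored base
  fb <- favored_base_map(c("GCC", "GCG"))
  expect_true(is.na(fb["A"]))
})

test_that("akashi_test recovers the generative odds ratio and the null", {
  set.seed(21)
  cfg <- simulation_config(seed = 21, n_genes = 80,
                           len_range = c(150, 150), trio = FALSE)
  b <- simulate_bundle(cfg, components = character(0))
  sites <- classify_bundle(b, "pairwise")
  r <- akashi_test(sites, b$truth$optimal_codons)
  expect_gt(r$or, 1.8); expect_lt(r$or, 3.0)
  expect_lt(r$p, 0.001)
  # masks partition counted sites exactly
  mask <- sites$prot_pos <= 75 & !is.na(sites$prot_pos)
  r1 <- akashi_test(sites, b$truth$optimal_codons, mask = mask)
  r2 <- akashi_test(sites, b$truth$optimal_codons, mask = !mask)
  s0 <- attr(r, "strata"); s1 <- attr(r1, "strata")
  s2 <- attr(r2, "strata")
  expect_equal(sum(s0$a + s0$b + s0$c + s0$d),
               sum(s1$a + s1$b + s1$c + s1$d) +
                 sum(s2$a + s2$b + s2$c + s2$d))
  expect_error(akashi_test(sites, b$truth$optimal_codons,
                           mask = rep(FALSE, nrow(sites))),
               "akashi_empty_mask")
  expect_error(akashi_test(sites, character(0)),
               "akashi_empty_optimal_set")
})

test_that("tRNA-RSCU follows the degeneracy-normalised formula", {
  r <- trna_rscu(c(AAA = 3, AAG = 1))
  expect_equal(r$rscu[r$codon == "AAA"], 1.5)
  expect_equal(r$rscu[r$codon == "AAG"], 0.5)
  # uniform copies within a family give RSCU 1
  r <- trna_rscu(c(GCA = 2, GCC = 2, GCG = 2, GCT = 2))
  expect_equal(r$rscu[r$family == "A"], rep(1, 4))
  # concentrated fourfold family
  r <- trna_rscu(c(GCA = 0, GCC = 0, GCG = 0, GCT = 8))
  expect_equal(r$rscu[r$family == "A"], c(0, 0, 0, 4))
  # zero-total families are undefined, flagged
  expect_true(all(is.na(r$rscu[r$family == "K"])))
  expect_false(any(r$defined[r$family == "K"]))
  expect_error(trna_rscu(c(AAA = -1)), "akashi_negative_copies")
})

test_that("tRNA-RSCU family sums equal the degeneracy", {
  set.seed(12)
  ct <- codon_table()
  for (i in 1:50) {
    copies <- stats::setNames(sample(0:6, 61, TRUE),
                              names(ct$family_of))
    r <- trna_rscu(copies)
    sums <- tapply(r$rscu, r$family, sum)
    for (f in names(sums)) {
      if (sum(copies[ct$families[[f]]]) > 0)
        expect_equal(unname(sums[f]), unname(ct$degeneracy[f]))
    }
  }
})

test_that("correlate returns exact and permutation p-values", {
  x <- 1:10
  expect_equal(correlate(x, x)$estimate, 1)
  expect_error(correlate(1:2, 2:1), "akashi_too_few_pairs")
  set.seed(8)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20, sd = 0.8)
  r <- correlate(x, y, permutations = 4000)
  expect_equal(r$p_perm, r$p_analytic, tolerance = 0.02)
  # NA entries dropped pairwise
  r2 <- correlate(c(x, NA), c(y, 1))
  expect_equal(r2$n, 20L)
  # grouped permutation requires equal group sizes
  expect_error(correlate(x, y, permutations = 10,
                         groups = rep(c(1, 2), c(5, 15))),
               "akashi_unequal_groups")
  g <- rep(1:4, each = 5)
  r3 <- correlate(x, y, permutations = 500, groups = g)
  expect_true(r3$p_perm > 0 && r3$p_perm <= 1)
})
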