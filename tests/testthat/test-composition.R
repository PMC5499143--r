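test_that("GC and GC3 fractions exclude N bases", {
  expect_equal(gc_content("ATGCGC"), 4 / 6)
  expect_equal(gc_content("ATGNNC"), 2 / 4)
  expect_equal(gc3_content("ATGGCGTAA"), 2 / 3)
  expect_equal(gc3_content("ATAATAATT"), 0)
  expect_error(gc_content(""), "akashi_empty_sequence")
  expect_error(gc3_content("ATGA"), "akashi_not_in_frame")
})

test_that("sliding windows follow the size/step arithmetic", {
  s <- random_cds(3)  # 15 nt
  w <- sliding_window_series(s)
  expect_equal(nrow(w), (15 - 9) / 3 + 1)
  w <- sliding_window_series("GCGGCGGCG")
  expect_equal(w$gc, 1); expect_equal(w$gc3, 1)
  w <- sliding_window_series("ATaataATA")
  expect_equal(w$gc, 0)
  expect_warning(w <- sliding_window_series("ATG"), "shorter")
  expect_equal(nrow(w), 0L)
})

test_that("whole-sequence GC equals the mean of exactly tiling windows", {
  set.seed(2)
  s <- random_cds(10)  # 36 nt; non-overlapping 9-nt windows tile it
  w <- sliding_window_series(s, size = 9, step = 9)
  expect_equal(mean(w$gc), gc_content(s))
})

test_that("domain regions and flanks are extracted with rejections", {
  # 300-codon protein, domain at 101-200: four 100-codon regions
  cds <- random_cds(300)
  dom <- data.frame(start = 101L, end = 200L)
  out <- extract_domain_regions(cds, dom)
  expect_equal(nrow(out$regions), 4L)
  expect_setequal(out$regions$region_type,
                  c("domain-5p", "domain-3p", "flank-5p", "flank-3p"))
  expect_equal(sort(unique(out$regions$label)), c("domain", "nondomain"))
  expect_true(all(nchar(out$regions$sequence) == 300L))
  # short flank rejected
  dom <- data.frame(start = 51L, end = 150L)
  out <- extract_domain_regions(cds, dom)
  expect_true("too-short" %in%
                out$rejected$reason[out$rejected$region_type == "flank-5p"])
  # flank overlapping a second domain rejected
  dom <- data.frame(start = c(101L, 230L), end = c(200L, 260L))
  out <- extract_domain_regions(cds, dom)
  rej <- out$rejected
  expect_true(any(rej$reason == "contains-domain"))
  # domain shorter than the region length rejected
  dom <- data.frame(start = 120L, end = 150L)
  out <- extract_domain_regions(cds, dom)
  expect_true(all(out$rejected$reason[grepl("domain",
                                            out$rejected$region_type)] ==
                    "too-short"))
})

test_that("compare_regions reports the domain shift in points", {
  x <- seq(0.4, 0.6, length.out = 50)
  same <- compare_regions(x, x)
  expect_equal(same$delta, 0)
  expect_gt(same$p, 0.9)
  shifted <- compare_regions(x + 0.05, x)
  expect_equal(shifted$delta, 5, tolerance = 1e-9)
  expect_lt(shifted$p, 0.01)
  expect_error(compare_regions(numeric(0), x), "akashi_empty_group")
})

test_that("simulated GC3 shift is recovered by the rank-sum comparison", {
  set.seed(14)
  dom <- rnorm(200, 0.55, 0.03)
  nondom <- rnorm(200, 0.50, 0.03)
  out <- compare_regions(dom, nondom)
  expect_equal(out$delta, 5, tolerance = 0.35)
  expect_lt(out$p, 1e-10)
  # oracle: the same comparison through stats::wilcox.test directly
  expect_equal(out$p, wilcox.test(dom, nondom)$p.value)
})

test_that("ENC reaches its theoretical limits", {
  ct <- codon_table()
  one_per_family <- unlist(lapply(ct$families, `[`, 1))
  biased <- rep(one_per_family, 40)
  expect_equal(enc(biased), 20, tolerance = 0.1)
  uniform <- rep(unlist(ct$families), 60)
  expect_equal(enc(uniform), 61, tolerance = 0.5)
})

test_that("ENC matches the independent implementation on random genes", {
  set.seed(31)
  for (i in 1:10) {
    cds <- random_cds(300)
    codons <- akashi:::split_codons(substr(cds, 1, nchar(cds) - 3))
    expect_equal(enc(cds), enc_oracle(codons), tolerance = 1e-6)
  }
})

test_that("ENC decreases as within-family usage concentrates", {
  # mix a fully biased and a fully uniform codon pool in varying ratio
  ct <- codon_table()
  biased <- rep(unlist(lapply(ct$families, `[`, 1)), 30)
  uniform <- rep(unlist(ct$families), 10)
  encs <- vapply(c(0, 0.5, 1), function(w) {
    n_b <- round(w * length(biased))
    enc(c(biased[seq_len(n_b)], uniform))
  }, numeric(1))
  expect_true(all(diff(encs) < 0))
})

test_that("Fop counts optimal codons over optimal-containing families", {
  opt <- c("AAG", "GCC")
  expect_equal(fop(c("AAG", "AAG", "GCC"), opt), 1)
  expect_equal(fop(c("AAA", "GCT"), opt), 0)
  # families without optimal codons are excluded from the denominator
  expect_equal(fop(c("AAG", "AAA", "TTT", "TTC"), opt), 0.5)
  # codons only from non-optimal families: undefined
  expect_true(is.na(fop(c("TTT", "TTC"), opt)))
  expect_error(fop("AAG", character(0)), "akashi_empty_optimal_set")
})

test_that("Fop is invariant to optimality-preserving recoding", {
  set.seed(6)
  opt <- unname(default_optimal_codons())
  cds <- random_cds(200)
  codons <- akashi:::split_codons(substr(cds, 1, nchar(cds) - 3))
  f1 <- fop(codons, opt)
  # recode every nonoptimal codon to another nonoptimal peer when one
  # exists; optimal codons stay
  recoded <- vapply(codons, function(cd) {
    if (cd %in% opt || cd == "ATG" || cd == "TGG") return(cd)
    peers <- setdiff(synonymous_peers(cd), opt)
    if (length(peers)) peers[1] else cd
  }, character(1), USE.NAMES = FALSE)
  expect_equal(fop(recoded, opt), f1)
})

test_that("HGC/LGC split partitions at the 60% boundary", {
  cds <- data.frame(
    gene_id = c("hi", "edge", "lo"),
    sequence = c(strrep("GCGGCC", 20), paste0(strrep("GCG", 20),
                                              strrep("ATA", 10)),
                 strrep("ATATTA", 20)),
    valid = TRUE, stringsAsFactors = FALSE)
  # middle gene has exactly 60% GC
  expect_equal(gc_content(cds$sequence[2]), 2 / 3)
  cds$sequence[2] <- paste0(strrep("GC", 30), strrep("AT", 20))  # 60%
  expect_equal(gc_content(cds$sequence[2]), 0.6)
  out <- split_hgc_lgc(cds)
  expect_setequal(out$hgc$gene_id, c("hi", "edge"))
  expect_setequal(out$lgc$gene_id, "lo")
  expect_equal(nrow(out$hgc) + nrow(out$lgc), nrow(cds))
  empty <- split_hgc_lgc(cds[0, ])
  expect_equal(nrow(empty$hgc), 0L)
})
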