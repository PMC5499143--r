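pair_aln <- function(prot_a, prot_b, cds_a, cds_b) {
  build_codon_alignment(c(gA = prot_a, gB = prot_b),
                        c(gA = cds_a, gB = cds_b))
}

test_that("codon alignments are back-translated and verified", {
  aln <- pair_aln("MK", "MK", "ATGAAATAA", "ATGAAGTAA")
  expect_equal(aln$codons["principal", ], c("ATG", "AAA"))
  expect_equal(aln$codons["sister", ], c("ATG", "AAG"))

  aln <- pair_aln("M-K", "MAK", "ATGAAATAA", "ATGGCAAAGTAA")
  expect_equal(unname(aln$codons["principal", 2]), "---")
  expect_equal(unname(aln$codons["sister", 2]), "GCA")

  expect_error(pair_aln("MK", "MK", "ATGCCCTAA", "ATGAAGTAA"),
               "akashi_translation_mismatch.*gA.*codon 2")
})

test_that("pairwise classification splits conserved/variable/excluded", {
  aln <- pair_aln("MKRT-", "MKKTW",
                  "ATGAAAAGAACTTAA", "ATGAAAAAAACGTGGTAA")
  s <- classify_pairwise(aln)
  expect_equal(s$state, c("conserved", "conserved", "variable",
                          "conserved", "excluded"))
  expect_equal(s$prot_pos, c(1L, 2L, 3L, 4L, NA))
  # state counts partition the columns
  expect_equal(sum(table(s$state)), aln$n_col)
})

test_that("phylogeny classification assigns lineages on ((P,S),O)", {
  aln <- make_trio_alignment(
    p = c("K", "K", "R", "K", "A", "-"),
    s = c("K", "R", "K", "K", "C", "K"),
    o = c("K", "K", "K", "R", "G", "K"))
  s <- classify_phylogeny(aln)
  expect_equal(s$state, c("conserved", "variable", "excluded", "excluded",
                          "excluded", "excluded"))
  expect_equal(s$lineage, c("none", "sister", "principal",
                            "outgroup-or-ancestral", "ambiguous", "none"))
  aln2 <- pair_aln("MK", "MK", "ATGAAATAA", "ATGAAGTAA")
  expect_error(classify_phylogeny(aln2), "akashi_missing_outgroup")
})

test_that("phylogeny classification agrees with pairwise on P=O columns", {
  set.seed(11)
  aa <- c("A", "K", "R", "C")
  for (rep in 1:20) {
    p <- sample(aa, 30, TRUE); s <- sample(aa, 30, TRUE)
    o <- sample(aa, 30, TRUE)
    trio <- make_trio_alignment(p, s, o)
    phylo <- classify_phylogeny(trio)
    pair <- classify_pairwise(trio)  # uses the (P, S) rows only
    agree <- p == o
    expect_equal(phylo$state[agree], pair$state[agree])
  }
})

test_that("phylogeny classification matches the Fitch parsimony oracle", {
  set.seed(42)
  states <- LETTERS[1:20][LETTERS[1:20] %in%
                            strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]
  p <- sample(states, 200, TRUE)
  s <- sample(states, 200, TRUE)
  o <- sample(states, 200, TRUE)
  got <- classify_phylogeny(make_trio_alignment(p, s, o))
  for (i in seq_len(200)) {
    want <- fitch_oracle(p[i], s[i], o[i])
    expect_equal(got$state[i], want$state)
    expect_equal(got$lineage[i], want$lineage)
  }
})

test_that("optimality-tied filter applies the three published criteria", {
  fav <- akashi::favored_base_map(c("GTA", "ATA"))  # Val and Ile favor A
  # single-base nonsynonymous change, same third base, same favored base
  r <- optimality_tied_filter("GTA", "ATA", fav)
  expect_true(r$keep)
  # third-base change is dropped, not an error
  r <- optimality_tied_filter("AAA", "AAG", fav)
  expect_false(r$keep)
  expect_equal(r$reason, "silent-base-changed")
  # identical codons pass vacuously even without a favored base
  expect_true(optimality_tied_filter("TTT", "TTT", fav)$keep)
  # family without a favored base drops the site
  r <- optimality_tied_filter("AAA", "GAA", fav)
  expect_equal(r$reason, "no-favored-base")
})

test_that("two-base pathways through a stop codon are dropped", {
  ct <- codon_table()
  fams <- names(ct$degeneracy)[ct$degeneracy >= 2]
  fav_all_A <- stats::setNames(rep("A", length(fams)), fams)
  # TTA -> CGA: ordering (pos2 first) passes through TGA (stop)
  r <- optimality_tied_filter("TTA", "CGA", fav_all_A)
  expect_false(r$keep)
  expect_equal(r$reason, "pathway-through-stop")
  # with a constant favored base, single-base third-preserving pairs keep
  r <- optimality_tied_filter(c("GTA", "CCA"), c("ATA", "CAA"), fav_all_A)
  expect_true(all(r$keep))
})

test_that("the tied filter demotes failing variable sites in a site table", {
  sites <- data.frame(gene = "g", column = 1:3, prot_pos = 1:3,
                      codon = c("GTA", "AAA", "AAA"),
                      codon_sister = c("ATA", "AAG", "AAA"),
                      state = c("variable", "variable", "conserved"),
                      lineage = "none", stringsAsFactors = FALSE)
  fav <- favored_base_map(c("GTA", "ATA", "AAA"))
  out <- apply_optimality_filter(sites, fav)
  expect_equal(out$state, c("variable", "excluded", "conserved"))
  expect_equal(out$tied_reason[2], "silent-base-changed")
})

test_that("domain annotation flags sites by protein position", {
  sites <- data.frame(gene = "g1", column = 1:8, prot_pos = c(1:7, NA),
                      codon = "AAA", codon_sister = "AAA",
                      state = "conserved", lineage = "none",
                      stringsAsFactors = FALSE)
  dom <- data.frame(gene_id = "g1", domain_id = "D", start = 5L, end = 10L)
  out <- annotate_domain(sites, dom, protein_length = 12L)
  expect_equal(out$in_domain, c(rep(FALSE, 4), rep(TRUE, 3), FALSE))
  expect_error(annotate_domain(sites, dom, protein_length = 8L),
               "akashi_domain_out_of_range")
  # no domains for the gene: all flags false
  out <- annotate_domain(sites, dom[0, ], protein_length = 12L)
  expect_false(any(out$in_domain))
})

test_that("structure annotation separates S- and L-codons by threshold", {
  sites <- data.frame(gene = "g", column = 1:3, prot_pos = 1:3,
                      codon = "AAA", codon_sister = "AAA",
                      state = "conserved", lineage = "none",
                      stringsAsFactors = FALSE)
  loops <- list(structure = strrep(".", 9), pair_prob = NULL)
  expect_equal(annotate_structure(sites, loops)$struct_class,
               rep("L", 3))
  st <- list(structure = "..(..)...", pair_prob = NULL)
  expect_equal(annotate_structure(sites, st)$struct_class,
               c("S", "S", "L"))
  # weakly paired third base (prob below threshold) becomes L
  st$pair_prob <- c(0, 0, 0.95, 0, 0, 0.30, 0, 0, 0)
  expect_equal(annotate_structure(sites, st)$struct_class,
               c("S", "L", "L"))
  short <- list(structure = "...", pair_prob = NULL)
  expect_error(annotate_structure(sites, short),
               "akashi_structure_too_short")
})

test_that("transcript thirds follow the floor(L/3) remainder rule", {
  mk <- function(n) data.frame(gene = "g", column = seq_len(n),
                               prot_pos = seq_len(n), codon = "AAA",
                               codon_sister = "AAA", state = "conserved",
                               lineage = "none", stringsAsFactors = FALSE)
  expect_equal(table(assign_thirds(mk(9))$third),
               table(rep(1:3, each = 3)))
  expect_equal(unname(table(assign_thirds(mk(10))$third)),
               array(c(3L, 3L, 4L)))
  expect_warning(out <- assign_thirds(mk(2)), "shorter")
  expect_equal(out$third, c(3L, 3L))
})

test_that("site classifications export as a TSV pseudoalignment", {
  path <- withr::local_tempfile(fileext = ".tsv")
  aln <- pair_aln("MK", "MK", "ATGAAATAA", "ATGAAGTAA")
  export_site_classification(classify_pairwise(aln), path)
  back <- read.delim(path)
  expect_equal(nrow(back), 2L)
  expect_true(all(c("gene", "column", "state") %in% names(back)))
})
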