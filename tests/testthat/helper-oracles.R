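# Independent oracles and fixture builders shared across the test files.
# Each oracle is coded straight from the textbook definition and never
# calls the package path it checks.

# Random informative 2x2 stratum sets (counts 0..max_count, at least one
# informative stratum, every stratum non-empty).
random_strata <- function(n_strata, max_count = 10, min_informative = 2) {
  repeat {
    st <- data.frame(
      a = sample(0:max_count, n_strata, replace = TRUE),
      b = sample(0:max_count, n_strata, replace = TRUE),
      c = sample(0:max_count, n_strata, replace = TRUE),
      d = sample(0:max_count, n_strata, replace = TRUE)
    )
    inf <- with(st, (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0)
    if (sum(inf) >= min_informative) return(st[inf, , drop = FALSE])
  }
}

# Reference Mantel-Haenszel via stats::mantelhaen.test (independent
# implementation of the same textbook formulas).
mh_reference <- function(strata) {
  arr <- array(0, dim = c(2, 2, nrow(strata)))
  for (i in seq_len(nrow(strata)))
    arr[, , i] <- matrix(c(strata$a[i], strata$c[i],
                           strata$b[i], strata$d[i]), 2)
  mt <- stats::mantelhaen.test(arr, correct = TRUE, exact = FALSE)
  list(or = unname(mt$estimate), chisq = unname(mt$statistic))
}

# Exhaustive Fitch parsimony on the rooted topology ((P,S),O): enumerate
# all internal-node state assignments, keep the minimal-cost ones, and
# record which branches change in each. Returns the site class the
# classifier should assign.
fitch_oracle <- function(p, s, o, states = LETTERS[1:20]) {
  grid <- expand.grid(anc = states, root = states,
                      stringsAsFactors = FALSE)
  cost <- (grid$anc != p) + (grid$anc != s) +
    (grid$root != o) + (grid$root != grid$anc)
  minimal <- grid[cost == min(cost), , drop = FALSE]
  if (min(cost) == 0) return(list(state = "conserved", lineage = "none"))
  branch_sets <- apply(minimal, 1, function(r) {
    paste(sort(c(if (r[["anc"]] != p) "principal",
                 if (r[["anc"]] != s) "sister",
                 if (r[["root"]] != o) "outgroup",
                 if (r[["root"]] != r[["anc"]]) "internal")),
          collapse = "+")
  })
  sets <- unique(branch_sets)
  if (identical(sets, "sister"))
    return(list(state = "variable", lineage = "sister"))
  if (identical(sets, "principal"))
    return(list(state = "excluded", lineage = "principal"))
  if (setequal(sets, c("outgroup", "internal")))
    return(list(state = "excluded", lineage = "outgroup-or-ancestral"))
  list(state = "excluded", lineage = "ambiguous")
}

# Build a codon_alignment object directly from per-species amino-acid
# vectors (codons chosen as the first codon of each amino acid's family;
# "-" marks a gap).
make_trio_alignment <- function(p, s, o, ids = c("gP", "gS", "gO")) {
  ct <- akashi::codon_table()
  codon_of <- function(aa) {
    vapply(aa, function(x)
      if (x == "-") "---" else ct$families[[x]][1], character(1),
      USE.NAMES = FALSE)
  }
  aa <- rbind(principal = p, sister = s, outgroup = o)
  codons <- rbind(principal = codon_of(p), sister = codon_of(s),
                  outgroup = codon_of(o))
  structure(list(codons = codons, aa = aa,
                 gene_ids = stats::setNames(ids,
                                            c("principal", "sister",
                                              "outgroup")),
                 n_col = length(p)),
            class = "codon_alignment")
}

# Brute-force optimality-tied pathway enumerator: keeps a pair iff the
# third bases match, both endpoint families have the same (defined)
# favored base, and every codon on every substitution ordering of the
# differing first/second positions is a sense codon whose family has
# that same favored base. Falls straight out of enumerating orderings.
brute_tied <- function(a, b, favored) {
  ct <- akashi::codon_table()
  fav <- function(codon) {
    f <- ct$family_of[codon]
    if (is.na(f)) NA_character_ else unname(favored[f])
  }
  if (a == b) return(TRUE)
  if (substr(a, 3, 3) != substr(b, 3, 3)) return(FALSE)
  fa <- fav(a); fb <- fav(b)
  if (is.na(fa) || is.na(fb) || fa != fb) return(FALSE)
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  orderings <- if (length(diffs) <= 1L) list(diffs) else
    list(diffs, rev(diffs))
  for (ord in orderings) {
    cur <- a
    for (pos in ord) {
      substr(cur, pos, pos) <- substr(b, pos, pos)
      is_end <- cur == b
      if (!akashi::is_sense_codon(cur)) return(FALSE)
      fc <- fav(cur)
      if (is.na(fc) || fc != fa) return(FALSE)
      if (is_end) break
    }
  }
  TRUE
}

# Independent ENC implementation, written as a literal per-amino-acid
# loop over Wright's estimator.
enc_oracle <- function(codons) {
  ct <- akashi::codon_table()
  groups <- list(`2` = c("F", "Y", "H", "Q", "N", "K", "D", "E", "C"),
                 `3` = "I",
                 `4` = c("V", "P", "T", "A", "G"),
                 `6` = c("L", "S", "R"))
  codons <- codons[akashi::is_sense_codon(codons)]
  aa_of <- akashi::translate_codons(codons)
  Fbar <- sapply(groups, function(aas) {
    vals <- c()
    for (aa in aas) {
      cods <- ct$families[[aa]]
      counts <- sapply(cods, function(cd) sum(codons == cd & aa_of == aa))
      n <- sum(counts)
      if (n >= 2) {
        f <- (n * sum((counts / n)^2) - 1) / (n - 1)
        if (!is.na(f) && f > 0) vals <- c(vals, f)
      }
    }
    if (length(vals)) mean(vals) else NA_real_
  })
  if (is.na(Fbar[["3"]])) Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  if (any(is.na(Fbar))) return(NA_real_)
  nc <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
    3 / Fbar[["6"]]
  min(61, max(20, nc))
}

# Random valid CDS of n internal codons (uniform sense codons).
random_cds <- function(n_codons) {
  triplets <- akashi:::.ACGT_TRIPLETS
  sense <- triplets[!triplets %in% c("TAA", "TAG", "TGA")]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}
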