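test_that("RSCU and RFSC match hand evaluation and their algebraic ties", {
  cnt <- count_table(AAA = 3, AAG = 1)
  r <- rscu(cnt)
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))
  f <- rfsc(cnt)
  expect_equal(unname(f[c("AAA", "AAG")]), c(0.75, 0.25))

  expect_equal(unname(rscu(count_table(AAA = 5, AAG = 5))[c("AAA", "AAG")]),
               c(1, 1))
  # single observed codon of the 6-fold Leu family
  expect_equal(unname(rscu(count_table(TTA = 4))["TTA"]), 6)
  # unobserved families stay undefined, not zero
  expect_true(is.na(rscu(cnt)["GGA"]))

  # family sums and the RSCU = n_i * RFSC identity on random tables
  set.seed(42)
  for (rep in 1:5) {
    cnt <- stats::setNames(as.numeric(stats::rpois(64, 8)), codons64)
    r <- rscu(cnt); f <- rfsc(cnt)
    for (aa in names(oracle_fams)) {
      fam <- intersect(oracle_fams[[aa]], inf59)
      if (!length(fam) || all(is.na(r[fam]))) next
      expect_equal(sum(r[fam]), length(fam))
      expect_equal(sum(f[fam]), 1)
    }
    ni <- vapply(inf59, function(cd) length(oracle_fams[[oracle_code[cd]]]),
                 numeric(1))
    expect_equal(r, f * ni, ignore_attr = TRUE)
  }
})

test_that("ENC hits its analytic limits and agrees with a brute-force evaluator", {
  # one codon per family, each amino acid seen twice -> all F = 1 -> ENC = 20
  one_per_family <- vapply(names(oracle_fams), function(aa)
    oracle_fams[[aa]][1], character(1))
  gene <- paste0("ATG", strrep(paste(one_per_family, collapse = ""), 2), "TAA")
  expect_equal(enc(codon_counts(gene)), 20)

  # exactly uniform usage in every family, 3540 codons -> ENC within 0.5 of 61
  uniform <- paste0("ATG", strrep(paste(inf59, collapse = ""), 60), "TAA")
  expect_gt(enc(codon_counts(uniform)), 60.5)
  expect_lte(enc(codon_counts(uniform)), 61)

  # agreement with the independent direct-formula evaluator, and
  # monotonicity: concentrating usage within a family never increases ENC
  base <- codon_counts(uniform)
  prev <- Inf
  for (shift in c(0, 20, 40, 55)) {
    cnt <- as.numeric(base); names(cnt) <- names(base)
    cnt["AAA"] <- cnt["AAA"] + shift
    cnt["AAG"] <- cnt["AAG"] - shift
    e <- enc(cnt)
    expect_equal(e, brute_enc(cnt), tolerance = 1e-12)
    expect_lte(e, prev)
    prev <- e
  }

  # a gene missing a whole degeneracy class of {2,4,6} has undefined ENC
  expect_true(is.na(enc(count_table(AAA = 5, AAG = 5))))
})

test_that("the expected-ENC curve has the right endpoints and symmetry", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_equal(expected_enc(0.5), 60.5)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s) - s, expected_enc(1 - s) - (1 - s))
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
})

test_that("SCUO spans its limits and matches a hand entropy computation", {
  uniform <- paste0("ATG", strrep(paste(inf59, collapse = ""), 2), "TAA")
  expect_equal(scuo(codon_counts(uniform)), 0)

  one_per_family <- vapply(names(oracle_fams), function(aa)
    oracle_fams[[aa]][1], character(1))
  gene <- paste0("ATG", strrep(paste(one_per_family, collapse = ""), 2), "TAA")
  expect_equal(scuo(codon_counts(gene)), 1)

  # Lys only, 3:1 -> O = 1 - H(0.75, 0.25)
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(scuo(count_table(AAA = 3, AAG = 1)), 1 - h)
  expect_equal(round(scuo(count_table(AAA = 3, AAG = 1)), 5), 0.18872)
})

test_that("MILC is -C at the reference null and grows away from it", {
  gene <- count_table(AAA = 6, AAG = 2, TTT = 4, TTC = 4, GGT = 2, GGC = 2,
                      GGA = 2, GGG = 2)
  ref <- gene * 50
  L <- sum(gene)
  C <- ((2 - 1) + (2 - 1) + (4 - 1)) / L   # Lys, Phe, Gly families present
  expect_equal(milc(gene, ref), -C)

  # moving usage away from the reference at fixed L strictly increases MILC
  vals <- vapply(0:2, function(k) {
    g <- gene
    g["AAA"] <- g["AAA"] + k
    g["AAG"] <- g["AAG"] - k
    milc(g, ref)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  # zero reference count for an observed codon: pseudocount keeps it finite
  ref0 <- ref; ref0["AAG"] <- 0
  expect_true(is.finite(milc(gene, ref0)))
})

test_that("CAI weights and scores follow the reference-set definition", {
  ref <- count_table(AAA = 30, AAG = 10, TTT = 20, TTC = 0)
  w <- cai_weights(ref)
  expect_equal(unname(w[c("AAA", "AAG")]), c(1, 1 / 3))
  expect_equal(unname(w["TTT"]), 1)
  expect_equal(unname(w["TTC"]), 0.01)        # unobserved codon floor
  expect_equal(cai_weights(ref * 10), w)      # scale invariance
  expect_true(is.na(w["GGA"]))                # family absent from reference

  expect_equal(cai(count_table(AAA = 7, TTT = 3), w), 1)
  expect_equal(cai(count_table(AAA = 1, AAG = 1), c(AAA = 1, AAG = 0.25)), 0.5)

  sim <- simulate_cds_set(10, c(100, 200), seed = 21)
  wref <- cai_weights(codon_counts(sim$set))
  for (s in sim$set$seq) {
    v <- cai(codon_counts(s), wref)
    expect_gt(v, 0); expect_lte(v, 1)
  }
  expect_error(cai_weights(count_table()), "empty")
})

test_that("Fop and CBI behave at their anchors", {
  opt <- c("AAA", "TTT")
  all_opt <- count_table(AAA = 10, TTT = 5)
  expect_equal(unname(fop_cbi(all_opt, opt)), c(1, 1))

  uniform <- count_table(AAA = 5, AAG = 5, TTT = 5, TTC = 5)
  expect_equal(unname(fop_cbi(uniform, opt)["CBI"]), 0)
  expect_equal(unname(fop_cbi(uniform, character(0))["Fop"]), 0)
})

test_that("protein properties: translation, GRAVY, aromaticity, pI", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_equal(unname(protein_properties("ATGAAATAA")["L_aa"]), 2)
  expect_error(translate_cds(paste0("ATG", "TAA", "AAATAA")), "internal stop")

  # poly-Ile: GRAVY is the single-residue hydropathy value
  poly_ile <- paste0(strrep("ATTATCATA", 3), "TAA")
  expect_equal(unname(protein_properties(poly_ile)["GRAVY"]), 4.5)
  expect_equal(unname(protein_properties(poly_ile)["aromaticity"]), 0)
  expect_equal(unname(protein_properties("TTTTACTGGTAA")["aromaticity"]), 1)

  # pI ordering: acidic << basic proteins; all within [0, 14]
  poly_asp <- paste0(strrep("GAT", 20), "TAA")
  poly_lys <- paste0(strrep("AAA", 20), "TAA")
  pi_d <- unname(protein_properties(poly_asp)["pI"])
  pi_k <- unname(protein_properties(poly_lys)["pI"])
  expect_lt(pi_d, 4.5)
  expect_gt(pi_k, 9)
  expect_true(pi_d >= 0 && pi_k <= 14)
})
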