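test_that("spacing ledger matches the printed intergenic column for all five species", {
  for (sp in mileewinae_species()) {
    g <- mileewinae_fixture(sp)
    printed <- attr(g, "printed_spacing")
    led <- compute_spacing_ledger(g, include_cr_boundaries = TRUE)
    led <- led[-nrow(led), ]  # drop the circular wrap pair
    expect_equal(led$spacing, unname(printed[led$next_gene]), label = sp)
  }
})

test_that("published boundary examples reproduce from the fixture", {
  mira <- compute_spacing_ledger(mileewinae_fixture("M_mira"))
  expect_equal(mira$spacing[mira$next_gene == "trnQ"], -3)
  expect_equal(mira$spacing[mira$prev_gene == "nad6"], -12)
  psex <- compute_spacing_ledger(mileewinae_fixture("P_sexmaculata"))
  expect_equal(psex$spacing[psex$prev_gene == "cytb"], 24)
  # abutting features give spacing zero
  g <- mitogenome("t", strrep("N", 20),
                  gene_features(c("trnI", "trnQ"), c(1, 11), c(10, 20), "H"))
  expect_equal(compute_spacing_ledger(g)$spacing, 0)
  # fewer than two features -> empty ledger
  expect_equal(nrow(compute_spacing_ledger(
    mitogenome("t", "NNNN", gene_features("trnI", 1, 4, "H")))), 0)
})

test_that("layout summary reports strand split and extrema seen in the study", {
  for (sp in mileewinae_species()) {
    s <- summarize_layout(mileewinae_fixture(sp))
    expect_equal(s$h_count, 23, label = sp)
    expect_equal(s$l_count, 14, label = sp)
    expect_equal(as.integer(s$h_by_class[c("PCG", "tRNA")]), c(9, 14), label = sp)
    expect_equal(as.integer(s$l_by_class[c("PCG", "tRNA", "rRNA")]), c(4, 8, 2),
                 label = sp)
  }
  psex <- summarize_layout(mileewinae_fixture("P_sexmaculata"))
  expect_equal(nrow(psex$overlaps), 10)
  expect_equal(nrow(psex$spacers), 14)
  # published count for M. sharpa is 16 overlaps; the printed coordinate
  # column itself yields 17 negative gaps, which is what the arithmetic gives
  sharpa <- summarize_layout(mileewinae_fixture("M_sharpa"))
  expect_equal(nrow(sharpa$overlaps), 17)
  single <- summarize_layout(mitogenome("t", "NNNN",
                                        gene_features("trnI", 1, 4, "H")))
  expect_equal(nrow(single$overlaps), 0)
  expect_equal(nrow(single$spacers), 0)
})

test_that("ledger plus gene lengths reconstructs genome length", {
  for (sp in mileewinae_species()) {
    g <- mileewinae_fixture(sp)
    f <- g$features
    led <- compute_spacing_ledger(g, include_cr_boundaries = TRUE)
    led <- led[-nrow(led), ]  # drop circular wrap pair
    expect_equal(sum(f$end - f$start + 1L) + sum(led$spacing),
                 genome_length(g), label = sp)
  }
})

test_that("spacing is antisymmetric under coordinate reflection", {
  g <- mileewinae_fixture("M_mira")
  L <- genome_length(g)
  f <- g$features
  refl <- gene_features(f$name, L - f$end + 1L, L - f$start + 1L,
                        ifelse(f$strand == "H", "L", "H"),
                        f$start_codon, f$stop_codon)
  gr <- mitogenome("refl", strrep("N", L), refl)
  a <- compute_spacing_ledger(g, include_cr_boundaries = TRUE)
  b <- compute_spacing_ledger(gr, include_cr_boundaries = TRUE)
  n <- nrow(a)
  expect_equal(b$spacing[seq_len(n - 1)], rev(a$spacing[seq_len(n - 1)]))
  expect_equal(b$prev_gene[seq_len(n - 1)], rev(a$next_gene[seq_len(n - 1)]))
})

test_that("gene-order signature is rotation invariant and strand sensitive", {
  sigs <- vapply(mileewinae_species(),
                 function(sp) gene_order_signature(mileewinae_fixture(sp)), "")
  expect_length(unique(sigs), 1)
  # rotate a genome by 1000 bp
  g <- mileewinae_fixture("M_mira")
  L <- genome_length(g)
  f <- g$features
  shift <- function(x) (x + 1000L - 1L) %% L + 1L
  rot <- mitogenome("rot", strrep("N", L),
                    gene_features(f$name, shift(f$start), shift(f$end),
                                  f$strand, f$start_codon, f$stop_codon))
  expect_equal(gene_order_signature(rot), gene_order_signature(g))
  # flipping one tRNA strand changes the signature
  f2 <- f
  f2$strand[f2$name == "trnG"] <- "L"
  flipped <- mitogenome("flip", strrep("N", L), f2)
  expect_false(gene_order_signature(flipped) == gene_order_signature(g))
  expect_error(gene_order_signature(mitogenome("e", "NNNN")), "no features")
})
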