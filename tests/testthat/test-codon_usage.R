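test_that("codon families partition the 62 non-stop codons with split Leu/Ser", {
  fam <- codon_families()
  expect_equal(nrow(fam), 62)
  expect_false(any(c("UAA", "UAG") %in% fam$codon))
  expect_setequal(fam$codon[fam$family == "Leu2"], c("UUA", "UUG"))
  expect_setequal(fam$codon[fam$family == "Leu1"], c("CUU", "CUC", "CUA", "CUG"))
  expect_setequal(fam$codon[fam$family == "Ser1"], c("AGU", "AGC", "AGA", "AGG"))
  expect_setequal(fam$codon[fam$family == "Ser2"], c("UCU", "UCC", "UCA", "UCG"))
  # UGA is tryptophan in the invertebrate mitochondrial code
  expect_equal(fam$amino_acid[fam$codon == "UGA"], "W")
  expect_equal(sum(fam$k[!duplicated(fam$family)]), 62)
})

test_that("RSCU matches hand computations and its defining identity", {
  r <- compute_rscu(c(UUA = 3, UUG = 1))
  expect_equal(r$rscu[r$codon == "UUA"], 1.5)
  expect_equal(r$rscu[r$codon == "UUG"], 0.5)
  r2 <- compute_rscu(c(UUA = 2, UUG = 2))
  expect_equal(r2$rscu[r2$family == "Leu2"], c(1, 1))
  r3 <- compute_rscu(c(GGU = 4, GGC = 0, GGA = 0, GGG = 0))
  expect_equal(sort(r3$rscu[r3$family == "Gly"]), c(0, 0, 0, 4))
  # empty family reports NA, not zero
  expect_true(all(is.na(r$rscu[r$family == "Gly"])))
  expect_error(compute_rscu(c(UUA = -1)), "negative")
})

test_that("mean RSCU is 1 in every non-empty family for random counts", {
  set.seed(91)
  fam <- codon_families()
  for (i in 1:20) {
    counts <- stats::setNames(rpois(62, lambda = sample(1:50, 1)), fam$codon)
    r <- compute_rscu(counts)
    means <- tapply(r$rscu, r$family, mean)
    nonzero <- tapply(r$count, r$family, sum) > 0
    expect_true(all(abs(means[nonzero] - 1) < 1e-9))
  }
})

test_that("codon extraction drops incomplete stops and flags internal stops", {
  g <- mitogenome("t", "ATGAAATA", gene_features("atp8", 1, 8, "H", "ATG", "TA"))
  expect_equal(extract_codons(g), list(atp8 = c("ATG", "AAA")))
  g2 <- mitogenome("t", "TTGAAATAA",
                   gene_features("atp8", 1, 9, "H", "TTG", "TAA"))
  expect_equal(classify_terminal_codons(g2)$start_codon, "TTG")
  # internal in-frame stop is a warning naming the gene, not an error
  g3 <- mitogenome("t", "ATGTAAAAATAA",
                   gene_features("atp8", 1, 12, "H", "ATG", "TAA"))
  expect_warning(extract_codons(g3), "atp8.*codon 2")
  # no PCGs -> empty result
  g4 <- mitogenome("t", "ACGTACGT", gene_features("trnI", 1, 4, "H"))
  expect_length(extract_codons(g4), 0)
})

test_that("terminal codon classification follows the span mod-3 rule", {
  # span = 1 mod 3 ending T -> incomplete stop T
  g <- mitogenome("t", "ATGAAAT", gene_features("atp8", 1, 7, "H", "ATG", "T"))
  tc <- classify_terminal_codons(g)
  expect_equal(tc$stop_codon, "T")
  expect_false(tc$complete)
  # complete TAG
  g2 <- mitogenome("t", "ATGAAATAG", gene_features("atp8", 1, 9, "H", "ATG", "TAG"))
  expect_true(classify_terminal_codons(g2)$complete)
  # span = 2 mod 3 ending CA is not a recognizable incomplete stop
  g3 <- mitogenome("t", "ATGAAACA", gene_features("atp8", 1, 8, "H", "ATG", "TA"))
  g3$sequence <- "ATGAAACA"
  expect_error(classify_terminal_codons(g3), "unrecognized incomplete")
  # span shorter than 6 bp
  g4 <- mitogenome("t", "ATGTA", gene_features("trnI", 1, 5, "H"))
  g4$features$gene_class <- "PCG"
  expect_error(classify_terminal_codons(g4), "shorter than 6")
})

test_that("synthetic genomes reproduce their specified terminal codons", {
  res <- generate_mitogenome(synth_spec(seed = 5))
  tc <- classify_terminal_codons(res$genome)
  got_stop <- stats::setNames(tc$stop_codon, tc$gene)
  got_start <- stats::setNames(tc$start_codon, tc$gene)
  expect_equal(got_stop[names(res$ground_truth$stop_codons)],
               res$ground_truth$stop_codons)
  expect_equal(got_start[names(res$ground_truth$start_codons)],
               res$ground_truth$start_codons)
})

test_that("AT-rich genomes use AT-only top codons and counts tie to PCG length", {
  g <- toy_real_genome()
  codons <- extract_codons(g)
  expect_equal(length(unlist(codons)) * 3, nchar(concatenate_pcgs(g)))
  counts <- count_codons(codons)
  top4 <- names(sort(counts, decreasing = TRUE))[1:4]
  expect_true(all(!grepl("[GC]", top4)))
  # start codons can be excluded
  counts_nostart <- count_codons(codons, include_start = FALSE)
  expect_equal(sum(counts) - sum(counts_nostart), 13)
})
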