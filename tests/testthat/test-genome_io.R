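test_that("gene names normalize across annotation styles and fail loudly", {
  expect_equal(normalize_gene_name(c("ND5", "COI", "COX3", "ATPase6", "cob")),
               c("nad5", "cox1", "cox3", "atp6", "cytb"))
  expect_equal(normalize_gene_name(c("tRNA-Leu(UUR)", "trnS(tga)", "D-loop",
                                     "16S ribosomal RNA")),
               c("trnL2", "trnS2", "control_region", "rrnL"))
  expect_error(normalize_gene_name("made_up_gene"), "unmappable")
})

test_that("feature validation enforces the coordinate and mod-3 invariants", {
  expect_error(mitogenome("x", "ACGT", gene_features("trnI", 2, 9, "H")),
               "outside")
  expect_error(
    mitogenome("x", strrep("A", 30),
               gene_features("atp8", 1, 10, "H", "ATG", "TAA")),
    "divisible by 3")
  # wrapping feature allowed only on circular genomes
  feats <- gene_features("trnI", 25, 4, "H")
  expect_silent(mitogenome("x", strrep("A", 30), feats, circular = TRUE))
  expect_error(mitogenome("x", strrep("A", 30), feats, circular = FALSE),
               "wrapping")
  expect_equal(feature_length(mitogenome("x", strrep("A", 30), feats), feats),
               30 - 25 + 1 + 4)
})

test_that("extract_feature_sequence handles strands and origin wrap", {
  g <- mitogenome("t", "ATGCCC", gene_features(c("trnI", "trnQ"), c(1, 1),
                                               c(3, 3), c("H", "L")))
  expect_equal(extract_feature_sequence(g, g$features[1, ]), "ATG")
  expect_equal(extract_feature_sequence(g, g$features[2, ]), "CAT")
  gw <- mitogenome("w", "AAATTT", gene_features("trnI", 5, 2, "H"))
  expect_equal(extract_feature_sequence(gw, "trnI"), "TTAA")
  gl <- mitogenome("w2", "AAATTT", gene_features("trnI", 5, 2, "L"))
  expect_equal(extract_feature_sequence(gl, "trnI"), "TTAA")  # revcomp of TTAA
  expect_error(extract_feature_sequence(mileewinae_fixture(), "trnI"),
               "placeholder")
})

test_that("coordinate-table fixtures load with correct lengths and reject bad input", {
  path <- system.file("extdata", "mileewinae_table1.tsv", package = "mitochar")
  g1 <- read_coordinate_table(path, 1)
  expect_equal(g1$features$end[g1$features$name == "trnI"], 64)
  expect_equal(genome_length(read_coordinate_table(path, "M_amplimacula")), 15436)
  expect_true(has_placeholder_sequence(g1))
  # degenerate/bad fixtures
  tf <- tempfile(fileext = ".tsv")
  writeLines("gene\tstrand\tfrom_A\tto_A", tf)
  expect_error(read_coordinate_table(tf, 1), "empty")
  writeLines(c("gene\tstrand\tto_A", "trnI\tH\t64"), tf)
  expect_error(read_coordinate_table(tf, 1), "from")
  writeLines(c("gene\tstrand\tfrom_A\tto_A", "trnI\tH\tx\t64"), tf)
  expect_error(read_coordinate_table(tf, 1), "coordinate")
})

test_that("every fixture PCG satisfies the incomplete-stop mod-3 rule", {
  for (sp in mileewinae_species()) {
    f <- mileewinae_fixture(sp)$features
    pcg <- f[f$gene_class == "PCG", ]
    trim <- ifelse(pcg$stop_codon == "TA", 2L, ifelse(pcg$stop_codon == "T", 1L, 0L))
    expect_true(all((pcg$end - pcg$start + 1L - trim) %% 3L == 0L), label = sp)
  }
})

test_that("GenBank write -> read round trip is lossless on synthetic genomes", {
  for (seed in 1:8) {
    g <- generate_mitogenome(synth_spec(seed = seed))$genome
    tf <- tempfile(fileext = ".gb")
    g2 <- read_genbank(write_genbank(g, tf))
    expect_identical(g2$sequence, g$sequence)
    expect_identical(g2$features, g$features)
    expect_identical(g2$circular, g$circular)
    expect_identical(g2$id, g$id)
    unlink(tf)
  }
  # origin-wrapping feature survives as a join() location
  gw <- mitogenome("wrap", strrep("ACGT", 10),
                   gene_features("trnI", 35, 6, "L"))
  tf <- tempfile(fileext = ".gb")
  gw2 <- read_genbank(write_genbank(gw, tf))
  expect_identical(gw2$features, gw$features)
  unlink(tf)
})

test_that("GenBank reader errors on malformed records and derives codons from sequence", {
  g <- toy_real_genome()
  tf <- tempfile(fileext = ".gb")
  write_genbank(g, tf)
  # codons are derived from the sequence, not qualifiers: no codon qualifiers
  # are written, yet the round trip restores Table-style annotations
  g2 <- read_genbank(tf)
  expect_false(anyNA(g2$features$stop_codon[g2$features$gene_class == "PCG"]))
  # multi-record file
  tf2 <- tempfile(fileext = ".gb")
  writeLines(c(readLines(tf), readLines(tf)), tf2)
  expect_error(read_genbank(tf2), "one GenBank record")
  # unmappable gene name
  lines <- readLines(tf)
  lines <- sub("/gene=\"trnI\"", "/gene=\"nonsense\"", lines, fixed = TRUE)
  writeLines(lines, tf2)
  expect_error(read_genbank(tf2), "unmappable")
  # record with zero features parses to an empty feature list
  writeLines(c("LOCUS       empty 6 bp DNA circular", "ORIGIN",
               "        1 acgtaa", "//"), tf2)
  g3 <- read_genbank(tf2)
  expect_equal(nrow(g3$features), 0)
  expect_equal(g3$sequence, "ACGTAA")
  unlink(c(tf, tf2))
})

test_that("FASTA round trip preserves sequences", {
  seqs <- c(a = "ACGTACGT", b = "TTTTAAAA")
  tf <- tempfile(fileext = ".fa")
  expect_equal(read_fasta(write_fasta(seqs, tf)), seqs)
  unlink(tf)
})
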