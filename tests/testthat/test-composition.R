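test_that("content and skew follow their definitions on hand cases", {
  expect_equal(content_and_skew("AATT")$at_skew, 0)
  x <- content_and_skew("AAAT")
  expect_equal(x$at_skew, 0.5)
  expect_equal(x$at_content, 100)
  y <- content_and_skew("GGGC")
  expect_equal(y$gc_skew, 0.5)
  expect_equal(y$gc_content, 100)
  expect_true(is.na(content_and_skew("GGGG")$at_skew))
  expect_true(is.na(content_and_skew("AAAA")$gc_skew))
  expect_error(content_and_skew(""), "non-empty")
  # N excluded from numerators and denominators; size keeps it
  z <- content_and_skew("AANT")
  expect_equal(z$size, 4)
  expect_equal(z$at_content, 100)
  expect_equal(z$at_skew, 1 / 3)
})

test_that("reverse complement negates both skews", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(50 + i * 7, c(A = .4, C = .1, G = .1, T = .4))
    a <- content_and_skew(s)
    b <- content_and_skew(reverse_complement(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
    expect_equal(b$at_content, a$at_content)
  }
})

test_that("PCG concatenation lengths reproduce the published aggregate sizes", {
  published <- c(M_mira = 10953, M_lamellata = 10947, M_sharpa = 10956,
                 M_amplimacula = 10947, P_sexmaculata = 10944)
  for (sp in names(published)) {
    pc <- concatenate_pcgs(mileewinae_fixture(sp))
    expect_equal(nchar(pc), unname(published[sp]), label = sp)
    expect_equal(nchar(pc) %% 3, 0, label = sp)
  }
  # complete-stop toy gene is untouched
  g <- mitogenome("t", "ATGAAATAA", gene_features("atp8", 1, 9, "H", "ATG", "TAA"))
  expect_equal(concatenate_pcgs(g), "ATGAAATAA")
  bad <- mitogenome("t", strrep("N", 10), gene_features("atp8", 1, 9, "H", "ATG", "TAA"))
  bad$features$end <- 10L  # corrupt after validation to hit the runtime check
  expect_error(concatenate_pcgs(bad), "atp8")
})

test_that("codon-position slices interleave back to the input", {
  expect_equal(codon_position_slices("ATGTTT"), list("AT", "TT", "GT"))
  expect_error(codon_position_slices("ATGA"), "divisible")
  set.seed(3)
  s <- random_dna(3 * 123)
  sl <- codon_position_slices(s)
  expect_true(all(nchar(unlist(sl)) == 123))
  rebuilt <- paste(as.vector(rbind(strsplit(sl[[1]], "")[[1]],
                                   strsplit(sl[[2]], "")[[1]],
                                   strsplit(sl[[3]], "")[[1]])), collapse = "")
  expect_equal(rebuilt, s)
})

test_that("region sizes reproduce the published size column for all species", {
  expected <- list(
    # region = c(per-species values in fixture order)
    "PCGs" = c(10953, 10947, 10956, 10947, 10944),
    "1st codon position" = c(3651, 3649, 3652, 3649, 3648),
    "l-rRNA" = c(1196, 1196, 1180, 1217, 1207),
    "s-rRNA" = c(748, 755, 740, 757, 750),
    "rRNAs" = c(1944, 1951, 1920, 1974, 1957),
    "tRNAs" = c(1438, 1439, 1422, 1440, 1429),
    "control_region" = c(591, 446, 601, 1062, 996),
    "Full genome" = c(14917, 14787, 14859, 15436, 15404))
  for (i in seq_along(mileewinae_species())) {
    rs <- region_sizes(mileewinae_fixture(mileewinae_species()[i]))
    for (region in names(expected)) {
      expect_equal(rs$size[rs$region == region], expected[[region]][i],
                   label = paste(mileewinae_species()[i], region))
    }
    expect_equal(rs$size[rs$region == "2nd codon position"],
                 rs$size[rs$region == "1st codon position"])
  }
})

test_that("region report works on real sequence and refuses placeholders", {
  g <- toy_real_genome()
  rep <- region_report(g)
  expect_true(all(c("PCGs", "tRNAs", "rRNAs", "control_region", "Full genome")
                  %in% rep$region))
  expect_equal(rep$size[rep$region == "PCGs"], 10953)
  # contents sum to 100 without ambiguous bases
  expect_equal(rep$at_content + rep$gc_content, rep(100, nrow(rep)))
  expect_error(region_report(mileewinae_fixture()), "real sequence")
  # all-AT genome has zero GC everywhere
  gat <- mitogenome("at", "ATATATATAATTTA",
                    gene_features("trnI", 1, 4, "H"))
  rr <- content_and_skew(gat$sequence)
  expect_equal(rr$gc_content, 0)
})
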