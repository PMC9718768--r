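#' Synonymous codon families of the invertebrate mitochondrial code
#'
#' The 62 non-stop codons of translation table 5 partitioned into
#' synonymous families, using the split two/four-fold convention for
#' leucine and serine that matches the two tRNAs decoding each: `Leu1` =
#' CUN, `Leu2` = UUA/UUG, `Ser1` = AGN (AGA/AGG are serine in this code),
#' `Ser2` = UCN. Stop codons (UAA, UAG) are excluded.
#'
#' @return A data frame with columns `codon` (RNA alphabet), `family`
#'   (e.g. `"Leu2"`), `amino_acid` (one-letter), and `k` (family size).
#' @export
#' @examples
#' subset(codon_families(), family == "Leu2")
codon_families <- function() {
  code <- Biostrings::getGeneticCode("5")
  codons_dna <- names(code)
  keep <- code != "*"
  codon <- chartr("T", "U", codons_dna[keep])
  aa <- unname(code[keep])
  fam <- vapply(seq_along(codon), function(i) {
    if (aa[i] == "L") {
      if (substr(codon[i], 1, 2) == "CU") "Leu1" else "Leu2"
    } else if (aa[i] == "S") {
      if (substr(codon[i], 1, 2) == "AG") "Ser1" else "Ser2"
    } else {
      aa_name <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                   Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                   K = "Lys", M = "Met", F = "Phe", P = "Pro", T = "Thr",
                   W = "Trp", Y = "Tyr", V = "Val")
      aa_name[[aa[i]]]
    }
  }, "")
  k <- as.integer(table(fam)[fam])
  data.frame(codon = codon, family = fam, amino_acid = aa, k = k,
             stringsAsFactors = FALSE)
}

#' Extract codons from every protein-coding gene
#'
#' Returns the coding-strand triplets of each PCG with trailing
#' incomplete-stop bases dropped. Complete terminal stop codons are
#' retained in the per-gene codon lists (they are excluded later by
#' [count_codons()]). An internal in-frame stop codon raises a warning
#' naming the gene and codon index (an annotation smell), not an error.
#'
#' @param genome A [mitogenome()] with a real sequence and PCG stop-codon
#'   annotations.
#' @return A named list, one character vector of codons per PCG, in genome
#'   order.
#' @export
extract_codons <- function(genome) {
  f <- genome$features
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  out <- list()
  stops <- c("TAA", "TAG")
  for (i in seq_len(nrow(pcg))) {
    s <- extract_feature_sequence(genome, pcg[i, ])
    trim <- incomplete_stop_bases(pcg$stop_codon[i])
    s <- substr(s, 1L, nchar(s) - trim)
    if (nchar(s) %% 3L != 0L) {
      stop("coding length of ", pcg$name[i], " not divisible by 3")
    }
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    internal <- which(codons[-length(codons)] %in% stops)
    if (length(internal)) {
      warning("internal in-frame stop codon(s) in ", pcg$name[i],
              " at codon ", paste(internal, collapse = ", "))
    }
    out[[pcg$name[i]]] <- codons
  }
  out
}

#' Classify terminal codons of every protein-coding gene
#'
#' Reads each PCG's coding-strand span and classifies its start codon
#' (first triplet) and stop codon: a trailing `TAA`/`TAG` when the span
#' length is divisible by 3, else the incomplete forms `TA` (length mod 3
#' = 2) or `T` (mod 3 = 1), completed in vivo by polyadenylation. Any
#' other terminus is an error, as is a span shorter than 6 bp.
#'
#' @param genome A [mitogenome()] with a real sequence.
#' @return A data frame with columns `gene`, `start_codon`, `stop_codon`,
#'   `complete` (logical).
#' @export
classify_terminal_codons <- function(genome) {
  f <- genome$features
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  res <- lapply(seq_len(nrow(pcg)), function(i) {
    s <- extract_feature_sequence(genome, pcg[i, ])
    n <- nchar(s)
    if (n < 6L) stop("PCG span of ", pcg$name[i], " shorter than 6 bp")
    rem <- n %% 3L
    tail <- substr(s, n - (if (rem == 0L) 2L else rem - 1L), n)
    ok <- (rem == 0L && tail %in% c("TAA", "TAG")) ||
      (rem == 2L && tail == "TA") || (rem == 1L && tail == "T")
    if (!ok) {
      stop("unrecognized ", if (rem == 0L) "" else "incomplete ",
           "stop codon for ", pcg$name[i], ": span ends ", sQuote(tail))
    }
    data.frame(gene = pcg$name[i], start_codon = substr(s, 1, 3),
               stop_codon = tail, complete = rem == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Count codons over the non-stop codons of translation table 5
#'
#' @param codons Output of [extract_codons()] (or a plain character vector
#'   of codons, DNA or RNA alphabet). Stop codons are dropped.
#' @param include_start Count each gene's initial codon (default `TRUE`;
#'   start codons are in-frame and code an amino acid).
#' @return A named integer vector over the 62 non-stop codons (RNA
#'   alphabet).
#' @export
count_codons <- function(codons, include_start = TRUE) {
  if (is.list(codons) && !include_start) {
    codons <- lapply(codons, function(x) x[-1])
  }
  v <- chartr("T", "U", toupper(unlist(codons, use.names = FALSE)))
  fams <- codon_families()
  counts <- table(factor(v, levels = fams$codon))
  stats::setNames(as.integer(counts), fams$codon)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon *i* in a synonymous family of size *k* with counts
#' *X_1..X_k* is `k * X_i / sum_j X_j`: the observed count relative to the
#' family mean under uniform usage. Within every family with nonzero total
#' the mean RSCU is exactly 1; a family with zero total has its RSCU
#' reported as `NA`.
#'
#' @param codon_counts Named numeric vector of non-negative codon counts
#'   (DNA or RNA alphabet); missing codons count 0; stop codons are
#'   ignored.
#' @return A data frame with columns `codon`, `family`, `amino_acid`, `k`,
#'   `count`, `rscu`.
#' @export
#' @examples
#' compute_rscu(c(UUA = 3, UUG = 1))[c("codon", "rscu")]
compute_rscu <- function(codon_counts) {
  if (any(codon_counts < 0)) stop("negative codon counts")
  fams <- codon_families()
  key <- chartr("T", "U", toupper(names(codon_counts)))
  fams$count <- 0
  hit <- match(key, fams$codon)
  fams$count[hit[!is.na(hit)]] <- as.numeric(codon_counts[!is.na(hit)])
  totals <- tapply(fams$count, fams$family, sum)
  fam_total <- as.numeric(totals[fams$family])
  fams$rscu <- ifelse(fam_total == 0, NA_real_,
                      fams$k * fams$count / fam_total)
  fams
}

#' One-call RSCU table for a genome
#'
#' Extracts codons from all PCGs, counts them, and computes RSCU.
#'
#' @inheritParams extract_codons
#' @inheritParams count_codons
#' @return See [compute_rscu()].
#' @export
rscu_table <- function(genome, include_start = TRUE) {
  compute_rscu(count_codons(extract_codons(genome), include_start = include_start))
}
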