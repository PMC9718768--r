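#' Base counts, content percentages and strand-asymmetry skews
#'
#' Computes the standard mitogenome composition row for a sequence: counts
#' of T, C, A, G; AT, GC and GT content in percent; and the strand-asymmetry
#' statistics AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C).
#' Ambiguous bases (`N`) are excluded from all numerators and denominators.
#' A skew whose denominator is zero is reported as `NA`, not 0.
#'
#' @param seq Non-empty DNA string.
#' @param region Optional label carried into the output row.
#' @return A one-row data frame with columns `region`, `size`, `count_T`,
#'   `count_C`, `count_A`, `count_G`, `at_content`, `gc_content`,
#'   `gt_content`, `at_skew`, `gc_skew`. `size` is the full sequence length
#'   including ambiguous bases; contents/skews are over unambiguous bases.
#' @export
#' @examples
#' content_and_skew("AAAT")$at_skew  # 0.5
content_and_skew <- function(seq, region = NA_character_) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("seq must be a single non-empty DNA string")
  }
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  a <- counts[["A"]]; c_ <- counts[["C"]]; g <- counts[["G"]]; t <- counts[["T"]]
  tot <- a + c_ + g + t
  if (tot == 0) stop("sequence has no unambiguous bases")
  pct <- function(x) 100 * x / tot
  skew <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(region = region, size = nchar(seq),
             count_T = t, count_C = c_, count_A = a, count_G = g,
             at_content = pct(a + t), gc_content = pct(g + c_),
             gt_content = pct(g + t),
             at_skew = skew(a - t, a + t), gc_skew = skew(g - c_, g + c_),
             stringsAsFactors = FALSE)
}

#' Concatenate the 13 protein-coding genes on their coding strands
#'
#' Joins each PCG's coding-strand sequence in genome order, with the
#' annotated trailing incomplete-stop bases removed (1 base for stop `T`,
#' 2 for `TA`), so that the result length is divisible by 3. Placeholder
#' genomes are accepted: the concatenation is then all `N` but has the
#' correct length, which is what the published aggregate PCG sizes count.
#'
#' @param genome A [mitogenome()] carrying PCG annotations with stop
#'   codons.
#' @return A DNA string; its length is the aggregate PCG size under the
#'   incomplete-stop-exclusion convention.
#' @export
#' @examples
#' nchar(concatenate_pcgs(mileewinae_fixture("M_mira")))  # 10953
concatenate_pcgs <- function(genome) {
  f <- genome$features
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  if (!nrow(pcg)) stop("genome has no protein-coding genes")
  pieces <- character(nrow(pcg))
  for (i in seq_len(nrow(pcg))) {
    len <- feature_length(genome, pcg[i, ])
    trim <- incomplete_stop_bases(pcg$stop_codon[i])
    if ((len - trim) %% 3L != 0L) {
      stop("coding length of ", pcg$name[i],
           " not divisible by 3 after removing incomplete-stop bases")
    }
    s <- if (has_placeholder_sequence(genome)) {
      strrep("N", len)
    } else {
      extract_feature_sequence(genome, pcg[i, ])
    }
    pieces[i] <- substr(s, 1L, len - trim)
  }
  paste(pieces, collapse = "")
}

#' Split a concatenated coding sequence into codon-position slices
#'
#' @param pcg_concat DNA string whose length is divisible by 3.
#' @return A list of three strings: bases at codon positions 1, 2 and 3.
#' @export
#' @examples
#' codon_position_slices("ATGTTT")  # "AT", "TT", "GT"
codon_position_slices <- function(pcg_concat) {
  n <- nchar(pcg_concat)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not divisible by 3")
  chars <- strsplit(pcg_concat, "", fixed = TRUE)[[1]]
  lapply(1:3, function(k) paste(chars[seq(k, n, by = 3L)], collapse = ""))
}

.region_sequences <- function(genome, placeholder_ok = FALSE) {
  f <- genome$features
  get <- function(feat) {
    if (placeholder_ok && has_placeholder_sequence(genome)) {
      strrep("N", feature_length(genome, feat))
    } else {
      extract_feature_sequence(genome, feat)
    }
  }
  concat_class <- function(cls) {
    rows <- which(f$gene_class == cls)
    if (!length(rows)) return(NULL)
    paste(vapply(rows, function(i) get(f[i, ]), ""), collapse = "")
  }
  out <- list()
  pcgs <- concatenate_pcgs(genome)
  out[["PCGs"]] <- pcgs
  slices <- codon_position_slices(pcgs)
  out[["1st codon position"]] <- slices[[1]]
  out[["2nd codon position"]] <- slices[[2]]
  out[["3rd codon position"]] <- slices[[3]]
  for (i in which(f$gene_class == "PCG")) out[[f$name[i]]] <- get(f[i, ])
  lr <- which(f$name == "rrnL"); sr <- which(f$name == "rrnS")
  if (length(lr)) out[["l-rRNA"]] <- get(f[lr[1], ])
  if (length(sr)) out[["s-rRNA"]] <- get(f[sr[1], ])
  rr <- concat_class("rRNA"); if (!is.null(rr)) out[["rRNAs"]] <- rr
  tr <- concat_class("tRNA"); if (!is.null(tr)) out[["tRNAs"]] <- tr
  cr <- which(f$gene_class == "CR")
  if (length(cr)) {
    # control region composition is reported on the deposited (H) strand
    feat <- f[cr[1], ]; feat$strand <- "H"
    out[["control_region"]] <- get(feat)
  }
  out[["Full genome"]] <- genome$sequence
  out
}

#' Per-region composition report
#'
#' One [content_and_skew()] row per reported region: the 13-PCG
#' concatenation (incomplete-stop bases excluded) and its three codon
#' position slices, each PCG over its full annotated span, `l-rRNA`,
#' `s-rRNA`, the rRNA and tRNA concatenations, the control region, and the
#' full genome. Per-gene, tRNA and rRNA rows are computed on coding
#' (sense) strand sequences; the full genome and control region on the
#' deposited (H) strand. With `strand_convention = "deposited"` all rows
#' are computed on the deposited strand instead (a sensitivity check).
#'
#' @param genome A [mitogenome()] with a real sequence.
#' @param strand_convention `"coding"` (default) or `"deposited"`.
#' @return A data frame of composition rows.
#' @export
region_report <- function(genome, strand_convention = c("coding", "deposited")) {
  strand_convention <- match.arg(strand_convention)
  if (has_placeholder_sequence(genome)) {
    stop("region_report needs a real sequence; use region_sizes() on ",
         "coordinate-only genomes")
  }
  g <- genome
  if (strand_convention == "deposited") g$features$strand <- "H"
  seqs <- .region_sequences(g)
  do.call(rbind, lapply(names(seqs), function(r) content_and_skew(seqs[[r]], r)))
}

#' Region sizes only (works on placeholder genomes)
#'
#' The `Size (bp)` column of the composition report, computable from
#' coordinates alone.
#'
#' @param genome A [mitogenome()] (placeholder sequence allowed).
#' @return A data frame with columns `region` and `size`.
#' @export
#' @examples
#' region_sizes(mileewinae_fixture("M_amplimacula"))
region_sizes <- function(genome) {
  seqs <- .region_sequences(genome, placeholder_ok = TRUE)
  data.frame(region = names(seqs), size = vapply(seqs, nchar, 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
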