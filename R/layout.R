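#' Signed spacing between consecutive genes
#'
#' For each pair of consecutive features in genome order, the signed gap
#' `start(next) - end(prev) - 1`: negative values are overlaps of
#' `|spacing|` bp, positive values intergenic spacers, zero abutting genes.
#' By default the pairs flanking the control region are omitted, matching
#' the convention under which published overlap/spacer tallies are
#' reported; with `include_cr_boundaries = TRUE` they are included, as is
#' the circular wrap pair (last feature back to the first).
#'
#' @param genome A [mitogenome()] (placeholder sequences are fine).
#' @param include_cr_boundaries Logical (default `FALSE`).
#' @return A data frame with columns `prev_gene`, `next_gene`, `spacing`.
#' @export
#' @examples
#' compute_spacing_ledger(mileewinae_fixture("M_mira"))[1:3, ]
compute_spacing_ledger <- function(genome, include_cr_boundaries = FALSE) {
  f <- genome$features
  empty <- data.frame(prev_gene = character(0), next_gene = character(0),
                      spacing = integer(0), stringsAsFactors = FALSE)
  if (nrow(f) < 2) return(empty)
  n <- nrow(f)
  led <- data.frame(prev_gene = f$name[-n], next_gene = f$name[-1],
                    spacing = f$start[-1] - f$end[-n] - 1L,
                    stringsAsFactors = FALSE)
  if (include_cr_boundaries) {
    if (genome$circular) {
      wrap <- genome_length(genome) - f$end[n] + f$start[1] - 1L
      led <- rbind(led, data.frame(prev_gene = f$name[n], next_gene = f$name[1],
                                   spacing = as.integer(wrap)))
    }
  } else {
    cr <- f$name[f$gene_class == "CR"]
    if (length(cr)) {
      led <- led[led$prev_gene != cr & led$next_gene != cr, , drop = FALSE]
    }
    rownames(led) <- NULL
  }
  led
}

#' Gene-order, strand and boundary-spacing summary
#'
#' Counts genes per strand (control region excluded) split by class,
#' collects overlaps and intergenic spacers from
#' [compute_spacing_ledger()], and reports the longest of each (ties broken
#' by genome order).
#'
#' @param genome A [mitogenome()].
#' @return A list of class `layout_summary` with elements `gene_order`,
#'   `h_count`, `l_count`, `h_by_class`, `l_by_class`, `overlaps`,
#'   `spacers`, `longest_overlap`, `longest_spacer`.
#' @export
summarize_layout <- function(genome) {
  f <- genome$features
  genes <- f[f$gene_class != "CR", , drop = FALSE]
  led <- compute_spacing_ledger(genome)
  overlaps <- led[led$spacing < 0, , drop = FALSE]
  spacers <- led[led$spacing > 0, , drop = FALSE]
  rownames(overlaps) <- rownames(spacers) <- NULL
  pick <- function(d, fun) {
    if (!nrow(d)) return(NULL)
    d[which(abs(d$spacing) == fun(abs(d$spacing)))[1], ]
  }
  by_class <- function(strand) {
    table(factor(genes$gene_class[genes$strand == strand],
                 c("PCG", "tRNA", "rRNA")))
  }
  structure(list(
    gene_order = data.frame(name = f$name, strand = f$strand,
                            stringsAsFactors = FALSE),
    h_count = sum(genes$strand == "H"), l_count = sum(genes$strand == "L"),
    h_by_class = by_class("H"), l_by_class = by_class("L"),
    overlaps = overlaps, spacers = spacers,
    longest_overlap = pick(overlaps, max), longest_spacer = pick(spacers, max)
  ), class = "layout_summary")
}

#' @export
print.layout_summary <- function(x, ...) {
  cat(sprintf("<layout> %d H-strand / %d L-strand genes; %d overlaps, %d spacers\n",
              x$h_count, x$l_count, nrow(x$overlaps), nrow(x$spacers)))
  if (!is.null(x$longest_overlap)) {
    cat(sprintf("  longest overlap: %d bp (%s-%s)\n",
                -x$longest_overlap$spacing, x$longest_overlap$prev_gene,
                x$longest_overlap$next_gene))
  }
  if (!is.null(x$longest_spacer)) {
    cat(sprintf("  longest spacer: %d bp (%s-%s)\n", x$longest_spacer$spacing,
                x$longest_spacer$prev_gene, x$longest_spacer$next_gene))
  }
  invisible(x)
}

#' Rotation-invariant gene-order signature
#'
#' A canonical string of `name(strand)` tokens over the circular gene
#' order, anchored at `trnI` when present, otherwise at the
#' lexicographically smallest rotation. Two genomes have equal signatures
#' iff their circular gene orders and strand assignments match.
#'
#' @param genome A [mitogenome()] with at least one feature.
#' @return A single string.
#' @export
gene_order_signature <- function(genome) {
  f <- genome$features
  if (!nrow(f)) stop("genome has no features")
  tokens <- paste0(f$name, "(", f$strand, ")")
  rotate <- function(v, k) if (k == 1) v else c(v[k:length(v)], v[seq_len(k - 1)])
  anchor <- match("trnI", f$name)
  if (!is.na(anchor)) {
    paste(rotate(tokens, anchor), collapse = ">")
  } else {
    cands <- vapply(seq_along(tokens),
                    function(k) paste(rotate(tokens, k), collapse = ">"), "")
    min(cands)
  }
}
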