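#' End-to-end characterization of one or more mitogenomes
#'
#' Runs the full analysis battery over a set of genomes: layout (gene
#' order, strand counts, overlap/spacer ledger) always; composition,
#' terminal-codon, RSCU and control-region repeat stages only for genomes
#' with real sequence (skips are recorded, not errors). Cross-genome
#' summaries compare gene-order signatures and boundary spacings.
#'
#' @param inputs A list of [mitogenome()] objects, GenBank file paths, or
#'   species names resolvable by [mileewinae_fixture()] (mixing allowed).
#' @param include_cr_boundaries Passed to [compute_spacing_ledger()].
#' @return A list of class `characterization_report`: per-genome entries
#'   (`layout`, `spacing`, `composition`, `terminal_codons`, `rscu`,
#'   `cr_repeats`, `skipped`) plus `gene_order_identical`, `signatures`
#'   and `boundaries` across genomes.
#' @export
#' @examples
#' rep <- characterize(as.list(mileewinae_species()))
#' rep$gene_order_identical
characterize <- function(inputs, include_cr_boundaries = FALSE) {
  if (!length(inputs)) stop("at least one input genome is required")
  genomes <- lapply(inputs, function(x) {
    if (inherits(x, "mitogenome")) return(x)
    if (is.character(x) && length(x) == 1) {
      if (file.exists(x)) return(read_genbank(x))
      if (x %in% mileewinae_species()) return(mileewinae_fixture(x))
      stop("input is neither a file nor a known fixture species: ", x)
    }
    stop("inputs must be mitogenome objects, file paths, or species names")
  })
  ids <- make.unique(vapply(genomes, function(g) g$id, ""))
  per <- lapply(genomes, function(g) {
    entry <- list(id = g$id,
                  layout = summarize_layout(g),
                  spacing = compute_spacing_ledger(g, include_cr_boundaries),
                  region_sizes = region_sizes(g), skipped = character(0))
    if (has_placeholder_sequence(g)) {
      entry$skipped <- c("composition", "terminal_codons", "rscu", "cr_repeats")
    } else {
      entry$composition <- region_report(g)
      entry$terminal_codons <- classify_terminal_codons(g)
      entry$rscu <- rscu_table(g)
      if (any(g$features$gene_class == "CR")) {
        entry$cr_repeats <- control_region_repeats(g)
      }
    }
    entry
  })
  names(per) <- ids
  sigs <- vapply(genomes, gene_order_signature, "")
  report <- structure(list(
    genomes = per,
    signatures = stats::setNames(sigs, ids),
    gene_order_identical = length(unique(sigs)) == 1L,
    boundaries = NULL
  ), class = "characterization_report")
  if (length(genomes) >= 2) report$boundaries <- compare_boundaries(report)
  report
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("<characterization> %d genome(s): %s\n", length(x$genomes),
              paste(names(x$genomes), collapse = ", ")))
  cat("  identical gene orders:", x$gene_order_identical, "\n")
  if (!is.null(x$boundaries)) {
    cat(sprintf("  %d boundaries compared, %d shared across all genomes\n",
                nrow(x$boundaries), sum(x$boundaries$shared)))
  }
  invisible(x)
}

#' Compare gene-boundary spacings across genomes
#'
#' For every gene boundary (ordered by genome position), lists each
#' genome's signed spacing and flags boundaries where all genomes agree.
#' Genomes with differing gene sets are compared on the intersection of
#' boundaries, with a warning.
#'
#' @param report A `characterization_report`, or a list of them (each
#'   contributing its genomes).
#' @return A data frame: `prev_gene`, `next_gene`, one spacing column per
#'   genome, and logical `shared`.
#' @export
compare_boundaries <- function(report) {
  reports <- if (inherits(report, "characterization_report")) list(report)
             else report
  ledgers <- list()
  for (r in reports) {
    for (nm in names(r$genomes)) ledgers[[nm]] <- r$genomes[[nm]]$spacing
  }
  if (length(ledgers) < 2) stop("need at least two genomes to compare")
  keys <- lapply(ledgers, function(l) paste(l$prev_gene, l$next_gene, sep = "-"))
  common <- Reduce(intersect, keys)
  if (!all(lengths(keys) == length(common))) {
    warning("genomes have differing boundary sets; comparing the intersection")
  }
  base <- ledgers[[1]]
  base_keys <- keys[[1]]
  keep <- base_keys %in% common
  out <- base[keep, c("prev_gene", "next_gene")]
  for (id in names(ledgers)) {
    out[[id]] <- ledgers[[id]]$spacing[match(base_keys[keep], keys[[id]])]
  }
  sp <- as.matrix(out[, names(ledgers), drop = FALSE])
  out$shared <- apply(sp, 1, function(v) length(unique(v)) == 1L)
  rownames(out) <- NULL
  out
}

#' Write a characterization report to TSV tables and combined JSON
#'
#' One TSV per table (spacing ledger, region sizes/composition, terminal
#' codons, RSCU, control-region repeats, boundary comparison) plus a
#' combined `report.json`. Sizes print as integers, percentages to 1
#' decimal and skews to 3 decimals; the JSON keeps full precision.
#'
#' @param report A `characterization_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_characterization <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_comp <- function(d) {
    for (col in c("at_content", "gc_content", "gt_content")) {
      d[[col]] <- sprintf("%.1f", d[[col]])
    }
    for (col in c("at_skew", "gc_skew")) d[[col]] <- sprintf("%.3f", d[[col]])
    d
  }
  wr <- function(d, file) {
    utils::write.table(d, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (id in names(report$genomes)) {
    g <- report$genomes[[id]]
    wr(g$spacing, paste0(id, "_spacing.tsv"))
    wr(g$region_sizes, paste0(id, "_region_sizes.tsv"))
    if (!is.null(g$composition)) wr(fmt_comp(g$composition), paste0(id, "_composition.tsv"))
    if (!is.null(g$terminal_codons)) wr(g$terminal_codons, paste0(id, "_codons.tsv"))
    if (!is.null(g$rscu)) wr(g$rscu, paste0(id, "_rscu.tsv"))
    if (!is.null(g$cr_repeats)) wr(g$cr_repeats, paste0(id, "_cr_repeats.tsv"))
  }
  if (!is.null(report$boundaries)) wr(report$boundaries, "boundaries.tsv")
  json <- list(
    gene_order_identical = report$gene_order_identical,
    signatures = as.list(report$signatures),
    genomes = lapply(report$genomes, function(g) {
      list(id = g$id, h_count = g$layout$h_count, l_count = g$layout$l_count,
           n_overlaps = nrow(g$layout$overlaps),
           n_spacers = nrow(g$layout$spacers),
           spacing = g$spacing, region_sizes = g$region_sizes,
           composition = g$composition, terminal_codons = g$terminal_codons,
           rscu = g$rscu, cr_repeats = g$cr_repeats, skipped = g$skipped)
    }),
    boundaries = report$boundaries)
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
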