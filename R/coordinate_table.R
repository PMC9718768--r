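#' Read a coordinate-table fixture into a placeholder mitogenome
#'
#' A coordinate table is a TSV with one row per gene and five species
#' column-groups, as transcribed from a comparative annotation table:
#' shared columns `gene` and `strand`, and per species `<sp>` the columns
#' `from_<sp>`, `to_<sp>`, `start_<sp>` (start codon), `stop_<sp>`
#' (stop codon, possibly incomplete `TA`/`T`), and `ig_<sp>` (the printed
#' signed intergenic/overlap count, blank meaning abutting). The returned
#' genome carries an all-`N` placeholder sequence whose length is the
#' largest `to` coordinate, so layout and size arithmetic run without real
#' bases while composition analyses refuse it.
#'
#' @param path Path to the TSV fixture.
#' @param species_index Integer (column-group position) or species name.
#' @return A [mitogenome()] object with placeholder sequence. The printed
#'   intergenic column is attached as attribute `"printed_spacing"`.
#' @export
#' @examples
#' g <- read_coordinate_table(
#'   system.file("extdata", "mileewinae_table1.tsv", package = "mitochar"), 1)
#' genome_length(g)
read_coordinate_table <- function(path, species_index = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("empty coordinate table: ", path)
  species <- unique(sub("^from_", "", grep("^from_", names(tab), value = TRUE)))
  if (!length(species)) stop("no 'from_<species>' column group found")
  sp <- if (is.character(species_index)) {
    if (!species_index %in% species) {
      stop("unknown species ", sQuote(species_index), "; available: ",
           paste(species, collapse = ", "))
    }
    species_index
  } else species[species_index]
  need <- paste0(c("from_", "to_"), sp)
  if (!all(c("gene", "strand", need) %in% names(tab))) {
    stop("missing column(s): ",
         paste(setdiff(c("gene", "strand", need), names(tab)), collapse = ", "))
  }
  from <- tab[[paste0("from_", sp)]]
  to <- tab[[paste0("to_", sp)]]
  if (!is.numeric(from) || !is.numeric(to) || anyNA(from) || anyNA(to)) {
    stop("non-numeric or missing coordinate in columns for ", sp)
  }
  start_col <- tab[[paste0("start_", sp)]]
  stop_col <- tab[[paste0("stop_", sp)]]
  if (is.null(start_col)) start_col <- rep(NA_character_, nrow(tab))
  if (is.null(stop_col)) stop_col <- rep(NA_character_, nrow(tab))
  start_col[!nzchar(trimws(as.character(start_col)))] <- NA
  stop_col[!nzchar(trimws(as.character(stop_col)))] <- NA
  feats <- gene_features(normalize_gene_name(tab$gene), from, to, tab$strand,
                         start_col, stop_col)
  L <- max(to)
  g <- mitogenome(sp, strrep("N", L), feats, circular = TRUE)
  printed <- tab[[paste0("ig_", sp)]]
  if (!is.null(printed)) {
    printed <- suppressWarnings(as.integer(printed))
    printed[is.na(printed)] <- 0L
    attr(g, "printed_spacing") <- stats::setNames(printed, tab$gene)
  }
  g
}

#' The shipped five-species Mileewinae coordinate fixture
#'
#' Loads one species from the coordinate table transcribed from the
#' published annotation of four *Mileewa* and one *Processina* mitogenomes.
#'
#' @param species One of `"M_mira"`, `"M_lamellata"`, `"M_sharpa"`,
#'   `"M_amplimacula"`, `"P_sexmaculata"`, or an index 1-5.
#' @return A placeholder [mitogenome()].
#' @export
#' @examples
#' genome_length(mileewinae_fixture("M_amplimacula"))  # 15436
mileewinae_fixture <- function(species = "M_mira") {
  path <- system.file("extdata", "mileewinae_table1.tsv", package = "mitochar")
  read_coordinate_table(path, species)
}

#' @rdname mileewinae_fixture
#' @export
mileewinae_species <- function() {
  c("M_mira", "M_lamellata", "M_sharpa", "M_amplimacula", "P_sexmaculata")
}
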