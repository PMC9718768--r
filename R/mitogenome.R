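#' Construct a gene feature table
#'
#' Builds the feature table used inside a [mitogenome()] object. Coordinates
#' are 1-based inclusive. A wrapping feature (`end < start`) is allowed only
#' on a circular genome and spans the origin.
#'
#' @param name Canonical gene symbols (see [mito_gene_vocabulary()]).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"H"` (deposited strand) or `"L"` (annotated on the
#'   complement).
#' @param start_codon,stop_codon Optional codon annotations for PCGs;
#'   `stop_codon` may be `"TAA"`, `"TAG"`, or the incomplete forms `"TA"`
#'   and `"T"`.
#' @return A data frame with columns `name`, `gene_class`, `start`, `end`,
#'   `strand`, `start_codon`, `stop_codon`.
#' @export
gene_features <- function(name, start, end, strand,
                          start_codon = NA_character_,
                          stop_codon = NA_character_) {
  n <- length(name)
  stopifnot(length(start) == n, length(end) == n)
  strand <- rep_len(strand, n)
  start_codon <- rep_len(as.character(start_codon), n)
  stop_codon <- rep_len(as.character(stop_codon), n)
  if (!all(strand %in% c("H", "L"))) stop("strand must be 'H' or 'L'")
  bad_stop <- !is.na(stop_codon) & !stop_codon %in% c("TAA", "TAG", "TA", "T")
  if (any(bad_stop)) {
    stop("unrecognized stop codon annotation: ",
         paste(sQuote(unique(stop_codon[bad_stop])), collapse = ", "))
  }
  data.frame(name = name, gene_class = gene_class_of(name),
             start = as.integer(start), end = as.integer(end),
             strand = strand, start_codon = start_codon,
             stop_codon = stop_codon, stringsAsFactors = FALSE)
}

#' Construct an annotated circular mitogenome
#'
#' The central data container: a DNA sequence (possibly an all-`N`
#' placeholder when only coordinates are known), an ordered feature table,
#' and a genetic code identifier (5 = invertebrate mitochondrial).
#'
#' @param id Accession-like identifier.
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param features Feature table from [gene_features()]; sorted by `start`
#'   on construction.
#' @param circular Logical; circular genomes permit wrapping features.
#' @param genetic_code Integer NCBI translation table id (default 5).
#' @return An object of class `mitogenome`.
#' @export
#' @examples
#' g <- mitogenome("toy", "ATGAAATAACCC",
#'                 gene_features("atp8", 1, 9, "H", "ATG", "TAA"))
#' g
mitogenome <- function(id, sequence, features = gene_features(character(0),
                       integer(0), integer(0), character(0)),
                       circular = TRUE, genetic_code = 5L) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("sequence must be over the alphabet {A,C,G,T,N}")
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  g <- structure(list(id = id, sequence = sequence, circular = circular,
                      features = features, genetic_code = as.integer(genetic_code)),
                 class = "mitogenome")
  validate_mitogenome(g)
  g
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp, %s, %d features (code %d)%s\n",
              x$id, format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), x$genetic_code,
              if (has_placeholder_sequence(x)) " [placeholder sequence]" else ""))
  if (nrow(x$features)) {
    cls <- table(factor(x$features$gene_class, c("PCG", "tRNA", "rRNA", "CR")))
    cat("  ", paste(names(cls), cls, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genome length in bp
#' @param genome A [mitogenome()] object.
#' @return Integer length of the sequence.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Is the sequence a coordinate-only placeholder?
#'
#' Coordinate-table fixtures carry an all-`N` placeholder sequence; layout
#' analyses accept them, composition analyses reject them.
#'
#' @param genome A [mitogenome()] object.
#' @return Logical.
#' @export
has_placeholder_sequence <- function(genome) {
  grepl("^N*$", genome$sequence)
}

#' Length of a feature, allowing origin-wrapping features
#'
#' @param genome A [mitogenome()] object.
#' @param feature A single row of the feature table.
#' @return Integer length in bp.
#' @export
feature_length <- function(genome, feature) {
  if (feature$end >= feature$start) {
    feature$end - feature$start + 1L
  } else {
    genome_length(genome) - feature$start + 1L + feature$end
  }
}

validate_mitogenome <- function(g) {
  L <- genome_length(g)
  f <- g$features
  if (nrow(f) == 0) return(invisible(TRUE))
  if (any(f$start < 1L) || any(f$end < 1L) || any(f$start > L) || any(f$end > L)) {
    stop("feature coordinates outside [1, ", L, "]")
  }
  wrapping <- f$end < f$start
  if (any(wrapping) && !g$circular) {
    stop("wrapping feature (end < start) on a linear genome: ",
         paste(f$name[wrapping], collapse = ", "))
  }
  if (sum(f$gene_class == "CR") > 1) stop("more than one control_region feature")
  # when the full complement is present each symbol appears exactly once
  if (nrow(f) >= 38 && anyDuplicated(f$name)) {
    stop("duplicated gene name(s): ",
         paste(unique(f$name[duplicated(f$name)]), collapse = ", "))
  }
  # PCG length minus incomplete-stop bases must be divisible by 3
  pcg <- f[f$gene_class == "PCG" & !is.na(f$stop_codon), , drop = FALSE]
  if (nrow(pcg)) {
    len <- mapply(function(i) feature_length(g, pcg[i, ]), seq_len(nrow(pcg)))
    trim <- incomplete_stop_bases(pcg$stop_codon)
    bad <- (len - trim) %% 3L != 0L
    if (any(bad)) {
      stop("PCG length minus incomplete-stop bases not divisible by 3: ",
           paste(pcg$name[bad], collapse = ", "))
    }
  }
  invisible(TRUE)
}

# number of annotated incomplete-stop bases (0 for complete TAA/TAG or NA)
incomplete_stop_bases <- function(stop_codon) {
  ifelse(is.na(stop_codon), 0L,
         ifelse(stop_codon == "TA", 2L, ifelse(stop_codon == "T", 1L, 0L)))
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string.
#' @return The reverse complement as a character string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the coding-strand sequence of a feature
#'
#' For `H`-strand features this is the deposited slice `start..end`; for
#' `L`-strand features it is the reverse complement of that slice. Wrapping
#' features (only on circular genomes) concatenate the tail and head of the
#' sequence before orientation.
#'
#' @param genome A [mitogenome()] object with a real (non-placeholder)
#'   sequence.
#' @param feature A single feature row, or a canonical gene symbol present
#'   in the genome.
#' @return DNA string of the feature's coding (sense) strand.
#' @export
#' @examples
#' g <- mitogenome("toy", "ATGCCC", gene_features("trnI", 1, 3, "L"))
#' extract_feature_sequence(g, "trnI")  # "CAT"
extract_feature_sequence <- function(genome, feature) {
  if (is.character(feature)) {
    idx <- match(feature, genome$features$name)
    if (is.na(idx)) stop("no feature named ", sQuote(feature))
    feature <- genome$features[idx, ]
  }
  if (has_placeholder_sequence(genome)) {
    stop("genome ", sQuote(genome$id), " has a placeholder sequence; ",
         "sequence-level analyses need real bases")
  }
  L <- genome_length(genome)
  if (feature$start > L || feature$end > L) stop("coordinates out of range")
  raw <- if (feature$end >= feature$start) {
    substr(genome$sequence, feature$start, feature$end)
  } else {
    if (!genome$circular) stop("wrapping feature on a linear genome")
    paste0(substr(genome$sequence, feature$start, L),
           substr(genome$sequence, 1L, feature$end))
  }
  if (feature$strand == "L") reverse_complement(raw) else raw
}
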