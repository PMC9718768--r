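#' Canonical concatenation order of the 13 protein-coding genes
#'
#' Genome order of the conserved insect mitogenome arrangement; used as
#' the fixed, reproducible gene order when concatenating alignments.
#'
#' @return Character vector of 13 gene symbols.
#' @export
pcg_gene_order <- function() {
  c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3", "nad5",
    "nad4", "nad4L", "nad6", "cytb", "nad1")
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Genes are concatenated in canonical genome order (see
#' [pcg_gene_order()]; genes absent from that list are appended in input
#' order). Taxa missing from a gene's alignment get a gap-fill block of
#' `-` so the matrix stays rectangular. The partition scheme enumerates
#' one partition per gene and codon position (`gene_posK`, stride 3 over
#' that gene's column block): 3g partitions for g genes, pairwise
#' disjoint, covering every column.
#'
#' @param per_gene_alignments Named list: gene -> named character vector
#'   of equal-length aligned coding-strand sequences (taxon -> sequence).
#'   Each alignment length must be divisible by 3.
#' @return A list of class `supermatrix` with elements `matrix` (named
#'   character vector taxon -> concatenated sequence) and `scheme` (data
#'   frame with columns `partition`, `gene`, `codon_pos`, `block_start`,
#'   `block_end`; the partition's columns are
#'   `seq(block_start + codon_pos - 1, block_end, by = 3)`).
#' @export
#' @examples
#' sm <- build_supermatrix(list(nad2 = c(t1 = "ATGAAA", t2 = "ATGTTT")))
#' sm$scheme
build_supermatrix <- function(per_gene_alignments) {
  if (!length(per_gene_alignments)) stop("no alignments supplied")
  genes <- names(per_gene_alignments)
  if (is.null(genes) || any(!nzchar(genes))) stop("alignments must be named by gene")
  ord <- c(intersect(pcg_gene_order(), genes), setdiff(genes, pcg_gene_order()))
  taxa <- unique(unlist(lapply(per_gene_alignments, names)))
  if (is.null(taxa) || any(!nzchar(taxa))) stop("every sequence needs a taxon name")
  lens <- integer(length(ord))
  for (i in seq_along(ord)) {
    aln <- per_gene_alignments[[ord[i]]]
    l <- unique(nchar(aln))
    if (length(l) != 1L) stop("ragged alignment for gene ", ord[i])
    if (l %% 3L != 0L) {
      stop("alignment length of ", ord[i], " (", l, ") not divisible by 3")
    }
    lens[i] <- l
  }
  mat <- stats::setNames(rep("", length(taxa)), taxa)
  scheme <- vector("list", 3L * length(ord))
  offset <- 0L
  for (i in seq_along(ord)) {
    aln <- per_gene_alignments[[ord[i]]]
    block <- stats::setNames(rep(strrep("-", lens[i]), length(taxa)), taxa)
    block[names(aln)] <- unname(aln)
    mat <- paste0(mat, block)
    for (k in 1:3) {
      scheme[[3L * (i - 1L) + k]] <- data.frame(
        partition = paste0(ord[i], "_pos", k), gene = ord[i], codon_pos = k,
        block_start = offset + 1L, block_end = offset + lens[i],
        stringsAsFactors = FALSE)
    }
    offset <- offset + lens[i]
  }
  names(mat) <- taxa
  structure(list(matrix = mat, scheme = do.call(rbind, scheme)),
            class = "supermatrix")
}

#' Columns of one partition
#'
#' @param scheme_row One row of a supermatrix `scheme`.
#' @return Integer vector of 1-based supermatrix column indices.
#' @export
partition_columns <- function(scheme_row) {
  seq.int(scheme_row$block_start + scheme_row$codon_pos - 1L,
          scheme_row$block_end, by = 3L)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$matrix), nchar(x$matrix[1]), nrow(x$scheme)))
  invisible(x)
}

#' Export a supermatrix for phylogenetic software
#'
#' Writes relaxed PHYLIP (`.phy`), NEXUS with a `sets` charset block
#' (`.nex`), and/or a RAxML-style partition file (`.part`, lines like
#' `DNA, nad2_pos1 = 1-969\3`). Output is byte-stable for fixed inputs.
#'
#' @param sm A [build_supermatrix()] result (or a named character vector
#'   plus a `scheme` data frame).
#' @param path_prefix Output path without extension.
#' @param formats Subset of `c("phylip", "nexus", "raxml")`.
#' @return Named character vector of written file paths, invisibly.
#' @export
export_matrix <- function(sm, path_prefix,
                          formats = c("phylip", "nexus", "raxml")) {
  bad <- setdiff(formats, c("phylip", "nexus", "raxml"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  mat <- sm$matrix; scheme <- sm$scheme
  if (!length(mat)) stop("empty matrix")
  if (is.null(names(mat)) || any(!nzchar(names(mat)))) stop("empty taxon name")
  paths <- character(0)
  if ("phylip" %in% formats) {
    p <- paste0(path_prefix, ".phy")
    writeLines(c(sprintf("%d %d", length(mat), nchar(mat[1])),
                 sprintf("%s  %s", names(mat), unname(mat))), p)
    paths["phylip"] <- p
  }
  if ("nexus" %in% formats) {
    p <- paste0(path_prefix, ".nex")
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(mat), nchar(mat[1])),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX",
               sprintf("    %s  %s", names(mat), unname(mat)),
               "  ;", "END;")
    if (!is.null(scheme) && nrow(scheme)) {
      lines <- c(lines, "BEGIN SETS;",
                 sprintf("  charset %s = %d-%d\\3;", scheme$partition,
                         scheme$block_start + scheme$codon_pos - 1L,
                         scheme$block_end),
                 "END;")
    }
    writeLines(lines, p)
    paths["nexus"] <- p
  }
  if ("raxml" %in% formats) {
    p <- paste0(path_prefix, ".part")
    writeLines(sprintf("DNA, %s = %d-%d\\3", scheme$partition,
                       scheme$block_start + scheme$codon_pos - 1L,
                       scheme$block_end), p)
    paths["raxml"] <- p
  }
  invisible(paths)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path File written by [export_matrix()] (header line, then one
#'   `name  sequence` line per taxon).
#' @return Named character vector taxon -> sequence.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  out <- stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = ""), ""),
                         vapply(parts, `[`, "", 1))
  if (length(out) != hdr[1] || any(nchar(out) != hdr[2])) {
    stop("PHYLIP dimensions disagree with the header")
  }
  out
}

#' Read a NEXUS data matrix and its charset block
#'
#' @param path File written by [export_matrix()].
#' @return A list of class `supermatrix` with `matrix` and `scheme`
#'   (charsets parsed back from `start-end\\3` definitions; `NULL` when no
#'   sets block is present).
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m0 <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1]
  m1 <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > m0)[1]
  body <- trimws(lines[(m0 + 1):(m1 - 1)])
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\\s+")
  mat <- stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = ""), ""),
                         vapply(parts, `[`, "", 1))
  cs <- grep("^\\s*charset\\s", lines, ignore.case = TRUE, value = TRUE)
  scheme <- NULL
  if (length(cs)) {
    m <- regmatches(cs, regexec(
      "charset\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\\\3\\s*;", cs, ignore.case = TRUE))
    scheme <- do.call(rbind, lapply(m, function(g) {
      first <- as.integer(g[3])
      part <- g[2]
      pos <- as.integer(sub(".*_pos([123])$", "\\1", part))
      data.frame(partition = part,
                 gene = sub("_pos[123]$", "", part), codon_pos = pos,
                 block_start = first - pos + 1L, block_end = as.integer(g[4]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(matrix = mat, scheme = scheme), class = "supermatrix")
}
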