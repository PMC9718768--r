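#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses a single-record GenBank flat file carrying `CDS`, `tRNA`, `rRNA`,
#' and `misc_feature`/`D-loop` features. Gene names are normalized to the
#' canonical vocabulary via [normalize_gene_name()]; features on
#' `complement(...)` get strand `L`; `join(a..len,1..b)` locations are read
#' as origin-wrapping features. For PCGs the start and stop codons are
#' derived from the CDS sequence itself (via the span-length mod-3 rule for
#' incomplete stops), not trusted from qualifiers.
#'
#' @param path Path to a GenBank flat file with exactly one record.
#' @return A [mitogenome()] object.
#' @seealso [write_genbank()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^LOCUS", lines)) != 1L) {
    stop("expected exactly one GenBank record in ", path)
  }
  locus <- lines[grepl("^LOCUS", lines)][1]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  acc_line <- lines[grepl("^ACCESSION", lines)]
  id <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else {
    strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  }

  # sequence: between ORIGIN and //
  o <- grep("^ORIGIN", lines)
  terminator <- grep("^//", lines)
  sequence <- ""
  if (length(o)) {
    seq_lines <- lines[(o[1] + 1):(terminator[terminator > o[1]][1] - 1)]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  }

  # feature block: from FEATURES to ORIGIN (or //)
  fstart <- grep("^FEATURES", lines)
  feats <- gene_features(character(0), integer(0), integer(0), character(0))
  if (length(fstart)) {
    fend <- if (length(o)) o[1] - 1L else terminator[1] - 1L
    block <- lines[(fstart[1] + 1):fend]
    # a new feature starts at column 6 with a key; qualifiers start with /
    key_idx <- grep("^ {5}\\S", block)
    keep <- c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")
    nm <- ch <- character(0); st <- en <- integer(0)
    for (i in seq_along(key_idx)) {
      from <- key_idx[i]
      to <- if (i < length(key_idx)) key_idx[i + 1] - 1L else length(block)
      entry <- block[from:to]
      key <- strsplit(trimws(entry[1]), "\\s+")[[1]][1]
      if (!key %in% keep) next
      loc <- sub("^\\s*\\S+\\s+", "", entry[1])
      # continuation lines of the location (no qualifier yet)
      j <- 2
      while (j <= length(entry) && !grepl("^\\s*/", entry[j])) {
        loc <- paste0(loc, trimws(entry[j])); j <- j + 1
      }
      parsed <- .parse_gb_location(loc)
      quals <- entry[grepl("^\\s*/", entry)]
      gname <- .gb_qualifier(quals, "gene")
      if (is.na(gname)) gname <- .gb_qualifier(quals, "product")
      if (is.na(gname) && key == "D-loop") gname <- "control_region"
      if (is.na(gname)) stop("feature without /gene or /product qualifier: ", entry[1])
      canon <- normalize_gene_name(gname)
      nm <- c(nm, canon); st <- c(st, parsed$start); en <- c(en, parsed$end)
      ch <- c(ch, if (parsed$complement) "L" else "H")
    }
    if (length(nm)) {
      L <- nchar(sequence)
      if (L > 0 && (any(st > L) | any(en > L))) {
        stop("feature coordinates beyond sequence length (", L, " bp)")
      }
      feats <- gene_features(nm, st, en, ch)
    }
  }
  g <- mitogenome(id, sequence, feats, circular = circular)
  if (!has_placeholder_sequence(g) && nchar(g$sequence) > 0) {
    g <- .annotate_terminal_codons(g)
  }
  g
}

.parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", inner)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", inner), ",")[[1]]
    rng <- do.call(rbind, lapply(parts, function(p) {
      as.integer(strsplit(p, "\\.\\.")[[1]])
    }))
    # origin-wrapping: first part runs to the end, second from 1
    list(start = rng[1, 1], end = rng[nrow(rng), 2], complement = complement)
  } else {
    xy <- as.integer(strsplit(inner, "\\.\\.")[[1]])
    if (length(xy) == 1L) xy <- c(xy, xy)
    if (anyNA(xy)) stop("cannot parse GenBank location: ", loc)
    list(start = xy[1], end = xy[2], complement = complement)
  }
}

.gb_qualifier <- function(quals, what) {
  hit <- grep(paste0("^\\s*/", what, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub("\"", "", sub(paste0("^\\s*/", what, "="), "", trimws(hit[1])))
}

# derive start/stop codon annotations for PCGs from the sequence itself
.annotate_terminal_codons <- function(genome) {
  f <- genome$features
  for (i in which(f$gene_class == "PCG")) {
    s <- extract_feature_sequence(genome, f[i, ])
    n <- nchar(s)
    f$start_codon[i] <- substr(s, 1, 3)
    rem <- n %% 3L
    tail <- substr(s, n - (if (rem == 0L) 2L else rem - 1L), n)
    if (rem == 0L) {
      if (!tail %in% c("TAA", "TAG")) {
        stop("no recognizable stop codon for ", f$name[i], " (ends ", tail, ")")
      }
    } else if (!(rem == 2L && tail == "TA") && !(rem == 1L && tail == "T")) {
      stop("unrecognized incomplete stop for ", f$name[i], " (ends ", tail, ")")
    }
    f$stop_codon[i] <- tail
  }
  genome$features <- f
  genome
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES, ORIGIN) that
#' [read_genbank()] parses back losslessly. Origin-wrapping features are
#' written as `join(a..len,1..b)` locations; control regions as `D-loop`.
#'
#' @param genome A [mitogenome()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  topo <- if (genome$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   INV", genome$id, L, topo),
           sprintf("ACCESSION   %s", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$gene_class[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop")
    span <- if (f$end[i] >= f$start[i]) {
      sprintf("%d..%d", f$start[i], f$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    }
    loc <- if (f$strand[i] == "L") sprintf("complement(%s)", span) else span
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", f$name[i]))
    if (key == "CDS") {
      out <- c(out, sprintf("                     /transl_table=%d", genome$genetic_code))
    }
  }
  out <- c(out, "ORIGIN")
  if (L > 0) {
    seq <- tolower(genome$sequence)
    starts <- seq(1L, L, by = 60L)
    for (s in starts) {
      chunk <- substr(seq, s, min(s + 59L, L))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers around Biostrings for the package's FASTA interchange.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
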