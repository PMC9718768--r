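#' Specification for a synthetic annotated mitogenome
#'
#' Describes the study conditions a generated genome should emulate: the
#' 37-gene + control-region order and strand layout, per-gene lengths and
#' signed boundary spacings (negative = overlap), PCG start/stop codons
#' (including incomplete stops `TA`/`T`), base-composition targets, and
#' tandem-repeat units to plant in the control region. Defaults mirror the
#' *M. mira* column of the shipped coordinate fixture: a 14,917 bp genome
#' with AT content target 0.79, full-genome AT skew 0.057 and GC skew
#' -0.101 on the drawn strand, and one planted 168 bp unit repeated twice
#' in the control region.
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   spec.
#' @param genome_order Data frame with columns `name`, `strand` (control
#'   region included, in genome order).
#' @param gene_lengths Named integer vector of feature lengths in bp.
#' @param spacing Named integer vector: for every feature after the first,
#'   the signed gap to the previous feature.
#' @param start_codons,stop_codons Named character vectors over the PCGs.
#' @param target_at AT fraction of drawn sequence (default 0.79).
#' @param target_at_skew,target_gc_skew Skews of drawn sequence (defaults
#'   0.057 and -0.101).
#' @param cr_at AT fraction for control-region flanks (default 0.85).
#' @param cr_repeats Data frame (or list of `c(period, copies)`) of repeat
#'   units to plant in the control region; copies may be fractional.
#' @param id Identifier for the generated genome.
#' @return A list of class `synth_spec`.
#' @export
#' @examples
#' spec <- synth_spec(seed = 1)
#' spec$gene_lengths[["nad5"]]
synth_spec <- function(seed = 1L, genome_order = NULL, gene_lengths = NULL,
                       spacing = NULL, start_codons = NULL, stop_codons = NULL,
                       target_at = 0.79, target_at_skew = 0.057,
                       target_gc_skew = -0.101, cr_at = 0.85,
                       cr_repeats = list(c(period = 168, copies = 2)),
                       id = "synthetic") {
  def <- .synth_defaults()
  if (is.null(genome_order)) genome_order <- def$genome_order
  if (is.null(gene_lengths)) gene_lengths <- def$gene_lengths
  if (is.null(spacing)) spacing <- def$spacing
  if (is.null(start_codons)) start_codons <- def$start_codons
  if (is.null(stop_codons)) stop_codons <- def$stop_codons
  if (is.data.frame(cr_repeats)) {
    cr_repeats <- lapply(seq_len(nrow(cr_repeats)), function(i) {
      c(period = cr_repeats$period[i], copies = cr_repeats$copies[i])
    })
  }
  nm <- genome_order$name
  stopifnot(all(nm %in% names(gene_lengths)),
            all(nm[-1] %in% names(spacing)))
  pcgs <- nm[gene_class_of(nm) == "PCG"]
  stopifnot(all(pcgs %in% names(start_codons)), all(pcgs %in% names(stop_codons)))
  trim <- incomplete_stop_bases(stop_codons[pcgs])
  bad <- (gene_lengths[pcgs] - trim) %% 3L != 0L
  if (any(bad)) {
    stop("PCG length minus incomplete-stop bases not divisible by 3: ",
         paste(pcgs[bad], collapse = ", "))
  }
  structure(list(seed = as.integer(seed), genome_order = genome_order,
                 gene_lengths = gene_lengths, spacing = spacing,
                 start_codons = start_codons, stop_codons = stop_codons,
                 target_at = target_at, target_at_skew = target_at_skew,
                 target_gc_skew = target_gc_skew, cr_at = cr_at,
                 cr_repeats = cr_repeats, id = id),
            class = "synth_spec")
}

.synth_defaults <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- mileewinae_fixture("M_mira")
    f <- g$features
    len <- stats::setNames(f$end - f$start + 1L, f$name)
    spacing <- stats::setNames(f$start[-1] - f$end[-nrow(f)] - 1L, f$name[-1])
    pcg <- f[f$gene_class == "PCG", ]
    cache <<- list(
      genome_order = data.frame(name = f$name, strand = f$strand,
                                stringsAsFactors = FALSE),
      gene_lengths = len, spacing = spacing,
      start_codons = stats::setNames(pcg$start_codon, pcg$name),
      stop_codons = stats::setNames(pcg$stop_codon, pcg$name))
    cache
  }
})

.base_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

# expected AT fraction of a codon drawn i.i.d. from `probs` conditional on
# not being a stop codon (TAA/TAG)
.codon_at_expect <- function(probs) {
  b <- names(probs)
  grid <- expand.grid(b1 = b, b2 = b, b3 = b, stringsAsFactors = FALSE)
  w <- probs[grid$b1] * probs[grid$b2] * probs[grid$b3]
  is_stop <- grid$b1 == "T" & grid$b2 == "A" & grid$b3 %in% c("A", "G")
  at <- (grid$b1 %in% c("A", "T")) + (grid$b2 %in% c("A", "T")) +
    (grid$b3 %in% c("A", "T"))
  sum(w[!is_stop] * at[!is_stop] / 3) / sum(w[!is_stop])
}

# base probabilities for codon bodies, calibrated so that the stop-codon
# rejection still yields the target AT content in expectation
.calibrated_codon_probs <- function(target_at, at_skew, gc_skew) {
  f <- function(a) .codon_at_expect(.base_probs(a, at_skew, gc_skew)) - target_at
  lo <- max(target_at - 0.05, 0.02)
  hi <- min(target_at + 0.10, 0.98)
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  .base_probs(a, at_skew, gc_skew)
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# sample n random non-stop codons (table 5 stops: TAA, TAG) as a flat base vector
.sample_codons <- function(n, probs) {
  if (n == 0L) return(character(0))
  bases <- names(probs)
  m <- matrix(sample(bases, 3L * n, replace = TRUE, prob = probs), ncol = 3L,
              byrow = TRUE)
  repeat {
    is_stop <- m[, 1] == "T" & m[, 2] == "A" & (m[, 3] == "A" | m[, 3] == "G")
    if (!any(is_stop)) break
    k <- sum(is_stop)
    m[is_stop, ] <- matrix(sample(bases, 3L * k, replace = TRUE, prob = probs),
                           ncol = 3L)
  }
  as.vector(t(m))
}

# random repeat unit whose tandem copies survive low-complexity masking:
# drawn from a mildly AT-rich composition and rejected unless a doubled copy
# (covering the copy junction) is free of the masking patterns
.sample_repeat_unit <- function(period, max_tries = 500L) {
  unit_probs <- c(A = 0.375, C = 0.125, G = 0.125, T = 0.375)
  for (i in seq_len(max_tries)) {
    u <- paste(sample(names(unit_probs), period, replace = TRUE,
                      prob = unit_probs), collapse = "")
    uu <- strrep(u, 2L)
    if (!grepl("([ACGT])\\1{5,}", uu, perl = TRUE) &&
        !grepl("([ACGT]{2})\\1{3,}", uu, perl = TRUE)) {
      return(u)
    }
  }
  stop("could not draw a low-complexity-free repeat unit of period ", period)
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic given the spec: builds coordinates from the length and
#' spacing ledgers, fills the genome with background bases drawn at the
#' target composition, writes every gene's coding-strand sequence (PCGs
#' get their specified start codon, stop-free internal codons, and the
#' specified possibly-incomplete stop), plants the requested tandem
#' repeats in AT-rich control-region flanks, and then repairs
#' reading-frame conflicts at gene overlaps: overlapping genes share
#' literal sequence, the later-starting gene's draw wins, and the
#' earlier gene's affected codons are re-drawn jointly with the
#' winner's mutable codons under both frames' constraints (bounded
#' retries, then an error).
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `genome` (a [mitogenome()]) and
#'   `ground_truth` (the spec, augmented with the control-region repeat
#'   placements in `cr_repeat_positions`).
#' @export
#' @examples
#' g <- generate_mitogenome(synth_spec(seed = 1))$genome
#' summarize_layout(g)$h_count  # 23
generate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  ord <- spec$genome_order
  n <- nrow(ord)
  len <- as.integer(spec$gene_lengths[ord$name])
  starts <- integer(n); ends <- integer(n)
  starts[1] <- 1L; ends[1] <- len[1]
  for (i in seq_len(n)[-1]) {
    starts[i] <- ends[i - 1L] + 1L + as.integer(spec$spacing[[ord$name[i]]])
    ends[i] <- starts[i] + len[i] - 1L
    if (starts[i] < 1L) stop("infeasible spacing ledger before ", ord$name[i])
  }
  L <- ends[n]
  cls <- gene_class_of(ord$name)
  probs <- .base_probs(spec$target_at, spec$target_at_skew, spec$target_gc_skew)
  cod_probs <- .calibrated_codon_probs(spec$target_at, spec$target_at_skew,
                                       spec$target_gc_skew)

  for (attempt in 1:20) {
    seqv <- sample(names(probs), L, replace = TRUE, prob = probs)
    gt_positions <- NULL
    for (i in seq_len(n)) {
      if (cls[i] == "PCG") {
        stopc <- spec$stop_codons[[ord$name[i]]]
        trim <- incomplete_stop_bases(stopc)
        body_n <- (len[i] - 3L - nchar(stopc)) %/% 3L
        coding <- c(strsplit(spec$start_codons[[ord$name[i]]], "")[[1]],
                    .sample_codons(body_n, cod_probs),
                    strsplit(stopc, "")[[1]])
      } else if (cls[i] == "CR") {
        res <- .build_cr(len[i], spec, probs)
        coding <- res$seq
        gt_positions <- res$positions
      } else {
        coding <- sample(names(probs), len[i], replace = TRUE, prob = probs)
      }
      idx <- starts[i]:ends[i]
      if (ord$strand[i] == "H") seqv[idx] <- coding
      else seqv[idx] <- rev(unname(.comp[coding]))
    }
    seqv <- .repair_pcg_frames(seqv, ord, cls, starts, ends, spec, cod_probs)
    if (!is.null(seqv)) break
    if (attempt == 20) stop("could not satisfy overlapping reading-frame constraints")
  }

  feats <- gene_features(ord$name, starts, ends, ord$strand,
                         ifelse(cls == "PCG", spec$start_codons[ord$name], NA),
                         ifelse(cls == "PCG", spec$stop_codons[ord$name], NA))
  genome <- mitogenome(spec$id, paste(seqv, collapse = ""), feats, circular = TRUE)
  gt <- spec
  gt$cr_repeat_positions <- gt_positions
  list(genome = genome, ground_truth = gt)
}

# control region: AT-rich flanks with planted tandem units; the unit-aligned
# bases flanking each planted block are forced to mismatch the unit so the
# realized copy number equals the requested one.
.build_cr <- function(cr_len, spec, genome_probs) {
  probs <- .base_probs(spec$cr_at, spec$target_at_skew, spec$target_gc_skew)
  draw <- function(k) sample(names(probs), k, replace = TRUE, prob = probs)
  blocks <- lapply(spec$cr_repeats, function(r) {
    p <- as.integer(r[["period"]]); cp <- as.numeric(r[["copies"]])
    unit <- strsplit(.sample_repeat_unit(p), "")[[1]]
    full <- floor(cp + 1e-9)
    fraclen <- round((cp - full) * p)
    list(unit = unit, period = p,
         seq = c(rep(unit, full), if (fraclen) unit[seq_len(fraclen)]))
  })
  sep <- 8L
  need <- sum(vapply(blocks, function(b) length(b$seq), 1L)) +
    sep * (length(blocks) + 1L)
  if (need > cr_len) {
    stop("control region of ", cr_len, " bp cannot hold the planted repeats (",
         need, " bp needed)")
  }
  out <- draw(cr_len)
  pos <- sep + 1L
  positions <- integer(0)
  spans <- list()
  for (b in blocks) {
    span <- length(b$seq)
    out[pos:(pos + span - 1L)] <- b$seq
    positions <- c(positions, pos)
    spans[[length(spans) + 1L]] <- c(pos, pos + span - 1L)
    pos <- pos + span + sep
  }
  # force mismatches at unit-aligned flank positions so the realized copy
  # number is exactly the requested one; a flank position between two blocks
  # may be constrained by both
  in_block <- rep(FALSE, cr_len)
  for (sp in spans) in_block[sp[1]:sp[2]] <- TRUE
  forbid <- vector("list", cr_len)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; p <- b$period
    first <- spans[[i]][1]; last <- spans[[i]][2]
    pre <- seq(to = first - 1L, length.out = min(p, first - 1L))
    for (j in pre) {
      if (!in_block[j]) {
        forbid[[j]] <- c(forbid[[j]], b$unit[((j - first) %% p) + 1L])
      }
    }
    frac <- (last - first + 1L) %% p
    post <- seq(from = last + 1L, length.out = min(p, cr_len - last))
    for (j in post) {
      if (!in_block[j]) {
        forbid[[j]] <- c(forbid[[j]], b$unit[((j - last - 1L + frac) %% p) + 1L])
      }
    }
    # break mononucleotide runs and dinucleotide alternations that would
    # otherwise cross the block boundary and get masked into the copies
    edge <- function(j, bases) {
      if (j >= 1L && j <= cr_len && !in_block[j]) {
        forbid[[j]] <<- c(forbid[[j]], bases)
      }
    }
    edge(first - 1L, b$unit[1:2])
    edge(first - 2L, b$unit[1])
    b_last <- out[last]; b_prev <- out[last - 1L]
    edge(last + 1L, c(b_last, b_prev))
    edge(last + 2L, b_last)
  }
  for (j in which(lengths(forbid) > 0)) {
    fb <- forbid[[j]]
    allowed <- setdiff(c("A", "C", "G", "T"), fb)
    while (!length(allowed)) {  # over-constrained: oldest constraints yield
      fb <- fb[-1]
      allowed <- setdiff(c("A", "C", "G", "T"), fb)
    }
    out[j] <- if (length(allowed) == 1L) allowed else {
      sample(allowed, 1L, prob = probs[allowed])
    }
  }
  list(seq = out, positions = positions)
}

# ---- overlap-aware reading-frame repair ----------------------------------

# coding position i of feature f -> genome coordinate
.coding_coord <- function(start, end, strand, i) {
  if (strand == "H") start + i - 1L else end - i + 1L
}

.read_coding <- function(seqv, start, end, strand) {
  if (strand == "H") seqv[start:end] else unname(.comp[rev(seqv[start:end])])
}

.is_stop <- function(b1, b2, b3) b1 == "T" & b2 == "A" & (b3 == "A" | b3 == "G")

# check one PCG's frame; returns indices (coding positions) of violations
.pcg_violations <- function(seqv, start, end, strand, start_codon, stop_codon) {
  coding <- .read_coding(seqv, start, end, strand)
  len <- length(coding)
  viol <- list()
  if (paste(coding[1:3], collapse = "") != start_codon) {
    viol[[length(viol) + 1L]] <- list(type = "exact", pos = 1:3,
                                      want = strsplit(start_codon, "")[[1]])
  }
  trim <- nchar(stop_codon) %% 3L
  tail_n <- nchar(stop_codon)
  want_tail <- strsplit(stop_codon, "")[[1]]
  if (!identical(coding[(len - tail_n + 1L):len], want_tail)) {
    viol[[length(viol) + 1L]] <- list(type = "exact",
                                      pos = (len - tail_n + 1L):len,
                                      want = want_tail)
  }
  ncod <- (len - trim) %/% 3L
  last_internal <- if (trim == 0L) ncod - 1L else ncod
  if (last_internal >= 2L) {
    i1 <- seq(4L, by = 3L, length.out = last_internal - 1L)
    stops <- which(.is_stop(coding[i1], coding[i1 + 1L], coding[i1 + 2L]))
    for (s in stops) {
      viol[[length(viol) + 1L]] <- list(type = "nonstop",
                                        pos = i1[s]:(i1[s] + 2L))
    }
  }
  viol
}

.repair_pcg_frames <- function(seqv, ord, cls, starts, ends, spec, probs) {
  pcg_idx <- which(cls == "PCG")
  if (!length(pcg_idx)) return(seqv)
  # immutable coding positions of each PCG: start codon + stop literal
  immutable_coords <- function(i) {
    len <- ends[i] - starts[i] + 1L
    tail_n <- nchar(spec$stop_codons[[ord$name[i]]])
    pos <- c(1:3, (len - tail_n + 1L):len)
    vapply(pos, function(p) .coding_coord(starts[i], ends[i], ord$strand[i], p), 1L)
  }
  check <- function(i) {
    .pcg_violations(seqv, starts[i], ends[i], ord$strand[i],
                    spec$start_codons[[ord$name[i]]],
                    spec$stop_codons[[ord$name[i]]])
  }
  codon_ok_in_frame <- function(i) {
    !length(check(i))
  }
  for (sweep in 1:10) {
    dirty <- FALSE
    for (i in pcg_idx) {
      viols <- check(i)
      if (!length(viols)) next
      dirty <- TRUE
      for (v in viols) {
        coords <- vapply(v$pos, function(p) {
          .coding_coord(starts[i], ends[i], ord$strand[i], p)
        }, 1L)
        # required genome-strand bases for exact constraints
        want_genome <- if (v$type == "exact") {
          if (ord$strand[i] == "H") v$want else unname(.comp[v$want])
        } else NULL
        # which downstream PCG (if any) owns each coordinate
        owner <- rep(NA_integer_, length(coords))
        for (j in pcg_idx) {
          if (starts[j] <= starts[i]) next
          inside <- coords >= starts[j] & coords <= ends[j]
          owner[inside] <- j
        }
        owners <- unique(owner[!is.na(owner)])
        # coordinates we may rewrite: everything except downstream-owner
        # immutable positions
        frozen <- unlist(lapply(owners, immutable_coords))
        if (v$type == "exact") {
          conflict <- coords %in% frozen & seqv[coords] != want_genome
          if (any(conflict)) return(NULL)  # infeasible draw; retry globally
          free <- !(coords %in% frozen)
          # the owners' codons touching these coords must be redrawn jointly
          redraw_coords <- integer(0)
          for (j in owners) {
            touched <- coords[!is.na(owner) & owner == j]
            cp <- vapply(touched, function(co) {
              if (ord$strand[j] == "H") co - starts[j] + 1L else ends[j] - co + 1L
            }, 1L)
            codons <- unique((cp - 1L) %/% 3L)
            cpos <- unlist(lapply(codons, function(cd) (3L * cd + 1L):(3L * cd + 3L)))
            cpos <- cpos[cpos >= 1L & cpos <= ends[j] - starts[j] + 1L]
            redraw_coords <- c(redraw_coords, vapply(cpos, function(p) {
              .coding_coord(starts[j], ends[j], ord$strand[j], p)
            }, 1L))
          }
          redraw_coords <- setdiff(unique(redraw_coords), c(coords, frozen))
          ok <- FALSE
          for (try in 1:300) {
            seqv[coords[free]] <- want_genome[free]
            if (length(redraw_coords)) {
              seqv[redraw_coords] <- sample(names(probs), length(redraw_coords),
                                            replace = TRUE, prob = probs)
            }
            if (all(vapply(owners, codon_ok_in_frame, TRUE)) &&
                (length(redraw_coords) || try == 1L)) {
              ok <- TRUE
            }
            if (ok || !length(redraw_coords)) break
          }
          if (!ok && length(owners)) return(NULL)
        } else {  # internal stop codon: any mutable base may change
          mutable <- setdiff(coords, frozen)
          if (!length(mutable)) return(NULL)
          ok <- FALSE
          for (try in 1:300) {
            seqv[mutable] <- sample(names(probs), length(mutable),
                                    replace = TRUE, prob = probs)
            coding <- .read_coding(seqv, starts[i], ends[i], ord$strand[i])
            if (!.is_stop(coding[v$pos[1]], coding[v$pos[2]], coding[v$pos[3]]) &&
                all(vapply(owners, codon_ok_in_frame, TRUE))) {
              ok <- TRUE; break
            }
          }
          if (!ok) return(NULL)
        }
      }
    }
    if (!dirty) return(seqv)
  }
  all_ok <- all(vapply(pcg_idx, function(i) !length(check(i)), TRUE))
  if (all_ok) seqv else NULL
}
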