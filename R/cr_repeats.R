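#' Mask low-complexity runs before repeat scanning
#'
#' Replaces mononucleotide runs of 6 bp or more and dinucleotide tandems
#' of 8 bp or more (4+ copies of a 2-mer) with `N`. Without masking, such
#' runs trivially satisfy every small period and saturate a tandem-repeat
#' scan. Masked positions never match anything, including each other.
#'
#' @param seq DNA string.
#' @return The masked sequence.
#' @export
#' @examples
#' mask_low_complexity("ACGAAAAAAACG")
mask_low_complexity <- function(seq) {
  mask_re <- function(s, re) {
    m <- gregexpr(re, s, perl = TRUE)[[1]]
    if (m[1] == -1) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_along(m)) {
      idx <- m[i]:(m[i] + attr(m, "match.length")[i] - 1L)
      chars[idx] <- "N"
    }
    paste(chars, collapse = "")
  }
  seq <- mask_re(seq, "([ACGT])\\1{5,}")
  mask_re(seq, "([ACGT]{2})\\1{3,}")
}

#' Detect tandem repeats with a mismatch-only identity model
#'
#' Scans every period in `[min_period, max_period]` and every start
#' position; a candidate survives if the second copy matches the
#' first-copy consensus at `min_identity` or better, and is then greedily
#' extended copy by copy while each full copy keeps that per-copy identity
#' to the consensus. A fractional final copy is the matching prefix of the
#' next segment (TRF-style copy numbers, reported to 1 decimal). Identity
#' is mismatch-only (no indels), computed over all bases beyond the first
#' copy. Maximal, non-nested hits are reported: a hit nested inside a
#' same-period hit is dropped; a hit whose span is contained in another
#' period's span with strictly higher identity is dropped; and
#' phase-shifted re-detections of one array (same-period hits overlapping
#' by at least one period) keep only the best-identity phase. Output is
#' sorted by start, then period.
#'
#' Low-complexity masking (see [mask_low_complexity()]) is applied first
#' by default, and a candidate whose consensus is a homopolymer is always
#' skipped, so homopolymers and microsatellites do not report.
#'
#' @param cr_seq Non-empty DNA string (typically a control region).
#' @param min_period,max_period Unit length range in bp; `max_period` is
#'   clamped to half the sequence length.
#' @param min_copies Minimum (fractional) copy number, default 2.
#' @param min_identity Minimum per-copy identity fraction, default 0.85.
#' @param homopolymer_mask Apply low-complexity masking (default `TRUE`).
#' @return A data frame with columns `start`, `end`, `period`, `copies`,
#'   `identity`, `consensus` (positions 1-based within `cr_seq`).
#' @export
#' @examples
#' find_tandem_repeats(paste0("ACGTTACGGT", strrep("ACGTA", 4), "TTGCA"),
#'                     min_period = 5, max_period = 10)
find_tandem_repeats <- function(cr_seq, min_period = 10L, max_period = 220L,
                                min_copies = 2, min_identity = 0.85,
                                homopolymer_mask = TRUE) {
  if (!is.character(cr_seq) || length(cr_seq) != 1 || nchar(cr_seq) == 0) {
    stop("cr_seq must be a single non-empty DNA string")
  }
  L <- nchar(cr_seq)
  if (min_period < 1L) stop("min_period must be >= 1")
  if (min_period > max_period) stop("min_period exceeds max_period")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]")
  if (min_copies < 1) stop("min_copies must be >= 1")
  max_period <- min(max_period, L %/% 2L)
  empty <- data.frame(start = integer(0), end = integer(0), period = integer(0),
                      copies = numeric(0), identity = numeric(0),
                      consensus = character(0), stringsAsFactors = FALSE)
  if (max_period < min_period) return(empty)

  masked <- if (homopolymer_mask) mask_low_complexity(toupper(cr_seq)) else toupper(cr_seq)
  x <- match(strsplit(masked, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))

  hits <- list()
  for (p in min_period:max_period) {
    eq <- !is.na(x[1:(L - p)]) & !is.na(x[(1 + p):L]) &
      x[1:(L - p)] == x[(1 + p):L]
    cs <- cumsum(eq)
    smax <- L - 2L * p + 1L
    if (smax < 1L) next
    score <- cs[(1:smax) + p - 1L] - c(0, cs)[1:smax]
    cand <- which(score >= min_identity * p - 1e-9)
    for (s in cand) {
      cons <- x[s:(s + p - 1L)]
      if (all(!is.na(cons)) && length(unique(cons)) == 1L) next  # homopolymer unit
      k <- 1L; total_match <- 0L
      repeat {
        cstart <- s + k * p
        if (cstart + p - 1L > L) break
        copy <- x[cstart:(cstart + p - 1L)]
        m <- sum(!is.na(copy) & !is.na(cons) & copy == cons)
        if (m < min_identity * p - 1e-9) break
        total_match <- total_match + m
        k <- k + 1L
      }
      if (k < 2L) next
      t <- 0L
      while (s + k * p + t <= L && t < p &&
             !is.na(cons[t + 1L]) && !is.na(x[s + k * p + t]) &&
             x[s + k * p + t] == cons[t + 1L]) {
        t <- t + 1L
      }
      copies <- k + t / p
      if (copies + 1e-9 < min_copies) next
      denom <- (k - 1L) * p + t
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = s + k * p + t - 1L, period = p,
        copies = round(copies, 1),
        identity = if (denom) (total_match + t) / denom else 1,
        consensus = substr(cr_seq, s, s + p - 1L), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    contains <- h$start <= h$start[i] & h$end >= h$end[i] &
      !(h$start == h$start[i] & h$end == h$end[i] & seq_len(nrow(h)) >= i)
    if (any(contains & h$period == h$period[i])) keep[i] <- FALSE
    if (any(contains & h$period != h$period[i] & h$identity > h$identity[i] + 1e-12)) {
      keep[i] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  # phase-shifted re-detections of one array: same-period hits overlapping by
  # at least one period are one repeat; keep the best-identity phase
  # (ties -> leftmost)
  h <- h[order(h$period, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  i <- 1L
  while (i <= nrow(h)) {
    j <- i
    while (j < nrow(h) && h$period[j + 1L] == h$period[i] &&
           h$start[j + 1L] <= h$end[j] - h$period[i] + 1L) {
      j <- j + 1L
    }
    cluster <- i:j
    best <- cluster[order(-h$identity[cluster], h$start[cluster])][1L]
    keep[setdiff(cluster, best)] <- FALSE
    i <- j + 1L
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start, h$period), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Tandem repeats of a genome's control region
#'
#' Convenience wrapper: extracts the control-region sequence (deposited
#' strand) and runs [find_tandem_repeats()].
#'
#' @param genome A [mitogenome()] with a real sequence and a
#'   `control_region` feature.
#' @param ... Passed to [find_tandem_repeats()].
#' @return See [find_tandem_repeats()].
#' @export
control_region_repeats <- function(genome, ...) {
  f <- genome$features
  cr <- which(f$gene_class == "CR")
  if (!length(cr)) stop("genome has no control_region feature")
  feat <- f[cr[1], ]; feat$strand <- "H"
  find_tandem_repeats(extract_feature_sequence(genome, feat), ...)
}
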