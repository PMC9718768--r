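# Independent brute-force tandem-repeat oracle: plain character-vector loops,
# no shared code with the package implementation.

oracle_mask <- function(chars) {
  L <- length(chars)
  # mononucleotide runs of 6+
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  for (i in which(r$lengths >= 6 & r$values %in% c("A", "C", "G", "T"))) {
    chars[(ends[i] - r$lengths[i] + 1):ends[i]] <- "N"
  }
  # dinucleotide tandems of 4+ copies (leftmost, non-overlapping, even length)
  i <- 1L
  while (i <= L - 7L) {
    u <- chars[c(i, i + 1L)]
    if (all(u %in% c("A", "C", "G", "T"))) {
      k <- 1L
      while (i + 2L * k + 1L <= L &&
             chars[i + 2L * k] == u[1] && chars[i + 2L * k + 1L] == u[2]) {
        k <- k + 1L
      }
      if (k >= 4L) {
        chars[i:(i + 2L * k - 1L)] <- "N"
        i <- i + 2L * k
        next
      }
    }
    i <- i + 1L
  }
  chars
}

oracle_find_repeats <- function(seq, min_period, max_period, min_copies = 2,
                                min_identity = 0.85, mask = TRUE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (mask) chars <- oracle_mask(chars)
  L <- length(chars)
  maxp <- min(max_period, L %/% 2L)
  acgt <- c("A", "C", "G", "T")
  nmatch <- function(a, b) sum(a == b & a %in% acgt & b %in% acgt)
  hits <- list()
  if (maxp >= min_period) {
    for (p in min_period:maxp) {
      for (s in seq_len(L - 2L * p + 1L)) {
        cons <- chars[s:(s + p - 1L)]
        if (all(cons %in% acgt) && length(unique(cons)) == 1L) next
        if (nmatch(chars[(s + p):(s + 2L * p - 1L)], cons) < min_identity * p - 1e-9) next
        k <- 1L
        total <- 0L
        while (s + (k + 1L) * p - 1L <= L) {
          m <- nmatch(chars[(s + k * p):(s + (k + 1L) * p - 1L)], cons)
          if (m < min_identity * p - 1e-9) break
          total <- total + m
          k <- k + 1L
        }
        if (k < 2L) next
        t <- 0L
        while (s + k * p + t <= L && t < p && cons[t + 1L] %in% acgt &&
               chars[s + k * p + t] == cons[t + 1L]) {
          t <- t + 1L
        }
        copies <- k + t / p
        if (copies + 1e-9 < min_copies) next
        denom <- (k - 1L) * p + t
        hits[[length(hits) + 1L]] <- data.frame(
          start = s, end = s + k * p + t - 1L, period = p,
          copies = round(copies, 1),
          identity = if (denom) (total + t) / denom else 1,
          consensus = paste(strsplit(toupper(seq), "")[[1]][s:(s + p - 1L)],
                            collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0), period = integer(0),
                      copies = numeric(0), identity = numeric(0),
                      consensus = character(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  # drop nested same-period hits and cross-period contained hits with worse
  # identity
  drop <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(nrow(h))) {
      if (i == j) next
      contains <- h$start[j] <= h$start[i] && h$end[j] >= h$end[i]
      same_span <- h$start[j] == h$start[i] && h$end[j] == h$end[i]
      if (same_span && j > i) contains <- FALSE
      if (!contains) next
      if (h$period[j] == h$period[i]) drop[i] <- TRUE
      if (h$period[j] != h$period[i] && h$identity[j] > h$identity[i] + 1e-12) {
        drop[i] <- TRUE
      }
    }
  }
  h <- h[!drop, , drop = FALSE]
  # keep the best phase among same-period hits overlapping by >= one period
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

# quick random DNA string
random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# a small fully annotated real-sequence genome for io/codon tests
toy_real_genome <- function(seed = 42) {
  generate_mitogenome(synth_spec(seed = seed))$genome
}
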