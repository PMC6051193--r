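# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths (prefix k-mer
# index, vectorised suffix scan) so agreement is informative.

rand_dna <- function(n, len, probs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

# O(n * m) adapter-trim oracle: leftmost i with >= min_overlap overlap and
# mismatch fraction <= rate, scanning every offset with a character loop.
oracle_trim <- function(seq, adapter, min_overlap, rate) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  if (n >= min_overlap) {
    for (i in 0:(n - min_overlap)) {
      L <- min(n - i, length(a))
      if (L < min_overlap) next
      mm <- sum(s[(i + 1):(i + L)] != a[1:L])
      if (mm <= rate * L + 1e-9) return(i)
    }
  }
  n
}

# Exact-occurrence oracle: (ref, strand, position) triples by direct substring
# comparison at every offset, on both strands in genome mode. Uses base
# substring() over all offsets — no index, independent of the package's
# k-mer-join implementation.
oracle_occurrences <- function(insert, refs) {
  targets <- list(c(insert, "+"))
  if (refs$mode == "genome") targets <- c(targets, list(c(revcomp(insert), "-")))
  hits <- list()
  for (nm in names(refs)) {
    s <- refs$seq[[nm]]
    L <- nchar(s)
    for (tg in targets) {
      n <- nchar(tg[1])
      if (n > L) next
      at <- which(substring(s, 1:(L - n + 1), n:L) == tg[1])
      for (p in at) {
        hits[[length(hits) + 1]] <- list(ref = nm, start = p - 1L,
                                         strand = tg[2])
      }
    }
  }
  hits
}

tiny_scheme <- function() barcode_scheme("NNNXXXXNN", c(TTGT = "s1"))

# simulated reads as a tibble, small and fast
tiny_sim <- function(seed = 1, n = 500, ...) {
  simulate_library(sim_config(seed = seed, n_molecules = n,
                              n_refs = 1, ref_length = 5000, ...))
}

molecule_of <- function(read_id) {
  as.integer(sub("/.*$", "", sub("^mol", "", read_id)))
}
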