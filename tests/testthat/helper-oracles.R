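# Independent oracles and small constructors used across tests.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rotate_str <- function(s, k) {
  n <- nchar(s)
  k <- ((k - 1L) %% n) + 1L
  if (k == 1L) return(s)
  paste0(substr(s, k, n), substr(s, 1L, k - 1L))
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# brute-force terminal-overlap oracle: scan every suffix length
brute_overlap <- function(s, min_overlap, frac) {
  v <- strsplit(s, "")[[1L]]
  n <- length(v)
  for (k in seq(n %/% 2L, min_overlap)) {
    if (sum(v[1:k] != v[(n - k + 1L):n]) <= frac * k) return(k)
  }
  0L
}

# brute-force MNV chain closure: merge any two groups holding consecutive
# SNVs within the window with equal partitions, until a fixed point
chain_closure_oracle <- function(pos, part, window) {
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  grp <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_len(length(pos) - 1L)) {
      if (pos[i + 1L] - pos[i] < window && part[i + 1L] == part[i] &&
          grp[i + 1L] != grp[i]) {
        grp[grp == grp[i + 1L]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (given margins) no more probable than observed
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0L || n2 == 0L || k == 0L || k == m + n2) return(1)
  supp <- max(0L, k - n2):min(k, m)
  probs <- dhyper(supp, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# build a masked alignment from a named character vector without introns
quick_masked <- function(seqs, ...) mask_alignment(seqs, NULL, ...)

# compact simulation config for tests
quick_config <- function(seed, genome_length = 20000L, k_region_length = 3000L,
                         n = c("REF-A" = 5L, "REF-B" = 3L,
                               "NONREF-S" = 8L, "NONREF-D" = 4L), ...) {
  simulation_config(seed = seed, genome_length = genome_length,
                    k_region_length = k_region_length,
                    n_types_per_subclade = n, ...)
}
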