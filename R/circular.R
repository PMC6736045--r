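# Canonicalization of circular-mapping contigs.
#
# De novo assemblies of circular genomes are emitted as linear strings with an
# arbitrary start, arbitrary strand, and usually a stretch of duplicated
# sequence at the end (the assembler walks past the origin).  Canonical form:
# duplication trimmed, strand fixed, rotated so the sequence begins at a
# reference anchor.

#' Find the terminal self-overlap of a circular-mapping contig
#'
#' Returns the longest suffix length `k >= min_overlap` such that the suffix
#' matches the prefix of the contig with at most `max_mismatch_frac * k`
#' mismatches (ungapped comparison); 0 when no such suffix exists.
#'
#' Candidate overlap lengths are located by matching the first `min_overlap`
#' bases of the contig (the seed) within the trailing half of the contig,
#' allowing `seed_mismatch` mismatches, and each candidate is then verified
#' over the full overlap.  This assumes mismatches are not concentrated in the
#' seed beyond the allowance, which holds at polish-level error densities.
#'
#' @param sequence Contig sequence (character scalar over A/C/G/T/N).
#' @param min_overlap Minimum overlap length considered (bp, >= 20).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the overlap.
#' @param seed_mismatch Mismatches allowed when seeding candidate lengths.
#' @return Integer overlap length in bp (0 when none).
#' @export
find_terminal_overlap <- function(sequence, min_overlap = 50L,
                                  max_mismatch_frac = 0.01,
                                  seed_mismatch = max(2L, ceiling(min_overlap * max_mismatch_frac))) {
  stopifnot(is.character(sequence), length(sequence) == 1L, min_overlap >= 20L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L * min_overlap)
    stop("contig shorter than 2*min_overlap (", n, " < ", 2L * min_overlap, ")")
  k_max <- n %/% 2L
  # seed: occurrences of the contig prefix within the trailing window
  seed <- substr(sequence, 1L, min_overlap)
  tail_start <- n - k_max + 1L
  tail_seq <- substr(sequence, tail_start, n)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(seed),
                                   Biostrings::DNAString(tail_seq),
                                   max.mismatch = seed_mismatch)
  if (length(hits) == 0L) return(0L)
  cand_k <- sort(n - (tail_start + BiocGenerics::start(hits) - 1L) + 1L,
                 decreasing = TRUE)
  cand_k <- cand_k[cand_k >= min_overlap & cand_k <= k_max]
  sc <- seq_chars(sequence)
  for (k in cand_k) {
    mism <- sum(sc[1:k] != sc[(n - k + 1L):n])
    if (mism <= max_mismatch_frac * k) return(as.integer(k))
  }
  0L
}

#' Rotate a circular contig so it starts at a reference anchor
#'
#' Searches both strands for a unique (near-)exact occurrence of `anchor` and
#' returns the rotation of the contig (or of its reverse complement) starting
#' at that occurrence.  Sequence content is preserved up to rotation and
#' strand.
#'
#' @param sequence Trimmed circular contig (character scalar).
#' @param anchor Anchor sequence (>= 20 bp); by convention the first bases of
#'   the reference genome.
#' @param max_mismatch_frac Mismatch fraction allowed in the anchor match.
#' @return Rotated sequence (character scalar).
#' @export
rotate_to_anchor <- function(sequence, anchor, max_mismatch_frac = 0.05) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(anchor) >= 20L)
  sequence <- toupper(sequence)
  anchor <- toupper(anchor)
  n <- nchar(sequence)
  if (nchar(anchor) > n) stop("anchor longer than contig")
  mm <- floor(max_mismatch_frac * nchar(anchor))
  find_hits <- function(s) {
    doubled <- paste0(s, substr(s, 1L, nchar(anchor) - 1L))
    h <- Biostrings::matchPattern(Biostrings::DNAString(anchor),
                                  Biostrings::DNAString(doubled),
                                  max.mismatch = mm)
    st <- BiocGenerics::start(h)
    st[st >= 1L & st <= n]  # drop edge overhangs; wrap duplicates collapse onto [1, n]
  }
  fwd <- find_hits(sequence)
  rev <- find_hits(revcomp(sequence))
  if (length(fwd) + length(rev) == 0L)
    stop("anchor not found on either strand (forward hits: 0, reverse hits: 0)")
  if (length(fwd) + length(rev) > 1L)
    stop("ambiguous anchor: ", length(fwd), " forward and ", length(rev),
         " reverse hit(s); refusing to pick one")
  if (length(fwd) == 1L) {
    s <- sequence; st <- fwd
  } else {
    s <- revcomp(sequence); st <- rev
  }
  if (st == 1L) return(s)
  paste0(substr(s, st, n), substr(s, 1L, st - 1L))
}

#' Canonicalize a circular-mapping contig
#'
#' Trims the terminal self-overlap, then rotates (and strand-flips if needed)
#' so the sequence starts at the anchor.  Idempotent: canonicalizing a
#' canonical contig returns it unchanged.
#'
#' @inheritParams find_terminal_overlap
#' @inheritParams rotate_to_anchor
#' @param anchor_mismatch_frac Mismatch fraction allowed in the anchor match.
#' @return List with `sequence` (canonical string), `overlap_trimmed` (bp)
#'   and `strand` (`"+"` or `"-"` relative to the input).
#' @export
canonicalize <- function(sequence, anchor, min_overlap = 50L,
                         max_mismatch_frac = 0.01,
                         anchor_mismatch_frac = 0.05) {
  k <- find_terminal_overlap(sequence, min_overlap = min_overlap,
                             max_mismatch_frac = max_mismatch_frac)
  trimmed <- if (k > 0L) substr(sequence, 1L, nchar(sequence) - k) else sequence
  rot <- rotate_to_anchor(trimmed, anchor,
                          max_mismatch_frac = anchor_mismatch_frac)
  strand <- if (grepl(toupper(trimmed), paste0(rot, rot), fixed = TRUE)) "+" else "-"
  list(sequence = rot, overlap_trimmed = as.integer(k), strand = strand)
}
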