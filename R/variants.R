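# Segregating-site matrices from intron-masked alignments: bi-allelic SNV
# extraction, MNV merging, pairwise difference classification and
# reference-error identification.

#' Mask intronic (and optionally gapped) columns of an alignment
#'
#' A column is masked out when it lies within any taxon's intron interval
#' (intervals are given in each taxon's own ungapped coordinates and are
#' projected through that taxon's gaps onto alignment columns), when any row
#' holds `N`, or -- with `drop_gap_columns = TRUE` -- when any row holds a
#' gap.  Intron presence-absence polymorphism therefore masks the affected
#' columns for all taxa.
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   a `DNAStringSet`, or a character matrix with taxon rownames.
#' @param intron_intervals data.frame with columns `type` (taxon), `start`,
#'   `end` (1-based inclusive, ungapped per-taxon coordinates); may be `NULL`.
#' @param drop_gap_columns Mask out columns holding a gap in any row.
#' @param ref_taxon Taxon whose ungapped coordinates are reported as
#'   `source_coords` (default: first row).
#' @return Object of class `masked_alignment`: list with `matrix` (taxa x
#'   columns), `keep` (logical per column), `source_coords` (1-based position
#'   in `ref_taxon`, `NA` at reference-gap columns) and masking `counts`.
#' @export
mask_alignment <- function(alignment, intron_intervals = NULL,
                           drop_gap_columns = TRUE, ref_taxon = NULL) {
  m <- as_aln_matrix(alignment)
  taxa <- rownames(m)
  nc <- ncol(m)
  if (is.null(ref_taxon)) ref_taxon <- taxa[1L]
  stopifnot(ref_taxon %in% taxa)

  intronic <- rep(FALSE, nc)
  if (!is.null(intron_intervals) && nrow(intron_intervals) > 0L) {
    stopifnot(all(c("type", "start", "end") %in% colnames(intron_intervals)))
    for (tx in unique(intron_intervals$type)) {
      if (!tx %in% taxa) next
      row <- m[tx, ]
      ungapped_len <- sum(row != "-")
      # alignment column of each ungapped position
      pos_of <- which(row != "-")
      iv <- intron_intervals[intron_intervals$type == tx, , drop = FALSE]
      if (any(iv$start < 1L | iv$end > ungapped_len | iv$start > iv$end))
        stop("intron interval outside sequence bounds for taxon ", tx)
      for (i in seq_len(nrow(iv)))
        intronic[pos_of[iv$start[i]:iv$end[i]]] <- TRUE
    }
  }
  has_gap <- colSums(m == "-") > 0L
  has_n <- colSums(m == "N") > 0L
  keep <- !intronic & !has_n & (if (drop_gap_columns) !has_gap else rep(TRUE, nc))

  ref_row <- m[ref_taxon, ]
  src <- rep(NA_integer_, nc)
  src[ref_row != "-"] <- seq_len(sum(ref_row != "-"))

  structure(list(matrix = m, keep = keep, source_coords = src,
                 ref_taxon = ref_taxon,
                 counts = c(total = nc, kept = sum(keep),
                            intronic = sum(intronic), gap = sum(has_gap),
                            ambiguous = sum(has_n))),
            class = "masked_alignment")
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat("Masked alignment:", nrow(x$matrix), "taxa x", ncol(x$matrix),
      "columns;", x$counts[["kept"]], "kept (",
      x$counts[["intronic"]], "intronic,", x$counts[["gap"]], "gapped,",
      x$counts[["ambiguous"]], "ambiguous masked out )\n")
  invisible(x)
}

# canonical key of the bipartition a column induces: membership string with
# the first taxon always on side "0"
partition_key <- function(col, allele_a) {
  paste(ifelse(col == allele_a, "0", "1"), collapse = "")
}

#' Extract bi-allelic SNVs from a masked alignment
#'
#' One variant per kept column holding exactly two residue states across taxa.
#' Monomorphic and multi-allelic columns are skipped; skip counts are
#' attached as the `"skipped"` attribute.
#'
#' @param masked A [mask_alignment()] result.
#' @return data.frame of class `variant_table` with one row per SNV:
#'   `kind`, `columns` (alignment column, list), `ordinal` (kept-column
#'   ordinal of the first member site), `ref_coord`, `allele_a` (allele of
#'   the first taxon), `allele_b`, `partition` (taxa membership string,
#'   first taxon = 0).
#' @export
extract_biallelic_snvs <- function(masked) {
  stopifnot(inherits(masked, "masked_alignment"))
  m <- masked$matrix
  kept <- which(masked$keep)
  mk <- m[, kept, drop = FALSE]
  # number of residue states per kept column, vectorized over the alphabet
  present <- vapply(DNA_BASES, function(b) colSums(mk == b) > 0L,
                    logical(length(kept)))
  if (length(kept) == 1L) present <- matrix(present, nrow = 1L)
  n_states <- rowSums(present)
  gapped <- colSums(mk == "-") > 0L  # indel columns never enter the SNV set
  bi <- which(n_states == 2L & !gapped)
  n_mono <- sum(n_states == 1L & !gapped)
  n_multi <- sum(n_states > 2L & !gapped)
  rows <- lapply(bi, function(j) {
    col <- mk[, j]
    a <- col[1L]
    b <- setdiff(unique(col), a)
    data.frame(kind = "SNV", ordinal = j, column = kept[j],
               ref_coord = masked$source_coords[kept[j]],
               allele_a = a, allele_b = b,
               partition = partition_key(col, a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(), ordinal = integer(),
                      column = integer(), ref_coord = integer(),
                      allele_a = character(), allele_b = character(),
                      partition = character(), stringsAsFactors = FALSE)
  out$columns <- as.list(out$column)
  attr(out, "skipped") <- c(monomorphic = n_mono, multiallelic = n_multi,
                            gapped = sum(gapped))
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Merge neighboring SNVs into multi-nucleotide variants
#'
#' Transitive chaining: consecutive bi-allelic SNVs closer than `window`
#' (default 15 bp) that induce the identical allelic partition of the taxa
#' are merged into one bi-allelic MNV whose alleles concatenate the member
#' alleles.  Each input SNV belongs to exactly one output variant.
#'
#' @param snvs A `variant_table` of SNVs sorted by position.
#' @param window Merge window (bp); sites merge when their spacing is
#'   strictly less than `window`.
#' @param coord Coordinate system for the spacing rule: `"kept"` (gap-stripped
#'   kept-column ordinals, the default) or `"reference"` (reference
#'   coordinates, where available).
#' @return `variant_table` of SNVs and MNVs in genomic order.
#' @export
merge_snvs_to_mnvs <- function(snvs, window = 15L, coord = c("kept", "reference")) {
  coord <- match.arg(coord)
  if (nrow(snvs) == 0L) return(snvs)
  pos <- if (coord == "kept") snvs$ordinal else snvs$ref_coord
  if (is.unsorted(pos, strictly = TRUE))
    stop("SNVs must be sorted by position")
  # chain id: break when spacing >= window or partition changes
  brk <- c(TRUE, diff(pos) >= window |
             snvs$partition[-1L] != snvs$partition[-nrow(snvs)])
  grp <- cumsum(brk)
  out <- lapply(split(seq_len(nrow(snvs)), grp), function(ix) {
    first <- ix[1L]
    data.frame(kind = if (length(ix) > 1L) "MNV" else "SNV",
               ordinal = snvs$ordinal[first],
               column = snvs$column[first],
               ref_coord = snvs$ref_coord[first],
               allele_a = paste(snvs$allele_a[ix], collapse = ""),
               allele_b = paste(snvs$allele_b[ix], collapse = ""),
               partition = snvs$partition[first],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$columns <- unname(lapply(split(snvs$column, grp), identity))
  res$n_sites <- vapply(res$columns, length, integer(1L))
  rownames(res) <- NULL
  class(res) <- c("variant_table", "data.frame")
  res
}

#' Export a binary genotype matrix from bi-allelic variants
#'
#' Rows are taxa, columns variants in genomic order; the designated reference
#' taxon's allele is coded 0 at every site, so its row is all zeros.
#'
#' @param variants A `variant_table` (SNVs and/or MNVs).
#' @param taxa Ordered taxa (must match the partition strings' order).
#' @param ref_taxon Taxon whose alleles define 0 (default: first).
#' @return Integer matrix taxa x variants over \{0, 1\}.
#' @export
export_genotype_matrix <- function(variants, taxa, ref_taxon = taxa[1L]) {
  stopifnot(ref_taxon %in% taxa)
  ri <- match(ref_taxon, taxa)
  g <- vapply(variants$partition, function(p) {
    bits <- as.integer(strsplit(p, "")[[1L]])
    if (length(bits) != length(taxa)) stop("partition/taxa length mismatch")
    if (bits[ri] == 1L) bits <- 1L - bits
    bits
  }, integer(length(taxa)))
  g <- matrix(g, nrow = length(taxa),
              dimnames = list(taxa, paste0("v", seq_len(nrow(variants)))))
  g
}

#' Classify the differences between two aligned sequences
#'
#' Maximal runs of disagreeing columns of a gapped pairwise alignment are
#' reported as one difference each: equal-length gap-free runs are single- /
#' double- / multi-nucleotide substitutions, runs gapped in the reference are
#' insertions, runs gapped in the query deletions.  Indels are anchored on
#' the preceding reference base (GenBank style, e.g. `C -> CC`), with
#' 1-based reference coordinates throughout.
#'
#' @param ref_aln,query_aln Aligned sequences (equal length, `-` for gaps).
#' @param features Optional data.frame (`feature`, `start`, `end`, `coding`
#'   logical) in reference coordinates, used to fill `affected_feature`.
#' @return data.frame with `position`, `ref_allele`, `alt_allele`,
#'   `category`, `affected_feature`.
#' @export
classify_pairwise_differences <- function(ref_aln, query_aln, features = NULL) {
  r <- seq_chars(ref_aln); q <- seq_chars(query_aln)
  if (length(r) != length(q)) stop("alignment rows differ in length")
  diffpos <- which(r != q)
  if (length(diffpos) == 0L)
    return(data.frame(position = integer(), ref_allele = character(),
                      alt_allele = character(), category = character(),
                      affected_feature = character(), stringsAsFactors = FALSE))
  refpos <- cumsum(r != "-")  # reference coordinate of each column
  runs <- split(diffpos, cumsum(c(1L, diff(diffpos) != 1L)))
  out <- lapply(runs, function(ix) {
    rs <- r[ix]; qs <- q[ix]
    ref_seg <- paste(rs[rs != "-"], collapse = "")
    qry_seg <- paste(qs[qs != "-"], collapse = "")
    lr <- nchar(ref_seg); lq <- nchar(qry_seg)
    if (lr == lq && !any(rs == "-") && !any(qs == "-")) {
      category <- if (lr == 1L) "single-nucleotide substitution"
        else if (lr == 2L) "double-nucleotide substitution"
        else "multi-nucleotide substitution"
      pos <- refpos[ix[1L]]
      ref_allele <- ref_seg; alt_allele <- qry_seg
    } else {
      # anchored indel (or complex run reported anchored)
      anchor_col <- ix[1L] - 1L
      anchor <- if (anchor_col >= 1L) r[anchor_col] else ""
      pos <- if (anchor_col >= 1L) refpos[anchor_col] else 1L
      ref_allele <- paste0(anchor, ref_seg)
      alt_allele <- paste0(anchor, qry_seg)
      category <- if (lq > lr) "insertion"
        else if (lr > lq) "deletion"
        else "complex"
    }
    data.frame(position = pos, ref_allele = ref_allele,
               alt_allele = alt_allele, category = category,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$affected_feature <- NA_character_
  if (!is.null(features) && nrow(features) > 0L) {
    for (i in seq_len(nrow(res))) {
      hit <- which(features$start <= res$position[i] &
                     features$end >= res$position[i])
      if (length(hit) > 0L) res$affected_feature[i] <- features$feature[hit[1L]]
    }
  }
  res
}

#' Classify one anchored reference/alternate allele pair
#'
#' Category rules as in [classify_pairwise_differences()], applied to a pair
#' of allele strings written in anchored style (indels carry one shared
#' anchor base, as in GenBank difference tables).
#'
#' @param ref,alt Allele strings.
#' @return One of `"single-nucleotide substitution"`,
#'   `"double-nucleotide substitution"`, `"multi-nucleotide substitution"`,
#'   `"insertion"`, `"deletion"`, `"complex"`.
#' @export
classify_difference <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (ref == alt) stop("alleles are identical")
  if (lr == la)
    return(switch(as.character(min(lr, 3L)),
                  "1" = "single-nucleotide substitution",
                  "2" = "double-nucleotide substitution",
                  "3" = "multi-nucleotide substitution"))
  if (la > lr && startsWith(alt, ref)) return("insertion")
  if (lr > la && startsWith(ref, alt)) return("deletion")
  "complex"
}

#' Partition reference-vs-focal differences into errors and polymorphisms
#'
#' A difference between the reference sequence and a focal assembled type is
#' a reference error precisely when every other assembled type carries the
#' focal type's allele at that position (the reference allele is private to
#' the reference).  If any other type carries the reference allele it is a
#' polymorphism candidate; positions with missing allele data are reported
#' unresolved, never silently classified.
#'
#' @param differences data.frame with at least `position`, `ref_allele`,
#'   `alt_allele` (focal type's allele).
#' @param allele_table Matrix or data.frame of alleles: rows = positions in
#'   the same order as `differences`, columns = the other assembled types.
#' @return `differences` with an added `status` column:
#'   `"reference error"`, `"polymorphism candidate"` or `"unresolved"`.
#' @export
identify_reference_errors <- function(differences, allele_table) {
  at <- as.matrix(allele_table)
  if (nrow(at) != nrow(differences))
    stop("allele_table must have one row per difference")
  status <- character(nrow(differences))
  for (i in seq_len(nrow(differences))) {
    alleles <- at[i, ]
    if (anyNA(alleles)) { status[i] <- "unresolved"; next }
    status[i] <- if (all(alleles == differences$alt_allele[i]))
      "reference error" else "polymorphism candidate"
  }
  differences$status <- status
  differences
}
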