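test_that("masking keeps everything when there is nothing to mask", {
  aln <- c(t1 = "ACGTACGT", t2 = "ACGTACGA", t3 = "ACGAACGT")
  m <- mask_alignment(aln)
  expect_true(all(m$keep))
  expect_identical(m$counts[["kept"]], 8L)
  expect_identical(m$source_coords, 1:8)
})

test_that("intron intervals mask the projected columns for all taxa", {
  # t2 has a gap, so its coordinates shift relative to alignment columns
  aln <- c(t1 = "AACCGGTTAA",
           t2 = "AA-CGGTTAA",
           t3 = "AACCGGTTAA")
  introns <- data.frame(type = "t2", start = 4, end = 6)  # t2's own coords
  m <- mask_alignment(aln, introns, drop_gap_columns = FALSE)
  # t2 positions 4..6 are alignment columns 5..7 (its gap sits at column 3)
  expect_identical(which(!m$keep), c(5L, 6L, 7L))
  # with gap dropping, column 3 goes too
  m2 <- mask_alignment(aln, introns, drop_gap_columns = TRUE)
  expect_identical(which(!m2$keep), c(3L, 5L, 6L, 7L))
  # a 3-column intron block shared by every taxon removes exactly 3 columns
  all_introns <- data.frame(type = c("t1", "t2", "t3"),
                            start = c(5, 4, 5), end = c(7, 6, 7))
  m3 <- mask_alignment(aln, all_introns, drop_gap_columns = FALSE)
  expect_identical(sum(!m3$keep), 3L)
})

test_that("gap columns and N columns are masked out when requested", {
  aln <- c(t1 = "ACGTNA", t2 = "AC-TNA")
  m <- mask_alignment(aln, drop_gap_columns = TRUE)
  expect_identical(which(m$keep), c(1L, 2L, 4L, 6L))
  m2 <- mask_alignment(aln, drop_gap_columns = FALSE)
  expect_identical(which(m2$keep), c(1L, 2L, 3L, 4L, 6L))
})

test_that("interval outside sequence bounds is an error", {
  aln <- c(t1 = "ACGTAC", t2 = "ACGTAC")
  expect_error(mask_alignment(aln, data.frame(type = "t1", start = 2, end = 9)),
               "bounds")
})

test_that("bi-allelic SNV extraction follows the two-state rule", {
  aln <- c(a = "AAAAT", b = "ACACT", c = "ACCGT", d = "AACAT")
  m <- mask_alignment(aln)
  snvs <- extract_biallelic_snvs(m)
  # col1, col5 monomorphic; col2 and col3 biallelic; col4 has three states
  expect_identical(nrow(snvs), 2L)
  expect_identical(snvs$column, c(2L, 3L))
  expect_identical(attr(snvs, "skipped"),
                   c(monomorphic = 2L, multiallelic = 1L, gapped = 0L))
  # partition encodes membership relative to the first taxon
  expect_identical(snvs$partition[1], "0110")
  expect_identical(snvs$partition[2], "0011")
})

test_that("MNV merging chains by window and identical partition", {
  snv <- function(ord, part, a = "A", b = "C")
    data.frame(kind = "SNV", ordinal = ord, column = ord, ref_coord = ord,
               allele_a = a, allele_b = b, partition = part,
               stringsAsFactors = FALSE)
  mk <- function(...) {
    d <- do.call(rbind, list(...))
    d$columns <- as.list(d$column)
    class(d) <- c("variant_table", "data.frame")
    d
  }
  # two SNVs 10 apart, same partition -> one 2-site MNV
  v <- merge_snvs_to_mnvs(mk(snv(1, "0011"), snv(11, "0011")))
  expect_identical(v$kind, "MNV")
  expect_identical(v$n_sites, 2L)
  expect_identical(v$allele_a, "AA")
  # same spacing, different partitions -> two SNVs
  v2 <- merge_snvs_to_mnvs(mk(snv(1, "0011"), snv(11, "0101")))
  expect_identical(v2$kind, c("SNV", "SNV"))
  # chain of three at spacings 10, 10 -> one 3-site MNV
  v3 <- merge_snvs_to_mnvs(mk(snv(1, "0011"), snv(11, "0011"), snv(21, "0011")))
  expect_identical(v3$n_sites, 3L)
  # spacing exactly the window does not merge
  v4 <- merge_snvs_to_mnvs(mk(snv(1, "0011"), snv(16, "0011")))
  expect_identical(v4$kind, c("SNV", "SNV"))
  expect_error(merge_snvs_to_mnvs(mk(snv(11, "0011"), snv(1, "0011"))),
               "sorted")
})

test_that("MNV merging equals the brute-force chain closure on random layouts", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    pos <- sort(sample.int(300, n))
    part <- sample(c("00111", "01011", "00101"), n, replace = TRUE)
    d <- data.frame(kind = "SNV", ordinal = pos, column = pos, ref_coord = pos,
                    allele_a = "A", allele_b = "C", partition = part,
                    stringsAsFactors = FALSE)
    d$columns <- as.list(d$column)
    class(d) <- c("variant_table", "data.frame")
    merged <- merge_snvs_to_mnvs(d, window = 15)
    oracle_grp <- chain_closure_oracle(pos, part, 15)
    oracle_sizes <- as.integer(table(factor(oracle_grp, levels = unique(oracle_grp))))
    expect_identical(merged$n_sites, oracle_sizes)
    # allele mass conserved: every SNV in exactly one output variant
    expect_identical(sum(merged$n_sites), n)
  }
})

test_that("merging is idempotent on already-merged output", {
  set.seed(62)
  pos <- sort(sample.int(200, 20))
  d <- data.frame(kind = "SNV", ordinal = pos, column = pos, ref_coord = pos,
                  allele_a = "A", allele_b = "C",
                  partition = sample(c("0011", "0101"), 20, replace = TRUE),
                  stringsAsFactors = FALSE)
  d$columns <- as.list(d$column)
  class(d) <- c("variant_table", "data.frame")
  m1 <- merge_snvs_to_mnvs(d)
  m2 <- merge_snvs_to_mnvs(m1)
  expect_identical(m1$allele_a, m2$allele_a)
  expect_identical(m1$ordinal, m2$ordinal)
})

test_that("pairwise difference classification reproduces anchored table styles", {
  # insertion: ref C, query CC (anchored on the preceding base)
  ref <- "TTGAC-ATTG"
  qry <- "TTGACCATTG"
  d <- classify_pairwise_differences(ref, qry)
  expect_identical(d$category, "insertion")
  expect_identical(d$ref_allele, "C")
  expect_identical(d$alt_allele, "CC")
  expect_identical(d$position, 5L)
  # double-nucleotide substitution: TC -> CT
  d2 <- classify_pairwise_differences("AATCAA", "AACTAA")
  expect_identical(d2$category, "double-nucleotide substitution")
  expect_identical(d2$ref_allele, "TC")
  # identical sequences
  expect_identical(nrow(classify_pairwise_differences("ACGT", "ACGT")), 0L)
  # deletion with feature annotation
  d3 <- classify_pairwise_differences(
    "AAGGTT", "AAG-TT",
    features = data.frame(feature = "gene1", start = 3, end = 5))
  expect_identical(d3$category, "deletion")
  expect_identical(d3$affected_feature, "gene1")
})

test_that("anchored allele pairs are categorized like the printed table rows", {
  expect_identical(classify_difference("C", "T"), "single-nucleotide substitution")
  expect_identical(classify_difference("TC", "CT"), "double-nucleotide substitution")
  expect_identical(classify_difference("C", "CC"), "insertion")
  expect_identical(classify_difference("C", "CTAC"), "insertion")
  expect_identical(classify_difference("AC", "A"), "deletion")
  expect_error(classify_difference("A", "A"), "identical")
})

test_that("reference errors separate exactly from planted polymorphisms", {
  cfg <- quick_config(71, genome_length = 6000, k_region_length = 200)
  ds <- generate_population(cfg)
  focal <- "T01"
  types <- ds$truth_clades$type
  others <- setdiff(types, focal)
  seqs <- lapply(ds$mitogenomes[types], function(s) strsplit(s, "")[[1]])
  focal_seq <- seqs[[focal]]
  # planted reference errors: positions where all types agree; the reference
  # gets a private allele there
  allmat <- do.call(rbind, seqs)
  n_alleles <- apply(allmat, 2, function(col) length(unique(col)))
  mono <- which(n_alleles == 1)
  err_pos <- sort(sample(mono, 5))
  # planted polymorphisms: biallelic positions where some other type differs
  # from focal; the reference carries that other allele
  other_differs <- vapply(seq_len(ncol(allmat)), function(p)
    any(allmat[others, p] != focal_seq[p]), logical(1))
  poly_all <- which(n_alleles == 2 & other_differs)
  poly_pos <- sort(sample(setdiff(poly_all, err_pos), 5))
  ref_seq <- focal_seq
  for (p in err_pos) ref_seq[p] <- setdiff(c("A", "C", "G", "T"), focal_seq[p])[1]
  for (p in poly_pos) {
    alt <- unique(vapply(seqs[others], `[`, character(1), p))
    ref_seq[p] <- setdiff(alt, focal_seq[p])[1]
  }
  pos <- sort(c(err_pos, poly_pos))
  diffs <- data.frame(position = pos,
                      ref_allele = ref_seq[pos],
                      alt_allele = focal_seq[pos],
                      stringsAsFactors = FALSE)
  allele_tab <- do.call(cbind, lapply(seqs[others], `[`, pos))
  res <- identify_reference_errors(diffs, allele_tab)
  expect_identical(res$status[res$position %in% err_pos],
                   rep("reference error", 5))
  expect_identical(res$status[res$position %in% poly_pos],
                   rep("polymorphism candidate", 5))
  # missing data is reported unresolved
  allele_tab2 <- allele_tab
  allele_tab2[1, 1] <- NA
  res2 <- identify_reference_errors(diffs, allele_tab2)
  expect_identical(res2$status[1], "unresolved")
})

test_that("genotype matrix export is reference-polarized and clusters clades", {
  cfg <- quick_config(81, genome_length = 12000, k_region_length = 200)
  ds <- generate_population(cfg)
  masked <- mask_alignment(ds$mitogenomes, ds$annotations)
  v <- merge_snvs_to_mnvs(extract_biallelic_snvs(masked))
  g <- export_genotype_matrix(v, names(ds$mitogenomes))
  expect_true(all(g %in% 0:1))
  expect_identical(unname(g["T01", ]), rep(0L, ncol(g)))
  # rows separate into the two true clades by Hamming distance
  d <- as.matrix(dist(g, method = "manhattan"))
  tc <- ds$truth_clades
  within <- d[tc$type[tc$clade == "REF"], tc$type[tc$clade == "REF"]]
  across <- d[tc$type[tc$clade == "REF"], tc$type[tc$clade == "NONREF"]]
  expect_lt(max(within), min(across))
})
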