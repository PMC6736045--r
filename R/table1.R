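# Packaged transcription of the published reference-vs-MT1 difference table.

#' Load the packaged reference-vs-MT1 difference table
#'
#' The 20 differences between the reference fission yeast mitogenome and the
#' MT1 assembly (position, anchored reference and MT1 alleles, affected gene,
#' amino-acid effect), transcribed from the published table.  RNA genes and
#' intergenic positions carry `N/A` in `aa_difference`.
#'
#' @return data.frame with columns `position`, `ref`, `alt`, `gene`,
#'   `aa_difference`, `detected_before`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "mitolineage",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Summarize a reference-vs-focal difference table
#'
#' Computes the difference category of every anchored ref/alt pair with
#' [classify_difference()] and tallies category counts, the number of
#' differences in protein-coding sequence (any gene other than the two rRNA
#' genes and intergenic positions) and the number altering amino acids
#' (a coding location with an amino-acid difference other than synonymous).
#'
#' @param tab data.frame as returned by [load_table1()].
#' @param noncoding_features Feature labels treated as non-protein-coding.
#' @return List with `differences` (the table plus `category` and `coding`
#'   columns), `category_counts`, `n_coding`, `n_aa_altering`.
#' @export
summarize_differences <- function(tab,
                                  noncoding_features = c("rnl", "rns", "Intergenic")) {
  tab$category <- mapply(classify_difference, tab$ref, tab$alt,
                         USE.NAMES = FALSE)
  tab$coding <- !tab$gene %in% noncoding_features
  aa_altering <- tab$coding & !tab$aa_difference %in% c("N/A", "Synonymous")
  list(differences = tab,
       category_counts = table(tab$category),
       n_coding = sum(tab$coding),
       n_aa_altering = sum(aa_altering))
}
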