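# Intron presence-absence analytics across the eight canonical mitochondrial
# intron insertion sites, plus intron-encoded-protein (IEP) feature rules.

INTRON_SITES <- c("cox1-I1a", "cox1-I1b", "cox1-I2a", "cox1-I2b",
                  "cox1-I3", "cox1-I4", "cob-I1", "cox2-I1")

# the cox1-I1b site hosts either the b or the b' intron variant, never both
I1B_SITE <- "cox1-I1b"

#' Build an intron presence-absence matrix from annotations
#'
#' Cells are `"absent"`, `"present"`, or at the cox1-I1b site
#' `"present:b"` / `"present:b'"` (the two mutually exclusive intron variants
#' sharing that insertion site).
#'
#' @param annotations data.frame with columns `type` and `feature` (site
#'   name; at the I1b site optionally suffixed `:b` or `:b'`).
#' @param types Optional character vector fixing row order (types without
#'   annotations get all-absent rows).
#' @param sites Site (column) names; defaults to the 8 canonical sites.
#' @return Character matrix, types x sites.
#' @export
build_presence_matrix <- function(annotations, types = NULL,
                                  sites = INTRON_SITES) {
  stopifnot(all(c("type", "feature") %in% colnames(annotations)))
  feat <- annotations$feature
  base <- sub(":b'?$", "", feat)
  variant <- ifelse(grepl(":b'$", feat), "b'",
                    ifelse(grepl(":b$", feat), "b", NA_character_))
  unknown <- !base %in% sites
  if (any(unknown))
    stop("unknown intron site label(s): ",
         paste(unique(feat[unknown]), collapse = ", "))
  if (any(!is.na(variant) & base != I1B_SITE))
    stop("b/b' variant labels are only valid at the ", I1B_SITE, " site")
  if (is.null(types)) types <- unique(annotations$type)
  m <- matrix("absent", length(types), length(sites),
              dimnames = list(types, sites))
  for (i in seq_len(nrow(annotations))) {
    tx <- annotations$type[i]
    if (!tx %in% types) next
    cur <- m[tx, base[i]]
    val <- if (is.na(variant[i])) "present" else paste0("present:", variant[i])
    if (base[i] == I1B_SITE && cur != "absent" && cur != val)
      stop("type ", tx, " annotated with both b and b' at ", I1B_SITE)
    m[tx, base[i]] <- val
  }
  m
}

#' Count distinct intron presence-absence patterns
#'
#' Rows are compared as whole state vectors; the b and b' states at the
#' cox1-I1b site count as distinct.
#'
#' @param matrix Presence matrix from [build_presence_matrix()].
#' @return List with `n_patterns` and `patterns` (data.frame mapping each
#'   pattern string to its member types and count).
#' @export
count_patterns <- function(matrix) {
  stopifnot(nrow(matrix) > 0L)
  key <- apply(matrix, 1L, paste, collapse = "|")
  tab <- split(rownames(matrix), key)
  patterns <- data.frame(pattern = names(tab),
                         n_types = lengths(tab),
                         types = vapply(tab, paste, character(1L),
                                        collapse = ","),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(n_patterns = length(tab), patterns = patterns)
}

#' Per-site intron occupancy
#'
#' Fraction of types carrying any intron at each site, overall or per clade.
#'
#' @param matrix Presence matrix.
#' @param clades Optional data.frame (`type`, `clade`) for grouped occupancy.
#' @return Named numeric vector (overall) or matrix clades x sites of
#'   fractions in `[0, 1]`.
#' @export
site_occupancy <- function(matrix, clades = NULL) {
  occ <- function(m) colMeans(m != "absent")
  if (is.null(clades)) return(occ(matrix))
  stopifnot(all(clades$type %in% rownames(matrix)))
  groups <- split(clades$type, clades$clade)
  if (length(groups) == 0L || any(lengths(groups) == 0L))
    stop("empty clade group")
  t(vapply(groups, function(tx) occ(matrix[tx, , drop = FALSE]),
           numeric(ncol(matrix))))
}

#' Per-site clade association tests
#'
#' For each intron site, a 2x2 table of clade membership against intron
#' presence, with a two-sided Fisher exact p-value.  Sites with degenerate
#' margins report p = 1 and are flagged.
#'
#' @param matrix Presence matrix.
#' @param clades data.frame (`type`, `clade`), exactly two clade labels.
#' @return data.frame per site: counts, `p`, `degenerate`.
#' @export
clade_association_test <- function(matrix, clades) {
  labs <- unique(clades$clade)
  if (length(labs) != 2L) stop("exactly two clades required")
  stopifnot(all(clades$type %in% rownames(matrix)))
  res <- lapply(colnames(matrix), function(site) {
    pres <- matrix[clades$type, site] != "absent"
    tab <- table(factor(clades$clade, levels = labs),
                 factor(pres, levels = c(TRUE, FALSE)))
    degen <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    p <- if (degen) 1 else fisher.test(tab)$p.value
    data.frame(site = site,
               present_1 = tab[1L, 1L], absent_1 = tab[1L, 2L],
               present_2 = tab[2L, 1L], absent_2 = tab[2L, 2L],
               p = p, degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:5] <- c(paste0(labs[1L], c("_present", "_absent")),
                       paste0(labs[2L], c("_present", "_absent")))
  out
}

#' Co-occurrence test for two intron sites
#'
#' Two-sided Fisher exact test (sum of outcome probabilities no larger than
#' the observed table's) of presence at `site_a` against presence at
#' `site_b`, typically within one subclade.
#'
#' @param matrix Presence matrix (possibly row-subset to a subclade).
#' @param site_a,site_b Site names.
#' @return List with `table` (2x2), `p`, `degenerate`.
#' @export
cooccurrence_test <- function(matrix, site_a, site_b) {
  stopifnot(site_a %in% colnames(matrix), site_b %in% colnames(matrix))
  a <- matrix[, site_a] != "absent"
  b <- matrix[, site_b] != "absent"
  tab <- table(factor(a, levels = c(TRUE, FALSE)),
               factor(b, levels = c(TRUE, FALSE)),
               dnn = c(site_a, site_b))
  degen <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  p <- if (degen) 1 else fisher.test(tab)$p.value
  list(table = tab, p = p, degenerate = degen)
}

#' Scan an intron-encoded protein for LAGLIDADG motifs and 8th-residue acidity
#'
#' Locates up to two LAGLIDADG-family motifs with a permissive pattern
#' (position 8 unconstrained) and reports whether the 8th residue of each is
#' acidic (D or E) -- the requirement for homing endonuclease activity.  The
#' protein is flagged endonuclease-degenerate when any motif's 8th residue is
#' non-acidic.
#'
#' @param protein Amino-acid sequence (single-letter, character scalar).
#' @param pattern Regular expression for the motif; must match at least 8
#'   residues so position 8 is defined.
#' @return List with `motifs` (data.frame: `start`, `motif`, `residue8`,
#'   `acidic`) and `degenerate` (TRUE when any motif is non-acidic; NA when
#'   no motif was found).
#' @export
laglidadg_acidity <- function(protein,
                              pattern = "[LIVMF].[GAS][LIVMFY][LIVMF][DNE][GASC].[GAST]") {
  protein <- toupper(protein)
  m <- gregexpr(pattern, protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(list(motifs = data.frame(start = integer(), motif = character(),
                                    residue8 = character(), acidic = logical(),
                                    stringsAsFactors = FALSE),
                degenerate = NA))
  starts <- as.integer(m)[seq_len(min(2L, length(m)))]
  lens <- attr(m, "match.length")[seq_len(min(2L, length(m)))]
  motifs <- data.frame(
    start = starts,
    motif = substring(protein, starts, starts + lens - 1L),
    residue8 = substring(protein, starts + 7L, starts + 7L),
    stringsAsFactors = FALSE)
  motifs$acidic <- motifs$residue8 %in% c("D", "E")
  list(motifs = motifs, degenerate = any(!motifs$acidic))
}

#' Check whether an intron ORF is in frame with the upstream exon
#'
#' An intron-encoded protein translated as a fusion with the 5' exon requires
#' the ORF start to sit a multiple of three nucleotides downstream of the
#' exon's reading-frame anchor.
#'
#' @param orf_start 1-based position of the ORF's first nucleotide.
#' @param frame_anchor 1-based position of the first nucleotide of any codon
#'   of the upstream exon's reading frame.
#' @param intron_interval Optional `c(start, end)`; when given, `orf_start`
#'   must lie within it.
#' @return List with `in_frame` (logical) and `offset` (0, 1 or 2 nt).
#' @export
iep_frame_check <- function(orf_start, frame_anchor, intron_interval = NULL) {
  if (!is.null(intron_interval) &&
      (orf_start < intron_interval[1L] || orf_start > intron_interval[2L]))
    stop("ORF start outside the intron interval")
  offset <- (orf_start - frame_anchor) %% 3L
  list(in_frame = offset == 0L, offset = as.integer(offset))
}
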