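# Inter-clade mosaic (recombinant) detection by an informative-site run scan.
# Formalizes the heatmap-inspection criterion: a mosaic genome shows long
# runs of clade-informative sites matching the opposite clade.

#' Scan genotypes for inter-clade mosaic segments
#'
#' Clade-informative sites are sites at which each clade has a consensus
#' allele with within-clade frequency at least `freq_threshold` and the two
#' consensus alleles differ.  For each taxon, maximal runs of at least
#' `min_run` consecutive informative sites matching the opposite clade's
#' consensus are scored against the taxon's background opposite-clade match
#' rate `bg`: the binomial tail probability of an all-opposite run of length
#' `r`, multiplied by the number of possible run start positions (a scan
#' statistic upper bound), then Bonferroni-corrected across all taxa-by-run
#' candidates; runs with adjusted p below `alpha` are reported.
#'
#' @param g Binary genotype matrix (taxa x sites, taxon rownames).
#' @param clades data.frame with columns `type` and `clade` (two clade
#'   labels); taxa flagged `mosaic = TRUE` (if the column exists) keep their
#'   nearest-clade label and are scanned like any other taxon but excluded
#'   from consensus computation.
#' @param freq_threshold Minimum within-clade consensus frequency for a site
#'   to count as clade-informative.
#' @param min_run Minimum run length (informative sites).
#' @param alpha Significance level after Bonferroni correction.
#' @return data.frame of class `mosaic_segments`: `type`, `start`, `end`
#'   (informative-site ordinals), `start_site`, `end_site` (genotype column
#'   indices), `n_sites`, `donor_clade`, `p_raw`, `p_adj`.  The informative
#'   site count is attached as attribute `"n_informative"`.
#' @export
mosaic_scan <- function(g, clades, freq_threshold = 0.8, min_run = 3L,
                        alpha = 0.05) {
  g <- as.matrix(g)
  stopifnot(all(clades$type %in% rownames(g)))
  labs <- unique(clades$clade)
  if (length(labs) != 2L) stop("exactly two clades required")
  excl <- if ("mosaic" %in% colnames(clades)) clades$type[clades$mosaic]
    else character()
  set1 <- setdiff(clades$type[clades$clade == labs[1L]], excl)
  set2 <- setdiff(clades$type[clades$clade == labs[2L]], excl)
  if (length(set1) == 0L || length(set2) == 0L)
    stop("a clade has no non-mosaic members")

  f1 <- colMeans(g[set1, , drop = FALSE])
  f2 <- colMeans(g[set2, , drop = FALSE])
  cons1 <- ifelse(f1 >= 0.5, 1L, 0L)
  cons2 <- ifelse(f2 >= 0.5, 1L, 0L)
  frac1 <- pmax(f1, 1 - f1)
  frac2 <- pmax(f2, 1 - f2)
  informative <- which(cons1 != cons2 & frac1 >= freq_threshold &
                         frac2 >= freq_threshold)
  if (length(informative) < min_run)
    stop("fewer informative sites (", length(informative),
         ") than min_run (", min_run, ")")

  cand <- list()
  for (i in seq_len(nrow(clades))) {
    tx <- clades$type[i]
    own <- if (clades$clade[i] == labs[1L]) cons1 else cons2
    opp <- if (clades$clade[i] == labs[1L]) cons2 else cons1
    gt <- g[tx, informative]
    is_opp <- gt == opp[informative] & gt != own[informative]
    bg <- mean(is_opp)
    if (bg == 0) next
    runs <- rle(as.vector(is_opp))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sel <- which(runs$values & runs$lengths >= min_run)
    for (s in sel) {
      r <- runs$lengths[s]
      cand[[length(cand) + 1L]] <- data.frame(
        type = tx, start = starts[s], end = ends[s],
        start_site = informative[starts[s]], end_site = informative[ends[s]],
        n_sites = r, donor_clade = if (clades$clade[i] == labs[1L]) labs[2L]
          else labs[1L],
        p_raw = min(1, (length(informative) - r + 1L) *
                      pbinom(r - 1L, r, bg, lower.tail = FALSE)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) {
    out <- data.frame(type = character(), start = integer(), end = integer(),
                      start_site = integer(), end_site = integer(),
                      n_sites = integer(), donor_clade = character(),
                      p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, cand)
    out$p_adj <- pmin(1, out$p_raw * nrow(out))
    out <- out[out$p_adj < alpha, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_informative") <- length(informative)
  class(out) <- c("mosaic_segments", "data.frame")
  out
}
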