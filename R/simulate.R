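# Forward simulator of two diverged mitogenome lineages with a linked
# K-region locus, intron presence-absence turnover, clonal replicates and
# optional planted inter-clade recombinants.  Emits full ground truth so the
# analysis modules can be tested by parameter recovery.

#' Canonical intron-site table used by the simulator
#'
#' Eight intron insertion sites (four group I, four group II) at fixed
#' reserved intervals of the simulated mitogenome.  `gain` and `loss` are
#' per-branch Bernoulli probabilities of intron gain and loss.
#'
#' @param genome_length Simulated mitogenome length (bp).
#' @param gain,loss Per-branch gain and loss probabilities.
#' @param width Width of each reserved intron interval (bp).
#' @return data.frame with columns `site`, `group`, `start`, `end`,
#'   `gain`, `loss`.
#' @export
default_intron_sites <- function(genome_length = 20000L, gain = 0.15,
                                 loss = 0.15,
                                 width = max(10L, genome_length %/% 50L)) {
  sites <- c("cox1-I1a", "cox1-I1b", "cox1-I2a", "cox1-I2b",
             "cox1-I3", "cox1-I4", "cob-I1", "cox2-I1")
  groups <- c("II", "I", "I", "I", "I", "II", "II", "II")
  start <- round(seq(0.3, 0.9, length.out = 8L) * genome_length)
  data.frame(site = sites, group = groups, start = start,
             end = start + width - 1L, gain = gain, loss = loss,
             stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults mirror the study conditions this package's analyses assume: a
#' ~20-kb circular mitogenome and a 6,530-bp K-region evolving on the same
#' two-lineage tree, a genome-wide mutation rate of 2.00e-10 substitutions
#' per site per generation with the K-region 1.27-fold faster, a lineage
#' split 3.13e7 generations ago, and four subclades (two per clade) holding
#' 10/4/40/14 sequence types.
#'
#' @param seed Integer seed; every random draw in the simulator derives from it.
#' @param genome_length,k_region_length Sequence lengths (bp).
#' @param mu Mitogenome substitution rate (substitutions/site/generation).
#' @param k_rate_multiplier K-region rate as a multiple of `mu`.
#' @param t_split Divergence time of the two clades (generations, >= 0).
#' @param subclade_splits Named numeric vector: per clade, the time
#'   (generations before present) at which its subclades split; must not
#'   exceed `t_split`.
#' @param n_types_per_subclade Named integer vector of sequence-type counts;
#'   names are `<CLADE>-<SUBCLADE>` labels and clades are inferred from the
#'   prefix before `-`.
#' @param clonal_copies Identical copies emitted per type (clonal isolates).
#' @param tip_radiation_frac Tips radiate star-like from their subclade
#'   ancestor at this fraction of the subclade split time; a scalar, or a
#'   named vector per subclade.  The default gives subclades named `*-D`
#'   ("diverse") a fraction of 0.6 and all others 0.1, reproducing the
#'   low-diversity ("similar") versus high-diversity ("diverse") subclade
#'   contrast the analyses expect.
#' @param intron_sites data.frame as produced by [default_intron_sites()].
#' @param recombination_plan List of lists with fields `recipient` (type id),
#'   `donor_clade`, `start`, `end` (1-based inclusive mitogenome segment).
#' @param indel_rate Reserved; substitutions-only baseline uses 0.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 20000L,
                              k_region_length = 6530L,
                              mu = 2.00e-10,
                              k_rate_multiplier = 1.27,
                              t_split = 3.13e7,
                              subclade_splits = c(REF = t_split / 10, NONREF = t_split / 10),
                              n_types_per_subclade = c("REF-A" = 10L, "REF-B" = 4L,
                                                       "NONREF-S" = 40L, "NONREF-D" = 14L),
                              clonal_copies = 1L,
                              tip_radiation_frac = NULL,
                              intron_sites = default_intron_sites(genome_length),
                              recombination_plan = list(),
                              indel_rate = 0) {
  if (t_split < 0) stop("t_split must be >= 0")
  if (length(n_types_per_subclade) == 0L || any(n_types_per_subclade < 1L))
    stop("every subclade must hold at least one type")
  clades <- unique(sub("-.*$", "", names(n_types_per_subclade)))
  if (length(clades) != 2L) stop("exactly two clades are required")
  if (!all(clades %in% names(subclade_splits)))
    stop("subclade_splits must name both clades")
  if (any(subclade_splits[clades] > t_split))
    stop("subclade split times must not exceed t_split")
  if (any(subclade_splits < 0)) stop("subclade split times must be >= 0")
  subclades <- names(n_types_per_subclade)
  if (is.null(tip_radiation_frac))
    tip_radiation_frac <- ifelse(grepl("-D$", subclades), 0.6, 0.1)
  if (length(tip_radiation_frac) == 1L)
    tip_radiation_frac <- rep(tip_radiation_frac, length(subclades))
  if (is.null(names(tip_radiation_frac)))
    names(tip_radiation_frac) <- subclades
  if (!all(subclades %in% names(tip_radiation_frac)))
    stop("tip_radiation_frac must name every subclade")
  tip_radiation_frac <- tip_radiation_frac[subclades]
  stopifnot(all(tip_radiation_frac >= 0), all(tip_radiation_frac <= 1),
            all(intron_sites$gain >= 0 & intron_sites$gain <= 1),
            all(intron_sites$loss >= 0 & intron_sites$loss <= 1),
            all(intron_sites$start >= 1),
            all(intron_sites$end <= genome_length))
  for (rc in recombination_plan) {
    stopifnot(all(c("recipient", "donor_clade", "start", "end") %in% names(rc)))
    if (rc$start < 1 || rc$end > genome_length || rc$start > rc$end)
      stop("recombination segment outside [1, genome_length]")
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 k_region_length = as.integer(k_region_length), mu = mu,
                 k_rate_multiplier = k_rate_multiplier, t_split = t_split,
                 subclade_splits = subclade_splits,
                 n_types_per_subclade = n_types_per_subclade,
                 clonal_copies = as.integer(clonal_copies),
                 tip_radiation_frac = tip_radiation_frac,
                 intron_sites = intron_sites,
                 recombination_plan = recombination_plan,
                 indel_rate = indel_rate, clades = clades),
            class = "sim_config")
}

# place a Poisson number of substitutions (mean mu*L*t) at uniform sites,
# Jukes-Cantor choice among the three alternative bases; multiple hits allowed
mutate_chars <- function(x, t, mu) {
  L <- length(x)
  k <- rpois(1L, mu * L * t)
  if (k == 0L) return(x)
  pos <- sample.int(L, k, replace = TRUE)
  for (i in seq_len(k)) {
    p <- pos[i]
    x[p] <- sample(setdiff(DNA_BASES, x[p]), 1L)
  }
  x
}

# evolve intron presence along one branch: per-site Bernoulli gain/loss
evolve_introns <- function(state, sites) {
  u <- runif(nrow(sites))
  gained <- !state & u < sites$gain
  lost <- state & u < sites$loss
  state[gained] <- TRUE
  state[lost] <- FALSE
  state
}

#' Generate a simulated population
#'
#' Simulates mitogenome and K-region sequences down a two-clade tree
#' (clade split at `t_split`, star-like subclades, star-like tip radiation),
#' evolves intron presence-absence by per-branch Bernoulli gain/loss at the
#' eight canonical sites, then applies any planted inter-clade recombination
#' by overwriting the recipient's segment with the donor-clade consensus.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()] object.
#' @return Object of class `sim_dataset`: list with `mitogenomes` and
#'   `k_regions` (named character vectors, one entry per clonal copy),
#'   `annotations` (intron intervals per type), `truth_clades`,
#'   `truth_recombinants`, `truth_intron_matrix`, `truth_t_split`, `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  Lk <- config$k_region_length
  mu <- config$mu
  muk <- config$mu * config$k_rate_multiplier
  sites <- config$intron_sites

  root_mt <- sample(DNA_BASES, L, replace = TRUE)
  root_k <- sample(DNA_BASES, Lk, replace = TRUE)
  root_introns <- runif(nrow(sites)) < 0.5

  subclades <- names(config$n_types_per_subclade)
  sub_clade <- sub("-.*$", "", subclades)
  n_total <- sum(config$n_types_per_subclade)
  type_ids <- sprintf("T%02d", seq_len(n_total))

  mito <- vector("list", n_total)
  kreg <- vector("list", n_total)
  intron_state <- matrix(FALSE, n_total, nrow(sites),
                         dimnames = list(type_ids, sites$site))
  truth <- data.frame(type = type_ids, clade = NA_character_,
                      subclade = NA_character_, stringsAsFactors = FALSE)

  # clade ancestors
  clade_state <- list()
  for (cl in config$clades) {
    t_sub <- config$subclade_splits[[cl]]
    b <- config$t_split - t_sub
    clade_state[[cl]] <- list(
      mt = mutate_chars(root_mt, b, mu),
      k = mutate_chars(root_k, b, muk),
      introns = evolve_introns(root_introns, sites))
  }

  idx <- 0L
  for (si in seq_along(subclades)) {
    cl <- sub_clade[si]
    t_sub <- config$subclade_splits[[cl]]
    t_tip <- config$tip_radiation_frac[[subclades[si]]] * t_sub
    anc <- clade_state[[cl]]
    sub_anc <- list(
      mt = mutate_chars(anc$mt, t_sub - t_tip, mu),
      k = mutate_chars(anc$k, t_sub - t_tip, muk),
      introns = evolve_introns(anc$introns, sites))
    for (j in seq_len(config$n_types_per_subclade[[si]])) {
      idx <- idx + 1L
      mito[[idx]] <- mutate_chars(sub_anc$mt, t_tip, mu)
      kreg[[idx]] <- mutate_chars(sub_anc$k, t_tip, muk)
      intron_state[idx, ] <- evolve_introns(sub_anc$introns, sites)
      truth$clade[idx] <- cl
      truth$subclade[idx] <- subclades[si]
    }
  }

  # planted inter-clade recombination: recipient segment <- donor consensus
  recomb <- list()
  for (rc in config$recombination_plan) {
    ri <- match(rc$recipient, type_ids)
    if (is.na(ri)) stop("recombination recipient not a type id: ", rc$recipient)
    donors <- which(truth$clade == rc$donor_clade)
    if (length(donors) == 0L) stop("no donor types in clade ", rc$donor_clade)
    seg <- rc$start:rc$end
    cons <- apply(do.call(rbind, lapply(mito[donors], `[`, seg)), 2L,
                  function(col) names(sort(table(col), decreasing = TRUE))[1L])
    mito[[ri]][seg] <- cons
    recomb[[length(recomb) + 1L]] <-
      list(type = rc$recipient, donor_clade = rc$donor_clade,
           start = rc$start, end = rc$end)
  }

  # b / b' labelling at the cox1-I1b site: the resident group I intron carries
  # the clade-specific variant (b in REF-side clade, b' otherwise)
  i1b <- match("cox1-I1b", sites$site)
  states <- matrix("absent", n_total, nrow(sites),
                   dimnames = list(type_ids, sites$site))
  states[intron_state] <- "present"
  if (!is.na(i1b)) {
    pres <- intron_state[, i1b]
    lab <- ifelse(truth$clade == config$clades[1L], "present:b", "present:b'")
    states[pres, i1b] <- lab[pres]
  }

  # clonal copies
  copies <- config$clonal_copies
  if (copies > 1L) {
    ids <- as.vector(t(outer(type_ids, seq_len(copies), sprintf,
                             fmt = "%s_c%d")))
    rep_idx <- rep(seq_len(n_total), each = copies)
  } else {
    ids <- type_ids
    rep_idx <- seq_len(n_total)
  }
  mito_v <- setNames(vapply(mito[rep_idx], chars_seq, character(1L)), ids)
  k_v <- setNames(vapply(kreg[rep_idx], chars_seq, character(1L)), ids)

  ann <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    pres <- which(intron_state[i, ])
    if (length(pres) == 0L) return(NULL)
    data.frame(type = type_ids[i], feature = sites$site[pres],
               start = sites$start[pres], end = sites$end[pres],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann))
    ann <- data.frame(type = character(), feature = character(),
                      start = integer(), end = integer())

  structure(list(mitogenomes = mito_v, k_regions = k_v,
                 annotations = ann, truth_clades = truth,
                 truth_recombinants = recomb,
                 truth_intron_matrix = states,
                 truth_t_split = config$t_split, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated two-lineage dataset\n")
  cat("  types:", nrow(x$truth_clades),
      " (", length(x$mitogenomes), "sequences incl. clonal copies )\n")
  cat("  mitogenome:", x$config$genome_length, "bp;  K-region:",
      x$config$k_region_length, "bp\n")
  cat("  clade split:", format(x$truth_t_split, big.mark = ","),
      "generations;  planted recombinants:", length(x$truth_recombinants), "\n")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits multi-FASTA mitogenomes and K-regions, a TSV intron annotation table
#' (1-based inclusive intervals) and TSV truth tables.  Everything round-trips
#' through [read_dataset()].
#'
#' @param dataset A `sim_dataset`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written file paths (the manifest).
#' @export
emit_files <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  manifest <- c(mitogenomes = f("mitogenomes.fasta"),
                k_regions = f("k_regions.fasta"),
                annotations = f("introns.tsv"),
                truth_clades = f("truth_clades.tsv"),
                truth_intron_matrix = f("truth_intron_matrix.tsv"),
                truth_recombinants = f("truth_recombinants.tsv"),
                truth_scalars = f("truth_scalars.tsv"))
  write_fasta(dataset$mitogenomes, manifest[["mitogenomes"]])
  write_fasta(dataset$k_regions, manifest[["k_regions"]])
  write.table(dataset$annotations, manifest[["annotations"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth_clades, manifest[["truth_clades"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  im <- data.frame(type = rownames(dataset$truth_intron_matrix),
                   dataset$truth_intron_matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(im, manifest[["truth_intron_matrix"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  rec <- if (length(dataset$truth_recombinants) > 0L)
    do.call(rbind, lapply(dataset$truth_recombinants, as.data.frame))
  else data.frame(type = character(), donor_clade = character(),
                  start = integer(), end = integer())
  write.table(rec, manifest[["truth_recombinants"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(key = "t_split", value = dataset$truth_t_split),
              manifest[["truth_scalars"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest
}

#' Read back a dataset written by [emit_files()]
#'
#' @param dir Directory holding the emitted files.
#' @return List with the same sequence, annotation and truth components as
#'   the in-memory `sim_dataset` (minus the configuration object).
#' @export
read_dataset <- function(dir) {
  f <- function(x) file.path(dir, x)
  im <- read.delim(f("truth_intron_matrix.tsv"), check.names = FALSE,
                   quote = "", stringsAsFactors = FALSE)
  m <- as.matrix(im[, -1L, drop = FALSE])
  rownames(m) <- im$type
  rec_df <- read.delim(f("truth_recombinants.tsv"), quote = "", stringsAsFactors = FALSE)
  rec <- lapply(seq_len(nrow(rec_df)), function(i) as.list(rec_df[i, ]))
  scalars <- read.delim(f("truth_scalars.tsv"), quote = "", stringsAsFactors = FALSE)
  list(mitogenomes = read_fasta(f("mitogenomes.fasta")),
       k_regions = read_fasta(f("k_regions.fasta")),
       annotations = read.delim(f("introns.tsv"), quote = "", stringsAsFactors = FALSE),
       truth_clades = read.delim(f("truth_clades.tsv"), quote = "", stringsAsFactors = FALSE),
       truth_intron_matrix = m,
       truth_recombinants = rec,
       truth_t_split = as.numeric(scalars$value[scalars$key == "t_split"]))
}
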