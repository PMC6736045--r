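test_that("simulation is deterministic given the seed", {
  cfg <- quick_config(7, genome_length = 2000, k_region_length = 500,
                      n = c("REF-A" = 2L, "NONREF-S" = 2L))
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$mitogenomes, b$mitogenomes)
  expect_identical(a$k_regions, b$k_regions)
  expect_identical(a$truth_intron_matrix, b$truth_intron_matrix)
})

test_that("zero divergence time yields identical sequences across clades", {
  cfg <- simulation_config(seed = 3, genome_length = 1500, k_region_length = 400,
                           t_split = 0, subclade_splits = c(REF = 0, NONREF = 0),
                           n_types_per_subclade = c("REF-A" = 2L, "NONREF-S" = 2L))
  ds <- generate_population(cfg)
  expect_length(unique(ds$mitogenomes), 1L)
  expect_length(unique(ds$k_regions), 1L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(t_split = -1), "t_split")
  expect_error(simulation_config(n_types_per_subclade = integer()), "subclade")
  expect_error(simulation_config(subclade_splits = c(REF = 1e9, NONREF = 1e6)),
               "exceed")
  expect_error(
    simulation_config(recombination_plan = list(
      list(recipient = "T01", donor_clade = "NONREF", start = 0, end = 10))),
    "segment")
})

test_that("pairwise K-region differences match the closed-form expectation", {
  # two lineages split T generations; expected differing sites under the
  # substitution model: L * 3/4 * (1 - exp(-4/3 * 2*T*mu_k))
  mu_k <- 2e-10 * 1.27
  T_split <- 3.13e7
  L <- 6530
  d <- 2 * T_split * mu_k
  expected <- L * 0.75 * (1 - exp(-4 / 3 * d))
  set.seed(21)
  n_rep <- 100
  obs <- vapply(sample.int(1e6, n_rep), function(s) {
    cfg <- simulation_config(seed = s, genome_length = 400,
                             k_region_length = L, t_split = T_split,
                             subclade_splits = c(REF = 0, NONREF = 0),
                             n_types_per_subclade = c("REF-A" = 1L, "NONREF-S" = 1L))
    ds <- generate_population(cfg)
    a <- strsplit(ds$k_regions[[1]], "")[[1]]
    b <- strsplit(ds$k_regions[[2]], "")[[1]]
    sum(a != b)
  }, numeric(1))
  # mean of n_rep Poisson-like counts: 3 standard errors
  expect_lt(abs(mean(obs) - expected), 3 * sd(obs) / sqrt(n_rep))
})

test_that("between-clade divergence grows linearly with split time (clock property)", {
  mu <- 2e-10
  ts <- c(1e6, 5e6, 1e7, 2.5e7, 5e7)
  set.seed(22)
  mean_d <- vapply(ts, function(tt) {
    mean(vapply(sample.int(1e6, 20), function(s) {
      cfg <- simulation_config(seed = s, genome_length = 300,
                               k_region_length = 5000, t_split = tt,
                               subclade_splits = c(REF = 0, NONREF = 0),
                               n_types_per_subclade = c("REF-A" = 1L, "NONREF-S" = 1L))
      ds <- generate_population(cfg)
      a <- strsplit(ds$k_regions[[1]], "")[[1]]
      b <- strsplit(ds$k_regions[[2]], "")[[1]]
      mean(a != b)
    }, numeric(1)))
  }, numeric(1))
  mu_k <- mu * 1.27
  slope <- coef(lm(mean_d ~ ts))[["ts"]]
  expect_lt(abs(slope - 2 * mu_k) / (2 * mu_k), 0.10)
})

test_that("K-region to mitogenome divergence ratio approaches the rate multiplier", {
  set.seed(23)
  ratios <- vapply(sample.int(1e6, 15), function(s) {
    cfg <- simulation_config(seed = s, genome_length = 50000,
                             k_region_length = 50000, t_split = 3.13e7,
                             subclade_splits = c(REF = 0, NONREF = 0),
                             n_types_per_subclade = c("REF-A" = 1L, "NONREF-S" = 1L),
                             intron_sites = default_intron_sites(50000, gain = 0, loss = 0))
    ds <- generate_population(cfg)
    pd <- function(x) {
      a <- strsplit(x[[1]], "")[[1]]; b <- strsplit(x[[2]], "")[[1]]
      mean(a != b)
    }
    pd(ds$k_regions) / pd(ds$mitogenomes)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1.27) / 1.27, 0.15)
})

test_that("planted recombinant segments equal the donor-clade consensus", {
  cfg <- quick_config(31, genome_length = 4000, k_region_length = 300,
                      recombination_plan = list(
                        list(recipient = "T02", donor_clade = "NONREF",
                             start = 1001, end = 2000)))
  ds <- generate_population(cfg)
  seg <- function(x) substr(x, 1001, 2000)
  donors <- ds$truth_clades$type[ds$truth_clades$clade == "NONREF"]
  cons <- apply(do.call(rbind, lapply(ds$mitogenomes[donors],
                                      function(s) strsplit(seg(s), "")[[1]])),
                2, function(col) names(sort(table(col), decreasing = TRUE))[1])
  expect_identical(seg(ds$mitogenomes[["T02"]]), paste(cons, collapse = ""))
  expect_identical(ds$truth_recombinants[[1]]$type, "T02")
})

test_that("emitted files round-trip losslessly and count records correctly", {
  cfg <- quick_config(41, genome_length = 1500, k_region_length = 300)
  ds <- generate_population(cfg)
  dir <- withr::local_tempdir()
  manifest <- emit_files(ds, dir)
  expect_true(all(file.exists(manifest)))
  back <- read_dataset(dir)
  expect_identical(back$mitogenomes, ds$mitogenomes)
  expect_identical(back$k_regions, ds$k_regions)
  expect_identical(back$truth_intron_matrix, ds$truth_intron_matrix)
  expect_equal(back$truth_clades, ds$truth_clades)
  expect_identical(back$truth_t_split, ds$truth_t_split)
  expect_length(back$mitogenomes, sum(cfg$n_types_per_subclade))
})

test_that("clonal copies are byte-identical replicates of their type", {
  cfg <- quick_config(51, genome_length = 1000, k_region_length = 200,
                      n = c("REF-A" = 2L, "NONREF-S" = 2L), clonal_copies = 3L)
  ds <- generate_population(cfg)
  expect_length(ds$mitogenomes, 12L)
  expect_identical(ds$mitogenomes[["T01_c1"]], ds$mitogenomes[["T01_c2"]])
  expect_identical(ds$k_regions[["T03_c1"]], ds$k_regions[["T03_c3"]])
})
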