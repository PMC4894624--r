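test_that("gene dropping is Mendelian-consistent with no error channel", {
  for (sc in c("scen1_family_specific", "scen3_compound_het", "null")) {
    study <- simulate_study(sim_config(scenario = sc, n_variants = 40,
                                       n_families = 2, seed = 61,
                                       emit_ibd = FALSE))
    expect_equal(nrow(mendelian_audit(study$pedigree, study$genotypes)), 0L,
                 label = paste("Mendelian audit under", sc))
  }
})

test_that("founder allele frequencies match the spectrum (binomial check)", {
  maf0 <- 0.3
  cfg <- sim_config(scenario = "null", pedigree_template = "nuclear",
                    n_families = 2500, n_variants = 2, region_length_cm = 1,
                    frequency_spectrum = function(k) rep(maf0, k),
                    seed = 62, emit_ibd = FALSE)
  study <- simulate_study(cfg)
  founders <- is.na(study$pedigree$father)
  keys <- paste(study$pedigree$fid, study$pedigree$iid, sep = ":")
  g <- study$genotypes[keys[founders], 1]
  n_alleles <- 2 * length(g)              # 10,000 founder alleles
  f_hat <- sum(g) / n_alleles
  se <- sqrt(maf0 * (1 - maf0) / n_alleles)
  expect_lt(abs(f_hat - maf0), 3 * se)
})

test_that("sib-pair true IBD states occur at (1/4, 1/2, 1/4)", {
  cfg <- sim_config(scenario = "null", pedigree_template = "nuclear",
                    n_families = 5000, n_variants = 2, region_length_cm = 1,
                    grid_cm = 1, seed = 63)
  study <- simulate_study(cfg)
  sib <- study$ibd[study$ibd$id1 == "3" & study$ibd$id2 == "4" &
                     study$ibd$position == 0, ]
  n <- nrow(sib)
  expect_equal(n, 5000L)
  props <- c(mean(sib$p0 == 1), mean(sib$p1 == 1), mean(sib$p2 == 1))
  target <- c(0.25, 0.5, 0.25)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(props - target) < 3 * se))

  # sib-pair exceedance rate of P(IBD != 0) at threshold 0.5 approaches 3/4
  exceed <- mean(1 - sib$p0 > 0.5)
  expect_lt(abs(exceed - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("realized recombination fraction converges to Haldane's theta", {
  # two markers 20 cM apart; count recombinant meioses via founder labels
  cfg <- sim_config(scenario = "null", pedigree_template = "nuclear",
                    n_families = 2000, n_variants = 2, region_length_cm = 20,
                    frequency_spectrum = function(k) rep(0.5, k),
                    seed = 64, emit_ibd = FALSE)
  set.seed(64)
  # reconstruct the realized gap from the generated variant positions
  study <- simulate_study(cfg)
  gap <- diff(study$variants$cm)
  theta <- haldane_theta(gap)
  recomb <- 0L; meioses <- 0L
  for (fam in study$truth$founder_labels) {
    for (i in 3:4) {               # the two children, two gametes each
      recomb <- recomb + (fam$L1[i, 1] != fam$L1[i, 2]) +
        (fam$L2[i, 1] != fam$L2[i, 2])
      meioses <- meioses + 2L
    }
  }
  rate <- recomb / meioses
  se <- sqrt(theta * (1 - theta) / meioses)
  expect_lt(abs(rate - theta), 3 * se)
})

test_that("scenario injections produce their designed causal structure", {
  # scen1: the causal variant segregates with affection under dominance
  s1 <- simulate_study(sim_config("scen1_family_specific", n_variants = 50,
                                  seed = 65, emit_ibd = FALSE))
  cv <- s1$truth$causal_variants
  dose <- s1$genotypes[, cv]
  aff <- s1$pedigree$affection == "affected"
  expect_true(all(aff == (dose >= 1)))     # full penetrance, no phenocopy
  expect_gte(sum(aff), 2L)
  expect_gte(nrow(eligible_pairs(s1$pedigree)), 1L)

  # scen2: each case carries its own causal variant, controls carry none
  s2 <- simulate_study(sim_config("scen2_gene_multivariant", n_cases = 10,
                                  n_variants = 200, variants_per_gene = 20,
                                  seed = 66, emit_ibd = FALSE))
  expect_equal(length(unique(s2$truth$causal_variants)), 10L)
  expect_equal(length(s2$truth$causal_gene), 1L)
  cases <- s2$pedigree$affection == "affected"
  for (k in seq_along(s2$truth$causal_variants)) {
    carrier <- which(s2$genotypes[, s2$truth$causal_variants[k]] >= 1)
    expect_true(which(cases)[k] %in% carrier)
  }

  # scen3: affected children are compound het in trans at the two causals
  s3 <- simulate_study(sim_config("scen3_compound_het", seed = 67,
                                  emit_ibd = FALSE))
  cvs <- s3$truth$causal_variants
  expect_equal(length(cvs), 2L)
  aff_children <- s3$pedigree$affection == "affected" &
    !is.na(s3$pedigree$father)
  expect_gte(sum(aff_children), 1L)
  expect_true(all(s3$genotypes[aff_children, cvs] == 1L))
})

test_that("the error channel perturbs genotypes at the configured rates", {
  set.seed(68)
  clean <- simulate_study(sim_config("null", n_variants = 200,
                                     pedigree_template = "three_generation_12",
                                     n_families = 5, seed = 69,
                                     frequency_spectrum = function(k) rep(0.4, k),
                                     emit_ibd = FALSE))
  noisy <- simulate_study(sim_config("null", n_variants = 200,
                                     pedigree_template = "three_generation_12",
                                     n_families = 5, seed = 69,
                                     frequency_spectrum = function(k) rep(0.4, k),
                                     error_model = list(missing_rate = 0.1),
                                     emit_ibd = FALSE))
  # same seed: genotype draws identical before the channel
  miss <- mean(is.na(noisy$genotypes))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / length(noisy$genotypes)))
  expect_equal(mean(is.na(clean$genotypes)), 0)

  het_clean <- sum(clean$genotypes == 1L)
  miscalled <- simulate_study(sim_config("null", n_variants = 200,
                                         pedigree_template = "three_generation_12",
                                         n_families = 5, seed = 69,
                                         frequency_spectrum = function(k) rep(0.4, k),
                                         error_model = list(miscall_het_to_hom = 0.2),
                                         emit_ibd = FALSE))
  het_noisy <- sum(miscalled$genotypes == 1L)
  lost <- (het_clean - het_noisy) / het_clean
  expect_lt(abs(lost - 0.2), 3 * sqrt(0.2 * 0.8 / het_clean))
})

test_that("simulation output is reproducible and writable", {
  a <- simulate_study(sim_config("scen1_family_specific", n_variants = 30,
                                 seed = 70, emit_ibd = FALSE))
  b <- simulate_study(sim_config("scen1_family_specific", n_variants = 30,
                                 seed = 70, emit_ibd = FALSE))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$causal_variants, b$truth$causal_variants)

  dir <- withr::local_tempdir()
  paths <- write_study(a, dir)
  expect_true(all(file.exists(paths)))
  back <- read_ped_map(paths[["ped"]], paths[["map"]])
  expect_equal(nrow(back$pedigree), nrow(a$pedigree))
  ft <- read_frequency_table(paths[["freq"]])
  expect_equal(nrow(ft), 30L)
})
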