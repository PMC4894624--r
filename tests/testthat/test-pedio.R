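test_that("PED/MAP parsing recovers pedigree, genotypes and variants", {
  fx <- write_trio_fixture()
  res <- read_ped_map(fx$ped, fx$map)

  expect_s3_class(res$pedigree, "pedigree")
  expect_equal(nrow(res$pedigree), 4L)
  expect_equal(res$pedigree$affection,
               c("unaffected", "unaffected", "affected", "unaffected"))
  expect_equal(dim(res$genotypes), c(4L, 2L))

  # v1: alleles A (5 copies) / C (2 copies, provisional minor), v2: G/T
  expect_equal(res$variants$allele_minor, c("C", "T"))
  expect_equal(unname(res$genotypes[, "v1"]), c(0L, 1L, 1L, 0L))
  expect_equal(unname(res$genotypes[, "v2"]), c(0L, 0L, 1L, 0L))
})

test_that("missing genotypes and malformed PED files are handled", {
  dir <- withr::local_tempdir()
  writeLines(c("F1 1 0 0 1 1 0 0", "F1 2 0 0 2 2 A C"),
             file.path(dir, "m.ped"))
  writeLines("1\tv1\t0\t100", file.path(dir, "m.map"))
  res <- read_ped_map(file.path(dir, "m.ped"), file.path(dir, "m.map"))
  expect_true(is.na(res$genotypes["F1:1", "v1"]))
  expect_equal(res$genotypes["F1:2", "v1"], 1L)

  # inconsistent column count names file and line
  writeLines(c("F1 1 0 0 1 1 A A", "F1 2 0 0 2 2 A"),
             file.path(dir, "bad.ped"))
  expect_error(read_ped_map(file.path(dir, "bad.ped"), file.path(dir, "m.map")),
               "line 2")

  # unknown parent reference names the child and the parent id
  writeLines("F1 3 9 2 1 2 A A", file.path(dir, "orphan.ped"))
  expect_error(read_ped_map(file.path(dir, "orphan.ped"), file.path(dir, "m.map")),
               "father")

  # duplicate individual id
  writeLines(c("F1 1 0 0 1 1 A A", "F1 1 0 0 1 1 A A"),
             file.path(dir, "dup.ped"))
  expect_error(read_ped_map(file.path(dir, "dup.ped"), file.path(dir, "m.map")),
               "duplicate")

  # half-specified parent rejected
  expect_error(pedigree(fid = "F1", iid = c("1", "2"),
                        father = c(NA, "1"), mother = c(NA, NA)),
               "one parent")
})

test_that("PED/MAP round-trip reproduces the genotype matrix", {
  study <- simulate_study(sim_config(scenario = "null",
                                     pedigree_template = "three_generation_12",
                                     n_variants = 30, seed = 11,
                                     emit_ibd = FALSE))
  dir <- withr::local_tempdir()
  write_ped_map(study$pedigree, study$genotypes, study$variants,
                file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  back <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))

  expect_equal(back$pedigree$iid, study$pedigree$iid)
  expect_equal(back$pedigree$affection, study$pedigree$affection)
  expect_equal(back$variants$bp, study$variants$bp)
  # genotypes identical up to allele-label orientation per variant
  for (v in study$variants$variant_id) {
    a <- study$genotypes[, v]
    b <- back$genotypes[rownames(study$genotypes), v]
    expect_true(identical(unname(a), unname(b)) ||
                  identical(unname(a), unname(2L - b)),
                label = paste("round-trip orientation at", v))
  }

  # degenerate: no variants at all
  writeLines(character(), file.path(dir, "e.map"))
  write_ped_map(study$pedigree, study$genotypes[, 0, drop = FALSE],
                study$variants[0, ], file.path(dir, "e.ped"),
                file.path(dir, "e.map"))
  e <- read_ped_map(file.path(dir, "e.ped"), file.path(dir, "e.map"))
  expect_equal(ncol(e$genotypes), 0L)
  expect_equal(nrow(e$pedigree), 12L)
})

test_that("Merlin-style IBD tables are validated on read", {
  dir <- withr::local_tempdir()
  writeLines(c("FAMILY ID1 ID2 POSITION P0 P1 P2",
               "F1 201 202 10.0 0.25 0.50 0.25"),
             file.path(dir, "ok.ibd"))
  tab <- read_ibd_table(file.path(dir, "ok.ibd"))
  expect_equal(nrow(tab), 1L)
  expect_equal(1 - tab$p0, 0.75)

  writeLines("F1 201 202 10.0 0.25 0.50 0.15", file.path(dir, "bad.ibd"))
  expect_error(read_ibd_table(file.path(dir, "bad.ibd")), "line 1")

  # simulator's indicator records round-trip through the reader
  study <- simulate_study(sim_config(scenario = "null", n_variants = 5,
                                     region_length_cm = 10, seed = 2))
  p <- file.path(dir, "sim.ibd")
  write_ibd_table(study$ibd, p)
  back <- read_ibd_table(p)
  expect_equal(back$p0, study$ibd$p0)
  expect_equal(back$position, study$ibd$position)
})

test_that("kinship matches closed forms and a gene-dropping oracle", {
  ped <- ped_template("three_generation_12")
  # closed forms
  expect_equal(kinship(ped, "1", "3"), 0.25)    # parent-offspring
  expect_equal(kinship(ped, "8", "9"), 0.25)    # full sibs
  expect_equal(kinship(ped, "8", "11"), 0.0625) # first cousins
  expect_equal(kinship(ped, "2", "4"), 0)       # married-in founders
  expect_equal(kinship(ped, "1", "8"), 0.125)   # grandparent

  # symmetry
  K <- kinship_matrix(ped)
  expect_equal(K, t(K))

  # Monte-Carlo gene-dropping oracle within 3 binomial SE
  for (pair in list(c("8", "11"), c("4", "8"), c("1", "12"))) {
    est <- kinship_mc_oracle(ped, pair[1], pair[2], n_rep = 20000)
    truth <- kinship(ped, pair[1], pair[2])
    se <- sqrt(truth * (1 - truth) / 20000)
    expect_lt(abs(est - truth), 3 * se + 1e-12,
              label = paste("kinship MC oracle for", pair[1], pair[2]))
  }
})

test_that("pair classification distinguishes parent-offspring, blood, unrelated", {
  ped <- ped_template("three_generation_12")
  expect_equal(classify_pair(ped, "1", "3"), "parent_offspring")
  expect_equal(classify_pair(ped, "8", "9"), "other_blood_relative")
  expect_equal(classify_pair(ped, "1", "11"), "other_blood_relative")
  expect_equal(classify_pair(ped, "2", "4"), "unrelated")
  expect_equal(classify_pair(ped, "4", "6"), "unrelated")

  # never parent_offspring at kinship zero: exhaustive over all pairs
  ids <- ped$iid
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1, length(ids))) {
      if (kinship(ped, ids[i], ids[j]) == 0)
        expect_false(classify_pair(ped, ids[i], ids[j]) == "parent_offspring")
    }
  }
})

test_that("bit size follows 2*non-founders - founders and is additive", {
  nuc <- ped_template("nuclear")
  expect_equal(bit_size(nuc), 2L)                    # 2*2 - 2
  big <- ped_template("three_generation_12")
  expect_equal(bit_size(big), 12L)                   # 2*8 - 4
  allf <- pedigree(fid = "F9", iid = c("a", "b", "c"))
  expect_equal(bit_size(allf), -3L)                  # degenerate, documented

  # additivity over disjoint sub-pedigrees
  nuc2 <- ped_template("nuclear", fid = "F2")
  both <- validate_pedigree(rbind(nuc, nuc2))
  expect_equal(bit_size(both), bit_size(nuc) + bit_size(nuc2))
})
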