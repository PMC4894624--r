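# trio helper: affected child het at both variants, one inherited from
# each parent; genotypes given as dosage rows (father, mother, child)
trio_fixture <- function(gf, gm, gc, sib = NULL,
                         sib_aff = "unaffected",
                         parent_aff = c("unaffected", "unaffected")) {
  n <- if (is.null(sib)) 3L else 4L
  ped <- pedigree(fid = "F1", iid = as.character(1:n),
                  father = c(NA, NA, rep("1", n - 2L)),
                  mother = c(NA, NA, rep("2", n - 2L)),
                  sex = c("male", "female", rep("unknown", n - 2L)),
                  affection = c(parent_aff, "affected",
                                if (!is.null(sib)) sib_aff))
  G <- rbind(gf, gm, gc, sib)
  rownames(G) <- paste0("F1:", 1:n)
  colnames(G) <- paste0("v", seq_len(ncol(G)))
  storage.mode(G) <- "integer"
  list(ped = ped, geno = G)
}

two_variant_gene <- data.frame(variant_id = c("v1", "v2"), gene_id = "G1",
                               stringsAsFactors = FALSE)

test_that("a trans-configured trio passes all five rules", {
  # v1 from father (Dd), v2 from mother (Dd); child het at both
  fx <- trio_fixture(gf = c(1L, 0L), gm = c(0L, 1L), gc = c(1L, 1L))
  res <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                           two_variant_gene, comphet_config(1))
  expect_true(all(res$variants$pass123))
  expect_true(res$genes$rule4)
  expect_true(res$genes$rule5)
  expect_true(res$genes$pass)
})

test_that("both variants from one parent fail the biparental rule", {
  fx <- trio_fixture(gf = c(1L, 1L), gm = c(0L, 0L), gc = c(1L, 1L))
  res <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                           two_variant_gene, comphet_config(1))
  expect_true(all(res$variants$pass123))
  expect_true(res$genes$rule4)
  expect_false(res$genes$rule5)
  expect_false(res$genes$pass)
})

test_that("a homozygous-minor unaffected sibling fails rule 2 at proportion 1", {
  fx <- trio_fixture(gf = c(1L, 0L), gm = c(1L, 1L), gc = c(1L, 1L),
                     sib = c(2L, 0L))
  res <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                           two_variant_gene, comphet_config(1))
  v1 <- res$variants[res$variants$variant_id == "v1", ]
  expect_false(v1$r2)
  expect_false(res$genes$pass)   # only v2 can pass rules 1-3
})

test_that("rule 3 rejects variants heterozygous in both parents", {
  # both parents het at v1: phase-ambiguous, child could carry both copies
  fx <- trio_fixture(gf = c(1L, 0L), gm = c(1L, 1L), gc = c(1L, 1L))
  res <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                           two_variant_gene, comphet_config(1))
  v1 <- res$variants[res$variants$variant_id == "v1", ]
  expect_false(v1$r3)
})

test_that("the affected-parent exception disables rule 5 under auto", {
  # both variants from the affected father; under auto, rule 5 is skipped
  fx <- trio_fixture(gf = c(1L, 1L), gm = c(0L, 0L), gc = c(1L, 1L),
                     parent_aff = c("affected", "unaffected"))
  # father affected but not het at both... he is het at both variants here,
  # so rule 1 (het in all affected) still holds for both variants
  res_auto <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                                two_variant_gene, comphet_config(1, "auto"))
  expect_false(res_auto$genes$rule5_applied)
  expect_true(res_auto$genes$pass)
  res_always <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                                  two_variant_gene, comphet_config(1, "always"))
  expect_false(res_always$genes$pass)
})

test_that("the proportion relaxation tolerates one discordant genotype", {
  # 20 affected children across 10 trios; one child has a miscalled
  # homozygote at v1 (violates rule 1 there)
  n_fam <- 10L
  peds <- list(); genos <- list()
  for (f in seq_len(n_fam)) {
    fid <- sprintf("T%02d", f)
    ped <- pedigree(fid = fid, iid = c("1", "2", "3", "4"),
                    father = c(NA, NA, "1", "1"),
                    mother = c(NA, NA, "2", "2"),
                    sex = c("male", "female", "unknown", "unknown"),
                    affection = c("unaffected", "unaffected",
                                  "affected", "affected"))
    G <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 1L))
    rownames(G) <- paste0(fid, ":", 1:4)
    colnames(G) <- c("v1", "v2")
    peds[[f]] <- ped; genos[[f]] <- G
  }
  ped_all <- validate_pedigree(do.call(rbind, peds))
  G_all <- do.call(rbind, genos)
  G_all["T01:3", "v1"] <- 2L    # one genotyping error among 20 affected

  strict <- compound_het_scan(ped_all, G_all, variant_table(2),
                              two_variant_gene, comphet_config(1))
  expect_false(strict$genes$pass)
  relaxed <- compound_het_scan(ped_all, G_all, variant_table(2),
                               two_variant_gene, comphet_config(0.95))
  expect_true(relaxed$genes$pass)
})

test_that("genes without genotyped affected individuals never pass", {
  fx <- trio_fixture(gf = c(1L, 0L), gm = c(0L, 1L), gc = c(1L, 1L))
  fx$ped$affection[] <- "unaffected"
  res <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                           two_variant_gene, comphet_config(1))
  expect_false(res$genes$pass)
  # and unmapped genes are simply absent
  gm_other <- data.frame(variant_id = "zzz", gene_id = "G9")
  res2 <- compound_het_scan(fx$ped, fx$geno, variant_table(2),
                            rbind(two_variant_gene, gm_other))
  expect_false("G9" %in% res2$genes$gene_id)
})
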