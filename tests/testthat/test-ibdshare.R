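test_that("sharing statistic counts only affected non-parent-offspring blood pairs", {
  # affected sib pair + affected father: eligible pair = the sib pair only
  ped <- pedigree(fid = "F1", iid = c("1", "2", "3", "4"),
                  father = c(NA, NA, "1", "1"), mother = c(NA, NA, "2", "2"),
                  sex = c("male", "female", "male", "female"),
                  affection = c("affected", "unaffected", "affected", "affected"))
  ep <- eligible_pairs(ped)
  expect_equal(nrow(ep), 1L)
  expect_setequal(c(ep$id1, ep$id2), c("3", "4"))

  ibd <- data.frame(fid = "F1",
                    id1 = c("3", "1", "1"), id2 = c("4", "3", "4"),
                    position = 10, p0 = c(0.1, 0, 0),
                    p1 = c(0.5, 1, 1), p2 = c(0.4, 0, 0),
                    stringsAsFactors = FALSE)
  track <- sharing_statistic(ped, ibd)
  expect_equal(track$value, 1.0)      # the sib pair has P(IBD!=0) = 0.9 > 0.5
  expect_equal(track$n_pairs, 1L)

  # all pairs with p0 = 1 give statistic 0
  ibd0 <- transform(ibd, p0 = 1, p1 = 0, p2 = 0)
  expect_equal(sharing_statistic(ped, ibd0)$value, 0)

  # no eligible pairs is an error
  ped1 <- ped; ped1$affection <- "unaffected"
  expect_error(sharing_statistic(validate_pedigree(ped1), ibd), "eligible")
})

test_that("pooled statistic is the pair-count-weighted mean of per-family values", {
  set.seed(51)
  peds <- list(); recs <- list()
  for (f in 1:3) {
    fid <- paste0("F", f)
    n_kids <- f + 1L
    ped <- pedigree(fid = fid, iid = as.character(seq_len(n_kids + 2L)),
                    father = c(NA, NA, rep("1", n_kids)),
                    mother = c(NA, NA, rep("2", n_kids)),
                    sex = c("male", "female", rep("unknown", n_kids)),
                    affection = c("unaffected", "unaffected",
                                  rep("affected", n_kids)))
    peds[[f]] <- ped
    kids <- as.character(2L + seq_len(n_kids))
    prs <- utils::combn(kids, 2)
    recs[[f]] <- data.frame(fid = fid, id1 = prs[1, ], id2 = prs[2, ],
                            position = 5,
                            p0 = sample(c(0.1, 0.9), ncol(prs), replace = TRUE),
                            stringsAsFactors = FALSE)
  }
  ped_all <- validate_pedigree(do.call(rbind, peds))
  ibd <- do.call(rbind, recs)
  ibd$p1 <- 1 - ibd$p0; ibd$p2 <- 0
  pooled <- sharing_statistic(ped_all, ibd)
  per_fam <- sharing_statistic(ped_all, ibd,
                               ibd_share_config(scope = "per_family"))
  expect_equal(pooled$value,
               sum(per_fam$value * per_fam$n_pairs) / sum(per_fam$n_pairs))
  # indicator-mean oracle
  expect_equal(pooled$value, mean(1 - ibd$p0 > 0.5))
})

test_that("variant projection assigns left-closed grid intervals", {
  track <- data.frame(position = c(10, 11), value = c(0.2, 0.8))
  vt <- variant_table(3)
  vt$cm <- c(10.4, 11.0, 12.5)
  proj <- project_to_variants(track, vt)
  expect_equal(proj$value, c(0.2, 0.8, 0.8))
  expect_equal(proj$extrapolated, c(FALSE, FALSE, TRUE))
  # variant left of the grid takes the first grid value, flagged
  vt$cm <- c(9.0, 10.0, 10.9)
  proj2 <- project_to_variants(track, vt)
  expect_equal(proj2$value, c(0.2, 0.2, 0.2))
  expect_equal(proj2$extrapolated, c(TRUE, FALSE, FALSE))
})

test_that("region calling matches a brute-force run scan", {
  track <- data.frame(position = c(0, 1, 2, 3), value = c(0.1, 0.9, 0.95, 0.2))
  reg <- call_regions(track, 0.5)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_cm, 1)
  expect_equal(reg$end_cm, 2)
  expect_equal(reg$peak_value, 0.95)
  expect_equal(reg$n_grid_points, 2L)

  expect_equal(nrow(call_regions(track, 1.0)), 0L)            # nothing above
  all_above <- call_regions(track, 0.05)
  expect_equal(nrow(all_above), 1L)                            # single span
  expect_equal(c(all_above$start_cm, all_above$end_cm), c(0, 3))

  # randomized equivalence against the oracle, both directions
  set.seed(52)
  for (r in 1:25) {
    pos <- seq(0, 29)
    val <- round(runif(30), 2)
    thr <- runif(1)
    for (dir in c("above", "below")) {
      got <- call_regions(data.frame(position = pos, value = val), thr, dir)
      want <- run_scan_oracle(pos, val, thr, above = dir == "above")
      expect_equal(nrow(got), length(want))
      if (length(want) > 0) {
        expect_equal(got$start_cm, vapply(want, `[[`, 0, "start"))
        expect_equal(got$end_cm, vapply(want, `[[`, 0, "end"))
      }
    }
  }

  expect_equal(nrow(call_regions(data.frame(position = numeric(),
                                            value = numeric()), 0.5)), 0L)
})

test_that("above/below calls partition non-boundary grid points", {
  set.seed(53)
  track <- data.frame(position = 0:49, value = runif(50))
  thr <- 0.5
  up <- call_regions(track, thr, "above")
  down <- call_regions(track, thr, "below")
  covered <- function(reg, p)
    any(p >= reg$start_cm & p <= reg$end_cm)
  for (p in track$position) {
    v <- track$value[track$position == p]
    if (v != thr)
      expect_true(xor(covered(up, p), covered(down, p)))
  }
})
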