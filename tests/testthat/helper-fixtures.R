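# Shared fixtures and independent oracles, built in code at test time.

# trio + unaffected sibling, two variants; returns temp PED/MAP paths
write_trio_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped_lines <- c(
    "F1 1 0 0 1 1  A A  G G",
    "F1 2 0 0 2 1  A C  G G",
    "F1 3 1 2 1 2  A C  G T",
    "F1 4 1 2 2 1  A A  G G"
  )
  map_lines <- c("1\tv1\t1.0\t1000000", "1\tv2\t2.0\t2000000")
  ped <- file.path(dir, "trio.ped")
  map <- file.path(dir, "trio.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}

# independent kinship oracle: Monte-Carlo gene dropping of a single
# unlinked locus with unique founder alleles; kinship = P(random allele
# from each is identical by descent)
kinship_mc_oracle <- function(ped, id1, id2, n_rep = 20000L, seed = 42L) {
  set.seed(seed)
  ord <- order(!is.na(ped$father))  # founders first; then iterate to fixpoint
  hits <- 0L
  for (r in seq_len(n_rep)) {
    a1 <- a2 <- stats::setNames(rep(NA_integer_, nrow(ped)), ped$iid)
    lab <- 0L
    remaining <- seq_len(nrow(ped))
    while (length(remaining) > 0L) {
      for (i in remaining) {
        if (is.na(ped$father[i])) {
          a1[i] <- (lab <- lab + 1L)
          a2[i] <- (lab <- lab + 1L)
        } else {
          fa <- match(ped$father[i], ped$iid)
          mo <- match(ped$mother[i], ped$iid)
          if (!is.na(a1[fa]) && !is.na(a1[mo])) {
            a1[i] <- if (stats::runif(1) < 0.5) a1[fa] else a2[fa]
            a2[i] <- if (stats::runif(1) < 0.5) a1[mo] else a2[mo]
          }
        }
      }
      remaining <- which(is.na(a1))
    }
    pick1 <- if (stats::runif(1) < 0.5) a1[[id1]] else a2[[id1]]
    pick2 <- if (stats::runif(1) < 0.5) a1[[id2]] else a2[[id2]]
    hits <- hits + (pick1 == pick2)
  }
  hits / n_rep
}

# brute-force threshold run scanner used against call_regions()
run_scan_oracle <- function(position, value, threshold, above = TRUE) {
  hit <- if (above) value > threshold else value < threshold
  regions <- list()
  i <- 1L
  while (i <= length(hit)) {
    if (hit[i]) {
      j <- i
      while (j < length(hit) && hit[j + 1L]) j <- j + 1L
      regions[[length(regions) + 1L]] <-
        c(start = position[i], end = position[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  regions
}

# genotype matrix helper: rows named F1:<i>, columns v1..vk
geno_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("F1:", seq_len(nrow(m)))
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# minimal variant table for k variants on chromosome 1, 1 cM apart
variant_table <- function(k, f_w = NA_real_, gene_id = NA_character_) {
  data.frame(variant_id = paste0("v", seq_len(k)), chrom = "1",
             bp = seq_len(k) * 1000000L, cm = as.numeric(seq_len(k)),
             allele_minor = "B", allele_major = "A",
             f_w = rep_len(f_w, k), gene_id = rep_len(gene_id, k),
             stringsAsFactors = FALSE)
}
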