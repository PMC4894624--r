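#' Built-in pedigree templates
#'
#' `"nuclear"`: two founder parents and two children.
#' `"three_generation_12"`: a 12-member three-generation family with 4
#' founders and 8 non-founders (bit size 12): a founder couple, three of
#' their children, two married-in spouses, and five grandchildren.
#'
#' @param template template name, or a [pedigree()] table passed through
#'   unchanged (custom structures).
#' @param fid family id stamped on the returned table.
#' @return a [pedigree()] table.
#' @export
ped_template <- function(template = c("nuclear", "three_generation_12"),
                         fid = "F1") {
  if (is.data.frame(template)) {
    template$fid <- fid
    return(validate_pedigree(template))
  }
  template <- match.arg(template)
  if (template == "nuclear") {
    ped <- pedigree(
      fid = fid, iid = c("1", "2", "3", "4"),
      father = c(NA, NA, "1", "1"), mother = c(NA, NA, "2", "2"),
      sex = c("male", "female", "male", "female")
    )
  } else {
    # gen 1: 1,2 (founders); gen 2: children 3,5,7 + spouses 4,6 (founders);
    # gen 3: 8,9,10 (of 3x4) and 11,12 (of 5x6)
    ped <- pedigree(
      fid = fid,
      iid = as.character(1:12),
      father = c(NA, NA, "1", NA, "1", NA, "1", "3", "3", "3", "5", "5"),
      mother = c(NA, NA, "2", NA, "2", NA, "2", "4", "4", "4", "6", "6"),
      sex = c("male", "female", "male", "female", "male", "female",
              "male", "male", "female", "male", "female", "male")
    )
  }
  ped
}

#' Simulation configuration
#'
#' Defines the study conditions for the gene-dropping simulator. Defaults:
#' a 100 cM autosomal region carrying `n_variants` diallelic variants
#' whose minor-allele frequencies are drawn from a spectrum of 80\% rare
#' (uniform on 0.001-0.01) and 20\% common (uniform on 0.05-0.5) variants;
#' variants are grouped into genes in consecutive blocks of
#' `variants_per_gene`; full penetrance and no phenocopies; a clean
#' genotyping channel.
#'
#' Scenarios:
#' \describe{
#'   \item{`scen1_family_specific`}{one rare causal variant per family,
#'     placed on a random founder haplotype; affection follows the
#'     configured Mendelian `disease_model` with `penetrance` and
#'     `phenocopy`; families are resampled until at least two affected
#'     members form a non-parent-offspring blood-relative pair.}
#'   \item{`scen2_gene_multivariant`}{`n_cases` unrelated affected
#'     singletons, each heterozygous for its own causal rare variant in
#'     one designated gene, plus `n_cases` unrelated unaffected
#'     singletons.}
#'   \item{`scen3_compound_het`}{nuclear families in which the father and
#'     mother each carry one of two rare variants in the designated gene;
#'     children are affected exactly when compound-heterozygous in trans;
#'     families are resampled until an affected child exists. Background
#'     copies of the two causal variants are cleared within the family so
#'     the configuration is strictly family-specific.}
#'   \item{`null`}{affection assigned independently of all genotypes
#'     (probability 0.5).}
#' }
#'
#' @param scenario one of the above.
#' @param pedigree_template see [ped_template()] (scen1 default:
#'   `"three_generation_12"`; scen3 uses `"nuclear"`).
#' @param n_families number of families (scen1/scen3/null).
#' @param n_cases number of unrelated cases (scen2).
#' @param n_variants number of variants in the region.
#' @param region_length_cm genetic length of the region (cM); physical
#'   positions assume 1 cM/Mb.
#' @param variants_per_gene gene block size.
#' @param frequency_spectrum function(k) returning k minor-allele
#'   frequencies; default the 80/20 rare/common mixture.
#' @param disease_model `"dominant"` or `"recessive"` (scen1).
#' @param penetrance,phenocopy P(affected | carrier genotype) and
#'   P(affected | non-carrier genotype).
#' @param error_model list: `miscall_het_to_hom` (het called homozygous
#'   for one of its alleles), `false_het_rate` (homozygote called het),
#'   `missing_rate`; all 0 by default.
#' @param grid_cm spacing of the true-IBD emission grid.
#' @param emit_ibd emit the true-IBD indicator table (can be large).
#' @param max_resample ascertainment resampling cap per family.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("scen1_family_specific",
                                    "scen2_gene_multivariant",
                                    "scen3_compound_het", "null"),
                       pedigree_template = NULL,
                       n_families = 1L, n_cases = 10L,
                       n_variants = 100L, region_length_cm = 100,
                       variants_per_gene = 5L,
                       frequency_spectrum = NULL,
                       disease_model = c("dominant", "recessive"),
                       penetrance = 1.0, phenocopy = 0.0,
                       error_model = list(miscall_het_to_hom = 0,
                                          false_het_rate = 0,
                                          missing_rate = 0),
                       grid_cm = 1.0, emit_ibd = TRUE,
                       max_resample = 1000L, seed = 1L) {
  scenario <- match.arg(scenario)
  disease_model <- match.arg(disease_model)
  if (is.null(pedigree_template))
    pedigree_template <- switch(scenario,
                                scen1_family_specific = "three_generation_12",
                                "nuclear")
  if (is.null(frequency_spectrum))
    frequency_spectrum <- function(k) {
      rare <- stats::runif(k, 0.001, 0.01)
      common <- stats::runif(k, 0.05, 0.5)
      ifelse(stats::runif(k) < 0.8, rare, common)
    }
  em <- utils::modifyList(list(miscall_het_to_hom = 0, false_het_rate = 0,
                               missing_rate = 0), error_model)
  stopifnot(n_variants >= 1L, region_length_cm > 0,
            penetrance >= 0, penetrance <= 1, phenocopy >= 0, phenocopy <= 1,
            all(unlist(em) >= 0), all(unlist(em) <= 1))
  structure(list(scenario = scenario, pedigree_template = pedigree_template,
                 n_families = as.integer(n_families),
                 n_cases = as.integer(n_cases),
                 n_variants = as.integer(n_variants),
                 region_length_cm = region_length_cm,
                 variants_per_gene = as.integer(variants_per_gene),
                 frequency_spectrum = frequency_spectrum,
                 disease_model = disease_model,
                 penetrance = penetrance, phenocopy = phenocopy,
                 error_model = em, grid_cm = grid_cm, emit_ibd = emit_ibd,
                 max_resample = as.integer(max_resample),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene-dropping pedigree simulation
#'
#' Draws founder haplotypes independently from the configured frequency
#' spectrum, transmits them through each pedigree with recombination
#' governed by [haldane_theta()] on the inter-variant cM gaps, injects the
#' scenario's causal configuration, assigns phenotypes, applies the
#' genotyping-error channel, and emits a true-IBD indicator table derived
#' from founder-allele identity on a cM grid.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `pedigree`, `genotypes` (dosage
#'   matrix, minor-allele counts), `variants` (with `gene_id` and true
#'   `maf`), `truth` (causal variant/gene ids per family, founder-label
#'   arrays), `ibd` (true-IBD indicator records, or `NULL`), `gene_map`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  nv <- config$n_variants
  bp <- sort(sample.int(round(config$region_length_cm * 1e6), nv))
  cm <- bp / 1e6
  maf <- config$frequency_spectrum(nv)
  vid <- sprintf("v%04d", seq_len(nv))
  gene_id <- sprintf("G%03d", (seq_len(nv) - 1L) %/% config$variants_per_gene + 1L)
  variants <- data.frame(variant_id = vid, chrom = "1", bp = bp, cm = cm,
                         allele_minor = "B", allele_major = "A",
                         f_w = NA_real_, gene_id = gene_id, maf = maf,
                         stringsAsFactors = FALSE)
  rare <- which(maf < 0.02)
  genes <- unique(gene_id)
  causal_gene <- genes[ceiling(length(genes) / 2)]

  fam_list <- switch(
    config$scenario,
    scen2_gene_multivariant = .sim_scen2(config, variants, causal_gene, rare),
    .sim_families(config, variants, causal_gene, rare)
  )

  ped <- do.call(rbind, lapply(fam_list, `[[`, "ped"))
  ped <- validate_pedigree(ped)
  geno <- do.call(rbind, lapply(fam_list, `[[`, "geno"))
  geno <- .apply_error_channel(geno, config$error_model)
  causal_variants <- unlist(lapply(fam_list, `[[`, "causal"))
  truth <- list(
    causal_variants = causal_variants,
    # gene-level truth: genes containing a causal variant (for scen2/scen3
    # this is the single designated gene)
    causal_gene = if (config$scenario == "null") character(0) else
      unique(variants$gene_id[match(causal_variants, variants$variant_id)]),
    founder_labels = lapply(fam_list, `[[`, "labels")
  )
  names(truth$founder_labels) <- vapply(fam_list,
                                        function(x) x$ped$fid[1L], "")
  ibd <- NULL
  if (config$emit_ibd)
    ibd <- .emit_true_ibd(fam_list, cm, config$grid_cm,
                          config$region_length_cm)
  structure(list(pedigree = ped, genotypes = geno, variants = variants,
                 truth = truth, ibd = ibd,
                 gene_map = variants[, c("variant_id", "gene_id")],
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study (%s): %d individual(s), %d variant(s), %d gene(s)\n",
              x$config$scenario, nrow(x$pedigree), nrow(x$variants),
              length(unique(x$variants$gene_id))))
  if (length(x$truth$causal_variants) > 0L)
    cat("  causal:", paste(unique(x$truth$causal_variants), collapse = ", "),
        "in gene", x$truth$causal_gene, "\n")
  invisible(x)
}

# One gamete: recombinant mosaic of the parent's two haplotype rows.
# `theta` has length nvar-1. Returns the transmitted haplotype and the
# matching founder-label vector.
.gamete <- function(hap_pair, lab_pair, theta) {
  nv <- ncol(hap_pair)
  cur <- 1L + (stats::runif(1) < 0.5)
  if (nv > 1L) {
    switches <- stats::runif(nv - 1L) < theta
    src <- 1L + (cumsum(c(cur - 1L, switches)) %% 2L)
  } else {
    src <- cur
  }
  idx <- cbind(src, seq_len(nv))
  list(hap = hap_pair[idx], lab = lab_pair[idx])
}

# Drops haplotypes through one family; returns per-individual haplotype
# and founder-label arrays (individuals x 2 x nvar as paired matrices).
.drop_family <- function(ped, maf, theta, label_offset = 0L) {
  ord <- .topological_order(ped)
  sub <- ped[ord, , drop = FALSE]
  n <- nrow(sub); nv <- length(maf)
  H1 <- H2 <- matrix(0L, n, nv)
  L1 <- L2 <- matrix(0L, n, nv)
  rownames(H1) <- rownames(H2) <- rownames(L1) <- rownames(L2) <- sub$iid
  lab <- label_offset
  for (i in seq_len(n)) {
    if (is.na(sub$father[i])) {
      H1[i, ] <- stats::rbinom(nv, 1L, maf)
      H2[i, ] <- stats::rbinom(nv, 1L, maf)
      L1[i, ] <- lab + 1L
      L2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      fa <- match(sub$father[i], sub$iid)
      mo <- match(sub$mother[i], sub$iid)
      g1 <- .gamete(rbind(H1[fa, ], H2[fa, ]), rbind(L1[fa, ], L2[fa, ]), theta)
      g2 <- .gamete(rbind(H1[mo, ], H2[mo, ]), rbind(L1[mo, ], L2[mo, ]), theta)
      H1[i, ] <- g1$hap; L1[i, ] <- g1$lab
      H2[i, ] <- g2$hap; L2[i, ] <- g2$lab
    }
  }
  keep <- match(ped$iid, sub$iid)
  list(H1 = H1[keep, , drop = FALSE], H2 = H2[keep, , drop = FALSE],
       L1 = L1[keep, , drop = FALSE], L2 = L2[keep, , drop = FALSE],
       n_labels = lab - label_offset)
}

.family_seed <- function(seed, f) (abs(seed) + 104729L * f) %% 2147483647L

# scen1 / scen3 / null: family-wise generation with ascertainment
.sim_families <- function(config, variants, causal_gene, rare) {
  maf <- variants$maf
  theta <- haldane_theta(diff(variants$cm))
  gene_vars <- which(variants$gene_id == causal_gene)
  out <- vector("list", config$n_families)
  # scen3: one founder mutation pair shared across families
  if (config$scenario == "scen3_compound_het") {
    cand <- intersect(gene_vars, rare)
    if (length(cand) < 2L)
      stop("designated gene has fewer than 2 rare variants; ",
           "increase n_variants or variants_per_gene")
    ch_pair <- sort(sample(cand, 2L))
  }
  if (config$scenario == "scen1_family_specific") {
    if (length(rare) < config$n_families)
      stop("not enough rare variants for family-specific causal assignment")
    causal_pool <- sample(rare, config$n_families)
  }
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%03d", f)
    ped <- ped_template(config$pedigree_template, fid = fid)
    set.seed(.family_seed(config$seed, f))
    causal <- switch(config$scenario,
                     scen1_family_specific = causal_pool[f],
                     scen3_compound_het = ch_pair,
                     integer(0))
    for (attempt in seq_len(config$max_resample)) {
      dr <- .drop_family(ped, maf, theta)
      aff <- NULL
      if (config$scenario == "scen1_family_specific") {
        founders <- which(is.na(ped$father))
        fo <- sample(founders, 1L)
        if (stats::runif(1) < 0.5) dr$H1[fo, causal] <- 1L
        else dr$H2[fo, causal] <- 1L
        # re-drop descendants so the injected allele transmits
        dr <- .redrop_from(ped, dr, theta, fo)
        dose <- dr$H1[, causal] + dr$H2[, causal]
        carrier <- if (config$disease_model == "dominant") dose >= 1L
                   else dose == 2L
        aff <- ifelse(carrier,
                      stats::runif(nrow(ped)) < config$penetrance,
                      stats::runif(nrow(ped)) < config$phenocopy)
        ped$affection <- ifelse(aff, "affected", "unaffected")
        ok <- sum(aff) >= 2L && nrow(eligible_pairs(ped)) >= 1L
      } else if (config$scenario == "scen3_compound_het") {
        founders <- which(is.na(ped$father))
        dr$H1[founders, causal] <- 0L
        dr$H2[founders, causal] <- 0L
        fa <- which(is.na(ped$father) & ped$sex == "male")[1L]
        mo <- which(is.na(ped$father) & ped$sex == "female")[1L]
        dr$H1[fa, causal[1L]] <- 1L
        dr$H1[mo, causal[2L]] <- 1L
        dr <- .redrop_from(ped, dr, theta, c(fa, mo))
        comp_het <- (dr$H1[, causal[1L]] + dr$H2[, causal[1L]] == 1L) &
          (dr$H1[, causal[2L]] + dr$H2[, causal[2L]] == 1L) &
          ((dr$H1[, causal[1L]] == 1L) != (dr$H1[, causal[2L]] == 1L) |
             (dr$H2[, causal[1L]] == 1L) != (dr$H2[, causal[2L]] == 1L))
        # trans configuration: the two minor alleles sit on opposite haplotypes
        trans <- (dr$H1[, causal[1L]] == 1L & dr$H2[, causal[2L]] == 1L) |
          (dr$H2[, causal[1L]] == 1L & dr$H1[, causal[2L]] == 1L)
        aff <- comp_het & trans
        aff[c(fa, mo)] <- FALSE
        ped$affection <- ifelse(aff, "affected", "unaffected")
        ok <- any(aff & !is.na(ped$father))
      } else {                              # null
        ped$affection <- ifelse(stats::runif(nrow(ped)) < 0.5,
                                "affected", "unaffected")
        ok <- TRUE
      }
      if (ok) break
      if (attempt == config$max_resample)
        stop("ascertainment failed after ", config$max_resample,
             " resamples for family ", fid)
    }
    geno <- dr$H1 + dr$H2
    rownames(geno) <- .key(ped$fid, ped$iid)
    colnames(geno) <- variants$variant_id
    out[[f]] <- list(ped = ped, geno = geno,
                     causal = variants$variant_id[causal],
                     labels = dr)
  }
  out
}

# Re-drop all non-founders after founder haplotypes were edited, keeping
# founder draws. Transmission randomness is redrawn, which is fine: the
# edit happens before any ascertainment decision.
.redrop_from <- function(ped, dr, theta, founders_edited) {
  ord <- .topological_order(ped)
  for (i in ord) {
    if (is.na(ped$father[i])) next
    fa <- match(ped$father[i], ped$iid)
    mo <- match(ped$mother[i], ped$iid)
    g1 <- .gamete(rbind(dr$H1[fa, ], dr$H2[fa, ]),
                  rbind(dr$L1[fa, ], dr$L2[fa, ]), theta)
    g2 <- .gamete(rbind(dr$H1[mo, ], dr$H2[mo, ]),
                  rbind(dr$L1[mo, ], dr$L2[mo, ]), theta)
    dr$H1[i, ] <- g1$hap; dr$L1[i, ] <- g1$lab
    dr$H2[i, ] <- g2$hap; dr$L2[i, ] <- g2$lab
  }
  dr
}

# scen2: unrelated affected singletons with distinct causal variants in
# the designated gene, plus matched unaffected singletons.
.sim_scen2 <- function(config, variants, causal_gene, rare) {
  maf <- variants$maf
  nv <- nrow(variants)
  gene_vars <- which(variants$gene_id == causal_gene)
  cand <- intersect(gene_vars, rare)
  if (length(cand) < config$n_cases)
    stop("designated gene has only ", length(cand),
         " rare variants for ", config$n_cases, " cases; ",
         "increase variants_per_gene")
  causal <- sample(cand, config$n_cases)
  out <- vector("list", 2L * config$n_cases)
  for (i in seq_len(2L * config$n_cases)) {
    case <- i <= config$n_cases
    fid <- sprintf("%s%03d", if (case) "CA" else "CO", i)
    set.seed(.family_seed(config$seed, 10000L + i))
    ped <- pedigree(fid = fid, iid = "1", sex = "unknown",
                    affection = if (case) "affected" else "unaffected")
    H1 <- matrix(stats::rbinom(nv, 1L, maf), 1L)
    H2 <- matrix(stats::rbinom(nv, 1L, maf), 1L)
    cv <- integer(0)
    if (case) {
      cv <- causal[i]
      H1[1L, cv] <- 1L; H2[1L, cv] <- 0L
    }
    geno <- H1 + H2
    rownames(geno) <- .key(ped$fid, ped$iid)
    colnames(geno) <- variants$variant_id
    L1 <- matrix(2L * i - 1L, 1L, nv); L2 <- matrix(2L * i, 1L, nv)
    out[[i]] <- list(ped = ped, geno = geno,
                     causal = variants$variant_id[cv],
                     labels = list(H1 = H1, H2 = H2, L1 = L1, L2 = L2))
  }
  out
}

.apply_error_channel <- function(geno, em) {
  if (em$miscall_het_to_hom > 0) {
    het <- which(!is.na(geno) & geno == 1L)
    hit <- het[stats::runif(length(het)) < em$miscall_het_to_hom]
    geno[hit] <- ifelse(stats::runif(length(hit)) < 0.5, 0L, 2L)
  }
  if (em$false_het_rate > 0) {
    hom <- which(!is.na(geno) & geno != 1L)
    hit <- hom[stats::runif(length(hom)) < em$false_het_rate]
    geno[hit] <- 1L
  }
  if (em$missing_rate > 0) {
    obs <- which(!is.na(geno))
    geno[obs[stats::runif(length(obs)) < em$missing_rate]] <- NA_integer_
  }
  geno
}

# IBD state of a pair from founder labels, vectorized over positions:
# 2 when the label pairs match under some pairing, 1 when exactly one
# allele is shared, else 0.
.ibd_state <- function(a1, a2, b1, b2) {
  ibd2 <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
  shared <- a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2
  2L * ibd2 + (shared & !ibd2)
}

.emit_true_ibd <- function(fam_list, cm, grid_cm, region_length_cm) {
  grid <- seq(0, region_length_cm, by = grid_cm)
  # label at a grid point = label at the variant at or left of it
  vidx <- pmax(1L, findInterval(grid, cm))
  ng <- length(grid)
  fid <- id1 <- id2 <- list(); pos <- st <- list()
  for (fam in fam_list) {
    ped <- fam$ped
    if (nrow(ped) < 2L) next
    L1 <- fam$labels$L1[, vidx, drop = FALSE]
    L2 <- fam$labels$L2[, vidx, drop = FALSE]
    ids <- ped$iid
    for (i in seq_len(nrow(ped) - 1L)) {
      for (j in seq((i + 1L), nrow(ped))) {
        k <- length(st) + 1L
        st[[k]] <- .ibd_state(L1[i, ], L2[i, ], L1[j, ], L2[j, ])
        fid[[k]] <- rep(ped$fid[1L], ng)
        id1[[k]] <- rep(ids[i], ng)
        id2[[k]] <- rep(ids[j], ng)
        pos[[k]] <- grid
      }
    }
  }
  if (length(st) == 0L) return(read_ibd_table_empty())
  s <- unlist(st)
  data.frame(fid = unlist(fid), id1 = unlist(id1), id2 = unlist(id2),
             position = unlist(pos), p0 = as.numeric(s == 0L),
             p1 = as.numeric(s == 1L), p2 = as.numeric(s == 2L),
             stringsAsFactors = FALSE)
}

#' Audit Mendelian consistency of a genotype matrix
#'
#' Checks every non-founder genotype against its parents' genotypes under
#' diallelic transmission (a child's dosage must be attainable as one
#' allele from each parent). Missing genotypes are skipped.
#'
#' @param ped a [pedigree()] table.
#' @param genotypes dosage matrix keyed `fid:iid`.
#' @return data frame of violations (`fid`, `iid`, `variant_id`); zero
#'   rows when fully consistent.
#' @export
mendelian_audit <- function(ped, genotypes) {
  keys <- .key(ped$fid, ped$iid)
  poss <- list(`0` = 0L, `1` = 0L:1L, `2` = 1L)
  bad <- list()
  for (i in which(!is.na(ped$father))) {
    fa <- match(.key(ped$fid[i], ped$father[i]), keys)
    mo <- match(.key(ped$fid[i], ped$mother[i]), keys)
    gc <- genotypes[keys[i], ]
    gf <- genotypes[keys[fa], ]
    gm <- genotypes[keys[mo], ]
    for (j in which(!is.na(gc) & !is.na(gf) & !is.na(gm))) {
      offer <- outer(poss[[as.character(gf[j])]],
                     poss[[as.character(gm[j])]], "+")
      if (!(gc[j] %in% offer))
        bad[[length(bad) + 1L]] <- data.frame(
          fid = ped$fid[i], iid = ped$iid[i],
          variant_id = colnames(genotypes)[j], stringsAsFactors = FALSE)
    }
  }
  if (length(bad) == 0L)
    return(data.frame(fid = character(), iid = character(),
                      variant_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

#' Write a simulated study to disk
#'
#' Emits the PLINK text PED/MAP pair, an external-style frequency table
#' built from the true minor-allele frequencies, the gene map, the
#' true-IBD table (when present) and a truth file listing causal ids.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "study.ped"),
             map = file.path(dir, "study.map"),
             freq = file.path(dir, "study.freq.tsv"),
             genemap = file.path(dir, "study.genes.tsv"),
             truth = file.path(dir, "study.truth.tsv"))
  write_ped_map(study$pedigree, study$genotypes, study$variants,
                paths[["ped"]], paths[["map"]])
  freq <- data.frame(variant_id = study$variants$variant_id,
                     chrom = study$variants$chrom, bp = study$variants$bp,
                     allele = study$variants$allele_minor,
                     freq = study$variants$maf, allele_count = 1000L)
  utils::write.table(freq, paths[["freq"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$gene_map, paths[["genemap"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(kind = c(rep("variant", length(study$truth$causal_variants)),
                               rep("gene", length(study$truth$causal_gene))),
                      id = c(study$truth$causal_variants,
                             study$truth$causal_gene),
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(study$ibd)) {
    paths[["ibd"]] <- file.path(dir, "study.ibd.txt")
    write_ibd_table(study$ibd, paths[["ibd"]])
  }
  invisible(paths)
}
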