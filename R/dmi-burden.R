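#' Weighted-sum burden statistic for a gene
#'
#' Madsen-Browning-style gene statistic: each individual accumulates
#' minor-allele counts over the gene's variants, each count weighted by
#' the inverse of the estimated standard deviation of the allele count
#' under the unaffected-group frequency,
#' \deqn{q_j = (m_j + 1) / (2 n_U + 2), \quad
#'       w_j = \sqrt{n_j q_j (1 - q_j)}, \quad
#'       \gamma_i = \sum_j c_{ij} / w_j,}
#' where \eqn{m_j} is the minor-allele count among genotyped unaffected
#' individuals, \eqn{n_U} their number, \eqn{n_j} the genotyped count at
#' variant j, and \eqn{c_{ij}} individual i's minor-allele count. The test
#' statistic is the rank sum (midranks for ties) of \eqn{\gamma} over
#' affected individuals; its null distribution comes from permuting
#' affection labels among individuals with known status, with the
#' weights (which depend on the unaffected group) re-estimated for every
#' permuted label assignment, as in the published procedure.
#'
#' When the number of distinct affected-label assignments
#' `choose(n, n_affected)` is at most `exhaustive_max`, the permutation
#' distribution is enumerated exactly and the p-value is
#' `#\{x_perm >= x\} / N`; otherwise `n_permutations` Monte-Carlo draws
#' give `p = (1 + #\{x_perm >= x\}) / (1 + n_permutations)`. `z`
#' standardizes `x` against the permutation distribution. If every
#' individual has the same burden the result is degenerate: `p = 1`,
#' `z = 0`, `degenerate = TRUE`.
#'
#' With no genotyped unaffected individuals, `q_j` falls back to the
#' external frequency `f_e` (same +1/+2 pseudo-counting with `m_e`
#' external alleles), and the fallback is flagged.
#'
#' @param genotypes dosage matrix oriented by [assign_minor_alleles()].
#' @param affection character vector aligned with rows.
#' @param gene_variants variant ids (columns) belonging to the gene.
#' @param n_permutations Monte-Carlo permutation count.
#' @param seed integer seed for the Monte-Carlo path.
#' @param f_e,m_e optional external frequencies and allele counts (named
#'   by variant id) for the no-unaffected fallback.
#' @param exhaustive_max enumerate exactly when the distinct label
#'   assignments do not exceed this.
#' @param within_family optional family-id vector aligned with rows;
#'   when supplied, labels are permuted within families only (the default
#'   free permutation matches the unrelated-samples formulation).
#' @return list: `x`, `z`, `p`, `gamma`, `method`
#'   (`"exhaustive"`/`"montecarlo"`), `degenerate`, `freq_fallback`.
#' @export
weighted_sum_statistic <- function(genotypes, affection, gene_variants,
                                   n_permutations = 1000L, seed = 1L,
                                   f_e = NULL, m_e = NULL,
                                   exhaustive_max = 10000L,
                                   within_family = NULL) {
  stopifnot(length(gene_variants) >= 1L)
  G <- genotypes[, gene_variants, drop = FALSE]
  if (!all(G %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  aff <- affection == "affected"
  n <- nrow(G)
  nA <- sum(aff)
  if (nA == 0L) stop("no affected individuals")
  known <- which(affection %in% c("affected", "unaffected"))

  Gz <- G
  Gz[is.na(Gz)] <- 0L                     # missing contributes no burden
  typed <- !is.na(G)
  n_j <- colSums(typed)

  # rank-sum of the weighted burden for one affected-label assignment;
  # weights are re-estimated from that assignment's unaffected group, as
  # in the published weighted-sum procedure
  burden_stats <- function(A) {           # A: n x B affected indicators
    U <- (affection != "unknown") - A     # unaffected under the assignment
    U[affection == "unknown", ] <- 0
    m <- crossprod(Gz, U)                 # minor-allele count in unaffected
    nU <- crossprod(typed + 0, U)         # genotyped unaffected count
    q <- (m + 1) / (2 * nU + 2)
    fallback <- FALSE
    if (any(nU == 0)) {
      idx <- which(nU == 0, arr.ind = TRUE)
      js <- unique(idx[, 1L])
      fe <- if (!is.null(f_e)) unlist(f_e)[gene_variants[js]] else
        rep(NA_real_, length(js))
      if (any(is.na(fe)))
        stop("no genotyped unaffected individuals and no external ",
             "frequency for variant ",
             gene_variants[js[which(is.na(fe))[1L]]])
      me <- if (!is.null(m_e)) unlist(m_e)[gene_variants[js]] else
        rep(0L, length(js))
      me[is.na(me)] <- 0L
      qf <- (fe * me + 1) / (me + 2)
      q[idx] <- qf[match(idx[, 1L], js)]
      fallback <- TRUE
    }
    W <- 1 / sqrt(n_j * q * (1 - q))      # nv x B inverse weights
    W[n_j == 0L, ] <- 0                   # fully missing variants carry nothing
    Gam <- Gz %*% W                       # n x B burdens
    R <- apply(Gam, 2L, rank)             # midranks for ties
    list(x = colSums(R * A), gamma = Gam, fallback = fallback)
  }

  obs <- burden_stats(matrix(as.numeric(aff), ncol = 1L))
  x <- obs$x[[1L]]
  gamma <- as.numeric(obs$gamma)
  freq_fallback <- obs$fallback

  if (stats::sd(gamma) == 0) {
    return(list(x = x, z = 0, p = 1, gamma = gamma, method = "degenerate",
                degenerate = TRUE, freq_fallback = freq_fallback))
  }

  # labels are reassigned among individuals with known affection status
  if (is.null(within_family) && choose(length(known), nA) <= exhaustive_max) {
    combos <- utils::combn(length(known), nA)
    A <- matrix(0, n, ncol(combos))
    A[cbind(known[as.vector(combos)],
            rep(seq_len(ncol(combos)), each = nA))] <- 1
    x_perm <- burden_stats(A)$x
    p <- sum(x_perm >= x) / length(x_perm)
    method <- "exhaustive"
  } else {
    set.seed(seed)
    A <- matrix(0, n, n_permutations)
    if (is.null(within_family)) {
      for (b in seq_len(n_permutations))
        A[known[sample.int(length(known), nA)], b] <- 1
    } else {
      fam <- as.character(within_family)
      for (b in seq_len(n_permutations)) {
        lab <- aff
        for (f in unique(fam)) {
          i <- intersect(which(fam == f), known)
          lab[i] <- lab[i][sample.int(length(i))]
        }
        A[lab, b] <- 1
      }
    }
    x_perm <- burden_stats(A)$x
    p <- (1 + sum(x_perm >= x)) / (1 + n_permutations)
    method <- "montecarlo"
  }
  sd_perm <- stats::sd(x_perm)
  z <- if (is.na(sd_perm) || sd_perm == 0) 0 else (x - mean(x_perm)) / sd_perm
  list(x = x, z = z, p = p, gamma = gamma, method = method,
       degenerate = FALSE, freq_fallback = freq_fallback)
}

#' Weighted-sum statistics for all genes
#'
#' Applies [weighted_sum_statistic()] gene by gene and returns a ranked
#' table. Genes are ranked by ascending p-value, ties broken by descending
#' `z` then by the genomic order of the gene's first variant.
#'
#' @inheritParams weighted_sum_statistic
#' @param gene_map data frame `variant_id`, `gene_id` (see
#'   [read_gene_map()]); variants absent from `genotypes` are ignored.
#' @param variants variant table (for tie-break genomic order).
#' @return data frame `gene_id`, `n_variants`, `x`, `z`, `p`, `method`,
#'   `rank`.
#' @export
weighted_sum_scan <- function(genotypes, affection, gene_map, variants,
                              n_permutations = 1000L, seed = 1L,
                              f_e = NULL, m_e = NULL,
                              exhaustive_max = 10000L) {
  gene_map <- gene_map[gene_map$variant_id %in% colnames(genotypes), ,
                       drop = FALSE]
  genes <- unique(gene_map$gene_id)
  rows <- lapply(seq_along(genes), function(k) {
    vs <- gene_map$variant_id[gene_map$gene_id == genes[k]]
    res <- weighted_sum_statistic(genotypes, affection, vs,
                                  n_permutations = n_permutations,
                                  seed = seed + k, f_e = f_e, m_e = m_e,
                                  exhaustive_max = exhaustive_max)
    data.frame(gene_id = genes[k], n_variants = length(vs), x = res$x,
               z = res$z, p = res$p, method = res$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(variants$chrom, variants$bp)
  first_pos <- vapply(out$gene_id, function(g) {
    vs <- gene_map$variant_id[gene_map$gene_id == g]
    min(match(vs, variants$variant_id[ord]))
  }, 0)
  o <- order(out$p, -out$z, first_pos)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
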