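#' Segregation scoring parameters
#'
#' Per-individual weights for the multiplicative segregation scores under
#' autosomal dominant and recessive models. Writing `D` for the minor
#' (putative disease) allele and `d` for the major allele, the defaults
#' are:
#' \itemize{
#'   \item dominant: affected `DD` 0.8, affected `dd` 0.5, unaffected `Dd`
#'     0.1, unaffected `DD` 0.01;
#'   \item recessive: affected `Dd` 0.5, affected `dd` 0.1, unaffected
#'     `DD` 0.1.
#' }
#' Every other genotype/phenotype combination scores 1. The sub-unit
#' weights tolerate genotyping error: a genotype violating the assumed
#' Mendelian model reduces, but does not zero, the variant's score. They
#' reflect roughly 50\% detection sensitivity, a 20\% heterozygote-to-
#' homozygote miscall rate and a 10\% false-positive call rate.
#'
#' @param dominant,recessive named numeric vectors of weights in (0, 1]
#'   with names among `"affected_DD"`, `"affected_Dd"`, `"affected_dd"`,
#'   `"unaffected_DD"`, `"unaffected_Dd"`, `"unaffected_dd"`.
#' @param default_other weight for unlisted combinations (and for missing
#'   genotypes or unknown phenotypes, which carry no evidence).
#' @return list of class `segregation_params`.
#' @export
segregation_params <- function(dominant = c(affected_DD = 0.8,
                                            affected_dd = 0.5,
                                            unaffected_Dd = 0.1,
                                            unaffected_DD = 0.01),
                               recessive = c(affected_Dd = 0.5,
                                             affected_dd = 0.1,
                                             unaffected_DD = 0.1),
                               default_other = 1.0) {
  for (w in list(dominant, recessive, default_other))
    if (any(w <= 0 | w > 1)) stop("segregation weights must lie in (0, 1]")
  structure(list(dominant = dominant, recessive = recessive,
                 default_other = default_other),
            class = "segregation_params")
}

# weight lookup vector indexed by paste(affection, dosage): full 3x2 grid,
# defaulting to `default_other`
.seg_weight_table <- function(model, params) {
  w <- params[[model]]
  full <- rep(params$default_other, 6L)
  names(full) <- c("affected_dd", "affected_Dd", "affected_DD",
                   "unaffected_dd", "unaffected_Dd", "unaffected_DD")
  full[names(w)] <- w
  full
}

#' Segregation score of a variant under a Mendelian model
#'
#' The product over individuals of the per-individual weight from
#' [segregation_params()], given each individual's minor-allele dosage and
#' affection status. Individuals with a missing genotype or unknown
#' affection contribute a neutral factor of 1. Higher scores indicate
#' genotype/phenotype patterns more consistent with the assumed model;
#' the score is used for ranking, not significance testing.
#'
#' @param genotypes dosage matrix oriented by [assign_minor_alleles()].
#' @param variant variant id (column) or index; or omit via
#'   [segregation_score_track()] to score all variants.
#' @param affection character vector aligned with genotype rows
#'   (`"affected"`, `"unaffected"`, `"unknown"`).
#' @param model `"dominant"` or `"recessive"`.
#' @param params a [segregation_params()].
#' @return numeric score in (0, 1].
#' @export
segregation_score <- function(genotypes, variant, affection,
                              model = c("dominant", "recessive"),
                              params = segregation_params()) {
  model <- match.arg(model)
  segregation_score_track(genotypes[, variant, drop = FALSE], affection,
                          model, params)[[1L]]
}

#' @rdname segregation_score
#' @param per_family optional factor/character vector of family ids aligned
#'   with rows; when supplied, the result is a matrix of per-family scores
#'   (families in rows) whose column-products equal the pooled scores.
#' @return `segregation_score_track` returns a named vector of scores over
#'   all variants (or a family-by-variant matrix under `per_family`).
#' @export
segregation_score_track <- function(genotypes, affection,
                                    model = c("dominant", "recessive"),
                                    params = segregation_params(),
                                    per_family = NULL) {
  model <- match.arg(model)
  wt <- .seg_weight_table(model, params)
  glab <- c("dd", "Dd", "DD")[genotypes + 1L]        # NA propagates
  key <- paste(affection, glab, sep = "_")
  W <- matrix(wt[key], nrow = nrow(genotypes), ncol = ncol(genotypes))
  W[is.na(W)] <- 1                                    # missing geno / unknown status
  if (is.null(per_family)) {
    out <- apply(W, 2L, prod)
    names(out) <- colnames(genotypes)
    return(out)
  }
  fams <- sort(unique(as.character(per_family)))
  out <- t(vapply(fams, function(f)
    apply(W[per_family == f, , drop = FALSE], 2L, prod),
    numeric(ncol(genotypes))))
  dimnames(out) <- list(fams, colnames(genotypes))
  out
}

#' Rank variants by segregation score
#'
#' Descending score; rank 1 is the best-supported variant. Ties are broken
#' by genomic order (the variant table's chromosome/bp order), so the
#' ranking is deterministic and independent of input permutation.
#'
#' @param scores named score vector from [segregation_score_track()].
#' @param variants variant table supplying genomic order.
#' @return data frame `variant_id`, `score`, `rank` sorted by rank.
#' @export
rank_variants_by_segregation <- function(scores, variants) {
  ord <- order(variants$chrom, variants$bp)
  ids <- variants$variant_id[ord]
  s <- scores[ids]
  o <- order(-s)              # stable: ties keep genomic order
  data.frame(variant_id = ids[o], score = unname(s[o]),
             rank = seq_along(ids), stringsAsFactors = FALSE)
}
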