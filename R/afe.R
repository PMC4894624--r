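#' Sample allele frequency at a variant
#'
#' Frequency of the tracked (minor-coded) allele among non-missing alleles,
#' together with the observed allele count. `n` counts alleles actually
#' genotyped (2 per non-missing genotype), not twice the sample size.
#'
#' @param genotypes dosage matrix (0/1/2/`NA`, minor-allele counts).
#' @param variant variant id (column name) or column index.
#' @return list with `f_s` (frequency, `NA` if the variant is entirely
#'   missing) and `n` (non-missing allele count).
#' @export
sample_allele_frequency <- function(genotypes, variant) {
  g <- genotypes[, variant]
  n <- 2L * sum(!is.na(g))
  if (n == 0L) return(list(f_s = NA_real_, n = 0L))
  list(f_s = sum(g, na.rm = TRUE) / n, n = n)
}

#' Weighted allele frequency
#'
#' Pools a sample frequency with an external-population frequency,
#' weighting each by its allele count:
#' \deqn{f_w = (n f_s + m f_e) / (n + m)}
#' When no external frequency is available, `f_w = f_s`. Pooling keeps
#' `f_w` strictly positive for any allele observed in either source, which
#' protects downstream likelihood computations from zero-frequency disease
#' alleles, and damps the enrichment of minor alleles within ascertained
#' families.
#'
#' @param f_s sample frequency in [0, 1].
#' @param n sample allele count (>= 0).
#' @param f_e external frequency, or `NA`/`NULL` if absent.
#' @param m external allele count.
#' @return `f_w`, a convex combination of `f_s` and `f_e`.
#' @export
weighted_frequency <- function(f_s, n, f_e = NULL, m = 0L) {
  if (is.null(f_e) || length(f_e) == 0L || is.na(f_e)) return(f_s)
  stopifnot(n >= 0, m >= 0)
  if (n + m == 0) stop("undefined weighted frequency: n + m = 0")
  (n * f_s + m * f_e) / (n + m)
}

#' Assign minor alleles and weighted frequencies
#'
#' For each variant, computes the weighted frequency of both alleles
#' (pooling sample counts with an external frequency table when supplied),
#' declares the allele with the smaller `f_w` the minor allele `D`, and
#' re-orients the genotype dosage matrix so that 2 = homozygous minor.
#' Heterozygosity and missingness are untouched; only the two homozygote
#' labels may swap. On an exact `f_w` tie the alphabetically first allele
#' is declared minor, so results are reproducible.
#'
#' External records whose allele matches neither sample allele are dropped
#' with a warning. Variants that are monomorphic in the sample take the
#' external allele (if any) as the minor allele candidate; lacking that,
#' the minor allele stays unassigned and `f_w` is 0 for the unobserved
#' allele slot.
#'
#' @param genotypes dosage matrix from [read_ped_map()].
#' @param variants variant table from [read_ped_map()].
#' @param freq_table optional external table from [read_frequency_table()].
#' @return list with re-oriented `genotypes` and `variants` whose
#'   `allele_minor`, `allele_major` and `f_w` columns are final; columns
#'   `f_s` and `n_sample` record the sample-only quantities for the minor
#'   allele.
#' @export
assign_minor_alleles <- function(genotypes, variants, freq_table = NULL) {
  nv <- nrow(variants)
  f_w_minor <- f_s_minor <- rep(NA_real_, nv)
  n_sample <- integer(nv)
  for (j in seq_len(nv)) {
    v <- variants[j, ]
    sf <- sample_allele_frequency(genotypes, v$variant_id)
    n_sample[j] <- sf$n
    a_min <- v$allele_minor     # provisional (count-based) orientation
    a_maj <- v$allele_major
    fe_min <- fe_maj <- NA_real_
    m_ext <- 0L
    if (!is.null(freq_table)) {
      hit <- freq_table[freq_table$variant_id == v$variant_id, , drop = FALSE]
      if (nrow(hit) > 0L) {
        # at a sample-monomorphic variant the external allele, if it is not
        # the observed major, names the unobserved minor allele
        ok <- !is.na(hit$allele) &
          (hit$allele %in% c(a_min, a_maj) |
             (is.na(a_min) & hit$allele != a_maj))
        if (any(!ok)) {
          warning(sprintf(
            "variant %s: external allele(s) %s match neither sample allele; ignored",
            v$variant_id, paste(hit$allele[!ok], collapse = ",")))
          hit <- hit[ok, , drop = FALSE]
        }
        if (nrow(hit) > 0L) {
          m_ext <- hit$allele_count[1L]
          fe <- hit$freq[1L]
          if (is.na(a_min) && hit$allele[1L] != a_maj) {
            a_min <- hit$allele[1L]
            variants$allele_minor[j] <- a_min
            fe_min <- fe; fe_maj <- 1 - fe
          } else if (!is.na(a_min) && hit$allele[1L] == a_min) {
            fe_min <- fe; fe_maj <- 1 - fe
          } else {
            fe_maj <- fe; fe_min <- 1 - fe
          }
        }
      }
    }
    if (is.na(a_min)) {
      # monomorphic or all-missing in sample, no external minor: nothing to flip
      f_s_minor[j] <- if (sf$n > 0L) 0 else NA_real_
      f_w_minor[j] <- weighted_frequency(if (sf$n > 0L) 0 else NA_real_,
                                         sf$n, fe_min, m_ext)
      next
    }
    if (!is.na(a_min) && is.na(variants$allele_major[j])) {
      # sample fully missing but external named the minor: frequencies are
      # external-only
      f_s_minor[j] <- NA_real_
      f_w_minor[j] <- fe_min
      next
    }
    if (is.na(v$allele_minor)) {
      # external-adopted minor at a monomorphic variant: genotypes all 0
      f_s_minor[j] <- 0
      f_w_minor[j] <- weighted_frequency(0, sf$n, fe_min, m_ext)
      next
    }
    fw_min <- weighted_frequency(sf$f_s, sf$n, fe_min, m_ext)
    fw_maj <- weighted_frequency(1 - sf$f_s, sf$n, fe_maj, m_ext)
    swap <- fw_maj < fw_min || (fw_maj == fw_min && a_maj < a_min)
    if (swap) {
      variants$allele_minor[j] <- a_maj
      variants$allele_major[j] <- a_min
      genotypes[, v$variant_id] <- 2L - genotypes[, v$variant_id]
      f_w_minor[j] <- fw_maj
      f_s_minor[j] <- 1 - sf$f_s
    } else {
      f_w_minor[j] <- fw_min
      f_s_minor[j] <- sf$f_s
    }
  }
  variants$f_w <- f_w_minor
  variants$f_s <- f_s_minor
  variants$n_sample <- n_sample
  list(genotypes = genotypes, variants = variants)
}
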