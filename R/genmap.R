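#' Haldane map function and its inverse
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under Haldane's no-interference model,
#' \deqn{\theta = 0.5 (1 - e^{-2 d / 100}),}
#' and back (`haldane_d`). Distances of 0 give theta = 0; theta approaches
#' the free-recombination limit 0.5 as d grows.
#'
#' @param d_cm genetic distance in cM (>= 0); vectorized.
#' @return recombination fraction in [0, 0.5).
#' @export
haldane_theta <- function(d_cm) {
  if (any(d_cm < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' @rdname haldane_theta
#' @param theta recombination fraction in [0, 0.5).
#' @export
haldane_d <- function(theta) {
  if (any(theta < 0 | theta >= 0.5)) stop("theta must lie in [0, 0.5)")
  -50 * log(1 - 2 * theta)
}

#' Interpolate genetic positions from a reference map
#'
#' Fills the `cm` column of a variant table by linear interpolation of the
#' sex-averaged Haldane positions of reference-map anchors against physical
#' position. Variants at an anchor bp take the anchor's cM exactly; between
#' anchors, cM is linear in bp. Beyond the first or last anchor the local
#' terminal slope is extended, clipped at 0 cM, so positions remain
#' non-decreasing in bp.
#'
#' @param variants variant table with `chrom` and `bp`.
#' @param reference_map data frame from [read_reference_map()]; every
#'   chromosome present among the variants needs at least 2 anchors.
#' @return the variant table with `cm` replaced.
#' @export
interpolate_cm <- function(variants, reference_map) {
  missing_chr <- setdiff(unique(variants$chrom), unique(reference_map$chrom))
  if (length(missing_chr) > 0L)
    stop("chromosome(s) absent from reference map: ",
         paste(missing_chr, collapse = ", "))
  for (ch in unique(variants$chrom)) {
    anch <- reference_map[reference_map$chrom == ch, ]
    anch <- anch[order(anch$bp), ]
    if (nrow(anch) < 2L)
      stop("reference map needs >= 2 anchors on chromosome ", ch)
    idx <- which(variants$chrom == ch)
    x <- variants$bp[idx]
    cm <- stats::approx(anch$bp, anch$cm, xout = x, rule = 2)$y
    # terminal-slope extrapolation outside the anchor span, clipped at 0
    k <- nrow(anch)
    lo <- x < anch$bp[1L]
    if (any(lo)) {
      slope <- (anch$cm[2L] - anch$cm[1L]) / (anch$bp[2L] - anch$bp[1L])
      cm[lo] <- pmax(0, anch$cm[1L] + slope * (x[lo] - anch$bp[1L]))
    }
    hi <- x > anch$bp[k]
    if (any(hi)) {
      slope <- (anch$cm[k] - anch$cm[k - 1L]) / (anch$bp[k] - anch$bp[k - 1L])
      cm[hi] <- pmax(0, anch$cm[k] + slope * (x[hi] - anch$bp[k]))
    }
    variants$cm[idx] <- cm
  }
  variants
}

#' Marker-pruning configuration
#'
#' Defaults follow the informative/independent selection criteria used to
#' prepare pedigree data for multipoint IBD and linkage computation:
#' weighted minor-allele frequency above 0.2, linkage-disequilibrium
#' pruning at a variance inflation factor of 1 (window 50 variants, step
#' 5, PLINK's documented window geometry), and a minimum inter-marker
#' spacing of 0.5 cM.
#'
#' @param maf_min minimum weighted minor-allele frequency (exclusive).
#' @param vif_max maximum variance inflation factor retained.
#' @param window,step sliding-window geometry for VIF pruning (variants).
#' @param min_spacing_cm minimum spacing between retained markers, cM.
#' @return list of class `prune_config`.
#' @export
prune_config <- function(maf_min = 0.2, vif_max = 1.0, window = 50L,
                         step = 5L, min_spacing_cm = 0.5) {
  stopifnot(maf_min >= 0, maf_min < 0.5, vif_max >= 1, window >= 2L,
            step >= 1L, min_spacing_cm >= 0)
  structure(list(maf_min = maf_min, vif_max = vif_max,
                 window = as.integer(window), step = as.integer(step),
                 min_spacing_cm = min_spacing_cm),
            class = "prune_config")
}

#' Select an informative, independent marker set
#'
#' Three sequential filters produce markers suitable for multipoint
#' engines that assume linkage equilibrium between markers:
#' \enumerate{
#'   \item informativeness: keep variants with weighted minor-allele
#'     frequency `f_w > maf_min`;
#'   \item LD pruning: sliding windows of `window` retained variants
#'     advancing by `step`; within a window, while any variant's variance
#'     inflation factor VIF = 1/(1 - R^2) (R^2 from regressing its 0/1/2
#'     dosage on the other retained window variants) exceeds
#'     `vif_max + 1e-9`, the variant with the largest VIF is removed
#'     (ties: the later variant goes);
#'   \item spacing: a left-to-right greedy scan keeps the first variant
#'     and drops any variant closer than `min_spacing_cm` to the last
#'     kept one.
#' }
#' Correlations use pairwise-complete dosages; monomorphic columns count
#' as VIF 1. The result is order-preserving and idempotent.
#'
#' @param genotypes dosage matrix (minor-allele counts).
#' @param variants variant table carrying `f_w` and `cm`.
#' @param config a [prune_config()].
#' @return character vector of retained variant ids, in genomic order.
#' @export
select_informative_independent <- function(genotypes, variants,
                                           config = prune_config()) {
  if (any(is.na(variants$cm)))
    stop("variants lack cM positions; run interpolate_cm() first")
  ord <- order(variants$chrom, variants$bp)
  variants <- variants[ord, , drop = FALSE]
  kept <- character(0)
  for (ch in unique(variants$chrom)) {
    sub <- variants[variants$chrom == ch, , drop = FALSE]
    ids <- sub$variant_id[!is.na(sub$f_w) & sub$f_w > config$maf_min]
    ids <- .vif_prune(genotypes, ids, config)
    ids <- .spacing_prune(ids, sub$cm[match(ids, sub$variant_id)],
                          config$min_spacing_cm)
    kept <- c(kept, ids)
  }
  kept
}

.vif_prune <- function(genotypes, ids, config) {
  eps <- 1e-9
  pos <- 1L
  repeat {
    if (length(ids) < 2L || pos > length(ids)) break
    win <- ids[pos:min(pos + config$window - 1L, length(ids))]
    if (length(win) >= 2L) {
      drop <- .vif_prune_window(genotypes[, win, drop = FALSE],
                                config$vif_max, eps)
      if (length(drop) > 0L) ids <- setdiff(ids, drop)
    }
    if (pos + config$window - 1L >= length(ids)) break
    pos <- pos + config$step
  }
  ids
}

# Iteratively removes the worst-VIF variant inside one window; returns the
# ids removed. VIFs come from the inverse correlation matrix of the dosage
# columns (pairwise-complete); exact collinearity is resolved by dropping
# the later member of a perfectly correlated pair.
.vif_prune_window <- function(X, vif_max, eps) {
  removed <- character(0)
  repeat {
    if (ncol(X) < 2L) break
    sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
    poly <- which(!is.na(sds) & sds > 0)
    if (length(poly) < 2L) break
    R <- suppressWarnings(
      stats::cor(X[, poly, drop = FALSE], use = "pairwise.complete.obs"))
    R[is.na(R)] <- 0
    diag(R) <- 1
    off <- R; diag(off) <- 0
    if (any(abs(off) >= 1 - 1e-12)) {
      w <- which(abs(off) >= 1 - 1e-12, arr.ind = TRUE)
      victim <- poly[max(w)]              # later column of the worst pair
      removed <- c(removed, colnames(X)[victim])
      X <- X[, -victim, drop = FALSE]
      next
    }
    vif <- tryCatch(diag(solve(R)), error = function(e) NULL)
    if (is.null(vif)) {                   # numerically singular window
      victim <- poly[length(poly)]
      removed <- c(removed, colnames(X)[victim])
      X <- X[, -victim, drop = FALSE]
      next
    }
    if (max(vif) <= vif_max + eps) break
    worst <- poly[max(which(vif == max(vif)))]
    removed <- c(removed, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  removed
}

.spacing_prune <- function(ids, cm, min_spacing_cm) {
  if (length(ids) == 0L) return(ids)
  keep <- logical(length(ids))
  keep[1L] <- TRUE
  last <- cm[1L]
  for (i in seq_along(ids)[-1L]) {
    if (cm[i] - last >= min_spacing_cm) {
      keep[i] <- TRUE
      last <- cm[i]
    }
  }
  ids[keep]
}
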