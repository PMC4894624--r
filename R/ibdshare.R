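#' IBD-sharing configuration
#'
#' @param grid_cm grid spacing in cM used when emitting or aligning IBD
#'   probability records (informational; records carry their own
#'   positions).
#' @param pair_threshold a pair shares a grid point identical-by-descent
#'   when P(IBD != 0) = 1 - p0 strictly exceeds this.
#' @param region_threshold grid points whose sharing statistic strictly
#'   exceeds this are merged into IBD regions.
#' @param scope `"pooled"` computes one statistic over all families'
#'   eligible pairs; `"per_family"` returns one track per family.
#' @return list of class `ibd_share_config`.
#' @export
ibd_share_config <- function(grid_cm = 1.0, pair_threshold = 0.5,
                             region_threshold = 0.5,
                             scope = c("pooled", "per_family")) {
  stopifnot(grid_cm > 0, pair_threshold > 0, pair_threshold < 1,
            region_threshold > 0, region_threshold <= 1)
  structure(list(grid_cm = grid_cm, pair_threshold = pair_threshold,
                 region_threshold = region_threshold,
                 scope = match.arg(scope)),
            class = "ibd_share_config")
}

#' IBD sharing statistic over a positional grid
#'
#' At each grid position, the proportion of eligible pairs sharing at
#' least one allele identical by descent. Eligible pairs are within-family
#' pairs of affected blood relatives, excluding parent-offspring pairs
#' (which always share exactly one allele IBD and are uninformative). A
#' pair counts as an IBD pair at a position when P(IBD != 0) = 1 - p0
#' strictly exceeds `pair_threshold`. Pairs without a record at a position
#' drop out of both numerator and denominator there.
#'
#' @param ped a [pedigree()] table.
#' @param ibd IBD probability records from [read_ibd_table()].
#' @param config an [ibd_share_config()].
#' @return data frame (`score_track`) with `position`, `value`,
#'   `n_pairs`; under `scope = "per_family"` an additional `fid` column.
#' @export
sharing_statistic <- function(ped, ibd, config = ibd_share_config()) {
  pairs <- eligible_pairs(ped)
  if (nrow(pairs) == 0L)
    stop("no eligible affected relative pairs (scope: ",
         config$scope, ")")
  pk <- paste(pairs$fid, pmin(pairs$id1, pairs$id2),
              pmax(pairs$id1, pairs$id2))
  rk <- paste(ibd$fid, pmin(ibd$id1, ibd$id2), pmax(ibd$id1, ibd$id2))
  rec <- ibd[rk %in% pk, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("IBD table contains no records for the eligible pairs")
  rec$is_ibd <- (1 - rec$p0) > config$pair_threshold
  if (config$scope == "pooled") {
    agg <- stats::aggregate(is_ibd ~ position, data = rec,
                            FUN = function(x) c(mean(x), length(x)))
    out <- data.frame(position = agg$position,
                      value = agg$is_ibd[, 1L],
                      n_pairs = as.integer(agg$is_ibd[, 2L]))
    out <- out[order(out$position), , drop = FALSE]
  } else {
    agg <- stats::aggregate(is_ibd ~ fid + position, data = rec,
                            FUN = function(x) c(mean(x), length(x)))
    out <- data.frame(fid = agg$fid, position = agg$position,
                      value = agg$is_ibd[, 1L],
                      n_pairs = as.integer(agg$is_ibd[, 2L]))
    out <- out[order(out$fid, out$position), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Eligible affected relative pairs for IBD sharing
#'
#' Within-family pairs where both members are affected, the pair is a
#' blood-relative pair (positive kinship) and not parent-offspring.
#'
#' @param ped a [pedigree()] table.
#' @return data frame `fid`, `id1`, `id2`, `kinship`.
#' @export
eligible_pairs <- function(ped) {
  out <- list()
  for (f in unique(ped$fid)) {
    sub <- ped[ped$fid == f, , drop = FALSE]
    affected <- sub$iid[sub$affection == "affected"]
    if (length(affected) < 2L) next
    K <- kinship_matrix(sub)
    for (i in seq_along(affected)[-length(affected)]) {
      for (j in seq((i + 1L), length(affected))) {
        id1 <- affected[i]; id2 <- affected[j]
        cls <- classify_pair(sub, id1, id2)
        if (cls == "other_blood_relative")
          out[[length(out) + 1L]] <-
            data.frame(fid = f, id1 = id1, id2 = id2,
                       kinship = K[id1, id2], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(fid = character(), id1 = character(),
                      id2 = character(), kinship = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Project a grid score track onto variants
#'
#' Each variant takes the value of the grid point at or immediately to the
#' left of its cM position (left-closed grid intervals). Variants outside
#' the grid span take the nearest grid endpoint and are flagged in the
#' `extrapolated` column.
#'
#' @param track data frame with `position` and `value` (one chromosome).
#' @param variants variant table with `cm`.
#' @return data frame `variant_id`, `cm`, `value`, `extrapolated`.
#' @export
project_to_variants <- function(track, variants) {
  stopifnot(nrow(track) > 0L)
  tr <- track[order(track$position), , drop = FALSE]
  idx <- findInterval(variants$cm, tr$position)
  extrapolated <- idx == 0L | variants$cm > tr$position[nrow(tr)]
  idx[idx == 0L] <- 1L
  data.frame(variant_id = variants$variant_id, cm = variants$cm,
             value = tr$value[idx], extrapolated = extrapolated,
             stringsAsFactors = FALSE)
}

#' Call threshold-exceeding regions on a score track
#'
#' Maximal runs of consecutive grid points whose value strictly exceeds
#' (`direction = "above"`) or falls strictly below (`"below"`) the
#' threshold. Used both for IBD regions (sharing statistic above a
#' threshold) and for linkage-style tracks (LOD above a threshold, or
#' p-values below one).
#'
#' @param track data frame with `position`, `value`, and optionally
#'   `chrom`.
#' @param threshold calling threshold.
#' @param direction `"above"` or `"below"`.
#' @return data frame `chrom` (if present), `start_cm`, `end_cm`,
#'   `peak_value`, `n_grid_points`; zero rows when nothing exceeds.
#' @export
call_regions <- function(track, threshold,
                         direction = c("above", "below")) {
  direction <- match.arg(direction)
  empty <- data.frame(chrom = character(), start_cm = numeric(),
                      end_cm = numeric(), peak_value = numeric(),
                      n_grid_points = integer(), stringsAsFactors = FALSE)
  if (nrow(track) == 0L) return(empty)
  if (is.null(track$chrom)) track$chrom <- "."
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$position), , drop = FALSE]
    hit <- if (direction == "above") tr$value > threshold
           else tr$value < threshold
    if (!any(hit)) next
    runs <- rle(hit)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      i <- starts[k]:ends[k]
      peak <- if (direction == "above") max(tr$value[i]) else min(tr$value[i])
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start_cm = tr$position[i[1L]],
                   end_cm = tr$position[i[length(i)]],
                   peak_value = peak, n_grid_points = length(i),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write called regions as a BED-like table
#'
#' Tab-delimited with a header line documenting that coordinates are in
#' centimorgans: `chrom`, `start_cm`, `end_cm`, `peak_value`,
#' `n_grid_points`.
#' @param regions output of [call_regions()].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates in cM (sex-averaged Haldane scale)", con)
  utils::write.table(regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
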