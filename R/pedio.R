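# Internal key joining family and individual ids; PLINK individual ids are
# only unique within a family.
.key <- function(fid, iid) paste(fid, iid, sep = ":")

#' Construct and validate a pedigree table
#'
#' A pedigree is a base data frame with one row per individual and columns
#' `fid`, `iid`, `father`, `mother` (`NA` for founders), `sex`
#' (`"male"`, `"female"`, `"unknown"`) and `affection` (`"affected"`,
#' `"unaffected"`, `"unknown"`). Multiple families may share one table.
#'
#' Validation enforces: unique individual ids within a family, parent ids
#' that resolve within the same family, both parents present or both absent
#' (half-specified parents are rejected so founder counts stay well
#' defined), acyclicity, and sex-consistent parent roles where sex is known.
#'
#' @param fid,iid,father,mother,sex,affection vectors of equal length;
#'   `father`/`mother` use `NA` (or `"0"`) for founders.
#' @return A `data.frame` of class `"pedigree"`.
#' @export
pedigree <- function(fid, iid, father = NA, mother = NA,
                     sex = "unknown", affection = "unknown") {
  ped <- data.frame(
    fid = as.character(fid), iid = as.character(iid),
    father = as.character(father), mother = as.character(mother),
    sex = as.character(sex), affection = as.character(affection),
    stringsAsFactors = FALSE
  )
  ped$father[ped$father %in% c("0", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "")] <- NA_character_
  validate_pedigree(ped)
}

#' @rdname pedigree
#' @param ped a candidate pedigree data frame.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("fid", "iid", "father", "mother", "sex", "affection") %in%
                  names(ped)))
  if (nrow(ped) < 1L) stop("pedigree must contain at least one individual")
  if (!all(ped$sex %in% c("male", "female", "unknown")))
    stop("sex must be one of 'male', 'female', 'unknown'")
  if (!all(ped$affection %in% c("affected", "unaffected", "unknown")))
    stop("affection must be one of 'affected', 'unaffected', 'unknown'")
  dup <- duplicated(.key(ped$fid, ped$iid))
  if (any(dup))
    stop("duplicate individual id(s) within family: ",
         paste(.key(ped$fid, ped$iid)[dup], collapse = ", "))
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("individual(s) with exactly one parent specified: ",
         paste(.key(ped$fid, ped$iid)[half], collapse = ", "))
  keys <- .key(ped$fid, ped$iid)
  for (col in c("father", "mother")) {
    ref <- !is.na(ped[[col]])
    bad <- ref & !(.key(ped$fid, ped[[col]]) %in% keys)
    if (any(bad))
      stop("unknown ", col, " id for individual(s): ",
           paste(sprintf("%s (%s=%s)", .key(ped$fid, ped$iid)[bad],
                         col, ped[[col]][bad]), collapse = ", "))
  }
  fsex <- ped$sex[match(.key(ped$fid, ped$father), keys)]
  if (any(!is.na(ped$father) & !is.na(fsex) & fsex == "female"))
    stop("a recorded father has sex 'female'")
  msex <- ped$sex[match(.key(ped$fid, ped$mother), keys)]
  if (any(!is.na(ped$mother) & !is.na(msex) & msex == "male"))
    stop("a recorded mother has sex 'male'")
  # acyclicity: repeatedly strip individuals whose parents are all stripped
  for (f in unique(ped$fid)) {
    sub <- ped[ped$fid == f, , drop = FALSE]
    if (is.na(.topological_order(sub)[1L]) && nrow(sub) > 0L)
      stop("pedigree for family ", f, " contains a cycle")
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Returns row indices of a single-family pedigree in founder-first
# topological order, or NA if the parent graph is cyclic.
.topological_order <- function(sub) {
  n <- nrow(sub)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(sub$father) | sub$father %in% sub$iid[placed]) &
      (is.na(sub$mother) | sub$mother %in% sub$iid[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) return(NA_integer_)
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  fams <- unique(x$fid)
  cat(sprintf("Pedigree table: %d individual(s) in %d family(ies)\n",
              nrow(x), length(fams)))
  cat(sprintf("  founders: %d, non-founders: %d, affected: %d\n",
              sum(is.na(x$father)), sum(!is.na(x$father)),
              sum(x$affection == "affected")))
  NextMethod()
  invisible(x)
}

#' Read PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PLINK text pedigree/genotype files. The PED
#' file carries six leading columns (family id, individual id, father,
#' mother, sex, phenotype) followed by two allele columns per variant; the
#' MAP file carries chromosome, variant id, genetic position (cM) and
#' physical position (bp). The pair `0 0` denotes a missing genotype.
#'
#' Genotypes are returned as minor-allele dosages (0, 1, 2, or `NA`)
#' relative to a provisional minor allele chosen by sample allele count
#' (ties broken alphabetically). [assign_minor_alleles()] finalizes the
#' orientation once weighted frequencies are available.
#'
#' Sex codes follow PLINK (1 = male, 2 = female, other = unknown), as do
#' phenotype codes (1 = unaffected, 2 = affected, 0/-9 = unknown).
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A list with elements `pedigree` (see [pedigree()]), `genotypes`
#'   (integer dosage matrix, rows keyed `fid:iid`, columns by variant id)
#'   and `variants` (a variant table: `variant_id`, `chrom`, `bp`, `cm`,
#'   `allele_minor`, `allele_major`, `f_w`).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- .read_token_lines(map_path)
  if (length(map_lines) > 0L) {
    nfield <- lengths(map_lines)
    if (any(nfield != 4L))
      stop(sprintf("%s: line %d has %d fields, expected 4 (chrom id cM bp)",
                   map_path, which(nfield != 4L)[1L],
                   nfield[nfield != 4L][1L]))
  }
  map <- as.data.frame(do.call(rbind, map_lines), stringsAsFactors = FALSE)
  if (nrow(map) > 0L) {
    names(map) <- c("chrom", "variant_id", "cm", "bp")
    map$cm <- as.numeric(map$cm)
    map$bp <- as.integer(map$bp)
    if (anyDuplicated(map$variant_id))
      stop(map_path, ": duplicate variant id(s): ",
           paste(unique(map$variant_id[duplicated(map$variant_id)]),
                 collapse = ", "))
  } else {
    map <- data.frame(chrom = character(), variant_id = character(),
                      cm = numeric(), bp = integer(),
                      stringsAsFactors = FALSE)
  }
  nvar <- nrow(map)

  ped_lines <- .read_token_lines(ped_path)
  nfield <- lengths(ped_lines)
  expect <- 6L + 2L * nvar
  if (any(nfield != expect))
    stop(sprintf("%s: line %d has %d fields, expected %d (6 + 2 x %d variants)",
                 ped_path, which(nfield != expect)[1L],
                 nfield[nfield != expect][1L], expect, nvar))
  n <- length(ped_lines)
  if (n == 0L) stop(ped_path, ": empty PED file")
  pm <- do.call(rbind, ped_lines)

  sex <- c("1" = "male", "2" = "female")[pm[, 5L]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[pm[, 6L]]
  aff[is.na(aff)] <- "unknown"
  ped <- pedigree(fid = pm[, 1L], iid = pm[, 2L],
                  father = pm[, 3L], mother = pm[, 4L],
                  sex = sex, affection = aff)

  a1 <- pm[, 6L + 2L * seq_len(nvar) - 1L, drop = FALSE]
  a2 <- pm[, 6L + 2L * seq_len(nvar), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: line %d, variant %s: half-missing genotype",
                 ped_path, w[1L], map$variant_id[w[2L]]))
  }

  geno <- matrix(NA_integer_, n, nvar,
                 dimnames = list(.key(ped$fid, ped$iid), map$variant_id))
  allele_minor <- allele_major <- rep(NA_character_, nvar)
  for (j in seq_len(nvar)) {
    al <- c(a1[, j], a2[, j])
    tab <- table(al[!is.na(al)])
    if (length(tab) > 2L)
      stop(sprintf("%s: variant %s has %d alleles; diallelic data required",
                   ped_path, map$variant_id[j], length(tab)))
    if (length(tab) == 0L) next            # all missing: orientation undefined
    alleles <- names(sort(tab))            # ascending count; stable name order
    if (length(tab) == 1L) {
      allele_major[j] <- alleles[1L]
      allele_minor[j] <- NA_character_
      geno[, j] <- ifelse(is.na(a1[, j]), NA_integer_, 0L)
    } else {
      if (tab[[1L]] == tab[[2L]]) alleles <- sort(names(tab))  # tie: alphabetical minor
      allele_minor[j] <- alleles[1L]
      allele_major[j] <- alleles[2L]
      geno[, j] <- (a1[, j] == alleles[1L]) + (a2[, j] == alleles[1L])
    }
  }

  variants <- data.frame(
    variant_id = map$variant_id, chrom = map$chrom, bp = map$bp, cm = map$cm,
    allele_minor = allele_minor, allele_major = allele_major,
    f_w = rep(NA_real_, nvar), stringsAsFactors = FALSE
  )
  ord <- order(variants$chrom, variants$bp)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  geno <- geno[, variants$variant_id, drop = FALSE]
  list(pedigree = ped, genotypes = geno, variants = variants)
}

.read_token_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  lapply(raw, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]. Genotype dosages are expanded to allele
#' pairs using the variant table's minor/major allele labels; missing
#' dosages become `0 0`. Reading the files back reproduces the genotype
#' matrix up to allele-label orientation.
#'
#' @param ped a [pedigree()] table.
#' @param genotypes dosage matrix as returned by [read_ped_map()].
#' @param variants variant table; where allele labels are missing
#'   (monomorphic or all-missing columns), placeholder labels `A`/`B` are
#'   written.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(ped, genotypes, variants, ped_path, map_path) {
  stopifnot(nrow(genotypes) == nrow(ped),
            ncol(genotypes) == nrow(variants))
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  affcode <- c(unaffected = "1", affected = "2", unknown = "0")[ped$affection]
  minor <- ifelse(is.na(variants$allele_minor), "A", variants$allele_minor)
  major <- ifelse(is.na(variants$allele_major), "B", variants$allele_major)
  n <- nrow(ped); nv <- nrow(variants)
  allele_cols <- matrix("0", n, 2L * nv)
  for (j in seq_len(nv)) {
    g <- genotypes[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, minor[j], major[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, minor[j], major[j]))
    allele_cols[, 2L * j - 1L] <- a1
    allele_cols[, 2L * j] <- a2
  }
  lead <- cbind(ped$fid, ped$iid,
                ifelse(is.na(ped$father), "0", ped$father),
                ifelse(is.na(ped$mother), "0", ped$mother),
                sexcode, affcode)
  writeLines(apply(cbind(lead, allele_cols), 1L, paste, collapse = " "),
             ped_path)
  map <- cbind(variants$chrom, variants$variant_id,
               format(variants$cm, trim = TRUE, scientific = FALSE),
               variants$bp)
  writeLines(if (nv > 0L) apply(map, 1L, paste, collapse = "\t") else character(),
             map_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a Merlin-style pairwise IBD table
#'
#' Whitespace-delimited columns: family id, individual id 1, individual id
#' 2, position (cM grid point or marker token), and the three IBD state
#' probabilities P(IBD=0), P(IBD=1), P(IBD=2). A header line (first field
#' non-numeric in the probability columns) is skipped. Probabilities must
#' lie on the simplex within 1e-6.
#'
#' @param path input path.
#' @return data frame `fid`, `id1`, `id2`, `position` (numeric where
#'   possible), `p0`, `p1`, `p2`.
#' @export
read_ibd_table <- function(path) {
  lines <- .read_token_lines(path)
  if (length(lines) == 0L)
    return(data.frame(fid = character(), id1 = character(), id2 = character(),
                      position = numeric(), p0 = numeric(), p1 = numeric(),
                      p2 = numeric(), stringsAsFactors = FALSE))
  nfield <- lengths(lines)
  if (any(nfield != 7L))
    stop(sprintf("%s: line %d has %d fields, expected 7", path,
                 which(nfield != 7L)[1L], nfield[nfield != 7L][1L]))
  m <- do.call(rbind, lines)
  first_data <- 1L
  if (is.na(suppressWarnings(as.numeric(m[1L, 5L])))) first_data <- 2L
  if (first_data > nrow(m))
    return(read_ibd_table_empty())
  m <- m[seq(first_data, nrow(m)), , drop = FALSE]
  out <- data.frame(
    fid = m[, 1L], id1 = m[, 2L], id2 = m[, 3L],
    position = suppressWarnings(as.numeric(m[, 4L])),
    p0 = as.numeric(m[, 5L]), p1 = as.numeric(m[, 6L]),
    p2 = as.numeric(m[, 7L]), stringsAsFactors = FALSE
  )
  if (any(out$id1 == out$id2))
    stop(path, ": self-pair (id1 == id2) at line ",
         which(out$id1 == out$id2)[1L] + first_data - 1L)
  s <- out$p0 + out$p1 + out$p2
  bad <- abs(s - 1) > 1e-6 | out$p0 < 0 | out$p1 < 0 | out$p2 < 0
  if (any(bad))
    stop(sprintf("%s: line %d: IBD probabilities sum to %.6g, not 1 (tolerance 1e-6)",
                 path, which(bad)[1L] + first_data - 1L, s[which(bad)[1L]]))
  out
}

read_ibd_table_empty <- function() {
  data.frame(fid = character(), id1 = character(), id2 = character(),
             position = numeric(), p0 = numeric(), p1 = numeric(),
             p2 = numeric(), stringsAsFactors = FALSE)
}

#' Write a pairwise IBD table in Merlin-style layout
#' @param ibd data frame as returned by [read_ibd_table()].
#' @param path output path.
#' @export
write_ibd_table <- function(ibd, path) {
  writeLines(c("FAMILY ID1 ID2 POSITION P0 P1 P2",
               sprintf("%s %s %s %s %g %g %g", ibd$fid, ibd$id1, ibd$id2,
                       format(ibd$position, trim = TRUE, scientific = FALSE),
                       ibd$p0, ibd$p1, ibd$p2)),
             path)
  invisible(path)
}

#' Read an external allele-frequency table
#'
#' Tab-delimited with header: `variant_id`, `chrom`, `bp`, `allele`,
#' `freq`, `allele_count`. `freq` is the population frequency of `allele`
#' and `allele_count` the number of observed alleles behind it.
#'
#' @param path input path.
#' @return data frame with those columns.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer",
                                          "character", "numeric", "integer"))
  names(tab) <- c("variant_id", "chrom", "bp", "allele", "freq", "allele_count")
  if (any(tab$freq < 0 | tab$freq > 1))
    stop(path, ": frequency outside [0, 1]")
  if (any(tab$allele_count < 0))
    stop(path, ": negative allele count")
  tab
}

#' Read a variant-to-gene assignment table
#'
#' Tab-delimited, two columns with header: `variant_id`, `gene_id`.
#' @param path input path.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  names(tab) <- c("variant_id", "gene_id")
  tab
}

#' Read a reference genetic map
#'
#' Tab-delimited with header: `chrom`, `bp`, `cm` (sex-averaged Haldane
#' positions). Within each chromosome, bp must be strictly increasing and
#' cM non-decreasing.
#' @param path input path.
#' @export
read_reference_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "numeric"))
  names(tab) <- c("chrom", "bp", "cm")
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    if (any(diff(sub$bp) <= 0))
      stop(path, ": duplicate bp anchors on chromosome ", ch)
    if (any(diff(sub$cm) < 0))
      stop(path, ": cM not non-decreasing on chromosome ", ch)
  }
  tab
}

#' Kinship coefficient between two pedigree members
#'
#' Standard recursive kinship: founders are mutually unrelated,
#' phi(i, i) = 0.5 (1 + phi(father_i, mother_i)), and for i not an ancestor
#' of j, phi(i, j) = 0.5 (phi(father_i, j) + phi(mother_i, j)).
#'
#' @param ped a [pedigree()] table (one or more families).
#' @param id1,id2 individual ids; `fid` disambiguates when ids repeat
#'   across families.
#' @param fid family id; may be omitted when `ped` holds a single family.
#' @return Kinship coefficient in [0, 0.5].
#' @export
kinship <- function(ped, id1, id2, fid = NULL) {
  sub <- .family_of(ped, c(id1, id2), fid)
  K <- kinship_matrix(sub)
  K[id1, id2]
}

#' @rdname kinship
#' @return `kinship_matrix` returns the full symmetric kinship matrix of a
#'   single-family pedigree, with individual ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(length(unique(ped$fid)) == 1L)
  ord <- .topological_order(ped)
  sub <- ped[ord, , drop = FALSE]
  n <- nrow(sub)
  K <- matrix(0, n, n, dimnames = list(sub$iid, sub$iid))
  fa <- match(sub$father, sub$iid)
  mo <- match(sub$mother, sub$iid)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      # parents precede i in topological order, so rows < i are complete
      for (j in seq_len(i - 1L)) {
        K[i, j] <- K[j, i] <- 0.5 * (K[fa[i], j] + K[mo[i], j])
      }
    }
  }
  K[ped$iid, ped$iid, drop = FALSE]
}

.family_of <- function(ped, ids, fid = NULL) {
  if (!is.null(fid)) {
    sub <- ped[ped$fid == fid, , drop = FALSE]
    if (nrow(sub) == 0L) stop("unknown family id: ", fid)
  } else {
    hit <- unique(ped$fid[ped$iid %in% ids])
    if (length(hit) == 0L) stop("unknown individual id(s): ",
                                paste(ids, collapse = ", "))
    if (length(hit) > 1L)
      stop("ids match multiple families; pass fid explicitly")
    sub <- ped[ped$fid == hit, , drop = FALSE]
  }
  missing_ids <- setdiff(ids, sub$iid)
  if (length(missing_ids) > 0L)
    stop("unknown individual id(s) in family ", sub$fid[1L], ": ",
         paste(missing_ids, collapse = ", "))
  sub
}

#' Classify the relationship of a pair of pedigree members
#'
#' Returns `"parent_offspring"` when one is a recorded parent of the other,
#' `"other_blood_relative"` for any other pair with positive kinship, and
#' `"unrelated"` otherwise. Parent-offspring pairs always share exactly one
#' allele identical by descent, which is why downstream IBD-sharing
#' statistics exclude them.
#'
#' @inheritParams kinship
#' @return One of `"parent_offspring"`, `"other_blood_relative"`,
#'   `"unrelated"`.
#' @export
classify_pair <- function(ped, id1, id2, fid = NULL) {
  sub <- .family_of(ped, c(id1, id2), fid)
  r1 <- sub[sub$iid == id1, ]
  r2 <- sub[sub$iid == id2, ]
  po <- (!is.na(r1$father) && r1$father == id2) ||
    (!is.na(r1$mother) && r1$mother == id2) ||
    (!is.na(r2$father) && r2$father == id1) ||
    (!is.na(r2$mother) && r2$mother == id1)
  if (po) return("parent_offspring")
  if (kinship_matrix(sub)[id1, id2] > 0) "other_blood_relative" else "unrelated"
}

#' Pedigree bit size
#'
#' Complexity measure governing exact pedigree-likelihood algorithms:
#' twice the number of non-founders minus the number of founders. Used to
#' decide whether a pedigree must be split before exact IBD/linkage
#' computation. Degenerate all-founder pedigrees yield a negative value.
#'
#' @param ped a [pedigree()] table; summed over families if several.
#' @return Integer bit size.
#' @export
bit_size <- function(ped) {
  nonf <- sum(!is.na(ped$father))
  2L * nonf - (nrow(ped) - nonf)
}
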