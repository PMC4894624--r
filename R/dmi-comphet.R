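#' Compound-heterozygosity filter configuration
#'
#' @param min_rule_proportion proportion of affected individuals (rules
#'   1-2) or affected children (rule 3) that must follow a rule for a
#'   variant to pass; 1 demands error-free adherence, the default 0.95
#'   tolerates occasional genotyping errors.
#' @param apply_rule5 `"auto"` skips the transmission rule when any
#'   affected child has an affected parent (the disease alleles then
#'   necessarily come from that parent, so requiring biparental
#'   transmission would be wrong); `"always"`/`"never"` force it.
#' @return list of class `comphet_config`.
#' @export
comphet_config <- function(min_rule_proportion = 0.95,
                           apply_rule5 = c("auto", "always", "never")) {
  stopifnot(min_rule_proportion > 0, min_rule_proportion <= 1)
  structure(list(min_rule_proportion = min_rule_proportion,
                 apply_rule5 = match.arg(apply_rule5)),
            class = "comphet_config")
}

#' Scan genes for compound-heterozygous configurations
#'
#' Applies five filtering rules for recessive compound heterozygosity,
#' where an affected individual carries two distinct heterozygous variants
#' in the same gene, one inherited from each parent. Variant-level rules
#' (proportions computed over genotyped individuals only):
#' \enumerate{
#'   \item the variant is heterozygous in (at least
#'     `min_rule_proportion` of) the affected individuals;
#'   \item the variant is not homozygous for the disease (minor) allele in
#'     (at least `min_rule_proportion` of) the unaffected individuals;
#'   \item among affected children heterozygous at the variant with both
#'     parents genotyped, at most one parent is heterozygous (for at
#'     least `min_rule_proportion` of such children).
#' }
#' Gene-level rules: (4) at least two variants pass rules 1-3; (5) among
#' the passing variants, at least one shows paternal and a different one
#' maternal transmission. A transmission is assigned when a heterozygous
#' affected child has exactly one minor-allele-carrying genotyped parent;
#' both-parents-heterozygous configurations are phase-ambiguous and carry
#' no rule-5 evidence. Empty rule denominators pass vacuously. Genes with
#' no mapped variants are absent from the output; if no genotyped affected
#' individual exists, every gene fails with a note.
#'
#' @param ped a [pedigree()] table (families pooled).
#' @param genotypes dosage matrix oriented by [assign_minor_alleles()].
#' @param variants variant table.
#' @param gene_map data frame `variant_id`, `gene_id`.
#' @param config a [comphet_config()].
#' @return list of class `comphet_result`: `genes` (one row per gene:
#'   `gene_id`, `n_variants`, `n_pass123`, `rule4`, `rule5`,
#'   `rule5_applied`, `pass`) and `variants` (per variant: rule-1/2/3
#'   proportions and flags, transmission evidence).
#' @export
compound_het_scan <- function(ped, genotypes, variants, gene_map,
                              config = comphet_config()) {
  gene_map <- gene_map[gene_map$variant_id %in% colnames(genotypes), ,
                       drop = FALSE]
  keys <- .key(ped$fid, ped$iid)
  stopifnot(all(rownames(genotypes) %in% keys))
  ped <- ped[match(rownames(genotypes), keys), , drop = FALSE]

  aff <- ped$affection == "affected"
  unaff <- ped$affection == "unaffected"
  any_affected <- any(aff & apply(!is.na(genotypes), 1L, any))

  # affected children with both parents genotyped (row indices)
  child_rows <- which(aff & !is.na(ped$father))
  fa_rows <- match(.key(ped$fid, ped$father), .key(ped$fid, ped$iid))[child_rows]
  mo_rows <- match(.key(ped$fid, ped$mother), .key(ped$fid, ped$iid))[child_rows]

  affected_parent <- any(!is.na(fa_rows) & aff[fa_rows]) ||
    any(!is.na(mo_rows) & aff[mo_rows])
  rule5_applied <- switch(config$apply_rule5,
                          always = TRUE, never = FALSE,
                          auto = !affected_parent)

  p_min <- config$min_rule_proportion
  vt <- lapply(unique(gene_map$variant_id), function(v) {
    g <- genotypes[, v]
    gen_aff <- aff & !is.na(g)
    gen_unaff <- unaff & !is.na(g)
    r1_prop <- if (sum(gen_aff) > 0L) mean(g[gen_aff] == 1L) else 1
    r2_prop <- if (sum(gen_unaff) > 0L) mean(g[gen_unaff] != 2L) else 1
    # rule 3 + transmission over affected het children with genotyped parents
    het_child <- child_rows[!is.na(g[child_rows]) & g[child_rows] == 1L &
                              !is.na(fa_rows) & !is.na(mo_rows)]
    fa_g <- g[fa_rows[match(het_child, child_rows)]]
    mo_g <- g[mo_rows[match(het_child, child_rows)]]
    both_typed <- !is.na(fa_g) & !is.na(mo_g)
    r3_den <- sum(both_typed)
    r3_prop <- if (r3_den > 0L)
      mean(fa_g[both_typed] != 1L | mo_g[both_typed] != 1L) else 1
    fa_carrier <- !is.na(fa_g) & fa_g >= 1L
    mo_carrier <- !is.na(mo_g) & mo_g >= 1L
    data.frame(variant_id = v,
               r1 = r1_prop >= p_min, r2 = r2_prop >= p_min,
               r3 = r3_prop >= p_min,
               r1_prop = r1_prop, r2_prop = r2_prop, r3_prop = r3_prop,
               paternal = any(both_typed & fa_carrier & !mo_carrier),
               maternal = any(both_typed & mo_carrier & !fa_carrier),
               stringsAsFactors = FALSE)
  })
  vt <- do.call(rbind, vt)
  vt$pass123 <- any_affected & vt$r1 & vt$r2 & vt$r3
  vt$gene_id <- gene_map$gene_id[match(vt$variant_id, gene_map$variant_id)]

  genes <- lapply(unique(gene_map$gene_id), function(gid) {
    sub <- vt[vt$gene_id == gid, , drop = FALSE]
    pass_v <- sub[sub$pass123, , drop = FALSE]
    rule4 <- nrow(pass_v) >= 2L
    rule5 <- if (!rule5_applied) TRUE else {
      # need paternal evidence at one passing variant, maternal at another
      ok <- FALSE
      if (nrow(pass_v) >= 2L && any(pass_v$paternal) && any(pass_v$maternal)) {
        for (i in which(pass_v$paternal)) {
          if (any(pass_v$maternal[-i])) { ok <- TRUE; break }
        }
      }
      ok
    }
    data.frame(gene_id = gid, n_variants = nrow(sub),
               n_pass123 = nrow(pass_v), rule4 = rule4, rule5 = rule5,
               rule5_applied = rule5_applied,
               pass = any_affected & rule4 & rule5,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, genes)
  rownames(genes) <- rownames(vt) <- NULL
  structure(list(genes = genes, variants = vt,
                 any_affected = any_affected),
            class = "comphet_result")
}

#' @export
print.comphet_result <- function(x, ...) {
  cat(sprintf("Compound-heterozygosity scan: %d gene(s), %d passing\n",
              nrow(x$genes), sum(x$genes$pass)))
  if (!x$any_affected)
    cat("  note: no genotyped affected individuals; all genes fail\n")
  print(x$genes, ...)
  invisible(x)
}
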