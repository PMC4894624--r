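#' Pipeline run configuration
#'
#' Validates input paths and module toggles before any stage runs. Every
#' enabled stage must be able to find its inputs; disabled stages are
#' skipped and their result columns reported as `NA`.
#'
#' @param ped,map paths to the PLINK text PED/MAP pair (required).
#' @param freq optional external frequency table ([read_frequency_table()]).
#' @param ibd optional Merlin-style pairwise IBD table.
#' @param genemap optional variant-to-gene table (required for the
#'   weighted-sum and compound-het stages).
#' @param refmap optional reference genetic map (required for the
#'   map-update stage).
#' @param modules character vector of stages to run, among
#'   `"map-update"`, `"afe"`, `"prune"`, `"dmi"`, `"ibd-share"`,
#'   `"regions"`. `"afe"` is always required.
#' @param out_dir output directory.
#' @param seed integer seed for permutation p-values.
#' @param n_permutations permutations for the weighted-sum stage.
#' @param prune a [prune_config()].
#' @param comphet a [comphet_config()].
#' @param ibd_share an [ibd_share_config()].
#' @param region_threshold,region_direction region calling on the IBD
#'   sharing track.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(ped, map, freq = NULL, ibd = NULL, genemap = NULL,
                       refmap = NULL,
                       modules = c("afe", "dmi"),
                       out_dir = "pedscreen-out", seed = 1L,
                       n_permutations = 1000L,
                       prune = prune_config(),
                       comphet = comphet_config(),
                       ibd_share = ibd_share_config(),
                       region_threshold = 0.5,
                       region_direction = "above") {
  known <- c("map-update", "afe", "prune", "dmi", "ibd-share", "regions")
  if (length(modules) == 0L)
    stop("validation error: no modules enabled")
  bad <- setdiff(modules, known)
  if (length(bad) > 0L)
    stop("validation error: unknown module(s): ", paste(bad, collapse = ", "))
  modules <- union(modules, "afe")      # downstream stages need f_w
  need <- function(path, label, stage) {
    if (is.null(path))
      stop("validation error: stage '", stage, "' requires ", label)
    if (!file.exists(path))
      stop("validation error: ", label, " not found: ", path)
  }
  need(ped, "a PED file", "input"); need(map, "a MAP file", "input")
  if ("map-update" %in% modules) need(refmap, "a reference map", "map-update")
  if ("dmi" %in% modules && !is.null(genemap)) need(genemap, "a gene map", "dmi")
  if ("ibd-share" %in% modules) need(ibd, "an IBD table", "ibd-share")
  if ("regions" %in% modules && !("ibd-share" %in% modules))
    stop("validation error: 'regions' requires 'ibd-share'")
  for (p in list(freq, genemap)) if (!is.null(p) && !file.exists(p))
    stop("validation error: input not found: ", p)
  structure(list(ped = ped, map = map, freq = freq, ibd = ibd,
                 genemap = genemap, refmap = refmap, modules = modules,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 prune = prune, comphet = comphet, ibd_share = ibd_share,
                 region_threshold = region_threshold,
                 region_direction = region_direction),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in fixed order: map update, weighted
#' allele-frequency estimation, marker pruning, disease-model
#' identification (segregation scores under both models, weighted-sum per
#' gene, compound-het rules) and IBD sharing with region calling.
#' Chromosomes are processed as independent sequential batches, so the
#' output is identical however the work is split. A merged tab-delimited
#' results table carries one row per input variant regardless of pruning
#' (pruning narrows analysis marker sets, never the reporting universe),
#' and a run log records the configuration, seed and per-stage timings.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the merged `results` data frame, the
#'   `regions` table (if called), and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("pedscreen %s",
                         as.character(utils::packageVersion("pedscreen"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("modules: %s", paste(config$modules, collapse = ",")))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %s: %.2fs", name,
                                       proc.time()[["elapsed"]] - t0))
    val
  }

  data <- t_stage("read", read_ped_map(config$ped, config$map))
  ped <- data$pedigree
  variants <- data$variants
  geno <- data$genotypes

  if ("map-update" %in% config$modules) {
    refmap <- read_reference_map(config$refmap)
    variants <- t_stage("map-update", interpolate_cm(variants, refmap))
  }

  freq_tab <- if (!is.null(config$freq)) read_frequency_table(config$freq)
  oriented <- t_stage("afe", assign_minor_alleles(geno, variants, freq_tab))
  geno <- oriented$genotypes
  variants <- oriented$variants

  results <- variants[, c("variant_id", "chrom", "bp", "cm", "allele_minor",
                          "allele_major", "f_w")]
  results$pruned_in <- NA
  results$seg_dominant <- NA_real_
  results$seg_recessive <- NA_real_
  results$gene_id <- NA_character_
  results$ws_p <- NA_real_
  results$ch_pass123 <- NA
  results$ch_gene_pass <- NA
  results$ibd_sharing <- NA_real_
  results$in_region <- NA

  if ("prune" %in% config$modules) {
    kept <- t_stage("prune",
                    select_informative_independent(geno, variants,
                                                   config$prune))
    results$pruned_in <- results$variant_id %in% kept
  }

  gene_map <- if (!is.null(config$genemap)) read_gene_map(config$genemap)
  if ("dmi" %in% config$modules) {
    seg <- t_stage("dmi-segregation", {
      list(dom = segregation_score_track(geno, ped$affection, "dominant"),
           rec = segregation_score_track(geno, ped$affection, "recessive"))
    })
    results$seg_dominant <- unname(seg$dom[results$variant_id])
    results$seg_recessive <- unname(seg$rec[results$variant_id])
    if (!is.null(gene_map)) {
      results$gene_id <- gene_map$gene_id[match(results$variant_id,
                                                gene_map$variant_id)]
      ws <- t_stage("dmi-weighted-sum",
                    weighted_sum_scan(geno, ped$affection, gene_map,
                                      variants,
                                      n_permutations = config$n_permutations,
                                      seed = config$seed))
      results$ws_p <- ws$p[match(results$gene_id, ws$gene_id)]
      ch <- t_stage("dmi-compound-het",
                    compound_het_scan(ped, geno, variants, gene_map,
                                      config$comphet))
      results$ch_pass123 <-
        ch$variants$pass123[match(results$variant_id,
                                  ch$variants$variant_id)]
      results$ch_gene_pass <-
        ch$genes$pass[match(results$gene_id, ch$genes$gene_id)]
    }
  }

  regions <- NULL
  if ("ibd-share" %in% config$modules) {
    ibd <- read_ibd_table(config$ibd)
    track <- t_stage("ibd-share",
                     sharing_statistic(ped, ibd, config$ibd_share))
    proj <- project_to_variants(track, variants)
    results$ibd_sharing <- proj$value[match(results$variant_id,
                                            proj$variant_id)]
    if ("regions" %in% config$modules) {
      regions <- t_stage("regions",
                         call_regions(track, config$region_threshold,
                                      config$region_direction))
      results$in_region <- vapply(results$cm, function(x)
        any(x >= regions$start_cm & x <= regions$end_cm), NA)
      write_regions(regions, file.path(config$out_dir, "regions.tsv"))
    }
  }

  res_path <- file.path(config$out_dir, "results.tsv")
  num <- vapply(results, is.numeric, NA)
  results[num] <- lapply(results[num], function(x) signif(x, 10))
  utils::write.table(results, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(log_lines, log_path)
  invisible(list(results = results, regions = regions,
                 paths = c(results = res_path, log = log_path)))
}
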