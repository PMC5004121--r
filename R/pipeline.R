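# End-to-end orchestration: annotate -> filter -> 6-mer tables -> MiDD
# tree -> motif PFMs -> clustering -> recurrent sites -> enrichment ->
# profiles -> skew, driven by a YAML (or in-memory) configuration. Every
# stage directory carries a provenance file with the configuration hash so
# reruns can skip completed stages.

pipeline_defaults <- function() {
  list(
    table = list(exclude_ccgg = TRUE, min_cov = 1L,
                 level_aggregation = "reads"),
    midd = list(alpha = 0.05, min_frac = 0.5, scale = 1000L,
                chi2_mode = "pooled"),
    logo = list(dominance_threshold = 0.4),
    cluster = list(min_shared = 100L, linkage = "complete",
                   mask_for_preferences = TRUE),
    sites = list(min_cov = 4L, min_samples = 4L, top_frac = 0.10,
                 recur_frac = 0.75),
    enrich = list(score_mode = "odds_ratio"),
    profile = list(bin_size = 20000L, smooth_window = 5L,
                   flank_bp = 500L, flank_bin = 50L, body_bins = 20L),
    skew = list(min_sites_per_strand = 3L, min_elements = 3L),
    regions = list(promoter_up = 500L, promoter_down = 100L,
                   intergenic_offset = 10000L, intergenic_len = 1000L,
                   ss_len = 200L, mi_min_intron = 500L),
    snv_dist = 1L)
}

merge_defaults <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) user[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      user[[k]] <- modifyList(defaults[[k]], as.list(user[[k]]))
  }
  user
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(rapply(config, as.character, how = "replace"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read and validate a pipeline configuration
#'
#' @param config YAML file path or list. Required keys: `samples` (list of
#'   records with `sample_id`, `path`, `cell_type`, `species`,
#'   `library_type`), `genome` (FASTA path), `out_dir`. Optional:
#'   `genes` (BED12), `repeats` (BED), `cpg_islands` (BED), `snv` (TSV),
#'   `autosomes`, `seed`, plus per-stage parameter blocks overriding the
#'   documented defaults.
#' @return validated config list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_defaults(config, pipeline_defaults())
  for (key in c("samples", "genome", "out_dir"))
    if (is.null(config[[key]])) stop("config missing key: ", key)
  config$samples <- rbindlist(lapply(config$samples, as.data.table),
                              fill = TRUE)
  required <- c("sample_id", "path", "cell_type", "species",
                "library_type")
  miss <- setdiff(required, names(config$samples))
  if (length(miss))
    stop("sample manifest missing fields: ", paste(miss, collapse = ", "))
  for (p in c(config$samples$path, config$genome, config$genes,
              config$repeats, config$cpg_islands, config[["snv"]]))
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  config$seed <- config$seed %||% 1L
  config
}

stage_done <- function(dir, hash) {
  f <- file.path(dir, ".provenance")
  file.exists(f) && identical(readLines(f)[1], hash)
}

stage_mark <- function(dir, hash, params) {
  writeLines(c(hash, sprintf("%s=%s", names(params),
                             vapply(params, function(x)
                               paste(format(x), collapse = ","),
                               character(1)))),
             file.path(dir, ".provenance"))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured cohort and writes stage outputs
#' (tables, MiDD tree, PFMs, dendrogram, site sets, enrichment, profiles,
#' skew scores) under `out_dir`. Stages whose provenance hash matches a
#' previous run are skipped, so interrupted runs resume. The recurrent-site
#' stage refuses RRBS samples by construction.
#'
#' @param config YAML path or list, see [read_pipeline_config()].
#' @return the output directory, invisibly; a `pipeline.log` file records
#'   call counts after each filter step.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  hash <- config_hash(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "pipeline.log")
  logit <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                             append = TRUE)
  cat(sprintf("# middcontext pipeline run, config hash %s, seed %d\n",
              hash, cfg$seed), file = logf)

  genome <- Biostrings::readDNAStringSet(cfg$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- if (!is.null(cfg$genes)) read_bed12_genes(cfg$genes)
  repeats <- if (!is.null(cfg$repeats)) load_regions(cfg$repeats)
  cpg <- if (!is.null(cfg$cpg_islands)) load_regions(cfg$cpg_islands)
  snv <- if (!is.null(cfg[["snv"]])) read_snv_list(cfg[["snv"]])
  subregions <- if (!is.null(genes))
    do.call(derive_gene_subregions, c(list(genes), cfg$regions))

  # -- stage: annotate + filter + per-sample tables -----------------------
  stage_tables <- file.path(out, "01_tables")
  dir.create(stage_tables, showWarnings = FALSE)
  manifest <- cfg$samples
  methylomes <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i]
    m <- read_cgmap(row$path, sample_id = row$sample_id,
                    species = row$species, cell_type = row$cell_type,
                    library_type = row$library_type)
    logit("%s: %d calls read", row$sample_id, n_calls(m))
    m <- tryCatch(annotate_contexts(m, genome), error = function(e)
      stop("stage annotate failed for sample ", row$sample_id, ": ",
           conditionMessage(e)))
    if (!is.null(snv)) {
      m <- filter_near_snv(m, snv, dist = cfg$snv_dist)
      logit("%s: %d calls removed near SNVs", row$sample_id,
            attr(m, "n_removed"))
    }
    methylomes[[row$sample_id]] <- m
  }

  masked_tables <- list(); full_tables <- list()
  mask_sets <- Filter(Negate(is.null),
                      c(list(repeats = repeats, cpg = cpg),
                        if (!is.null(subregions))
                          list(genes = subregions$geneBody)))
  for (id in names(methylomes)) {
    m <- methylomes[[id]]
    full_tables[[id]] <- do.call(sixmer_table, c(
      list(m, class_filter = "CH"), cfg$table))
    mm <- if (length(mask_sets) && isTRUE(cfg$cluster$mask_for_preferences))
      mask_regions(m, mask_sets, mode = "exclude") else m
    logit("%s: %d calls after masking", id, n_calls(mm))
    masked_tables[[id]] <- do.call(sixmer_table, c(
      list(mm, class_filter = "CW"), cfg$table))
    fwrite(full_tables[[id]],
           file.path(stage_tables, paste0(id, ".CH.tsv")), sep = "\t")
  }
  stage_mark(stage_tables, hash, cfg$table)

  # -- stage: MiDD tree ---------------------------------------------------
  stage_midd <- file.path(out, "02_midd")
  if (!stage_done(stage_midd, hash)) {
    dir.create(stage_midd, showWarnings = FALSE)
    tree <- do.call(build_midd_tree, c(list(full_tables), cfg$midd))
    midd_tree_serialize(tree, file.path(stage_midd, "tree.json"), "json")
    midd_tree_serialize(tree, file.path(stage_midd, "tree.txt"), "text")
    stage_mark(stage_midd, hash, cfg$midd)
  }

  # -- stage: motif PFMs --------------------------------------------------
  stage_logo <- file.path(out, "03_motifs")
  if (!stage_done(stage_logo, hash)) {
    dir.create(stage_logo, showWarnings = FALSE)
    for (id in names(masked_tables)) {
      pfm <- normalized_pfm(masked_tables[[id]])
      write_pfm_jaspar(pfm, file.path(stage_logo, paste0(id, ".jaspar")),
                       name = sprintf("%s_%s", id,
                                      consensus_string(
                                        pfm, cfg$logo$dominance_threshold)))
    }
    stage_mark(stage_logo, hash, cfg$logo)
  }

  # -- stage: clustering --------------------------------------------------
  stage_clust <- file.path(out, "04_clustering")
  if (!stage_done(stage_clust, hash) && length(masked_tables) >= 2L) {
    dir.create(stage_clust, showWarnings = FALSE)
    cl <- cluster_samples(masked_tables, linkage = cfg$cluster$linkage,
                          min_shared = cfg$cluster$min_shared)
    write_newick(cl, file.path(stage_clust, "dendrogram.nwk"))
    write_distance_tsv(cl, file.path(stage_clust, "distance.tsv"))
    stage_mark(stage_clust, hash,
               c(cfg$cluster, masked = length(mask_sets) > 0L))
  }

  # -- stage: recurrent sites + enrichment --------------------------------
  stage_sites <- file.path(out, "05_sites")
  wgbs <- methylomes[manifest[library_type != "RRBS", sample_id]]
  sites <- NULL
  if (!is.null(cfg$sites$samples)) {
    chosen <- manifest[sample_id %in% cfg$sites$samples]
    if (any(chosen$library_type == "RRBS"))
      stop("validation error: RRBS sample configured for the recurrent-site stage")
    wgbs <- methylomes[chosen$sample_id]
  }
  if (length(wgbs) >= cfg$sites$min_samples) {
    dir.create(stage_sites, showWarnings = FALSE)
    sites <- recurrent_sites(wgbs, min_cov = cfg$sites$min_cov,
                             min_samples = cfg$sites$min_samples,
                             top_frac = cfg$sites$top_frac,
                             recur_frac = cfg$sites$recur_frac)
    write_sites_bed(sites, file.path(stage_sites, "recurrent"))
    stage_mark(stage_sites, hash, cfg$sites)
  }
  stage_enrich <- file.path(out, "06_enrichment")
  if (!is.null(sites) && (!is.null(subregions) || !is.null(repeats))) {
    dir.create(stage_enrich, showWarnings = FALSE)
    autosomes <- cfg$autosomes %||% unique(sites$background$chrom)
    klasses <- c(subregions %||% list(),
                 if (!is.null(repeats)) split(
                   repeats, S4Vectors::mcols(repeats)$family))
    results <- list()
    for (k in names(klasses)) {
      res <- tryCatch(
        region_enrichment(sites, klasses[[k]], autosomes,
                          score_mode = cfg$enrich$score_mode, label = k),
        error = function(e) NULL)
      if (!is.null(res)) results[[k]] <- res
    }
    if (length(results))
      write_enrichment_tsv(results, file.path(stage_enrich,
                                              "enrichment.tsv"))
    stage_mark(stage_enrich, hash, cfg$enrich)
  }

  # -- stage: profiles ----------------------------------------------------
  stage_prof <- file.path(out, "07_profiles")
  if (!stage_done(stage_prof, hash)) {
    dir.create(stage_prof, showWarnings = FALSE)
    chroms <- names(genome)
    for (id in names(methylomes)) {
      prof <- chromosome_profile(methylomes[[id]], chroms[1],
                                 bin_size = cfg$profile$bin_size,
                                 smooth_window = cfg$profile$smooth_window,
                                 chrom_length = Biostrings::width(
                                   genome[chroms[1]]))
      write_profile_tsv(prof, file.path(stage_prof,
                                        paste0(id, ".chrom.tsv")))
    }
    if (!is.null(repeats) && length(repeats)) {
      fam <- S4Vectors::mcols(repeats)$family
      for (f in unique(fam)) {
        mp <- metaregion_profile(methylomes[[1]], repeats[fam == f],
                                 flank_bp = cfg$profile$flank_bp,
                                 flank_bin = cfg$profile$flank_bin,
                                 body_bins = cfg$profile$body_bins,
                                 strand_mode = "by_strand")
        write_profile_tsv(mp, file.path(stage_prof,
                                        paste0("meta_", f, ".tsv")))
      }
    }
    stage_mark(stage_prof, hash, cfg$profile)
  }

  # -- stage: strand skew -------------------------------------------------
  stage_skew <- file.path(out, "08_skew")
  if (!is.null(genes)) {
    dir.create(stage_skew, showWarnings = FALSE)
    introns <- gene_introns(genes)
    results <- lapply(methylomes, strand_skew_score, regions = introns,
                      min_sites_per_strand = cfg$skew$min_sites_per_strand,
                      min_elements = cfg$skew$min_elements,
                      label = "intron")
    write_skew_tsv(results, file.path(stage_skew, "skew.tsv"))
    stage_mark(stage_skew, hash, cfg$skew)
  }
  logit("pipeline complete")
  invisible(out)
}
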