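# Seeded synthetic methylome cohorts with planted ground truth: i.i.d.
# genomes with planted gene models and repeat families, per-cell-type 6-mer
# motif preferences, region-localised CW enrichment, repeat-subfamily level
# gradients and strand-asymmetric intron methylation. Coverage is negative
# binomial, methylated reads binomial. A fixed master seed determines every
# byte of output.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort generator. The defaults
#' describe the cohort structure the analysis expects: a 4 x 500 kb genome
#' at GC 0.42, two cell types crossed with two species (three replicates
#' each), sparse CW methylation (base rate 0.03) with a strong cell-type
#' 6-mer motif (8x), low CC (0.01) and high CG (0.8) backgrounds, mild
#' species effects, repeat-family CW factors including a young-to-ancient
#' LINE-like gradient, an antisense-biased intron skew for the ESC-like
#' cell type, and negative-binomial coverage with mean 10.
#'
#' @param seed master seed; determines all output.
#' @param n_chrom,chrom_len,gc genome shape and composition.
#' @param samples data.frame with columns `sample_id`, `cell_type`,
#'   `species`, `library_type`.
#' @param cell_type_profiles per cell type: `base_cw`, `base_cc`,
#'   `base_cg` rates (optionally `base_ca`/`base_ct` overriding `base_cw`
#'   per dinucleotide), a named `motif_effects` vector (IUPAC consensus ->
#'   multiplicative factor on the true level), and `preference_sd`, the
#'   log-scale spread of a graded cell-type 6-mer preference: each cell
#'   type gets a fixed position-by-nucleotide log-factor matrix (drawn
#'   once, deterministically from the master seed) whose per-position sums
#'   scale the CW level of every site, so samples of one cell type share a
#'   rich 6-mer preference ranking while cell types differ.
#' @param species_effects per species: global `scale` on non-CG rates and
#'   an optional `motif_effects` vector.
#' @param region_effects named vector: repeat family -> multiplicative CW
#'   factor.
#' @param subfamily_gradient named vector in age order: LINE-like
#'   subfamily -> CW factor (young subfamilies get lower factors).
#' @param intron_strand_skew named vector: cell type -> antisense/sense CW
#'   ratio inside introns.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   model (`size = 1/dispersion`).
#' @param noise_sd per-site Gaussian jitter on the true level.
#' @param genes_per_chrom,repeats_per_chrom planted annotation density.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chrom = 4L, chrom_len = 500000L, gc = 0.42,
    samples = NULL,
    cell_type_profiles = NULL,
    species_effects = NULL,
    region_effects = c(AluY = 2),
    subfamily_gradient = c(L1PA = 0.3, L1MB = 0.7, L1ME = 1.0),
    intron_strand_skew = c(neuron = 1.0, esc = 1.5),
    coverage_mean = 10, coverage_dispersion = 0.3,
    noise_sd = 0.01,
    genes_per_chrom = 4L, repeats_per_chrom = 24L) {
  if (is.null(samples)) {
    grid <- CJ(replicate = 1:3, species = c("human", "mouse"),
               cell_type = c("neuron", "esc"))
    samples <- data.table(
      sample_id = sprintf("%s_%s_r%d", grid$species, grid$cell_type,
                          grid$replicate),
      cell_type = grid$cell_type, species = grid$species,
      library_type = "WGBS")
  }
  samples <- as.data.table(samples)
  if (anyDuplicated(samples$sample_id))
    stop("config error: duplicate sample ids")
  if (is.null(cell_type_profiles))
    cell_type_profiles <- list(
      neuron = list(base_cw = 0.03, base_cc = 0.01, base_cg = 0.8,
                    motif_effects = c(TNCACC = 8), preference_sd = 0.3),
      esc = list(base_cw = 0.03, base_cc = 0.01, base_cg = 0.8,
                 motif_effects = c(NNCAGT = 8), preference_sd = 0.3))
  # species act as a background: a global level scale (rank-preserving),
  # so context preference stays a cell-type property
  if (is.null(species_effects))
    species_effects <- list(
      human = list(scale = 1.0),
      mouse = list(scale = 1.3))
  missing_ct <- setdiff(unique(samples$cell_type),
                        names(cell_type_profiles))
  if (length(missing_ct))
    stop("config error: no profile for cell type(s): ",
         paste(missing_ct, collapse = ", "))
  stopifnot(seed == as.integer(seed), gc > 0, gc < 1,
            coverage_mean >= 0, coverage_dispersion > 0, noise_sd >= 0)
  structure(list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.integer(chrom_len), gc = gc, samples = samples,
    cell_type_profiles = cell_type_profiles,
    species_effects = species_effects,
    region_effects = region_effects,
    subfamily_gradient = subfamily_gradient,
    intron_strand_skew = intron_strand_skew,
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    noise_sd = noise_sd,
    genes_per_chrom = as.integer(genes_per_chrom),
    repeats_per_chrom = as.integer(repeats_per_chrom)),
    class = "sim_config")
}

# repeat families planted by default: three SINE-like (Alu) and the
# LINE-like subfamilies of the age gradient
sim_repeat_families <- function(config) {
  line_fams <- names(config$subfamily_gradient)
  data.table(
    family = c("AluY", "AluSx", "AluJo", line_fams),
    len = c(300L, 300L, 300L, rep(2000L, length(line_fams))))
}

#' Simulate a genome with planted annotations
#'
#' I.i.d. nucleotides at the configured GC content; non-overlapping
#' multi-exon gene models on alternating strands followed by repeat
#' intervals labelled by family. Deterministic per seed.
#'
#' @param config a [simulation_config()].
#' @return object of class `sim_genome`: list with `genome`
#'   (DNAStringSet), `genes` (list of [gene_model()]), `repeats`
#'   (stranded `GRanges` with `family`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- vapply(chroms, function(ch)
    paste(sample(names(probs), config$chrom_len, replace = TRUE,
                 prob = probs), collapse = ""), character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  genes <- list()
  rep_rows <- list()
  fams <- sim_repeat_families(config)
  for (ch in chroms) {
    cursor <- 12000L                      # room for the intergenic window
    for (g in seq_len(config$genes_per_chrom)) {
      n_ex <- sample(3:5, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(600:1500, n_ex - 1L, replace = TRUE)
      glen <- sum(ex_len) + sum(in_len)
      if (cursor + glen > config$chrom_len - 2000L)
        stop("packing error: genes exceed genome capacity")
      strand <- if (g %% 2L == 1L) "+" else "-"
      starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ex <- data.table(start = starts, end = starts + ex_len - 1L)
      if (strand == "-") ex <- ex[rev(seq_len(nrow(ex)))]
      genes[[length(genes) + 1L]] <-
        gene_model(ch, strand, ex,
                   gene_id = sprintf("%s_g%d", ch, g))
      cursor <- cursor + glen + sample(3000:5000, 1)
    }
    # repeats packed after the gene block, alternating strands
    fam_idx <- rep_len(seq_len(nrow(fams)), config$repeats_per_chrom)
    for (r in seq_len(config$repeats_per_chrom)) {
      fam <- fams[fam_idx[r]]
      cursor <- cursor + sample(300:1200, 1)
      if (cursor + fam$len > config$chrom_len)
        stop("packing error: repeats exceed genome capacity")
      rep_rows[[length(rep_rows) + 1L]] <- data.table(
        chrom = ch, start = cursor, end = cursor + fam$len - 1L,
        strand = if (r %% 2L == 0L) "-" else "+",
        family = fam$family)
      cursor <- cursor + fam$len
    }
  }
  repeats <- if (length(rep_rows)) {
    dt <- rbindlist(rep_rows)
    region_set(dt$chrom, dt$start - 1L, dt$end, strand = dt$strand,
               name = dt$family, family = dt$family, label = "repeats")
  } else region_set(character(), integer(), integer(), label = "repeats")
  structure(list(genome = genome, genes = genes, repeats = repeats,
                 config = config),
            class = "sim_genome")
}

#' Write a simulated genome and annotations to disk
#'
#' Emits `genome.fa`, `repeats.bed` (BED6 with the family in the name
#' column) and `genes.bed` (BED12).
#'
#' @param sim a `sim_genome`.
#' @param dir output directory (created if absent).
#' @return named vector of paths, invisibly.
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             repeats = file.path(dir, "repeats.bed"),
             genes = file.path(dir, "genes.bed"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_regions_bed(sim$repeats, paths["repeats"])
  write_bed12_genes(sim$genes, paths["genes"])
  invisible(paths)
}

# all cytosine sites of the genome on both strands with true 6-mer
# contexts; cached on the sim_genome the first time it is needed
genome_cytosine_sites <- function(sim) {
  cached <- attr(sim, "cytosine_sites")
  if (!is.null(cached)) return(cached)
  out <- rbindlist(lapply(names(sim$genome), function(ch) {
    s <- as.character(sim$genome[[ch]])
    len <- nchar(s)
    fwd <- paste0("NN", s, "NNN")
    rcs <- as.character(Biostrings::reverseComplement(sim$genome[[ch]]))
    rev <- paste0("NN", rcs, "NNN")
    letters <- strsplit(s, "")[[1]]
    pos_p <- which(letters == "C")
    pos_m <- which(letters == "G")
    rbind(
      data.table(chrom = ch, pos = pos_p, strand = "+",
                 sixmer = substring(fwd, pos_p, pos_p + 5L)),
      data.table(chrom = ch, pos = pos_m, strand = "-",
                 sixmer = substring(rev, len - pos_m + 1L,
                                    len - pos_m + 6L)))
  }))
  setorder(out, chrom, pos, strand)
  out
}

# cache site table and per-consensus/region masks on a sim_genome
prepare_sim_genome <- function(sim) {
  if (!is.null(attr(sim, "cytosine_sites"))) return(sim)
  sites <- genome_cytosine_sites(sim)
  attr(sim, "cytosine_sites") <- sites
  sitegr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, sites$pos))
  fam <- S4Vectors::mcols(sim$repeats)$family
  fam_masks <- lapply(unique(fam), function(f)
    IRanges::overlapsAny(sitegr, sim$repeats[fam == f],
                         ignore.strand = TRUE))
  names(fam_masks) <- unique(fam)
  attr(sim, "family_masks") <- fam_masks
  introns <- gene_introns(sim$genes)
  hit <- GenomicRanges::findOverlaps(sitegr, introns, ignore.strand = TRUE)
  anti <- rep(FALSE, nrow(sites))
  anti[S4Vectors::queryHits(hit)] <-
    sites$strand[S4Vectors::queryHits(hit)] !=
    as.character(GenomicRanges::strand(introns))[S4Vectors::subjectHits(hit)]
  attr(sim, "intron_antisense") <- anti
  attr(sim, "mask_env") <- new.env(parent = emptyenv())
  sim
}

# logical mask of sites whose true 6-mer matches an IUPAC consensus
consensus_mask <- function(sites, consensus) {
  grepl(iupac_regex(consensus), sites$sixmer, perl = TRUE)
}

# the graded 6-mer preference of one cell type: a 4 x 6 matrix of
# log-factors, drawn from N(0, preference_sd) under a seed derived from the
# master seed and the cell type's index, independent of the sampling RNG
cell_preference_matrix <- function(config, cell_type) {
  prof <- config$cell_type_profiles[[cell_type]]
  psd <- prof$preference_sd %||% 0
  eps <- matrix(0, 4L, 6L, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (psd > 0) {
    idx <- match(cell_type, names(config$cell_type_profiles))
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    set.seed((config$seed %% 10000000L) * 100L + idx)
    eps[] <- rnorm(24L, 0, psd)
    eps["C", 3L] <- 0                      # the fixed cytosine carries none
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  eps
}

# multiplicative per-site preference factor exp(sum_p eps[letter_p, p]);
# 'N' letters contribute nothing
preference_factor <- function(sites, eps) {
  if (all(eps == 0)) return(rep(1, nrow(sites)))
  logf <- numeric(nrow(sites))
  for (p in seq_len(6L)) {
    letter <- substr(sites$sixmer, p, p)
    row <- match(letter, rownames(eps))
    hit <- !is.na(row)
    logf[hit] <- logf[hit] + eps[cbind(row[hit], p)]
  }
  exp(logf)
}

# memoised consensus masks, shared across the samples of a cohort via the
# environment attached by prepare_sim_genome
cached_consensus_mask <- function(sim, consensus) {
  env <- attr(sim, "mask_env")
  if (is.null(env))
    return(consensus_mask(attr(sim, "cytosine_sites"), consensus))
  if (is.null(env[[consensus]]))
    env[[consensus]] <- consensus_mask(attr(sim, "cytosine_sites"),
                                       consensus)
  env[[consensus]]
}

# RRBS emulation: only sites within +/- window of a CCGG occurrence
rrbs_mask <- function(sim, sites, window = 40L) {
  hits <- rbindlist(lapply(names(sim$genome), function(ch) {
    m <- Biostrings::matchPattern("CCGG", sim$genome[[ch]])
    if (length(m) == 0L) return(NULL)
    data.table(chrom = ch,
               start = pmax(1L, IRanges::start(m) - window),
               end = IRanges::end(m) + window)
  }))
  if (is.null(hits) || nrow(hits) == 0L) return(rep(FALSE, nrow(sites)))
  IRanges::overlapsAny(
    GenomicRanges::GRanges(sites$chrom,
                           IRanges::IRanges(sites$pos, sites$pos)),
    GenomicRanges::GRanges(hits$chrom,
                           IRanges::IRanges(hits$start, hits$end)),
    ignore.strand = TRUE)
}

#' Simulate one methylome over a simulated genome
#'
#' Every cytosine (both strands) gets a true methylation level: the base
#' rate of its context class times any matching motif, species, repeat
#' family and intron-antisense factors, plus Gaussian jitter, clipped to
#' `[0, 1]`. Coverage is negative binomial; methylated reads binomial;
#' zero-coverage sites are omitted. RRBS samples only report sites near
#' CCGG occurrences.
#'
#' @param sim a `sim_genome` (ideally pre-processed by repeated calls; the
#'   site table is cached on the object).
#' @param sample_row single-row data.frame with `sample_id`, `cell_type`,
#'   `species`, `library_type`.
#' @param seed per-sample seed.
#' @param config defaults to `sim$config`.
#' @return a `methylome` with true 6-mer contexts annotated.
#' @export
simulate_methylome <- function(sim, sample_row, seed,
                               config = sim$config) {
  sim <- prepare_sim_genome(sim)
  sites <- attr(sim, "cytosine_sites")
  set.seed(seed)
  prof <- config$cell_type_profiles[[sample_row$cell_type]]
  sp_eff <- config$species_effects[[sample_row$species]] %||%
    list(scale = 1, motif_effects = NULL)
  h <- substr(sites$sixmer, 4, 4)
  p <- numeric(nrow(sites))
  p[h == "A"] <- prof$base_ca %||% prof$base_cw
  p[h == "T"] <- prof$base_ct %||% prof$base_cw
  p[h == "C"] <- prof$base_cc
  p[h == "G"] <- prof$base_cg
  noncg <- h %in% c("A", "C", "T")
  p[noncg] <- p[noncg] * (sp_eff$scale %||% 1)
  motif_factors <- c(prof$motif_effects, sp_eff$motif_effects)
  for (cons in names(motif_factors)) {
    m <- cached_consensus_mask(sim, cons)
    p[m] <- p[m] * motif_factors[[cons]]
  }
  cw <- h %in% c("A", "T")
  if ((prof$preference_sd %||% 0) > 0) {
    eps <- cell_preference_matrix(config, sample_row$cell_type)
    pref <- preference_factor(sites, eps)
    p[cw] <- p[cw] * pref[cw]
  }
  fam_masks <- attr(sim, "family_masks")
  fam_factors <- c(config$region_effects, config$subfamily_gradient)
  cw <- h %in% c("A", "T")
  for (f in names(fam_factors))
    if (!is.null(fam_masks[[f]])) {
      m <- fam_masks[[f]] & cw
      p[m] <- p[m] * fam_factors[[f]]
    }
  skew <- config$intron_strand_skew[sample_row$cell_type]
  if (!is.na(skew) && skew != 1) {
    m <- attr(sim, "intron_antisense") & cw
    p[m] <- p[m] * skew
  }
  if (config$noise_sd > 0) p <- p + rnorm(length(p), 0, config$noise_sd)
  p <- pmin(pmax(p, 0), 1)
  coverage <- rnbinom(length(p), mu = config$coverage_mean,
                      size = 1 / config$coverage_dispersion)
  keep <- coverage > 0L
  if (identical(sample_row$library_type, "RRBS"))
    keep <- keep & rrbs_mask(sim, sites)
  calls <- sites[keep]
  calls[, n_total := coverage[keep]]
  calls[, n_meth := rbinom(.N, n_total, p[keep])]
  new_methylome(calls, sample_id = sample_row$sample_id,
                species = sample_row$species,
                cell_type = sample_row$cell_type,
                library_type = sample_row$library_type)
}

#' Simulate a full cohort with ground-truth record
#'
#' Simulates the genome once, then one methylome per configured sample
#' with per-sample seeds drawn deterministically from the master seed.
#' When `dir` is given, the genome, annotations, one CGmap per sample and
#' a machine-readable `truth.json` describing every planted effect are
#' written there.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @return list with `sim` (the `sim_genome`), `methylomes` (named list),
#'   and `truth` (planted-effect record).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  sim <- simulate_genome(config)
  sim <- prepare_sim_genome(sim)
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L,
                             nrow(config$samples))
  methylomes <- lapply(seq_len(nrow(config$samples)), function(i)
    simulate_methylome(sim, config$samples[i], sample_seeds[i],
                       config = config))
  names(methylomes) <- config$samples$sample_id
  # named atomic vectors must become JSON objects, not bare arrays
  listify <- function(x) {
    if (is.list(x) && !is.data.frame(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  truth <- list(
    seed = config$seed,
    genome = list(n_chrom = config$n_chrom, chrom_len = config$chrom_len,
                  gc = config$gc),
    samples = config$samples,
    cell_type_profiles = config$cell_type_profiles,
    species_effects = config$species_effects,
    region_effects = as.list(config$region_effects),
    subfamily_gradient = as.list(config$subfamily_gradient),
    intron_strand_skew = as.list(config$intron_strand_skew),
    coverage = list(mean = config$coverage_mean,
                    dispersion = config$coverage_dispersion),
    noise_sd = config$noise_sd,
    cell_preferences = sapply(names(config$cell_type_profiles),
                              function(ct)
                                cell_preference_matrix(config, ct),
                              simplify = FALSE))
  truth <- listify(truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sim_genome(sim, dir)
    for (m in methylomes)
      write_cgmap(m, file.path(dir, paste0(m$sample_id, ".cgmap")))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(sim = sim, methylomes = methylomes, truth = truth)
}
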