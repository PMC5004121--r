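# shared builders for fixtures constructed in code

# quick methylome from parallel vectors; sixmer defaults to a CA context
mk_methylome <- function(chrom = "chr1", pos, strand = "+",
                         sixmer = "AACAAA", n_meth = 1L, n_total = 2L,
                         sample_id = "s", library_type = "WGBS", ...) {
  n <- max(lengths(list(pos, strand, sixmer, n_meth, n_total)))
  new_methylome(
    data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
               strand = rep_len(strand, n), sixmer = rep_len(sixmer, n),
               n_meth = rep_len(n_meth, n), n_total = rep_len(n_total, n)),
    sample_id = sample_id, library_type = library_type, ...)
}

# context table straight from keys and levels
mk_table <- function(keys, mw, site_count = 10L, class = "CH", ...) {
  new_context_table(
    data.frame(sixmer = keys, site_count = rep_len(site_count, length(keys)),
               M_w = mw),
    pattern_class = class, ...)
}

# every 6-mer matching a degenerate pattern string
all_kmers <- function(pattern = "NNCHNN") {
  sets <- lapply(strsplit(pattern, "")[[1]], iupac_letters)
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  sort(apply(grid, 1, paste, collapse = ""))
}

# small single-cell-type cohort configuration used across tests
quick_config <- function(seed, n_samples = 2L, chrom_len = 50000L,
                         n_chrom = 2L, cell_type = "ct",
                         profiles = NULL, ...) {
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(n_samples)),
    cell_type = cell_type, species = "human", library_type = "WGBS")
  if (is.null(profiles))
    profiles <- list(ct = list(base_cw = 0.03, base_cc = 0.01,
                               base_cg = 0.8, motif_effects = NULL))
  simulation_config(
    seed = seed, n_chrom = n_chrom, chrom_len = chrom_len,
    samples = samples, cell_type_profiles = profiles,
    species_effects = list(human = list(scale = 1)),
    region_effects = NULL, subfamily_gradient = NULL,
    intron_strand_skew = c(ct = 1.0),
    genes_per_chrom = if (chrom_len >= 50000L) 2L else 0L,
    repeats_per_chrom = if (chrom_len >= 50000L) 6L else 0L, ...)
}

fixture_cohort <- function() {
  paths <- system.file("extdata",
                       paste0("toy_sample", c("A", "B", "C", "D"),
                              ".cgmap"),
                       package = "middcontext")
  lapply(paths, function(p)
    read_cgmap(p, sample_id = sub("\\.cgmap$", "", basename(p))))
}

# brute-force bipartition oracle: all unordered two-block partitions of a
# letter set, independent of the package's enumeration
brute_bipartitions <- function(letters) {
  k <- length(letters)
  if (k < 2L) return(list())
  seen <- character(0); out <- list()
  for (size in 1:(k - 1L)) {
    combos <- utils::combn(letters, size, simplify = FALSE)
    for (A in combos) {
      B <- setdiff(letters, A)
      key <- paste(sort(c(paste(sort(A), collapse = ""),
                          paste(sort(B), collapse = ""))), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(A = sort(A), B = sort(B))
    }
  }
  out
}

# cohort of 6 WGBS samples over a 2 x 100 kb genome with planted
# per-dinucleotide CH rates (the MiDD recovery study conditions)
midd_cohort_config <- function(seed, ca, ct, cc = 0.01) {
  samples <- data.frame(sample_id = sprintf("s%d", 1:6), cell_type = "ct",
                        species = "sp", library_type = "WGBS")
  simulation_config(
    seed = seed, n_chrom = 2L, chrom_len = 100000L, samples = samples,
    cell_type_profiles = list(ct = list(base_ca = ca, base_ct = ct,
                                        base_cc = cc, base_cg = 0.8,
                                        motif_effects = NULL)),
    species_effects = list(sp = list(scale = 1)),
    region_effects = NULL, subfamily_gradient = NULL,
    intron_strand_skew = c(ct = 1),
    genes_per_chrom = 2L, repeats_per_chrom = 6L)
}

midd_root_of <- function(seed, ca, ct) {
  co <- simulate_cohort(midd_cohort_config(seed, ca, ct))
  tabs <- lapply(co$methylomes, sixmer_table, class_filter = "CH")
  build_midd_tree(tabs, max_depth = 2L)
}

split_id <- function(s) {
  if (is.null(s)) return("none")
  sprintf("%d:%s|%s", s$pos, paste(s$A, collapse = ""),
          paste(s$B, collapse = ""))
}

# 2 cell types x 2 species x 2 replicates with the default planted
# preferences (the Fig-2-style clustering study conditions)
celltype_species_config <- function(seed) {
  grid <- expand.grid(rep = 1:2, species = c("human", "mouse"),
                      cell_type = c("neuron", "esc"),
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%d", grid$species, grid$cell_type,
                        grid$rep),
    cell_type = grid$cell_type, species = grid$species,
    library_type = "WGBS")
  simulation_config(seed = seed, n_chrom = 2L, chrom_len = 100000L,
                    samples = samples, genes_per_chrom = 2L,
                    repeats_per_chrom = 6L)
}
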