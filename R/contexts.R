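#' Annotate calls with their genomic 6-mer context
#'
#' Fills the `sixmer` column of a methylome from the genome: 2 bp upstream +
#' the cytosine + 3 bp downstream, read 5'->3' on the call's own strand
#' (reverse-complemented for '-' calls). Positions beyond chromosome ends
#' are padded with 'N'. Calls whose central genomic base is not a cytosine
#' on the stated strand are dropped, with the count recorded in attribute
#' `n_dropped_noncytosine` and reported via `message()`.
#'
#' @param methylome a `methylome`.
#' @param genome `Biostrings::DNAStringSet` or path to a FASTA file; must
#'   contain every chromosome referenced by the calls.
#' @return the annotated `methylome`.
#' @export
annotate_contexts <- function(methylome, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  calls <- copy(methylome$calls)
  if (nrow(calls) == 0L) return(methylome)
  missing <- setdiff(unique(calls$chrom), names(genome))
  if (length(missing))
    stop("lookup error: chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  calls[, sixmer := {
    s <- as.character(genome[[chrom[1]]])
    len <- nchar(s)
    fwd <- paste0("NN", s, "NNN")
    rev <- paste0("NN", as.character(
      Biostrings::reverseComplement(genome[[chrom[1]]])), "NNN")
    ifelse(strand == "+",
           substring(fwd, pos, pos + 5L),
           substring(rev, len - pos + 1L, len - pos + 6L))
  }, by = chrom]
  ok <- substr(calls$sixmer, 3, 3) == "C"
  n_drop <- sum(!ok)
  if (n_drop > 0L)
    message(sprintf("annotate_contexts: dropped %d call(s) without a genomic C on the stated strand",
                    n_drop))
  out <- replace_calls(methylome, calls[ok])
  attr(out, "n_dropped_noncytosine") <- n_drop
  out
}

#' Classify 6-mer contexts into CG / CW / CC
#'
#' The class is decided by the base following the cytosine: G gives CG,
#' A or T give CW (W = \{A, T\}), C gives CC, and an ambiguous 'N' gives
#' "unknown".
#'
#' @param sixmer character vector of 6-mer contexts (central base must be C).
#' @return character vector in \{"CG", "CW", "CC", "unknown"\}.
#' @export
classify_context <- function(sixmer) {
  if (!all(substr(sixmer, 3, 3) == "C"))
    stop("contract violation: central base of sixmer must be 'C'")
  h <- substr(sixmer, 4, 4)
  out <- rep("unknown", length(sixmer))
  out[h == "G"] <- "CG"
  out[h %in% c("A", "T")] <- "CW"
  out[h == "C"] <- "CC"
  out
}

# TRUE for calls whose central dinucleotide matches a class filter
match_context_class <- function(sixmer, class) {
  h <- substr(sixmer, 4, 4)
  switch(class,
         CH = h %in% c("A", "C", "T"),
         CW = h %in% c("A", "T"),
         CA = h == "A",
         CT = h == "T",
         CC = h == "C",
         CG = h == "G",
         stop("unknown context class: ", class))
}

#' Remove calls near single-nucleotide variants
#'
#' Discards every call within `dist` bp of an SNV on the same chromosome
#' (symmetric window, the SNV base itself included). The number of removed
#' calls is stored in attribute `n_removed`.
#'
#' @param methylome a `methylome`.
#' @param snv_positions data.frame/data.table with columns `chrom` and `pos`
#'   (1-based), e.g. from [read_snv_list()].
#' @param dist window radius in bp (default 1).
#' @return filtered `methylome` with attribute `n_removed`.
#' @export
filter_near_snv <- function(methylome, snv_positions, dist = 1L) {
  stopifnot(dist >= 0L)
  calls <- methylome$calls
  snv <- as.data.table(snv_positions)
  if (nrow(snv) == 0L || nrow(calls) == 0L) {
    out <- replace_calls(methylome, calls)
    attr(out, "n_removed") <- 0L
    return(out)
  }
  windows <- snv[, .(chrom = as.character(chrom),
                     start = as.integer(pos) - as.integer(dist),
                     end = as.integer(pos) + as.integer(dist))]
  setkey(windows, chrom, start, end)
  probe <- calls[, .(chrom, start = pos, end = pos)]
  hit <- foverlaps(probe, windows, which = TRUE, nomatch = NULL)
  drop <- unique(hit$xid)
  out <- replace_calls(methylome,
                       if (length(drop)) calls[-drop] else calls)
  attr(out, "n_removed") <- length(drop)
  out
}

#' Keep or drop calls overlapping genomic regions
#'
#' Positional masking: a call is "inside" when its cytosine base overlaps
#' any interval of any supplied region set; interval strand is ignored.
#' `exclude` drops inside calls, `include` keeps only them. Overlapping
#' intervals behave as their union.
#'
#' @param methylome a `methylome`.
#' @param region_sets a `GRanges` or list of `GRanges` (see [load_regions()]).
#' @param mode "exclude" or "include".
#' @return filtered `methylome`.
#' @export
mask_regions <- function(methylome, region_sets,
                         mode = c("exclude", "include")) {
  mode <- match.arg(mode)
  if (is(region_sets, "GRanges")) region_sets <- list(region_sets)
  gr <- if (length(region_sets) == 0L) GenomicRanges::GRanges()
        else do.call(c, unname(lapply(region_sets, function(g) {
          S4Vectors::mcols(g) <- NULL
          g
        })))
  calls <- methylome$calls
  if (nrow(calls) == 0L) return(methylome)
  inside <- if (length(gr) == 0L) rep(FALSE, nrow(calls)) else
    IRanges::overlapsAny(
      GenomicRanges::GRanges(calls$chrom,
                             IRanges::IRanges(calls$pos, calls$pos)),
      gr, ignore.strand = TRUE)
  keep <- if (mode == "exclude") !inside else inside
  replace_calls(methylome, calls[keep])
}

#' Per-6-mer aggregate methylation table
#'
#' Aggregates calls into one row per fully resolved 6-mer context ('N'-free)
#' matching a context class. `M_w` is the aggregate methylation level of the
#' pattern: read-weighted (`sum(n_meth)/sum(n_total)`, default) or the
#' unweighted mean of per-site levels. 6-mers containing the CCGG substring
#' can be excluded to keep RRBS and WGBS comparable.
#'
#' @param methylome a `methylome` with annotated contexts.
#' @param class_filter one of "CH", "CW", "CA", "CT", "CC", "CG".
#' @param exclude_ccgg drop 6-mers containing "CCGG".
#' @param min_cov minimum read coverage for a call to contribute (default 1).
#' @param level_aggregation "reads" (read-weighted) or "sites".
#' @return a `context_table`: data.table with columns `sixmer`,
#'   `site_count`, `M_w`, carrying the construction parameters as
#'   attributes.
#' @export
sixmer_table <- function(methylome, class_filter = "CH",
                         exclude_ccgg = FALSE, min_cov = 1L,
                         level_aggregation = c("reads", "sites")) {
  level_aggregation <- match.arg(level_aggregation)
  calls <- methylome$calls
  keep <- !grepl("N", calls$sixmer, fixed = TRUE) &
    calls$n_total >= min_cov &
    match_context_class(calls$sixmer, class_filter)
  if (exclude_ccgg)
    keep <- keep & !grepl("CCGG", calls$sixmer, fixed = TRUE)
  sub <- calls[keep]
  tab <- if (level_aggregation == "reads") {
    sub[, .(site_count = .N, M_w = sum(n_meth) / sum(n_total)), by = sixmer]
  } else {
    sub[, .(site_count = .N, M_w = mean(n_meth / n_total)), by = sixmer]
  }
  setorder(tab, sixmer)
  new_context_table(tab, pattern_class = class_filter,
                    exclude_ccgg = exclude_ccgg,
                    level_aggregation = level_aggregation,
                    min_cov = min_cov, sample_id = methylome$sample_id)
}

#' Construct a context table directly
#'
#' Mostly useful for tests and synthetic inputs; [sixmer_table()] is the
#' normal constructor.
#'
#' @param tab data.frame with columns `sixmer`, `site_count`, `M_w`.
#' @param pattern_class,exclude_ccgg,level_aggregation,min_cov,sample_id
#'   construction metadata.
#' @return a `context_table`.
#' @export
new_context_table <- function(tab, pattern_class = "CH",
                              exclude_ccgg = FALSE,
                              level_aggregation = "reads", min_cov = 1L,
                              sample_id = NA_character_) {
  tab <- as.data.table(tab)
  stopifnot(all(c("sixmer", "site_count", "M_w") %in% names(tab)))
  if (nrow(tab)) {
    if (any(tab$M_w < 0 | tab$M_w > 1)) stop("M_w must lie in [0, 1]")
    if (any(tab$site_count < 1L)) stop("site_count must be >= 1")
    if (!all(match_context_class(tab$sixmer, pattern_class)))
      stop("keys do not match pattern class ", pattern_class)
    if (anyDuplicated(tab$sixmer)) stop("duplicate 6-mer keys")
  }
  setattr(tab, "class", c("context_table", class(tab)))
  setattr(tab, "pattern_class", pattern_class)
  setattr(tab, "exclude_ccgg", exclude_ccgg)
  setattr(tab, "level_aggregation", level_aggregation)
  setattr(tab, "min_cov", min_cov)
  setattr(tab, "sample_id", sample_id)
  tab
}

#' @export
print.context_table <- function(x, ...) {
  cat(sprintf("<context_table> %s, %d 6-mer(s), sample %s\n",
              attr(x, "pattern_class"), nrow(x), attr(x, "sample_id")))
  NextMethod()
}
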