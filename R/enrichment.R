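# Recurrent methylated CW sites and their enrichment in genomic regions.
# Background: CW sites covered >= min_cov reads in >= min_samples samples.
# Foreground: background sites ranking in the top fraction by level in at
# least recur_frac of the samples where they are covered.

cw_site_table <- function(methylomes, min_cov) {
  stopifnot(length(methylomes) >= 1L)
  rbindlist(lapply(methylomes, function(m) {
    calls <- m$calls[match_context_class(sixmer, "CW")]
    calls[, .(chrom, pos, strand, level = n_meth / n_total,
              cov_ok = n_total >= min_cov, sample_id = m$sample_id)]
  }))
}

new_site_sets <- function(background, foreground, params = list()) {
  setorder(background, chrom, pos, strand)
  setorder(foreground, chrom, pos, strand)
  structure(list(background = background, foreground = foreground,
                 params = params),
            class = "site_sets")
}

#' @export
print.site_sets <- function(x, ...) {
  cat(sprintf("<site_sets> background %d, foreground %d CW sites\n",
              nrow(x$background), nrow(x$foreground)))
  invisible(x)
}

#' Recurrently methylated CW sites across a cohort
#'
#' Background: CW sites with coverage >= `min_cov` reads in at least
#' `min_samples` samples. Per sample, the background sites covered in that
#' sample are ranked by methylation level and the top `top_frac` flagged
#' (ties at the cutoff break by genomic position, deterministically).
#' Foreground: sites flagged in at least `recur_frac` of the samples in
#' which they meet the coverage floor. RRBS samples are rejected.
#'
#' @param methylomes list of >= `min_samples` WGBS `methylome`s with CW
#'   contexts annotated.
#' @param min_cov per-sample coverage floor (default 4).
#' @param min_samples samples required for the background (default 4).
#' @param top_frac per-sample fraction flagged as highly methylated
#'   (default 0.10).
#' @param recur_frac recurrence fraction over covered samples
#'   (default 0.75).
#' @return a `site_sets` with `background` and `foreground` site tables
#'   (chrom, 1-based pos, strand).
#' @export
recurrent_sites <- function(methylomes, min_cov = 4L, min_samples = 4L,
                            top_frac = 0.10, recur_frac = 0.75) {
  if (length(methylomes) < min_samples)
    stop(sprintf("configuration error: %d methylomes supplied, %d required",
                 length(methylomes), min_samples))
  if (any(vapply(methylomes, function(m) m$library_type, character(1)) ==
          "RRBS"))
    stop("configuration error: recurrent_sites accepts non-RRBS samples only")
  sites <- cw_site_table(methylomes, min_cov)
  bg <- sites[cov_ok == TRUE, .(n_cov = .N), by = .(chrom, pos, strand)][
    n_cov >= min_samples]
  if (nrow(bg) == 0L)
    return(new_site_sets(bg[, .(chrom, pos, strand)],
                         bg[, .(chrom, pos, strand)],
                         params = as.list(environment())[
                           c("min_cov", "min_samples", "top_frac",
                             "recur_frac")]))
  elig <- merge(sites[cov_ok == TRUE], bg[, .(chrom, pos, strand)],
                by = c("chrom", "pos", "strand"))
  setorder(elig, sample_id, -level, chrom, pos, strand)
  elig[, flagged := seq_len(.N) <= ceiling(top_frac * .N), by = sample_id]
  rec <- elig[, .(n_cov = .N, n_flag = sum(flagged)),
              by = .(chrom, pos, strand)]
  fg <- rec[n_flag >= recur_frac * n_cov, .(chrom, pos, strand)]
  new_site_sets(bg[, .(chrom, pos, strand)], fg,
                params = list(min_cov = min_cov, min_samples = min_samples,
                              top_frac = top_frac, recur_frac = recur_frac,
                              mode = "recurrent"))
}

#' Recurrent CW sites from a merged meta-methylome
#'
#' For small cohorts the samples are merged site-wise (read counts summed)
#' into one meta-methylome. Background: sites in the top `cov_quantile`
#' fraction by merged coverage (i.e. at or above the `1 - cov_quantile`
#' coverage quantile). Foreground: the top `top_frac` of background sites
#' by merged methylation level.
#'
#' @param methylomes list of >= 1 `methylome`s with CW contexts annotated.
#' @param cov_quantile retained coverage fraction (default 0.80).
#' @param top_frac foreground fraction of the background (default 0.10).
#' @return a `site_sets`.
#' @export
meta_recurrent_sites <- function(methylomes, cov_quantile = 0.80,
                                 top_frac = 0.10) {
  stopifnot(length(methylomes) >= 1L)
  merged <- rbindlist(lapply(methylomes, function(m)
    m$calls[match_context_class(sixmer, "CW"),
            .(chrom, pos, strand, n_meth, n_total)]))
  merged <- merged[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
                   by = .(chrom, pos, strand)]
  if (nrow(merged) == 0L)
    return(new_site_sets(merged[, .(chrom, pos, strand)],
                         merged[, .(chrom, pos, strand)],
                         params = list(mode = "meta")))
  cut <- quantile(merged$n_total, probs = 1 - cov_quantile, type = 1L)
  bg <- merged[n_total >= cut]
  bg[, level := n_meth / n_total]
  setorder(bg, -level, chrom, pos, strand)
  k <- ceiling(top_frac * nrow(bg))
  fg <- bg[seq_len(k), .(chrom, pos, strand)]
  new_site_sets(bg[, .(chrom, pos, strand)], fg,
                params = list(cov_quantile = cov_quantile,
                              top_frac = top_frac, mode = "meta"))
}

sites_in_region <- function(sites, regions) {
  if (nrow(sites) == 0L) return(logical(0))
  # disjoint chromosome namespaces are a legitimate "all outside" answer
  suppressWarnings(IRanges::overlapsAny(
    GenomicRanges::GRanges(sites$chrom,
                           IRanges::IRanges(sites$pos, sites$pos)),
    regions, ignore.strand = TRUE))
}

#' Region enrichment of recurrent CW sites
#'
#' Per autosome, the enrichment score of the foreground in a region class
#' is the log2 odds ratio
#' `log2((fg_in/fg_out) / (bg_in/bg_out))`
#' (or the log2 observed/expected ratio with `score_mode = "obs_exp"`).
#' Autosomes with a zero cell receive a 0.5 pseudo-count in all four cells
#' and are flagged. Mean, SD and a two-tailed one-sample t-test against 0
#' are computed across autosome scores.
#'
#' @param sites a `site_sets`.
#' @param regions `GRanges` region class.
#' @param autosomes chromosomes entering the score (sex chromosomes should
#'   be excluded by the caller).
#' @param score_mode "odds_ratio" (default) or "obs_exp".
#' @param label region class label for reporting.
#' @return object of class `enrichment_result`: per-autosome scores, mean,
#'   sd, `pvalue`, flags.
#' @export
region_enrichment <- function(sites, regions, autosomes,
                              score_mode = c("odds_ratio", "obs_exp"),
                              label = NULL) {
  score_mode <- match.arg(score_mode)
  label <- label %||% S4Vectors::metadata(regions)$label %||% "region"
  fg <- sites$foreground; bg <- sites$background
  fg_in_all <- sites_in_region(fg, regions)
  bg_in_all <- sites_in_region(bg, regions)
  scores <- c(); flagged <- character(0)
  for (chr in autosomes) {
    fi <- sum(fg_in_all & fg$chrom == chr)
    fo <- sum(!fg_in_all & fg$chrom == chr)
    bi <- sum(bg_in_all & bg$chrom == chr)
    bo <- sum(!bg_in_all & bg$chrom == chr)
    if (bi < 1L || bo < 1L) next   # region class absent (or saturating) here
    if (min(fi, fo, bi, bo) == 0L) {
      fi <- fi + 0.5; fo <- fo + 0.5; bi <- bi + 0.5; bo <- bo + 0.5
      flagged <- c(flagged, chr)
    }
    s <- if (score_mode == "odds_ratio") log2((fi / fo) / (bi / bo))
         else log2((fi / (fi + fo)) / (bi / (bi + bo)))
    scores[chr] <- s
  }
  if (length(scores) == 0L)
    stop("undefined-result error: region class has no scorable autosome")
  p <- if (length(scores) >= 2L && sd(scores) > 0)
    t.test(scores, mu = 0)$p.value else NA_real_
  structure(list(label = label, scores = scores,
                 mean = mean(scores), sd = sd(scores), pvalue = p,
                 degenerate = is.na(p), pseudo_chroms = flagged,
                 score_mode = score_mode),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: mean log2 %s = %.3f (sd %.3f, p = %s, %d autosomes)\n",
              x$label, if (x$score_mode == "odds_ratio") "OR" else "obs/exp",
              x$mean, x$sd, format.pval(x$pvalue), length(x$scores)))
  invisible(x)
}

#' Write site sets as BED files
#'
#' Emits `<prefix>.background.bed` and `<prefix>.foreground.bed` (BED6,
#' 0-based).
#'
#' @param sites a `site_sets`.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_sites_bed <- function(sites, prefix) {
  paths <- paste0(prefix, c(".background.bed", ".foreground.bed"))
  for (i in 1:2) {
    dt <- list(sites$background, sites$foreground)[[i]]
    fwrite(dt[, .(chrom, start = pos - 1L, end = pos, name = "CW",
                  score = 0L, strand)],
           paths[i], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Enrichment results as a TSV table
#'
#' @param results list of `enrichment_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  chroms <- unique(unlist(lapply(results, function(r) names(r$scores))))
  rows <- rbindlist(lapply(results, function(r) {
    row <- as.list(r$scores[chroms])
    names(row) <- chroms
    c(list(region = r$label, mean = r$mean, sd = r$sd, pvalue = r$pvalue),
      row)
  }), fill = TRUE)
  fwrite(rows, path, sep = "\t")
  invisible(path)
}
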