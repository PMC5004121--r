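# Strand-specific skew of CW methylation within stranded elements.
# Per element the sense and antisense site-mean levels are compared; the
# signed score is sign(mean difference) * (-log2 p) from a paired
# two-tailed t-test across elements, so positive scores mean higher
# methylation on the sense strand.

#' Strand skew score of CW methylation in a region class
#'
#' For every element with at least `min_sites_per_strand` covered CW sites
#' on each strand, the unweighted mean methylation level is computed per
#' strand ("sense" = call strand equals the element strand). A paired
#' two-tailed t-test across elements compares sense and antisense means;
#' the score is `sign(mean(sense - antisense)) * (-log2 p)`.
#'
#' @param methylome a `methylome` with annotated contexts.
#' @param regions stranded `GRanges` (e.g. introns or a TE family).
#' @param min_sites_per_strand per-element, per-strand site floor
#'   (default 3).
#' @param min_elements minimum number of qualifying elements for a defined
#'   score (default 3).
#' @param label region class label.
#' @return object of class `skew_result`: list with `mean_sense`,
#'   `mean_antisense`, `n_elements`, `pvalue`, `score` (NA when too few
#'   elements qualify).
#' @export
strand_skew_score <- function(methylome, regions,
                              min_sites_per_strand = 3L,
                              min_elements = 3L, label = NULL) {
  label <- label %||% S4Vectors::metadata(regions)$label %||% "region"
  elstrand <- as.character(GenomicRanges::strand(regions))
  if (any(elstrand == "*")) stop("regions must be stranded")
  calls <- methylome$calls[match_context_class(sixmer, "CW")]
  insufficient <- structure(
    list(label = label, sample_id = methylome$sample_id,
         mean_sense = NA_real_, mean_antisense = NA_real_,
         n_elements = 0L, pvalue = NA_real_, score = NA_real_),
    class = "skew_result")
  if (nrow(calls) == 0L) return(insufficient)
  callgr <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$pos, calls$pos))
  hits <- GenomicRanges::findOverlaps(callgr, regions, ignore.strand = TRUE)
  if (length(hits) == 0L) return(insufficient)
  dt <- data.table(
    element = S4Vectors::subjectHits(hits),
    sense = calls$strand[S4Vectors::queryHits(hits)] ==
      elstrand[S4Vectors::subjectHits(hits)],
    level = calls[S4Vectors::queryHits(hits), n_meth / n_total])
  per <- dt[, .(s_mean = mean(level[sense]), s_n = sum(sense),
                a_mean = mean(level[!sense]), a_n = sum(!sense)),
            by = element]
  per <- per[s_n >= min_sites_per_strand & a_n >= min_sites_per_strand]
  if (nrow(per) < min_elements) {
    insufficient$n_elements <- nrow(per)
    return(insufficient)
  }
  diffs <- per$s_mean - per$a_mean
  d <- mean(diffs)
  p <- if (sd(diffs) == 0) 1 else t.test(per$s_mean, per$a_mean,
                                         paired = TRUE)$p.value
  score <- if (d == 0) 0 else sign(d) * (-log2(p))
  structure(
    list(label = label, sample_id = methylome$sample_id,
         mean_sense = mean(per$s_mean), mean_antisense = mean(per$a_mean),
         n_elements = nrow(per), pvalue = p, score = score),
    class = "skew_result")
}

#' @export
print.skew_result <- function(x, ...) {
  cat(sprintf("<skew_result> %s (%s): S = %s (p = %s, %d elements; sense %.4f vs antisense %.4f)\n",
              x$label, x$sample_id,
              ifelse(is.na(x$score), "NA", sprintf("%.3f", x$score)),
              format.pval(x$pvalue), x$n_elements,
              x$mean_sense, x$mean_antisense))
  invisible(x)
}

#' Write skew results as TSV
#'
#' @param results list of `skew_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skew_tsv <- function(results, path) {
  dt <- rbindlist(lapply(results, function(r)
    data.table(region = r$label, sample_id = r$sample_id,
               mean_sense = r$mean_sense, mean_antisense = r$mean_antisense,
               n_elements = r$n_elements, pvalue = r$pvalue,
               score = r$score)))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
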