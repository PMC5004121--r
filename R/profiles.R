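# Binned methylation profiles: fixed-width chromosome bins and
# metaregion (gene/TE) profiles with fixed-width flanks and a
# length-rescaled body.

# centered NA-skipping rolling mean (edge windows truncated)
roll_mean_na <- function(x, window) {
  if (window <= 1L || length(x) == 0L) return(x)
  out <- zoo::rollapply(x, width = window,
                        FUN = function(v) mean(v, na.rm = TRUE),
                        align = "center", partial = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Binned methylation profile along a chromosome
#'
#' Splits one chromosome into fixed-width bins and reports, per bin and
#' context, the read-weighted mean methylation level, raw and smoothed
#' (centered rolling mean over `smooth_window` bins, NA bins skipped).
#'
#' @param methylome a `methylome` with annotated contexts.
#' @param chrom chromosome to profile.
#' @param bin_size bin width in bp (default 20000).
#' @param contexts central dinucleotide classes (default CA, CC, CG, CT).
#' @param smooth_window rolling-mean window in bins (default 5).
#' @param chrom_length optional length of the chromosome; defaults to the
#'   last covered position.
#' @return object of class `chromosome_profile`: list with `bins`
#'   (start/end, 1-based), matrices `raw` and `smoothed` (bins x contexts),
#'   and per-bin site/read `counts`.
#' @export
chromosome_profile <- function(methylome, chrom, bin_size = 20000L,
                               contexts = c("CA", "CC", "CG", "CT"),
                               smooth_window = 5L, chrom_length = NULL) {
  calls <- methylome$calls[chrom, on = "chrom"]
  if (nrow(calls) == 0L || all(is.na(calls$pos)))
    stop("lookup error: no calls on chromosome ", chrom)
  chrom_length <- chrom_length %||% max(calls$pos)
  nbins <- ceiling(chrom_length / bin_size)
  bins <- data.table(bin = seq_len(nbins),
                     start = (seq_len(nbins) - 1L) * bin_size + 1L,
                     end = pmin(seq_len(nbins) * bin_size,
                                as.integer(chrom_length)))
  calls <- calls[, dinuc := substr(sixmer, 3, 4)][dinuc %in% contexts]
  calls[, bin := pmin((pos - 1L) %/% bin_size + 1L, nbins)]
  agg <- calls[, .(level = sum(n_meth) / sum(n_total), n_sites = .N,
                   n_reads = sum(n_total)), by = .(bin, dinuc)]
  raw <- matrix(NA_real_, nrow = nbins, ncol = length(contexts),
                dimnames = list(NULL, contexts))
  counts <- matrix(0L, nrow = nbins, ncol = length(contexts),
                   dimnames = list(NULL, contexts))
  raw[cbind(agg$bin, match(agg$dinuc, contexts))] <- agg$level
  counts[cbind(agg$bin, match(agg$dinuc, contexts))] <- agg$n_sites
  smoothed <- apply(raw, 2, roll_mean_na, window = smooth_window)
  structure(list(chrom = chrom, bin_size = bin_size, bins = bins,
                 raw = raw, smoothed = smoothed, counts = counts,
                 smooth_window = smooth_window),
            class = "chromosome_profile")
}

#' Spatial correlation of context profiles
#'
#' Pearson correlation of per-bin levels between context classes over bins
#' covered in both, with distance `1 - r^2` and a complete-linkage
#' dendrogram over the contexts. Context pairs with zero variance get an
#' undefined r and distance 1 (flagged).
#'
#' @param profile a [chromosome_profile()].
#' @param use "raw" (default) or "smoothed" matrix.
#' @param min_bins minimum shared non-NA bins per pair (default 3).
#' @return list with the correlation matrix `r`, `distance`, `hclust`, and
#'   `flagged` pairs.
#' @export
context_profile_correlation <- function(profile, use = c("raw", "smoothed"),
                                        min_bins = 3L) {
  use <- match.arg(use)
  mat <- profile[[use]]
  k <- ncol(mat)
  if (k < 2L) stop("need at least two contexts")
  r <- matrix(1, k, k, dimnames = list(colnames(mat), colnames(mat)))
  flagged <- character(0)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- complete.cases(mat[, c(i, j)])
    if (sum(ok) < min_bins)
      stop(sprintf("contexts %s/%s share %d bins (< %d)",
                   colnames(mat)[i], colnames(mat)[j], sum(ok), min_bins))
    x <- mat[ok, i]; y <- mat[ok, j]
    if (sd(x) == 0 || sd(y) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      flagged <- c(flagged, paste0(colnames(mat)[i], "/", colnames(mat)[j]))
    } else {
      r[i, j] <- r[j, i] <- cor(x, y)
    }
  }
  d <- 1 - r^2
  d[is.na(d)] <- 1
  diag(d) <- 0
  list(r = r, distance = d, hclust = hclust(as.dist(d), "complete"),
       flagged = flagged)
}

#' Metaregion methylation profile with flanks
#'
#' Averages methylation across a set of stranded elements: fixed-width
#' flank bins of `flank_bin` bp on both sides and a body linearly rescaled
#' into `body_bins` bins regardless of element length (sites are assigned
#' to body bins by fractional overlap, so short elements are kept).
#' '-'-strand elements are reversed so bin 1 is always the element 5' end.
#' With `strand_mode = "by_strand"`, sense (call strand equals element
#' strand) and antisense calls are reported separately.
#'
#' @param methylome a `methylome` with annotated contexts.
#' @param regions stranded `GRanges` elements.
#' @param flank_bp flank width in bp (default 500); must be a multiple of
#'   `flank_bin`.
#' @param flank_bin flank bin width in bp (default 50).
#' @param body_bins number of rescaled body bins (default 20).
#' @param context_class context filter, see [sixmer_table()] classes
#'   (default "CW").
#' @param strand_mode "combined" or "by_strand".
#' @return object of class `metaregion_profile`: data.table with columns
#'   `bin`, `segment` (upstream/body/downstream), `strand` (sense /
#'   antisense / combined), `level`, `n_sites`, `w_total`.
#' @export
metaregion_profile <- function(methylome, regions, flank_bp = 500L,
                               flank_bin = 50L, body_bins = 20L,
                               context_class = "CW",
                               strand_mode = c("combined", "by_strand")) {
  strand_mode <- match.arg(strand_mode)
  if (flank_bp %% flank_bin != 0L)
    stop("flank_bp must be a multiple of flank_bin")
  nflank <- flank_bp %/% flank_bin
  elstrand <- as.character(GenomicRanges::strand(regions))
  if (any(elstrand == "*")) stop("regions must be stranded")
  calls <- methylome$calls[match_context_class(sixmer, context_class)]
  callgr <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$pos, calls$pos))
  expanded <- GenomicRanges::resize(regions,
                                    GenomicRanges::width(regions) +
                                      2L * flank_bp, fix = "center")
  hits <- GenomicRanges::findOverlaps(callgr, expanded,
                                      ignore.strand = TRUE)
  ci <- S4Vectors::queryHits(hits); ei <- S4Vectors::subjectHits(hits)
  if (length(ci) == 0L)
    return(empty_metaregion(nflank, body_bins, strand_mode,
                            flank_bp, flank_bin))
  el_start <- GenomicRanges::start(regions)[ei]
  el_end <- GenomicRanges::end(regions)[ei]
  el_len <- el_end - el_start + 1L
  minus <- elstrand[ei] == "-"
  pos <- calls$pos[ci]
  # 0-based offset from the element 5' end; negative = upstream flank
  off <- ifelse(minus, el_end - pos, pos - el_start)
  sense <- (calls$strand[ci] == elstrand[ei])
  strand_lab <- if (strand_mode == "by_strand")
    ifelse(sense, "sense", "antisense") else "combined"
  nm <- calls$n_meth[ci]; nt <- calls$n_total[ci]

  upstream <- off < 0L
  downstream <- off >= el_len
  body <- !upstream & !downstream

  pieces <- list()
  if (any(upstream)) {
    b <- nflank - ((-off[upstream] - 1L) %/% flank_bin)  # 1..nflank
    pieces$up <- data.table(bin = b, segment = "upstream",
                            strand = strand_lab[upstream], w = 1,
                            n_meth = nm[upstream], n_total = nt[upstream])
  }
  if (any(downstream)) {
    b <- (off[downstream] - el_len[downstream]) %/% flank_bin + 1L
    pieces$down <- data.table(bin = b, segment = "downstream",
                              strand = strand_lab[downstream], w = 1,
                              n_meth = nm[downstream],
                              n_total = nt[downstream])
  }
  if (any(body)) {
    u0 <- off[body] * body_bins / el_len[body]
    u1 <- (off[body] + 1L) * body_bins / el_len[body]
    b0 <- pmin(floor(u0), body_bins - 1L)
    b1 <- pmin(ceiling(u1 - 1e-9) - 1L, body_bins - 1L)
    span <- b1 - b0 + 1L
    idx <- rep(seq_along(u0), span)
    binb <- b0[idx] + (sequence(span) - 1L)
    frac <- (pmin(u1[idx], binb + 1) - pmax(u0[idx], binb)) /
      (u1[idx] - u0[idx])
    pieces$body <- data.table(bin = binb + 1L, segment = "body",
                              strand = strand_lab[body][idx], w = frac,
                              n_meth = nm[body][idx], n_total = nt[body][idx])
  }
  long <- rbindlist(pieces)
  agg <- long[, .(w_meth = sum(w * n_meth), w_total = sum(w * n_total),
                  n_sites = sum(w)),
              by = .(segment, bin, strand)]
  agg[, level := w_meth / w_total]
  full <- metaregion_axis(nflank, body_bins, strand_mode)
  out <- merge(full, agg[, .(segment, bin, strand, level, n_sites, w_total)],
               by = c("segment", "bin", "strand"), all.x = TRUE)
  seg_order <- c(upstream = 1L, body = 2L, downstream = 3L)
  out <- out[order(seg_order[segment], bin, strand)]
  structure(out,
            class = c("metaregion_profile", class(out)),
            flank_bp = flank_bp, flank_bin = flank_bin,
            body_bins = body_bins, context_class = context_class,
            strand_mode = strand_mode, n_elements = length(regions))
}

metaregion_axis <- function(nflank, body_bins, strand_mode) {
  strands <- if (strand_mode == "by_strand") c("sense", "antisense")
             else "combined"
  CJ(segment = c("upstream", "body", "downstream"),
     bin = seq_len(max(nflank, body_bins)),
     strand = strands)[
       (segment == "body" & bin <= body_bins) |
         (segment != "body" & bin <= nflank)]
}

empty_metaregion <- function(nflank, body_bins, strand_mode,
                             flank_bp, flank_bin) {
  out <- metaregion_axis(nflank, body_bins, strand_mode)
  out[, `:=`(level = NA_real_, n_sites = NA_real_, w_total = NA_real_)]
  structure(out, class = c("metaregion_profile", class(out)),
            flank_bp = flank_bp, flank_bin = flank_bin,
            body_bins = body_bins, strand_mode = strand_mode,
            n_elements = 0L)
}

#' Write a metaregion or chromosome profile as TSV
#'
#' @param profile a `metaregion_profile` or `chromosome_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "chromosome_profile")) {
    dt <- data.table(bin = profile$bins$bin, start = profile$bins$start,
                     end = profile$bins$end)
    for (ctx in colnames(profile$raw)) {
      dt[[paste0(ctx, "_raw")]] <- profile$raw[, ctx]
      dt[[paste0(ctx, "_smoothed")]] <- profile$smoothed[, ctx]
    }
    fwrite(dt, path, sep = "\t")
  } else {
    fwrite(as.data.table(profile), path, sep = "\t")
  }
  invisible(path)
}

#' Export a chromosome profile as bedGraph
#'
#' One track per requested context, written to
#' `<prefix>.<context>.bedGraph` (0-based starts). NA bins are skipped.
#'
#' @param profile a `chromosome_profile`.
#' @param prefix output path prefix.
#' @param use "raw" or "smoothed".
#' @return written paths, invisibly.
#' @export
write_profile_bedgraph <- function(profile, prefix,
                                   use = c("raw", "smoothed")) {
  use <- match.arg(use)
  mat <- profile[[use]]
  paths <- character(0)
  for (ctx in colnames(mat)) {
    keep <- !is.na(mat[, ctx])
    dt <- data.table(chrom = profile$chrom,
                     start = profile$bins$start[keep] - 1L,
                     end = profile$bins$end[keep],
                     value = mat[keep, ctx])
    p <- sprintf("%s.%s.bedGraph", prefix, ctx)
    fwrite(dt, p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
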