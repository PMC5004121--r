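# Minimum dependence decomposition (MiDD): recursively bipartition a
# degenerate 6-mer pattern at the position whose two nucleotide blocks have
# the most significantly different methylation frequencies, adopting at
# each node the split reported as most significant by at least half the
# samples.

#' Degenerate 6-mer pattern
#'
#' A pattern is a list of six allowed-nucleotide sets. Position 3 (the
#' methylated cytosine) is always fixed to \{C\}.
#'
#' @param sets list of six character vectors over \{A, C, G, T\}.
#' @return object of class `midd_pattern`.
#' @export
midd_pattern <- function(sets) {
  stopifnot(length(sets) == 6L)
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (any(lengths(sets) == 0L)) stop("empty position set")
  if (!identical(sets[[3]], "C")) stop("position 3 must be {C}")
  if (!all(unlist(sets) %in% c("A", "C", "G", "T")))
    stop("pattern letters must be A/C/G/T")
  structure(sets, class = "midd_pattern")
}

#' @rdname midd_pattern
#' @param string IUPAC string, e.g. "NNCHNN".
#' @export
pattern_from_string <- function(string) {
  stopifnot(nchar(string) == 6L)
  midd_pattern(lapply(strsplit(string, "")[[1]], iupac_letters))
}

#' @rdname midd_pattern
#' @export
pattern_ch <- function() pattern_from_string("NNCHNN")

#' @rdname midd_pattern
#' @export
pattern_cw <- function() pattern_from_string("NNCWNN")

#' IUPAC string of a pattern
#' @param pattern a `midd_pattern`.
#' @export
pattern_string <- function(pattern) {
  paste(vapply(pattern, iupac_code, character(1)), collapse = "")
}

#' @export
print.midd_pattern <- function(x, ...) {
  cat("<midd_pattern>", pattern_string(x), "\n")
  invisible(x)
}

#' Which 6-mer keys match a pattern
#' @param keys character vector of 6-mers.
#' @param pattern a `midd_pattern`.
#' @return logical vector.
#' @export
pattern_match <- function(keys, pattern) {
  if (length(keys) == 0L) return(logical(0))
  ok <- rep(TRUE, length(keys))
  for (p in seq_len(6L))
    ok <- ok & substr(keys, p, p) %in% pattern[[p]]
  ok
}

bp_id <- function(bp) {
  sprintf("%d:%s|%s", bp$pos, paste(bp$A, collapse = ""),
          paste(bp$B, collapse = ""))
}

#' Enumerate all bipartitions of a pattern
#'
#' For every position except the fixed cytosine, every unordered split of
#' its allowed set into two non-empty blocks is emitted: a position with k
#' letters contributes `2^(k-1) - 1` bipartitions. Block A is canonically
#' the lexicographically smaller block, and the listing order (position
#' ascending, then block A by subset enumeration) is deterministic.
#'
#' @param pattern a `midd_pattern`.
#' @return list of bipartitions `list(pos, A, B)`.
#' @export
enumerate_bipartitions <- function(pattern) {
  out <- list()
  for (p in setdiff(seq_len(6L), 3L)) {
    letters <- pattern[[p]]
    k <- length(letters)
    if (k < 2L) next
    rest <- letters[-1L]
    for (mask in 0:(2^(k - 1L) - 2L)) {
      inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(k - 1L) - 1L))))
      A <- letters[inA]          # contains the smallest letter, so lex-min
      B <- letters[!inA]
      out[[length(out) + 1L]] <- list(pos = p, A = A, B = B)
    }
  }
  out
}

# Pearson chi-squared on a 2x2 without continuity correction; degenerate
# margins give chi2 = 0, p = 1.
pearson_chi2_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    return(list(chi2 = 0, pvalue = 1))
  E <- outer(rs, cs) / n
  chi2 <- sum((tab - E)^2 / E)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  list(chi2 = chi2, pvalue = max(p, .Machine$double.xmin))
}

#' Chi-squared test of one bipartition
#'
#' Each 6-mer pattern `w` in a subgroup contributes `round(scale * M_w)`
#' methylated and `scale - round(scale * M_w)` unmethylated pseudo-counts
#' ("occurrences in `scale` cases"). In the default pooled mode the
#' pseudo-counts are summed per subgroup into a 2x2 subgroup-by-state table
#' (each 6-mer weighted equally by its `scale` cases); in stratified mode
#' each subgroup instead contributes its mean count out of `scale`, so
#' subgroups of different sizes carry equal weight. Pearson chi-squared,
#' 1 df, no continuity correction.
#'
#' @param table a `context_table`.
#' @param bipartition as produced by [enumerate_bipartitions()].
#' @param pattern optional `midd_pattern` restricting which keys of `table`
#'   take part (defaults to all keys).
#' @param scale pseudo-count scale (default 1000).
#' @param chi2_mode "pooled" or "stratified".
#' @return object of class `bipartition_test`: list with `bipartition`,
#'   `chi2`, `pvalue`.
#' @export
bipartition_test <- function(table, bipartition, pattern = NULL,
                             scale = 1000L,
                             chi2_mode = c("pooled", "stratified")) {
  chi2_mode <- match.arg(chi2_mode)
  keys <- table$sixmer
  mw <- table$M_w
  if (!is.null(pattern)) {
    keep <- pattern_match(keys, pattern)
    keys <- keys[keep]; mw <- mw[keep]
  }
  letter <- substr(keys, bipartition$pos, bipartition$pos)
  inA <- letter %in% bipartition$A
  inB <- letter %in% bipartition$B
  if (!any(inA) || !any(inB))
    stop("undefined-test error: a subgroup has no matching 6-mers")
  cw <- round(scale * mw)
  if (chi2_mode == "pooled") {
    a <- sum(cw[inA]); b <- sum(inA) * scale - a
    c_ <- sum(cw[inB]); d <- sum(inB) * scale - c_
  } else {
    a <- round(mean(cw[inA])); b <- scale - a
    c_ <- round(mean(cw[inB])); d <- scale - c_
  }
  res <- pearson_chi2_2x2(a, b, c_, d)
  structure(list(bipartition = bipartition, chi2 = res$chi2,
                 pvalue = res$pvalue, chi2_mode = chi2_mode),
            class = "bipartition_test")
}

#' Most significant bipartition of a pattern in one sample
#'
#' Evaluates every enumerated bipartition of `pattern` against `table` and
#' returns the one with the smallest p-value, provided p < `alpha`. Ties
#' break by larger chi-squared, then by canonical enumeration order.
#' Bipartitions leaving a subgroup without any matching 6-mer are skipped.
#'
#' @inheritParams bipartition_test
#' @param pattern a `midd_pattern`.
#' @param alpha significance threshold (default 0.05).
#' @return a `bipartition_test`, or `NULL` when nothing is significant.
#' @export
top_bipartition <- function(table, pattern, alpha = 0.05, scale = 1000L,
                            chi2_mode = "pooled") {
  bps <- enumerate_bipartitions(pattern)
  if (length(bps) == 0L) return(NULL)
  table <- table[pattern_match(table$sixmer, pattern)]   # subset once
  best <- NULL
  for (bp in bps) {
    res <- tryCatch(
      bipartition_test(table, bp, scale = scale, chi2_mode = chi2_mode),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) ||
        res$pvalue < best$pvalue ||
        (res$pvalue == best$pvalue && res$chi2 > best$chi2))
      best <- res
  }
  if (is.null(best) || best$pvalue >= alpha) NULL else best
}

#' Cross-sample consensus bipartition
#'
#' Adopts the modal top bipartition when it was reported as the top
#' significant split by at least `min_frac` of all samples. Support is
#' `(n, m)`: `n` samples report the adopted split as their top, `m` report
#' any significant split. Ties between modal candidates break by smaller
#' mean p-value.
#'
#' @param per_sample_tops list of [top_bipartition()] results (`NULL`
#'   allowed) in sample order.
#' @param min_frac consensus fraction over all samples (default 0.5).
#' @return `list(bipartition, n, m)` or `NULL`.
#' @export
consensus_split <- function(per_sample_tops, min_frac = 0.5) {
  stopifnot(length(per_sample_tops) >= 1L)
  m <- sum(!vapply(per_sample_tops, is.null, logical(1)))
  if (m == 0L) return(NULL)
  ids <- vapply(per_sample_tops, function(t)
    if (is.null(t)) NA_character_ else bp_id(t$bipartition), character(1))
  ps <- vapply(per_sample_tops, function(t)
    if (is.null(t)) NA_real_ else t$pvalue, numeric(1))
  counts <- table(ids[!is.na(ids)])
  cand <- names(counts)[counts == max(counts)]
  if (length(cand) > 1L) {
    meanp <- vapply(cand, function(id) mean(ps[ids == id], na.rm = TRUE),
                    numeric(1))
    cand <- cand[order(meanp, cand)][1]
  }
  n <- as.integer(counts[cand])
  if (n < ceiling(min_frac * length(per_sample_tops))) return(NULL)
  bp <- per_sample_tops[[which(ids == cand)[1]]]$bipartition
  list(bipartition = bp, n = n, m = as.integer(m))
}

#' Build the hierarchical MiDD motif tree across samples
#'
#' Starting from `root_pattern`, each node evaluates [top_bipartition()]
#' per sample and [consensus_split()] across samples; when a split is
#' adopted the pattern's set at the split position is replaced by each
#' block, and the procedure recurses into both children until no consensus
#' split remains.
#'
#' @param tables named list of `context_table`, one per sample, sharing the
#'   6-mer key space.
#' @param root_pattern starting `midd_pattern` (default `pattern_ch()`).
#' @param alpha per-sample significance threshold (default 0.05).
#' @param min_frac consensus fraction (default 0.5).
#' @param scale pseudo-count scale (default 1000).
#' @param chi2_mode "pooled" or "stratified".
#' @param max_depth maximum number of split levels below the root
#'   (default `Inf`); nodes at the depth limit stay leaves.
#' @return object of class `midd_tree`.
#' @export
build_midd_tree <- function(tables, root_pattern = pattern_ch(),
                            alpha = 0.05, min_frac = 0.5, scale = 1000L,
                            chi2_mode = "pooled", max_depth = Inf) {
  stopifnot(length(tables) >= 1L)
  grow <- function(pattern, depth = 0L) {
    node <- list(pattern = pattern, split = NULL, n = 0L, m = 0L,
                 children = NULL)
    if (depth >= max_depth) return(node)
    tops <- lapply(tables, top_bipartition, pattern = pattern,
                   alpha = alpha, scale = scale, chi2_mode = chi2_mode)
    cons <- consensus_split(unname(tops), min_frac = min_frac)
    if (is.null(cons)) return(node)
    node$split <- cons$bipartition
    node$n <- cons$n
    node$m <- cons$m
    child_pattern <- function(block) {
      sets <- unclass(pattern)
      sets[[cons$bipartition$pos]] <- block
      midd_pattern(sets)
    }
    node$children <- list(grow(child_pattern(cons$bipartition$A), depth + 1L),
                          grow(child_pattern(cons$bipartition$B), depth + 1L))
    node
  }
  structure(
    list(root = grow(root_pattern),
         samples = names(tables) %||% seq_along(tables),
         params = list(alpha = alpha, min_frac = min_frac, scale = scale,
                       chi2_mode = chi2_mode)),
    class = "midd_tree")
}

midd_node_lines <- function(node, depth = 0L) {
  indent <- strrep("  ", depth)
  label <- pattern_string(node$pattern)
  line <- if (is.null(node$split)) {
    sprintf("%s%s (leaf)", indent, label)
  } else {
    sprintf("%s%s split pos %d: {%s}|{%s} [n/m = %d/%d]", indent, label,
            node$split$pos, paste(node$split$A, collapse = ","),
            paste(node$split$B, collapse = ","), node$n, node$m)
  }
  c(line, if (!is.null(node$children))
    unlist(lapply(node$children, midd_node_lines, depth = depth + 1L)))
}

#' @export
print.midd_tree <- function(x, ...) {
  cat("<midd_tree>", length(x$samples), "sample(s), alpha =",
      x$params$alpha, "\n")
  cat(midd_node_lines(x$root), sep = "\n")
  invisible(x)
}

#' Leaf patterns of a MiDD tree
#' @param tree a `midd_tree`.
#' @return character vector of leaf pattern strings (IUPAC).
#' @export
midd_leaves <- function(tree) {
  walk <- function(node) {
    if (is.null(node$children)) return(pattern_string(node$pattern))
    unlist(lapply(node$children, walk))
  }
  walk(tree$root)
}

midd_node_list <- function(node) {
  out <- list(pattern = pattern_string(node$pattern))
  if (!is.null(node$split)) {
    out$split <- list(pos = node$split$pos,
                      A = paste(node$split$A, collapse = ""),
                      B = paste(node$split$B, collapse = ""))
    out$support <- list(n = node$n, m = node$m)
    out$children <- lapply(node$children, midd_node_list)
  }
  out
}

#' Serialize a MiDD tree
#'
#' @param tree a `midd_tree`.
#' @param path optional file; when given, JSON (or indented text with
#'   `format = "text"`) is written there.
#' @param format "json" or "text".
#' @return JSON string or character vector of lines, invisibly when
#'   writing to a file.
#' @export
midd_tree_serialize <- function(tree, path = NULL,
                                format = c("json", "text")) {
  format <- match.arg(format)
  out <- if (format == "json") {
    jsonlite::toJSON(list(samples = tree$samples, params = tree$params,
                          tree = midd_node_list(tree$root)),
                     auto_unbox = TRUE, pretty = TRUE)
  } else {
    midd_node_lines(tree$root)
  }
  if (!is.null(path)) {
    writeLines(as.character(out), path)
    return(invisible(out))
  }
  out
}
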