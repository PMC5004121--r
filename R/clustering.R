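# Sample comparison by 6-mer methylation preference: distance is
# 1 - rho^2 with rho the Spearman rank correlation of the paired M_w
# vectors over the shared 6-mer keys (anticorrelated preferences count as
# similar, following the squared-correlation definition).

#' Context preference distance between two samples
#'
#' @param tableA,tableB `context_table`s.
#' @param min_shared minimum number of shared 6-mer keys (default 100).
#' @return distance in `[0, 1]`.
#' @export
preference_distance <- function(tableA, tableB, min_shared = 100L) {
  shared <- merge(tableA[, .(sixmer, a = M_w)], tableB[, .(sixmer, b = M_w)],
                  by = "sixmer")
  if (nrow(shared) < min_shared)
    stop(sprintf("insufficient-overlap error: %d shared 6-mers (< %d)",
                 nrow(shared), min_shared))
  if (sd(shared$a) == 0 || sd(shared$b) == 0) {
    warning("zero variance in a preference vector; distance set to 1")
    return(1)
  }
  rho <- cor(shared$a, shared$b, method = "spearman")
  1 - rho^2
}

#' Pairwise preference distance matrix
#'
#' @param tables named list of `context_table`s.
#' @inheritParams preference_distance
#' @return symmetric matrix of distances with zero diagonal.
#' @export
preference_distance_matrix <- function(tables, min_shared = 100L) {
  ids <- names(tables) %||% as.character(seq_along(tables))
  n <- length(tables)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- tryCatch(
      preference_distance(tables[[i]], tables[[j]], min_shared = min_shared),
      error = function(e) stop(sprintf("pair (%s, %s): %s", ids[i], ids[j],
                                       conditionMessage(e)), call. = FALSE))
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Cluster samples by context preference
#'
#' Complete-linkage agglomerative clustering on the `1 - rho^2` preference
#' distance matrix. Deterministic for a given input order.
#'
#' @param tables named list of `context_table`s (>= 2 samples).
#' @param linkage agglomeration method (default "complete").
#' @inheritParams preference_distance
#' @return object of class `sample_clustering`: list with the `hclust`
#'   tree, the distance `matrix`, and a `newick` string with merge heights
#'   as branch lengths.
#' @export
cluster_samples <- function(tables, linkage = "complete",
                            min_shared = 100L) {
  stopifnot(length(tables) >= 2L)
  d <- preference_distance_matrix(tables, min_shared = min_shared)
  hc <- hclust(as.dist(d), method = linkage)
  structure(list(hclust = hc, distance = d,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering>", nrow(x$distance), "samples,",
      x$hclust$method, "linkage\n")
  print(x$hclust)
  invisible(x)
}

#' Write a sample dendrogram as Newick
#'
#' @param clustering a `sample_clustering`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  writeLines(clustering$newick, path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param clustering a `sample_clustering`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(clustering, path) {
  dt <- data.table(sample = rownames(clustering$distance),
                   as.data.table(clustering$distance))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
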