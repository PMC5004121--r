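# Normalized motif frequencies. Genomic 6-mer abundance is unbalanced, so
# per-position nucleotide weights are the MEAN of M_w over the stored
# 6-mers carrying that nucleotide, not a sum over sites; frequencies then
# close to 1 within each position.

NUCS <- c("A", "C", "G", "T")

#' Normalized position frequency matrix of a methylation motif
#'
#' For each position p and nucleotide n, the weight is the mean `M_w` over
#' stored 6-mers with letter n at p (0 when no such 6-mer); frequencies are
#' the weights normalized to sum to 1 within the position. If a position
#' has zero total weight (all matching `M_w` are 0), frequencies fall back
#' to uniform over the letters observed there and a warning is raised.
#'
#' @param table a non-empty `context_table` (apply CCGG exclusion when
#'   building it, see [sixmer_table()]).
#' @return a `pfm`: 4 x 6 numeric matrix (rows A, C, G, T; columns sum to
#'   1) with the construction metadata as attributes.
#' @export
normalized_pfm <- function(table) {
  if (nrow(table) == 0L) stop("empty context table")
  letters <- sixmer_letter_matrix(table$sixmer)
  mw <- table$M_w
  f <- matrix(0, nrow = 4L, ncol = 6L, dimnames = list(NUCS, NULL))
  for (p in seq_len(6L)) {
    w <- vapply(NUCS, function(n) {
      hit <- letters[, p] == n
      if (!any(hit)) 0 else mean(mw[hit])
    }, numeric(1))
    tot <- sum(w)
    if (tot > 0) {
      f[, p] <- w / tot
    } else {
      present <- NUCS %in% letters[, p]
      warning(sprintf("position %d has zero total weight; using uniform frequencies", p))
      f[present, p] <- 1 / sum(present)
    }
  }
  structure(f, class = c("pfm", "matrix"),
            pattern_class = attr(table, "pattern_class"),
            exclude_ccgg = attr(table, "exclude_ccgg"),
            sample_id = attr(table, "sample_id"))
}

#' Degenerate consensus string of a PFM
#'
#' Per position, the smallest IUPAC code covering every nucleotide whose
#' frequency reaches `dominance_threshold`; 'N' when none does.
#'
#' @param pfm a [normalized_pfm()] matrix.
#' @param dominance_threshold frequency needed for a letter to enter the
#'   consensus set (default 0.4).
#' @return 6-character IUPAC string.
#' @export
consensus_string <- function(pfm, dominance_threshold = 0.4) {
  paste(vapply(seq_len(ncol(pfm)), function(p) {
    dom <- rownames(pfm)[pfm[, p] >= dominance_threshold]
    if (length(dom) == 0L) "N" else iupac_code(dom)
  }, character(1)), collapse = "")
}

#' Write a PFM in JASPAR-style tab format
#'
#' @param pfm a `pfm`.
#' @param path output file.
#' @param name motif identifier for the header.
#' @return `path`, invisibly.
#' @export
write_pfm_jaspar <- function(pfm, path, name = "motif") {
  lines <- c(paste0(">", name),
             vapply(NUCS, function(n)
               paste0(n, "  [ ", paste(sprintf("%.6f", pfm[n, ]),
                                       collapse = " "), " ]"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a PFM in MEME minimal motif format
#'
#' @inheritParams write_pfm_jaspar
#' @param nsites reported site count for the motif header.
#' @return `path`, invisibly.
#' @export
write_pfm_meme <- function(pfm, path, name = "motif", nsites = 100L) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: +", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "",
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     ncol(pfm), nsites),
             vapply(seq_len(ncol(pfm)), function(p)
               paste(sprintf("%.6f", pfm[, p]), collapse = "  "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
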