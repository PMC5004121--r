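# IUPAC degenerate nucleotide codes, keyed by the sorted letter set.
IUPAC_BY_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' IUPAC code for a set of nucleotides
#'
#' @param letters character vector of nucleotides from \{A, C, G, T\}.
#' @return single IUPAC letter covering exactly that set.
#' @export
iupac_code <- function(letters) {
  key <- paste(sort(unique(letters)), collapse = "")
  code <- IUPAC_BY_SET[key]
  if (is.na(code)) stop("not a nucleotide set: ", key)
  unname(code)
}

#' Nucleotides covered by an IUPAC code
#'
#' @param code single IUPAC letter.
#' @return character vector of plain nucleotides.
#' @export
iupac_letters <- function(code) {
  key <- names(IUPAC_BY_SET)[match(code, IUPAC_BY_SET)]
  if (is.na(key)) stop("unknown IUPAC code: ", code)
  strsplit(key, "")[[1]]
}

#' Reverse complement of sequence strings
#'
#' Vectorised; accepts the degenerate alphabet (IUPAC letters and N).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split 6-mer keys into an n x 6 character matrix (one column per position)
sixmer_letter_matrix <- function(keys) {
  stopifnot(all(nchar(keys) == 6L))
  m <- vapply(seq_len(6L), function(p) substr(keys, p, p),
              character(length(keys)))
  matrix(m, nrow = length(keys), ncol = 6L)
}

# convert an IUPAC consensus string (e.g. "TNCACC") to an anchored regex
iupac_regex <- function(consensus) {
  parts <- vapply(strsplit(consensus, "")[[1]], function(ch) {
    letters <- iupac_letters(ch)
    if (length(letters) == 1L) letters else
      paste0("[", paste(letters, collapse = ""), "]")
  }, character(1))
  paste0("^", paste(parts, collapse = ""), "$")
}
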