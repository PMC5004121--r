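#' Construct a methylome object
#'
#' A methylome holds one per-cytosine call table plus sample metadata. Calls
#' are kept sorted by (chrom, pos, strand) and must be unique per site and
#' strand. Methylation level of a call is `n_meth / n_total`.
#'
#' @param calls data.frame/data.table with columns `chrom`, `pos` (1-based),
#'   `strand` ('+'/'-'), `sixmer` (6-character context, central base C, 'N'
#'   allowed), `n_meth`, `n_total`.
#' @param sample_id,species,cell_type sample metadata labels.
#' @param library_type "WGBS" or "RRBS".
#' @return object of class `methylome`.
#' @export
new_methylome <- function(calls, sample_id = NA_character_,
                          species = NA_character_, cell_type = NA_character_,
                          library_type = c("WGBS", "RRBS")) {
  library_type <- match.arg(library_type)
  calls <- as.data.table(calls)
  required <- c("chrom", "pos", "strand", "sixmer", "n_meth", "n_total")
  missing <- setdiff(required, names(calls))
  if (length(missing))
    stop("calls missing columns: ", paste(missing, collapse = ", "))
  calls <- calls[, ..required]
  calls[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
               strand = as.character(strand), sixmer = as.character(sixmer),
               n_meth = as.integer(n_meth), n_total = as.integer(n_total))]
  validate_calls(calls)
  setorder(calls, chrom, pos, strand)
  structure(
    list(sample_id = sample_id, species = species, cell_type = cell_type,
         library_type = library_type, calls = calls),
    class = "methylome")
}

validate_calls <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(calls))
  if (any(calls$n_total < 1L))
    stop("validation error: n_total must be >= 1")
  if (any(calls$n_meth > calls$n_total))
    stop("validation error: n_meth > n_total")
  if (any(calls$n_meth < 0L))
    stop("validation error: negative n_meth")
  if (!all(calls$strand %in% c("+", "-")))
    stop("validation error: strand must be '+' or '-'")
  if (!all(nchar(calls$sixmer) == 6L & substr(calls$sixmer, 3, 3) == "C"))
    stop("validation error: sixmer must be 6 characters with central C")
  if (anyDuplicated(calls, by = c("chrom", "pos", "strand")))
    stop("validation error: duplicate (chrom, pos, strand)")
  invisible(calls)
}

# rebuild a methylome around a filtered call table, keeping metadata
replace_calls <- function(methylome, calls) {
  out <- methylome
  calls <- as.data.table(calls)
  setorder(calls, chrom, pos, strand)
  out$calls <- calls
  out
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s (%s, %s, %s): %d calls on %d chromosome(s)\n",
              x$sample_id, x$species, x$cell_type, x$library_type,
              nrow(x$calls), data.table::uniqueN(x$calls$chrom)))
  invisible(x)
}

#' Number of calls in a methylome
#' @param x methylome.
#' @export
n_calls <- function(x) nrow(x$calls)
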