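# CGmap dialect (BS-Seeker2): 8 tab-separated columns
#   chrom, nucleotide (C|G), pos (1-based), context (CG|CHG|CHH|--),
#   dinucleotide (CA|CC|CG|CT|--), level, n_meth, n_total
# The nucleotide column encodes the strand: 'C' = forward, 'G' = reverse.

open_maybe_gz <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a CGmap methylation call file
#'
#' Parses the 8-column BS-Seeker2 CGmap dialect (optionally gzipped) into a
#' [new_methylome()] object. Strand is '+' when the nucleotide column is 'C'
#' and '-' when it is 'G'. Lines with zero total reads are dropped. The
#' 6-mer context is seeded from the dinucleotide column as `NN<dinuc>NN`;
#' run [annotate_contexts()] against the genome to fill the full context.
#'
#' @param path CGmap file, plain or gzip.
#' @param sample_id,species,cell_type,library_type metadata for the sample.
#' @return a `methylome`.
#' @export
read_cgmap <- function(path, sample_id = basename(path),
                       species = NA_character_, cell_type = NA_character_,
                       library_type = "WGBS") {
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  if (length(lines) == 0L)
    return(new_methylome(
      data.table(chrom = character(), pos = integer(), strand = character(),
                 sixmer = character(), n_meth = integer(), n_total = integer()),
      sample_id = sample_id, species = species, cell_type = cell_type,
      library_type = library_type))
  nfields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfields != 8L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected 8 tab-separated columns, found %d",
                 bad[1], nfields[bad[1]]))
  dt <- fread(text = lines, sep = "\t", header = FALSE,
              col.names = c("chrom", "nuc", "pos", "ctx3", "dinuc",
                            "level", "n_meth", "n_total"),
              colClasses = list(character = c(1, 2, 4, 5)))
  if (!all(dt$nuc %in% c("C", "G")))
    stop("parse error: nucleotide column must be 'C' or 'G'")
  if (any(dt$n_meth > dt$n_total))
    stop("validation error: n_meth > n_total")
  dt <- dt[n_total > 0L]
  calls <- dt[, .(chrom, pos = as.integer(pos),
                  strand = ifelse(nuc == "C", "+", "-"),
                  sixmer = paste0("NN", dinuc, "NN"),
                  n_meth = as.integer(n_meth), n_total = as.integer(n_total))]
  new_methylome(calls, sample_id = sample_id, species = species,
                cell_type = cell_type, library_type = library_type)
}

#' Write a methylome as a CGmap file
#'
#' Emits the 8-column CGmap dialect, sorted by (chrom, pos). The level
#' column is printed with six decimals; the three-letter context column is
#' derived from the 6-mer ("--" when the neighbouring bases are unknown).
#'
#' @param methylome a `methylome`.
#' @param path output file; ".gz" suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(methylome, path) {
  calls <- methylome$calls
  dinuc <- substr(calls$sixmer, 3, 4)
  h <- substr(calls$sixmer, 4, 4)
  third <- substr(calls$sixmer, 5, 5)
  ctx3 <- ifelse(h == "G", "CG",
          ifelse(h == "N" | third == "N", "--",
          ifelse(third == "G", "CHG", "CHH")))
  out <- data.table(
    chrom = calls$chrom,
    nuc = ifelse(calls$strand == "+", "C", "G"),
    pos = calls$pos, ctx3 = ctx3, dinuc = dinuc,
    level = sprintf("%.6f", calls$n_meth / calls$n_total),
    n_meth = calls$n_meth, n_total = calls$n_total)
  setorder(out, chrom, pos)
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con), add = TRUE)
  ok <- tryCatch({
    writeLines(do.call(paste, c(as.list(out), sep = "\t")), con)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a two-column SNV position list
#'
#' @param path TSV with columns chrom and 1-based position (no header).
#' @return data.table with columns `chrom`, `pos`.
#' @export
read_snv_list <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "pos"))
  dt[, .(chrom = as.character(chrom), pos = as.integer(pos))]
}
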