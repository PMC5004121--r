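# Region sets are GRanges (1-based, inclusive, as usual in R) carrying a
# `family` metadata column and optionally a `name`. All text interchange
# (BED) uses 0-based half-open coordinates; conversion happens only here.

#' Build a region set from 0-based half-open intervals
#'
#' @param chrom,start,end vectors; `start`/`end` in BED convention
#'   (0-based, half-open).
#' @param strand '+'/'-'/'.' per interval (recycled).
#' @param name,family labels per interval (recycled).
#' @param label optional set-level label stored as metadata.
#' @return sorted `GRanges` with `name` and `family` columns.
#' @export
region_set <- function(chrom, start, end, strand = ".", name = ".",
                       family = ".", label = NULL) {
  if (any(end <= start))
    stop("validation error: end must be > start (0-based half-open)")
  n <- length(chrom)
  strand <- rep_len(strand, n)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end), strand = strand)
  S4Vectors::mcols(gr)$name <- rep_len(name, length(gr))
  S4Vectors::mcols(gr)$family <- rep_len(family, length(gr))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Load genomic regions from BED or GFF3
#'
#' BED coordinates (0-based half-open) are converted to the in-memory
#' 1-based convention; GFF3 features (1-based inclusive) pass through.
#' The region family label is taken from `family_field`: for BED that is
#' the name column (4), for GFF3 an attribute name (e.g. "ID").
#'
#' @param path file path.
#' @param format "bed" or "gff"; guessed from the extension by default.
#' @param family_field which field carries the family label (BED: "name";
#'   GFF: attribute name).
#' @param label optional set-level label.
#' @return sorted `GRanges` with `name` and `family` columns.
#' @export
load_regions <- function(path, format = NULL, family_field = NULL,
                         label = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff" else "bed"
  }
  format <- match.arg(format, c("bed", "gff"))
  if (format == "bed") {
    dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
    if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
    bad <- which(dt[[3]] <= dt[[2]])
    if (length(bad))
      stop(sprintf("validation error at line %d: end <= start", bad[1]))
    name <- if (ncol(dt) >= 4L) as.character(dt[[4]]) else "."
    strand <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else "."
    region_set(as.character(dt[[1]]), as.integer(dt[[2]]),
               as.integer(dt[[3]]), strand = strand, name = name,
               family = name, label = label)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if (any(GenomicRanges::width(gr) < 1L))
      stop("validation error: empty GFF feature")
    fam <- if (!is.null(family_field) &&
               family_field %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)[[family_field]])
    else as.character(S4Vectors::mcols(gr)$type)
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$name <- fam
    S4Vectors::mcols(out)$family <- fam
    out <- GenomeInfoDb::sortSeqlevels(out)
    out <- GenomicRanges::sort(out, ignore.strand = TRUE)
    if (!is.null(label)) S4Vectors::metadata(out)$label <- label
    out
  }
}

#' Write a region set as BED6
#'
#' @param regions `GRanges` with a `family` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  fam <- S4Vectors::mcols(regions)$family %||% rep(".", length(regions))
  strand <- as.character(GenomicRanges::strand(regions))
  strand[strand == "*"] <- "."
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = fam, score = 0L, strand = strand)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Construct a gene model
#'
#' @param chrom chromosome.
#' @param strand '+' or '-'.
#' @param exons data.frame with 1-based inclusive `start`, `end` columns,
#'   in transcription order (exon 1 first).
#' @param gene_id label.
#' @return object of class `gene_model`; the TSS is derived from exon 1.
#' @export
gene_model <- function(chrom, strand, exons, gene_id = NA_character_) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L)
  exons <- as.data.table(exons)[, .(start = as.integer(start),
                                    end = as.integer(end))]
  if (any(exons$end < exons$start)) stop("exon end < start")
  ord <- if (strand == "+") order(exons$start) else -order(-exons$start)
  if (strand == "+" && is.unsorted(exons$start))
    stop("exons must be in transcription order")
  if (strand == "-" && is.unsorted(-exons$start))
    stop("exons must be in transcription order")
  tss <- if (strand == "+") exons$start[1] else exons$end[1]
  structure(list(chrom = chrom, strand = strand, tss = tss,
                 exons = exons, gene_id = gene_id),
            class = "gene_model")
}

#' Read gene models from BED12
#'
#' Exon blocks become [gene_model()] exons; the thick/score fields are
#' ignored. Coordinates convert from BED to 1-based.
#'
#' @param path BED12 file.
#' @return list of `gene_model`.
#' @export
read_bed12_genes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 12L) stop("BED12 requires 12 columns")
  lapply(seq_len(nrow(dt)), function(i) {
    chromStart <- as.integer(dt[[2]][i])
    sizes <- as.integer(strsplit(sub(",$", "", dt[[11]][i]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", dt[[12]][i]), ",")[[1]])
    strand <- as.character(dt[[6]][i])
    ex <- data.table(start = chromStart + starts + 1L,
                     end = chromStart + starts + sizes)
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex)))]
    gene_model(as.character(dt[[1]][i]), strand, ex,
               gene_id = as.character(dt[[4]][i]))
  })
}

#' Write gene models as BED12
#'
#' @param genes list of `gene_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed12_genes <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    ex <- g$exons[order(start)]
    chromStart <- ex$start[1] - 1L
    chromEnd <- ex$end[nrow(ex)]
    sizes <- paste0(paste(ex$end - ex$start + 1L, collapse = ","), ",")
    starts <- paste0(paste(ex$start - 1L - chromStart, collapse = ","), ",")
    paste(g$chrom, chromStart, chromEnd, g$gene_id, 0, g$strand,
          chromStart, chromEnd, "0,0,0", nrow(ex), sizes, starts,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# map a window given as 0-based offsets [s, e) relative to the TSS into
# genomic 1-based coordinates; '-' genes reflect the window about the TSS
rel_window <- function(tss, strand, s, e) {
  if (strand == "+") c(start = tss + s, end = tss + e - 1L)
  else c(start = tss - e, end = tss - 1L - s)
}

#' Derive the standard gene subregions
#'
#' Builds the region classes used throughout the analysis, all computed in
#' transcription direction and inheriting the gene strand:
#' \describe{
#'   \item{promoter}{`promoter_up` bp upstream of the TSS to
#'     `promoter_down` bp downstream (default -500/+100).}
#'   \item{1stExon / postExon}{first exon; exons 2 and later.}
#'   \item{postIntron}{introns 2 and later (transcription order).}
#'   \item{post5SS / post3SS / postMI}{first / last `ss_len` bp of each
#'     posterior intron and its central remainder (the remainder is dropped
#'     when the intron is shorter than `mi_min_intron`).}
#'   \item{geneBody}{TSS to transcription end.}
#'   \item{intergenic}{a window of `intergenic_len` bp located
#'     `intergenic_offset` bp upstream of the TSS.}
#' }
#' Windows are clipped at position 1; exact duplicate intervals are removed
#' within each class.
#'
#' @param genes list of [gene_model()].
#' @param promoter_up,promoter_down promoter window in bp (defaults 500/100).
#' @param intergenic_offset,intergenic_len intergenic window placement
#'   (defaults 10000/1000).
#' @param ss_len splice-site window inside posterior introns (default 200).
#' @param mi_min_intron minimum intron length for a postMI region
#'   (default 500).
#' @return named list of `GRanges`, one per region class.
#' @export
derive_gene_subregions <- function(genes, promoter_up = 500L,
                                   promoter_down = 100L,
                                   intergenic_offset = 10000L,
                                   intergenic_len = 1000L,
                                   ss_len = 200L, mi_min_intron = 500L) {
  acc <- list(promoter = list(), `1stExon` = list(), postExon = list(),
              postIntron = list(), post5SS = list(), postMI = list(),
              post3SS = list(), intergenic = list(), geneBody = list())
  push <- function(class, g, start, end) {
    start <- max(1L, as.integer(start))
    if (end < start) return()
    acc[[class]][[length(acc[[class]]) + 1L]] <<-
      data.table(chrom = g$chrom, start = start, end = as.integer(end),
                 strand = g$strand, name = g$gene_id)
  }
  for (g in genes) {
    w <- rel_window(g$tss, g$strand, -promoter_up, promoter_down)
    push("promoter", g, w["start"], w["end"])
    w <- rel_window(g$tss, g$strand, -intergenic_offset,
                    -intergenic_offset + intergenic_len)
    push("intergenic", g, w["start"], w["end"])
    ex <- g$exons
    push("1stExon", g, ex$start[1], ex$end[1])
    if (nrow(ex) >= 2L)
      for (i in 2:nrow(ex)) push("postExon", g, ex$start[i], ex$end[i])
    push("geneBody", g, min(ex$start), max(ex$end))
    # introns in transcription order: between consecutive exons
    if (nrow(ex) >= 3L) {
      for (i in 2:(nrow(ex) - 1L)) {       # posterior introns: 2nd and later
        if (g$strand == "+") {
          istart <- ex$end[i] + 1L; iend <- ex$start[i + 1L] - 1L
        } else {
          istart <- ex$end[i + 1L] + 1L; iend <- ex$start[i] - 1L
        }
        if (iend < istart) next
        ilen <- iend - istart + 1L
        push("postIntron", g, istart, iend)
        k <- min(ss_len, ilen)
        if (g$strand == "+") {
          push("post5SS", g, istart, istart + k - 1L)
          push("post3SS", g, iend - k + 1L, iend)
          if (ilen >= mi_min_intron)
            push("postMI", g, istart + ss_len, iend - ss_len)
        } else {
          push("post5SS", g, iend - k + 1L, iend)
          push("post3SS", g, istart, istart + k - 1L)
          if (ilen >= mi_min_intron)
            push("postMI", g, istart + ss_len, iend - ss_len)
        }
      }
    }
  }
  out <- lapply(names(acc), function(class) {
    rows <- acc[[class]]
    if (length(rows) == 0L)
      return(region_set(character(), integer(), integer(), label = class))
    dt <- unique(rbindlist(rows))
    region_set(dt$chrom, dt$start - 1L, dt$end, strand = dt$strand,
               name = dt$name, family = class, label = class)
  })
  names(out) <- names(acc)
  out
}

#' All introns of a set of gene models
#'
#' Strand-aware: intron intervals inherit the host gene strand. Used for
#' intron skew analyses where "sense" means the gene strand.
#'
#' @param genes list of `gene_model`.
#' @param posterior_only keep only introns 2 and later (default FALSE).
#' @return `GRanges` of introns.
#' @export
gene_introns <- function(genes, posterior_only = FALSE) {
  rows <- list()
  for (g in genes) {
    ex <- g$exons
    if (nrow(ex) < 2L) next
    from <- if (posterior_only) 2L else 1L
    if (from > nrow(ex) - 1L) next
    for (i in from:(nrow(ex) - 1L)) {
      if (g$strand == "+") {
        istart <- ex$end[i] + 1L; iend <- ex$start[i + 1L] - 1L
      } else {
        istart <- ex$end[i + 1L] + 1L; iend <- ex$start[i] - 1L
      }
      if (iend < istart) next
      rows[[length(rows) + 1L]] <-
        data.table(chrom = g$chrom, start = istart, end = iend,
                   strand = g$strand, name = g$gene_id)
    }
  }
  if (length(rows) == 0L)
    return(region_set(character(), integer(), integer(), label = "intron"))
  dt <- rbindlist(rows)
  region_set(dt$chrom, dt$start - 1L, dt$end, strand = dt$strand,
             name = dt$name, family = "intron", label = "intron")
}
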