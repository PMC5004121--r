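test_that("read_cgmap maps fields, drops uncovered sites, validates input", {
  f <- withr::local_tempfile(fileext = ".cgmap")
  writeLines(c("chr1\tC\t100\tCHH\tCA\t0.75\t3\t4",
               "chr1\tG\t150\tCHH\tCT\t0.00\t0\t5",
               "chr2\tC\t7\tCG\tCG\t1.00\t2\t2",
               "chr1\tC\t300\tCHH\tCC\t0.00\t0\t0"), f)
  m <- read_cgmap(f, sample_id = "t")
  expect_equal(nrow(m$calls), 3L)          # zero-coverage line dropped
  first <- m$calls[1]
  expect_equal(first$chrom, "chr1")
  expect_equal(first$pos, 100L)
  expect_equal(first$strand, "+")
  expect_equal(first$n_meth, 3L)
  expect_equal(first$n_total, 4L)
  expect_equal(first$sixmer, "NNCANN")     # dinucleotide seeds positions 3-4
  expect_equal(m$calls[pos == 150L, strand], "-")

  empty <- withr::local_tempfile(fileext = ".cgmap")
  file.create(empty)
  expect_equal(n_calls(read_cgmap(empty)), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\tC\t100\tCHH\tCA\t0.75\t3\t4",
               "chr1\tC\t101\tCHH\tCA\t0.75\t3"), bad)
  expect_error(read_cgmap(bad), "line 2")
  bad2 <- withr::local_tempfile()
  writeLines("chr1\tC\t100\tCHH\tCA\t0.75\t5\t4", bad2)
  expect_error(read_cgmap(bad2), "n_meth > n_total")
})

test_that("write_cgmap emits the dialect and round-trips, including gzip", {
  m <- mk_methylome(pos = c(10L, 20L), strand = c("+", "-"),
                    sixmer = c("TTCACC", "AACTGA"),
                    n_meth = c(3L, 1L), n_total = c(4L, 9L))
  f <- withr::local_tempfile(fileext = ".cgmap")
  write_cgmap(m, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == 8L))
  expect_equal(fields[[1]][2], "C")
  expect_equal(fields[[2]][2], "G")        # '-' strand encodes nucleotide G
  expect_equal(fields[[1]][5], "CA")

  cfg <- quick_config(seed = 11, n_samples = 1L, chrom_len = 20000L)
  co <- simulate_cohort(cfg)
  orig <- co$methylomes$s1
  for (ext in c(".cgmap", ".cgmap.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cgmap(orig, path)
    back <- read_cgmap(path, sample_id = orig$sample_id)
    back <- annotate_contexts(back, co$sim$genome)
    expect_identical(back$calls, orig$calls)
  }
})

test_that("annotate_contexts slices the genome strand-appropriately", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTTCACCGGTGAAA"))
  # '+' call at the cytosine at pos 6: bases 4..9 give "TTCACC"
  m <- mk_methylome(pos = 6L, strand = "+", sixmer = "NNCANN")
  expect_equal(annotate_contexts(m, genome)$calls$sixmer, "TTCACC")
  # '-' call at a forward G: forward [p-3..p+2] reverse-complemented
  p <- 10L
  mm <- mk_methylome(pos = p, strand = "-", sixmer = "NNCANN")
  expected <- revcomp(substr("ACGTTCACCGGTGAAA", p - 3L, p + 2L))
  expect_equal(annotate_contexts(mm, genome)$calls$sixmer, expected)
  # boundary padding with N
  m1 <- mk_methylome(pos = 10L, strand = "+",
                     sixmer = "NNCANN",
                     chrom = "chr2")
  genome2 <- Biostrings::DNAStringSet(c(chr2 = paste0(strrep("A", 9), "CAA")))
  m1$calls$pos <- 1L
  genome2 <- Biostrings::DNAStringSet(c(chr2 = "CAAAAA"))
  out <- annotate_contexts(m1, genome2)
  expect_equal(out$calls$sixmer, "NNCAAA")
  # non-cytosine centre dropped with a message
  m2 <- mk_methylome(pos = c(1L, 2L), strand = "+", sixmer = "NNCANN",
                     chrom = "chr2")
  expect_message(out2 <- annotate_contexts(m2, genome2), "dropped 1")
  expect_equal(out2$calls$pos, 1L)
  expect_error(annotate_contexts(mk_methylome(pos = 1L, chrom = "chrX"),
                                 genome2), "lookup error")
})

test_that("context annotation is strand-symmetric under genome mirroring", {
  cfg <- quick_config(seed = 5, n_samples = 1L, chrom_len = 5000L,
                      n_chrom = 1L)
  co <- simulate_cohort(cfg)
  m <- co$methylomes$s1
  len <- Biostrings::width(co$sim$genome)[1]
  mirrored_genome <- Biostrings::reverseComplement(co$sim$genome)
  names(mirrored_genome) <- names(co$sim$genome)
  flipped <- m$calls[, .(chrom, pos = len - pos + 1L,
                         strand = ifelse(strand == "+", "-", "+"),
                         sixmer = "NNCANN", n_meth, n_total)]
  out <- annotate_contexts(replace_calls(m, flipped), mirrored_genome)
  merged <- merge(out$calls, m$calls[, .(pos2 = len - pos + 1L, sixmer)],
                  by.x = "pos", by.y = "pos2")
  expect_equal(nrow(merged), nrow(m$calls))
  expect_identical(merged$sixmer.x, merged$sixmer.y)
})

test_that("classify_context follows the H base", {
  expect_equal(classify_context(c("TTCACC", "AACGTT", "AACNTT", "GGCCGG")),
               c("CW", "CG", "unknown", "CC"))
  expect_error(classify_context("AAAGTT"), "contract violation")
})

test_that("filter_near_snv removes symmetric windows and counts removals", {
  m <- mk_methylome(pos = c(99L, 100L, 101L, 103L))
  snv <- data.frame(chrom = "chr1", pos = 100L)
  out <- filter_near_snv(m, snv, dist = 1L)
  expect_equal(out$calls$pos, 103L)
  expect_equal(attr(out, "n_removed"), 3L)
  out0 <- filter_near_snv(m, snv, dist = 0L)
  expect_equal(out0$calls$pos, c(99L, 101L, 103L))
  other <- filter_near_snv(m, data.frame(chrom = "chr9", pos = 100L))
  expect_equal(n_calls(other), 4L)
  expect_equal(attr(other, "n_removed"), 0L)
})

test_that("filter_near_snv matches a brute-force oracle and is order-stable", {
  set.seed(42)
  for (i in 1:20) {
    pos <- sample.int(200L, 30L)
    snv_pos <- sample.int(200L, 5L)
    dist <- sample(0:3, 1)
    m <- mk_methylome(pos = pos)
    out <- filter_near_snv(m, data.frame(chrom = "chr1", pos = snv_pos),
                           dist = dist)
    keep_oracle <- vapply(sort(pos), function(p)
      all(abs(p - snv_pos) > dist), logical(1))
    expect_equal(out$calls$pos, sort(pos)[keep_oracle])
    expect_equal(attr(out, "n_removed") + n_calls(out), n_calls(m))
    # order of input must not matter
    m_shuf <- mk_methylome(pos = sample(pos))
    out2 <- filter_near_snv(m_shuf,
                            data.frame(chrom = "chr1", pos = snv_pos),
                            dist = dist)
    expect_identical(out2$calls, out$calls)
  }
})

test_that("mask_regions applies interval union semantics", {
  m <- mk_methylome(pos = c(5L, 15L, 25L))
  rs <- region_set("chr1", 10L, 20L)          # 0-based half-open [10, 20)
  expect_equal(mask_regions(m, rs, "exclude")$calls$pos, c(5L, 25L))
  expect_equal(mask_regions(m, rs, "include")$calls$pos, 15L)
  empty <- region_set(character(), integer(), integer())
  expect_equal(n_calls(mask_regions(m, empty, "include")), 0L)
  expect_identical(mask_regions(m, empty, "exclude")$calls, m$calls)
  # interval strand is ignored for masking
  rs_minus <- region_set("chr1", 10L, 20L, strand = "-")
  expect_equal(mask_regions(m, rs_minus, "exclude")$calls$pos, c(5L, 25L))
})

test_that("sixmer_table aggregates levels per 6-mer with the stated filters", {
  m <- mk_methylome(pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                    sixmer = c("TTCACC", "TTCACC", "TCCCGG", "AACTNA",
                               "GGCAAA", "ACCGGT"),
                    n_meth = c(3L, 1L, 2L, 1L, 1L, 1L),
                    n_total = c(4L, 4L, 2L, 2L, 3L, 2L))
  tab <- sixmer_table(m, class_filter = "CH")
  expect_equal(tab[sixmer == "TTCACC", M_w], 4 / 8)   # read-weighted
  expect_false("AACTNA" %in% tab$sixmer)              # N-containing dropped
  expect_true("TCCCGG" %in% tab$sixmer)               # a CC-class key
  tab2 <- sixmer_table(m, class_filter = "CH", exclude_ccgg = TRUE)
  expect_false("TCCCGG" %in% tab2$sixmer)             # contains CCGG
  tab3 <- sixmer_table(m, class_filter = "CH", min_cov = 4L)
  expect_false("GGCAAA" %in% tab3$sixmer)
  # class filters restrict on the central dinucleotide
  expect_equal(sixmer_table(m, "CW")$sixmer, c("GGCAAA", "TTCACC"))
  expect_equal(sixmer_table(m, "CG")$sixmer, "ACCGGT")
  expect_false("ACCGGT" %in% tab$sixmer)              # CG is outside CH
  # per-site aggregation switch
  tabs <- sixmer_table(m, "CH", level_aggregation = "sites")
  expect_equal(tabs[sixmer == "TTCACC", M_w], mean(c(3 / 4, 1 / 4)))
})

test_that("sixmer_table matches a per-site brute-force recomputation", {
  cfg <- quick_config(seed = 23, n_samples = 1L, chrom_len = 50000L,
                      n_chrom = 1L)
  m <- simulate_cohort(cfg)$methylomes$s1
  m <- replace_calls(m, m$calls[1:min(1000L, .N)])
  tab <- sixmer_table(m, class_filter = "CH")
  calls <- as.data.frame(m$calls)
  h <- substr(calls$sixmer, 4, 4)
  keep <- h %in% c("A", "C", "T") & !grepl("N", calls$sixmer, fixed = TRUE)
  calls <- calls[keep, ]
  for (k in unique(calls$sixmer)) {
    sub <- calls[calls$sixmer == k, ]
    expect_identical(tab[sixmer == k, M_w],
                     sum(sub$n_meth) / sum(sub$n_total))
    expect_identical(tab[sixmer == k, site_count], nrow(sub))
  }
  expect_setequal(tab$sixmer, unique(calls$sixmer))
})
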