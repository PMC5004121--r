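test_that("chromosome_profile bins read-weighted levels and smooths them", {
  m <- mk_methylome(pos = c(100L, 30100L), sixmer = "AACAAA",
                    n_meth = c(3L, 1L), n_total = c(4L, 1L))
  prof <- chromosome_profile(m, "chr1", bin_size = 20000L,
                             chrom_length = 60000L)
  expect_equal(nrow(prof$bins), 3L)
  expect_equal(unname(prof$raw[1, "CA"]), 0.75)
  expect_equal(unname(prof$raw[2, "CA"]), 1.0)
  expect_true(is.na(prof$raw[3, "CA"]))
  expect_true(all(is.na(prof$raw[, "CG"])))
  expect_error(chromosome_profile(m, "chrZ"), "lookup error")

  # constant profile: smoothing is a fixed point
  mc <- mk_methylome(pos = seq(1000L, 99000L, by = 1000L),
                     sixmer = "AACAAA", n_meth = 1L, n_total = 2L)
  pc <- chromosome_profile(mc, "chr1", bin_size = 10000L,
                           chrom_length = 100000L)
  expect_equal(pc$smoothed[, "CA"], pc$raw[, "CA"])

  # step profile: rolling mean matches the hand computation
  pos <- seq(500L, 9500L, by = 1000L)          # 10 bins of 1 kb
  lv <- ifelse(pos < 5000L, 0L, 1L)
  ms <- mk_methylome(pos = pos, sixmer = "AACAAA",
                     n_meth = as.integer(lv), n_total = 1L)
  ps <- chromosome_profile(ms, "chr1", bin_size = 1000L,
                           smooth_window = 3L, chrom_length = 10000L)
  hand <- vapply(seq_len(10L), function(i)
    mean(ps$raw[max(1, i - 1):min(10, i + 1), "CA"]), numeric(1))
  expect_equal(ps$smoothed[, "CA"], hand)
})

test_that("smoothing approximately preserves the overall profile mean", {
  set.seed(8)
  m <- mk_methylome(pos = sort(sample.int(200000L, 400L)),
                    sixmer = "AACAAA",
                    n_meth = rbinom(400L, 5L, 0.3), n_total = 5L)
  m <- replace_calls(m, m$calls[n_meth <= n_total])
  prof <- chromosome_profile(m, "chr1", bin_size = 5000L,
                             smooth_window = 5L, chrom_length = 200000L)
  raw_mean <- mean(prof$raw[, "CA"], na.rm = TRUE)
  smooth_mean <- mean(prof$smoothed[, "CA"], na.rm = TRUE)
  expect_lt(abs(raw_mean - smooth_mean), 0.02)
})

test_that("context_profile_correlation computes 1 - r^2 distances", {
  base <- sin(seq(0, 4 * pi, length.out = 30)) / 4 + 0.5
  raw <- cbind(CA = base, CT = 0.5 * base + 0.1,
               CC = rep(0.3, 30))
  prof <- structure(list(raw = raw), class = "chromosome_profile")
  res <- context_profile_correlation(prof)
  expect_equal(res$r["CA", "CA"], 1)
  expect_equal(res$r["CA", "CT"], 1)              # affine transform
  expect_equal(res$distance["CA", "CT"], 0)
  expect_true(is.na(res$r["CA", "CC"]))           # zero variance flagged
  expect_equal(res$distance["CA", "CC"], 1)
  expect_true("CA/CC" %in% res$flagged)
  # concordant CA/CT merge before the independent context joins
  set.seed(2)
  raw2 <- cbind(CA = base, CT = base + rnorm(30, 0, 0.02),
                CC = runif(30))
  res2 <- context_profile_correlation(
    structure(list(raw = raw2), class = "chromosome_profile"))
  first <- res2$hclust$merge[1, ]
  expect_setequal(res2$hclust$labels[-first],
                  c("CA", "CT"))
})

test_that("metaregion_profile places sites into flank and body bins", {
  # one '+' element [1001, 2000], one sense CW site at its 5' end
  el <- region_set("chr1", 1000L, 2000L, strand = "+")
  m <- mk_methylome(pos = 1001L, sixmer = "AACAAA", n_meth = 2L,
                    n_total = 2L)
  prof <- metaregion_profile(m, el, strand_mode = "by_strand")
  body_sense <- as.data.frame(prof)[prof$segment == "body" &
                                      prof$strand == "sense", ]
  expect_equal(body_sense$level[body_sense$bin == 1], 1.0)
  expect_true(all(is.na(body_sense$level[body_sense$bin > 1])))
  expect_true(all(is.na(
    as.data.frame(prof)[prof$strand == "antisense", "level"])))
  # flank bins: site 1 bp upstream lands in the innermost upstream bin
  up <- mk_methylome(pos = 1000L, sixmer = "AACAAA", n_meth = 1L,
                     n_total = 1L)
  pu <- metaregion_profile(up, el, flank_bp = 500L, flank_bin = 50L)
  updat <- as.data.frame(pu)[pu$segment == "upstream", ]
  expect_equal(updat$level[updat$bin == 10], 1.0)
  # downstream flank on the far side
  dn <- mk_methylome(pos = 2001L, sixmer = "AACAAA", n_meth = 0L,
                     n_total = 1L)
  pd <- metaregion_profile(dn, el)
  dndat <- as.data.frame(pd)[pd$segment == "downstream", ]
  expect_equal(dndat$level[dndat$bin == 1], 0)
})

test_that("short elements spread sites over body bins by fractional overlap", {
  el <- region_set("chr1", 1000L, 1005L, strand = "+")   # length 5 < 20 bins
  m <- mk_methylome(pos = 1003L, sixmer = "AACAAA", n_meth = 1L,
                    n_total = 1L)
  prof <- metaregion_profile(m, el, body_bins = 20L)
  body <- as.data.frame(prof)[prof$segment == "body", ]
  covered <- body[!is.na(body$level), ]
  # site occupies element offsets [2, 3) -> bins 9..12 of 20
  expect_equal(covered$bin, 9:12)
  expect_equal(sum(covered$w_total), 1.0)
})

test_that("metaregion profiles are invariant under genome mirroring", {
  cfg <- quick_config(seed = 17, n_samples = 1L, chrom_len = 60000L,
                      n_chrom = 1L)
  co <- simulate_cohort(cfg)
  m <- co$methylomes$s1
  reps <- co$sim$repeats
  len <- cfg$chrom_len
  prof <- metaregion_profile(m, reps, strand_mode = "by_strand")
  # mirror: positions reflected, strands flipped, element intervals mapped
  flip <- m$calls[, .(chrom, pos = len - pos + 1L,
                      strand = ifelse(strand == "+", "-", "+"),
                      sixmer, n_meth, n_total)]
  mm <- replace_calls(m, flip)
  st <- as.character(GenomicRanges::strand(reps))
  mirrored <- region_set(
    as.character(GenomicRanges::seqnames(reps)),
    len - GenomicRanges::end(reps),
    len - GenomicRanges::start(reps) + 1L,
    strand = ifelse(st == "+", "-", "+"),
    family = S4Vectors::mcols(reps)$family)
  prof_m <- metaregion_profile(mm, mirrored, strand_mode = "by_strand")
  expect_equal(as.data.frame(prof_m), as.data.frame(prof))
  # element order permutation changes nothing either
  prof_p <- metaregion_profile(m, rev(reps), strand_mode = "by_strand")
  expect_equal(as.data.frame(prof_p), as.data.frame(prof))
})

test_that("strand_skew_score is zero for balance and antisymmetric exactly", {
  el <- region_set("chr1", c(0L, 2000L, 4000L), c(1000L, 3000L, 5000L),
                   strand = "+")
  pos_in <- function(k) as.integer(c(k * 2000 + seq(100, 400, 100),
                                     k * 2000 + seq(500, 800, 100)))
  calls <- data.table::rbindlist(lapply(0:2, function(k)
    data.table::data.table(
      chrom = "chr1", pos = pos_in(k),
      strand = rep(c("+", "-"), each = 4L),
      sixmer = "AACAAA",
      n_meth = rep(c(1L, 1L), each = 4L), n_total = 2L)))
  m <- new_methylome(calls, sample_id = "bal")
  res <- strand_skew_score(m, el)
  expect_equal(res$score, 0)
  expect_equal(res$pvalue, 1)

  # plant an antisense excess (with between-element spread so the paired
  # t-test is non-degenerate) and check the sign plus exact antisymmetry
  calls2 <- data.table::copy(calls)
  calls2[strand == "-", n_meth := 2L]
  calls2[strand == "-" & pos > 2400L & pos < 2900L,
         n_meth := c(2L, 2L, 2L, 1L)]
  m2 <- new_methylome(calls2, sample_id = "skewed")
  r2 <- strand_skew_score(m2, el)
  expect_lt(r2$score, 0)
  flipped <- data.table::copy(calls2)
  flipped[, strand := ifelse(strand == "+", "-", "+")]
  r3 <- strand_skew_score(new_methylome(flipped, sample_id = "flip"), el)
  expect_equal(r3$score, -r2$score)
  expect_equal(r3$pvalue, r2$pvalue)
  expect_equal(r3$mean_sense, r2$mean_antisense)
})

test_that("strand_skew_score reports insufficient data honestly", {
  el <- region_set("chr1", 0L, 1000L, strand = "+")
  m <- mk_methylome(pos = c(10L, 20L, 30L), strand = c("+", "+", "-"),
                    sixmer = "AACAAA")
  res <- strand_skew_score(m, el)
  expect_true(is.na(res$score))
  expect_equal(res$n_elements, 0L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_skew_tsv(list(res), f)
  expect_equal(nrow(read.delim(f)), 1L)
})

test_that("planted intron antisense skew is detected in simulated cohorts", {
  cfg <- quick_config(seed = 41, n_samples = 1L, chrom_len = 80000L,
                      n_chrom = 1L)
  cfg$intron_strand_skew <- c(ct = 1.6)
  co <- simulate_cohort(cfg)
  introns <- gene_introns(co$sim$genes)
  res <- strand_skew_score(co$methylomes$s1, introns)
  expect_lt(res$score, 0)
  expect_lt(res$pvalue, 0.05)
  expect_gt(res$mean_antisense, res$mean_sense)
})
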