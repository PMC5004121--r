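test_that("bipartition enumeration matches brute-force subset counting", {
  root <- pattern_ch()
  bps <- enumerate_bipartitions(root)
  expect_length(bps, 31L)                  # 7 + 7 + 3 + 7 + 7
  counts <- table(vapply(bps, `[[`, 0L, "pos"))
  expect_equal(unname(counts[as.character(c(1, 2, 4, 5, 6))]),
               c(7L, 7L, 3L, 7L, 7L), ignore_attr = TRUE)
  for (p in c(1L, 2L, 4L, 5L, 6L)) {
    want <- brute_bipartitions(root[[p]])
    got <- Filter(function(b) b$pos == p, bps)
    key <- function(b) paste(paste(b$A, collapse = ""),
                             paste(b$B, collapse = ""), sep = "|")
    # same unordered splits, regardless of block orientation
    norm <- function(b) paste(sort(c(paste(b$A, collapse = ""),
                                     paste(b$B, collapse = ""))),
                              collapse = "|")
    expect_setequal(vapply(got, norm, ""), vapply(want, norm, ""))
    # canonical orientation: block A is lexicographically smaller
    for (b in got)
      expect_true(paste(b$A, collapse = "") < paste(b$B, collapse = ""))
  }
  # H-position splits are exactly the three listed ones
  hsplits <- vapply(Filter(function(b) b$pos == 4L, bps),
                    function(b) paste(paste(b$A, collapse = ""),
                                      paste(b$B, collapse = ""), sep = "|"),
                    "")
  expect_setequal(hsplits, c("A|CT", "AC|T", "AT|C"))
  # singleton positions contribute nothing
  narrow <- midd_pattern(list("A", "A", "C", c("A", "T"), "G", "G"))
  expect_length(enumerate_bipartitions(narrow), 1L)
})

test_that("bipartition_test reproduces the worked 2x2 example and edge cases", {
  tab <- mk_table(c("AACACC", "AACCCC"), c(0.9, 0.6))
  bp <- list(pos = 4L, A = "A", B = "C")
  res <- bipartition_test(tab, bp, scale = 1000L)
  # [[900, 100], [600, 400]]: E = 750/250 per row, chi2 = 240 exactly
  expect_equal(res$chi2, 240)
  expect_equal(res$pvalue, pchisq(240, 1, lower.tail = FALSE))
  # independence and degenerate tables
  same <- mk_table(c("AACACC", "AACCCC"), c(0.4, 0.4))
  res0 <- bipartition_test(same, bp)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$pvalue, 1)
  zero <- mk_table(c("AACACC", "AACCCC"), c(0, 0))
  resz <- bipartition_test(zero, bp)
  expect_equal(resz$chi2, 0)
  expect_equal(resz$pvalue, 1)
  # symmetric in the two blocks
  swapped <- bipartition_test(tab, list(pos = 4L, A = "C", B = "A"))
  expect_equal(swapped$chi2, res$chi2)
  expect_equal(swapped$pvalue, res$pvalue)
  # empty subgroup is a contract violation
  expect_error(bipartition_test(tab, list(pos = 4L, A = "T", B = "C")),
               "undefined-test")
})

test_that("pooled chi-squared agrees with stats::chisq.test on random tables", {
  set.seed(99)
  suffix <- all_kmers("NNCANN")
  bp <- list(pos = 4L, A = "A", B = "T")
  for (i in 1:200) {
    nA <- sample(1:6, 1); nB <- sample(1:6, 1)
    keysA <- sample(all_kmers("AACANN"), nA)
    keysB <- sample(all_kmers("AACTNN"), nB)
    mw <- round(runif(nA + nB), 3)
    tab <- mk_table(c(keysA, keysB), mw)
    res <- bipartition_test(tab, bp, scale = 1000L)
    # independent pooled 2x2 and textbook Pearson statistic
    cA <- sum(round(1000 * mw[seq_len(nA)]))
    cB <- sum(round(1000 * mw[nA + seq_len(nB)]))
    mat <- matrix(c(cA, 1000 * nA - cA, cB, 1000 * nB - cB),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(mat) == 0) || any(colSums(mat) == 0)) {
      expect_equal(res$chi2, 0)
    } else {
      oracle <- suppressWarnings(stats::chisq.test(mat, correct = FALSE))
      expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-12)
      expect_equal(res$pvalue, unname(oracle$p.value), tolerance = 1e-12)
    }
    expect_gte(res$chi2, 0)
    expect_true(res$pvalue > 0 && res$pvalue <= 1)
  }
})

test_that("top_bipartition recovers a planted split and honours alpha", {
  keys <- all_kmers("NNCHNN")
  h <- substr(keys, 4, 4)
  planted <- ifelse(h %in% c("A", "T"), 0.8, 0.02)
  tab <- mk_table(keys, planted)
  top <- top_bipartition(tab, pattern_ch())
  expect_equal(top$bipartition$pos, 4L)
  expect_equal(top$bipartition$A, c("A", "T"))
  expect_equal(top$bipartition$B, "C")
  flat <- mk_table(keys, rep(0.3, length(keys)))
  expect_null(top_bipartition(flat, pattern_ch()))
  expect_null(top_bipartition(tab, pattern_ch(), alpha = 0))
})

test_that("consensus_split applies the at-least-half rule with support counts", {
  bpX <- list(pos = 4L, A = c("A", "T"), B = "C")
  bpY <- list(pos = 1L, A = "A", B = c("C", "G", "T"))
  t_of <- function(bp, p = 1e-6)
    structure(list(bipartition = bp, chi2 = 100, pvalue = p),
              class = "bipartition_test")
  six <- list(t_of(bpX), t_of(bpX), t_of(bpX), t_of(bpX),
              t_of(bpY), NULL)
  cons <- consensus_split(six)
  expect_equal(cons$bipartition$A, c("A", "T"))
  expect_equal(cons$n, 4L)
  expect_equal(cons$m, 5L)
  # boundary: 3 of 6 meets "at least half"
  edge <- list(t_of(bpX), t_of(bpX), t_of(bpX), t_of(bpY), t_of(bpY), NULL)
  expect_equal(consensus_split(edge)$n, 3L)
  expect_null(consensus_split(list(NULL, NULL)))
  # modal tie broken by smaller mean p
  tie <- list(t_of(bpX, 0.04), t_of(bpY, 0.001))
  expect_equal(consensus_split(tie, min_frac = 0.5)$bipartition$pos, 1L)
})

test_that("build_midd_tree handles degenerate cohorts and tiles patterns", {
  keys <- all_kmers("NNCHNN")
  flat <- mk_table(keys, rep(0.3, length(keys)))
  tree <- build_midd_tree(list(s1 = flat, s2 = flat))
  expect_null(tree$root$split)
  expect_equal(midd_leaves(tree), "NNCHNN")

  # empty tables give a single-leaf tree
  empty <- mk_table(character(0), numeric(0))
  expect_equal(midd_leaves(build_midd_tree(list(a = empty))), "NNCHNN")

  # structured cohort: leaves tile the root key space exactly
  h <- substr(keys, 4, 4)
  lv <- ifelse(h %in% c("A", "T"), 0.30, 0.01)
  set.seed(1)
  tabs <- lapply(1:3, function(i)
    mk_table(keys, pmin(pmax(lv + rnorm(length(keys), 0, 0.002), 0), 1)))
  names(tabs) <- paste0("s", 1:3)
  tree <- build_midd_tree(tabs, max_depth = 4L)
  leaves <- midd_leaves(tree)
  member <- sapply(leaves, function(l)
    pattern_match(keys, pattern_from_string(l)))
  expect_true(all(rowSums(member) == 1L))  # each key in exactly one leaf
})

test_that("a single-sample tree equals the greedy recursive decomposition", {
  keys <- all_kmers("NNCHNN")
  set.seed(7)
  h <- substr(keys, 4, 4)
  lv <- ifelse(h %in% c("A", "T"), 0.25, 0.02) +
    ifelse(substr(keys, 1, 1) == "T", 0.1, 0) +
    rnorm(length(keys), 0, 0.01)
  tab <- mk_table(keys, pmin(pmax(lv, 0), 1))
  tree <- build_midd_tree(list(only = tab), max_depth = 3L)
  # independent greedy oracle using top_bipartition directly
  greedy <- function(pattern, depth) {
    top <- top_bipartition(tab, pattern)
    if (is.null(top) || depth == 0L) return(pattern_string(pattern))
    reduce <- function(block) {
      sets <- unclass(pattern)
      sets[[top$bipartition$pos]] <- block
      midd_pattern(sets)
    }
    c(greedy(reduce(top$bipartition$A), depth - 1L),
      greedy(reduce(top$bipartition$B), depth - 1L))
  }
  expect_equal(midd_leaves(tree), greedy(pattern_ch(), 3L))
})

test_that("trees serialize to text and JSON with IUPAC labels", {
  keys <- all_kmers("NNCHNN")
  h <- substr(keys, 4, 4)
  tab <- mk_table(keys, ifelse(h %in% c("A", "T"), 0.3, 0.01))
  tree <- build_midd_tree(list(s1 = tab), max_depth = 1L)
  txt <- midd_tree_serialize(tree, format = "text")
  expect_match(txt[1], "NNCHNN")
  expect_match(txt[1], "n/m = 1/1")
  js <- jsonlite::fromJSON(midd_tree_serialize(tree, format = "json"))
  expect_equal(js$tree$pattern, "NNCHNN")
  expect_equal(js$tree$split$A, "AT")
  expect_equal(sort(c(js$tree$children$pattern)), c("NNCCNN", "NNCWNN"))
  f <- withr::local_tempfile(fileext = ".json")
  midd_tree_serialize(tree, f)
  expect_true(file.exists(f))
})
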