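test_that("filter_excluded removes exact (sub)sequences and their rc", {
  set.seed(3)
  trna <- rand_seq(120)
  reads <- make_reads(c(substr(trna, 20, 40),
                        reverse_complement(substr(trna, 50, 70)),
                        rand_seq(21)))
  out <- filter_excluded(reads, list(trna = trna))
  expect_equal(nrow(out$removed), 2L)
  expect_equal(unique(out$removed$excluded_by), "trna")
  expect_equal(out$kept$sequence, reads$sequence[3])
  ## no exclusion sets: everything kept
  expect_equal(nrow(filter_excluded(reads)$kept), 3L)

  ## random partition equals the naive scan
  seqs <- vapply(1:30, function(i) rand_seq(20), character(1))
  excl <- list(setA = vapply(1:3, function(i) rand_seq(200), character(1)))
  ## plant half the reads inside the exclusion set
  planted <- vapply(1:15, function(i) {
    src <- excl$setA[sample(3, 1)]
    p <- sample(180, 1); substr(src, p, p + 19)
  }, character(1))
  reads2 <- make_reads(c(seqs, planted))
  res <- filter_excluded(reads2, excl)
  naive_removed <- vapply(reads2$sequence, function(s) {
    any(grepl(s, excl$setA, fixed = TRUE)) ||
      any(grepl(rc_naive(s), excl$setA, fixed = TRUE))
  }, logical(1))
  expect_equal(sort(res$removed$sequence),
               sort(reads2$sequence[naive_removed]))
})

test_that("map_exact reports all sense-strand placements and only those", {
  set.seed(12)
  t1 <- rand_seq(200)
  read <- substr(t1, 11, 31)                       # positions [10, 31)
  hits <- map_exact(make_reads(read), c(t1 = t1))
  expect_equal(hits$position, 10L)
  expect_equal(hits$transcript_id, "t1")

  ## a read occurring twice
  dup <- paste0(rand_seq(50), "ACGTACGTACGTACGTACGTA", rand_seq(30),
                "ACGTACGTACGTACGTACGTA", rand_seq(20))
  h2 <- map_exact(make_reads("ACGTACGTACGTACGTACGTA"), c(tx = dup))
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$position, c(50L, 101L))

  ## antisense occurrences are not reported
  h3 <- map_exact(make_reads(reverse_complement(read)), c(t1 = t1))
  expect_equal(nrow(h3), 0L)

  ## random reads vs transcripts equal the naive scan
  txs <- setNames(vapply(1:8, function(i) rand_seq(300), character(1)),
                  sprintf("x%d", 1:8))
  reads <- c(vapply(1:40, function(i) rand_seq(21), character(1)),
             vapply(1:40, function(i) {
               t <- sample(8, 1); p <- sample(280, 1)
               substr(txs[[t]], p, p + 20)
             }, character(1)))
  got <- map_exact(make_reads(reads), txs)
  want <- oracle_map_exact(reads, txs)
  want <- want[order(want$transcript_id, want$position, want$sequence), ]
  expect_equal(got[c("sequence", "transcript_id", "position")],
               want, ignore_attr = TRUE)

  ## self-check: every hit re-verifies by direct substring equality
  ok <- mapply(function(s, id, p) {
    substr(txs[[id]], p + 1, p + nchar(s)) == s
  }, got$sequence, got$transcript_id, got$position)
  expect_true(all(ok))
})

test_that("size_distribution tallies unique and total correctly", {
  hits <- data.frame(
    sequence = c("AAAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCC",
                 "AAAAAAAAAAAAAAAAAAAAA"),
    count = c(5L, 7L, 5L),
    transcript_id = c("t1", "t1", "t2"), position = c(0L, 5L, 9L),
    stringsAsFactors = FALSE)
  sd <- size_distribution(hits)
  expect_equal(sd$length, 21L)
  expect_equal(sd$unique, 2L)       # multi-mapping counts once
  expect_equal(sd$total, 12L)
  expect_equal(nrow(size_distribution(hits[0, ])), 0L)
})

test_that("strand_bias boundaries match the One/Equal/Bias rule", {
  pair <- data.frame(id_a = "a", id_b = "b", stringsAsFactors = FALSE)
  mk <- function(ca, cb) {
    h <- data.frame(
      sequence = c(sprintf("AAAAAAAAAAAAAAAAAAAA%d", seq_len(max(ca, 1))),
                   sprintf("CCCCCCCCCCCCCCCCCCCC%d", seq_len(max(cb, 1)))),
      count = 1L,
      transcript_id = rep(c("a", "b"), c(max(ca, 1), max(cb, 1))),
      position = 0L, stringsAsFactors = FALSE)
    h[c(rep(TRUE, ca), rep(FALSE, max(ca, 1) - ca),
        rep(TRUE, cb), rep(FALSE, max(cb, 1) - cb)), ]
  }
  expect_equal(strand_bias(pair, mk(5, 10))$category, "Equal")   # ratio 0.5
  expect_equal(strand_bias(pair, mk(10, 5))$category, "Equal")   # ratio 2
  expect_equal(strand_bias(pair, mk(9, 2))$category, "Bias")     # 4.5
  expect_equal(strand_bias(pair, mk(1, 10))$category, "Bias")    # 0.1
  expect_equal(strand_bias(pair, mk(12, 0))$category, "One")
  expect_equal(strand_bias(pair, mk(0, 3))$category, "One")
  expect_error(strand_bias(pair, mk(0, 0)), "no hits")
})

test_that("every pair with hits gets exactly one category", {
  set.seed(31)
  pairs <- data.frame(id_a = sprintf("a%d", 1:10),
                      id_b = sprintf("b%d", 1:10), stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(1:10, function(i) {
    n <- sample(0:6, 1)
    if (n == 0) return(NULL)
    data.frame(sequence = vapply(seq_len(n), function(j) rand_seq(21),
                                 character(1)),
               count = sample(1:9, n, replace = TRUE),
               transcript_id = sample(c(sprintf("a%d", i),
                                        sprintf("b%d", i)), n,
                                      replace = TRUE),
               position = 0L, stringsAsFactors = FALSE)
  }))
  sb <- strand_bias_all(pairs, hits)
  with_hits <- vapply(1:10, function(i) {
    any(hits$transcript_id %in% c(sprintf("a%d", i), sprintf("b%d", i)))
  }, logical(1))
  expect_equal(nrow(sb), sum(with_hits))
  expect_true(all(sb$category %in% c("One", "Equal", "Bias")))
})

test_that("enrichment_stats follows the density/chi-squared definitions", {
  e <- enrichment_stats(No = 10, Nt = 20, Lo = 100, Lt = 1000)
  expect_equal(e$Do, 0.1)
  expect_equal(e$Dt, 0.02)
  expect_equal(e$score, 5.0)
  ## null case: observed split equals expectation
  e0 <- enrichment_stats(No = 5, Nt = 50, Lo = 100, Lt = 1000)
  expect_equal(e0$score, 1)
  expect_equal(e0$chi2, 0)
  expect_equal(e0$p, 1)
  expect_error(enrichment_stats(0, 0, 10, 100), "Nt")
  ## agrees with stats::chisq.test's goodness-of-fit statistic
  cs <- suppressWarnings(stats::chisq.test(c(10, 10), p = c(0.1, 0.9)))
  e2 <- enrichment_stats(No = 10, Nt = 20, Lo = 100, Lt = 1000)
  expect_equal(e2$chi2, unname(cs$statistic))
  expect_equal(e2$p, cs$p.value)
})

test_that("enrichment counts loci in overlap intervals per pair and pooled", {
  set.seed(44)
  core <- rand_seq(100)
  a <- paste0(rand_seq(100), core, rand_seq(300))       # overlap [100, 200)
  b <- paste0(rand_seq(50), reverse_complement(core), rand_seq(350))
  seqs <- c(ta = a, tb = b)
  ann <- transcript_table(transcript_id = c("ta", "tb"),
                          chromosome = c("c1", "c2"),
                          strand = c("+", "+"),
                          start = c(0, 0), end = nchar(seqs))
  pairs <- classify_locus(call_nat_pairs(seqs), ann)
  reads <- make_reads(c(substr(a, 111, 131),   # in overlap on a
                        substr(a, 301, 321),   # outside
                        substr(b, 61, 81),     # in overlap on b
                        substr(b, 401, 421)))  # outside
  hits <- map_exact(reads, seqs)
  enr <- enrichment(pairs, hits, seqs)
  pp <- enr[enr$scope == "per_pair", ]
  expect_equal(pp$No, 2)
  expect_equal(pp$Nt, 4)
  expect_gte(pp$Lo, 2L * 100L)      # both transcripts' overlap intervals
  expect_equal(pp$Lt, nchar(a) + nchar(b))
  pooled <- enr[enr$scope == "pooled", ]
  expect_equal(pooled$No, sum(pp$No))
})

test_that("density_ttest is paired, directional and handles degeneracy", {
  d0 <- data.frame(Do = c(1, 2, 3), Dt = c(1, 2, 3))
  r0 <- density_ttest(d0)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  d1 <- data.frame(Do = c(1, 2, 3) + 0.5 + rnorm(3, 0, 1e-6),
                   Dt = c(1, 2, 3))
  r1 <- density_ttest(d1)
  expect_lt(r1$p, 1e-4)
  expect_equal(r1$direction, 1)
  expect_error(density_ttest(d1[1, , drop = FALSE]), ">= 2")

  ## matches stats::t.test on a random cohort
  set.seed(8)
  d2 <- data.frame(Do = runif(30), Dt = runif(30))
  r2 <- density_ttest(d2)
  tt <- t.test(d2$Do, d2$Dt, paired = TRUE)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p, tt$p.value)
})
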