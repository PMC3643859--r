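test_that("map_degradome is exact: one mismatch kills the hit", {
  set.seed(5)
  tx <- rand_seq(300)
  tag <- substr(tx, 51, 70)
  expect_equal(map_degradome(make_reads(tag), c(t1 = tx))$position, 50L)
  mut <- tag
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  expect_equal(nrow(map_degradome(make_reads(mut), c(t1 = tx))), 0L)
})

test_that("extract_long_degradome clips the +/-20 window at bounds", {
  set.seed(6)
  tx <- rand_seq(1000)
  w <- extract_long_degradome(tx, position = 100L, tag_len = 20L)
  expect_equal(c(w$window_start, w$window_end), c(80L, 140L))
  expect_equal(w$sequence, substr(tx, 81, 140))
  w2 <- extract_long_degradome(tx, position = 5L, tag_len = 20L)
  expect_equal(c(w2$window_start, w2$window_end), c(0L, 45L))
  w3 <- extract_long_degradome(tx, position = 990L, tag_len = 20L)
  expect_equal(w3$window_end, 1000L)
  ## slice identity on random cases
  for (i in 1:10) {
    p <- sample(0:980, 1)
    w <- extract_long_degradome(tx, p, 20L)
    expect_equal(w$sequence, substr(tx, w$window_start + 1, w$window_end))
  }
})

test_that("scan_candidate_sites reports siRNA-coordinate mismatches", {
  set.seed(9)
  sirna <- rand_seq(21)
  win <- paste0(rand_seq(20), reverse_complement(sirna), rand_seq(20))
  sites <- scan_candidate_sites(sirna, win)
  perfect <- sites[sites$n_mismatch == 0, ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$site_start, 20L)
  expect_equal(perfect$mismatch_positions[[1]], integer(0))

  ## a substitution at the site base pairing siRNA position 10
  win10 <- win
  j0 <- 20 + (21 - 10)                 # 0-based site offset = L - p
  old <- substr(win10, j0 + 1, j0 + 1)
  substr(win10, j0 + 1, j0 + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  s10 <- scan_candidate_sites(sirna, win10)
  s10 <- s10[s10$site_start == 20, ]
  expect_equal(s10$mismatch_positions[[1]], 10L)

  ## window offset is added to reported coordinates
  shifted <- scan_candidate_sites(sirna, win, window_start = 500L)
  expect_equal(shifted$site_start[shifted$n_mismatch == 0], 520L)
})

test_that("planted substitution positions are recovered exhaustively", {
  set.seed(10)
  sirna <- rand_seq(21)
  perfect_site <- reverse_complement(sirna)
  mutate_at <- function(site, sirna_positions) {
    for (p in sirna_positions) {
      j <- 21 - p + 1
      old <- substr(site, j, j)
      substr(site, j, j) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    site
  }
  check <- function(positions) {
    site <- mutate_at(perfect_site, positions)
    win <- paste0("AAAA", site, "TTTT")
    got <- scan_candidate_sites(sirna, win)
    got <- got[got$site_start == 4, ]
    expect_equal(got$mismatch_positions[[1]], sort(as.integer(positions)))
  }
  for (p in 1:21) check(p)                               # all singles
  doubles <- combn(21, 2)
  for (i in sample(ncol(doubles), 60)) check(doubles[, i])
  triples <- combn(21, 3)
  for (i in sample(ncol(triples), 60)) check(triples[, i])
  ## four substitutions exceed the budget: site not returned
  site4 <- mutate_at(perfect_site, c(2, 8, 14, 20))
  win4 <- paste0("AAAA", site4, "TTTT")
  got4 <- scan_candidate_sites(sirna, win4)
  expect_false(any(got4$site_start == 4))
})

test_that("compiled bulk scan equals the R reference scanner", {
  set.seed(14)
  for (rep in 1:10) {
    sirna <- rand_seq(sample(19:24, 1))
    win <- rand_seq(60)
    ## plant a near-complementary site half the time
    if (rep %% 2 == 0) {
      site <- reverse_complement(sirna)
      substr(site, 3, 3) <- "A"
      win <- paste0(substr(win, 1, 10), site,
                    substr(win, 11 + nchar(site), 60))
    }
    ref <- scan_candidate_sites(sirna, win)
    bulk <- natpipe:::.scan_windows(win, reverse_complement(sirna),
                                    nchar(sirna), 3L, FALSE)
    expect_equal(bulk$offset, ref$site_start)
    expect_equal(bulk$n_mismatch, ref$n_mismatch)
    if (length(bulk$offset)) {
      expect_equal(bulk$mismatch_positions,
                   unclass(ref$mismatch_positions), ignore_attr = TRUE)
    }
  }
})

test_that("schwab_filter implements the three positional clauses", {
  expect_true(schwab_filter(integer(0)))     # perfect complementarity
  expect_false(schwab_filter(10L))           # no mismatch at 10-11
  expect_false(schwab_filter(11L))
  expect_false(schwab_filter(c(1L, 2L)))     # <2 mismatches in 1-9
  expect_true(schwab_filter(c(3L, 14L, 20L)))
  expect_true(schwab_filter(5L))
  expect_false(schwab_filter(c(12L, 13L, 14L)))  # <3 after position 11
  expect_true(schwab_filter(c(12L, 13L)))
})

test_that("classify_origin assigns a/s/o and the multiple flag", {
  pairs <- data.frame(id_a = c("A", "C"), id_b = c("B", "D"),
                      stringsAsFactors = FALSE)
  expect_equal(classify_origin("X", "A", pairs, "B")$origin, "a")
  expect_equal(classify_origin("X", "B", pairs, "A")$origin, "a")
  expect_equal(classify_origin("X", "A", pairs, "A")$origin, "s")
  expect_equal(classify_origin("X", "D", pairs, "A")$origin, "o")
  expect_false(classify_origin("X", "A", pairs, "B")$multiple_flag)
  expect_true(classify_origin("X", "A", pairs,
                              sprintf("t%d", 1:7))$multiple_flag)
  expect_false(classify_origin("X", "A", pairs,
                               sprintf("t%d", 1:5))$multiple_flag)
  expect_error(classify_origin("X", "A", pairs, character(0)), "source")
})

test_that("call_targets composes the full calling chain", {
  set.seed(20)
  ## construct a NAT pair and a cleavage scenario by hand
  core <- rand_seq(80)
  a <- paste0(rand_seq(120), core, rand_seq(300))
  b <- paste0(rand_seq(60), reverse_complement(core), rand_seq(240))
  sirna <- substr(a, 301, 321)                 # from a, outside overlap
  site <- reverse_complement(sirna)
  target <- paste0(rand_seq(150), site, rand_seq(150))
  seqs <- c(ta = a, tb = b, tc = target)
  pairs <- data.frame(id_a = "ta", id_b = "tb", stringsAsFactors = FALSE)
  tag <- substr(target, 150 + (21 - 10) + 1, 150 + (21 - 10) + 20)
  dhits <- map_degradome(make_reads(tag, 5L), seqs)
  calls <- call_targets(make_reads(sirna, 3L), dhits, pairs, seqs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$target_id, "tc")
  expect_equal(calls$site_start, 150)
  expect_equal(calls$origin, "o")
  expect_equal(calls$tag_support, 5)

  ## same scenario with a mismatch at siRNA position 11: zero calls
  site11 <- site
  j <- 21 - 11 + 1
  substr(site11, j, j) <- setdiff(c("A", "C", "G", "T"),
                                  substr(site11, j, j))[1]
  target11 <- paste0(substr(target, 1, 150), site11,
                     substr(target, 172, nchar(target)))
  seqs11 <- c(ta = a, tb = b, tc = target11)
  tag11 <- substr(target11, 150 + 11 + 1, 150 + 11 + 20)
  dhits11 <- map_degradome(make_reads(tag11, 5L), seqs11)
  calls11 <- call_targets(make_reads(sirna, 3L), dhits11, pairs, seqs11)
  expect_equal(nrow(calls11), 0L)

  ## shrinking the window flank never adds a call
  calls_narrow <- call_targets(make_reads(sirna, 3L), dhits, pairs, seqs,
                               flank = 5L)
  expect_lte(nrow(calls_narrow), nrow(calls))

  ## self-verification: recorded mismatches reproduce from the site slice
  for (r in seq_len(nrow(calls))) {
    site_seq <- substr(seqs[[calls$target_id[r]]],
                       calls$site_start[r] + 1, calls$site_end[r])
    rcq <- reverse_complement(calls$sirna[r])
    mm <- which(strsplit(site_seq, "")[[1]] != strsplit(rcq, "")[[1]])
    expect_equal(sort(nchar(rcq) - mm + 1L),
                 sort(calls$mismatch_positions[[r]]))
  }
})
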