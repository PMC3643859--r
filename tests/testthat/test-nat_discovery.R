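test_that("reverse_complement is correct and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")      # palindrome
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACXT"), "illegal")
  set.seed(4)
  for (i in 1:20) {
    s <- rand_seq(sample(5:80, 1), c("A", "C", "G", "T", "N"))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), rc_naive(s))
  }
})

test_that("find_antisense_blocks recovers perfect antisense and nothing else", {
  set.seed(7)
  s <- rand_seq(100)
  b <- find_antisense_blocks(s, reverse_complement(s))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$a_start, b$a_end, b$b_start, b$b_end), c(0L, 100L, 0L, 100L))
  expect_equal(b$identity, 1.0)

  ## no complementarity: a sequence against itself yields nothing
  expect_equal(nrow(find_antisense_blocks(s, s)), 0L)

  ## independent random 200-mers: no block at the default thresholds,
  ## confirmed by the brute-force diagonal scan
  p <- alignment_params()
  for (i in 1:5) {
    x <- rand_seq(200); y <- rand_seq(200)
    expect_equal(nrow(find_antisense_blocks(x, y, p)), 0L)
    expect_false(is.finite(oracle_pair_best(x, y, p)))
  }
})

test_that("blocks embedded mid-sequence get correct coordinates on both strands", {
  set.seed(21)
  core <- rand_seq(60)
  a <- paste0(rand_seq(50), core, rand_seq(40))          # core at [50, 110)
  b <- paste0(rand_seq(30), reverse_complement(core), rand_seq(70))
  blocks <- find_antisense_blocks(a, b)
  best <- blocks[1, ]
  ## X-drop may extend a few chance matches past the planted boundary,
  ## but the planted core must be contained and re-verifiable
  expect_gte(best$a_end - best$a_start, 60L)
  expect_lte(best$a_start, 50L)
  expect_gte(best$a_end, 110L)
  ## coordinate contract: slice of a aligns to rc of slice of b
  sa <- substr(a, best$a_start + 1, best$a_end)
  sb <- substr(b, best$b_start + 1, best$b_end)
  matches <- sum(strsplit(sa, "")[[1]] ==
                   strsplit(reverse_complement(sb), "")[[1]])
  expect_equal(matches, best$matches)
})

test_that("karlin_altschul_evalue follows the closed form", {
  p <- alignment_params()
  expect_equal(karlin_altschul_evalue(0, 100, 200, p), p$K * 100 * 200)
  expect_equal(karlin_altschul_evalue(10, 200, 300, p),
               2 * karlin_altschul_evalue(10, 100, 300, p))
  ## independent recomputation at the documented defaults
  p2 <- alignment_params(lambda = 1.33, K = 0.621)
  expect_equal(karlin_altschul_evalue(25, 1000, 1000, p2),
               0.621 * 1e6 * exp(-1.33 * 25))
  expect_gt(karlin_altschul_evalue(24, 1000, 1000, p2),
            karlin_altschul_evalue(25, 1000, 1000, p2))
})

test_that("call_nat_pairs finds planted pairs, shared partners, no noise", {
  set.seed(33)
  s <- rand_seq(500)
  seqs <- c(t1 = s, t2 = reverse_complement(s))
  pairs <- call_nat_pairs(seqs)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap_length, 500L)
  expect_equal(c(pairs$id_a, pairs$id_b), c("t1", "t2"))

  ## three paralogs sharing one antisense partner -> 3 pairs
  block <- rand_seq(80)
  paralogs <- vapply(1:3, function(i) {
    paste0(rand_seq(40), block, rand_seq(40))
  }, character(1))
  names(paralogs) <- paste0("px", 1:3)
  seqs2 <- c(paralogs,
             partner = paste0(rand_seq(60), reverse_complement(block),
                              rand_seq(30)))
  pairs2 <- call_nat_pairs(seqs2)
  expect_equal(nrow(pairs2), 3L)
  ## ids are sorted lexicographically within a pair, so the shared
  ## antisense partner appears as id_a here
  expect_true(all(pairs2$id_a == "partner" | pairs2$id_b == "partner"))
  ## matches the brute-force all-pairs scan
  orc <- oracle_call_pairs(seqs2, alignment_params())
  expect_equal(paste(pairs2$id_a, pairs2$id_b), paste(orc$id_a, orc$id_b))
  expect_equal(pairs2$score, orc$score)

  ## 50 random unrelated transcripts -> 0 pairs
  seqs3 <- setNames(vapply(1:50, function(i) rand_seq(300), character(1)),
                    sprintf("r%02d", 1:50))
  expect_equal(nrow(call_nat_pairs(seqs3)), 0L)
  expect_equal(nrow(oracle_call_pairs(seqs3, alignment_params())), 0L)
})

test_that("call_nat_pairs is invariant under input order", {
  set.seed(55)
  core <- rand_seq(70)
  seqs <- c(a1 = paste0(rand_seq(30), core, rand_seq(30)),
            b1 = paste0(rand_seq(10), reverse_complement(core),
                        rand_seq(50)),
            c1 = rand_seq(150), d1 = rand_seq(150))
  p1 <- call_nat_pairs(seqs)
  p2 <- call_nat_pairs(seqs[c(3, 1, 4, 2)])
  expect_equal(p1, p2)
})

test_that("tightening thresholds never adds a pair", {
  set.seed(77)
  mk <- function() {
    core <- rand_seq(sample(31:120, 1))
    c(paste0(rand_seq(20), core, rand_seq(20)),
      paste0(rand_seq(20), reverse_complement(core), rand_seq(20)))
  }
  seqs <- unlist(lapply(1:6, function(i) mk()))
  names(seqs) <- sprintf("t%02d", seq_along(seqs))
  base <- call_nat_pairs(seqs, alignment_params())
  key <- function(p) paste(p$id_a, p$id_b)
  stricter_e <- call_nat_pairs(seqs, alignment_params(evalue_max = 1e-20))
  expect_true(all(key(stricter_e) %in% key(base)))
  stricter_o <- call_nat_pairs(seqs, alignment_params(min_overlap = 80L))
  expect_true(all(key(stricter_o) %in% key(base)))
  expect_true(all(stricter_o$overlap_length >= 80L))
})

test_that("classify_locus applies the cis definition exactly", {
  ann <- transcript_table(
    transcript_id = c("A", "B", "C", "D", "E"),
    chromosome = c("chr1", "chr1", "chr2", "chr1", "chr1"),
    strand = c("+", "-", "-", "+", "-"),
    start = c(100, 400, 400, 700, 2000),
    end = c(600, 900, 900, 1500, 2500)
  )
  mkpair <- function(a, b) {
    p <- data.frame(id_a = a, id_b = b, a_start = 0L, a_end = 40L,
                    b_start = 0L, b_end = 40L, overlap_length = 40L,
                    score = 40L, evalue = 1e-12, identity = 1,
                    locus_class = NA_character_,
                    orientation = NA_character_, stringsAsFactors = FALSE)
    class(p) <- c("nat_pairs", "data.frame"); p
  }
  expect_equal(classify_locus(mkpair("A", "B"), ann)$locus_class, "cis")
  expect_equal(classify_locus(mkpair("A", "C"), ann)$locus_class, "trans")
  ## same-strand genomic overlap (inverted repeat) is trans
  expect_equal(classify_locus(mkpair("A", "D"), ann)$locus_class, "trans")
  ## same chromosome, disjoint spans, opposite strands: trans
  expect_equal(classify_locus(mkpair("A", "E"), ann)$locus_class, "trans")
  expect_error(classify_locus(mkpair("A", "Z"), ann), "Z")
  expect_error(classify_cis_orientation(mkpair("A", "C"), ann), "trans")
})

test_that("cis orientation typing matches the geometric definition", {
  ann <- transcript_table(
    transcript_id = c("P1", "M1", "M2", "P2", "P3", "M3"),
    chromosome = "chr1", strand = c("+", "-", "-", "+", "+", "-"),
    start = c(100, 400, 1100, 1400, 3000, 3200),
    end = c(500, 700, 1500, 1700, 3900, 3500)
  )
  ori <- function(a, b) {
    p <- data.frame(id_a = a, id_b = b, a_start = 0L, a_end = 31L,
                    b_start = 0L, b_end = 31L, overlap_length = 31L,
                    score = 31L, evalue = 1e-12, identity = 1,
                    locus_class = NA_character_,
                    orientation = NA_character_, stringsAsFactors = FALSE)
    class(p) <- c("nat_pairs", "data.frame")
    classify_cis_orientation(p, ann)
  }
  expect_equal(ori("P1", "M1"), "convergent")   # plus gene starts first
  expect_equal(ori("M2", "P2"), "divergent")    # minus gene starts first
  expect_equal(ori("P3", "M3"), "enclosed")     # containment
})

test_that("antisense degree and cross-class membership tally correctly", {
  p <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "d"),
                  locus_class = c("cis", "trans", "trans"),
                  stringsAsFactors = FALSE)
  deg <- antisense_degree(p)
  expect_equal(deg$n_antisense_partners[match(c("a", "b", "c", "d"),
                                              deg$transcript_id)],
               c(2L, 2L, 1L, 1L))
  expect_equal(nrow(antisense_degree(p[0, ])), 0L)

  memb <- cross_class_membership(p)
  expect_equal(memb$both, c("a", "b"))
  expect_equal(memb$cis_only, character(0))
  expect_equal(memb$trans_only, c("c", "d"))
  expect_equal(sort(c(memb$cis_only, memb$trans_only, memb$both)),
               sort(unique(c(p$id_a, p$id_b))))

  ## random pair sets: degree equals an independent naive recount
  set.seed(9)
  for (i in 1:5) {
    ids <- sprintf("t%d", 1:12)
    sel <- t(combn(ids, 2))[sample(66, 20), ]
    pr <- data.frame(id_a = pmin(sel[, 1], sel[, 2]),
                     id_b = pmax(sel[, 1], sel[, 2]),
                     stringsAsFactors = FALSE)
    pr <- pr[!duplicated(pr), ]
    deg <- antisense_degree(pr)
    for (r in seq_len(nrow(deg))) {
      id <- deg$transcript_id[r]
      expect_equal(deg$n_antisense_partners[r],
                   sum(pr$id_a == id) + sum(pr$id_b == id))
    }
  }
})
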