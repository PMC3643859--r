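# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation: plain decision tables, naive
# scans and explicit enumeration.

# -- sequences ---------------------------------------------------------

rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

rc_naive <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# -- cis/trans decision table (criterion: orientation classifier) ------

oracle_locus <- function(chrom_a, start_a, end_a, strand_a,
                         chrom_b, start_b, end_b, strand_b) {
  if (chrom_a != chrom_b) return(list(class = "trans",
                                      orientation = "not_applicable"))
  overlaps <- start_a < end_b && start_b < end_a
  if (!overlaps) return(list(class = "trans",
                             orientation = "not_applicable"))
  if (strand_a == strand_b) return(list(class = "trans",
                                        orientation = "not_applicable"))
  a_in_b <- start_b <= start_a && end_a <= end_b
  b_in_a <- start_a <= start_b && end_b <= end_a
  if (a_in_b || b_in_a) return(list(class = "cis",
                                    orientation = "enclosed"))
  if (strand_a == "+") {
    p_start <- start_a; m_start <- start_b
  } else {
    p_start <- start_b; m_start <- start_a
  }
  list(class = "cis",
       orientation = if (p_start < m_start) "convergent" else "divergent")
}

# -- brute-force antisense pair scan (criterion: NAT-caller oracle) ----

# Best block on one diagonal given mismatch positions: for q = 0.. ,
# the longest segment containing exactly q mismatches is the span between
# the mismatches flanking a window of q consecutive ones; score = len-3q
# under +1/-2 scoring.  A valid block needs len >= min_overlap and
# identity >= min_identity; optimal blocks never start or end on a
# mismatch, so this enumeration is exhaustive over candidate optima.
oracle_best_diag_score <- function(mm, L, min_overlap, min_identity) {
  best <- -Inf
  q_max <- min(length(mm), floor(L * (1 - min_identity) / min_identity))
  aug <- c(0L, mm, L + 1L)
  for (q in 0:q_max) {
    t <- length(mm)
    if (q > t) break
    spans <- aug[(q + 2L):(t + 2L)] - aug[seq_len(t - q + 1L)] - 1L
    span <- max(spans)
    if (span < min_overlap) next
    if (q / span > 1 - min_identity) next
    best <- max(best, span - 3L * q)
  }
  best
}

oracle_pair_best <- function(seq_a, seq_b, params) {
  enc <- function(s) {
    v <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
    unname(v[strsplit(s, "")[[1]]])
  }
  a <- enc(seq_a); b <- enc(rc_naive(seq_b))
  m <- length(a); n <- length(b)
  best <- -Inf
  for (d in (-(n - 1L)):(m - 1L)) {
    i0 <- max(1L, 1L + d); i1 <- min(m, n + d)
    L <- i1 - i0 + 1L
    if (L < params$min_overlap) next
    ai <- a[i0:i1]; bi <- b[(i0 - d):(i1 - d)]
    mm <- which(ai != bi | ai == 0L)
    sc <- oracle_best_diag_score(mm, L, params$min_overlap,
                                 params$min_identity)
    best <- max(best, sc)
  }
  best
}

# All-pairs scan: returns data.frame id_a, id_b (sorted), score for every
# pair whose best block passes the E-value cutoff.
oracle_call_pairs <- function(seqs, params) {
  ids <- names(seqs)
  out <- list()
  for (x in seq_along(seqs)) {
    for (y in seq_along(seqs)) {
      if (y <= x) next
      ia <- x; ib <- y
      if (ids[ia] > ids[ib]) { tmp <- ia; ia <- ib; ib <- tmp }
      sc <- oracle_pair_best(seqs[[ia]], seqs[[ib]], params)
      if (!is.finite(sc)) next
      ev <- params$K * nchar(seqs[[ia]]) * nchar(seqs[[ib]]) *
        exp(-params$lambda * sc)
      if (ev > params$evalue_max) next
      out[[length(out) + 1L]] <- data.frame(
        id_a = ids[ia], id_b = ids[ib], score = sc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$id_a, res$id_b), , drop = FALSE]
}

# -- naive substring scans ---------------------------------------------

oracle_map_exact <- function(read_seqs, tx_seqs) {
  rows <- list()
  for (s in unique(read_seqs)) {
    for (t in names(tx_seqs)) {
      L <- nchar(tx_seqs[[t]]); l <- nchar(s)
      if (l > L) next
      for (p in 0:(L - l)) {
        if (substr(tx_seqs[[t]], p + 1, p + l) == s) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = s, transcript_id = t, position = p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sequence = character(0), transcript_id = character(0),
                      position = integer(0)))
  }
  do.call(rbind, rows)
}

# -- Schwab clause evaluation, written independently -------------------

oracle_schwab <- function(positions) {
  seed_mm <- sum(positions >= 1 & positions <= 9)
  central_mm <- sum(positions >= 10 & positions <= 11)
  tail_mm <- sum(positions >= 12)
  (seed_mm < 2) && (central_mm == 0) && (tail_mm < 3)
}

# -- exhaustive structure enumeration (criterion: folding oracle) ------

oracle_max_pairs <- function(seq, min_loop = 3L) {
  v <- strsplit(seq, "")[[1]]
  ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(v[i], v[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(v))
}

# dot-bracket balance check
is_balanced <- function(structure) {
  depth <- 0L
  for (ch in strsplit(structure, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
  }
  depth == 0L
}

# -- tiny fixture builders ---------------------------------------------

make_reads <- function(seqs, counts = rep(1L, length(seqs))) {
  data.frame(read_id = sprintf("r%d", seq_along(seqs)),
             sequence = seqs, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 11L) {
  sim_config(
    seed = seed,
    n_background = 20L,
    n_cis = c(convergent = 2L, divergent = 2L, enclosed = 2L),
    n_trans_families = 2L, trans_family_size = 2L,
    gene_length_range = c(800L, 1500L),
    overlap_range = c(31L, 200L),
    smallrna = list(n_reads = 600L, n_excluded = 10L),
    degradome = list(n_targets = 6L, n_decoys = 6L, noise_tags = 5L),
    hairpins = list(n_planted = 1L)
  )
}
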