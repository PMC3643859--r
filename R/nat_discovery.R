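## NAT pair calling: ungapped antisense seed-and-extend alignment between
## transcripts, gapless Karlin-Altschul E-values, and locus-based
## cis/trans classification with cis orientation typing.

#' Alignment and pair-calling parameters
#'
#' Scoring is +1 match / -2 mismatch, ungapped, with X-drop extension.
#' `lambda` and `K` are the gapless Karlin-Altschul parameters for that
#' score system at uniform base composition (lambda solves
#' `0.25*exp(lambda) + 0.75*exp(-2*lambda) = 1`, giving 1.3328).
#' A pair is called when the best antisense block has
#' `E <= evalue_max` and length `>= min_overlap` at `>= min_identity`.
#'
#' @param match_score,mismatch_penalty integers (penalty is negative).
#' @param word_size exact-match seed length, >= 8.
#' @param xdrop stop extension when the running score falls this far below
#'   the best score seen.
#' @param lambda,K Karlin-Altschul parameters, both > 0.
#' @param evalue_max E-value cutoff for calling a pair.
#' @param min_overlap minimum antisense block length in nt.
#' @param min_identity minimum block identity (matches/length).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match_score = 1L, mismatch_penalty = -2L,
                             word_size = 11L, xdrop = 20L,
                             lambda = 1.3328, K = 0.621,
                             evalue_max = 1e-9, min_overlap = 31L,
                             min_identity = 0.95) {
  stopifnot(lambda > 0, K > 0, word_size >= 8L, min_overlap >= word_size,
            match_score > 0, mismatch_penalty < 0, xdrop > 0)
  structure(list(match_score = as.integer(match_score),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 word_size = as.integer(word_size),
                 xdrop = as.integer(xdrop),
                 lambda = lambda, K = K,
                 evalue_max = evalue_max,
                 min_overlap = as.integer(min_overlap),
                 min_identity = min_identity),
            class = "alignment_params")
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param sequence character vector of sequences over `A,C,G,T,N`.
#' @return character vector of the same length.
#' @export
reverse_complement <- function(sequence) {
  if (any(grepl("[^ACGTN]", sequence))) {
    stop("illegal character in sequence (expected A,C,G,T,N)", call. = FALSE)
  }
  comp <- chartr("ACGTN", "TGCAN", sequence)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## integer encoding: A=1 C=2 G=3 T=4, N=0 (never matches anything)
.encode_seq <- function(s) {
  v <- utf8ToInt(s)
  out <- integer(length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}

.enumerate_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

## Extend a batch of seeds for one (a, b) pair and apply the block
## thresholds.  Seeds are 1-based starts on a / rc_b; seeds falling inside
## an already-extended block on the same diagonal are skipped.
.blocks_from_seeds <- function(a_int, brc_int, seeds_i, seeds_j, params,
                               len_b) {
  k <- params$word_size
  d <- seeds_i - seeds_j
  ord <- order(d, seeds_i)
  blocks <- list()
  last_d <- NA_integer_; covered_to <- -1L
  for (s in ord) {
    if (is.na(last_d) || d[s] != last_d) {
      last_d <- d[s]; covered_to <- -1L
    }
    if (seeds_i[s] <= covered_to) next
    ext <- .extend_seed(a_int, brc_int, seeds_i[s], seeds_j[s], k,
                        params$match_score, params$mismatch_penalty,
                        params$xdrop)
    covered_to <- ext[2]
    len <- ext[2] - ext[1] + 1L
    matches <- ext[4]
    if (len < params$min_overlap) next
    if (matches / len < params$min_identity) next
    blocks[[length(blocks) + 1L]] <- data.frame(
      a_start = ext[1] - 1L, a_end = ext[2],
      b_start = len_b - (ext[3] - 1L + len), b_end = len_b - (ext[3] - 1L),
      length = len, matches = matches, score = ext[5],
      identity = matches / len
    )
  }
  if (length(blocks) == 0L) return(.empty_blocks())
  out <- unique(do.call(rbind, blocks))
  out[order(-out$score, out$a_start), , drop = FALSE]
}

#' Find antisense complementary blocks between two transcripts
#'
#' Seed-and-extend ungapped local alignment of `seq_a` against the reverse
#' complement of `seq_b`: exact `word_size`-mers are seeded, extended with
#' X-drop under +1/-2 scoring, and blocks shorter than `min_overlap` or
#' below `min_identity` are dropped.  Coordinates on `b` are reported in
#' `b`'s own sense orientation (0-based half-open).
#'
#' @param seq_a,seq_b sequences over `A,C,G,T,N`.
#' @param params [alignment_params()].
#' @return data.frame with columns `a_start,a_end,b_start,b_end,length,
#'   matches,score,identity`, ordered by decreasing score then `a_start`.
#' @export
find_antisense_blocks <- function(seq_a, seq_b, params = alignment_params()) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  k <- params$word_size
  rc_b <- reverse_complement(seq_b)
  m <- nchar(seq_a); n <- nchar(seq_b)
  if (m < k || n < k) return(.empty_blocks())
  a_int <- .encode_seq(seq_a)
  b_int <- .encode_seq(rc_b)

  ## seed positions: exact shared k-mers between seq_a and rc_b
  kb <- .enumerate_kmers(rc_b, k)
  map <- split(seq_along(kb), kb)
  ka <- .enumerate_kmers(seq_a, k)
  hit_idx <- which(ka %in% names(map) & !grepl("N", ka, fixed = TRUE))
  if (length(hit_idx) == 0L) return(.empty_blocks())
  seeds_i <- integer(0); seeds_j <- integer(0)
  for (i in hit_idx) {
    js <- map[[ka[i]]]
    seeds_i <- c(seeds_i, rep.int(i, length(js)))
    seeds_j <- c(seeds_j, js)
  }
  .blocks_from_seeds(a_int, b_int, seeds_i, seeds_j, params, n)
}

.empty_blocks <- function() {
  data.frame(a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             length = integer(0), matches = integer(0),
             score = integer(0), identity = numeric(0))
}

#' Gapless Karlin-Altschul E-value
#'
#' `E = K * len_a * len_b * exp(-lambda * score)`: the expected number of
#' ungapped local alignments scoring at least `score` between random
#' sequences of the two lengths.
#'
#' @param score alignment score (>= 0).
#' @param len_a,len_b sequence lengths.
#' @param params [alignment_params()] supplying `lambda` and `K`.
#' @return numeric E-value.
#' @export
karlin_altschul_evalue <- function(score, len_a, len_b,
                                   params = alignment_params()) {
  stopifnot(all(score >= 0))
  params$K * as.numeric(len_a) * as.numeric(len_b) *
    exp(-params$lambda * score)
}

.sequences_of <- function(transcripts) {
  if (inherits(transcripts, "nat_transcripts")) {
    seqs <- transcripts$sequence
    names(seqs) <- transcripts$transcript_id
    if (anyNA(seqs)) stop("transcript table has missing sequences",
                          call. = FALSE)
    return(seqs)
  }
  if (is.character(transcripts) && !is.null(names(transcripts))) {
    return(transcripts)
  }
  stop("transcripts must be a named character vector or nat_transcripts",
       call. = FALSE)
}

#' Call NAT pairs from a transcript set
#'
#' Every unordered pair of transcripts sharing a seed between one sequence
#' and the reverse complement of the other is aligned with
#' [find_antisense_blocks()]; the best block per pair is kept (highest
#' score, ties broken by leftmost start on the first transcript) and the
#' pair is emitted iff `E <= evalue_max` and block length `>= min_overlap`.
#' Self-pairs are excluded.  The result is invariant under input order and
#' sorted by `(id_a, id_b)` with `id_a < id_b`.
#'
#' @param transcripts named character vector of sequences, or a
#'   `nat_transcripts` table carrying sequences.
#' @param params [alignment_params()].
#' @return data.frame of class `nat_pairs` with transcript-local overlap
#'   intervals (0-based half-open), `overlap_length`, `score`, `evalue`;
#'   `locus_class`/`orientation` are `NA` until [classify_locus()].
#' @export
call_nat_pairs <- function(transcripts, params = alignment_params()) {
  seqs <- .sequences_of(transcripts)
  if (length(seqs) < 2L) stop("need at least 2 transcripts", call. = FALSE)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  k <- params$word_size
  lens <- nchar(seqs)
  enc <- lapply(seqs, .encode_seq)
  rc <- reverse_complement(seqs)
  enc_rc <- lapply(rc, .encode_seq)

  ## global seed join: every exact k-mer shared between some transcript
  ## and the reverse complement of another (N-containing k-mers excluded)
  fwd_km <- lapply(seqs, .enumerate_kmers, k = k)
  fwd <- data.frame(
    key = unlist(fwd_km, use.names = FALSE),
    tx = rep.int(seq_along(seqs), lengths(fwd_km)),
    pos = unlist(lapply(lengths(fwd_km), seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  fwd <- fwd[!grepl("N", fwd$key, fixed = TRUE), ]
  rc_km <- lapply(rc, .enumerate_kmers, k = k)
  rcv <- data.frame(
    key = unlist(rc_km, use.names = FALSE),
    tx = rep.int(seq_along(seqs), lengths(rc_km)),
    pos = unlist(lapply(lengths(rc_km), seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  rcv <- rcv[!grepl("N", rcv$key, fixed = TRUE), ]
  seeds <- merge(fwd, rcv, by = "key", suffixes = c("_a", "_b"))
  seeds <- seeds[seeds$tx_a != seeds$tx_b, , drop = FALSE]
  if (nrow(seeds) == 0L) return(.empty_pairs())

  ## canonicalise: pair (x, y) with id(x) < id(y); the seed is a shared
  ## k-mer between seq_x (at i) and rc(seq_y) (at j)
  flip <- ids[seeds$tx_a] > ids[seeds$tx_b]
  i_pos <- ifelse(flip, lens[seeds$tx_b] - seeds$pos_b - k + 2L,
                  seeds$pos_a)
  j_pos <- ifelse(flip, lens[seeds$tx_a] - seeds$pos_a - k + 2L,
                  seeds$pos_b)
  x_idx <- ifelse(flip, seeds$tx_b, seeds$tx_a)
  y_idx <- ifelse(flip, seeds$tx_a, seeds$tx_b)
  pair_key <- paste(x_idx, y_idx, sep = "|")
  by_pair <- split(seq_along(pair_key), pair_key)

  rows <- vector("list", length(by_pair))
  r <- 0L
  for (sel in by_pair) {
    r <- r + 1L
    ia <- x_idx[sel[1]]; ib <- y_idx[sel[1]]
    blocks <- .blocks_from_seeds(enc[[ia]], enc_rc[[ib]],
                                 i_pos[sel], j_pos[sel], params, lens[ib])
    if (nrow(blocks) == 0L) next
    best <- blocks[1, ]
    ev <- karlin_altschul_evalue(best$score, lens[ia], lens[ib], params)
    if (ev > params$evalue_max) next
    rows[[r]] <- data.frame(
      id_a = ids[ia], id_b = ids[ib],
      a_start = best$a_start, a_end = best$a_end,
      b_start = best$b_start, b_end = best$b_end,
      overlap_length = best$length, score = best$score,
      evalue = ev, identity = best$identity,
      locus_class = NA_character_, orientation = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(.empty_pairs())
  out <- do.call(rbind, rows)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nat_pairs", "data.frame")
  out
}

.empty_pairs <- function() {
  out <- data.frame(id_a = character(0), id_b = character(0),
                    a_start = integer(0), a_end = integer(0),
                    b_start = integer(0), b_end = integer(0),
                    overlap_length = integer(0), score = integer(0),
                    evalue = numeric(0), identity = numeric(0),
                    locus_class = character(0), orientation = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("nat_pairs", "data.frame")
  out
}

#' Classify NAT pairs as cis or trans, and type cis pairs
#'
#' A pair is *cis* iff both genes are on the same chromosome, their genomic
#' spans overlap by at least 1 bp, and their annotated strands are opposite;
#' otherwise *trans*.  Cis pairs are typed by gene-span geometry:
#' *enclosed* if one span contains the other, else *convergent* when the
#' plus-strand gene starts first (the shared region covers both 3' ends)
#' and *divergent* when the minus-strand gene starts first (both 5' ends).
#' Trans pairs get orientation `not_applicable`.
#'
#' @param pairs `nat_pairs` data.frame.
#' @param annotations `nat_transcripts` table with genomic coordinates.
#' @return `pairs` with `locus_class` and `orientation` filled in.
#' @export
classify_locus <- function(pairs, annotations) {
  idx_a <- match(pairs$id_a, annotations$transcript_id)
  idx_b <- match(pairs$id_b, annotations$transcript_id)
  if (anyNA(idx_a) || anyNA(idx_b)) {
    missing_id <- c(pairs$id_a[is.na(idx_a)], pairs$id_b[is.na(idx_b)])[1]
    stop("no annotation for transcript ", missing_id, call. = FALSE)
  }
  a <- annotations[idx_a, ]; b <- annotations[idx_b, ]
  span_overlap <- a$chromosome == b$chromosome &
    a$genomic_start < b$genomic_end & b$genomic_start < a$genomic_end
  opposite <- a$strand != b$strand
  is_cis <- span_overlap & opposite
  pairs$locus_class <- ifelse(is_cis, "cis", "trans")
  pairs$orientation <- "not_applicable"
  if (any(is_cis)) {
    pairs$orientation[is_cis] <-
      .cis_orientation(a[is_cis, , drop = FALSE], b[is_cis, , drop = FALSE])
  }
  pairs
}

.cis_orientation <- function(a, b) {
  enclosed <- (a$genomic_start <= b$genomic_start &
                 a$genomic_end >= b$genomic_end) |
    (b$genomic_start <= a$genomic_start & b$genomic_end >= a$genomic_end)
  p_start <- ifelse(a$strand == "+", a$genomic_start, b$genomic_start)
  m_start <- ifelse(a$strand == "-", a$genomic_start, b$genomic_start)
  ifelse(enclosed, "enclosed",
         ifelse(p_start < m_start, "convergent", "divergent"))
}

#' Orientation of a single cis pair
#'
#' Convenience wrapper around the geometry rule used by [classify_locus()];
#' errors when the pair is not cis.
#'
#' @param pair one row of a classified `nat_pairs` data.frame.
#' @param annotations `nat_transcripts` table.
#' @return one of `"convergent"`, `"divergent"`, `"enclosed"`.
#' @export
classify_cis_orientation <- function(pair, annotations) {
  classified <- classify_locus(pair, annotations)
  if (any(classified$locus_class != "cis")) {
    stop("classify_cis_orientation called on a trans pair", call. = FALSE)
  }
  classified$orientation
}

#' Number of distinct antisense partners per transcript
#'
#' @param pairs `nat_pairs` data.frame.
#' @return data.frame `transcript_id`, `n_antisense_partners`, sorted by id.
#' @export
antisense_degree <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(transcript_id = character(0),
                      n_antisense_partners = integer(0)))
  }
  tab <- table(c(pairs$id_a, pairs$id_b))
  out <- data.frame(transcript_id = names(tab),
                    n_antisense_partners = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$transcript_id), , drop = FALSE]
}

#' Partition transcripts by cis/trans pair membership
#'
#' @param pairs classified `nat_pairs` data.frame.
#' @return list with character vectors `cis_only`, `trans_only`, `both`.
#' @export
cross_class_membership <- function(pairs) {
  if (anyNA(pairs$locus_class)) {
    stop("locus_class not set; run classify_locus first", call. = FALSE)
  }
  cis_ids <- unique(c(pairs$id_a[pairs$locus_class == "cis"],
                      pairs$id_b[pairs$locus_class == "cis"]))
  trans_ids <- unique(c(pairs$id_a[pairs$locus_class == "trans"],
                        pairs$id_b[pairs$locus_class == "trans"]))
  list(cis_only = sort(setdiff(cis_ids, trans_ids)),
       trans_only = sort(setdiff(trans_ids, cis_ids)),
       both = sort(intersect(cis_ids, trans_ids)))
}
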