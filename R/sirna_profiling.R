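## Small RNA profiling on NAT transcripts: exclusion filtering, exact
## sense-strand mapping, per-pair strand bias (One/Equal/Bias), and the
## chi-squared test for enrichment of small RNA loci in the overlap region.

#' Collapse identical read sequences
#'
#' Sums abundances over records with the same sequence; the id of the first
#' record is kept.
#'
#' @param reads data.frame from [read_abundance_reads()].
#' @return collapsed data.frame (`read_id`, `sequence`, `count`).
#' @export
collapse_reads <- function(reads) {
  agg <- stats::aggregate(count ~ sequence, data = reads, FUN = sum)
  first <- reads[!duplicated(reads$sequence), c("read_id", "sequence")]
  out <- merge(first, agg, by = "sequence", sort = FALSE)
  out <- out[, c("read_id", "sequence", "count")]
  out[order(out$sequence), , drop = FALSE]
}

#' Screen reads against exclusion sets
#'
#' A read is removed iff its sequence, or its reverse complement, occurs as
#' an exact substring of any sequence in any exclusion set (structural
#' ncRNAs, transposable elements, ...).  The removal log records which set
#' claimed each read.
#'
#' @param reads data.frame (`read_id`, `sequence`, `count`).
#' @param exclusion_sets named list of character vectors of sequences;
#'   empty list or `NULL` keeps everything.
#' @return list with `kept` (data.frame) and `removed` (data.frame with an
#'   extra `excluded_by` column).
#' @export
filter_excluded <- function(reads, exclusion_sets = NULL) {
  if (is.null(exclusion_sets) || length(exclusion_sets) == 0L) {
    return(list(kept = reads,
                removed = cbind(reads[0, ], excluded_by = character(0))))
  }
  claimed_by <- rep(NA_character_, nrow(reads))
  rc <- reverse_complement(reads$sequence)
  for (set_name in names(exclusion_sets)) {
    haystack <- paste(exclusion_sets[[set_name]], collapse = "#")
    todo <- which(is.na(claimed_by))
    if (length(todo) == 0L) break
    hit <- vapply(todo, function(i) {
      grepl(reads$sequence[i], haystack, fixed = TRUE) ||
        grepl(rc[i], haystack, fixed = TRUE)
    }, logical(1))
    claimed_by[todo[hit]] <- set_name
  }
  removed <- reads[!is.na(claimed_by), , drop = FALSE]
  removed$excluded_by <- claimed_by[!is.na(claimed_by)]
  list(kept = reads[is.na(claimed_by), , drop = FALSE], removed = removed)
}

#' Map reads exactly onto transcripts (sense strand only)
#'
#' Reports every exact, full-length, sense-orientation occurrence of each
#' unique read sequence on each transcript; multi-mapping reads are
#' reported at every placement.  Antisense occurrences are not reported:
#' the antisense partner is its own transcript.  Identical read records are
#' collapsed (abundances summed) before mapping.
#'
#' @param reads data.frame (`read_id`, `sequence`, `count`).
#' @param transcripts named character vector of transcript sequences, or a
#'   `nat_transcripts` table.
#' @return data.frame of hits: `sequence`, `count`, `transcript_id`,
#'   `position` (0-based start on the transcript).
#' @export
map_exact <- function(reads, transcripts) {
  seqs <- .sequences_of(transcripts)
  reads <- collapse_reads(reads)
  ## one concatenated haystack with '#' separators; matches cannot span '#'
  lens <- nchar(seqs)
  offsets <- c(0L, cumsum(lens + 1L))[seq_along(seqs)]
  haystack <- paste(seqs, collapse = "#")
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    pat <- reads$sequence[i]
    starts <- gregexpr(pat, haystack, fixed = TRUE)[[1]]
    if (starts[1] == -1L) next
    starts <- as.integer(starts) - 1L          # 0-based in haystack
    t_idx <- findInterval(starts, offsets)
    rows[[i]] <- data.frame(
      sequence = pat, count = reads$count[i],
      transcript_id = names(seqs)[t_idx],
      position = starts - offsets[t_idx],
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      transcript_id = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$position, out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Read length distribution of mapped small RNAs
#'
#' @param hits data.frame from [map_exact()].
#' @return data.frame `length`, `unique` (distinct sequences; a sequence
#'   hitting several transcripts counts once), `total` (abundance-weighted
#'   distinct sequences).
#' @export
size_distribution <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(length = integer(0), unique = integer(0),
                      total = integer(0)))
  }
  per_seq <- hits[!duplicated(hits$sequence), c("sequence", "count")]
  len <- nchar(per_seq$sequence)
  uni <- table(len)
  tot <- tapply(per_seq$count, len, sum)
  data.frame(length = as.integer(names(uni)),
             unique = as.integer(uni),
             total = as.integer(tot[names(uni)]))
}

#' Strand bias of small RNA production within a NAT pair
#'
#' Ratio of abundances (or distinct-sequence counts) between the two
#' transcripts of a pair, classified as in the field's convention:
#' `One` - only one transcript produced reads; `Equal` - ratio in
#' `[0.5, 2]` (boundaries inclusive); `Bias` - ratio `< 0.5` or `> 2`.
#'
#' @param pair one row of a `nat_pairs` data.frame.
#' @param hits data.frame from [map_exact()].
#' @param weighting `"total"` (abundance-weighted, default) or `"unique"`.
#' @return data.frame `pair_id`, `count_a`, `count_b`, `ratio`, `category`.
#' @export
strand_bias <- function(pair, hits, weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  tally <- function(id) {
    h <- hits[hits$transcript_id == id, , drop = FALSE]
    h <- h[!duplicated(h$sequence), , drop = FALSE]
    if (weighting == "total") sum(h$count) else nrow(h)
  }
  count_a <- tally(pair$id_a)
  count_b <- tally(pair$id_b)
  if (count_a == 0 && count_b == 0) {
    stop("no hits on either transcript of pair ", pair$id_a, "/", pair$id_b,
         call. = FALSE)
  }
  ratio <- count_a / count_b
  category <- if (xor(count_a == 0, count_b == 0)) {
    "One"
  } else if (ratio >= 0.5 && ratio <= 2) {
    "Equal"
  } else {
    "Bias"
  }
  data.frame(pair_id = paste(pair$id_a, pair$id_b, sep = "|"),
             count_a = count_a, count_b = count_b,
             ratio = ratio, category = category,
             stringsAsFactors = FALSE)
}

#' Strand bias for every pair with at least one hit
#'
#' @param pairs `nat_pairs` data.frame.
#' @inheritParams strand_bias
#' @return row-bound [strand_bias()] results (pairs without hits skipped).
#' @export
strand_bias_all <- function(pairs, hits, weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    p <- pairs[r, ]
    if (!any(hits$transcript_id %in% c(p$id_a, p$id_b))) return(NULL)
    strand_bias(p, hits, weighting)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(pair_id = character(0), count_a = numeric(0),
                      count_b = numeric(0), ratio = numeric(0),
                      category = character(0)))
  }
  do.call(rbind, rows)
}

#' Enrichment statistic from raw counts
#'
#' Given `No` unique small RNA loci in the overlap region (total length
#' `Lo`) out of `Nt` loci on the whole transcripts (total length `Lt`),
#' computes the densities `Do = No/Lo` and `Dt = Nt/Lt`, the enrichment
#' score `Do/Dt`, and a 1-df chi-squared goodness-of-fit test of the
#' observed split `(No, Nt - No)` against the uniform expectation
#' `(Nt*Lo/Lt, Nt*(1 - Lo/Lt))`.
#'
#' @param No,Nt,Lo,Lt counts and lengths; requires `Nt >= 1`, `Lo >= 1`,
#'   `Lt > Lo`, `No <= Nt`.
#' @return data.frame `No, Nt, Lo, Lt, Do, Dt, score, chi2, p`.
#' @export
enrichment_stats <- function(No, Nt, Lo, Lt) {
  if (any(Nt < 1)) stop("Nt must be >= 1", call. = FALSE)
  stopifnot(all(Lo >= 1), all(Lt > Lo), all(No <= Nt), all(No >= 0))
  Do <- No / Lo
  Dt <- Nt / Lt
  p_exp <- Lo / Lt
  e1 <- Nt * p_exp
  e2 <- Nt * (1 - p_exp)
  chi2 <- (No - e1)^2 / e1 + ((Nt - No) - e2)^2 / e2
  data.frame(No = No, Nt = Nt, Lo = Lo, Lt = Lt, Do = Do, Dt = Dt,
             score = Do / Dt, chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Overlap-region enrichment of small RNA loci, per pair and pooled
#'
#' For each NAT pair, a small RNA locus is a distinct
#' `(sequence, transcript, position)` placement; it is *in the overlap* iff
#' its start position lies within the pair's overlap interval on that
#' transcript.  `Lo` is the summed overlap length over the two transcripts
#' (twice the block length) and `Lt` the summed transcript lengths.  The
#' pooled row sums `No`, `Nt`, `Lo`, `Lt` over the per-pair rows.  Pairs
#' without hits are skipped (`Nt = 0` leaves the statistic undefined).
#'
#' @param pairs `nat_pairs` data.frame.
#' @param hits data.frame from [map_exact()].
#' @param transcripts named character vector or `nat_transcripts` table
#'   (for transcript lengths).
#' @param weighting `"unique"` (default: each placement counts once) or
#'   `"total"` (abundance-weighted placements).
#' @return data.frame with columns `scope` (`per_pair`/`pooled`),
#'   `pair_id`, and the [enrichment_stats()] columns.
#' @export
enrichment <- function(pairs, hits, transcripts,
                       weighting = c("unique", "total")) {
  weighting <- match.arg(weighting)
  seqs <- .sequences_of(transcripts)
  lens <- nchar(seqs)
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    ha <- hits[hits$transcript_id == p$id_a, , drop = FALSE]
    hb <- hits[hits$transcript_id == p$id_b, , drop = FALSE]
    w <- function(h) if (weighting == "unique") nrow(h) else sum(h$count)
    Nt <- w(ha) + w(hb)
    if (Nt < 1) next
    in_ov_a <- ha[ha$position >= p$a_start & ha$position < p$a_end, ,
                  drop = FALSE]
    in_ov_b <- hb[hb$position >= p$b_start & hb$position < p$b_end, ,
                  drop = FALSE]
    No <- w(in_ov_a) + w(in_ov_b)
    Lo <- 2L * p$overlap_length
    Lt <- lens[[p$id_a]] + lens[[p$id_b]]
    st <- enrichment_stats(No, Nt, Lo, Lt)
    rows[[r]] <- cbind(data.frame(scope = "per_pair",
                                  pair_id = paste(p$id_a, p$id_b, sep = "|"),
                                  stringsAsFactors = FALSE), st)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no pair has any mapped small RNA (Nt = 0 everywhere)",
         call. = FALSE)
  }
  per_pair <- do.call(rbind, rows)
  pooled <- enrichment_stats(sum(per_pair$No), sum(per_pair$Nt),
                             sum(per_pair$Lo), sum(per_pair$Lt))
  pooled <- cbind(data.frame(scope = "pooled", pair_id = ".",
                             stringsAsFactors = FALSE), pooled)
  out <- rbind(per_pair, pooled)
  rownames(out) <- NULL
  out
}

#' Paired t-test of overlap vs whole-transcript small RNA density
#'
#' Tests `Do` against `Dt` across NAT pairs (the two densities are measured
#' on the same pair, so the test is paired) and reports the direction of
#' the mean difference.
#'
#' @param per_pair_results the `per_pair` rows of an [enrichment()] result
#'   (any data.frame with `Do` and `Dt` columns).
#' @return list `t`, `p` (two-sided), `direction` (sign of mean `Do - Dt`),
#'   `n`.
#' @export
density_ttest <- function(per_pair_results) {
  d <- per_pair_results$Do - per_pair_results$Dt
  if (length(d) < 2L) stop("need >= 2 pairs for the t-test", call. = FALSE)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, direction = 0, n = length(d)))
    return(list(t = sign(mean(d)) * Inf, p = 0,
                direction = sign(mean(d)), n = length(d)))
  }
  tt <- stats::t.test(per_pair_results$Do, per_pair_results$Dt,
                      paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       direction = sign(mean(d)), n = length(d))
}
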