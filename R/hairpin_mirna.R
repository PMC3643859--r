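## Pre-miRNA hairpin screening of NAT transcripts: extract a +/-200 nt
## precursor window around a small RNA locus, fold it with the built-in
## base-pair-maximisation engine, and check the structure for miRNA-like
## stem-loop features.  Also intersects an external miRNA target list with
## NAT membership.

#' Extract the precursor window around a small RNA locus
#'
#' @param transcript_seq transcript sequence.
#' @param position 0-based start of the small RNA on the transcript.
#' @param srna_len small RNA length.
#' @param flank context on each side, default 200.
#' @return list `start`, `end` (0-based half-open, clipped), `sequence`,
#'   `mir_start`, `mir_end` (small RNA interval relative to the window).
#' @export
extract_precursor <- function(transcript_seq, position, srna_len,
                              flank = 200L) {
  L <- nchar(transcript_seq)
  w0 <- max(0L, position - flank)
  w1 <- min(L, position + srna_len + flank)
  list(start = w0, end = w1,
       sequence = substr(transcript_seq, w0 + 1L, w1),
       mir_start = position - w0,
       mir_end = position - w0 + srna_len)
}

#' Fold a sequence into a pseudoknot-free secondary structure
#'
#' The built-in engine is a Nussinov-style base-pair-maximisation dynamic
#' program: it maximises the number of nested base pairs over
#' `{AU, UA, GC, CG, GU, UG}` with a minimum hairpin loop of `min_loop`
#' unpaired bases, and uses a deterministic traceback (the 5'-most base is
#' paired whenever an optimal structure allows it, with its 5'-most
#' optimal partner).  A thermodynamic folder can replace it through
#' `engine`: any function taking a sequence and returning a list with
#' elements `structure` (dot-bracket) and `pairs`.
#'
#' @param sequence nucleotide sequence (DNA alphabet; T is read as U).
#' @param min_loop minimum hairpin loop length, default 3.
#' @param engine optional replacement folding function.
#' @param min_len shortest foldable sequence; the screening default (40)
#'   reflects that shorter windows cannot hold a miRNA duplex.
#' @return list `structure` (dot-bracket string) and `pairs` (base pair
#'   count).
#' @export
fold <- function(sequence, min_loop = 3L, engine = NULL, min_len = 40L) {
  if (nchar(sequence) < min_len) {
    stop("sequence too short to fold (", nchar(sequence), " < ", min_len,
         " nt)", call. = FALSE)
  }
  if (!is.null(engine)) {
    out <- engine(sequence)
  } else {
    out <- .nussinov_fold(normalize_sequence(sequence), as.integer(min_loop))
  }
  stopifnot(nchar(out$structure) == nchar(sequence))
  out
}

#' Fold with the built-in engine regardless of length
#' @inheritParams fold
#' @keywords internal
fold_engine <- function(sequence, min_loop = 3L) {
  .nussinov_fold(normalize_sequence(sequence), as.integer(min_loop))
}

#' Partner vector of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector: `p[i]` is the 1-based partner of base `i`, or 0.
#' @export
pairing_partners <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure", call. = FALSE)
  p
}

#' Hairpin screening criteria
#'
#' Explicit, configurable stand-ins for a MirCheck-style feature check.
#'
#' @param max_unpaired_mir maximum unpaired bases in the miRNA region (4).
#' @param max_bulge_mir maximum run of consecutive unpaired bases in the
#'   miRNA region (2).
#' @param min_stem_pairs minimum base pairs in the stem enclosing the
#'   terminal loop (15).
#' @param max_loop_tail maximum miRNA bases allowed to extend past its
#'   innermost pair toward the terminal loop before the implied miRNA*
#'   is considered to overlap the loop (2).
#' @return list of thresholds.
#' @export
hairpin_criteria <- function(max_unpaired_mir = 4L, max_bulge_mir = 2L,
                             min_stem_pairs = 15L, max_loop_tail = 2L) {
  list(max_unpaired_mir = max_unpaired_mir, max_bulge_mir = max_bulge_mir,
       min_stem_pairs = min_stem_pairs, max_loop_tail = max_loop_tail)
}

#' Check a folded precursor for pre-miRNA-like features
#'
#' Pass requires all of: (i) the miRNA arm pairs into one contiguous
#' opposite arm on a single side of a stem-loop; (ii) unpaired bases in
#' the miRNA region `<= max_unpaired_mir`; (iii) the largest internal
#' bulge in the miRNA region `<= max_bulge_mir`; (iv) the implied miRNA*
#' does not overlap the terminal loop (at most `max_loop_tail` miRNA bases
#' extend past the innermost pair toward the loop); (v) the stem enclosing
#' the terminal loop holds `>= min_stem_pairs` base pairs.
#'
#' @param sequence precursor sequence.
#' @param structure dot-bracket structure of the same length.
#' @param mir_start,mir_end small RNA interval within the precursor
#'   (0-based half-open).
#' @param criteria [hairpin_criteria()].
#' @return list `verdict` (logical), `metrics` (unpaired_in_mir,
#'   max_bulge_in_mir, stem_pairs, arm_side, star_overlap_loop,
#'   one_sided_arm), `failed` (character vector of failed criteria).
#' @export
check_hairpin <- function(sequence, structure, mir_start, mir_end,
                          criteria = hairpin_criteria()) {
  n <- nchar(sequence)
  if (nchar(structure) != n) {
    stop("structure/sequence length mismatch", call. = FALSE)
  }
  stopifnot(mir_start >= 0, mir_end <= n, mir_end > mir_start)
  p <- pairing_partners(structure)
  mir <- (mir_start + 1L):mir_end            # 1-based positions
  mir_len <- length(mir)

  ## the duplex run: the longest stretch of miRNA bases pairing one
  ## opposite arm, where consecutive pairs may be separated by at most
  ## max_bulge_mir unpaired bases on either strand.  Stray pairs (loop
  ## hairpins, distant contacts) fall outside the run.
  best_run <- function(side_pos) {
    if (length(side_pos) == 0L) return(integer(0))
    x <- side_pos; y <- p[x]
    breaks <- which(diff(x) - 1L > criteria$max_bulge_mir |
                      abs(diff(y)) - 1L > criteria$max_bulge_mir)
    seg_id <- cumsum(c(0L, seq_along(x)[-1] %in% (breaks + 1L)))
    segs <- split(x, seg_id)
    segs[[which.max(lengths(segs))]]
  }
  cand5 <- mir[p[mir] > max(mir)]
  cand3 <- mir[p[mir] > 0L & p[mir] < min(mir)]
  run5 <- best_run(cand5); run3 <- best_run(cand3)
  use5 <- length(run5) >= length(run3)
  run <- if (use5) run5 else run3
  arm_side <- if (length(run) == 0L) NA_character_ else
    if (use5) "5p" else "3p"

  duplex_pairs <- length(run)
  unpaired_in_mir <- mir_len - duplex_pairs
  mir_gaps <- if (duplex_pairs > 1L) max(diff(run) - 1L) else 0L

  failed <- character(0)
  metrics <- list(unpaired_in_mir = unpaired_in_mir,
                  max_bulge_in_mir = mir_gaps,
                  stem_pairs = 0L, arm_side = arm_side,
                  star_overlap_loop = NA, duplex_pairs = duplex_pairs,
                  one_sided_arm = FALSE)

  if (duplex_pairs == 0L) {
    metrics$star_overlap_loop <- TRUE
    return(list(verdict = FALSE, metrics = metrics,
                failed = c("one_sided_arm", "unpaired_in_mir",
                           "star_overlap_loop", "stem_pairs")))
  }

  ## (i) one contiguous opposite arm: at most a couple of stray pairs
  ## land off the duplex side
  n_other <- length(if (use5) cand3 else cand5)
  metrics$one_sided_arm <- n_other <= criteria$max_bulge_mir
  if (!metrics$one_sided_arm) failed <- c(failed, "one_sided_arm")

  ## (ii) unpaired bases in the miRNA region
  if (unpaired_in_mir > criteria$max_unpaired_mir) {
    failed <- c(failed, "unpaired_in_mir")
  }
  ## (iii) largest internal bulge inside the duplex run
  if (mir_gaps > criteria$max_bulge_mir) failed <- c(failed, "max_bulge")

  ## (iv) + (v): terminal loop and enclosing stem, from the run's
  ## innermost pair
  if (use5) {
    a <- max(run); pa <- p[a]                  # loop sits 3' of the miRNA
    tail_len <- max(mir) - a
    stem_pairs <- sum(p > 0 & seq_len(n) < p & seq_len(n) <= a & p >= pa)
  } else {
    a <- min(run); pa <- p[a]                  # loop sits 5' of the miRNA
    tail_len <- a - min(mir)
    stem_pairs <- sum(p > 0 & seq_len(n) < p & seq_len(n) <= pa & p >= a)
  }
  metrics$stem_pairs <- stem_pairs
  metrics$star_overlap_loop <- tail_len > criteria$max_loop_tail
  if (metrics$star_overlap_loop) failed <- c(failed, "star_overlap_loop")
  if (stem_pairs < criteria$min_stem_pairs) failed <- c(failed, "stem_pairs")

  list(verdict = length(failed) == 0L, metrics = metrics, failed = failed)
}

#' Screen small RNA loci for pre-miRNA-like hairpins
#'
#' For each distinct small RNA placement, extracts the +/-`flank`
#' precursor window, folds it and applies [check_hairpin()].
#'
#' @param hits data.frame from [map_exact()].
#' @param transcripts named character vector or `nat_transcripts` table.
#' @param flank precursor flank, default 200.
#' @param criteria [hairpin_criteria()].
#' @param max_loci cap on the number of screened loci (most abundant
#'   first; ties broken by transcript then position).  `Inf` screens all.
#' @return data.frame with one row per screened locus: `transcript_id`,
#'   `position`, `srna`, window coordinates, `structure`, metrics and
#'   `verdict`.
#' @export
screen_hairpins <- function(hits, transcripts, flank = 200L,
                            criteria = hairpin_criteria(),
                            max_loci = Inf) {
  seqs <- .sequences_of(transcripts)
  loci <- hits[!duplicated(hits[c("transcript_id", "position", "sequence")]),
               , drop = FALSE]
  loci <- loci[order(-loci$count, loci$transcript_id, loci$position,
                     loci$sequence), , drop = FALSE]
  if (nrow(loci) > max_loci) loci <- loci[seq_len(max_loci), , drop = FALSE]
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    h <- loci[i, ]
    prec <- extract_precursor(seqs[[h$transcript_id]], h$position,
                              nchar(h$sequence), flank)
    if (nchar(prec$sequence) < 40L) next
    fd <- fold(prec$sequence)
    chk <- check_hairpin(prec$sequence, fd$structure,
                         prec$mir_start, prec$mir_end, criteria)
    rows[[i]] <- data.frame(
      transcript_id = h$transcript_id, position = h$position,
      srna = h$sequence, count = h$count,
      window_start = prec$start, window_end = prec$end,
      structure = fd$structure,
      unpaired_in_mir = chk$metrics$unpaired_in_mir,
      max_bulge_in_mir = chk$metrics$max_bulge_in_mir,
      stem_pairs = chk$metrics$stem_pairs,
      arm_side = chk$metrics$arm_side,
      star_overlap_loop = chk$metrics$star_overlap_loop,
      verdict = chk$verdict,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(0), position = integer(0),
                      srna = character(0), count = integer(0),
                      window_start = integer(0), window_end = integer(0),
                      structure = character(0),
                      unpaired_in_mir = integer(0),
                      max_bulge_in_mir = integer(0),
                      stem_pairs = integer(0), arm_side = character(0),
                      star_overlap_loop = logical(0), verdict = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dinucleotide shuffle of a sequence
#'
#' Random Eulerian-walk shuffle preserving dinucleotide composition; used
#' as the negative control for hairpin discrimination.
#'
#' @param sequence nucleotide sequence.
#' @return shuffled sequence with the same dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(sequence)
  ## edges of the dinucleotide multigraph, successors per symbol
  succ <- split(ch[-1], ch[-n])
  ## random last-edge choice per vertex fixes a spanning arborescence to
  ## the terminal symbol; here we take the simpler route: shuffle successor
  ## lists and retry until the walk uses every edge
  for (attempt in 1:100) {
    bags <- lapply(succ, sample)
    ptr <- stats::setNames(rep(1L, length(bags)), names(bags))
    out <- character(n)
    out[1] <- ch[1]
    ok <- TRUE
    for (i in 2:n) {
      v <- out[i - 1]
      k <- ptr[[v]]
      if (is.null(bags[[v]]) || k > length(bags[[v]])) { ok <- FALSE; break }
      out[i] <- bags[[v]][k]
      ptr[[v]] <- k + 1L
    }
    if (ok) return(paste(out, collapse = ""))
  }
  ## fall back to a plain shuffle (composition-preserving only)
  paste(sample(ch), collapse = "")
}

#' Intersect an external miRNA target list with NAT membership
#'
#' @param mirna_targets data.frame with columns `target_id`, `mirna` and
#'   optionally `validated` (logical).
#' @param nat_pairs `nat_pairs` data.frame.
#' @return `mirna_targets` with an `is_nat_member` column (`TRUE` iff the
#'   target appears in at least one pair).
#' @export
nat_mirna_target_intersect <- function(mirna_targets, nat_pairs) {
  members <- unique(c(nat_pairs$id_a, nat_pairs$id_b))
  mirna_targets$is_nat_member <- mirna_targets$target_id %in% members
  if (is.null(mirna_targets$validated)) mirna_targets$validated <- FALSE
  mirna_targets
}
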