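## Seeded synthetic genomes, transcriptomes, small RNA and degradome
## libraries with a ground-truth manifest.  The generator states a small
## idealised world with the structure the pipeline is designed to detect:
## cis pairs of all three orientations with perfectly complementary
## overlaps, trans families sharing one antisense partner, small RNA
## clouds concentrated in overlap regions with tunable strand bias,
## degradome tags at planted cleavage sites (compliant and rule-violating),
## and inverted-repeat pre-miRNA precursors.

#' Simulation configuration
#'
#' Defaults state the simulated world once: overlap lengths are drawn
#' log-uniformly from 31-500 nt (the smallest reported NAT overlap is
#' 31 bp and the distribution is strongly right-skewed), read lengths have
#' modes at 21/22/24 nt, background GC is 35% (legume-like), small RNA
#' abundances are geometric (long-tailed), and the overlap concentration
#' factor is 5.
#'
#' @param seed integer seed; fixes the entire output.
#' @param n_background number of unrelated background genes.
#' @param n_cis named integer vector: cis pairs per orientation.
#' @param n_trans_families,trans_family_size trans-NAT families (each
#'   family: `trans_family_size` homologous genes sharing one antisense
#'   partner).
#' @param overlap_range overlap length range (min >= 31).
#' @param gene_length_range transcript length range.
#' @param gc background GC content.
#' @param smallrna list: `n_reads`, `length_weights` (named, lengths
#'   20-25), `f` (overlap concentration: per-base sampling rate inside the
#'   overlap is `f`-fold the outside rate), `bias_mix` (One/Equal/Bias
#'   proportions), `geom_prob` (abundance ~ geometric), `n_excluded`
#'   (decoy reads planted in the exclusion sets).
#' @param degradome list: `n_targets` (rule-compliant planted targets),
#'   `n_decoys` (rule-violating sites), `noise_tags`, `tag_len`,
#'   `tag_count`, `guide_count`.
#' @param hairpins list: `n_planted`, `arm_len`, `loop_range`,
#'   `mature_len`, `mature_count`.  The default arm (220 nt) makes the
#'   +/-200 nt screening window fall inside the planted stem.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background = 100L,
                       n_cis = c(convergent = 7L, divergent = 7L,
                                 enclosed = 6L),
                       n_trans_families = 10L,
                       trans_family_size = 3L,
                       overlap_range = c(31L, 500L),
                       gene_length_range = c(1000L, 3000L),
                       gc = 0.35,
                       smallrna = list(),
                       degradome = list(),
                       hairpins = list()) {
  sr <- utils::modifyList(list(
    n_reads = 4000L,
    length_weights = c(`20` = 0.04, `21` = 0.30, `22` = 0.22,
                       `23` = 0.06, `24` = 0.30, `25` = 0.08),
    f = 5,
    bias_mix = c(One = 0.4, Equal = 0.2, Bias = 0.4),
    geom_prob = 0.4,
    n_excluded = 50L
  ), smallrna)
  dg <- utils::modifyList(list(
    n_targets = 30L, n_decoys = 30L, noise_tags = 20L,
    tag_len = 20L, tag_count = 5L, guide_count = 10L, guide_len = 21L
  ), degradome)
  hp <- utils::modifyList(list(
    n_planted = 3L, arm_len = 220L, loop_range = c(8L, 15L),
    mature_len = 21L, mature_count = 30L
  ), hairpins)
  stopifnot(overlap_range[1] >= 31L, sr$f > 0, n_background >= 0,
            all(n_cis >= 0), gene_length_range[1] > overlap_range[1])
  structure(list(seed = as.integer(seed), n_background = n_background,
                 n_cis = n_cis, n_trans_families = n_trans_families,
                 trans_family_size = trans_family_size,
                 overlap_range = overlap_range,
                 gene_length_range = gene_length_range, gc = gc,
                 smallrna = sr, degradome = dg, hairpins = hp),
            class = "sim_config")
}

#' Random nucleotide sequence at a given GC content
#' @param n length; @param gc GC fraction.
#' @return character scalar.
#' @export
random_seq <- function(n, gc = 0.35) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.rloguniform <- function(n, lo, hi) {
  as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))
}

.rlen <- function(n, range) {
  if (range[1] == range[2]) rep.int(range[1], n) else
    sample(range[1]:range[2], n, replace = TRUE)
}

## simple genome placement book-keeping: round-robin chromosomes with gaps
.placer <- function(n_chrom = 5L, gap = 2000L) {
  cursors <- stats::setNames(rep(0L, n_chrom), paste0("chr", seq_len(n_chrom)))
  i <- 0L
  function(len) {
    i <<- i %% n_chrom + 1L
    chrom <- names(cursors)[i]
    start <- cursors[[chrom]] + gap
    cursors[[chrom]] <<- start + len
    list(chromosome = chrom, start = start, end = start + len)
  }
}

#' Simulate the genome: transcripts, coordinates and planted NAT pairs
#'
#' Cis pairs are built by placing opposite-strand gene spans with the
#' requested overlap geometry on a shared genomic segment, so the
#' transcript sequences are perfectly complementary over the overlap.
#' Trans families copy the reverse complement of a partner-gene block into
#' `trans_family_size` paralogs on other chromosomes.  Background genes
#' are i.i.d. random sequence.
#'
#' @param config [sim_config()].
#' @return list `transcripts` (a `nat_transcripts` table with sequences)
#'   and `manifest` (planted pairs with class, orientation and
#'   transcript-local overlap intervals; protected-interval registry).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  place <- .placer()
  rows <- list()
  pair_rows <- list()
  protected <- list()   # transcript_id -> list of c(start, end)

  add_tx <- function(id, chrom, strand, gstart, gend, seq) {
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = id, chromosome = chrom,
      strand = strand, genomic_start = gstart, genomic_end = gend,
      sequence = seq, stringsAsFactors = FALSE)
  }
  protect <- function(id, s, e) {
    protected[[id]] <<- c(protected[[id]], list(c(s, e)))
  }
  add_pair <- function(id1, ov1, id2, ov2, class, orientation, L) {
    if (id1 > id2) { tmp <- id1; id1 <- id2; id2 <- tmp
                     tmp <- ov1; ov1 <- ov2; ov2 <- tmp }
    pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
      id_a = id1, id_b = id2, a_start = ov1[1], a_end = ov1[2],
      b_start = ov2[1], b_end = ov2[2], overlap_length = L,
      locus_class = class, orientation = orientation,
      stringsAsFactors = FALSE)
  }

  ## --- cis pairs -----------------------------------------------------
  k <- 0L
  for (ori in names(config$n_cis)) {
    for (r in seq_len(config$n_cis[[ori]])) {
      k <- k + 1L
      L <- .rloguniform(1, config$overlap_range[1],
                        min(config$overlap_range[2],
                            config$gene_length_range[1] - 2L))
      lens <- .rlen(2, config$gene_length_range)
      lenP <- max(lens[1], L + 2L); lenM <- max(lens[2], L + 2L)
      if (ori == "convergent") {
        P <- c(0L, lenP); M <- c(lenP - L, lenP - L + lenM)
      } else if (ori == "divergent") {
        M <- c(0L, lenM); P <- c(lenM - L, lenM - L + lenP)
      } else {                        # enclosed: minus gene inside plus gene
        lenM <- L
        P <- c(0L, lenP)
        off <- sample(seq_len(lenP - L - 1L), 1L)
        M <- c(off, off + L)
      }
      seg_len <- max(P[2], M[2])
      seg <- random_seq(seg_len, config$gc)
      loc <- place(seg_len)
      idP <- sprintf("cis%02d_s", k); idM <- sprintf("cis%02d_as", k)
      seqP <- substr(seg, P[1] + 1L, P[2])
      seqM <- reverse_complement(substr(seg, M[1] + 1L, M[2]))
      add_tx(idP, loc$chromosome, "+", loc$start + P[1], loc$start + P[2],
             seqP)
      add_tx(idM, loc$chromosome, "-", loc$start + M[1], loc$start + M[2],
             seqM)
      O <- c(max(P[1], M[1]), min(P[2], M[2]))
      ovP <- c(O[1] - P[1], O[2] - P[1])
      ovM <- c(M[2] - O[2], M[2] - O[1])
      protect(idP, ovP[1], ovP[2]); protect(idM, ovM[1], ovM[2])
      add_pair(idP, ovP, idM, ovM, "cis", ori, O[2] - O[1])
    }
  }

  ## --- trans families ------------------------------------------------
  for (fam in seq_len(config$n_trans_families)) {
    L <- .rloguniform(1, config$overlap_range[1],
                      min(config$overlap_range[2],
                          config$gene_length_range[1] - 2L))
    lenY <- .rlen(1, config$gene_length_range)
    seqY <- random_seq(lenY, config$gc)
    u <- sample(seq_len(lenY - L - 1L), 1L)
    block <- substr(seqY, u + 1L, u + L)
    idY <- sprintf("trans%02d_as", fam)
    locY <- place(lenY)
    add_tx(idY, locY$chromosome, "+", locY$start, locY$end, seqY)
    protect(idY, u, u + L)
    ins <- reverse_complement(block)
    for (mmb in seq_len(config$trans_family_size)) {
      lenX <- .rlen(1, config$gene_length_range)
      v <- sample(seq_len(lenX - L - 1L), 1L)
      seqX <- random_seq(lenX, config$gc)
      substr(seqX, v + 1L, v + L) <- ins
      idX <- sprintf("trans%02d_t%d", fam, mmb)
      locX <- place(lenX)
      add_tx(idX, locX$chromosome, "+", locX$start, locX$end, seqX)
      protect(idX, v, v + L)
      add_pair(idX, c(v, v + L), idY, c(u, u + L), "trans",
               "not_applicable", L)
    }
  }

  ## --- background genes ----------------------------------------------
  for (b in seq_len(config$n_background)) {
    lenB <- .rlen(1, config$gene_length_range)
    locB <- place(lenB)
    add_tx(sprintf("bg%03d", b), locB$chromosome, "+", locB$start,
           locB$end, random_seq(lenB, config$gc))
  }

  transcripts <- do.call(rbind, rows)
  class(transcripts) <- c("nat_transcripts", "data.frame")
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  list(transcripts = transcripts,
       manifest = list(pairs = pairs, protected = protected,
                       config = config))
}

## free start positions of an interval of length `len` on a transcript,
## avoiding protected intervals entirely
.free_starts <- function(tx_len, len, protected_iv, pad = 0L) {
  ok <- rep(TRUE, tx_len - len + 1L)
  for (iv in protected_iv) {
    lo <- max(1L, iv[1] - len + 1L - pad)
    hi <- min(length(ok), iv[2] + pad)
    if (lo <= hi) ok[lo:hi] <- FALSE
  }
  which(ok) - 1L   # 0-based starts
}

#' Plant inverted-repeat pre-miRNA precursors into NAT transcripts
#'
#' Each precursor is `arm + loop + reverse_complement(arm)`; the mature
#' small RNA is the 3'-most `mature_len` nt of the 5' arm (adjacent to the
#' loop), and is added to the small RNA library.  Hosts are NAT
#' transcripts with enough unprotected room, in id order.
#'
#' @param sim result of [simulate_genome()].
#' @param config [sim_config()].
#' @return `sim` with modified transcript sequences, extra manifest entry
#'   `hairpins`, and `mature_reads` (data.frame to merge into the small
#'   RNA library).
#' @export
plant_hairpins <- function(sim, config) {
  set.seed(config$seed + 3L)
  hp <- config$hairpins
  if (hp$n_planted == 0L) {
    sim$manifest$hairpins <- NULL
    sim$mature_reads <- NULL
    return(sim)
  }
  loop_max <- hp$loop_range[2]
  need <- 2L * hp$arm_len + loop_max
  tx <- sim$transcripts
  nat_ids <- sort(unique(c(sim$manifest$pairs$id_a, sim$manifest$pairs$id_b)))
  planted <- list(); mature_rows <- list()
  n_done <- 0L
  for (id in nat_ids) {
    if (n_done >= hp$n_planted) break
    i <- match(id, tx$transcript_id)
    tx_len <- nchar(tx$sequence[i])
    starts <- .free_starts(tx_len, need, sim$manifest$protected[[id]])
    if (length(starts) == 0L) next
    s <- starts[sample.int(length(starts), 1L)]
    arm <- random_seq(hp$arm_len, sim$manifest$config$gc)
    loop_len <- sample(hp$loop_range[1]:hp$loop_range[2], 1L)
    precursor <- paste0(arm, random_seq(loop_len, sim$manifest$config$gc),
                        reverse_complement(arm))
    substr(tx$sequence[i], s + 1L, s + nchar(precursor)) <- precursor
    mature_start <- s + hp$arm_len - hp$mature_len
    mature <- substr(tx$sequence[i], mature_start + 1L,
                     mature_start + hp$mature_len)
    sim$manifest$protected[[id]] <-
      c(sim$manifest$protected[[id]], list(c(s, s + nchar(precursor))))
    planted[[length(planted) + 1L]] <- data.frame(
      transcript_id = id, hp_start = s, hp_end = s + nchar(precursor),
      arm_len = hp$arm_len, loop_len = loop_len,
      mature_start = mature_start, mature = mature,
      stringsAsFactors = FALSE)
    mature_rows[[length(mature_rows) + 1L]] <- data.frame(
      read_id = sprintf("mat%02d_%d", length(planted), hp$mature_count),
      sequence = mature, count = hp$mature_count,
      stringsAsFactors = FALSE)
    n_done <- n_done + 1L
  }
  if (n_done < hp$n_planted) {
    stop("could not place ", hp$n_planted, " hairpins (", n_done,
         " placed); transcripts too short", call. = FALSE)
  }
  sim$transcripts <- tx
  sim$manifest$hairpins <- do.call(rbind, planted)
  sim$mature_reads <- do.call(rbind, mature_rows)
  sim
}

## mismatch templates (siRNA coordinates, 5' end = 1) for planted targets
.compliant_templates <- list(
  integer(0), c(5L), c(15L), c(3L, 14L), c(14L, 20L), c(1L, 12L, 20L),
  c(9L, 13L, 19L), c(5L, 12L), c(20L), c(2L, 15L, 21L)
)
.violating_templates <- list(
  c(10L), c(11L), c(1L, 5L), c(10L, 11L), c(2L, 9L, 15L), c(3L, 10L),
  c(12L, 13L, 14L), c(11L, 20L), c(4L, 8L), c(1L, 10L, 12L)
)

.mutate_base <- function(base) {
  cycle <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  cycle[[base]]
}

#' Plant degradome cleavage scenarios (compliant targets and decoys)
#'
#' For each scenario a guide siRNA is cut from a non-overlap region of a
#' NAT transcript, a target site (the guide's reverse complement with
#' template mismatches) is written into the target transcript, and a
#' degradome tag is emitted with its 5' end at the canonical cleavage
#' position (opposite siRNA positions 10/11).  Origins rotate through
#' `a` (target = the guide source's NAT partner), `s` (target = the
#' source itself) and `o` (target = a background gene).  Decoys use
#' rule-violating mismatch templates and must yield no target call.
#'
#' @param sim result of [simulate_genome()] (after [plant_hairpins()]).
#' @param config [sim_config()].
#' @return `sim` with modified transcripts, manifest entry `targets`,
#'   `guide_reads` (to merge into the small RNA library) and `tags`
#'   (degradome reads data.frame).
#' @export
simulate_degradome <- function(sim, config) {
  set.seed(config$seed + 2L)
  dg <- config$degradome
  pairs <- sim$manifest$pairs
  tx <- sim$transcripts
  bg_ids <- tx$transcript_id[grepl("^bg", tx$transcript_id)]
  glen <- dg$guide_len
  n_total <- dg$n_targets + dg$n_decoys
  target_rows <- list(); guide_rows <- list(); tag_rows <- list()
  origins <- c("a", "s", "o")
  partner_of <- function(id) {
    unique(c(pairs$id_b[pairs$id_a == id], pairs$id_a[pairs$id_b == id]))
  }

  for (i in seq_len(n_total)) {
    compliant <- i <= dg$n_targets
    tmpl <- if (compliant) {
      .compliant_templates[[(i - 1L) %% length(.compliant_templates) + 1L]]
    } else {
      j <- i - dg$n_targets
      .violating_templates[[(j - 1L) %% length(.violating_templates) + 1L]]
    }
    origin <- origins[(i - 1L) %% 3L + 1L]

    ## plan the scenario: walk the pair list until one offers room for
    ## both the guide (an unprotected region of a member; an
    ## enclosed-orientation antisense gene is wall-to-wall overlap and
    ## has none) and the target site.  Site placement uses pad = 30 so
    ## the long-degradome window (site +/- ~30 nt) stays clear of overlap
    ## regions and other planted features: only the planted guide can
    ## match inside it.  The end filter leaves room for the tag.
    planned <- FALSE
    for (attempt in 0:(nrow(pairs) - 1L)) {
      pr <- pairs[(i - 1L + attempt) %% nrow(pairs) + 1L, ]
      g_starts <- integer(0)
      for (source_id in c(pr$id_a, pr$id_b)) {
        si <- match(source_id, tx$transcript_id)
        g_starts <- .free_starts(nchar(tx$sequence[si]), glen,
                                 sim$manifest$protected[[source_id]])
        if (length(g_starts)) break
      }
      if (length(g_starts) == 0L) next
      partner_id <- if (source_id == pr$id_a) pr$id_b else pr$id_a
      ## origin o targets a NAT transcript of a *different* pair (the
      ## degradome is mapped onto NAT transcripts only, so targets are
      ## always NAT members; 'o' means the siRNA's own pair is unrelated)
      t_cands <- switch(origin, a = partner_id, s = source_id, o = {
        pr2 <- pairs[(i + attempt) %% nrow(pairs) + 1L, ]
        setdiff(c(pr2$id_a, pr2$id_b),
                c(pr$id_a, pr$id_b, partner_of(pr$id_a), partner_of(pr$id_b)))
      })
      t_starts <- integer(0)
      for (target_id in t_cands) {
        ti <- match(target_id, tx$transcript_id)
        t_len <- nchar(tx$sequence[ti])
        t_starts <- .free_starts(t_len, glen,
                                 sim$manifest$protected[[target_id]],
                                 pad = 30L)
        t_starts <- t_starts[t_starts >= 40L &
                               t_starts <= t_len - glen - 40L]
        if (length(t_starts)) break
      }
      if (length(t_starts) == 0L) next
      planned <- TRUE
      break
    }
    if (!planned) {
      stop("no pair offers room for degradome scenario ", i, " (origin ",
           origin, ")", call. = FALSE)
    }
    g_pos <- g_starts[sample.int(length(g_starts), 1L)]
    guide <- substr(tx$sequence[si], g_pos + 1L, g_pos + glen)
    sim$manifest$protected[[source_id]] <-
      c(sim$manifest$protected[[source_id]], list(c(g_pos, g_pos + glen)))

    ## site: rc(guide) with template mismatches, written into the target
    site <- reverse_complement(guide)
    for (p in tmpl) {
      j0 <- glen - p          # 0-based site offset pairing siRNA pos p
      substr(site, j0 + 1L, j0 + 1L) <-
        .mutate_base(substr(site, j0 + 1L, j0 + 1L))
    }
    ## recompute site room now that the guide interval is protected: when
    ## target == source the site must not overwrite the guide itself
    t_len <- nchar(tx$sequence[ti])
    t_starts <- .free_starts(t_len, glen,
                             sim$manifest$protected[[target_id]],
                             pad = 30L)
    t_starts <- t_starts[t_starts >= 40L & t_starts <= t_len - glen - 40L]
    if (length(t_starts) == 0L) {
      stop("no room left for target site on ", target_id, call. = FALSE)
    }
    s_pos <- t_starts[sample.int(length(t_starts), 1L)]
    substr(tx$sequence[ti], s_pos + 1L, s_pos + glen) <- site
    sim$manifest$protected[[target_id]] <-
      c(sim$manifest$protected[[target_id]], list(c(s_pos, s_pos + glen)))

    ## tag 5' end opposite siRNA position 10
    anchor <- s_pos + glen - 10L
    tag <- substr(tx$sequence[ti], anchor + 1L, anchor + dg$tag_len)
    tag_rows[[length(tag_rows) + 1L]] <- data.frame(
      read_id = sprintf("tag%03d_%d", i, dg$tag_count),
      sequence = tag, count = dg$tag_count, stringsAsFactors = FALSE)
    guide_rows[[length(guide_rows) + 1L]] <- data.frame(
      read_id = sprintf("guide%03d_%d", i, dg$guide_count),
      sequence = guide, count = dg$guide_count, stringsAsFactors = FALSE)
    target_rows[[length(target_rows) + 1L]] <- data.frame(
      sirna = guide, source_id = source_id, target_id = target_id,
      site_start = s_pos, site_end = s_pos + glen,
      mismatches = paste(tmpl, collapse = ","),
      origin_expected = origin, expect_accept = compliant,
      tag = tag, stringsAsFactors = FALSE)
  }

  for (nz in seq_len(dg$noise_tags)) {
    tag_rows[[length(tag_rows) + 1L]] <- data.frame(
      read_id = sprintf("noise%03d_1", nz),
      sequence = random_seq(dg$tag_len, sim$manifest$config$gc),
      count = 1L, stringsAsFactors = FALSE)
  }

  sim$transcripts <- tx
  sim$manifest$targets <- do.call(rbind, target_rows)
  sim$guide_reads <- do.call(rbind, guide_rows)
  sim$tags <- do.call(rbind, tag_rows)
  sim
}

#' Sample the small RNA library
#'
#' Reads are exact substrings of the (final) NAT transcript sequences.
#' Within each pair, the per-base sampling rate inside the overlap is
#' `f`-fold the outside rate; the transcript of origin follows the pair's
#' drawn strand-bias category (`One`: all reads from one transcript;
#' `Equal`: 50/50; `Bias`: 80/20).  Lengths follow `length_weights`,
#' abundances are geometric.  Guide-siRNA source regions and other
#' protected intervals are never sampled, so planted features stay
#' unambiguous.  Decoy reads that are substrings of the exclusion sets are
#' appended to exercise the exclusion filter.
#'
#' @param sim result of the upstream simulation stages.
#' @param config [sim_config()].
#' @return `sim` with `reads` (the merged library), `exclusion_sets`
#'   (named list of sequences) and manifest entry `smallrna`.
#' @export
simulate_smallrnas <- function(sim, config) {
  set.seed(config$seed + 1L)
  sr <- config$smallrna
  pairs <- sim$manifest$pairs
  tx <- sim$transcripts
  seqs <- stats::setNames(tx$sequence, tx$transcript_id)
  lw <- sr$length_weights
  rlens <- as.integer(names(lw))

  n_pairs <- nrow(pairs)
  alloc <- as.integer(stats::rmultinom(1, sr$n_reads,
                                       rep(1 / n_pairs, n_pairs)))
  categories <- sample(names(sr$bias_mix), n_pairs, replace = TRUE,
                       prob = sr$bias_mix)
  read_rows <- list(); pair_meta <- list()

  for (pi in seq_len(n_pairs)) {
    pr <- pairs[pi, ]
    designated <- sample(c("a", "b"), 1L)
    p_designated <- switch(categories[pi], One = 1, Equal = 0.5, Bias = 0.8)
    n_i <- alloc[pi]
    meta <- list(pair_id = paste(pr$id_a, pr$id_b, sep = "|"),
                 category = categories[pi], designated = designated,
                 n_reads = n_i)
    pair_meta[[pi]] <- meta
    if (n_i == 0L) next
    for (rd in seq_len(n_i)) {
      side <- if (stats::runif(1) < p_designated) designated else
        setdiff(c("a", "b"), designated)
      id <- if (side == "a") pr$id_a else pr$id_b
      ov <- if (side == "a") c(pr$a_start, pr$a_end) else
        c(pr$b_start, pr$b_end)
      rl <- sample(rlens, 1L, prob = lw)
      tx_len <- nchar(seqs[[id]])
      L_ov <- ov[2] - ov[1]
      p_ov <- sr$f * L_ov / (sr$f * L_ov + (tx_len - L_ov))
      if (stats::runif(1) < p_ov) {
        start <- ov[1] + sample.int(max(1L, L_ov - rl + 1L), 1L) - 1L
      } else {
        allowed <- .free_starts(tx_len, rl,
                                c(sim$manifest$protected[[id]], list(ov)),
                                pad = 4L)
        if (length(allowed) == 0L) next
        start <- allowed[sample.int(length(allowed), 1L)]
      }
      start <- min(start, tx_len - rl)
      read_rows[[length(read_rows) + 1L]] <- data.frame(
        sequence = substr(seqs[[id]], start + 1L, start + rl),
        count = stats::rgeom(1, sr$geom_prob) + 1L,
        origin_id = id, origin_pos = start,
        stringsAsFactors = FALSE)
    }
  }

  lib <- do.call(rbind, read_rows)
  if (!is.null(lib)) {
    lib$read_id <- sprintf("sr%05d_%d", seq_len(nrow(lib)), lib$count)
  }

  ## exclusion sets and planted decoy reads
  exclusion_sets <- list(
    rfam = stats::setNames(
      vapply(1:5, function(i) random_seq(500L, config$gc), character(1)),
      sprintf("rfam%02d", 1:5)),
    te = stats::setNames(
      vapply(1:3, function(i) random_seq(1000L, config$gc), character(1)),
      sprintf("te%02d", 1:3))
  )
  excl_rows <- list()
  for (e in seq_len(sr$n_excluded)) {
    set_name <- sample(names(exclusion_sets), 1L)
    src <- exclusion_sets[[set_name]][[
      sample.int(length(exclusion_sets[[set_name]]), 1L)]]
    start <- sample.int(nchar(src) - 21L, 1L)
    cnt <- stats::rgeom(1, sr$geom_prob) + 1L
    excl_rows[[length(excl_rows) + 1L]] <- data.frame(
      read_id = sprintf("xdec%03d_%d", e, cnt),
      sequence = substr(src, start, start + 20L),
      count = cnt,
      expected_set = set_name,
      stringsAsFactors = FALSE)
  }
  excluded <- do.call(rbind, excl_rows)

  reads <- rbind(
    if (!is.null(lib)) lib[, c("read_id", "sequence", "count")],
    if (!is.null(sim$mature_reads)) sim$mature_reads,
    if (!is.null(sim$guide_reads)) sim$guide_reads,
    if (!is.null(excluded)) excluded[, c("read_id", "sequence", "count")]
  )
  sim$reads <- reads
  sim$exclusion_sets <- exclusion_sets
  sim$manifest$smallrna <- list(
    per_pair = do.call(rbind, lapply(pair_meta, as.data.frame)),
    excluded = excluded,
    f = sr$f
  )
  sim
}

#' Run every simulation stage and (optionally) write the file bundle
#'
#' Stage order: genome, hairpin planting, degradome planting, small RNA
#' sampling.  With `outdir`, writes `transcripts.fa`, `genes.tsv`,
#' `srna.fa`, `degradome.fa`, `exclude_rfam.fa`, `exclude_te.fa`,
#' `mirna_targets.tsv` and `truth.json`, after verifying that every
#' planted feature is re-locatable in the emitted sequences.
#'
#' @param config [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return the full simulation state (invisibly when writing).
#' @export
simulate_all <- function(config, outdir = NULL) {
  sim <- simulate_genome(config)
  sim <- plant_hairpins(sim, config)
  sim <- simulate_degradome(sim, config)
  sim <- simulate_smallrnas(sim, config)

  ## a small synthetic miRNA target list for the intersection stage
  nat_ids <- sort(unique(c(sim$manifest$pairs$id_a, sim$manifest$pairs$id_b)))
  bg_ids <- sim$transcripts$transcript_id[
    grepl("^bg", sim$transcripts$transcript_id)]
  n_nat <- min(6L, length(nat_ids)); n_bg <- min(4L, length(bg_ids))
  sim$manifest$mirna_targets <- data.frame(
    target_id = c(nat_ids[seq_len(n_nat)], bg_ids[seq_len(n_bg)]),
    mirna = sprintf("syn-miR%03d", seq_len(n_nat + n_bg)),
    validated = rep(c(TRUE, FALSE), length.out = n_nat + n_bg),
    is_nat_expected = rep(c(TRUE, FALSE), c(n_nat, n_bg)),
    stringsAsFactors = FALSE)

  verify_manifest(sim)
  if (!is.null(outdir)) {
    write_simulation(sim, outdir)
    return(invisible(sim))
  }
  sim
}

#' Check that every planted feature is re-locatable in the emitted data
#'
#' Verifies overlap complementarity of every planted pair, exact presence
#' of guide siRNAs, planted sites, tags and hairpin matures, and that
#' excluded decoys are substrings of their exclusion set.
#'
#' @param sim full simulation state.
#' @return `TRUE` (invisibly); errors on any inconsistency.
#' @export
verify_manifest <- function(sim) {
  seqs <- stats::setNames(sim$transcripts$sequence,
                          sim$transcripts$transcript_id)
  pr <- sim$manifest$pairs
  for (i in seq_len(nrow(pr))) {
    a <- substr(seqs[[pr$id_a[i]]], pr$a_start[i] + 1L, pr$a_end[i])
    b <- substr(seqs[[pr$id_b[i]]], pr$b_start[i] + 1L, pr$b_end[i])
    if (a != reverse_complement(b)) {
      stop("manifest inconsistency: pair ", pr$id_a[i], "/", pr$id_b[i],
           " overlap is not complementary", call. = FALSE)
    }
  }
  tg <- sim$manifest$targets
  for (i in seq_len(NROW(tg))) {
    if (!grepl(tg$sirna[i], seqs[[tg$source_id[i]]], fixed = TRUE)) {
      stop("manifest inconsistency: guide siRNA ", i, " not in its source",
           call. = FALSE)
    }
    if (!grepl(tg$tag[i], seqs[[tg$target_id[i]]], fixed = TRUE)) {
      stop("manifest inconsistency: tag ", i, " not in its target",
           call. = FALSE)
    }
  }
  hp <- sim$manifest$hairpins
  for (i in seq_len(NROW(hp))) {
    s <- seqs[[hp$transcript_id[i]]]
    mat <- substr(s, hp$mature_start[i] + 1L,
                  hp$mature_start[i] + nchar(hp$mature[i]))
    if (mat != hp$mature[i]) {
      stop("manifest inconsistency: hairpin mature ", i, " mismatch",
           call. = FALSE)
    }
  }
  if (!is.null(sim$manifest$smallrna)) {
    ex <- sim$manifest$smallrna$excluded
    for (i in seq_len(NROW(ex))) {
      hay <- paste(sim$exclusion_sets[[ex$expected_set[i]]], collapse = "#")
      if (!grepl(ex$sequence[i], hay, fixed = TRUE)) {
        stop("manifest inconsistency: excluded decoy ", i,
             " not in its exclusion set", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Write the simulation bundle to disk
#'
#' @param sim full simulation state.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tx <- sim$transcripts
  write_fasta(stats::setNames(tx$sequence, tx$transcript_id),
              file.path(outdir, "transcripts.fa"))
  genes <- data.frame(tx$transcript_id, tx$chromosome,
                      tx$genomic_start + 1L, tx$genomic_end, tx$strand)
  utils::write.table(genes, file.path(outdir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_fasta(stats::setNames(sim$reads$sequence, sim$reads$read_id),
              file.path(outdir, "srna.fa"))
  if (!is.null(sim$tags)) {
    write_fasta(stats::setNames(sim$tags$sequence, sim$tags$read_id),
                file.path(outdir, "degradome.fa"))
  }
  write_fasta(sim$exclusion_sets$rfam,
              file.path(outdir, "exclude_rfam.fa"))
  write_fasta(sim$exclusion_sets$te, file.path(outdir, "exclude_te.fa"))
  utils::write.table(
    sim$manifest$mirna_targets[c("target_id", "mirna", "validated")],
    file.path(outdir, "mirna_targets.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- sim$manifest
  manifest$protected <- NULL
  manifest$config <- unclass(manifest$config)
  jsonlite::write_json(manifest, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
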