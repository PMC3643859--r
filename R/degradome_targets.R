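## nat-siRNA target calling from degradome 5' tags: exact tag mapping,
## +/-20 nt "long degradome" windows, Patscan-style mismatch scanning
## (<=3 substitutions, no indels) and the position-specific filter on the
## mismatch profile, then origin coding (a/s/o, multiple).

#' Map degradome 5' tags onto transcripts
#'
#' Exact, full-length, sense-orientation matches only; every placement is
#' reported.  The tag's 5' end is `position` (0-based).
#'
#' @param tags data.frame (`read_id`, `sequence`, `count`).
#' @param transcripts named character vector or `nat_transcripts` table.
#' @return data.frame of hits as in [map_exact()].
#' @export
map_degradome <- function(tags, transcripts) {
  map_exact(tags, transcripts)
}

#' Extract the long degradome window around a tag
#'
#' The window is the tag footprint extended by `flank` nt on both sides,
#' clipped at the transcript bounds.
#'
#' @param transcript_seq transcript sequence.
#' @param position 0-based 5' position of the tag on the transcript.
#' @param tag_len tag length in nt.
#' @param flank context size, default 20.
#' @return list `window_start`, `window_end` (0-based half-open),
#'   `sequence`, `anchor` (= `position`).
#' @export
extract_long_degradome <- function(transcript_seq, position, tag_len,
                                   flank = 20L) {
  L <- nchar(transcript_seq)
  w0 <- max(0L, position - flank)
  w1 <- min(L, position + tag_len + flank)
  list(window_start = w0, window_end = w1,
       sequence = substr(transcript_seq, w0 + 1L, w1),
       anchor = position)
}

## site[j] (0-based offset within the site) pairs the siRNA base at
## 1-based position  len - j  counted from the siRNA 5' end.
.mismatch_positions <- function(site_int, rc_sirna_int, len) {
  mm <- which(site_int != rc_sirna_int | site_int == 0L)
  sort(len - (mm - 1L))
}

#' Scan a long-degradome window for candidate siRNA target sites
#'
#' Slides the reverse complement of the siRNA along the window and keeps
#' every offset with at most `max_mismatch` substitutions (no indels).
#' Mismatch positions are reported in siRNA coordinates: position 1 is the
#' siRNA 5' end, which pairs the 3'-most base of the site.  `N` never
#' matches.  G:U wobble counts as a full mismatch unless `gu_half = TRUE`,
#' in which case each wobble contributes 0.5 to the mismatch budget and is
#' dropped from the reported positions.
#'
#' @param sirna siRNA sequence (sense, 5'->3').
#' @param window_seq window sequence (transcript sense).
#' @param window_start 0-based offset of the window on its transcript
#'   (added to the reported site coordinates).
#' @param max_mismatch substitution budget, default 3.
#' @param gu_half downgrade G:U wobble to half weight (default `FALSE`).
#' @return data.frame `site_start`, `site_end` (0-based half-open,
#'   transcript coordinates), `n_mismatch`, and list column
#'   `mismatch_positions`.
#' @export
scan_candidate_sites <- function(sirna, window_seq, window_start = 0L,
                                 max_mismatch = 3, gu_half = FALSE) {
  len <- nchar(sirna)
  wlen <- nchar(window_seq)
  if (len > wlen) return(.empty_sites())
  rc <- reverse_complement(sirna)
  rc_int <- .encode_seq(rc)
  w_int <- .encode_seq(window_seq)
  rows <- list()
  for (off in 0:(wlen - len)) {
    site_int <- w_int[(off + 1L):(off + len)]
    mmpos <- .mismatch_positions(site_int, rc_int, len)
    weight <- length(mmpos)
    if (gu_half && weight > 0) {
      ## wobble: siRNA G opposite site T, or siRNA T opposite site G;
      ## in rc space that is rc=C/site=T or rc=A/site=G
      j <- len - mmpos + 1L  # site offsets (1-based), parallel to mmpos
      wob <- (rc_int[j] == 2L & site_int[j] == 4L) |
        (rc_int[j] == 1L & site_int[j] == 3L)
      weight <- sum(!wob) + 0.5 * sum(wob)
      mmpos <- mmpos[!wob]
    }
    if (weight > max_mismatch) next
    rows[[length(rows) + 1L]] <- data.frame(
      site_start = window_start + off,
      site_end = window_start + off + len,
      n_mismatch = length(mmpos)
    )
    rows[[length(rows)]]$mismatch_positions <- I(list(mmpos))
  }
  if (length(rows) == 0L) return(.empty_sites())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_sites <- function() {
  out <- data.frame(site_start = integer(0), site_end = integer(0),
                    n_mismatch = integer(0))
  out$mismatch_positions <- I(list())
  out
}

#' Position-specific mismatch filter for siRNA target sites
#'
#' Accepts a candidate site iff its mismatch profile (siRNA coordinates,
#' 5' end = position 1) has fewer than two mismatches in positions 1-9,
#' none in positions 10-11, and fewer than three after position 11:
#' `#{p <= 9} <= 1  AND  #{p in {10,11}} = 0  AND  #{p >= 12} <= 2`.
#'
#' @param mismatch_positions integer vector of 1-based siRNA positions.
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
schwab_filter <- function(mismatch_positions) {
  p <- mismatch_positions
  sum(p <= 9) <= 1 && sum(p == 10 | p == 11) == 0 && sum(p >= 12) <= 2
}

#' Origin code of a nat-siRNA target call
#'
#' `a`: the target forms a NAT pair with a transcript the siRNA derives
#' from (the classic nat-siRNA geometry); `s`: the siRNA derives from the
#' target transcript itself; `o`: the siRNA guides cleavage of an
#' unrelated transcript.  `multiple` flags siRNAs carried by more than
#' five distinct transcripts.
#'
#' @param sirna siRNA sequence.
#' @param target_id targeted transcript.
#' @param nat_pairs `nat_pairs` data.frame.
#' @param sirna_sources character vector of transcript ids carrying the
#'   siRNA exactly (from [map_exact()]).
#' @return list `origin` (`"a"`, `"s"` or `"o"`) and `multiple_flag`.
#' @export
classify_origin <- function(sirna, target_id, nat_pairs, sirna_sources) {
  if (length(sirna_sources) == 0L) {
    stop("siRNA ", sirna, " has no source transcript; upstream mapping bug",
         call. = FALSE)
  }
  partner_of_target <- unique(c(
    nat_pairs$id_b[nat_pairs$id_a == target_id],
    nat_pairs$id_a[nat_pairs$id_b == target_id]
  ))
  origin <- if (any(sirna_sources %in% partner_of_target)) {
    "a"
  } else if (target_id %in% sirna_sources) {
    "s"
  } else {
    "o"
  }
  list(origin = origin, multiple_flag = length(unique(sirna_sources)) > 5L)
}

#' Call nat-siRNA targets from degradome tags
#'
#' For every degradome tag placement, the +/-`flank` long-degradome window
#' is extracted and scanned against every query siRNA; sites passing the
#' position-specific mismatch filter become target calls, deduplicated on
#' `(sirna, transcript, site)` with tag support summed, origin-coded, and
#' deterministically sorted.
#'
#' @param sirnas data.frame of query small RNAs (`sequence`, `count`);
#'   typically the unique NAT-derived siRNAs from [map_exact()].
#' @param degradome_hits data.frame from [map_degradome()].
#' @param nat_pairs classified `nat_pairs` data.frame.
#' @param transcripts named character vector or `nat_transcripts` table.
#' @param srna_hits small RNA hits used to resolve each siRNA's source
#'   transcripts (defaults to mapping `sirnas` onto `transcripts`).
#' @param flank long-degradome context, default 20.
#' @param max_mismatch substitution budget for the scan, default 3.
#' @param gu_half see [scan_candidate_sites()].
#' @return data.frame: `sirna`, `sirna_abundance`, `target_id`,
#'   `site_start`, `site_end` (0-based half-open), list column
#'   `mismatch_positions`, `n_mismatch`, `origin`, `multiple_flag`,
#'   `tag_support`.
#' @export
call_targets <- function(sirnas, degradome_hits, nat_pairs, transcripts,
                         srna_hits = NULL, flank = 20L, max_mismatch = 3,
                         gu_half = FALSE) {
  seqs <- .sequences_of(transcripts)
  sirnas <- sirnas[!duplicated(sirnas$sequence), , drop = FALSE]
  if (is.null(srna_hits)) {
    srna_hits <- map_exact(
      data.frame(read_id = sprintf("q%d", seq_len(nrow(sirnas))),
                 sequence = sirnas$sequence, count = sirnas$count),
      transcripts)
  }
  source_map <- split(srna_hits$transcript_id, srna_hits$sequence)

  if (nrow(degradome_hits) == 0L || nrow(sirnas) == 0L) {
    return(.empty_calls())
  }
  ## bulk scan (compiled): every siRNA against every long-degradome window
  wins <- lapply(seq_len(nrow(degradome_hits)), function(h) {
    hit <- degradome_hits[h, ]
    extract_long_degradome(seqs[[hit$transcript_id]], hit$position,
                           nchar(hit$sequence), flank)
  })
  cand <- .scan_windows(vapply(wins, `[[`, character(1), "sequence"),
                        reverse_complement(sirnas$sequence),
                        nchar(sirnas$sequence),
                        as.integer(max_mismatch), isTRUE(gu_half))
  if (length(cand$win_idx) == 0L) return(.empty_calls())
  keep <- vapply(cand$mismatch_positions, schwab_filter, logical(1))
  if (!any(keep)) return(.empty_calls())
  rows <- lapply(which(keep), function(i) {
    w <- cand$win_idx[i]; q <- cand$q_idx[i]
    s0 <- wins[[w]]$window_start + cand$offset[i]
    list(sirna = sirnas$sequence[q],
         sirna_abundance = sirnas$count[q],
         target_id = degradome_hits$transcript_id[w],
         site_start = s0,
         site_end = s0 + nchar(sirnas$sequence[q]),
         mismatch_positions = cand$mismatch_positions[[i]],
         n_mismatch = cand$n_mismatch[i],
         tag_support = degradome_hits$count[w])
  })

  ## dedup on (sirna, transcript, site); tag support summed over tags
  key <- vapply(rows, function(r) {
    paste(r$sirna, r$target_id, r$site_start, sep = "|")
  }, character(1))
  support <- tapply(vapply(rows, `[[`, numeric(1), "tag_support"), key, sum)
  rows <- rows[!duplicated(key)]
  key <- key[!duplicated(key)]

  out <- data.frame(
    sirna = vapply(rows, `[[`, character(1), "sirna"),
    sirna_abundance = vapply(rows, `[[`, numeric(1), "sirna_abundance"),
    target_id = vapply(rows, `[[`, character(1), "target_id"),
    site_start = vapply(rows, `[[`, numeric(1), "site_start"),
    site_end = vapply(rows, `[[`, numeric(1), "site_end"),
    n_mismatch = vapply(rows, `[[`, numeric(1), "n_mismatch"),
    stringsAsFactors = FALSE
  )
  out$mismatch_positions <- I(lapply(rows, `[[`, "mismatch_positions"))
  out$tag_support <- as.numeric(support[key])

  oc <- lapply(seq_len(nrow(out)), function(i) {
    classify_origin(out$sirna[i], out$target_id[i], nat_pairs,
                    unique(source_map[[out$sirna[i]]]))
  })
  out$origin <- vapply(oc, `[[`, character(1), "origin")
  out$multiple_flag <- vapply(oc, `[[`, logical(1), "multiple_flag")

  o <- order(out$sirna, out$target_id, out$site_start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_calls <- function() {
  out <- data.frame(sirna = character(0), sirna_abundance = numeric(0),
                    target_id = character(0), site_start = numeric(0),
                    site_end = numeric(0), n_mismatch = numeric(0),
                    stringsAsFactors = FALSE)
  out$mismatch_positions <- I(list())
  out$tag_support <- numeric(0)
  out$origin <- character(0)
  out$multiple_flag <- logical(0)
  out
}
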