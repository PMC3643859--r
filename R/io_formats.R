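## Readers/writers for the external formats the pipeline touches, plus the
## canonical coordinate convention: everything internal is 0-based half-open;
## everything emitted to TSV is 1-based inclusive.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Normalise a nucleotide sequence
#'
#' Uppercases and converts RNA U to DNA T. Under the strict policy any
#' residual character outside `A,C,G,T,N` is an error.
#'
#' @param x character vector of sequences.
#' @param alphabet_policy `"strict"` (default) errors on non-ACGTN
#'   characters; `"mask"` replaces them with `N`.
#' @return normalised character vector.
#' @export
normalize_sequence <- function(x, alphabet_policy = c("strict", "mask")) {
  alphabet_policy <- match.arg(alphabet_policy)
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    if (alphabet_policy == "strict") {
      i <- which(bad)[1]
      ch <- regmatches(x[i], regexpr("[^ACGTN]", x[i]))
      stop("illegal character '", ch, "' in sequence ", i, call. = FALSE)
    }
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalised (U to T, uppercased); the record id is the first
#' whitespace-delimited token of the header. Record order is preserved.
#'
#' @param path FASTA file (plain or gzipped).
#' @param alphabet_policy see [normalize_sequence()].
#' @return named character vector of sequences (names are the ids).
#' @export
read_fasta <- function(path, alphabet_policy = c("strict", "mask")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id: ", dup[1], call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- tryCatch(
    normalize_sequence(seqs, alphabet_policy),
    error = function(e) {
      stop(conditionMessage(e), " (file ", path, ")", call. = FALSE)
    }
  )
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Build a transcript record table
#'
#' The canonical container for annotated transcripts: one row per transcript
#' with genomic span in the internal 0-based half-open convention and,
#' optionally, the spliced sense-strand sequence.
#'
#' @param transcript_id,gene_id,chromosome,strand,start,end,sequence vectors.
#' @return data.frame with class `nat_transcripts`.
#' @export
transcript_table <- function(transcript_id, gene_id = transcript_id,
                             chromosome, strand, start, end,
                             sequence = NA_character_) {
  stopifnot(all(strand %in% c("+", "-")))
  if (any(end <= start)) {
    stop("genomic_end must exceed genomic_start", call. = FALSE)
  }
  out <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chromosome = as.character(chromosome),
    strand = as.character(strand),
    genomic_start = as.integer(start),
    genomic_end = as.integer(end),
    sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("nat_transcripts", "data.frame")
  out
}

#' Read gene coordinates from GFF3 or a 5-column table
#'
#' `gff3` keeps rows of type `mRNA` and takes the transcript id from the
#' `ID` attribute. `tsv5` expects columns
#' `transcript_id chromosome start(1-based) end strand` with or without a
#' header. All coordinates are converted to 0-based half-open.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"tsv5"`.
#' @return `nat_transcripts` table without sequences.
#' @export
read_gene_table <- function(path, dialect = c("tsv5", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "gff3") {
    gff <- rtracklayer::readGFF(path)
    gff <- gff[gff$type == "mRNA", , drop = FALSE]
    if (nrow(gff) == 0L) stop("no mRNA rows in ", path, call. = FALSE)
    id <- as.character(gff$ID)
    chrom <- as.character(gff$seqid)
    start1 <- as.integer(gff$start)
    end1 <- as.integer(gff$end)
    strand <- as.character(gff$strand)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 5L) stop("tsv5 needs 5 columns, got ", ncol(tab),
                             call. = FALSE)
    ## tolerate a header row
    if (!grepl("^[0-9]+$", as.character(tab[1, 3]))) tab <- tab[-1, ]
    id <- as.character(tab[[1]])
    chrom <- as.character(tab[[2]])
    start1 <- as.integer(as.character(tab[[3]]))
    end1 <- as.integer(as.character(tab[[4]]))
    strand <- as.character(tab[[5]])
  }
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         strand[which(!strand %in% c("+", "-"))[1]], call. = FALSE)
  }
  if (any(start1 > end1)) stop("start > end in ", path, call. = FALSE)
  ## 1-based inclusive -> 0-based half-open
  transcript_table(id, id, chrom, strand, start1 - 1L, end1)
}

#' Read small RNA or degradome reads with abundances
#'
#' Two dialects: `fasta_suffix` (headers of the form `>id_COUNT`) and `tsv2`
#' (`sequence<TAB>count`). With `dialect = "auto"` the first record is
#' sniffed. Identical sequences are kept as separate records; collapsing is
#' an explicit downstream step.
#'
#' @param path reads file.
#' @param dialect `"auto"`, `"fasta_suffix"` or `"tsv2"`.
#' @param min_len,max_len length filter bounds; `NULL` disables (degradome
#'   tags are read unfiltered, small RNA libraries default to 15-40 nt at
#'   mapping time, not here).
#' @return data.frame with columns `read_id`, `sequence`, `count`.
#' @export
read_abundance_reads <- function(path,
                                 dialect = c("auto", "fasta_suffix", "tsv2"),
                                 min_len = NULL, max_len = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (startsWith(first, ">")) "fasta_suffix" else "tsv2"
  }
  if (dialect == "fasta_suffix") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty reads file: ", path, call. = FALSE)
    hdr <- sub("\\s.*$", "", names(set))
    count_str <- sub("^.*_", "", hdr)
    if (any(!grepl("^[0-9]+$", count_str))) {
      bad <- hdr[which(!grepl("^[0-9]+$", count_str))[1]]
      stop("cannot parse abundance from header '", bad,
           "' (expected >id_COUNT)", call. = FALSE)
    }
    out <- data.frame(
      read_id = hdr,
      sequence = normalize_sequence(as.character(set)),
      count = as.integer(count_str),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("tsv2 needs 2 columns", call. = FALSE)
    cnt <- suppressWarnings(as.integer(as.character(tab[[2]])))
    if (anyNA(cnt)) {
      stop("non-integer count in record ", which(is.na(cnt))[1], call. = FALSE)
    }
    out <- data.frame(
      read_id = sprintf("r%d", seq_len(nrow(tab))),
      sequence = normalize_sequence(as.character(tab[[1]])),
      count = cnt,
      stringsAsFactors = FALSE
    )
  }
  if (any(out$count < 1L)) stop("count must be >= 1", call. = FALSE)
  if (!is.null(min_len)) out <- out[nchar(out$sequence) >= min_len, ]
  if (!is.null(max_len)) out <- out[nchar(out$sequence) <= max_len, ]
  rownames(out) <- NULL
  out
}

## ---- table writers (all 1-based inclusive on disk) -----------------------

#' Write / read the NAT pair table
#'
#' Columns: `id_a id_b overlap_len evalue class orientation a_start a_end
#' b_start b_end` with transcript-local overlap coordinates emitted 1-based
#' inclusive. Rows are sorted by `(id_a, id_b)`.
#'
#' @param pairs `nat_pairs` data.frame from [call_nat_pairs()].
#' @param path output TSV.
#' @export
write_nat_table <- function(pairs, path) {
  out <- data.frame(
    id_a = pairs$id_a, id_b = pairs$id_b,
    overlap_len = pairs$overlap_length,
    evalue = formatC(pairs$evalue, format = "e", digits = 3),
    class = pairs$locus_class,
    orientation = pairs$orientation,
    a_start = pairs$a_start + 1L, a_end = pairs$a_end,
    b_start = pairs$b_start + 1L, b_end = pairs$b_end,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nat_table
#' @export
read_nat_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pairs <- data.frame(
    id_a = tab$id_a, id_b = tab$id_b,
    a_start = tab$a_start - 1L, a_end = tab$a_end,
    b_start = tab$b_start - 1L, b_end = tab$b_end,
    overlap_length = tab$overlap_len,
    score = if ("score" %in% names(tab)) tab$score else NA_integer_,
    evalue = as.numeric(tab$evalue),
    locus_class = tab$class,
    orientation = tab$orientation,
    stringsAsFactors = FALSE
  )
  class(pairs) <- c("nat_pairs", "data.frame")
  pairs
}

#' Write the nat-siRNA target table
#'
#' Columns mirror a degradome target supplement: siRNA sequence and
#' abundance, target id, 1-based inclusive site, mismatch positions
#' (comma-joined, 5' end of the siRNA = position 1), origin code
#' (`a`/`s`/`o`), multiple flag and supporting degradome tag count.
#'
#' @param calls data.frame from [call_targets()].
#' @param path output TSV.
#' @export
write_target_table <- function(calls, path) {
  out <- data.frame(
    sirna = calls$sirna,
    sirna_abundance = calls$sirna_abundance,
    target_id = calls$target_id,
    site_start = calls$site_start + 1L,
    site_end = calls$site_end,
    mismatches = vapply(calls$mismatch_positions, function(v) {
      if (length(v) == 0L) "." else paste(v, collapse = ",")
    }, character(1)),
    origin = calls$origin,
    multiple = ifelse(calls$multiple_flag, "yes", "no"),
    tag_support = calls$tag_support,
    stringsAsFactors = FALSE
  )
  o <- order(out$sirna, out$target_id, out$site_start)
  utils::write.table(out[o, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the enrichment table
#'
#' One row per scope (a NAT pair or the pooled set) with the raw counts
#' No/Nt/Lo/Lt, densities per kilobase, enrichment score and the 1-df
#' chi-squared test.
#'
#' @param results data.frame from [enrichment()].
#' @param path output TSV.
#' @export
write_enrichment_table <- function(results, path) {
  out <- results
  out$Do_per_kb <- out$Do * 1000
  out$Dt_per_kb <- out$Dt * 1000
  out <- out[order(out$scope, out$pair_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write small RNA / degradome hits
#'
#' Positions are emitted 1-based inclusive.
#' @param hits data.frame from [map_exact()] or [map_degradome()].
#' @param path output TSV.
#' @export
write_hits_table <- function(hits, path) {
  out <- data.frame(
    sequence = hits$sequence, count = hits$count,
    transcript_id = hits$transcript_id,
    start = hits$position + 1L,
    end = hits$position + nchar(hits$sequence),
    stringsAsFactors = FALSE
  )
  o <- order(out$transcript_id, out$start, out$sequence)
  utils::write.table(out[o, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_table
#' @export
read_hits_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    sequence = tab$sequence, count = tab$count,
    transcript_id = tab$transcript_id,
    position = tab$start - 1L,
    stringsAsFactors = FALSE
  )
}

#' Write dot-bracket structures as Vienna-style 3-line records
#'
#' @param ids,seqs,structs parallel character vectors.
#' @param path output file.
#' @export
write_dotbracket <- function(ids, seqs, structs, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(structs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(c(paste0(">", ids[i]), seqs[i], structs[i]), con)
  }
  invisible(path)
}
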