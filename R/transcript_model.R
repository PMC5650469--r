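#' Load a spliced transcriptome from FASTA + GFF3
#'
#' Builds per-transcript sequences by splicing annotated exons in 5'->3' mRNA
#' order (minus-strand genes are reverse-complemented) and expresses CDS
#' bounds in 0-based, half-open transcript coordinates. Transcripts whose
#' exons overlap another transcript on the same genomic strand, transcripts
#' named on an exclusion list, and transcripts whose CDS length is not a
#' multiple of three are flagged `masked` and skipped by downstream
#' quantitation and site calling (they are never dropped).
#'
#' The FASTA may hold either genome contigs referenced by the GFF3, or the
#' transcript sequences themselves when the GFF3 describes single-exon
#' records in transcript coordinates.
#'
#' @param fasta_path Path to the FASTA file.
#' @param gff_path Path to a GFF3 file with exon and CDS features whose
#'   `Parent` (or `ID`) attributes group them into transcripts.
#' @param er_path Optional path to a two-column TSV (`transcript_id`,
#'   `er_associated` as 0/1) flagging ER-associated transcripts.
#' @param exclude Optional character vector of transcript IDs to mask
#'   (e.g. annotations marked dubious).
#'
#' @return A tibble of class `ridd_transcriptome` with columns
#'   `transcript_id`, `sequence`, `length`, `cds_start`, `cds_end`
#'   (0-based half-open), `er_associated` and `masked`.
#' @export
load_transcriptome <- function(fasta_path, gff_path, er_path = NULL,
                               exclude = NULL) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(gff_path, format = "gff3")

  feats <- gff[tolower(as.character(gff$type)) %in% c("exon", "cds")]
  if (length(feats) == 0L) stop("no exon/CDS features found in ", gff_path)
  p <- S4Vectors::mcols(feats)$Parent
  if (methods::is(p, "List")) {
    parent <- vapply(p, function(x) if (length(x)) x[[1]] else NA_character_,
                     character(1))
  } else {
    parent <- as.character(p)
  }
  id <- as.character(S4Vectors::mcols(feats)$ID)
  parent[is.na(parent)] <- id[is.na(parent)]
  if (anyNA(parent)) stop("GFF exon/CDS features lack Parent and ID attributes")
  parent <- sub("^(mRNA|transcript):", "", parent)

  ftab <- tibble::tibble(
    transcript_id = parent,
    type = tolower(as.character(feats$type)),
    seqname = as.character(GenomicRanges::seqnames(feats)),
    start = GenomicRanges::start(feats),  # 1-based closed, per GFF
    end = GenomicRanges::end(feats),
    strand = as.character(GenomicRanges::strand(feats))
  )

  missing_seq <- setdiff(unique(ftab$seqname), names(genome))
  if (length(missing_seq) > 0L) {
    stop("GFF records reference sequences absent from the FASTA: ",
         paste(missing_seq, collapse = ", "))
  }

  build_one <- function(df) {
    exons <- df[df$type == "exon", , drop = FALSE]
    if (nrow(exons) == 0L) exons <- df[df$type == "cds", , drop = FALSE]
    minus <- exons$strand[1] == "-"
    exons <- exons[order(exons$start, decreasing = minus), , drop = FALSE]
    segs <- purrr::map_chr(seq_len(nrow(exons)), function(i) {
      s <- Biostrings::subseq(genome[[exons$seqname[i]]],
                              exons$start[i], exons$end[i])
      if (minus) s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    seq <- paste(segs, collapse = "")

    # genomic -> transcript coordinate (0-based) for a genomic position
    ex_len <- exons$end - exons$start + 1L
    cum <- cumsum(c(0L, ex_len))
    g2t <- function(gpos) {
      for (i in seq_len(nrow(exons))) {
        if (gpos >= exons$start[i] && gpos <= exons$end[i]) {
          off <- if (minus) exons$end[i] - gpos else gpos - exons$start[i]
          return(cum[i] + off)
        }
      }
      NA_integer_
    }

    cds <- df[df$type == "cds", , drop = FALSE]
    if (nrow(cds) == 0L) {
      cds_start <- 0L
      cds_end <- nchar(seq)
    } else {
      first <- if (minus) max(cds$end) else min(cds$start)
      last <- if (minus) min(cds$start) else max(cds$end)
      cds_start <- g2t(first)
      cds_end <- g2t(last) + 1L
    }
    tibble::tibble(
      seqname = exons$seqname[1], strand = exons$strand[1],
      g_start = min(exons$start), g_end = max(exons$end),
      sequence = seq, length = nchar(seq),
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
    )
  }

  tx <- ftab %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::group_modify(~ build_one(.x)) %>%
    dplyr::ungroup()

  # mask same-strand genomic overlap between distinct transcripts
  gr <- GenomicRanges::GRanges(tx$seqname,
                               IRanges::IRanges(tx$g_start, tx$g_end),
                               strand = tx$strand)
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  ov <- ov[S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)]
  masked <- seq_len(nrow(tx)) %in% S4Vectors::queryHits(ov)

  bad_cds <- (tx$cds_end - tx$cds_start) %% 3L != 0L
  if (any(bad_cds)) {
    warning("CDS length not divisible by 3; masking: ",
            paste(tx$transcript_id[bad_cds], collapse = ", "))
  }
  masked <- masked | bad_cds
  if (!is.null(exclude)) masked <- masked | tx$transcript_id %in% exclude

  er <- rep(NA, nrow(tx))
  if (!is.null(er_path)) {
    ertab <- readr::read_tsv(er_path, col_names = c("transcript_id", "er"),
                             col_types = "ci", progress = FALSE)
    er <- as.logical(ertab$er[match(tx$transcript_id, ertab$transcript_id)])
  }

  out <- tibble::tibble(
    transcript_id = tx$transcript_id,
    sequence = tx$sequence,
    length = as.integer(tx$length),
    cds_start = tx$cds_start,
    cds_end = tx$cds_end,
    er_associated = er,
    masked = masked
  )
  stopifnot(all(out$cds_start >= 0), all(out$cds_end <= out$length),
            all(out$cds_start < out$cds_end))
  class(out) <- c("ridd_transcriptome", class(out))
  out
}

#' Write transcript sequences to FASTA
#'
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- transcripts$transcript_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write transcript annotation to GFF3
#'
#' Emits one single-exon gene/mRNA/exon/CDS record per transcript in
#' transcript coordinates (seqname = transcript ID), the companion of
#' [write_transcriptome_fasta()] for round-tripping through
#' [load_transcriptome()].
#'
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_gff <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    id <- tx$transcript_id
    writeLines(c(
      sprintf("%s\triddseq\tgene\t1\t%d\t.\t+\t.\tID=gene:%s", id,
              tx$length, id),
      sprintf("%s\triddseq\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=gene:%s", id,
              tx$length, id, id),
      sprintf("%s\triddseq\texon\t1\t%d\t.\t+\t.\tID=%s.e1;Parent=%s", id,
              tx$length, id, id),
      sprintf("%s\triddseq\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c1;Parent=%s", id,
              tx$cds_start + 1L, tx$cds_end, id, id)
    ), con)
  }
  invisible(path)
}

#' Reading frame of a transcript position
#'
#' Frame 0 means the base is the first base of a codon. Vectorized over
#' `transcript_id` and `pos`.
#'
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param transcript_id Transcript identifier(s).
#' @param pos 0-based transcript position(s); must lie within the CDS.
#' @return Integer vector of frames in `{0, 1, 2}`.
#' @export
frame_of <- function(transcripts, transcript_id, pos) {
  i <- match(transcript_id, transcripts$transcript_id)
  if (anyNA(i)) stop("unknown transcript: ",
                     paste(unique(transcript_id[is.na(i)]), collapse = ", "))
  cs <- transcripts$cds_start[i]
  ce <- transcripts$cds_end[i]
  if (any(pos < cs | pos >= ce)) stop("position not in CDS")
  as.integer((pos - cs) %% 3L)
}

#' Classify the trinucleotide motif at a putative cleavage position
#'
#' `pos` indexes the 3'-terminal G of a candidate UG/C site (cleavage occurs
#' between `pos` and `pos + 1`); the classified trinucleotide is
#' `sequence[pos-1 .. pos+1]`. Sequences are held in the DNA alphabet, so
#' UG/C is matched as `TGC`. A site is `near_UGC` when the trinucleotide
#' differs from `TGC` at exactly one of its three positions. Positions at a
#' transcript boundary (no flanking base on one side) are classified `other`
#' with a warning. Vectorized over `transcript_id` and `pos`.
#'
#' @inheritParams frame_of
#' @return Factor with levels `UGC`, `near_UGC`, `other`.
#' @export
classify_motif <- function(transcripts, transcript_id, pos) {
  i <- match(transcript_id, transcripts$transcript_id)
  if (anyNA(i)) stop("unknown transcript: ",
                     paste(unique(transcript_id[is.na(i)]), collapse = ", "))
  len <- transcripts$length[i]
  at_edge <- pos < 1L | pos > len - 2L
  if (any(at_edge)) warning("position at transcript boundary classified 'other'")
  tri <- rep(NA_character_, length(pos))
  ok <- !at_edge
  tri[ok] <- stringr::str_sub(transcripts$sequence[i[ok]], pos[ok], pos[ok] + 2L)
  classify_trinucleotide(tri)
}

# Hamming-distance classification of a trinucleotide against TGC.
classify_trinucleotide <- function(tri) {
  ref <- c("T", "G", "C")
  d <- vapply(tri, function(t) {
    if (is.na(t) || nchar(t) != 3L) return(NA_integer_)
    sum(strsplit(t, "")[[1]] != ref)
  }, integer(1), USE.NAMES = FALSE)
  out <- dplyr::case_when(
    is.na(d) ~ "other",
    d == 0L ~ "UGC",
    d == 1L ~ "near_UGC",
    TRUE ~ "other"
  )
  factor(out, levels = c("UGC", "near_UGC", "other"))
}
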