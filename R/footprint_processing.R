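#' Footprint size classes
#'
#' Footprints of 15-18 nt (`short`) report ribosomes stalled at truncated
#' mRNA 3' ends; 25-34 nt (`long`) are canonical elongating-ribosome
#' footprints (and disome-protected fragments). Everything else, including
#' the 20-22 nt alternate-conformation population, is `other`.
#'
#' @param length Integer vector of read lengths (nt).
#' @return Factor with levels `short`, `long`, `other`.
#' @export
classify_size <- function(length) {
  out <- dplyr::case_when(
    length >= 15 & length <= 18 ~ "short",
    length >= 25 & length <= 34 ~ "long",
    TRUE ~ "other"
  )
  factor(out, levels = c("short", "long", "other"))
}

#' Read aligned reads from SAM/BAM or TSV
#'
#' Accepts alignments to a transcriptome (one reference sequence per
#' transcript). SAM files are converted to BAM internally and parsed with
#' Rsamtools; the read length is the reference-space width of the CIGAR.
#' `n_alignments` is taken from the `NH` tag when present (secondary
#' alignments additionally force `n_alignments >= 2`), otherwise 1.
#' TSV input must have columns `transcript_id`, `start` (0-based), `length`,
#' and optionally `n_alignments`.
#'
#' @param path Path to a `.sam`, `.bam` or tabular file.
#' @return Tibble with columns `transcript_id`, `start` (0-based `length`,
#'   `n_alignments`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    res <- Rsamtools::scanBam(
      bam,
      param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "cigar", "flag"), tag = "NH"
      )
    )[[1]]
    keep <- !is.na(res$pos)
    nh <- res$tag$NH
    if (is.null(nh)) nh <- rep(1L, length(res$pos))
    nh[is.na(nh)] <- 1L
    secondary <- bitwAnd(res$flag, 256L) > 0L
    nh <- pmax(nh, ifelse(secondary, 2L, 1L))
    tibble::tibble(
      transcript_id = as.character(res$rname)[keep],
      start = res$pos[keep] - 1L,
      length = GenomicAlignments::cigarWidthAlongReferenceSpace(
        res$cigar[keep]
      ),
      n_alignments = as.integer(nh[keep])
    )
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (!"n_alignments" %in% names(tab)) tab$n_alignments <- 1L
    tibble::as_tibble(tab[, c("transcript_id", "start", "length",
                              "n_alignments")])
  }
}

#' Build a per-nucleotide end-assigned density track
#'
#' Assigns one count per uniquely-mapping read at its 3' end (footprints) or
#' 5' end (mRNA-Seq), optionally shifted by a fixed offset (negative =
#' towards the 5' end; the canonical P-site shifts are -2 for short and -14
#' for long footprints). Counts shifted outside the transcript are dropped
#' (never clamped to the boundary) and tallied in the `n_dropped` attribute.
#'
#' The library size used for rpm conversion counts every uniquely-mapping
#' read in the *sample* the track was cut from: for footprint libraries all
#' reads of 15-34 nt regardless of the size class requested, for mRNA-Seq
#' (`size_class = "all"`) every read. Pass `library_total` to override.
#'
#' @param reads Tibble with `transcript_id`, `start`, `length`,
#'   `n_alignments` (reads with `n_alignments > 1` are discarded).
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param size_class One of `"short"`, `"long"`, `"other"`, `"all"`.
#' @param assignment `"three_prime"` or `"five_prime"`.
#' @param shift Integer offset added to the assigned position.
#' @param library_total Optional override for the library size (reads).
#' @return A sparse tibble of class `ridd_track` with columns
#'   `transcript_id`, `pos`, `count` and attributes `units` (`"counts"`),
#'   `library_total`, `size_class`, `assignment`, `shift`, `n_dropped`.
#' @export
build_density <- function(reads, transcripts,
                          size_class = c("short", "long", "other", "all"),
                          assignment = c("three_prime", "five_prime"),
                          shift = 0L) {
  size_class <- match.arg(size_class)
  assignment <- match.arg(assignment)
  uni <- dplyr::filter(reads, .data$n_alignments <= 1L)
  lib <- if (size_class == "all") {
    nrow(uni)
  } else {
    sum(uni$length >= 15 & uni$length <= 34)
  }
  sel <- if (size_class == "all") uni else {
    dplyr::filter(uni, classify_size(.data$length) == size_class)
  }
  tx_len <- setNames(transcripts$length, transcripts$transcript_id)
  assigned <- if (assignment == "three_prime") {
    sel$start + sel$length - 1L
  } else {
    sel$start
  }
  pos <- assigned + as.integer(shift)
  len <- tx_len[sel$transcript_id]
  inb <- !is.na(len) & pos >= 0L & pos < len
  n_dropped <- sum(!inb)
  if (n_dropped > 0L) {
    message(n_dropped, " read(s) assigned outside the transcript were dropped")
  }
  track <- tibble::tibble(transcript_id = sel$transcript_id[inb],
                          pos = pos[inb]) %>%
    dplyr::count(.data$transcript_id, .data$pos, name = "count") %>%
    dplyr::mutate(count = as.numeric(.data$count))
  new_track(track, units = "counts", library_total = lib,
            size_class = size_class, assignment = assignment,
            shift = as.integer(shift), n_dropped = n_dropped)
}

new_track <- function(df, units, library_total, size_class, assignment,
                      shift, n_dropped = 0L) {
  attr(df, "units") <- units
  attr(df, "library_total") <- library_total
  attr(df, "size_class") <- size_class
  attr(df, "assignment") <- assignment
  attr(df, "shift") <- shift
  attr(df, "n_dropped") <- n_dropped
  class(df) <- unique(c("ridd_track", class(df)))
  df
}

#' Convert a raw-count track to reads per million mapped (rpm)
#'
#' Divides every count by the library size in millions. Refuses to convert a
#' track that is already in rpm.
#'
#' @param track A `ridd_track` in raw counts.
#' @param library_total Optional override of the track's library size (reads).
#' @return The track with `count` in rpm and `units = "rpm"`.
#' @export
to_rpm <- function(track, library_total = NULL) {
  if (attr(track, "units") == "rpm") stop("track is already in rpm")
  lib <- library_total %||% attr(track, "library_total")
  if (is.null(lib) || lib <= 0) stop("library_total must be > 0")
  out <- dplyr::mutate(track, count = .data$count / (lib / 1e6))
  attr(out, "units") <- "rpm"
  attr(out, "library_total") <- lib
  class(out) <- class(track)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense per-position vector for one transcript (zeros included)
track_vector <- function(track, transcript_id, length) {
  v <- numeric(length)
  sub <- track[track$transcript_id == transcript_id, ]
  v[sub$pos + 1L] <- sub$count
  v
}

#' Gene-level footprint density in rpkm
#'
#' Sums track counts over the CDS excluding the first and last five codons
#' (15 nt at each end, guarding against initiation/termination artifacts),
#' then divides by the included length in kilobases and the library size in
#' millions. Use a P-site-shifted track (-2 short / -14 long) for gene
#' quantitation. Masked transcripts and CDSs of 30 nt or less yield `NA`.
#'
#' @param track A `ridd_track` in raw counts.
#' @param transcripts A `ridd_transcriptome` tibble.
#' @return Tibble `transcript_id`, `rpkm`.
#' @export
gene_rpkm <- function(track, transcripts) {
  if (attr(track, "units") != "counts") {
    stop("gene_rpkm expects a raw-count track")
  }
  lib_m <- attr(track, "library_total") / 1e6
  short_cds <- !transcripts$masked &
    (transcripts$cds_end - transcripts$cds_start) <= 30L
  if (any(short_cds)) {
    warning("CDS of 30 nt or less; rpkm undefined for: ",
            paste(transcripts$transcript_id[short_cds], collapse = ", "))
  }
  bounds <- transcripts %>%
    dplyr::transmute(.data$transcript_id, .data$masked,
                     lo = .data$cds_start + 15L, hi = .data$cds_end - 15L)
  sums <- track %>%
    dplyr::inner_join(bounds, by = "transcript_id") %>%
    dplyr::filter(.data$pos >= .data$lo, .data$pos < .data$hi) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  bounds %>%
    dplyr::left_join(sums, by = "transcript_id") %>%
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0),
      rpkm = dplyr::if_else(
        .data$masked | .data$hi <= .data$lo,
        NA_real_,
        .data$n / ((.data$hi - .data$lo) / 1000) / lib_m
      )
    ) %>%
    dplyr::select("transcript_id", "rpkm")
}

#' Footprint size distribution
#'
#' Fraction of reads at each length over the profiled range 15-34 nt.
#'
#' @param reads Tibble with a `length` column.
#' @return Tibble `length`, `n`, `fraction` covering 15-34 nt (zeros kept);
#'   fractions sum to 1.
#' @export
size_distribution <- function(reads) {
  if (nrow(reads) == 0L) stop("no reads")
  sub <- dplyr::filter(reads, .data$length >= 15, .data$length <= 34)
  if (nrow(sub) == 0L) stop("no reads in the 15-34 nt range")
  sub %>%
    dplyr::count(.data$length) %>%
    tidyr::complete(length = 15:34, fill = list(n = 0L)) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Per-gene enrichment ratio between two samples
#'
#' Ratio of gene-level densities (e.g. +DTT / -DTT rpkm). Genes must exceed
#' `min_density` in *both* samples to be reported.
#'
#' @param quant_a,quant_b Tibbles `transcript_id`, `rpkm` (numerator /
#'   denominator).
#' @param min_density Minimum density required in both samples.
#' @return Tibble `transcript_id`, `rpkm_a`, `rpkm_b`, `ratio`.
#' @export
gene_enrichment_ratio <- function(quant_a, quant_b, min_density = 0) {
  dplyr::inner_join(
    dplyr::rename(quant_a, rpkm_a = "rpkm"),
    dplyr::rename(quant_b, rpkm_b = "rpkm"),
    by = "transcript_id"
  ) %>%
    dplyr::filter(!is.na(.data$rpkm_a), !is.na(.data$rpkm_b),
                  .data$rpkm_a > .env$min_density,
                  .data$rpkm_b > .env$min_density) %>%
    dplyr::mutate(ratio = .data$rpkm_a / .data$rpkm_b)
}

#' Export a density track as bedGraph-like TSV
#'
#' @param track A `ridd_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  readr::write_tsv(track, path)
  invisible(path)
}

#' Plot a footprint size distribution
#'
#' @param dist Output of [size_distribution()].
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "footprint length (nt)", y = "fraction of reads") +
    ggplot2::theme_classic()
}
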