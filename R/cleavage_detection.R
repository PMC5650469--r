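#' Thresholds for cleavage-site detection
#'
#' Defaults follow the hard-threshold scheme used for UPR-induced
#' stall-site calling: a position is called when its stress/control density
#' ratio (after mRNA-level correction) exceeds `ratio_min` and its density
#' exceeds `pause_min` times the gene background. Positions with no control
#' reads receive `pseudocount_reads` reads (converted to rpm with that
#' library's size) so a lower bound on the ratio is computable.
#' `viz_min_rpm` flags the visualization-grade subset with density present
#' in both conditions; `strong_pause` and `metagene_pause`/`metagene_min_rpm`
#' select the strong and metagene-grade site tiers.
#'
#' @param ratio_min Minimum mRNA-corrected density ratio (default 10).
#' @param pause_min Minimum pause score (default 2).
#' @param pseudocount_reads Reads assigned to zero-count control positions.
#' @param viz_min_rpm Joint density floor for visualization-grade sites.
#' @param strong_pause Pause score defining "strong" sites (default 100).
#' @param metagene_pause Pause score for metagene anchors (default 200).
#' @param metagene_min_rpm Minimum stress density for metagene anchors.
#' @return A list of class `ridd_params`.
#' @export
detection_params <- function(ratio_min = 10, pause_min = 2,
                             pseudocount_reads = 1, viz_min_rpm = 1.5,
                             strong_pause = 100, metagene_pause = 200,
                             metagene_min_rpm = 10) {
  p <- list(ratio_min = ratio_min, pause_min = pause_min,
            pseudocount_reads = pseudocount_reads, viz_min_rpm = viz_min_rpm,
            strong_pause = strong_pause, metagene_pause = metagene_pause,
            metagene_min_rpm = metagene_min_rpm)
  stopifnot(all(unlist(p) > 0))
  class(p) <- "ridd_params"
  p
}

#' Position-wise stress/control density ratio with mRNA correction
#'
#' For every position covered in either condition, computes the ratio of
#' short-footprint 3'-end density (+ stress / - stress, rpm). Control
#' positions with zero reads are floored at the rpm equivalent of
#' `pseudocount_reads` reads in the control library. The raw ratio is then
#' divided by the gene-level mRNA-Seq ratio (+/-) so that abundance-driven
#' changes cancel and surviving signal is positional; genes whose mRNA
#' ratio is undefined keep a correction factor of 1 (with a warning).
#'
#' @param track_plus,track_minus Unshifted 3'-end `ridd_track`s in rpm
#'   (short class) for the stress (+) and control (-) conditions.
#' @param mrna_plus,mrna_minus Gene-level mRNA-Seq quantitations
#'   (`transcript_id`, `rpkm`).
#' @param params A [detection_params()] list.
#' @return Tibble `transcript_id`, `pos`, `density_plus`, `density_minus`
#'   (pseudocounted), `mrna_factor`, `ratio` (corrected).
#' @export
positionwise_ratio <- function(track_plus, track_minus, mrna_plus, mrna_minus,
                               params = detection_params()) {
  stopifnot(attr(track_plus, "units") == "rpm",
            attr(track_minus, "units") == "rpm")
  pseudo <- params$pseudocount_reads * 1e6 / attr(track_minus, "library_total")

  mr <- dplyr::inner_join(
    dplyr::rename(mrna_plus, mp = "rpkm"),
    dplyr::rename(mrna_minus, mm = "rpkm"),
    by = "transcript_id"
  ) %>%
    dplyr::mutate(mrna_factor = .data$mp / .data$mm)
  bad <- !is.finite(mr$mrna_factor) | mr$mrna_factor <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with undefined mRNA ratio; correction ",
            "factor set to 1")
    mr$mrna_factor[bad] <- 1
  }

  dplyr::full_join(
    dplyr::rename(tibble::as_tibble(track_plus), density_plus = "count"),
    dplyr::rename(tibble::as_tibble(track_minus), density_minus = "count"),
    by = c("transcript_id", "pos")
  ) %>%
    dplyr::mutate(
      density_plus = tidyr::replace_na(.data$density_plus, 0),
      density_minus = pmax(tidyr::replace_na(.data$density_minus, 0),
                           .env$pseudo)
    ) %>%
    dplyr::left_join(mr[, c("transcript_id", "mrna_factor")],
                     by = "transcript_id") %>%
    dplyr::mutate(
      mrna_factor = tidyr::replace_na(.data$mrna_factor, 1),
      ratio = (.data$density_plus / .data$density_minus) / .data$mrna_factor
    ) %>%
    dplyr::arrange(.data$transcript_id, .data$pos)
}

#' Pause scores for covered positions
#'
#' The pause score of a position is its density divided by the mean
#' per-position density of its gene, where the gene background is the mean
#' over all CDS positions excluding the first and last 15 nt (zeros
#' included, mirroring the rpkm exclusion rule). A zero background yields
#' `Inf`. Masked transcripts are skipped.
#'
#' @param track A `ridd_track` (any units; the score is unit-free).
#' @param transcripts A `ridd_transcriptome` tibble.
#' @return Tibble `transcript_id`, `pos`, `pause_score` for positions with
#'   nonzero density in unmasked transcripts.
#' @export
pause_scores <- function(track, transcripts) {
  bounds <- transcripts %>%
    dplyr::filter(!.data$masked) %>%
    dplyr::transmute(.data$transcript_id,
                     lo = .data$cds_start + 15L, hi = .data$cds_end - 15L) %>%
    dplyr::filter(.data$hi > .data$lo)
  bg <- tibble::as_tibble(track) %>%
    dplyr::inner_join(bounds, by = "transcript_id") %>%
    dplyr::filter(.data$pos >= .data$lo, .data$pos < .data$hi) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop") %>%
    dplyr::right_join(bounds, by = "transcript_id") %>%
    dplyr::mutate(background = tidyr::replace_na(.data$total, 0) /
                    (.data$hi - .data$lo))
  tibble::as_tibble(track) %>%
    dplyr::inner_join(bg[, c("transcript_id", "background")],
                      by = "transcript_id") %>%
    dplyr::mutate(pause_score = dplyr::if_else(
      .data$background > 0, .data$count / .data$background, Inf
    )) %>%
    dplyr::select("transcript_id", "pos", "pause_score")
}

#' Detect UPR-induced cleavage/stall sites
#'
#' Calls single-nucleotide cleavage sites from short-footprint 3'-end
#' density: positions within the CDS of unmasked transcripts whose
#' mRNA-corrected stress/control ratio exceeds `params$ratio_min` and whose
#' pause score exceeds `params$pause_min`. Each site is annotated with its
#' UG/C motif class, reading frame, densities, and flags marking the
#' visualization-grade (`viz_pass`: > `viz_min_rpm` in both conditions),
#' strong (`strong`: pause > `strong_pause`) and metagene-grade
#' (`metagene_pass`: pause > `metagene_pause` and density >=
#' `metagene_min_rpm`) tiers.
#'
#' @inheritParams positionwise_ratio
#' @param transcripts A `ridd_transcriptome` tibble.
#' @return Tibble of class `ridd_sites`; one row per called site with
#'   columns `transcript_id`, `pos`, `density_plus`, `density_minus`,
#'   `mrna_factor`, `ratio`, `pause_score`, `motif`, `frame`, `viz_pass`,
#'   `strong`, `metagene_pass`.
#' @export
detect_sites <- function(track_plus, track_minus, mrna_plus, mrna_minus,
                         transcripts, params = detection_params()) {
  rat <- positionwise_ratio(track_plus, track_minus, mrna_plus, mrna_minus,
                            params)
  ps <- pause_scores(track_plus, transcripts)
  cds <- transcripts %>%
    dplyr::filter(!.data$masked) %>%
    dplyr::select("transcript_id", "cds_start", "cds_end")
  sites <- rat %>%
    dplyr::inner_join(ps, by = c("transcript_id", "pos")) %>%
    dplyr::inner_join(cds, by = "transcript_id") %>%
    dplyr::filter(.data$pos >= .data$cds_start, .data$pos < .data$cds_end,
                  .data$ratio > .env$params$ratio_min,
                  .data$pause_score > .env$params$pause_min)
  pseudo <- params$pseudocount_reads * 1e6 / attr(track_minus, "library_total")
  if (nrow(sites) > 0L) {
    sites <- sites %>%
      dplyr::mutate(
        motif = classify_motif(transcripts, .data$transcript_id, .data$pos),
        frame = frame_of(transcripts, .data$transcript_id, .data$pos),
        viz_pass = .data$density_plus > .env$params$viz_min_rpm &
          .data$density_minus > .env$params$viz_min_rpm &
          .data$density_minus > .env$pseudo,
        strong = .data$pause_score > .env$params$strong_pause,
        metagene_pass = .data$pause_score > .env$params$metagene_pause &
          .data$density_plus >= .env$params$metagene_min_rpm
      ) %>%
      dplyr::select(-"cds_start", -"cds_end")
  } else {
    sites <- sites %>%
      dplyr::mutate(motif = factor(character(),
                                   levels = c("UGC", "near_UGC", "other")),
                    frame = integer(), viz_pass = logical(),
                    strong = logical(), metagene_pass = logical()) %>%
      dplyr::select(-"cds_start", -"cds_end")
  }
  attr(sites, "params") <- params
  class(sites) <- unique(c("ridd_sites", class(sites)))
  sites
}

#' Most-downstream cleavage-site analysis
#'
#' Restricts to transcripts carrying at least one UG/C site, marks the
#' maximum-position (most 3') site on each, and reports the fraction of
#' those most-downstream sites that are themselves UG/C -- the signature of
#' a primary endonuclease cut triggering upstream no-go decay.
#'
#' @param sites A `ridd_sites` tibble.
#' @return List with `sites` (input restricted to UG/C-containing
#'   transcripts, plus `is_most_downstream`), `per_transcript` (one row per
#'   transcript with its most-downstream site) and `fraction_ugc`.
#' @export
most_downstream_analysis <- function(sites) {
  if (nrow(sites) == 0L) stop("no sites")
  with_ugc <- sites %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::filter(any(.data$motif == "UGC")) %>%
    dplyr::mutate(is_most_downstream = .data$pos == max(.data$pos)) %>%
    dplyr::ungroup()
  per_tx <- with_ugc %>%
    dplyr::filter(.data$is_most_downstream) %>%
    dplyr::distinct(.data$transcript_id, .keep_all = TRUE)
  list(
    sites = with_ugc,
    per_transcript = per_tx,
    fraction_ugc = mean(per_tx$motif == "UGC")
  )
}

#' Aggregate cleavage sites to transcript-level calls
#'
#' Summarizes called sites per transcript and reports cohort-level
#' fractions: the share of affected transcripts with at least one UG/C
#' site, the share of the remainder carrying only near-UG/C sites, and the
#' ER-associated fraction among UG/C-bearing transcripts (missing when ER
#' flags are unavailable). Also tabulates site counts by motif class.
#'
#' @param sites A `ridd_sites` tibble.
#' @param transcripts A `ridd_transcriptome` tibble (source of ER flags).
#' @return Object of class `ridd_call_summary`: list with `transcripts`
#'   (per-transcript tibble), `motif_counts` and `cohort` (named list of
#'   fractions and counts). `tidy()` returns the per-transcript table,
#'   `glance()` the cohort summary.
#' @export
transcript_aggregation <- function(sites, transcripts) {
  if (nrow(sites) == 0L) {
    out <- list(
      transcripts = tibble::tibble(
        transcript_id = character(), n_sites = integer(),
        has_ugc_site = logical(), has_near_ugc_site = logical(),
        most_downstream_motif = factor(character(),
                                       levels = c("UGC", "near_UGC", "other")),
        er_associated = logical()
      ),
      motif_counts = tibble::tibble(
        motif = factor(c("UGC", "near_UGC", "other"),
                       levels = c("UGC", "near_UGC", "other")),
        n = c(0L, 0L, 0L)
      ),
      cohort = list(n_transcripts = 0L, n_ugc_transcripts = 0L,
                    fraction_ugc_transcripts = NA_real_,
                    fraction_near_ugc_only = NA_real_,
                    fraction_er_among_ugc = NA_real_)
    )
    class(out) <- "ridd_call_summary"
    return(out)
  }
  per_tx <- sites %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(
      n_sites = dplyr::n(),
      has_ugc_site = any(.data$motif == "UGC"),
      has_near_ugc_site = any(.data$motif == "near_UGC"),
      most_downstream_motif = .data$motif[which.max(.data$pos)],
      .groups = "drop"
    ) %>%
    dplyr::left_join(
      transcripts[, c("transcript_id", "er_associated")],
      by = "transcript_id"
    )
  motif_counts <- sites %>%
    dplyr::count(.data$motif, .drop = FALSE)
  ugc <- dplyr::filter(per_tx, .data$has_ugc_site)
  non_ugc <- dplyr::filter(per_tx, !.data$has_ugc_site)
  cohort <- list(
    n_transcripts = nrow(per_tx),
    n_ugc_transcripts = nrow(ugc),
    fraction_ugc_transcripts = nrow(ugc) / nrow(per_tx),
    fraction_near_ugc_only = if (nrow(non_ugc) > 0L) {
      mean(non_ugc$has_near_ugc_site)
    } else NA_real_,
    fraction_er_among_ugc = if (nrow(ugc) > 0L && !all(is.na(ugc$er_associated))) {
      mean(ugc$er_associated, na.rm = TRUE)
    } else NA_real_
  )
  out <- list(transcripts = per_tx, motif_counts = motif_counts,
              cohort = cohort)
  class(out) <- "ridd_call_summary"
  out
}

#' Nucleotide-frequency matrix around cleavage sites
#'
#' Per-offset base frequencies in a window around the 3'-terminal G of each
#' site, the in-pipeline replacement for an external motif search. Sites too
#' close to a transcript edge are excluded (tallied in the `n_excluded`
#' attribute).
#'
#' @param sites A `ridd_sites` tibble (or any tibble with `transcript_id`,
#'   `pos`).
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param flank Number of nucleotides on each side of the site.
#' @param frame Optional frame filter (requires a `frame` column).
#' @return Tibble with `offset` (-flank..flank) and columns `A`, `C`, `G`,
#'   `T` summing to 1 per row; attributes `n_sites`, `n_excluded`.
#' @export
sequence_context_matrix <- function(sites, transcripts, flank = 5L,
                                    frame = NULL) {
  stopifnot(flank >= 1L)
  if (!is.null(frame)) sites <- dplyr::filter(sites, .data$frame == .env$frame)
  i <- match(sites$transcript_id, transcripts$transcript_id)
  len <- transcripts$length[i]
  ok <- sites$pos - flank >= 0L & sites$pos + flank < len
  n_excluded <- sum(!ok)
  if (sum(ok) == 0L) stop("no sites far enough from transcript edges")
  seqs <- stringr::str_sub(transcripts$sequence[i[ok]],
                           sites$pos[ok] - flank + 1L,
                           sites$pos[ok] + flank + 1L)
  mat <- t(vapply(seqs, function(s) strsplit(s, "")[[1]],
                  character(2L * flank + 1L), USE.NAMES = FALSE))
  freq <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    tibble::tibble(offset = j - flank - 1L,
                   A = tab[["A"]], C = tab[["C"]],
                   G = tab[["G"]], T = tab[["T"]])
  }) %>%
    dplyr::mutate(dplyr::across(c("A", "C", "G", "T"),
                                ~ .x / (.data$A + .data$C + .data$G + .data$T)))
  attr(freq, "n_sites") <- sum(ok)
  attr(freq, "n_excluded") <- n_excluded
  freq
}

#' @export
tidy.ridd_call_summary <- function(x, ...) x$transcripts

#' @export
glance.ridd_call_summary <- function(x, ...) {
  tibble::as_tibble(x$cohort)
}

#' @export
glance.ridd_sites <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_ugc = sum(x$motif == "UGC"),
    n_near_ugc = sum(x$motif == "near_UGC"),
    n_other = sum(x$motif == "other"),
    n_strong = sum(x$strong),
    n_metagene = sum(x$metagene_pass),
    n_transcripts = dplyr::n_distinct(x$transcript_id)
  )
}

#' Scatter plot of site densities in the two conditions
#'
#' @param object A `ridd_sites` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ridd_sites <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$density_minus,
                               y = .data$density_plus,
                               colour = .data$motif)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "density, control (rpm)", y = "density, stress (rpm)",
                  colour = "motif") +
    ggplot2::theme_classic()
}
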