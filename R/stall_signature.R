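#' Footprint length by anchor reading frame
#'
#' Tabulates the lengths of reads whose 3' ends coincide with a set of
#' anchor positions (mode `"at_anchor"`, the footprint-size-by-frame
#' diagnostic) or fall within a fixed window immediately upstream of them
#' (mode `"window"`). Because the ribosome advances in 3-nt steps and its 5'
#' boundary is trimmed flush, stall-read length tracks the frame of the
#' terminal base (16/17/18 nt for frames 0/1/2, with a minority 15-nt
#' population at frame 2 from ribosomes that translocate once more).
#'
#' @param reads Tibble with `transcript_id`, `start`, `length`.
#' @param anchors Tibble with `transcript_id`, `pos` and a `frame` column.
#' @param mode `"at_anchor"` (3' end exactly at the anchor) or `"window"`
#'   (3' end within `window` nt upstream of and including the anchor).
#' @param window Window length for mode `"window"` (nt).
#' @return Tibble `length`, `frame`, `n` (complete grid over observed
#'   lengths 15-34 and frames 0-2).
#' @export
size_by_frame_histogram <- function(reads, anchors, mode = c("at_anchor",
                                                             "window"),
                                    window = 24L) {
  mode <- match.arg(mode)
  reads <- dplyr::mutate(reads, end3 = .data$start + .data$length - 1L)
  joined <- dplyr::inner_join(
    reads, anchors[, c("transcript_id", "pos", "frame")],
    by = "transcript_id", relationship = "many-to-many"
  )
  hits <- if (mode == "at_anchor") {
    dplyr::filter(joined, .data$end3 == .data$pos)
  } else {
    dplyr::filter(joined, .data$end3 <= .data$pos,
                  .data$end3 > .data$pos - .env$window)
  }
  hits %>%
    dplyr::count(.data$length, .data$frame) %>%
    tidyr::complete(length = 15:34, frame = 0:2, fill = list(n = 0L))
}

#' Observed versus background frame usage of cleavage sites
#'
#' Compares the reading-frame distribution of called sites of a motif class
#' against the frame distribution of all occurrences of that motif class in
#' the (unmasked) transcriptome CDS -- the background an unbiased
#' endonuclease would sample.
#'
#' @param sites A `ridd_sites` tibble (typically pre-filtered to strong
#'   sites).
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param motif_class Motif class to compare (default `"UGC"`).
#' @return Tibble `frame`, `observed`, `background` (fractions summing
#'   to 1 in each column).
#' @export
frame_bias <- function(sites, transcripts, motif_class = "UGC") {
  obs <- sites %>%
    dplyr::filter(.data$motif == .env$motif_class) %>%
    dplyr::count(.data$frame) %>%
    tidyr::complete(frame = 0:2, fill = list(n = 0L)) %>%
    dplyr::mutate(observed = .data$n / sum(.data$n)) %>%
    dplyr::select("frame", "observed")
  bg <- motif_positions(transcripts, motif_class) %>%
    dplyr::count(.data$frame) %>%
    tidyr::complete(frame = 0:2, fill = list(n = 0L)) %>%
    dplyr::mutate(background = .data$n / sum(.data$n)) %>%
    dplyr::select("frame", "background")
  dplyr::left_join(obs, bg, by = "frame")
}

# all CDS positions (G of the trinucleotide) of a motif class, with frames
motif_positions <- function(transcripts, motif_class = "UGC") {
  purrr::map_dfr(
    which(!transcripts$masked),
    function(i) {
      tx <- transcripts[i, ]
      lo <- max(tx$cds_start, 1L)
      hi <- min(tx$cds_end, tx$length - 2L) - 1L
      if (hi < lo) return(NULL)
      pos <- lo:hi
      tri <- stringr::str_sub(tx$sequence, pos, pos + 2L)
      cls <- classify_trinucleotide(tri)
      g <- pos[cls == motif_class]
      if (length(g) == 0L) return(NULL)
      tibble::tibble(transcript_id = tx$transcript_id, pos = g,
                     frame = as.integer((g - tx$cds_start) %% 3L))
    }
  )
}

#' Equal-weight metagene average around anchor positions
#'
#' Averages track density in a fixed window around each anchor, giving every
#' anchor equal weight (no per-anchor renormalization). Anchors whose window
#' extends beyond either transcript end are excluded and tallied.
#'
#' @param track A `ridd_track` (use rpm for comparability across libraries).
#' @param anchors Tibble with `transcript_id`, `pos`.
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param window Integer length-2 vector: smallest and largest offset
#'   (anchor = 0), default `c(-200, 50)`.
#' @return Tibble of class `ridd_metagene` with `offset`, `mean_density`;
#'   attributes `n_anchors`, `n_excluded`, `size_class`.
#' @export
metagene_average <- function(track, anchors, transcripts,
                             window = c(-200L, 50L)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  len <- setNames(transcripts$length, transcripts$transcript_id)
  anchors <- dplyr::mutate(anchors, .len = len[.data$transcript_id])
  ok <- anchors$pos + window[1] >= 0L & anchors$pos + window[2] < anchors$.len
  n_excluded <- sum(!ok)
  use <- anchors[ok, , drop = FALSE]
  if (nrow(use) == 0L) stop("no usable anchors (all windows out of bounds)")
  offsets <- seq.int(window[1], window[2])
  grid <- tidyr::crossing(
    dplyr::mutate(use[, c("transcript_id", "pos")],
                  .anchor = dplyr::row_number()),
    offset = offsets
  ) %>%
    dplyr::mutate(pos = .data$pos + .data$offset)
  prof <- grid %>%
    dplyr::left_join(tibble::as_tibble(track),
                     by = c("transcript_id", "pos")) %>%
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0)) %>%
    dplyr::group_by(.data$offset) %>%
    dplyr::summarise(mean_density = sum(.data$count) / nrow(use),
                     .groups = "drop")
  attr(prof, "n_anchors") <- nrow(use)
  attr(prof, "n_excluded") <- n_excluded
  attr(prof, "size_class") <- attr(track, "size_class")
  class(prof) <- unique(c("ridd_metagene", class(prof)))
  prof
}

#' Autocorrelation of the upstream segment of a metagene profile
#'
#' Extracts the profile over `offsets`, subtracts its mean, and computes the
#' unbiased sample autocorrelation for lags 0 to n-1.
#'
#' @param profile A `ridd_metagene` tibble.
#' @param offsets Offsets to analyze (default -200..-1, the region upstream
#'   of the anchor).
#' @return Tibble of class `ridd_acf` with `lag`, `acf`.
#' @export
profile_autocorrelation <- function(profile, offsets = -200:-1) {
  seg <- profile$mean_density[match(offsets, profile$offset)]
  if (anyNA(seg)) stop("profile does not cover the requested offsets")
  x <- seg - mean(seg)
  if (all(x == 0)) stop("constant profile: autocorrelation undefined")
  n <- length(x)
  ac <- vapply(0:(n - 1L), function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / (n - k)
  }, numeric(1))
  out <- tibble::tibble(lag = 0:(n - 1L), acf = ac)
  class(out) <- unique(c("ridd_acf", class(out)))
  out
}

#' Power spectrum of a lag series with peak-period extraction
#'
#' Blackman-Tukey correlogram: the cosine transform of the even-extended
#' lag series, zero-padded (default 1024 points) for period resolution.
#' The dominant period is the highest local maximum with period inside
#' `period_range`; the secondary period is the next-ranked local maximum
#' after excluding periods within 20% of the dominant one (the dominant
#' peak and its immediate shoulder). Peak periods are refined by parabolic
#' interpolation across the apex bin and reported both raw and rounded to
#' the nearest integer nucleotide.
#'
#' @param lag_series A `ridd_acf` tibble (or any tibble with `lag`, `acf`).
#' @param pad FFT length after zero padding.
#' @param period_range Periods (nt) searched for peaks.
#' @return Tibble of class `ridd_periodogram` with `period`, `power`;
#'   attributes `dominant_period`, `secondary_period` (integer nt),
#'   `dominant_period_raw`, `secondary_period_raw`, `dominant_power`,
#'   `secondary_power`.
#' @export
power_spectrum <- function(lag_series, pad = 1024L,
                           period_range = c(3, 100)) {
  ac <- lag_series$acf
  n <- length(ac)
  stopifnot(n >= 64L, pad >= 2L * n)
  even <- c(ac, numeric(pad - 2L * n + 1L), rev(ac[-1L]))
  S <- Re(fft(even))[seq_len(pad / 2L)]
  idx <- 2:(pad / 2L)              # skip the zero-frequency bin
  period <- pad / (idx - 1L)
  pw <- abs(S[idx])                # magnitude spectrum (S is real)

  lm <- which(diff(sign(diff(pw))) == -2L) + 1L
  lm <- lm[period[lm] >= period_range[1] & period[lm] <= period_range[2]]
  lm <- lm[order(pw[lm], decreasing = TRUE)]
  interp <- function(i) {
    if (i <= 1L || i >= length(pw)) return(period[i])
    y <- pw[(i - 1L):(i + 1L)]
    den <- y[1] - 2 * y[2] + y[3]
    d <- if (den == 0) 0 else 0.5 * (y[1] - y[3]) / den
    pad / (idx[i] - 1L + d)
  }
  dom_raw <- sec_raw <- NA_real_
  dom_pw <- sec_pw <- NA_real_
  if (length(lm) >= 1L) {
    dom_raw <- interp(lm[1])
    dom_pw <- pw[lm[1]]
    rest <- lm[abs(period[lm] - period[lm[1]]) > 0.2 * period[lm[1]]]
    if (length(rest) >= 1L) {
      sec_raw <- interp(rest[1])
      sec_pw <- pw[rest[1]]
    }
  }
  out <- tibble::tibble(period = period, power = pw)
  attr(out, "dominant_period") <- as.integer(round(dom_raw))
  attr(out, "secondary_period") <- as.integer(round(sec_raw))
  attr(out, "dominant_period_raw") <- dom_raw
  attr(out, "secondary_period_raw") <- sec_raw
  attr(out, "dominant_power") <- dom_pw
  attr(out, "secondary_power") <- sec_pw
  class(out) <- unique(c("ridd_periodogram", class(out)))
  out
}

#' @export
glance.ridd_periodogram <- function(x, ...) {
  tibble::tibble(
    dominant_period = attr(x, "dominant_period"),
    secondary_period = attr(x, "secondary_period"),
    dominant_period_raw = attr(x, "dominant_period_raw"),
    secondary_period_raw = attr(x, "secondary_period_raw"),
    dominant_power = attr(x, "dominant_power"),
    secondary_power = attr(x, "secondary_power")
  )
}

#' Power at (or near) a given period
#'
#' Maximum spectral power within +/- `halfwidth` nt of `period`, a helper
#' for directional comparisons (e.g. disomes on versus off).
#'
#' @param spec A `ridd_periodogram`.
#' @param period Target period (nt).
#' @param halfwidth Search half-width (nt).
#' @return Numeric scalar.
#' @export
power_at_period <- function(spec, period, halfwidth = 1) {
  sel <- abs(spec$period - period) <= halfwidth
  if (!any(sel)) return(NA_real_)
  max(spec$power[sel])
}

#' Disome localization offset
#'
#' Position of the long-footprint 3'-end metagene maximum upstream of the
#' anchors, reported as nucleotides upstream. A collided (trailing)
#' ribosome's footprint ends ~16 nt upstream of the lead ribosome's stall
#' site. Returns `NA` when the window is flat.
#'
#' @param long_track Unshifted 3'-end `ridd_track` of the long (25-34 nt)
#'   class.
#' @param anchors Tibble with `transcript_id`, `pos`.
#' @param transcripts A `ridd_transcriptome` tibble.
#' @param window Offsets searched (default -40..-1).
#' @return Integer nt upstream (positive), or `NA`.
#' @export
disome_offset <- function(long_track, anchors, transcripts,
                          window = c(-40L, -1L)) {
  prof <- metagene_average(long_track, anchors, transcripts, window = window)
  if (diff(range(prof$mean_density)) == 0) return(NA_integer_)
  as.integer(-prof$offset[which.max(prof$mean_density)])
}

#' @export
autoplot.ridd_metagene <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                       y = .data$mean_density)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "orange") +
    ggplot2::labs(x = "offset from anchor (nt)", y = "mean density") +
    ggplot2::theme_classic()
}

#' @export
autoplot.ridd_periodogram <- function(object, ...) {
  sub <- dplyr::filter(object, .data$period <= 100)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$period, y = .data$power)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(x = "period (nt)", y = "power") +
    ggplot2::theme_classic()
}
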