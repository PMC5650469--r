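#' Score a chemical-genomic colony-size fitness screen
#'
#' Per strain, computes the mean (over replicates, on the log scale) of
#' `log2(size_treated / size_untreated)`, standardizes across strains
#' (z-score), and calls hits at `|z| > z_cut`: `resistant` above the cutoff
#' (grows relatively better under the drug), `sensitive` below. Zero colony
#' sizes are floored at half the smallest nonzero size observed in the same
#' condition so borderline strains stay scoreable; completely inviable
#' strains should be excluded upstream.
#'
#' @param records Tibble with `strain_id`, `replicate`, `size_untreated`,
#'   `size_treated`.
#' @param z_cut Z-score cutoff (default 2).
#' @return Tibble of class `ridd_screen` with `strain_id`, `log_ratio`,
#'   `z_score`, `call` (factor `resistant`/`sensitive`/`none`).
#' @export
score_screen <- function(records, z_cut = 2) {
  stopifnot(all(c("strain_id", "replicate", "size_untreated",
                  "size_treated") %in% names(records)))
  if (dplyr::n_distinct(records$strain_id) < 3L) {
    stop("need at least 3 strains")
  }
  if (any(records$size_untreated < 0 | records$size_treated < 0)) {
    stop("colony sizes must be non-negative")
  }
  floor_u <- min(records$size_untreated[records$size_untreated > 0]) / 2
  floor_t <- min(records$size_treated[records$size_treated > 0]) / 2
  per_strain <- records %>%
    dplyr::mutate(
      su = pmax(.data$size_untreated, .env$floor_u),
      st = pmax(.data$size_treated, .env$floor_t)
    ) %>%
    dplyr::group_by(.data$strain_id) %>%
    dplyr::summarise(log_ratio = mean(log2(.data$st / .data$su)),
                     .groups = "drop")
  s <- sd(per_strain$log_ratio)
  if (!is.finite(s) || s == 0) stop("degenerate screen: zero variance")
  out <- per_strain %>%
    dplyr::mutate(
      z_score = (.data$log_ratio - mean(.data$log_ratio)) / .env$s,
      call = factor(
        dplyr::case_when(
          .data$z_score > .env$z_cut ~ "resistant",
          .data$z_score < -.env$z_cut ~ "sensitive",
          TRUE ~ "none"
        ),
        levels = c("resistant", "sensitive", "none")
      )
    )
  attr(out, "z_cut") <- z_cut
  class(out) <- unique(c("ridd_screen", class(out)))
  out
}

#' @export
glance.ridd_screen <- function(x, ...) {
  tibble::tibble(
    n_strains = nrow(x),
    n_resistant = sum(x$call == "resistant"),
    n_sensitive = sum(x$call == "sensitive"),
    hit_fraction = mean(x$call != "none"),
    z_cut = attr(x, "z_cut")
  )
}

#' Rank plot of screen z-scores with hit cutoffs
#'
#' @param object A `ridd_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ridd_screen <- function(object, ...) {
  z_cut <- attr(object, "z_cut")
  df <- dplyr::arrange(object, .data$log_ratio) %>%
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z_score,
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(yintercept = z_cut, colour = "blue",
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -z_cut, colour = "red",
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(resistant = "blue",
                                            sensitive = "red",
                                            none = "grey60")) +
    ggplot2::labs(x = "strain rank", y = "z-score") +
    ggplot2::theme_classic()
}
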