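#' Simulation parameters for the stall/no-go-decay read simulator
#'
#' The generative model follows the endonucleolytic-cleavage mechanism: an
#' activated endonuclease cut at a planted UG/C site stalls a ribosome at
#' the new truncated 3' end; the stalled ribosome templates iterative
#' upstream no-go cleavage on a rigid 14-nt ribosome-ruler lattice, with
#' disome (stacked-ribosome) rounds protecting every other rung and
#' emitting long trailing-ribosome footprints ~16 nt upstream of the lead.
#' Disome formation is persistent (Markov): a stack formed at one rung
#' tends to re-form at the next, which keeps the 28-nt register of the
#' alternating intensity phase-locked to the primary site. Cleavage
#' positions scatter by 1-2 nt around the lattice (the endonuclease cuts
#' within the mRNA channel), decomposed into a per-site ladder registration
#' offset and an independent per-rung scatter.
#'
#' Stall-read length follows the frame of the terminal base (16 + frame);
#' frame-2 stalls translocate once more with probability `p_translocate`,
#' shortening the footprint to 15 nt. Genotype effects are scalar
#' multipliers on stall-derived read depth: loss of ribosome rescue
#' (`dom34`) and of 3'->5' decay (`ski2`) each stabilize the stall
#' signature, maximally in the double knockout.
#'
#' @param seed Integer seed; all outputs are deterministic given it.
#' @param n_transcripts Number of transcripts.
#' @param cds_length_range CDS length range (nt; rounded to multiples of 3).
#' @param utr_length 5' and 3' UTR length (nt).
#' @param n_planted_ugc Planted UG/C sites per transcript.
#' @param site_frames Frames (0/1/2) cycled over planted sites.
#' @param p_cleave Activation probability per planted site under stress.
#' @param basal_p_cleave Leak activation probability without stress.
#' @param stall_depth Mean stall reads per no-go rung in the WT background.
#' @param anchor_boost Depth multiplier at the primary (anchor) stall.
#' @param p_translocate Probability a frame-2 stall yields a 15-mer.
#' @param ngd_step No-go cleavage spacing (nt; the ribosome-ruler lattice).
#' @param p_disome Disome probability at the first round.
#' @param p_disome_persist Disome probability after a disome round.
#' @param p_disome_after_mono Disome probability after a monosome round.
#' @param p_continue Per-round chain continuation probability.
#' @param site_offset_values,site_offset_probs Per-site ladder registration
#'   offset distribution (nt).
#' @param scatter_values,scatter_probs Per-rung cleavage scatter (nt).
#' @param disome_end_values,disome_end_probs Trailing-ribosome 3'-end
#'   trimming scatter (nt).
#' @param long_lengths,long_length_probs Long-footprint length model
#'   (25-34 nt, peaked at 28-31).
#' @param background_rate Long-footprint background (reads per nt).
#' @param short_background_rate Short-footprint background (reads per nt).
#' @param mrna_read_rate mRNA-Seq reads per nt of transcript.
#' @param mrna_read_length mRNA-Seq read length (nt).
#' @param mrna_decay_factor mRNA abundance multiplier for cleaved
#'   transcripts under stress.
#' @param dom34_mult,ski2_mult Genotype depth multipliers.
#' @param er_prob_target,er_prob_other Probability a transcript with /
#'   without a planted site is flagged ER-associated.
#' @return A list of class `ridd_sim_params`.
#' @export
sim_params <- function(seed = 42L,
                       n_transcripts = 60L,
                       cds_length_range = c(1200L, 1800L),
                       utr_length = 30L,
                       n_planted_ugc = 1L,
                       site_frames = 0:2,
                       p_cleave = 0.9,
                       basal_p_cleave = 0.02,
                       stall_depth = 2,
                       anchor_boost = 5,
                       p_translocate = 1 / 3,
                       ngd_step = 14L,
                       p_disome = 0.85,
                       p_disome_persist = 0.9,
                       p_disome_after_mono = 0.5,
                       p_continue = 0.9,
                       site_offset_values = -3:3,
                       site_offset_probs = c(1, 2, 3, 4, 3, 2, 1) / 16,
                       scatter_values = -2:2,
                       scatter_probs = c(1, 2, 3, 2, 1) / 9,
                       disome_end_values = -1:1,
                       disome_end_probs = c(0.2, 0.6, 0.2),
                       long_lengths = 25:34,
                       long_length_probs = c(1, 2, 4, 8, 20, 26, 16, 11, 7,
                                             5) / 100,
                       background_rate = 0.2,
                       short_background_rate = 0.02,
                       mrna_read_rate = 0.3,
                       mrna_read_length = 50L,
                       mrna_decay_factor = 0.4,
                       dom34_mult = 6,
                       ski2_mult = 3,
                       er_prob_target = 0.9,
                       er_prob_other = 0.1) {
  p <- as.list(environment())
  probs <- c(p$p_cleave, p$basal_p_cleave, p$p_translocate, p$p_disome,
             p$p_disome_persist, p$p_disome_after_mono, p$p_continue)
  stopifnot(all(probs >= 0 & probs <= 1), p$ngd_step >= 1L,
            abs(sum(p$site_offset_probs) - 1) < 1e-9,
            abs(sum(p$scatter_probs) - 1) < 1e-9,
            abs(sum(p$long_length_probs) - 1) < 1e-9)
  class(p) <- "ridd_sim_params"
  p
}

sample1 <- function(values, probs) {
  values[sample.int(length(values), 1L, prob = probs)]
}

#' Generate a synthetic transcriptome with planted UG/C sites
#'
#' Random-sequence transcripts with UTRs and an in-frame CDS; each carries
#' `n_planted_ugc` planted `TGC` trinucleotides at recorded positions and
#' frames (frames cycle through `site_frames` across sites). Planted sites
#' keep at least 200 + `ngd_step` nt of CDS upstream and 60 nt downstream so
#' metagene windows and cleavage ladders fit. ER-association flags are
#' drawn with higher probability for transcripts carrying planted sites.
#'
#' @param params A [sim_params()] list.
#' @return List with `transcripts` (a `ridd_transcriptome`) and
#'   `truth_sites` (tibble `transcript_id`, `pos`, `frame`).
#' @export
generate_transcriptome <- function(params = sim_params()) {
  set.seed(params$seed)
  n <- params$n_transcripts
  up_margin <- 200L + 4L * params$ngd_step
  down_margin <- 60L
  rows <- vector("list", n)
  truth <- vector("list", n)
  frame_cycle <- rep_len(params$site_frames, n * params$n_planted_ugc)
  k <- 0L
  for (i in seq_len(n)) {
    cds_len <- sample(seq(params$cds_length_range[1],
                          params$cds_length_range[2], by = 3L), 1L)
    len <- cds_len + 2L * params$utr_length
    cds_start <- params$utr_length
    cds_end <- cds_start + cds_len
    if (cds_len < up_margin + down_margin + 6L) {
      stop("CDS too short for the requested planted-site margins")
    }
    seq_chr <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
    sites <- integer(params$n_planted_ugc)
    for (j in seq_len(params$n_planted_ugc)) {
      k <- k + 1L
      f <- frame_cycle[k]
      lo <- cds_start + up_margin
      hi <- cds_end - down_margin
      cand <- seq.int(lo, hi)
      cand <- cand[(cand - cds_start) %% 3L == f]
      pos <- sample(cand, 1L)
      stringr::str_sub(seq_chr, pos, pos + 2L) <- "TGC"
      sites[j] <- pos
    }
    tid <- sprintf("synthTx%03d", i)
    rows[[i]] <- tibble::tibble(
      transcript_id = tid, sequence = seq_chr, length = len,
      cds_start = cds_start, cds_end = cds_end,
      er_associated = NA, masked = FALSE
    )
    truth[[i]] <- tibble::tibble(
      transcript_id = tid, pos = sites,
      frame = frame_cycle[(k - params$n_planted_ugc + 1L):k]
    )
  }
  transcripts <- dplyr::bind_rows(rows)
  truth_sites <- dplyr::bind_rows(truth)
  has_site <- transcripts$transcript_id %in% truth_sites$transcript_id
  transcripts$er_associated <- ifelse(
    runif(nrow(transcripts)) <
      ifelse(has_site, params$er_prob_target, params$er_prob_other),
    TRUE, FALSE
  )
  class(transcripts) <- c("ridd_transcriptome", class(transcripts))
  list(transcripts = transcripts, truth_sites = truth_sites)
}

#' Simulate aligned footprint and mRNA-Seq reads for one library
#'
#' Implements the generative mechanism described in [sim_params()] for a
#' given genotype and condition. Every planted site activates independently
#' (`p_cleave` with stress, `basal_p_cleave` without); an activated site
#' emits anchor stall reads, then iterates no-go rounds along the 14-nt
#' lattice until chain termination or the CDS start, emitting short stall
#' reads per rung and long disome reads on disome rounds. Poisson
#' backgrounds of long and short footprints cover every CDS, and mRNA-Seq
#' reads are drawn uniformly with abundance reduced on cleaved transcripts
#' under stress.
#'
#' @param txome Output of [generate_transcriptome()].
#' @param params A [sim_params()] list.
#' @param genotype One of `"WT"`, `"dom34"`, `"ski2"`, `"dom34_ski2"`.
#' @param condition `"plusDTT"` or `"minusDTT"`.
#' @return List of class `ridd_sim` with `footprints` and `mrna` read
#'   tibbles (`transcript_id`, `start`, `length`, `n_alignments`), and
#'   `truth` (list: `sites` with `activated`, `rounds` with per-round rung
#'   geometry, `abundance`), plus `genotype` and `condition`.
#' @export
simulate_reads <- function(txome, params = sim_params(),
                           genotype = c("dom34_ski2", "WT", "dom34", "ski2"),
                           condition = c("plusDTT", "minusDTT")) {
  genotype <- match.arg(genotype)
  condition <- match.arg(condition)
  gi <- match(genotype, c("WT", "dom34", "ski2", "dom34_ski2"))
  ci <- match(condition, c("plusDTT", "minusDTT"))
  set.seed((params$seed + 7919L * gi + 104729L * ci) %% .Machine$integer.max)

  transcripts <- txome$transcripts
  truth_sites <- txome$truth_sites
  mult <- (if (genotype %in% c("dom34", "dom34_ski2")) params$dom34_mult else 1) *
    (if (genotype %in% c("ski2", "dom34_ski2")) params$ski2_mult else 1)
  p_act <- if (condition == "plusDTT") params$p_cleave else params$basal_p_cleave
  lam <- params$stall_depth * mult

  tx_ix <- match(truth_sites$transcript_id, transcripts$transcript_id)
  fp <- list()
  rounds <- list()
  activated <- logical(nrow(truth_sites))

  emit_stall <- function(tid, end3, cds_start, n) {
    if (n <= 0L) return(NULL)
    f <- (end3 - cds_start) %% 3L
    lens <- rep(16L + f, n)
    if (f == 2L) {
      lens[runif(n) < params$p_translocate] <- 15L
    }
    tibble::tibble(transcript_id = tid, start = end3 - lens + 1L,
                   length = lens)
  }

  for (s in seq_len(nrow(truth_sites))) {
    if (runif(1) >= p_act) next
    activated[s] <- TRUE
    tx <- transcripts[tx_ix[s], ]
    P <- truth_sites$pos[s]
    tid <- tx$transcript_id

    fp[[length(fp) + 1L]] <-
      emit_stall(tid, P, tx$cds_start, rpois(1L, lam * params$anchor_boost))

    eta <- sample1(params$site_offset_values, params$site_offset_probs)
    m <- 0L
    dis_prev <- NA
    r <- 0L
    repeat {
      if (runif(1) > params$p_continue) break
      pd <- if (is.na(dis_prev)) params$p_disome
            else if (dis_prev) params$p_disome_persist
            else params$p_disome_after_mono
      dis <- runif(1) < pd
      lead_end <- if (m == 0L) P else NA_integer_
      if (dis) {
        # trailing ribosome of the disome: long footprint ending ~16 nt
        # upstream of the lead ribosome's 3' end
        lead_x <- if (m == 0L) {
          P
        } else {
          P - params$ngd_step * m + eta
        }
        lf <- (lead_x - tx$cds_start) %% 3L
        nlong <- rpois(1L, lam)
        if (nlong > 0L && lead_x >= tx$cds_start) {
          e3 <- lead_x - (16L + lf) +
            vapply(seq_len(nlong), function(.)
              sample1(params$disome_end_values, params$disome_end_probs),
              integer(1))
          ll <- sample(params$long_lengths, nlong, replace = TRUE,
                       prob = params$long_length_probs)
          keep <- e3 - ll + 1L >= 0L
          if (any(keep)) {
            fp[[length(fp) + 1L]] <- tibble::tibble(
              transcript_id = tid, start = (e3 - ll + 1L)[keep],
              length = ll[keep]
            )
          }
        }
      }
      m_next <- m + (if (dis) 2L else 1L)
      rung_pos <- P - params$ngd_step * m_next
      r <- r + 1L
      if (rung_pos < tx$cds_start) {
        rounds[[length(rounds) + 1L]] <- tibble::tibble(
          transcript_id = tid, site_pos = P, round = r, rung = m_next,
          rung_pos = rung_pos, disome = dis, terminated = TRUE,
          read_pos = NA_integer_
        )
        break
      }
      x <- rung_pos + eta +
        sample1(params$scatter_values, params$scatter_probs)
      x_ok <- x >= tx$cds_start && x >= 17L
      if (x_ok) {
        fp[[length(fp) + 1L]] <-
          emit_stall(tid, x, tx$cds_start, rpois(1L, lam))
      }
      rounds[[length(rounds) + 1L]] <- tibble::tibble(
        transcript_id = tid, site_pos = P, round = r, rung = m_next,
        rung_pos = rung_pos, disome = dis, terminated = FALSE,
        read_pos = if (x_ok) x else NA_integer_
      )
      dis_prev <- dis
      m <- m_next
    }
  }

  # Poisson footprint backgrounds along each CDS
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    span <- tx$cds_end - tx$cds_start
    nl <- rpois(1L, params$background_rate * span)
    if (nl > 0L) {
      e3 <- sample(seq.int(tx$cds_start, tx$cds_end - 1L), nl, replace = TRUE)
      ll <- sample(params$long_lengths, nl, replace = TRUE,
                   prob = params$long_length_probs)
      keep <- e3 - ll + 1L >= 0L
      fp[[length(fp) + 1L]] <- tibble::tibble(
        transcript_id = tx$transcript_id, start = (e3 - ll + 1L)[keep],
        length = ll[keep]
      )
    }
    ns <- rpois(1L, params$short_background_rate * span)
    if (ns > 0L) {
      e3 <- sample(seq.int(tx$cds_start, tx$cds_end - 1L), ns, replace = TRUE)
      sl <- sample(15:18, ns, replace = TRUE)
      keep <- e3 - sl + 1L >= 0L
      fp[[length(fp) + 1L]] <- tibble::tibble(
        transcript_id = tx$transcript_id, start = (e3 - sl + 1L)[keep],
        length = sl[keep]
      )
    }
  }

  footprints <- dplyr::bind_rows(fp)
  footprints$n_alignments <- 1L

  # mRNA-Seq with condition-dependent abundance on cleaved transcripts
  cleaved <- truth_sites$transcript_id[activated]
  ab <- tibble::tibble(
    transcript_id = transcripts$transcript_id,
    factor = ifelse(condition == "plusDTT" &
                      transcripts$transcript_id %in% cleaved,
                    params$mrna_decay_factor, 1)
  )
  mr <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    nmr <- rpois(1L, params$mrna_read_rate * tx$length * ab$factor[i])
    if (nmr > 0L) {
      st <- sample(seq.int(0L, tx$length - params$mrna_read_length), nmr,
                   replace = TRUE)
      mr[[length(mr) + 1L]] <- tibble::tibble(
        transcript_id = tx$transcript_id, start = st,
        length = params$mrna_read_length
      )
    }
  }
  mrna <- dplyr::bind_rows(mr)
  mrna$n_alignments <- 1L

  truth <- list(
    sites = dplyr::mutate(truth_sites, activated = activated),
    rounds = if (length(rounds) > 0L) dplyr::bind_rows(rounds) else
      tibble::tibble(transcript_id = character(), site_pos = integer(),
                     round = integer(), rung = integer(),
                     rung_pos = integer(), disome = logical(),
                     terminated = logical(), read_pos = integer()),
    abundance = ab
  )
  out <- list(footprints = footprints, mrna = mrna, truth = truth,
              genotype = genotype, condition = condition)
  class(out) <- "ridd_sim"
  out
}

#' Simulate a paired stress/control experiment
#'
#' Convenience wrapper: one transcriptome, one genotype, reads for both
#' conditions.
#'
#' @inheritParams simulate_reads
#' @return List with `transcripts`, `truth_sites`, `plus` and `minus`
#'   (each a `ridd_sim`).
#' @export
simulate_experiment <- function(params = sim_params(),
                                genotype = "dom34_ski2") {
  txome <- generate_transcriptome(params)
  list(
    transcripts = txome$transcripts,
    truth_sites = txome$truth_sites,
    plus = simulate_reads(txome, params, genotype, "plusDTT"),
    minus = simulate_reads(txome, params, genotype, "minusDTT")
  )
}

#' Write simulator outputs to disk
#'
#' Writes the footprint and mRNA read tables as TSV, the footprints
#' additionally as SAM (one reference per transcript), the truth tables as
#' TSV, and the parameters as JSON (seed included).
#'
#' @param sim A `ridd_sim` object.
#' @param transcripts The matching `ridd_transcriptome`.
#' @param params The [sim_params()] used.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim_outputs <- function(sim, transcripts, params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    footprints_tsv = file.path(dir, "footprints.tsv"),
    footprints_sam = file.path(dir, "footprints.sam"),
    mrna_tsv = file.path(dir, "mrna.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_rounds = file.path(dir, "truth_rounds.tsv"),
    params_json = file.path(dir, "params.json")
  )
  readr::write_tsv(sim$footprints, paths[["footprints_tsv"]])
  write_sam(sim$footprints, transcripts, paths[["footprints_sam"]])
  readr::write_tsv(sim$mrna, paths[["mrna_tsv"]])
  readr::write_tsv(sim$truth$sites, paths[["truth_sites"]])
  readr::write_tsv(sim$truth$rounds, paths[["truth_rounds"]])
  p <- unclass(params)
  jsonlite::write_json(p, paths[["params_json"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

# minimal SAM writer for transcript-space alignments
write_sam <- function(reads, transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", transcripts$transcript_id,
                     transcripts$length), con)
  if (nrow(reads) > 0L) {
    seqs <- setNames(transcripts$sequence, transcripts$transcript_id)
    seq_str <- stringr::str_sub(seqs[reads$transcript_id],
                                reads$start + 1L,
                                reads$start + reads$length)
    writeLines(sprintf("r%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                       seq_len(nrow(reads)), reads$transcript_id,
                       reads$start + 1L, reads$length, seq_str,
                       reads$n_alignments), con)
  }
  invisible(path)
}
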