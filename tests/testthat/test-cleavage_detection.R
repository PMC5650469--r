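library(dplyr)

test_that("pseudocounting reproduces the one-read lower-bound ratio", {
  # 2.44 rpm against zero control reads in a 4,098,361-read library:
  # the control floor is one read = 0.244 rpm, so the ratio is 10
  plus <- make_track(tibble::tibble(transcript_id = "t1", pos = 50L,
                                    count = 2.44))
  minus <- make_track(tibble::tibble(transcript_id = "t1",
                                     pos = integer(0), count = numeric(0)),
                      library_total = 4098361)
  mq <- tibble::tibble(transcript_id = "t1", rpkm = 5)
  r <- positionwise_ratio(plus, minus, mq, mq)
  expect_equal(r$ratio, 10, tolerance = 1e-4)
  expect_equal(r$density_minus, 0.244, tolerance = 1e-4)
})

test_that("identical tracks give unit ratios", {
  tr <- make_track(tibble::tibble(transcript_id = "t1", pos = c(10L, 20L),
                                  count = c(1, 3)))
  mq <- tibble::tibble(transcript_id = "t1", rpkm = 2)
  r <- positionwise_ratio(tr, tr, mq, mq)
  expect_equal(r$ratio, c(1, 1))
})

test_that("mRNA correction divides out gene-level abundance changes", {
  plus <- make_track(tibble::tibble(transcript_id = "t1", pos = 30L,
                                    count = 20))
  minus <- make_track(tibble::tibble(transcript_id = "t1", pos = 30L,
                                     count = 1))
  mp <- tibble::tibble(transcript_id = "t1", rpkm = 1)
  mm <- tibble::tibble(transcript_id = "t1", rpkm = 2)  # mRNA halved (+/- = 0.5)
  r <- positionwise_ratio(plus, minus, mp, mm)
  expect_equal(r$ratio, 40)
})

test_that("an undefined mRNA ratio falls back to factor 1 with a warning", {
  plus <- make_track(tibble::tibble(transcript_id = "t1", pos = 30L,
                                    count = 6))
  minus <- make_track(tibble::tibble(transcript_id = "t1", pos = 30L,
                                     count = 2))
  mp <- tibble::tibble(transcript_id = "t1", rpkm = 1)
  mm <- tibble::tibble(transcript_id = "t1", rpkm = 0)
  expect_warning(r <- positionwise_ratio(plus, minus, mp, mm), "mRNA")
  expect_equal(r$ratio, 3)
})

test_that("pause scores normalize by the trimmed gene mean", {
  # uniform coverage scores 1 everywhere
  tx <- make_transcriptome(strrep("A", 132), 0, 132, "u1")
  uni <- make_track(tibble::tibble(transcript_id = "u1", pos = 0:131,
                                   count = 2))
  ps <- pause_scores(uni, tx)
  expect_true(all(abs(ps$pause_score - 1) < 1e-12))

  # single spike on an otherwise empty 102-position window: 10 / (10/102)
  spike <- make_track(tibble::tibble(transcript_id = "u1", pos = 60L,
                                     count = 10))
  ps2 <- pause_scores(spike, tx)
  expect_equal(ps2$pause_score, 10 / (10 / 102))

  # spike outside the trimmed window has zero background -> Inf
  edge <- make_track(tibble::tibble(transcript_id = "u1", pos = 5L,
                                    count = 4))
  expect_equal(pause_scores(edge, tx)$pause_score, Inf)
})

# toy two-condition fixture: one planted spike over a uniform floor
spike_fixture <- function(spike = 50, floor_count = 0.1, spike_pos = 150L) {
  tx <- random_tx(402, 0, 402, plant_tgc_at = spike_pos, seed = 77)
  floor_pos <- setdiff(seq(20L, 380L, by = 4L), spike_pos)
  plus <- make_track(tibble::tibble(
    transcript_id = tx$transcript_id,
    pos = c(spike_pos, floor_pos),
    count = c(spike, rep(floor_count, length(floor_pos)))
  ))
  minus <- make_track(tibble::tibble(
    transcript_id = tx$transcript_id,
    pos = floor_pos,
    count = rep(floor_count, length(floor_pos))
  ))
  mq <- tibble::tibble(transcript_id = tx$transcript_id, rpkm = 1)
  list(tx = tx, plus = plus, minus = minus, mq = mq)
}

test_that("a planted spike with high ratio and pause is called once", {
  f <- spike_fixture()
  sites <- detect_sites(f$plus, f$minus, f$mq, f$mq, f$tx)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 150L)
  expect_equal(as.character(sites$motif), "UGC")
})

test_that("a spike over a high uniform background fails the pause filter", {
  f <- spike_fixture(spike = 50, floor_count = 150)
  sites <- detect_sites(f$plus, f$minus, f$mq, f$mq, f$tx)
  expect_equal(nrow(sites), 0L)
})

test_that("detection returns nothing on identical conditions", {
  f <- spike_fixture()
  sites <- detect_sites(f$plus, f$plus, f$mq, f$mq, f$tx)
  expect_equal(nrow(sites), 0L)
})

test_that("tightening any threshold never adds sites", {
  ex <- sim_main()
  sm <- cached("main_short_minus", to_rpm(build_density(
    ex$minus$footprints, ex$transcripts, "short", "three_prime", 0)))
  mp <- cached("main_mrna_plus", gene_rpkm(build_density(
    ex$plus$mrna, ex$transcripts, "all", "five_prime", 0), ex$transcripts))
  mm <- cached("main_mrna_minus", gene_rpkm(build_density(
    ex$minus$mrna, ex$transcripts, "all", "five_prime", 0), ex$transcripts))
  base <- cached("main_sites", detect_sites(
    ex$short_plus, sm, mp, mm, ex$transcripts))
  for (p in list(detection_params(ratio_min = 100),
                 detection_params(pause_min = 20))) {
    tight <- detect_sites(ex$short_plus, sm, mp, mm, ex$transcripts, p)
    expect_true(nrow(tight) <= nrow(base))
    expect_true(all(paste(tight$transcript_id, tight$pos) %in%
                      paste(base$transcript_id, base$pos)))
  }
})

test_that("site motif and frame agree with independent recomputation", {
  ex <- sim_main()
  sites <- get("main_sites", envir = .sim_cache)
  i <- match(sites$transcript_id, ex$transcripts$transcript_id)
  tri <- stringr::str_sub(ex$transcripts$sequence[i], sites$pos,
                          sites$pos + 2L)
  ref <- strsplit("TGC", "")[[1]]
  dist <- vapply(tri, function(t) sum(strsplit(t, "")[[1]] != ref),
                 integer(1), USE.NAMES = FALSE)
  expect_equal(as.character(sites$motif),
               ifelse(dist == 0, "UGC",
                      ifelse(dist == 1, "near_UGC", "other")))
  expect_equal(sites$frame,
               as.integer((sites$pos - ex$transcripts$cds_start[i]) %% 3L))
})

test_that("most-downstream sites identify the primary cut", {
  mk_sites <- function(df) {
    df$motif <- factor(df$motif, levels = c("UGC", "near_UGC", "other"))
    class(df) <- c("ridd_sites", class(df))
    df
  }
  s <- mk_sites(tibble::tibble(
    transcript_id = c("a", "a", "a", "b", "b"),
    pos = c(100L, 200L, 300L, 100L, 300L),
    motif = c("other", "other", "UGC", "UGC", "other")
  ))
  res <- most_downstream_analysis(s)
  expect_equal(res$fraction_ugc, 0.5)
  a <- res$per_transcript[res$per_transcript$transcript_id == "a", ]
  expect_equal(a$pos, 300L)
  expect_equal(as.character(a$motif), "UGC")
  expect_error(most_downstream_analysis(s[0, ]), "no sites")
})

test_that("generative construction makes every most-downstream site UG/C", {
  params <- sim_params(seed = 60, n_transcripts = 30, p_cleave = 1,
                       basal_p_cleave = 0)
  ex <- simulate_experiment(params)
  sp <- to_rpm(build_density(ex$plus$footprints, ex$transcripts, "short",
                             "three_prime", 0))
  sm <- to_rpm(build_density(ex$minus$footprints, ex$transcripts, "short",
                             "three_prime", 0))
  mp <- gene_rpkm(build_density(ex$plus$mrna, ex$transcripts, "all",
                                "five_prime", 0), ex$transcripts)
  mm <- gene_rpkm(build_density(ex$minus$mrna, ex$transcripts, "all",
                                "five_prime", 0), ex$transcripts)
  sites <- detect_sites(sp, sm, mp, mm, ex$transcripts)
  res <- most_downstream_analysis(sites)
  expect_equal(res$fraction_ugc, 1)
})

test_that("transcript aggregation reports cohort fractions and motif table", {
  mk_sites <- function(df) {
    df$motif <- factor(df$motif, levels = c("UGC", "near_UGC", "other"))
    class(df) <- c("ridd_sites", class(df))
    df
  }
  tx <- make_transcriptome(rep(strrep("A", 60), 10), 0, 60,
                           sprintf("t%02d", 1:10),
                           er_associated = c(rep(TRUE, 9), FALSE))
  s <- mk_sites(tibble::tibble(
    transcript_id = sprintf("t%02d", 1:10),
    pos = rep(30L, 10),
    motif = rep("UGC", 10)
  ))
  agg <- transcript_aggregation(s, tx)
  expect_equal(agg$cohort$fraction_er_among_ugc, 0.9)
  expect_equal(agg$cohort$fraction_ugc_transcripts, 1)
  expect_equal(nrow(tidy(agg)), 10L)

  s2 <- mk_sites(tibble::tibble(
    transcript_id = c("t01", "t01", "t02", "t03"),
    pos = c(10L, 20L, 30L, 40L),
    motif = c("UGC", "UGC", "near_UGC", "other")
  ))
  agg2 <- transcript_aggregation(s2, tx)
  expect_equal(agg2$motif_counts$n, c(2L, 1L, 1L))

  empty <- transcript_aggregation(s[0, ], tx)
  expect_equal(nrow(tidy(empty)), 0L)
  expect_true(is.na(glance(empty)$fraction_er_among_ugc))
})

test_that("sequence context is one-hot at the motif and flat elsewhere", {
  set.seed(90)
  n <- 1000L
  seqs <- vapply(seq_len(n), function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                 collapse = ""),
           "TGC",
           paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                 collapse = ""))
  }, character(1))
  tx <- make_transcriptome(seqs, 0, 21, sprintf("s%04d", seq_len(n)))
  sites <- tibble::tibble(transcript_id = tx$transcript_id, pos = 11L)
  m <- sequence_context_matrix(sites, tx, flank = 5)
  expect_equal(m$T[m$offset == -1], 1)
  expect_equal(m$G[m$offset == 0], 1)
  expect_equal(m$C[m$offset == 1], 1)
  flat <- m[abs(m$offset) > 1, c("A", "C", "G", "T")]
  expect_true(all(abs(as.matrix(flat) - 0.25) < 0.05))
  expect_true(all(abs(rowSums(as.matrix(m[, c("A", "C", "G", "T")])) - 1)
                  < 1e-12))
})

test_that("single sites give one-hot rows and edge sites are excluded", {
  tx <- make_transcriptome("AATTGCAAA", 0, 9, "one")
  m <- sequence_context_matrix(tibble::tibble(transcript_id = "one",
                                              pos = 4L), tx, flank = 2)
  expect_true(all(apply(as.matrix(m[, c("A", "C", "G", "T")]), 1, max) == 1))
  sites <- tibble::tibble(transcript_id = c("one", "one"), pos = c(4L, 1L))
  m2 <- sequence_context_matrix(sites, tx, flank = 2)
  expect_equal(attr(m2, "n_excluded"), 1L)
  expect_error(
    sequence_context_matrix(tibble::tibble(transcript_id = "one", pos = 0L),
                            tx, flank = 5),
    "far enough"
  )
})
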