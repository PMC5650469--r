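# Shared fixtures: in-code transcriptomes, tracks, and cached simulator runs.

make_transcriptome <- function(sequence, cds_start, cds_end,
                               transcript_id = sprintf("tx%02d",
                                                       seq_along(sequence)),
                               er_associated = NA, masked = FALSE) {
  tx <- tibble::tibble(
    transcript_id = transcript_id,
    sequence = sequence,
    length = nchar(sequence),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    er_associated = er_associated,
    masked = masked
  )
  class(tx) <- c("ridd_transcriptome", class(tx))
  tx
}

# random in-frame CDS transcript, optionally with a planted TGC
random_tx <- function(len = 300L, cds_start = 30L, cds_end = len - 30L,
                      plant_tgc_at = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  if (!is.null(plant_tgc_at)) {
    stringr::str_sub(s, plant_tgc_at, plant_tgc_at + 2L) <- "TGC"
  }
  make_transcriptome(s, cds_start, cds_end)
}

# direct sparse-track constructor (bypasses read assignment)
make_track <- function(df, units = "rpm", library_total = 1e6,
                       size_class = "short", assignment = "three_prime",
                       shift = 0L) {
  riddseq:::new_track(tibble::as_tibble(df), units = units,
                      library_total = library_total,
                      size_class = size_class, assignment = assignment,
                      shift = shift)
}

# Simulator runs are shared across test files through this session cache.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

sim_frame_run <- function(frame, n_transcripts, seed) {
  key <- sprintf("sim_f%s_n%d_s%d", paste(frame, collapse = ""),
                 n_transcripts, seed)
  cached(key, {
    params <- riddseq::sim_params(seed = seed, n_transcripts = n_transcripts,
                                  site_frames = frame)
    ex <- riddseq::simulate_experiment(params)
    ex$params <- params
    ex$short_plus <- riddseq::to_rpm(riddseq::build_density(
      ex$plus$footprints, ex$transcripts, "short", "three_prime", 0))
    ex$anchors <- dplyr::filter(ex$plus$truth$sites, activated)
    ex
  })
}

# the main frame-0 run used by periodicity, disome and detection checks
sim_main <- function() sim_frame_run(0L, 220L, 101L)
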