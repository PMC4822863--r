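# End-to-end orchestration: synthesize the stimulus set, run the
# periphery, train, analyze and rank, writing delimited artifacts with
# JSON provenance sidecars. Also the miniature deterministic fixture used
# for fast checks.

#' Run the modelling pipeline
#'
#' Executes the requested stages in order: `synth` (write the standard
#' stimulus WAVs and manifest), `periphery` (place codes for every
#' stimulus), `train` (fit [pitch_snn()]), `analyze` (vector-strength
#' matrix and stacked ISIH tables) and `rank` (vowel pitch-ranking
#' table). Later stages reuse in-memory results of earlier ones; every
#' numeric artifact is a delimited table and every stage writes a JSON
#' sidecar with the seed and settings, so a rerun with the same
#' configuration reproduces the outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("synth", "periphery", "train", "analyze",
#'   "rank")`.
#' @param pitches Pitch ladder (Hz).
#' @param type Training mode passed to [pitch_snn()].
#' @param params,map,control Model configuration.
#' @param seed Master seed.
#' @return Invisibly, a list with the fitted model (if trained) and the
#'   paths written.
#' @export
run_pipeline <- function(out_dir, stages = c("synth", "periphery", "train",
                                             "analyze", "rank"),
                         pitches = semitone_ladder(98, 493),
                         type = "mixed", params = snn_params(),
                         map = cochlear_map(), control = snn_control(),
                         seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  model <- NULL
  sidecar <- function(name, extra = list()) {
    p <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(c(list(stage = name, seed = seed,
                                n_pitches = length(pitches),
                                n_channels = length(map$cfs_hz)), extra),
                         p, auto_unbox = TRUE, digits = NA)
    p
  }
  ss <- NULL
  if (any(c("synth", "periphery") %in% stages)) {
    ss <- stimulus_set(pitches)
  }
  if ("synth" %in% stages) {
    wav_dir <- file.path(out_dir, "stimuli")
    dir.create(wav_dir, showWarnings = FALSE)
    ss$manifest$path <- file.path("stimuli",
                                  paste0(ss$manifest$label, ".wav"))
    for (r in seq_len(nrow(ss$manifest)))
      write_wav(ss$waves[[ss$manifest$label[r]]],
                file.path(out_dir, ss$manifest$path[r]))
    mp <- file.path(out_dir, "manifest.tsv")
    utils::write.table(ss$manifest, mp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, mp, sidecar("synth"))
  }
  if ("periphery" %in% stages) {
    pc <- vapply(ss$waves, function(w)
      place_code(auditory_periphery(w, map)),
      numeric(length(map$cfs_hz)))
    df <- data.frame(cf_hz = map$cfs_hz, position_mm = map$positions_mm,
                     pc, check.names = FALSE)
    pp <- file.path(out_dir, "place_codes.tsv")
    utils::write.table(df, pp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, pp, sidecar("periphery"))
  }
  if (any(c("train", "analyze", "rank") %in% stages)) {
    model <- pitch_snn(pitches, type = type, params = params, map = map,
                       control = control, seed = seed)
    wp <- file.path(out_dir, "weights.tsv")
    utils::write.table(
      data.frame(pitch_hz = rownames(model$weights), model$weights,
                 check.names = FALSE),
      wp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, wp,
               sidecar("train", list(type = type,
                                     eta_scale = control$eta_scale,
                                     time_scale = control$time_scale)))
  }
  if ("analyze" %in% stages) {
    vs <- vs_matrix(model, seed = seed)
    vp <- file.path(out_dir, "vs_matrix.tsv")
    utils::write.table(data.frame(neuron_hz = rownames(vs), vs,
                                  check.names = FALSE),
                       vp, sep = "\t", row.names = FALSE, quote = FALSE)
    st <- stacked_isih(model, seed = seed)
    sm <- t(vapply(st, `[[`, numeric(length(st[[1]]$smoothed)), "smoothed"))
    sp <- file.path(out_dir, "stacked_isih.tsv")
    utils::write.table(data.frame(pitch_hz = attr(st, "pitches"), sm,
                                  check.names = FALSE),
                       sp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, vp, sp, sidecar("analyze"))
  }
  if ("rank" %in% stages) {
    pool <- isih_pool(model, seed = seed)
    res <- pitch_ranking_experiment(pool, seed = seed)
    rp <- file.path(out_dir, "ranking.tsv")
    utils::write.table(res, rp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, rp, sidecar("rank"))
  }
  invisible(list(model = model, paths = paths))
}

#' Miniature deterministic fixture
#'
#' A reduced model of the full pipeline for fast checks: a short pitch
#' ladder, a coarse cochlear map over the same positional range, and a
#' compressed training schedule (larger learning-rate scaling with
#' correspondingly fewer presentations; the `eta * T` product is
#' preserved). Qualitative behaviour -- homeostatic rate convergence and
#' the emergence of phase locking -- matches the full model.
#'
#' @param seed Integer seed.
#' @param n_pitches Number of pitch categories (ladder starts at 110 Hz,
#'   major-third steps).
#' @param n_channels Cochlear channels, spread over the apical 3--12 mm
#'   (CF ~88--750 Hz) where the fixture pitches live; the coarser full
#'   0.1 mm grid is unnecessary at this scale.
#' @param type Training mode.
#' @return A [pitch_snn] fit.
#' @export
pitch_fixture <- function(seed = 1, n_pitches = 3, n_channels = 24,
                          type = "tone") {
  pitches <- 110 * 2^(seq(0, by = 4, length.out = n_pitches) / 12)
  pitch_snn(pitches, type = type,
            map = cochlear_map(n_channels, d_range = c(3, 12)),
            control = snn_control(analysis_reps = 4),
            seed = seed)
}
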