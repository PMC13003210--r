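# Readers/writers: 16-bit PCM WAV, trace/feature CSVs, cohort manifest
# JSON and the pipeline configuration. The WAV codec is implemented
# directly (no audio package ships with the analysis environment).

#' Write an audio trace as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit signed PCM,
#' mono.
#'
#' @param audio an [audio_trace()].
#' @param path output file.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_trace"))
  x <- pmax(-1, pmin(1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(audio$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file into an audio trace
#'
#' @param path WAV file (PCM 16-bit; first channel used).
#' @param channel channel label to attach.
#' @return an [audio_trace()] with samples in \[-1, 1\].
#' @export
read_wav <- function(path, channel = "anterior-right") {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  fs <- NULL; nchan <- 1L; bits <- 16L
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV is supported")
      nchan <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM is supported")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (nchan > 1) pcm <- pcm[seq(1, length(pcm), by = nchan)]
  audio_trace(pcm / 32767, fs, channel)
}

#' Write / read an impedance trace as CSV (`time_s`, `value_ohm`)
#' @param trace an [impedance_trace()]; `path` the CSV file.
#' @export
write_bioz_csv <- function(trace, path) {
  stopifnot(inherits(trace, "impedance_trace"))
  utils::write.csv(data.frame(
    time_s = (seq_along(trace$samples) - 1) / trace$fs,
    value_ohm = trace$samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bioz_csv
#' @param excitation_khz excitation-frequency label to attach.
#' @export
read_bioz_csv <- function(path, excitation_khz = 150) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value_ohm") %in% names(d)))
  fs <- 1 / stats::median(diff(d$time_s))
  impedance_trace(d$value_ohm, round(fs, 6), excitation_khz)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the processing cascade with their standard
#' values. Serializes losslessly to/from JSON.
#'
#' @param ... overrides as `section$name = value` lists, e.g.
#'   `ip = list(bp_hi = 1.4)`.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ip = list(resample_hz = 100, artifact_hi = 1.5, artifact_lo = 0.5,
              bp_lo = 0.1, bp_hi = 1.0, detect_win_s = 32,
              detect_overlap_s = 2, min_peak_dist_s = 0.67,
              sqi_win_s = 32, sqi_hop_s = 8, sqi_cov = 0.3,
              sqi_corr = 0.7, sqi_coverage = 0.6, mad_k = 5,
              mad_window = 30),
    ls = list(resample_hz = 4000, bp_lo = 100, bp_hi = 1000,
              psd_win_ms = 64, psd_overlap = 0.75, mad_k = 4,
              mad_window = 30),
    fusion = list(win_s = 32, overlap = 0.75, mad_k = 5),
    stats = list(alpha = 0.05, bh_m = 2),
    seed = 1)
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop(sprintf("unknown config section '%s'", sec))
    if (is.list(over[[sec]])) {
      for (k in names(over[[sec]])) {
        if (!k %in% names(cfg[[sec]]))
          stop(sprintf("unknown config key '%s$%s'", sec, k))
        cfg[[sec]][[k]] <- over[[sec]][[k]]
      }
    } else cfg[[sec]] <- over[[sec]]
  }
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  with(cfg$ip, {
    if (bp_lo >= bp_hi) stop("config error: ip$bp_lo must be < ip$bp_hi")
    if (artifact_lo >= artifact_hi)
      stop("config error: ip$artifact_lo must be < ip$artifact_hi")
  })
  if (cfg$ls$bp_lo >= cfg$ls$bp_hi)
    stop("config error: ls$bp_lo must be < ls$bp_hi")
  cfg
}

#' Save / load a pipeline configuration as JSON
#' @param cfg a [pipeline_config()]; `path` the JSON file.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[setdiff(names(raw), "seed")]
  cfg <- do.call(pipeline_config, args)
  if (!is.null(raw$seed)) cfg$seed <- raw$seed
  cfg
}

#' Write a synthetic recording (or cohort) to disk
#'
#' Each recording becomes a directory with `bioz.csv`, `audio.wav` and
#' `truth.csv`; a cohort-level `manifest.json` lists ids and labels.
#'
#' @param recs list of recordings from [generate_cohort()] (or a single
#'   recording in a length-1 list).
#' @param dir output directory.
#' @export
write_cohort <- function(recs, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", dir))
  manifest <- attr(recs, "manifest")
  for (r in recs) {
    rd <- file.path(dir, r$id)
    dir.create(rd, showWarnings = FALSE)
    write_bioz_csv(r$bioz, file.path(rd, "bioz.csv"))
    write_wav(r$audio, file.path(rd, "audio.wav"))
    utils::write.csv(r$truth, file.path(rd, "truth.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory containing `manifest.json`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest.json not found in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    rd <- file.path(dir, manifest$id[i])
    base <- list(id = manifest$id[i],
                 participant_id = manifest$participant_id[i],
                 group = manifest$group[i],
                 time_point = manifest$time_point[i])
    # a corrupt recording must not abort the batch: record the error and
    # let downstream processing report the per-recording failure
    tryCatch({
      bioz_f <- file.path(rd, "bioz.csv")
      wav_f <- file.path(rd, "audio.wav")
      if (!file.exists(bioz_f)) stop("missing bioimpedance file: ", bioz_f)
      if (!file.exists(wav_f)) stop("missing audio file: ", wav_f)
      truth_f <- file.path(rd, "truth.csv")
      c(base, list(bioz = read_bioz_csv(bioz_f), audio = read_wav(wav_f),
                   truth = if (file.exists(truth_f))
                     utils::read.csv(truth_f)))
    }, error = function(e) c(base, list(error = conditionMessage(e))))
  })
  names(recs) <- manifest$id
  attr(recs, "manifest") <- manifest
  recs
}
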