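#' Read and write recordings as CSV
#'
#' Recordings are exchanged as plain CSV with columns `time_s`, `ecg`,
#' `ppg`, one file per 24-s measurement. The time column must be uniform
#' to within 1e-6 relative tolerance; the sampling rate is recovered from
#' it on read.
#'
#' @param path File path.
#' @return A `bp_recording` (without truth block).
#' @export
read_recording <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "ecg", "ppg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("recording file is missing column(s): ", paste(miss, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-increasing time at row ", which(dt <= 0)[1] + 1L)
  step <- dt[1]
  bad <- which(abs(dt - step) > 1e-6 * max(step, 1e-12))
  if (length(bad)) {
    stop("non-uniform sampling at row ", bad[1] + 1L)
  }
  fs <- 1 / step
  structure(list(subject_id = NA_character_, fs = fs,
                 duration = nrow(df) / fs,
                 ecg = df$ecg, ppg = df$ppg, truth = NULL),
            class = "bp_recording")
}

#' @rdname read_recording
#' @param rec A `bp_recording`.
#' @param digits Decimal digits written.
#' @export
write_recording <- function(rec, path, digits = 9) {
  n <- length(rec$ecg)
  df <- data.frame(time_s = round((seq_len(n) - 1) / rec$fs, digits),
                   ecg = round(rec$ecg, digits),
                   ppg = round(rec$ppg, digits))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a session manifest
#'
#' Serializes a `bp_session` to JSON: subject demographics, event order
#' with timestamps, manual readings, device estimates and QC outcomes when
#' present, and the recording file names (recordings themselves are
#' written as CSV next to the manifest).
#'
#' @param session A `bp_session`.
#' @param dir Output directory (created if needed).
#' @param name Base name for the manifest and recording files.
#' @return Path of the manifest (invisibly).
#' @export
write_session <- function(session, dir, name = session$subject$subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip_event <- function(ev, tag) {
    out <- ev[setdiff(names(ev), "recording")]
    if (!is.null(ev$recording)) {
      fn <- sprintf("%s_%s.csv", name, gsub("[^A-Za-z0-9]", "", tag))
      write_recording(ev$recording, file.path(dir, fn))
      out$recording_file <- fn
    }
    out
  }
  manifest <- list(
    subject = session$subject,
    calibration = lapply(seq_along(session$calibration), function(i) {
      cp <- session$calibration[[i]]
      list(manual = strip_event(cp$manual, cp$manual$label),
           watch = strip_event(cp$watch, cp$watch$label))
    }),
    events = lapply(session$events, function(ev) strip_event(ev, ev$label))
  )
  path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @param path Manifest path.
#' @export
read_session <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  dir <- dirname(path)
  load_event <- function(ev) {
    if (!is.null(ev$recording_file)) {
      ev$recording <- read_recording(file.path(dir, ev$recording_file))
      ev$recording$subject_id <- m$subject$subject_id
    }
    ev
  }
  structure(list(
    subject = m$subject,
    calibration = lapply(m$calibration, function(cp)
      list(manual = load_event(cp$manual), watch = load_event(cp$watch))),
    events = lapply(m$events, load_event)
  ), class = "bp_session")
}

#' Serialize a trained model to JSON (and back)
#'
#' The model is stored as a single portable JSON file: architecture,
#' activation, standardization constants, all weight matrices, batch-norm
#' parameters and running statistics, and the search log.
#'
#' @param model A `bp_model`.
#' @param path Output path.
#' @return `path` (invisibly) / the restored `bp_model`.
#' @export
write_model <- function(model, path) {
  ser <- list(
    activation = model$activation,
    layer_sizes = model$layer_sizes,
    final_hidden_dim = model$final_hidden_dim,
    x_center = model$x_center, x_scale = model$x_scale,
    schema = model$schema, hash = model$hash,
    layers = lapply(model$net$layers, function(ly)
      list(W = ly$W, gamma = ly$gamma, beta = ly$beta,
           run_mean = ly$run_mean, run_var = ly$run_var)),
    W_out = model$net$W_out, b_out = model$net$b_out,
    search_log = model$search_log
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  as_mat <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = length(m), byrow = TRUE)
  }
  net <- list(
    layers = lapply(s$layers, function(ly)
      list(W = as_mat(ly$W), gamma = as.numeric(unlist(ly$gamma)),
           beta = as.numeric(unlist(ly$beta)),
           run_mean = as.numeric(unlist(ly$run_mean)),
           run_var = as.numeric(unlist(ly$run_var)))),
    W_out = as_mat(s$W_out), b_out = as.numeric(unlist(s$b_out))
  )
  structure(list(net = net, activation = s$activation,
                 layer_sizes = as.integer(unlist(s$layer_sizes)),
                 final_hidden_dim = as.integer(s$final_hidden_dim),
                 x_center = setNames(as.numeric(s$x_center), s$schema),
                 x_scale = setNames(as.numeric(s$x_scale), s$schema),
                 schema = s$schema, hash = s$hash,
                 search_log = s$search_log),
            class = "bp_model")
}
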