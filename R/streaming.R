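#' Continuous-query configuration
#'
#' Describes one micro-batch run: a file source of 5-second packets, a
#' trained-model artifact, an append-only sink table and a checkpoint
#' directory for exactly-once restart. With `carry_over = TRUE` (default)
#' beats straddling packet edges are recovered by retaining signal context
#' between batches, so streaming output matches a batch run over the
#' concatenated record beat-for-beat; with `carry_over = FALSE` each packet
#' is processed strictly on its own and boundary beats are dropped.
#'
#' @param source_dir Packet directory (see [open_stream]).
#' @param model_path Model artifact from [save_model].
#' @param sink_path CSV sink table path.
#' @param checkpoint_dir Checkpoint directory (created if needed).
#' @param trigger_interval Trigger interval in seconds (default 5).
#' @param carry_over Recover beats across packet boundaries.
#' @param realtime Pace batches to the trigger interval in wall-clock time
#'   (default FALSE: batches run back-to-back, the processing-time trigger).
#' @param pipeline A [default_config]-shaped list of pipeline settings.
#' @return Object of class `query_config`.
#' @export
query_config <- function(source_dir, model_path, sink_path, checkpoint_dir,
                         trigger_interval = 5, carry_over = TRUE,
                         realtime = FALSE, pipeline = default_config()) {
  stopifnot(trigger_interval > 0)
  dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(source_dir = source_dir, model_path = model_path,
                 sink_path = sink_path, checkpoint_dir = checkpoint_dir,
                 trigger_interval = trigger_interval,
                 carry_over = isTRUE(carry_over),
                 realtime = isTRUE(realtime), pipeline = pipeline),
            class = "query_config")
}

ENGINE_VERSION <- 1L

checkpoint_path <- function(config) {
  file.path(config$checkpoint_dir, "checkpoint.json")
}

read_checkpoint <- function(config) {
  p <- checkpoint_path(config)
  if (!file.exists(p)) {
    return(list(last_committed = -1L, emitted_r = integer(0),
                version = ENGINE_VERSION))
  }
  ck <- jsonlite::read_json(p, simplifyVector = TRUE)
  if (!identical(as.integer(ck$version), ENGINE_VERSION)) {
    stop("checkpoint engine version mismatch", call. = FALSE)
  }
  list(last_committed = as.integer(ck$last_committed),
       emitted_r = as.integer(ck$emitted_r), version = ENGINE_VERSION)
}

write_checkpoint <- function(config, ck) {
  p <- checkpoint_path(config)
  tmp <- paste0(p, ".tmp")
  jsonlite::write_json(list(last_committed = ck$last_committed,
                            emitted_r = ck$emitted_r,
                            version = ENGINE_VERSION),
                       tmp, auto_unbox = TRUE)
  file.rename(tmp, p)  # atomic commit
  invisible(p)
}

#' Idempotent append to the sink table
#'
#' The sink is an append-only CSV table
#' `detections(packet_index, record, r_index, label, ts)`. Re-delivery of a
#' packet index that is already present is a no-op, which makes the
#' sink-then-checkpoint commit protocol exactly-once under crashes.
#'
#' @param predictions data.frame with columns `packet_index`, `record`,
#'   `r_index`, `label`.
#' @param sink_path Sink CSV path.
#' @return Logical: `TRUE` if rows were appended, `FALSE` if the packet was
#'   already committed (no-op).
#' @export
sink_write <- function(predictions, sink_path) {
  stopifnot(all(c("packet_index", "record", "r_index", "label") %in%
                  names(predictions)))
  new <- predictions[, c("packet_index", "record", "r_index", "label")]
  new$ts <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
  if (file.exists(sink_path)) {
    existing_idx <- unique(read.csv(sink_path)$packet_index)
    pk <- unique(new$packet_index)
    if (length(pk) > 0 && all(pk %in% existing_idx)) return(FALSE)
    new <- new[!(new$packet_index %in% existing_idx), , drop = FALSE]
    write.table(new, sink_path, sep = ",", append = TRUE,
                col.names = FALSE, row.names = FALSE, qmethod = "double")
  } else {
    write.csv(new, sink_path, row.names = FALSE)
  }
  TRUE
}

#' Read the sink table back
#'
#' @param sink_path Sink CSV path.
#' @return data.frame of detections (zero rows if the sink does not exist).
#' @export
sink_read <- function(sink_path) {
  if (!file.exists(sink_path)) {
    return(data.frame(packet_index = integer(0), record = character(0),
                      r_index = integer(0), label = character(0),
                      ts = character(0), stringsAsFactors = FALSE))
  }
  read.csv(sink_path, stringsAsFactors = FALSE)
}

now_ms <- function() as.numeric(Sys.time()) * 1000

# Finalization margin (samples) for carry-over streaming: beats whose
# 200-sample window ends within this distance of the received prefix are
# deferred to a later batch, because the FIR edge transient, the
# moving-window integrator, peak snapping and the refractory comparison can
# still change there. The final batch flushes everything.
STREAM_DEFER_MARGIN <- 256L

#' Run the continuous query over a packet source
#'
#' Executes the full per-batch pipeline — denoise, R-peak detection,
#' segmentation, wavelet features, classification — once per packet, in
#' stream order, committing each batch to the sink and then to the
#' checkpoint before the next batch starts. On restart with the same
#' checkpoint directory, committed batches are skipped and a batch whose
#' sink write completed but whose checkpoint did not is re-delivered as a
#' no-op, so every beat reaches the sink exactly once. An unparseable
#' packet is quarantined (logged, zero beats) and the stream continues.
#'
#' @param config A [query_config].
#' @param fail_at Fault-injection hook for testing: a list
#'   `list(packet_index =, stage =)` with stage one of `"before_sink"`,
#'   `"after_sink"`, `"after_checkpoint"`; the engine stops with an error at
#'   that point, leaving the checkpoint/sink as a real crash would.
#' @param quiet Suppress per-batch progress lines.
#' @return List with `results` (one `batch_result` per packet processed in
#'   this run), `sink_path`, `quarantined` (packet indices).
#' @export
run_query <- function(config, fail_at = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "query_config"))
  model <- load_model(config$model_path)
  stream <- open_stream(config$source_dir)
  ck <- read_checkpoint(config)
  pl <- config$pipeline
  spec <- filter_spec(pl$filter$low_cut, pl$filter$high_cut,
                      pl$filter$num_taps)
  results <- list()
  quarantined <- integer(0)
  prefix <- numeric(0)       # raw samples received so far (carry-over mode)
  emitted <- ck$emitted_r
  n_pk <- stream$n_packets
  if (n_pk == 0) {
    return(list(results = list(), sink_path = config$sink_path,
                quarantined = integer(0)))
  }
  maybe_fail <- function(k, stage) {
    if (!is.null(fail_at) && k == fail_at$packet_index &&
        identical(stage, fail_at$stage)) {
      stop(sprintf("injected crash at packet %d (%s)", k, stage),
           call. = FALSE)
    }
  }
  for (k in 0:(n_pk - 1L)) {
    t0 <- now_ms()
    pk <- tryCatch(read_stream_packet(stream, k), error = function(e) e)
    t_read <- now_ms()
    if (inherits(pk, "error")) {
      message(sprintf("[batch %d] quarantined: %s", k, conditionMessage(pk)))
      quarantined <- c(quarantined, k)
      if (k > ck$last_committed) {
        ck$last_committed <- k
        write_checkpoint(config, ck)
      }
      next
    }
    if (config$carry_over) prefix <- c(prefix, pk$samples)
    if (k <= ck$last_committed) next  # already committed (restart replay)

    last_batch <- k == n_pk - 1L
    if (config$carry_over) {
      n_pre <- length(prefix)
      filt <- bandpass_fir(prefix, spec)
      peaks <- detect_r_peaks(filt, fs = ECG_FS,
                              refractory_s = pl$rpeak$refractory_s)
      horizon <- if (last_batch) n_pre - 1L else n_pre - 1L - STREAM_DEFER_MARGIN
      elig <- peaks[peaks - pl$segment$pre >= 0L &
                      peaks + pl$segment$post <= horizon &
                      !(peaks %in% emitted)]
      beats <- segment_beats(filt, elig, pre = pl$segment$pre,
                             post = pl$segment$post)
    } else {
      if (length(pk$samples) > spec$num_taps) {
        filt <- bandpass_fir(pk$samples, spec)
        local_peaks <- detect_r_peaks(filt, fs = ECG_FS,
                                      refractory_s = pl$rpeak$refractory_s)
      } else {
        filt <- numeric(0)
        local_peaks <- integer(0)
      }
      beats <- segment_beats(filt, local_peaks, pre = pl$segment$pre,
                             post = pl$segment$post)
      beats$r_index <- beats$r_index + as.integer(pk$start_sample)
    }
    if (nrow(beats$X) > 0) {
      feats <- extract_feature_matrix(beats, wavelet = pl$features$wavelet)
      pred <- predict_beats(model, feats$X)
      labels <- as.character(pred$label)
    } else {
      labels <- character(0)
    }
    preds <- data.frame(packet_index = k,
                        record = if (is.na(pk$record)) "record" else pk$record,
                        r_index = beats$r_index,
                        label = labels, stringsAsFactors = FALSE)
    t_compute <- now_ms()
    maybe_fail(k, "before_sink")
    sink_write(preds, config$sink_path)
    maybe_fail(k, "after_sink")
    t_sink <- now_ms()
    emitted <- c(emitted, beats$r_index)
    ck$last_committed <- k
    ck$emitted_r <- emitted
    write_checkpoint(config, ck)
    maybe_fail(k, "after_checkpoint")
    res <- structure(list(packet_index = k, n_beats = nrow(preds),
                          predictions = preds,
                          timings = c(read_ms = t_read - t0,
                                      compute_ms = t_compute - t_read,
                                      sink_ms = t_sink - t_compute,
                                      total_ms = t_sink - t0)),
                     class = "batch_result")
    results[[length(results) + 1L]] <- res
    if (!quiet) {
      message(sprintf("[batch %d] %d beats in %.1f ms (read %.1f, compute %.1f, sink %.1f)",
                      k, res$n_beats, res$timings["total_ms"],
                      res$timings["read_ms"], res$timings["compute_ms"],
                      res$timings["sink_ms"]))
    }
    if (config$realtime) {
      spent <- (now_ms() - t0) / 1000
      if (spent < config$trigger_interval) {
        Sys.sleep(config$trigger_interval - spent)
      }
    }
  }
  list(results = results, sink_path = config$sink_path,
       quarantined = quarantined)
}

#' Per-batch timing summary from the progress reporter
#'
#' Collects the per-batch stage timings (read, compute, sink, total) of a
#' [run_query] run into one table, one row per batch, with the mean of each
#' stage attached; optionally exported as CSV.
#'
#' @param results List of `batch_result` objects (from `run_query()$results`).
#' @param path Optional CSV output path.
#' @return data.frame with columns `packet_index`, `n_beats`, `read_ms`,
#'   `compute_ms`, `sink_ms`, `total_ms`; mean timings in
#'   `attr(, "summary")`.
#' @export
progress_report <- function(results, path = NULL) {
  if (length(results) == 0) stop("no batches to report", call. = FALSE)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(packet_index = r$packet_index, n_beats = r$n_beats,
               read_ms = r$timings[["read_ms"]],
               compute_ms = r$timings[["compute_ms"]],
               sink_ms = r$timings[["sink_ms"]],
               total_ms = r$timings[["total_ms"]])
  }))
  attr(df, "summary") <- colMeans(df[, c("read_ms", "compute_ms",
                                         "sink_ms", "total_ms")])
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
  }
  df
}
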