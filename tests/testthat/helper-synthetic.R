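# Shared fixture builders; everything is generated in code at test time.

# A noise-free record: the signal is exactly the sum of template waveforms.
clean_record <- function(class_label = "NORMAL", duration = 10, seed = 1,
                         mean_rr = 0.8, rr_jitter = 0) {
  generate_record(
    rhythm_spec(mean_rr = mean_rr, rr_jitter = rr_jitter,
                duration = duration, noise_sd = 0, baseline_wander_amp = 0,
                seed = seed),
    beat_template(class_label))
}

noisy_record <- function(class_label = "NORMAL", duration = 30, seed = 1,
                         mean_rr = 0.8, noise_sd = 0.05) {
  jit <- if (class_label == "AF") 0.2 else 0.05
  generate_record(
    rhythm_spec(mean_rr = mean_rr, rr_jitter = jit, duration = duration,
                noise_sd = noise_sd, seed = seed),
    beat_template(class_label))
}

# Three-morphology packet stream + ground truth in a temp dir.
make_stream <- function(dir, seconds_each = 35, noise_sd = 0.05,
                        seed = 40) {
  specs <- list(
    list(rhythm = rhythm_spec(mean_rr = 0.8, rr_jitter = 0.05,
                              duration = seconds_each, noise_sd = noise_sd,
                              seed = seed + 1),
         template = beat_template("NORMAL")),
    list(rhythm = rhythm_spec(mean_rr = 0.8, rr_jitter = 0.05,
                              duration = seconds_each, noise_sd = noise_sd,
                              seed = seed + 2),
         template = beat_template("RBBB")),
    list(rhythm = rhythm_spec(mean_rr = 0.7, rr_jitter = 0.2,
                              duration = seconds_each, noise_sd = noise_sd,
                              seed = seed + 3),
         template = beat_template("AF")))
  generate_dataset(specs, dir)
}

# Small trained random-forest artifact for streaming tests.
make_model <- function(path, seed = 3, scale = 0.05) {
  bm <- synthetic_benchmark(seed = seed, scale = scale)
  mod <- train_classifier(bm$train, "random_forest", seed = seed)
  save_model(mod, path)
  path
}

# Batch-mode reference pipeline over one concatenated signal.
batch_pipeline <- function(signal, model) {
  filt <- bandpass_fir(signal, filter_spec())
  peaks <- detect_r_peaks(filt)
  beats <- segment_beats(filt, peaks)
  fm <- extract_feature_matrix(beats)
  pb <- predict_beats(model, fm$X)
  data.frame(r_index = beats$r_index, label = as.character(pb$label),
             stringsAsFactors = FALSE)
}

# Brute-force one-vs-rest confusion counting, element by element.
brute_force_metrics <- function(truth, pred) {
  classes <- c("NORMAL", "RBBB", "AF")
  out <- list()
  for (cl in classes) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] != cl && pred[i] != cl) tn <- tn + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    out[[cl]] <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  }
  out
}
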