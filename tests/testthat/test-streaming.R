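# One shared model artifact and stream for the module tests.
local_stream_fixture <- function(env = parent.frame(), seconds_each = 20,
                                 seed = 50) {
  td <- withr::local_tempdir(.local_envir = env)
  src <- file.path(td, "src")
  ds <- make_stream(src, seconds_each = seconds_each, seed = seed)
  mp <- file.path(td, "model.rds")
  make_model(mp, seed = 3)
  list(dir = td, src = src, ds = ds, model_path = mp,
       model = load_model(mp))
}

test_that("a finite stream yields one committed batch per packet", {
  fx <- local_stream_fixture()
  qc <- query_config(fx$src, fx$model_path,
                     file.path(fx$dir, "sink.csv"),
                     file.path(fx$dir, "ckpt"))
  res <- run_query(qc)
  n_pk <- open_stream(fx$src)$n_packets
  expect_length(res$results, n_pk)
  expect_equal(vapply(res$results, `[[`, integer(1), "packet_index"),
               0:(n_pk - 1))
  det <- sink_read(qc$sink_path)
  expect_equal(nrow(det), sum(vapply(res$results, `[[`, numeric(1),
                                     "n_beats")))
})

test_that("an empty source exits cleanly with zero batches", {
  td <- withr::local_tempdir()
  src <- file.path(td, "empty"); dir.create(src)
  mp <- file.path(td, "m.rds"); make_model(mp)
  qc <- query_config(src, mp, file.path(td, "sink.csv"),
                     file.path(td, "ckpt"))
  res <- run_query(qc)
  expect_length(res$results, 0)
})

test_that("streaming with carry-over equals batch processing beat-for-beat", {
  fx <- local_stream_fixture(seconds_each = 25, seed = 60)
  batch <- batch_pipeline(fx$ds$signal, fx$model)
  qc <- query_config(fx$src, fx$model_path,
                     file.path(fx$dir, "sink.csv"),
                     file.path(fx$dir, "ckpt"), carry_over = TRUE)
  run_query(qc)
  det <- sink_read(qc$sink_path)
  det <- det[order(det$r_index), ]
  expect_identical(det$r_index, batch$r_index)
  expect_identical(det$label, batch$label)
})

test_that("without carry-over each packet stands alone", {
  fx <- local_stream_fixture(seconds_each = 20, seed = 70)
  qc <- query_config(fx$src, fx$model_path,
                     file.path(fx$dir, "sink2.csv"),
                     file.path(fx$dir, "ckpt2"), carry_over = FALSE)
  run_query(qc)
  det <- sink_read(qc$sink_path)
  # every beat window must fit inside its own packet
  for (i in seq_len(nrow(det))) {
    local_r <- det$r_index[i] %% 1800
    expect_gte(local_r, 69)
  }
  # strict per-packet reading finds no fewer batches
  expect_equal(sort(unique(det$packet_index)),
               0:(open_stream(fx$src)$n_packets - 1))
})

test_that("sink writes are idempotent per packet and append in order", {
  td <- withr::local_tempdir()
  sink <- file.path(td, "sink.csv")
  p0 <- data.frame(packet_index = 0L, record = "r", r_index = c(100L, 400L),
                   label = c("NORMAL", "AF"))
  p1 <- data.frame(packet_index = 1L, record = "r", r_index = 2000L,
                   label = "RBBB")
  expect_true(sink_write(p0, sink))
  n1 <- nrow(sink_read(sink))
  expect_false(sink_write(p0, sink))  # re-delivery is a no-op
  expect_equal(nrow(sink_read(sink)), n1)
  expect_true(sink_write(p1, sink))
  det <- sink_read(sink)
  expect_equal(det$packet_index, c(0L, 0L, 1L))
  expect_equal(det$label, c("NORMAL", "AF", "RBBB"))
  expect_equal(det$r_index, c(100L, 400L, 2000L))
})

test_that("crash at any stage boundary preserves exactly-once delivery", {
  fx <- local_stream_fixture(seconds_each = 35, seed = 80)
  batch <- batch_pipeline(fx$ds$signal, fx$model)
  n_pk <- open_stream(fx$src)$n_packets
  expect_gte(n_pk, 20)
  for (stage in c("before_sink", "after_sink", "after_checkpoint")) {
    for (crash_pk in c(0L, 7L, n_pk - 1L)) {
      wd <- withr::local_tempdir()
      qc <- query_config(fx$src, fx$model_path,
                         file.path(wd, "sink.csv"), file.path(wd, "ckpt"))
      expect_error(
        run_query(qc, fail_at = list(packet_index = crash_pk, stage = stage)),
        "injected crash")
      res2 <- run_query(qc)  # restart from the checkpoint
      det <- sink_read(qc$sink_path)
      det <- det[order(det$r_index), ]
      expect_identical(det$r_index, batch$r_index,
                       info = paste(stage, crash_pk))
      expect_identical(det$label, batch$label, info = paste(stage, crash_pk))
      expect_equal(anyDuplicated(det$r_index), 0)
      # checkpointed batches are not re-produced after restart; a batch whose
      # sink write landed but whose checkpoint did not is reprocessed (its
      # re-delivery is a no-op)
      done_before <- if (stage == "after_checkpoint") crash_pk + 1L
                     else crash_pk
      expected_idx <- if (done_before <= n_pk - 1L) {
        seq.int(done_before, n_pk - 1L)
      } else integer(0)
      expect_equal(vapply(res2$results, `[[`, integer(1), "packet_index"),
                   expected_idx)
    }
  }
})

test_that("committed packet indices form a contiguous prefix at all times", {
  fx <- local_stream_fixture(seconds_each = 20, seed = 90)
  qc <- query_config(fx$src, fx$model_path,
                     file.path(fx$dir, "sink3.csv"),
                     file.path(fx$dir, "ckpt3"))
  expect_error(run_query(qc, fail_at = list(packet_index = 5L,
                                            stage = "after_sink")),
               "injected crash")
  ck <- ecgstream:::read_checkpoint(qc)
  det <- sink_read(qc$sink_path)
  expect_equal(sort(unique(det$packet_index)), 0:5)   # sink ahead by one
  expect_equal(ck$last_committed, 4L)                  # checkpoint behind
  run_query(qc)
  ck2 <- ecgstream:::read_checkpoint(qc)
  expect_equal(ck2$last_committed, open_stream(fx$src)$n_packets - 1L)
})

test_that("a poisoned packet is quarantined and the stream continues", {
  fx <- local_stream_fixture(seconds_each = 20, seed = 95)
  # corrupt packet 1 in place
  bad <- file.path(fx$src, "packet_00001.csv")
  writeLines(c("# fs=360 start_sample=1800 record=stream", "value_mv",
               "0.1", "not-a-number", "0.2"), bad)
  qc <- query_config(fx$src, fx$model_path,
                     file.path(fx$dir, "sink4.csv"),
                     file.path(fx$dir, "ckpt4"), carry_over = FALSE)
  res <- suppressMessages(run_query(qc))
  expect_equal(res$quarantined, 1L)
  det <- sink_read(qc$sink_path)
  expect_false(1L %in% det$packet_index)
  expect_true(all(setdiff(0:(open_stream(fx$src)$n_packets - 1), 1L) %in%
                    det$packet_index))
})

test_that("progress reports carry per-batch stage timings", {
  fx <- local_stream_fixture(seconds_each = 20, seed = 97)
  qc <- query_config(fx$src, fx$model_path,
                     file.path(fx$dir, "sink5.csv"),
                     file.path(fx$dir, "ckpt5"))
  res <- run_query(qc)
  td <- withr::local_tempdir()
  rep <- progress_report(res$results, path = file.path(td, "timings.csv"))
  expect_equal(nrow(rep), open_stream(fx$src)$n_packets)
  expect_true(all(rep$read_ms >= 0 & rep$compute_ms >= 0 & rep$sink_ms >= 0))
  expect_true(all(rep$total_ms >= pmax(rep$read_ms, rep$compute_ms,
                                       rep$sink_ms)))
  sm <- attr(rep, "summary")
  expect_equal(unname(sm["total_ms"]), mean(rep$total_ms))
  expect_true(file.exists(file.path(td, "timings.csv")))
  expect_error(progress_report(list()), "no batches")
})
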