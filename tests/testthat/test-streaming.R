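test_that("accelerated playback processes every generated epoch exactly once", {
  sf <- small_fixture()
  st <- run_stream(sf$recording, 16, sf$model, sf$baseline,
                   keep_epochs = TRUE)
  expect_identical(st$epochs_generated, 40L)
  expect_identical(st$epochs_captured, 40L)
  expect_identical(st$epochs_processed, 40L)
  expect_identical(st$epochs_lost, 0L)
  expect_identical(st$epoch_loss_fraction, 0)
  expect_identical(sort(st$predictions$epoch_index), 0:39)
  expect_identical(sum(st$label_histogram), st$epochs_processed)
  expect_null(st$error)
})

test_that("processed epochs are bit-exact slices of the source recording", {
  sf <- small_fixture()
  st <- run_stream(sf$recording, 16, sf$model, sf$baseline,
                   max_epochs = 5, keep_epochs = TRUE)
  n_per <- 16 * 256
  for (j in seq_along(st$processed_epochs)) {
    i <- st$predictions$epoch_index[j]
    expect_identical(st$processed_epochs[[j]],
                     sf$recording$samples[(i * n_per + 1):((i + 1) * n_per)])
  }
})

test_that("max_epochs caps the stream and a single epoch yields one count", {
  sf <- small_fixture()
  st <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 1)
  expect_identical(st$epochs_processed, 1L)
  expect_identical(sum(st$label_histogram), 1L)
})

test_that("overflow follows the counted drop-oldest policy", {
  sf <- small_fixture()
  # service time twice the collection time, capacity 4:
  # hand-simulated schedule drops epochs 4 and 6 of 12 and processes 10
  st <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 12,
                   buffer_capacity = 4, simulated_proc_time_s = 32)
  expect_identical(st$epochs_generated, 12L)
  expect_identical(st$epochs_processed, 10L)
  expect_identical(st$epochs_lost, 2L)
  expect_identical(setdiff(0:11, st$predictions$epoch_index), c(4L, 6L))
  # conservation after the final drain
  expect_identical(st$epochs_generated, st$epochs_processed + st$epochs_lost)
  # loss begins only once more than `capacity` epochs are pending:
  # with 8 arrivals nothing is dropped yet, the 9th arrival forces a drop
  st8 <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 8,
                    buffer_capacity = 4, simulated_proc_time_s = 32)
  expect_identical(st8$epochs_lost, 0L)
  st9 <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 9,
                    buffer_capacity = 4, simulated_proc_time_s = 32)
  expect_identical(st9$epochs_lost, 1L)
})

test_that("the zero-loss guarantee holds while processing outpaces collection", {
  sf <- small_fixture()
  # even a large simulated service time below the epoch length loses nothing
  st <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 20,
                   buffer_capacity = 2, simulated_proc_time_s = 15.9)
  expect_identical(st$epochs_lost, 0L)
  expect_identical(st$epochs_processed, 20L)
})

test_that("live_report is a pure rendering of the stats", {
  sf <- small_fixture()
  st <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 3)
  before <- st
  txt <- capture.output(live_report(st))
  expect_identical(st, before)
  expect_true(any(grepl("3/3/3", txt)))
  expect_true(any(grepl("histogram", txt)))
  # empty stream renders all-zero counts
  st0 <- run_stream(sf$recording, 16, sf$model, sf$baseline, max_epochs = 0)
  txt0 <- capture.output(live_report(st0))
  expect_true(any(grepl("0/0/0", txt0)))
  expect_identical(sum(st0$label_histogram), 0L)
})

test_that("timing profile reports analytic collection time and cumulative processing", {
  sf <- small_fixture()
  tp <- timing_profile(sf$recording, sf$model, sf$baseline,
                       n_epochs = c(1, 10, 20), epoch_length_s = 16)
  expect_identical(tp$collection_time_s, c(16, 160, 320))
  expect_true(all(diff(tp$processing_time_s) >= 0))
  expect_equal(tp$processing_pct_of_collection,
               100 * tp$processing_time_s / tp$collection_time_s)
})

test_that("the hardware-loop source streams the quantized signal", {
  sf <- small_fixture()
  src <- hardware_loop_source(sf$recording)
  st <- run_stream(src, 16, sf$model, sf$baseline, max_epochs = 10)
  expect_identical(st$epochs_processed, 10L)
  expect_identical(st$epoch_loss_fraction, 0)
  # quantization is mild: predictions still reflect the class structure
  expect_gte(mean(st$predictions$label ==
                    sf$labels$label[st$predictions$epoch_index + 1]), 0.9)
})
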