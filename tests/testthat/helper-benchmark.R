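# Shared fixture for the end-to-end screening benchmark: one 2,000-phantom
# corpus (side 100, balanced referable / non-referable), preprocessed once
# per session and cached on disk so several training runs can reuse it.

BENCH_SEED <- 20260L
ORDERING_EPOCHS <- 4L

benchmark_data_path <- function() {
  path <- file.path(tempdir(), sprintf("entropyDR-bench-%d.rds", BENCH_SEED))
  if (!file.exists(path)) {
    corpus <- benchmark_corpus(1000L, side = 100L, seed = BENCH_SEED)
    data <- preprocess_corpus(corpus)
    saveRDS(data, path)
  }
  path
}
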