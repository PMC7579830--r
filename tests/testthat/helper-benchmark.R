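# The scaled CV benchmark is shared by several acceptance checks
# (recovery, ablation direction, length direction); compute it once per
# test session and cache.
.bench_cache <- new.env(parent = emptyenv())

scaled_benchmark <- function() {
  if (is.null(.bench_cache$grid))
    .bench_cache$grid <- synthetic_benchmark(seeds = 1:5)
  .bench_cache$grid
}
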