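# Independent oracles used across the suite; deliberately brute-force and
# kept separate from the implementation paths they check.

# all coordinates of a (possibly origin-wrapping) inclusive range
range_coords <- function(start, end, L) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, L), seq.int(1, end))
}

# maximum overlap depth of half-open pixel intervals, by sweep line
sweep_max_depth <- function(x_start, x_end) {
  if (!length(x_start)) return(0L)
  ev <- rbind(data.frame(x = x_start, d = 1L), data.frame(x = x_end, d = -1L))
  ev <- ev[order(ev$x, ev$d), ]  # ends (-1) before starts (+1) at ties
  max(cumsum(ev$d))
}

# small deterministic fixture genome shared by layout/navigation tests
small_fixture <- function(seed = 11L, n_operons = 8L) {
  generate_synthetic_genome(fixture_spec(seed = seed, n_operons = n_operons))$replicon
}

# unclamped span a wrapped view would cover (overview-level contract)
raw_span_for_test <- function(v) v$n_lines * bases_per_line(v)

# tiny hand-built replicon with a known sequence
toy_replicon <- function(topology = "circular", L = 1000L) {
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  replicon("toy", L, topology, sequence = seq)
}
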