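# Shared fixtures, built in code. The germline reference is deterministic
# for a given seed, so one cached copy serves the whole suite.

tiny_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_germline_set(seed = 42)
    cache
  }
})

# Merged-read (primer-trimmed, N-gap-masked) form of a full rearrangement.
merged_form <- function(ref, full_sequence, read_length = 112L) {
  merged_coords(amplicon_of(ref, full_sequence), ref, read_length)$sequence
}

# Small study-shaped simulation used by several files.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_run(simulation_config(
        seed = 11, n_samples = 3, n_groups = 4, n_unproductive = 1,
        group_sizes = c(3, 2, 2, 2), coverage = 800,
        contamination = c(0.2, 0.4), migration_rate = 0.4,
        sequencing_error_rate = 0, low_quality_read_fraction = 0.02))
    }
    cache
  }
})
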