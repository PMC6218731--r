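# Shared fixtures: small synthetic datasets built once per test run.

# a clean, fully deterministic configuration: no noise, no wander, no
# artifacts, no morphology jitter, fixed heart rate
clean_config <- function(n_cases = 4, segments_per_case = 3, seed = 7,
                         hr = 60, mix = c(1, 1, 1) / 3) {
  synth_config(n_cases = n_cases, segments_per_case = segments_per_case,
               category_mix = mix, seed = seed,
               noise_sd = 0, wander_amp = 0, artifact_rate = 0,
               morph_jitter = c(0, 0, 0), heart_rate_range = c(hr, hr))
}

# memoized datasets, so expensive generation runs once per R session
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

clean_dataset <- function() {
  fixture("clean", function() generate_dataset(clean_config()))
}

default_dataset <- function() {
  fixture("default", function()
    generate_dataset(synth_config(n_cases = 10, segments_per_case = 20,
                                  seed = 11)))
}

# one clean normalized pulse for feature unit tests
triangle_pulse <- function(n = 101) {
  normalize_pulse(c(seq(0, 1, length.out = (n + 1) / 2),
                    seq(1, 0, length.out = (n + 1) / 2)[-1]), n_points = n)
}
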