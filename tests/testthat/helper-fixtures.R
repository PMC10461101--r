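## Shared synthetic fixtures. Expensive end-to-end runs are built once per
## session and cached; every fixture is generated in code at test time.

tiny_config <- function(seed = 101L, ...) {
  args <- list(seed = seed, n_chrom = 2L, chrom_length = 30000L,
               n_known_mirnas = 2L, n_novel_mirnas = 4L,
               n_genes = 40L, n_tfs = 4L, depth = 800L,
               targets_per_mirna = rep(2L, 4L), n_coexpr = 1L,
               transcript_len = 300L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## tiny zero-noise end-to-end run: exact truth recovery expected
tiny_zn_run <- function() cached("tiny_zn", function() {
  cfg <- zero_noise_config(tiny_config(seed = 101L))
  simulate_and_run(101L, dir = tempfile("znrun"), cfg = cfg)
})

## tiny default-noise end-to-end run
tiny_noise_run <- function() cached("tiny_noise", function() {
  simulate_and_run(102L, dir = tempfile("nrun"),
                   cfg = tiny_config(seed = 102L))
})

## study-sized zero-noise run: 12 novel miRNAs carrying 39 target pairs
full_zn_run <- function() cached("full_zn", function() {
  cfg <- zero_noise_config(synthetic_config(seed = 401L, depth = 4000L))
  simulate_and_run(401L, dir = tempfile("fullzn"), cfg = cfg)
})

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
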