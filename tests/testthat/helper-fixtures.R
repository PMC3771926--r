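# Shared pipeline runs, built lazily once per test session and reused
# across test files.

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Fig.-2-style topology: 3 families of 5 plus one sequence carrying all
# three domains
chaining_run <- function() {
  fixture("chaining", function() {
    ds <- generate_dataset(n_families = 3, members_per_family = 5,
                           multi_domain_fraction = 1 / 15,
                           remote_fraction = 0, seed = 21)
    multi <- names(which(table(ds$annotations$seq_id) > 1))
    dir <- file.path(tempdir(), "conregid-chaining")
    suppressMessages(
      run_pipeline(ds$sequences, dir, pipeline_config(seed = 33)))
    list(ds = ds, dir = dir, multi = multi)
  })
}

# planted-domain recovery study: 6 families x 30 members, 10%
# multi-domain, 15% remote
recovery_run <- function() {
  fixture("recovery", function() {
    ds <- generate_dataset(seed = 101)
    dir <- file.path(tempdir(), "conregid-recovery")
    suppressMessages(
      run_pipeline(ds$sequences, dir, pipeline_config(seed = 101)))
    list(ds = ds, dir = dir)
  })
}

# single 250-member family, split by the max-group rule upstream
family250_run <- function() {
  fixture("family250", function() {
    ds <- generate_dataset(n_families = 1, members_per_family = 250,
                           multi_domain_fraction = 0, seed = 77)
    dir <- file.path(tempdir(), "conregid-family250")
    suppressMessages(
      run_pipeline(ds$sequences, dir, pipeline_config(seed = 77)))
    list(ds = ds, dir = dir)
  })
}
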