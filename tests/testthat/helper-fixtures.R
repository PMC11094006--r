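# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# 30-species / 3-phyla catalog used throughout
fx_taxonomy <- function() {
  fixture("tax", make_reference_taxonomy(3, 30, seed = 101))
}

fx_refs <- function() {
  fixture("refs", synthesize_marker_references(fx_taxonomy(), gene_length = 900,
                                               seed = 101))
}

fx_db <- function() fixture("db", as_ref_db(fx_refs()))

# pairwise identity matrix over the 30 reference markers
fx_ref_identity <- function() {
  fixture("refid", {
    seqs <- fx_refs()$sequences
    n <- length(seqs)
    m <- diag(1, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
      }
    }
    dimnames(m) <- list(names(seqs), names(seqs))
    m
  })
}

# 12-sample synthetic spring survey (acidic vs alkaline), moderate depth
fx_dataset <- function() {
  fixture("ds", {
    tax <- fx_taxonomy()
    simulate_springs(tax, spring_scenario(tax, n_samples = 12,
                                          reads_per_sample = 2e4, seed = 202))
  })
}

# full pipeline result on fx_dataset (computed once; reused by several tests)
fx_profile <- function() {
  fixture("profile", profile_community(fx_dataset(), seed = 303))
}

# tiny two-genus taxonomy for ambiguity fixtures
fx_make_raw_refs <- function(sequences, lineage_rows) {
  structure(list(sequences = sequences, lineages = lineage_rows),
            class = "marker_refs")
}
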