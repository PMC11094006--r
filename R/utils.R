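# Internal helpers shared across modules.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIX <- c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
                 family = "f__", genus = "g__", species = "s__")
DNA_ALPHABET <- c("A", "C", "G", "T")

#' @noRd
abort <- function(..., class = "springcomm_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Run code with a temporarily fixed RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `code`, and restores the previous state on exit, so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed. Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 69069 + stream * 1234567) %% 2147483647
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort("'", name, "' must be a single integer >= ", min)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi ||
      (lo_open && x == lo)) {
    abort("'", name, "' must be a single number in ",
          if (lo_open) "(" else "[", lo, ", ", hi, "]")
  }
  as.numeric(x)
}

check_sequence <- function(x, name = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    abort("'", name, "' must be a single non-empty string")
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_ALPHABET)) {
    bad <- unique(chars[!chars %in% DNA_ALPHABET])
    abort("'", name, "' contains characters outside A/C/G/T: ",
          paste(bad, collapse = ", "))
  }
  x
}

random_dna <- function(length) {
  paste(sample(DNA_ALPHABET, length, replace = TRUE), collapse = "")
}

# Jukes-Cantor site-wise mutation: branch length t in expected substitutions
# per site; each site changes to one of the other three bases with the exact
# JC marginal probability 3/4 (1 - exp(-4t/3)).
mutate_jc <- function(seq, t) {
  if (t <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    idx <- which(hit)
    cur <- chars[idx]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_ALPHABET, b), 1L), "")
    chars[idx] <- repl
  }
  paste(chars, collapse = "")
}

# JC divergence (per-branch, leaf to ancestor) that yields expected leaf-leaf
# identity `id` between two tips whose paths to the common ancestor are
# independent: identity = 1/4 + 3/4 exp(-4 (2t)/3).
jc_branch_length <- function(id) {
  if (id <= 0.25) abort("target identity must exceed 0.25 for a JC model")
  -(3 / 8) * log((4 * id - 1) / 3)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Minimal deterministic FASTA writer (60-column wrap) used so that simulator
# outputs are byte-identical across runs.
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  nm <- names(seqs)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", nm[i]), con, sep = "\n")
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con, sep = "\n")
  }
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}
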