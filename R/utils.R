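# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators take explicit seeds; none
# leaks state into the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Normalize a nucleotide string: uppercase, U -> T. Errors on anything
# outside {A, C, G, T, U, N}. N never counts as G downstream.
norm_seq <- function(sequence) {
  if (is(sequence, "XString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "U", toupper(sequence))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    stop("illegal sequence characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single positive count
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
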