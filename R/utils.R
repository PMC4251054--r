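# Shared internal helpers.

# Deterministic integer in [0, 2^31) derived from a string and a salt.
# Used to give every URL its own reproducible probe stream without
# consuming the global RNG. FNV-1a style accumulation in double precision
# (exact below 2^53), reduced mod 2^31 - 1.
hash_seed <- function(x, salt = 0L) {
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(paste0(s, ":", salt))) {
      h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2147483647
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Run code with a private RNG state, restoring the caller's afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# ASCII transliteration of the kind affiliation strings need ("hôpital" ->
# "hopital"); case preserved.
to_ascii <- function(x) {
  stringi::stri_trans_general(x, "Latin-ASCII")
}

assert_df_cols <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
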