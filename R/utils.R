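`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic stream splitting; result always a valid 32-bit seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483587 * 48271 + as.numeric(k) * 10007) %%
               2147483587)
}

is_date <- function(x) inherits(x, "Date")

as_iso_date <- function(x, what = "date") {
  if (is_date(x)) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(out) && !anyNA(x))
    stop("could not parse ", what, " as ISO-8601 (YYYY-MM-DD): ",
         paste(utils::head(as.character(x)[is.na(out)], 3), collapse = ", "),
         call. = FALSE)
  out
}
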