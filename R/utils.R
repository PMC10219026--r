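#' @keywords internal
"_PACKAGE"

.snptata_cache <- new.env(parent = emptyenv())

cache_get <- function(key, value) {
  if (!exists(key, envir = .snptata_cache, inherits = FALSE)) {
    assign(key, value, envir = .snptata_cache)
  }
  get(key, envir = .snptata_cache, inherits = FALSE)
}

# Deterministic 31-bit sub-seed derived from a global seed and a stable
# stream label, so each sub-generator has its own reproducible stream and
# adding a generator does not perturb existing ones.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 1000003L
  as.integer((as.numeric(seed) * 1009 + h * 9176) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}
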