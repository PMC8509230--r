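# Internal helpers shared across stages.

# Derive reproducible per-stage seeds from one master seed. Stages consume
# substreams by name so toggling one stage never perturbs another.
.stage_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

# Config hash for provenance stamps in artifacts; base tools only.
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

.assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi), call. = FALSE)
  invisible(x)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}
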