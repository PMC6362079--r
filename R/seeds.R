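# Deterministic seed fan-out. A master seed plus a tag path yields a child
# seed below 2^31 so each stage/record can be re-run in isolation without
# consuming the global RNG stream in a position-dependent way.

seed_child <- function(seed, ...) {
  tags <- unlist(lapply(list(...), function(t) {
    if (is.character(t)) utf8ToInt(t) else as.integer(t)
  }))
  h <- as.double(seed %% 2147483647L)
  for (k in tags) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
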