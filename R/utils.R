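#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so simulation helpers never perturb
# the session stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic 31-bit hash of a character key, used to derive independent
# per-sample seeds from one scenario seed. Adding samples to a design never
# perturbs the draws of existing ones.
hash_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(paste0(":", key))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort2 <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cafcyto_error")))
}
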