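# Internal helpers shared across modules.

# Deterministic substream seed: mixes a master seed with a task label so that
# adding one simulation task never perturbs the draws of another.  FNV-1a on
# the label, folded into the master seed and kept inside the 32-bit integer
# range R requires of set.seed().
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 5381
  for (b in utf8ToInt(as.character(tag))) {
    # polynomial rolling hash kept inside the exact-double integer range
    h <- (h * 127 + b) %% 2147483629
  }
  as.integer((abs(master) + h) %% 2147483647)
}

# FNV-1a hash of an arbitrary R object (via its JSON serialization), used to
# stamp outputs with a short provenance hash of the configuration.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 127 + b) %% 2147483629
  }
  sprintf("%08x", h)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# one minus exp(-x) without cancellation for small x
one_m_exp <- function(x) -expm1(-x)

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
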