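# Internal helpers shared across modules.

# Canonical string key for an edge matrix whose rows are already sorted
# pairs. Protein ids come from tab-separated files, so a tab is a safe
# separator.
edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  paste(edges[, 1L], edges[, 2L], sep = "\t")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream label,
# so each sub-generator draws from its own stream.
derive_seed <- function(seed, stream) {
  offs <- c(network = 101L, modules = 211L, orthology = 307L,
            localization = 401L, expression = 503L, essential = 601L,
            retry = 701L, shuffle = 809L)
  off <- offs[[stream]]
  as.integer((as.numeric(seed) * 1103L + off * 12289L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
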