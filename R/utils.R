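# Internal constants and helpers shared across modules.

# IUPAC nucleotide codes and their expansions into unambiguous bases.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

BASES <- c("A", "C", "G", "T")
MISSING_STATES <- c("N", "?", "-")
ALLOWED_ALPHABET <- c(names(IUPAC_EXPANSION), "-", "?")
BACKGROUND_LABEL <- "BACKGROUND"

is_missing_state <- function(x, gaps_new = FALSE) {
  miss <- if (gaps_new) c("N", "?") else MISSING_STATES
  x %in% miss
}

# Ambiguity codes other than the four bases (N is handled as missing).
is_ambiguity_code <- function(x) {
  x %in% setdiff(names(IUPAC_EXPANSION), c(BASES, "N"))
}

# Does observed state `x` possibly equal base `b`? TRUE for b itself and for
# any ambiguity code whose expansion contains b. Missing states are handled
# upstream and never reach this predicate.
state_could_match <- function(x, b) {
  exp <- IUPAC_EXPANSION[x]
  vapply(seq_along(x), function(i) {
    e <- exp[[i]]
    !is.null(e) && b[i] %in% e
  }, logical(1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points funnel through this
# so a single integer seed makes whole runs reproducible.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable polynomial hash of a label, folded into [0, 2^31 - 2]. Used to
# derive independent per-taxon RNG streams from one root seed, so adding a
# query taxon does not perturb the results for the others. Exact in double
# arithmetic: intermediate values stay below 2^53.
stable_hash <- function(label) {
  h <- 17
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

derive_seed <- function(root_seed, label) {
  as.integer((as.numeric(root_seed) + stable_hash(label)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
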