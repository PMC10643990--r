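# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# The four joint occupancy states of the two neighboring insertion sites
# (site "a" first, site "d" second), in fixed index order.
OCC_STATES <- c("--", "-D", "A-", "AD")

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Approximate residue composition of halophilic archaeal proteomes: acidic
# residues (D, E) are strongly over-represented relative to K/R.  Used as the
# default scaffold composition for synthetic sequences.
HALO_AA_FREQ <- c(
  A = 0.095, C = 0.008, D = 0.095, E = 0.085, F = 0.035, G = 0.085,
  H = 0.020, I = 0.040, K = 0.025, L = 0.075, M = 0.018, N = 0.030,
  P = 0.045, Q = 0.030, R = 0.060, S = 0.060, T = 0.060, V = 0.085,
  W = 0.012, Y = 0.037
)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible sub-seed from a master seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
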