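#' Round half-up
#'
#' Rounds to `digits` decimal places with exact halves rounded away from
#' zero (for non-negative input, upward). Base [round()] is round-half-even,
#' which does not match how clinical tables conventionally print
#' percentages (e.g. 17/392 x 100 = 4.336... prints as 4.3 but
#' 4.35 would print as 4.4, never 4.3).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.25, 1)  # 2.3, where round(2.25, 1) gives 2.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Normalisation key used everywhere a disease or marker name is compared:
# case-insensitive, leading/trailing/internal whitespace collapsed.
canonical_key <- function(x) {
  tolower(stringr::str_squish(as.character(x)))
}

# Likelihood guard: keeps a single atypical result from annihilating a
# candidate (and protects user-supplied numeric frequencies of 0 or 1).
clamp01 <- function(p, eps = 0.01) {
  pmin(pmax(p, eps), 1 - eps)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All simulator entry points run inside this.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream-splitting: one user-facing seed, one sub-stream per
# generator stage, kept inside 32-bit integer range.
split_seed <- function(seed, stage) {
  s <- (abs(as.double(seed)) %% 1e7) * 131 + stage * 7919
  as.integer(s %% 2147483647)
}

# Percentage formatted the way differentials are displayed: half-up, one
# decimal. `p` is a probability on [0, 1].
format_pct <- function(p) {
  sprintf("%.1f", round_half_up(100 * p, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
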