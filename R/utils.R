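#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derived stream seed that stays inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream)) %% 2147483559L) + 1L
}

# Truncated-normal sampler by inverse-CDF (lower truncation only or both).
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Column-standardize a matrix (center, unit SD); constant columns become 0.
standardize_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  s[s < .Machine$double.eps] <- 1
  sweep(x, 2L, s, "/")
}
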