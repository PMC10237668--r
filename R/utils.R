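#' @keywords internal
"_PACKAGE"

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: one root seed, one documented offset per
# stochastic operation (see derive_seed() callers). Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}

# Multivariate normal draws / log-density via Cholesky (small dimensions only).
rmvnorm_chol <- function(n, mean, chol_cov) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol_cov, 2, mean, `+`)
}

dmvnorm_chol_log <- function(x, mean, chol_cov) {
  d <- length(mean)
  xc <- sweep(x, 2, mean, `-`)
  # solve t(R) y = t(xc) where cov = t(R) R
  y <- backsolve(chol_cov, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * colSums(y^2)
}

# FNV-1a 32-bit hash of a character scalar; used to stamp run artifacts.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)
    # h * 16777619 mod 2^32, split so intermediates stay exact in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cp <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "causalprosody_error")))
}
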