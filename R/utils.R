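`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ltf_invalid_parameter", "error")))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(name, " must be a single positive finite number")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_invalid(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

#' Derive a deterministic child seed from a root seed
#'
#' One root seed governs a whole simulated experiment; per-entity streams
#' (specimen, well, randomization) are derived by mixing integer indices
#' into the root so that entity k's draws do not depend on how many draws
#' entity k-1 consumed. All arithmetic stays below 2^53 so the result is
#' exact in doubles; the value returned is in [1, 2^31 - 2].
#'
#' @param seed integer root seed.
#' @param ... integer indices identifying the entity (specimen number, well
#'   number, ...); mixed in order.
#' @return a single integer usable with [set.seed()].
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483629
  for (k in seq_along(idx)) {
    h <- (h * 31259 + as.double(idx[k]) * 7919 + 104729 * k) %% 2147483629
  }
  as.integer(h + 1)
}

# Multiplicative lognormal noise factors with mean 1 and the requested
# coefficient of variation (cv in percent). cv = 0 returns exact ones.
lnorm_factor <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + (cv_percent / 100)^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Sample coefficient of variation in percent (n-1 denominator).
cv_percent <- function(x) 100 * stats::sd(x) / mean(x)

# FNV-1a hash of a character scalar; returned as 8 hex digits. Used for
# config fingerprints in manifests (no external digest dependency).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) # keep in int range
    h <- (as.double(bitwAnd(as.integer(h), 2147483647L)) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
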