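# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

tiny_panel <- function() {
  analyte_panel(c("IFN-gamma", "CXCL10", "IL-1Ra"),
                lloq = c(2.5, 1.5, 8), uloq = c(5000, 3000, 16000))
}

noise_free_kinetics <- function(...) {
  kinetics_spec(measurement_cv = 0, cv_at_200 = 0, ...)
}

# A well series built directly from (time, conc) vectors for one analyte.
make_series <- function(t_h, conc, analyte = "IFN-gamma",
                        schedule = data.frame(t_start_h = c(0, 20),
                                              t_end_h = c(20, 48),
                                              treatment = c("IgG", "ICI")),
                        censor = rep("none", length(t_h)),
                        specimen_id = "S001", well_id = "W1",
                        design = "sequential") {
  well_series(specimen_id, well_id, design, schedule,
              data.frame(t_h = t_h, analyte = analyte, conc_pg_ml = conc,
                         censor = censor, stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# Literal step-by-step MAD-trimmed modified Z-score, coded independently of
# the package implementation (explicit loops, no shared helpers).
oracle_modz <- function(x, trim_k = 2, scale_c = 0.6745, saturation = 10) {
  sorted <- sort(x)
  n <- length(sorted)
  med <- if (n %% 2 == 1) sorted[(n + 1) / 2] else
    (sorted[n / 2] + sorted[n / 2 + 1]) / 2
  devs <- sort(abs(x - med))
  mad0 <- if (n %% 2 == 1) devs[(n + 1) / 2] else
    (devs[n / 2] + devs[n / 2 + 1]) / 2
  trimmed <- if (mad0 > 0) x[abs(x - med) <= trim_k * mad0] else x
  ts <- sort(trimmed); nt <- length(ts)
  m_star <- if (nt %% 2 == 1) ts[(nt + 1) / 2] else
    (ts[nt / 2] + ts[nt / 2 + 1]) / 2
  tdev <- sort(abs(trimmed - m_star))
  mad_star <- if (nt %% 2 == 1) tdev[(nt + 1) / 2] else
    (tdev[nt / 2] + tdev[nt / 2 + 1]) / 2
  if (mad_star == 0) mad_star <- 1.4826 * sum(abs(trimmed - m_star)) / nt
  if (mad_star == 0) return(rep(0, length(x)))
  z <- scale_c * (x - m_star) / mad_star
  z[z > saturation] <- saturation
  z[z < -saturation] <- -saturation
  z
}

# Greedy minimum-variance (Ward) agglomeration by enumerating all merges;
# heights reported as sqrt(2 * delta ESS), the ward.D2 convention.
oracle_ward <- function(x) {
  groups <- lapply(seq_len(nrow(x)), identity)
  merges <- list(); heights <- numeric(0)
  while (length(groups) > 1) {
    best <- NULL; bestd <- Inf
    for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      A <- x[groups[[i]], , drop = FALSE]
      B <- x[groups[[j]], , drop = FALSE]
      d <- nrow(A) * nrow(B) / (nrow(A) + nrow(B)) *
        sum((colMeans(A) - colMeans(B))^2)
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <- sort(unlist(groups[best]))
    heights <- c(heights, sqrt(2 * bestd))
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Flatten an hclust merge table into the same sorted-leaf-set sequence.
hclust_merge_sets <- function(h) {
  lapply(seq_len(nrow(h$merge)), function(k) {
    f <- function(v) unlist(lapply(v, function(e)
      if (e < 0) -e else f(h$merge[e, ])))
    sort(f(h$merge[k, ]))
  })
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Closed-form OLS slope via the normal equations.
oracle_ols_slope <- function(t, y) {
  X <- cbind(1, t)
  solve(t(X) %*% X, t(X) %*% y)[2]
}
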