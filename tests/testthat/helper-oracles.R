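# Independent brute-force oracles used to cross-check the pipeline. These
# deliberately use lm()/dhyper()/combn() rather than any package internals.

# earliest qualifying 5-point window by evaluating EVERY window with lm()
oracle_catastrophe <- function(trace, t_init_s, threshold_nm_s = 150,
                               window = 5L) {
  t <- trace$time_s
  y <- trace$length_um * 1000
  i0 <- which(t >= t_init_s)[1]
  n <- length(t)
  starts <- i0:(n - window + 1L)
  for (s in starts) {
    idx <- s:(s + window - 1L)
    sl <- unname(coef(lm(y[idx] ~ t[idx]))[2])
    if (sl < -threshold_nm_s) return(t[s])
  }
  NA_real_
}

# least-squares two-segment changepoint on a single-switch trace
oracle_changepoint <- function(t, y) {
  n <- length(t)
  sse <- rep(Inf, n)
  for (k in 3:(n - 2)) {
    f1 <- lm(y[1:k] ~ t[1:k])
    f2 <- lm(y[k:n] ~ t[k:n])
    sse[k] <- sum(residuals(f1)^2) + sum(residuals(f2)^2)
  }
  which.min(sse)
}

# maximal three-rule window on each side of a known switch index, judged
# with lm(); returns a data frame of the (up to two) events. `last_idx`
# bounds the search to the moving part of the trace (before any clamp at
# zero length).
oracle_single_switch_events <- function(trace, switch_idx, min_points = 3L,
                                        min_delta_um = 0.5, min_r2 = 0.80,
                                        last_idx = length(trace$time_s)) {
  t <- trace$time_s; y <- trace$length_um
  n <- last_idx
  best_in <- function(lo, hi) {
    best <- NULL
    for (a in lo:(hi - min_points + 1L)) {
      for (b in (a + min_points - 1L):hi) {
        dl <- y[b] - y[a]
        if (abs(dl) < min_delta_um) next
        fit <- lm(y[a:b] ~ t[a:b])
        r2 <- summary(fit)$r.squared
        if (r2 < min_r2) next
        if (is.null(best) || (b - a) > (best$b - best$a))
          best <- list(a = a, b = b, dl = dl)
      }
    }
    best
  }
  out <- list()
  for (side in list(c(1L, switch_idx), c(switch_idx, n))) {
    if (side[2] - side[1] + 1L >= min_points) {
      bb <- best_in(side[1], side[2])
      if (!is.null(bb))
        out[[length(out) + 1L]] <- data.frame(
          kind = if (bb$dl > 0) "assembly" else "disassembly",
          start_idx = bb$a, end_idx = bb$b)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), start_idx = integer(), end_idx = integer())
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  combs <- combn(length(pooled), n)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  m <- ncol(combs)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p_value = min(1, p))
}

# exact two-sided Fisher p by hypergeometric enumeration
oracle_fisher <- function(tab) {
  k <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); s <- sum(tab[, 1])
  supp <- max(0, s - n2):min(m, s)
  probs <- dhyper(supp, m, n2, s)
  p_obs <- dhyper(k, m, n2, s)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# convenience: noiseless piecewise-linear growth-then-shrink trace
make_switch_trace <- function(v_grow_um_min, v_shrink_um_min, t_switch_s,
                              duration_s, dt_s, noise_sd_um = 0, seed = 1) {
  t <- seq(0, duration_s, by = dt_s)
  L <- ifelse(t <= t_switch_s, v_grow_um_min / 60 * t,
              pmax(v_grow_um_min / 60 * t_switch_s -
                     v_shrink_um_min / 60 * (t - t_switch_s), 0))
  L_true <- L
  if (noise_sd_um > 0) {
    set.seed(seed)
    L <- pmax(L + rnorm(length(L), 0, noise_sd_um), 0)
  }
  tr <- length_trace(t, L, frame_interval_s = dt_s)
  attr(tr, "truth") <- list(k_switch = max(which(t <= t_switch_s)),
                            k_floor = max(which(L_true > 0)))
  tr
}
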