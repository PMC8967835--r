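# Independent literal-formula oracles. These deliberately avoid the
# package's code paths: statistics are computed with explicit loops and
# first-principles formulas, the dip statistic by linear programming over
# unimodal CDFs, and AUC by exhaustive pairwise counting.

o_mean <- function(x) sum(x) / length(x)

o_sd <- function(x) {
  n <- length(x); m <- o_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (n - 1))
}

o_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

o_median <- function(x) {
  x <- sort(x); n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# type-7 (linear interpolation) quantile, written out
o_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

o_iqr <- function(x) o_quantile7(x, 0.75) - o_quantile7(x, 0.25)

o_entropy <- function(x, B) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  width <- (hi - lo) / B
  cnt <- integer(B)
  for (v in x) {
    b <- min(B, floor((v - lo) / width) + 1)
    cnt[b] <- cnt[b] + 1
  }
  h <- 0
  for (c_ in cnt) if (c_ > 0) {
    p <- c_ / length(x)
    h <- h - p * log(p)
  }
  h
}

o_acf <- function(x, k) {
  n <- length(x); m <- o_mean(x)
  den <- 0
  for (v in x) den <- den + (v - m)^2
  if (den == 0) return(0)
  num <- 0
  for (i in 1:(n - k)) num <- num + (x[i] - m) * (x[i + k] - m)
  num / den
}

o_maxfft <- function(window, fs, band = c(0.5, 3.5)) {
  x <- window - o_mean(window)
  mag <- Mod(stats::fft(x))
  n <- length(x)
  best_f <- NA_real_; best_m <- -Inf
  for (k in 1:floor(n / 2)) {
    f <- k * fs / n
    if (f >= band[1] && f <= band[2] && mag[k + 1] > best_m) {
      best_m <- mag[k + 1]; best_f <- f
    }
  }
  best_f
}

# ---- exact dip statistic by linear programming over unimodal CDFs ----
# For each candidate mode (a jump at a distinct sample point), minimize
# the sup-band half-width d over nondecreasing piecewise-linear CDFs that
# are convex left of the mode and concave right of it. A cheap
# convex-hull feasibility bound per placement prunes the LP calls.

o_lower_hull <- function(xs, ys) {
  n <- length(xs)
  if (n <= 2) return(ys)
  hull <- c(1L, 2L)
  for (i in 3:n) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      if ((ys[b] - ys[a]) * (xs[i] - xs[a]) >=
          (ys[i] - ys[a]) * (xs[b] - xs[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  stats::approx(xs[hull], ys[hull], xout = xs)$y
}
o_upper_hull <- function(xs, ys) -o_lower_hull(xs, -ys)

o_dip <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  v <- unique(x)
  m <- length(v)
  if (m == 1) return(0)
  cc <- cumsum(tabulate(match(x, v), m)) / n
  cprev <- c(0, cc[-m])

  left_ok <- function(d, p) {
    ub <- pmin(1, cprev[1:p] + d)
    lb <- pmax(0, c(if (p > 1) cc[1:(p - 1)], cprev[p]) - d)
    if (any(lb > ub + 1e-12)) return(FALSE)
    if (p == 1) return(TRUE)
    all(o_lower_hull(v[1:p], ub) >= lb - 1e-12)
  }
  right_ok <- function(d, p) {
    ub <- pmin(1, c(cc[p], if (p < m) cprev[(p + 1):m]) + d)
    lb <- pmax(0, cc[p:m] - d)
    if (any(lb > ub + 1e-12)) return(FALSE)
    if (p == m) return(TRUE)
    all(o_upper_hull(v[p:m], lb) <= ub + 1e-12)
  }
  lb_placement <- function(p) {
    lo <- 0; hi <- 0.5
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (left_ok(mid, p) && right_ok(mid, p)) hi <- mid else lo <- mid
    }
    lo
  }
  lp_placement <- function(p, lb_p) {
    pos <- c(v[1:p], v[p:m])
    lo <- c(if (p > 1) cc[1:(p - 1)], cprev[p], cc[p:m])
    hi <- c(if (p > 1) cprev[1:(p - 1)], cprev[p], cc[p],
            if (p < m) cprev[(p + 1):m])
    k <- length(pos)
    nv <- k + 1L
    A1 <- list(); b1 <- c(); A2 <- list(); b2 <- c()
    for (j in 1:k) {
      r <- numeric(nv); r[j] <- 1; r[nv] <- -1
      A1[[length(A1) + 1]] <- r; b1 <- c(b1, hi[j])
      r <- numeric(nv); r[j] <- 1; r[nv] <- 1
      A2[[length(A2) + 1]] <- r; b2 <- c(b2, lo[j])
    }
    for (j in 1:(k - 1)) {
      r <- numeric(nv); r[j] <- -1; r[j + 1] <- 1
      A2[[length(A2) + 1]] <- r; b2 <- c(b2, 0)
    }
    add_slope <- function(j, sign) {
      d1 <- pos[j + 1] - pos[j]; d2 <- pos[j + 2] - pos[j + 1]
      if (d1 <= 0 || d2 <= 0) return()
      # scaled by d1 d2 / (d1 + d2) so coefficients stay O(1) even for
      # nearly-tied support points (keeps the simplex well conditioned)
      r <- numeric(nv)
      r[j] <- -d2 / (d1 + d2); r[j + 1] <- 1; r[j + 2] <- -d1 / (d1 + d2)
      if (sign > 0) { A1[[length(A1) + 1]] <<- r; b1 <<- c(b1, 0) }
      else { A2[[length(A2) + 1]] <<- r; b2 <<- c(b2, 0) }
    }
    if (p >= 3) for (j in 1:(p - 2)) add_slope(j, +1)
    if (k - (p + 1) >= 2) for (j in (p + 1):(k - 2)) add_slope(j, -1)
    obj <- numeric(nv); obj[nv] <- 1
    A1m <- do.call(rbind, A1); A2m <- do.call(rbind, A2)
    # near-tied support points make the polytope ill-conditioned and the
    # dense simplex can return infeasible or impossible "solutions";
    # accept a solve only if its solution satisfies every constraint and
    # its value respects the placement's hull lower bound
    for (epsv in c(1e-10, 1e-8, 1e-6, 1e-11)) {
      res <- try(boot::simplex(a = obj, A1 = A1m, b1 = b1,
                               A2 = A2m, b2 = b2, maxi = FALSE,
                               eps = epsv), silent = TRUE)
      if (inherits(res, "try-error") || res$solved != 1) next
      sol <- res$soln
      viol <- max(c(A1m %*% sol - b1, b2 - A2m %*% sol, 0))
      if (viol < 1e-9 && res$value >= lb_p - 1e-9) return(res$value)
    }
    Inf
  }

  lbs <- vapply(1:m, lb_placement, numeric(1))
  ord <- order(lbs)
  best <- Inf
  for (p in ord) {
    if (lbs[p] >= best - 1e-12) break
    best <- min(best, lp_placement(p, lbs[p]))
  }
  best
}

o_dip_p <- function(x, B = 2000L) {
  d <- o_dip(x)
  null <- ppgaf:::dip_null_sample(length(x), B)
  (1 + sum(null >= d)) / (length(null) + 1)
}

# ---- exhaustive pairwise AUC ----
o_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
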