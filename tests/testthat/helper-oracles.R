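# Independent reference implementations used as oracles. They share no code
# with the package paths they check.

# Exhaustive-enumeration COW: tries every admissible placement of the sample
# segment boundaries and returns the best total correlation (same tie rule:
# minimal cumulative |stretch|).
cow_oracle <- function(ref, samp, segment_len, slack) {
  bounds <- murivoc:::cow_bounds(length(ref), segment_len)
  N <- length(bounds) - 1
  LS <- length(samp)
  dref <- diff(bounds)
  seg_corr <- function(u0, u1, x0, x1) {
    m <- u1 - u0 + 1
    pos <- seq(x0, x1, length.out = m)
    lo <- pmin(floor(pos), x1 - 1)
    fr <- pos - lo
    b <- (1 - fr) * samp[lo + 1] + fr * samp[lo + 2]
    a <- ref[(u0:u1) + 1]
    ac <- a - mean(a); bc <- b - mean(b)
    sa <- sqrt(sum(ac^2)); sb <- sqrt(sum(bc^2))
    if (sa < 1e-12 || sb < 1e-12) return(0)
    sum(ac * bc) / (sa * sb)
  }
  best <- NULL
  recurse <- function(i, x, score, stretch) {
    if (i == N) {
      if (x != LS - 1) return()
      if (is.null(best) || score > best$score + 1e-12 ||
          (score > best$score - 1e-12 && stretch < best$stretch))
        best <<- list(score = score, stretch = stretch)
      return()
    }
    for (d in max(1, dref[i + 1] - slack):(dref[i + 1] + slack)) {
      x2 <- x + d
      if (x2 > LS - 1) next
      recurse(i + 1, x2,
              score + seg_corr(bounds[i + 1], bounds[i + 2], x, x2),
              stretch + abs(d - dref[i + 1]))
    }
  }
  recurse(0, 0, 0, 0)
  best
}

# Closed-form PLS for a univariate centred response: the A-component
# coefficient vector is the least-squares solution restricted to the Krylov
# subspace span{X'y, (X'X)X'y, ...}.
krylov_pls <- function(Xc, yc, A) {
  s <- crossprod(Xc, yc)
  G <- crossprod(Xc)
  V <- matrix(0, ncol(Xc), A)
  for (a in seq_len(A)) {
    v <- if (a == 1) s else G %*% V[, a - 1]
    if (a > 1)
      v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1), drop = FALSE], v)
    V[, a] <- v / sqrt(sum(v^2))
  }
  V %*% solve(t(V) %*% G %*% V, t(V) %*% s)
}

# Two-sided exact Mann-Whitney p by full enumeration of all C(n, n1)
# equally likely rank assignments (tie-free inputs).
mw_enum_p <- function(a, b) {
  n1 <- length(a)
  vals <- c(a, b)
  rk <- rank(vals)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(vals), n1)
  us <- apply(idx, 2, function(ii) sum(rk[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
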