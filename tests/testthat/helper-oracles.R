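# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (explicit step-up, breadth-first
# flood fill, numerical quadrature, enumeration) and never call the code
# paths they verify.

# Benjamini-Hochberg step-up by explicit rank scan
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  below <- which(p[o] <= q * seq_len(m) / m)
  out <- rep(FALSE, m)
  if (length(below)) out[o[seq_len(max(below))]] <- TRUE
  out
}

# connected components by breadth-first flood fill
flood_oracle <- function(x, connectivity = 26) {
  dm <- dim(x)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs)
  lab <- array(0L, dm)
  cur <- 0L
  for (start in which(x)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue <- list(as.integer(arrayInd(start, dm)))
    while (length(queue)) {
      c0 <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- c0 + offs[k, ]
        if (all(nb >= 1) && all(nb <= dm) && x[nb[1], nb[2], nb[3]] &&
            lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cur
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition of the foreground
same_partition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0 | lab2 > 0]
  f2 <- lab2[lab1 > 0 | lab2 > 0]
  if (any(f1 == 0) || any(f2 == 0)) return(FALSE)
  all(tapply(f2, f1, function(v) length(unique(v))) == 1) &&
    all(tapply(f1, f2, function(v) length(unique(v))) == 1)
}

# least-squares CV score by numerical quadrature of the squared density
cv_quad_oracle <- function(values, h) {
  n <- length(values)
  fhat <- function(t) vapply(t, function(ti) mean(dnorm(ti, values, h)),
                             numeric(1))
  int <- integrate(function(t) fhat(t)^2,
                   min(values) - 12 * h, max(values) + 12 * h,
                   subdivisions = 5000L, rel.tol = 1e-10)$value
  loo <- vapply(seq_len(n),
                function(i) mean(dnorm(values[i], values[-i], h)),
                numeric(1))
  int - 2 * mean(loo)
}

# mixture CDF by numerical quadrature of the density
cdf_quad_oracle <- function(x, centers, weights, h) {
  integrate(function(t)
    vapply(t, function(ti) sum(weights * dnorm(ti, centers, h)), numeric(1)),
    lower = min(centers) - 14 * h, upper = x,
    subdivisions = 5000L, rel.tol = 1e-10)$value
}

# order-statistic quantiles by direct sorted interpolation (type 7)
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    hh <- (n - 1) * pp + 1
    lo <- floor(hh)
    if (lo >= n) return(s[n])
    s[lo] + (hh - lo) * (s[lo + 1] - s[lo])
  }, numeric(1))
}

# exact two-sided Wilcoxon signed-rank p by enumerating all sign patterns
wilcox_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small helper: map_stack from a matrix on a full cubic grid
toy_stack <- function(values, dim = NULL, modality = "CBF",
                      session = "baseline") {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (is.null(dim)) {
    n <- ncol(values)
    dim <- c(n, 1, 1)
  }
  map_stack(values, array(TRUE, dim), modality, session)
}
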