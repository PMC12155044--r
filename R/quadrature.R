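# Deterministic feature-adapted quadrature for the time-since-infection
# integral
#
#   p(y | lambda, a) = e^{-lambda a} p(y|m=0)
#                      + int_0^a lambda e^{-lambda tau} (1/K) sum_k p(y | f_k(tau)) dtau
#
# The integrand can be arbitrarily spiky in tau when the noise kernel is
# narrow (small nu, small eps), so the decay branch is integrated in the
# antibody-level domain m = f_k(tau) (change of variables through
# dtau = -dm / (alpha m^r)), with composite Gauss-Legendre panels whose
# boundaries track the exact support and transition points of the closed-form
# noise kernel. Two supplementary grids handle what the m-domain grid cannot:
# a log-spaced tau tail for the fully-decayed regime (m below a small
# fraction of the kernel scale, where the kernel is flat in m but the
# exposure weight e^{-lambda tau} still varies), and the rise branch
# (m = y0 e^{mu tau}). Node positions and coefficients are independent of
# lambda, so one precomputation serves every likelihood evaluation in an
# optimization run.

# Gauss-Legendre rule on [-1, 1] via the Golub-Welsch eigenproblem (cached)
.gl_cache <- new.env(parent = emptyenv())
.gl_rule <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1L) {
    rule <- list(x = 0, w = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- diag(0, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    rule <- list(x = e$values[ord], w = 2 * (e$vectors[1L, ord])^2)
  }
  .gl_cache[[key]] <- rule
  rule
}

# Composite GL nodes from a matrix of per-row sorted panel boundaries.
# B: n x (P+1), rows nondecreasing. Returns x, w matrices n x (P*G).
# Zero-width panels yield zero weights (their nodes are inert).
.gl_from_breaks <- function(B, G) {
  rule <- .gl_rule(G)
  n <- nrow(B)
  P <- ncol(B) - 1L
  half <- pmax(B[, -1L, drop = FALSE] - B[, -(P + 1L), drop = FALSE], 0) / 2
  mid <- (B[, -1L, drop = FALSE] + B[, -(P + 1L), drop = FALSE]) / 2
  idx <- rep(seq_len(P), each = G)
  xr <- rep(rule$x, times = P)   # recycled down columns via rep(..., each = n)
  wr <- rep(rule$w, times = P)
  halfE <- half[, idx, drop = FALSE]
  list(
    x = mid[, idx, drop = FALSE] + halfE * rep(xr, each = n),
    w = halfE * rep(wr, each = n)
  )
}

# enforce nondecreasing rows (guards rounding near clamped boundaries)
.row_cummax <- function(B) {
  for (p in 2:ncol(B)) B[, p] <- pmax(B[, p], B[, p - 1L])
  B
}

# row-wise sort of four vectors by compare-exchange network
.sort_rows4 <- function(a, b, c, d) {
  lo1 <- pmin(a, b); hi1 <- pmax(a, b)
  lo2 <- pmin(c, d); hi2 <- pmax(c, d)
  s1 <- pmin(lo1, lo2); t1 <- pmax(lo1, lo2)
  t2 <- pmin(hi1, hi2); s4 <- pmax(hi1, hi2)
  s2 <- pmin(t1, t2); s3 <- pmax(t1, t2)
  cbind(s1, s2, s3, s4, deparse.level = 0)
}

# row-wise sort of three vectors
.sort_rows3 <- function(a, b, c) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  s1 <- pmin(lo, c); t1 <- pmax(lo, c)
  s2 <- pmin(hi, t1); s3 <- pmax(hi, t1)
  cbind(s1, s2, s3, deparse.level = 0)
}

# row-wise sort of eight vectors (Batcher merge-exchange, 19 compare-exchanges)
.sort_rows8 <- function(v1, v2, v3, v4, v5, v6, v7, v8) {
  ce <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  v <- list(v1, v2, v3, v4, v5, v6, v7, v8)
  ce(1, 2); ce(3, 4); ce(5, 6); ce(7, 8)
  ce(1, 3); ce(2, 4); ce(5, 7); ce(6, 8)
  ce(2, 3); ce(6, 7); ce(1, 5); ce(4, 8)
  ce(2, 6); ce(3, 7)
  ce(2, 5); ce(4, 7)
  ce(3, 5); ce(4, 6)
  ce(4, 5)
  do.call(cbind, c(v, list(deparse.level = 0)))
}

# insert one more vector into a row-sorted matrix (bubble pass of
# compare-exchanges from the top)
.sort_rows_insert <- function(S, x) {
  P <- ncol(S)
  out <- matrix(0, nrow(S), P + 1L)
  for (p in P:1) {
    out[, p + 1L] <- pmax(S[, p], x)
    x <- pmin(S[, p], x)
  }
  out[, 1L] <- x
  out
}

# kinetics parameters of one draw as a plain list with the rise rate attached
.draw_par <- function(draws, k) {
  th <- as.list(draws[k, c("y0", "y1", "t1", "alpha", "r")])
  th$mu <- log(th$y1 / th$y0) / th$t1
  th
}

# branch-free trajectory/inverse for a single draw (r is scalar here):
# y(t) = y0 exp(mu min(t, t1)) * D(max(t - t1, 0)) with D the decay factor
.ab <- function(t, th) {
  dt <- pmax(t - th$t1, 0)
  base <- th$y0 * exp(th$mu * pmin(t, th$t1))
  d <- th$r - 1
  if (d < 1e-12) {
    base * exp(-th$alpha * dt)
  } else {
    base * exp(-log1p(d * th$alpha * th$y1^d * dt) / d)
  }
}

.ttl <- function(m, th) {
  d <- th$r - 1
  if (d < 1e-12) {
    th$t1 + log(th$y1 / m) / th$alpha
  } else {
    th$t1 + (exp(-d * log(m)) - th$y1^(-d)) / (th$alpha * d)
  }
}

# fraction of the kernel-center scale below which the m-domain grid hands
# over to the log-spaced tau tail
.TAIL_FRAC <- 0.02

# --- density nodes (uncensored observation y) --------------------------------
# Returns list(tau, coef): n x J matrices for one kinetics draw such that the
# draw's contribution to p(y|lambda,a) is lambda_d * rowSums(coef * exp(-lambda_d tau)).
.nodes_density_draw <- function(y, a_d, th, nu, sigma, G, Z, include_rise) {
  cc <- y * exp(1.5 * sigma^2)          # kernel center (upper transition)
  m_hi <- cc * exp(Z * sigma)           # kernel support, upper reach
  m_lo <- cc * exp(-Z * sigma) - nu     # kernel support, lower reach
  floor_m <- pmax(m_hi * 1e-18, 1e-300)

  # kernel feature points: edges of the uniform component and of the
  # lognormal bump (collapse onto {y - nu, y} when sigma = 0)
  F1 <- cc - nu - 2.5 * sigma * cc
  F2 <- cc - nu
  F3 <- cc * exp(-2.5 * sigma)
  F4 <- cc
  F5 <- cc * exp(2.5 * sigma)

  # decay branch, m-domain grid. Breakpoints merge two families: the noise
  # kernel's transition points (resolve narrow kernels) and the titres at
  # log-spaced times since peak (bound the variation of the exposure weight
  # and of the 1/(alpha m^r) Jacobian within each panel).
  f_a <- .ab(pmax(a_d, th$t1), th)                  # titre at the survey age
  lo_raw <- ifelse(a_d > th$t1, f_a, Inf)           # decay unattainable below
  hi <- pmin(th$y1, m_hi)
  # hand the sub-floor region to the tau-domain tail only when the kernel
  # support reaches all the way to 0 (unbounded 1/m^r otherwise); a positive
  # support edge is itself the natural grid floor
  floor_cc <- ifelse(m_lo > floor_m, 0, .TAIL_FRAC * cc)
  mg_lo <- pmin(hi, pmax(lo_raw, m_lo, floor_cc, floor_m))
  # geometric ladder above the grid floor: bounds the 1/m^r Jacobian ratio
  # per panel and resolves a kernel cut in its Gaussian tail by the age
  # truncation
  L1 <- mg_lo * (hi / mg_lo)^(1 / 3)
  L2 <- mg_lo * (hi / mg_lo)^(2 / 3)
  Td <- pmax(a_d - th$t1, 0)
  T1 <- .ab(th$t1 + 0.8 * Td, th)
  T2 <- .ab(th$t1 + 0.5 * Td, th)
  T3 <- .ab(th$t1 + 0.2 * Td, th)
  cl <- function(v) pmin(hi, pmax(v, mg_lo))
  S <- .sort_rows8(cl(F1), cl(F2), cl(F3), cl(F4), cl(F5), cl(L1), cl(L2), cl(T1))
  S <- .sort_rows_insert(S, cl(T2))
  S <- .sort_rows_insert(S, cl(T3))
  Bm <- .row_cummax(cbind(mg_lo, S, hi, deparse.level = 0))
  gm <- .gl_from_breaks(Bm, G)
  m <- pmax(gm$x, floor_m)
  tau_m <- pmin(.ttl(pmin(m, th$y1), th), a_d)
  kern_m <- .pmeas_density(y, m, nu, sigma) * exp(-(log(th$alpha) + th$r * log(m)))
  coef_m <- gm$w * kern_m

  # decay tail, tau-domain log-spaced grid from the m-grid handover to age
  t_c <- pmin(pmax(.ttl(mg_lo, th), th$t1), a_d)
  e1 <- pmax(t_c - th$t1, 0)
  e2 <- pmax(a_d - th$t1, 0)
  e1f <- pmax(e1, e2 * 1e-4)
  h1 <- th$t1 + exp((2 * log(e1f) + log(e2)) / 3)
  h2 <- th$t1 + exp((log(e1f) + 2 * log(e2)) / 3)
  Bt <- .row_cummax(cbind(t_c, pmax(h1, t_c), pmax(h2, t_c), pmax(a_d, t_c),
                          deparse.level = 0))
  gt <- .gl_from_breaks(Bt, G)
  coef_t <- gt$w * .pmeas_density(y, .ab(gt$x, th), nu, sigma)
  tau_t <- gt$x

  tau <- cbind(tau_m, tau_t, deparse.level = 0)
  coef <- cbind(coef_m, coef_t, deparse.level = 0)

  # rise branch, m-domain grid on (y0, f(min(t1, a)))
  if (include_rise) {
    r_hi <- pmin(th$y0 * exp(th$mu * pmin(th$t1, a_d)), m_hi)
    r_lo <- pmin(pmax(th$y0, m_lo, floor_m), r_hi)
    clr <- function(v) pmin(r_hi, pmax(v, r_lo))
    Sr <- .sort_rows4(clr(F2), clr(F3), clr(F4), clr(F5))
    Br <- .row_cummax(cbind(r_lo, Sr, r_hi, deparse.level = 0))
    gr <- .gl_from_breaks(Br, G)
    mr <- pmax(gr$x, floor_m)
    tau_r <- pmin(log(mr / th$y0) / th$mu, a_d)
    coef_r <- gr$w * .pmeas_density(y, mr, nu, sigma) / (th$mu * mr)
    tau <- cbind(tau, tau_r, deparse.level = 0)
    coef <- cbind(coef, coef_r, deparse.level = 0)
  }
  coef[!is.finite(coef)] <- 0
  list(tau = tau, coef = coef)
}

# --- censored-below nodes: contribution to P(Y <= L | lambda, a) -------------
.nodes_cens_low_draw <- function(L, a_d, th, nu, sigma, G, Z, include_rise) {
  m_start <- pmin(th$y1, L * exp(Z * sigma))   # largest m with P(Y <= L | m) > 0
  f_a <- .ab(pmax(a_d, th$t1), th)
  active <- a_d > th$t1
  t_start <- ifelse(active, pmin(.ttl(pmax(pmin(m_start, th$y1), f_a * 0 + 1e-300), th), a_d), a_d)
  mA <- pmax(pmin(L, th$y1), 1e-300)
  tA <- ifelse(active, pmin(.ttl(mA, th), a_d), a_d)
  # geometric fill (in time since peak) between the m = L crossing and age:
  # covers both the saturation shoulder of the censoring probability and the
  # slowly varying exposure weight over the remaining decades
  e1 <- pmax(tA - th$t1, pmax(a_d - th$t1, 0) * 1e-6, 1e-8)
  e2 <- pmax(a_d - th$t1, e1)
  g1 <- th$t1 + exp((3 * log(e1) + log(e2)) / 4)
  g2 <- th$t1 + exp((2 * log(e1) + 2 * log(e2)) / 4)
  g3 <- th$t1 + exp((log(e1) + 3 * log(e2)) / 4)
  B <- .row_cummax(cbind(t_start, tA, pmin(g1, a_d), pmin(g2, a_d),
                         pmin(g3, a_d), a_d, deparse.level = 0))
  gd <- .gl_from_breaks(B, G)
  tau <- gd$x
  coef <- gd$w * .pmeas_cdf(L, .ab(gd$x, th), nu, sigma)

  if (include_rise) {
    t1a <- pmin(th$t1, a_d)
    clr <- function(m) pmin(pmax(m, th$y0), th$y0 * exp(th$mu * t1a))
    t_end <- log(clr(m_start) / th$y0) / th$mu
    tL <- log(clr(L) / th$y0) / th$mu
    Br <- .row_cummax(cbind(0, pmin(tL, t_end), t_end, deparse.level = 0))
    gr <- .gl_from_breaks(Br, G)
    coef_r <- gr$w * .pmeas_cdf(L, .ab(gr$x, th), nu, sigma)
    tau <- cbind(tau, gr$x, deparse.level = 0)
    coef <- cbind(coef, coef_r, deparse.level = 0)
  }
  coef[!is.finite(coef)] <- 0
  list(tau = tau, coef = coef)
}

# --- censored-above nodes: contribution to P(Y >= H | lambda, a) -------------
.nodes_cens_high_draw <- function(H, a_d, th, nu, sigma, G, Z, include_rise) {
  m_min <- H * exp(-Z * sigma) - nu           # smallest m with P(Y >= H | m) > 0
  f_a <- .ab(pmax(a_d, th$t1), th)
  cld <- function(m) pmax(pmin(m, th$y1), pmax(f_a, 1e-300))
  active <- a_d > th$t1
  t_end <- ifelse(active, pmin(.ttl(cld(pmax(m_min, 1e-300)), th), a_d), a_d)
  tH <- ifelse(active, pmin(.ttl(cld(pmax(H, 1e-300)), th), a_d), a_d)
  tHn <- ifelse(active, pmin(.ttl(cld(pmax(H - nu, 1e-300)), th), a_d), a_d)
  t1v <- pmin(th$t1, a_d)
  B <- .row_cummax(cbind(t1v, tH, tHn, t_end, deparse.level = 0))
  gd <- .gl_from_breaks(B, G)
  tau <- gd$x
  coef <- gd$w * (1 - .pmeas_cdf(H, .ab(gd$x, th), nu, sigma))

  if (include_rise) {
    t1a <- pmin(th$t1, a_d)
    clr <- function(m) pmin(pmax(m, th$y0), th$y0 * exp(th$mu * t1a))
    t0 <- log(clr(pmax(m_min, 1e-300)) / th$y0) / th$mu
    tr1 <- log(clr(pmax(H - nu, 1e-300)) / th$y0) / th$mu
    tr2 <- log(clr(pmax(H, 1e-300)) / th$y0) / th$mu
    Br <- .row_cummax(cbind(t0, tr1, tr2, t1a, deparse.level = 0))
    gr <- .gl_from_breaks(Br, G)
    coef_r <- gr$w * (1 - .pmeas_cdf(H, .ab(gr$x, th), nu, sigma))
    tau <- cbind(tau, gr$x, deparse.level = 0)
    coef <- cbind(coef, coef_r, deparse.level = 0)
  }
  coef[!is.finite(coef)] <- 0
  list(tau = tau, coef = coef)
}

# --- assembly ----------------------------------------------------------------

# Build the lambda-independent precomputation for a set of target values of
# one kind ("density" for p(y), "cdf" for P(Y <= q), "surv" for P(Y >= q)).
# The quadrature nodes are packed into flat vectors (zero-coefficient nodes
# from clamped panels dropped), with the contract
#   value_i(lambda) = exp(-ld * a_d_i) * p0_i
#                     + ld * sum_{j: row_j = i} coef_j * exp(-ld * tau_j),
# ld = lambda / 365.25, mixing equally over the K kinetics draws.
.pre_block <- function(kind, yq, age_yr, model) {
  n <- length(yq)
  a_d <- age_yr * 365.25
  nu <- model$nu; sigma <- model$sigma
  G <- model$n_nodes; Z <- model$z_span
  K <- nrow(model$draws)
  builder <- switch(kind,
    density = .nodes_density_draw,
    cdf = .nodes_cens_low_draw,
    surv = .nodes_cens_high_draw
  )
  p0 <- switch(kind,
    density = .pmeas_density(yq, 0, nu, sigma),
    cdf = .pmeas_cdf(yq, 0, nu, sigma),
    surv = 1 - .pmeas_cdf(yq, 0, nu, sigma)
  )
  taus <- vector("list", K)
  coefs <- vector("list", K)
  for (k in seq_len(K)) {
    th <- .draw_par(model$draws, k)
    nb <- builder(yq, a_d, th, nu, sigma, G, Z, model$include_rise)
    taus[[k]] <- nb$tau
    coefs[[k]] <- nb$coef / K
  }
  list(
    n = n, a_d = a_d, p0 = p0,
    tau = do.call(cbind, taus),
    coef = do.call(cbind, coefs)
  )
}

# Evaluate a precomputed block at one incidence rate (per person-year)
.eval_block <- function(block, lambda) {
  ld <- lambda / 365.25
  if (block$n == 0L) return(numeric(0))
  exp(-ld * block$a_d) * block$p0 +
    ld * .rowSums(block$coef * exp(-ld * block$tau), block$n, ncol(block$tau))
}

# Value and first two derivatives with respect to ld = lambda_day of every
# per-observation density/mass in a block (for Newton steps and exact
# curvature-based standard errors).
.eval_block_deriv <- function(block, ld) {
  n <- block$n
  J <- ncol(block$tau)
  P <- exp(-ld * block$a_d) * block$p0
  z <- block$coef * exp(-ld * block$tau)
  zt <- z * block$tau
  S0 <- .rowSums(z, n, J)
  S1 <- .rowSums(zt, n, J)
  S2 <- .rowSums(zt * block$tau, n, J)
  list(
    val = P + ld * S0,
    d1 = -block$a_d * P + S0 - ld * S1,
    d2 = block$a_d^2 * P - 2 * S1 + ld * S2
  )
}
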