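# Strict Heaviside: H(0) = 0. Used for inflammation tiers and the tensile
# stress gate, so thresholds act by strict inequality.
h_pos <- function(x) as.numeric(x > 0)

# positive part, vectorised
ppart <- function(x) pmax(x, 0)

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "airwaymorph_input_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort_bad_arg(sprintf(
      "`%s` = %g violates the constraint %s%g, <= %g.",
      name, x, if (strict_lower) "> " else ">= ", lower, upper
    ))
  }
  invisible(x)
}

# Cumulative integral of y(x) on a (possibly non-uniform) grid using
# piecewise parabolic interpolation (averaged left/right three-point
# parabolas). Fourth-order on smooth integrands, which the transmural
# equilibrium residual needs: plain trapezoids limit the shooting solve to
# ~1e-5 relative accuracy on the default grids.
cumquad <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort_bad_arg("`x` and `y` must have equal length.")
  if (n < 2L) return(rep(0, n))
  if (n == 2L) return(c(0, 0.5 * (y[1] + y[2]) * (x[2] - x[1])))

  # integral over [a, b] of the parabola through (x0,y0), (x1,y1), (x2,y2)
  para_int <- function(x0, x1, x2, y0, y1, y2, a, b) {
    ii <- function(p, q) {
      (b^3 - a^3) / 3 - (p + q) * (b^2 - a^2) / 2 + p * q * (b - a)
    }
    y0 * ii(x1, x2) / ((x0 - x1) * (x0 - x2)) +
      y1 * ii(x0, x2) / ((x1 - x0) * (x1 - x2)) +
      y2 * ii(x0, x1) / ((x2 - x0) * (x2 - x1))
  }

  i <- seq_len(n - 1L)
  a <- x[i]
  b <- x[i + 1L]

  # left-shifted parabola (valid for i >= 2), right-shifted (i <= n-2)
  iL <- pmax(i - 1L, 1L)
  left <- para_int(x[iL], x[iL + 1L], x[iL + 2L],
                   y[iL], y[iL + 1L], y[iL + 2L], a, b)
  iR <- pmin(i, n - 2L)
  right <- para_int(x[iR], x[iR + 1L], x[iR + 2L],
                    y[iR], y[iR + 1L], y[iR + 2L], a, b)

  w <- rep(0.5, n - 1L)
  w[1L] <- 0    # first interval: only the right-anchored parabola is centred
  w[n - 1L] <- 1 # last interval: only the left-anchored one
  seg <- w * left + (1 - w) * right
  c(0, cumsum(seg))
}

# quadrature weight vector for the same averaged-parabola scheme:
# sum(w * y) equals the last entry of cumquad(x, y). Precomputed once per
# grid so the shooting residual is a single dot product per layer.
.quad_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  if (n == 2L) return(c(0.5, 0.5) * (x[2] - x[1]))
  i <- seq_len(n - 1L)
  a <- x[i]
  b <- x[i + 1L]
  coef3 <- function(x0, x1, x2) {
    ii <- function(p, q) {
      (b^3 - a^3) / 3 - (p + q) * (b^2 - a^2) / 2 + p * q * (b - a)
    }
    list(ii(x1, x2) / ((x0 - x1) * (x0 - x2)),
         ii(x0, x2) / ((x1 - x0) * (x1 - x2)),
         ii(x0, x1) / ((x2 - x0) * (x2 - x1)))
  }
  iL <- pmax(i - 1L, 1L)
  L <- coef3(x[iL], x[iL + 1L], x[iL + 2L])
  iR <- pmin(i, n - 2L)
  R <- coef3(x[iR], x[iR + 1L], x[iR + 2L])
  w <- rep(0.5, n - 1L)
  w[1L] <- 0
  w[n - 1L] <- 1
  idx_all <- c(iL, iL + 1L, iL + 2L, iR, iR + 1L, iR + 2L)
  val_all <- c(w * L[[1]], w * L[[2]], w * L[[3]],
               (1 - w) * R[[1]], (1 - w) * R[[2]], (1 - w) * R[[3]])
  out <- numeric(n)
  agg <- rowsum(val_all, idx_all)
  out[as.integer(rownames(agg))] <- agg
  out
}

# cumulative trapezoid (used where the integrand is only piecewise smooth,
# e.g. growth dilatation with Heaviside-tiered sources)
cumtrap <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(0.5 * (y[-n] + y[-1L]) * diff(x)))
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
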