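# Power-law fitting. Two routes, recorded in the fit's `method` tag:
#   * "mle"    — discrete maximum likelihood for the degree distribution,
#                with the lower cutoff x_min chosen by minimal KS distance and
#                a semiparametric bootstrap goodness-of-fit p-value
#                (Clauset-Shalizi-Newman procedure).
#   * "loglog" — ordinary least squares on (log10 k, log10 y) for
#                degree-aggregated curves, which are not probability
#                distributions and therefore get a residual-bootstrap
#                lack-of-fit p-value instead of a KS one.

# Hurwitz zeta(s, q) = sum_{n>=0} (q+n)^-s for s > 1, by Euler-Maclaurin.
# Accuracy ~1e-12 for s in (1, 30], q >= 1 — ample for likelihoods and CDFs.
hurwitz_zeta <- function(s, q) {
  stopifnot(s > 1, q > 0)
  N <- 15
  k <- 0:(N - 1)
  a <- q + N
  sum((q + k)^(-s)) +
    a^(1 - s) / (s - 1) +
    0.5 * a^(-s) +
    s * a^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * a^(-s - 3) / 720 +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) * a^(-s - 5) / 30240
}

# Discrete power-law log-likelihood for x >= xmin.
pl_loglik <- function(alpha, x, xmin) {
  -length(x) * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

pl_mle_alpha <- function(x, xmin, interval = c(1.01, 12)) {
  optimize(function(a) pl_loglik(a, x, xmin),
           interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

# KS distance between the empirical CDF of x (>= xmin) and the fitted
# discrete power-law CDF.
pl_ks <- function(x, alpha, xmin) {
  x <- sort(x)
  ux <- unique(x)
  zx <- hurwitz_zeta(alpha, xmin)
  cdf_model <- vapply(ux, function(v) 1 - hurwitz_zeta(alpha, v + 1) / zx,
                      numeric(1))
  # both CDFs are right-continuous step functions with the same atoms, so the
  # sup distance is attained at an observed value
  cdf_emp <- cumsum(tabulate(match(x, ux))) / length(x)
  max(abs(cdf_emp - cdf_model))
}

# Fit alpha and xmin jointly: scan candidate xmin values (unique degrees
# leaving at least `min_tail` tail observations), keep the KS-minimising one.
pl_fit_core <- function(x, xmin = NULL, min_tail = 10) {
  x <- x[x >= 1]
  if (length(unique(x)) < 2) {
    stop("degenerate input: fewer than two distinct positive degrees",
         call. = FALSE)
  }
  cands <- if (is.null(xmin)) {
    u <- sort(unique(x))
    u[vapply(u, function(v) sum(x >= v), numeric(1)) >= min_tail &
        vapply(u, function(v) length(unique(x[x >= v])), numeric(1)) >= 2]
  } else {
    xmin
  }
  if (length(cands) == 0) cands <- min(x)
  best <- NULL
  for (xm in cands) {
    tail_x <- x[x >= xm]
    a <- pl_mle_alpha(tail_x, xm)
    ks <- pl_ks(tail_x, a, xm)
    if (is.null(best) || ks < best$ks) {
      best <- list(alpha = a, xmin = xm, ks = ks, n_tail = length(tail_x))
    }
  }
  best
}

#' Sample from a discrete power law
#'
#' Inverse-transform sampling of `P(X = x) ~ x^-alpha` for `x >= xmin`, using
#' a doubling-then-bisection search on the exact complementary CDF
#' `P(X >= x) = zeta(alpha, x) / zeta(alpha, xmin)`.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param xmin Lower cutoff (integer >= 1).
#' @param seed Optional RNG seed.
#' @return Integer vector of length `n`.
#' @export
rpl_discrete <- function(n, alpha, xmin = 1, seed = NULL) {
  stopifnot(alpha > 1, xmin >= 1)
  with_seed(seed, {
    zmin <- hurwitz_zeta(alpha, xmin)
    ccdf <- function(x) hurwitz_zeta(alpha, x) / zmin
    u <- runif(n)
    vapply(u, function(ui) {
      # return the largest x with P(X >= x) > ui; P(X >= xmin) = 1 > ui a.s.
      hi <- xmin
      while (ccdf(hi + 1) > ui) hi <- 2 * hi + 1
      lo <- max(xmin, (hi - 1) %/% 2)      # ccdf(lo) > ui by construction
      while (lo < hi) {
        mid <- (lo + hi + 1) %/% 2
        if (ccdf(mid) > ui) lo <- mid else hi <- mid - 1
      }
      as.numeric(lo)
    }, numeric(1))
  })
}

new_power_law_fit <- function(exponent, sign, xmin, ks, p_value, n_boot,
                              method, n_tail, intercept = NA_real_,
                              seed = NULL) {
  structure(
    list(exponent = exponent, sign = sign, xmin = xmin, ks = ks,
         p_value = p_value, n_boot = n_boot, method = method,
         n_tail = n_tail, intercept = intercept, seed = seed),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> method:", x$method,
      " exponent:", signif(x$exponent, 4),
      paste0("(", x$sign, ")"),
      " xmin:", x$xmin,
      if (!is.na(x$ks)) paste(" KS:", signif(x$ks, 3)) else "",
      if (!is.na(x$p_value)) paste(" p:", signif(x$p_value, 3)) else "",
      "\n")
  invisible(x)
}

#' Fit a discrete power law to a degree sample
#'
#' Maximum-likelihood exponent for `P(k) ~ k^-gamma`, `k >= x_min`, with
#' `x_min` selected by minimising the Kolmogorov-Smirnov distance between the
#' empirical tail and the fitted model. The goodness-of-fit p-value is the
#' fraction of `n_boot` semiparametric bootstrap datasets (power-law tail
#' redrawn from the fitted model, body resampled from the observed sub-cutoff
#' degrees) whose own refitted KS distance is at least the observed one; a
#' p-value above ~0.1 means the power law cannot be rejected.
#'
#' @param degrees Integer vector of node degrees (a multiset of k).
#' @param xmin Optional fixed lower cutoff; default: scan and choose by KS.
#' @param n_boot Bootstrap replicates for the p-value (default 2500). Set to
#'   0 to skip the bootstrap (p-value `NA`).
#' @param seed RNG seed for the bootstrap.
#' @param min_tail Smallest admissible tail size during the x_min scan.
#' @return A `power_law_fit` with `method = "mle"`, `sign = "negative"`.
#' @export
fit_degree_distribution <- function(degrees, xmin = NULL, n_boot = 2500,
                                    seed = NULL, min_tail = 10) {
  degrees <- as.numeric(degrees)
  if (length(degrees) < 50) {
    warning("fewer than 50 observations: exponent estimate will be noisy")
  }
  fit <- pl_fit_core(degrees, xmin = xmin, min_tail = min_tail)
  p <- NA_real_
  if (n_boot > 0) {
    x <- degrees[degrees >= 1]
    n <- length(x)
    body <- x[x < fit$xmin]
    p_tail <- fit$n_tail / n
    ks_boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        from_tail <- runif(n) < p_tail
        n_t <- sum(from_tail)
        synth <- c(
          if (n_t > 0) rpl_discrete(n_t, fit$alpha, fit$xmin) else numeric(0),
          if (n - n_t > 0) sample(body, n - n_t, replace = TRUE) else numeric(0)
        )
        bf <- tryCatch(pl_fit_core(synth, xmin = xmin, min_tail = min_tail),
                       error = function(e) NULL)
        if (is.null(bf)) NA_real_ else bf$ks
      }, numeric(1))
    })
    p <- mean(ks_boot >= fit$ks, na.rm = TRUE)
  }
  new_power_law_fit(fit$alpha, "negative", fit$xmin, fit$ks, p,
                    if (n_boot > 0) n_boot else 0L, "mle", fit$n_tail,
                    seed = seed)
}

#' Fit a power law to a degree curve by log-log least squares
#'
#' Ordinary least squares of `log10 y` on `log10 k` for degree-aggregated
#' curves such as `C(k)`, `Cn(k)` or mean centrality per degree class. The
#' stored exponent is the magnitude of the slope with its sign recorded
#' separately (`"negative"` for decaying curves, `"positive"` for growing
#' ones). The p-value is a residual-bootstrap lack-of-fit probability: the
#' observed statistic is the largest absolute log10 residual, and the p-value
#' is the fraction of replicates (fitted line plus resampled residuals,
#' refitted) with an at-least-as-large statistic. Nonpositive y values are
#' dropped with a warning.
#'
#' @param curve A `degree_curve` (or data frame with columns `k`, `y`).
#' @param n_boot Residual bootstrap replicates (default 1000; 0 skips).
#' @param seed RNG seed for the bootstrap.
#' @param xmin Optional lower degree cutoff; points with `k < xmin` dropped.
#' @return A `power_law_fit` with `method = "loglog"`.
#' @export
fit_loglog <- function(curve, n_boot = 1000, seed = NULL, xmin = NULL) {
  k <- curve$k
  y <- curve$y
  if (!is.null(xmin)) {
    keep <- k >= xmin
    k <- k[keep]
    y <- y[keep]
  }
  bad <- !is.finite(y) | y <= 0 | k <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive/non-finite point(s) dropped from log-log fit")
    k <- k[!bad]
    y <- y[!bad]
  }
  if (length(k) < 3) stop("fewer than 3 positive points: cannot fit", call. = FALSE)
  lx <- log10(k)
  ly <- log10(y)
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2])
  res <- residuals(fit)
  fv <- fitted(fit)
  d_obs <- max(abs(res))
  p <- NA_real_
  if (n_boot > 0) {
    d_boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        ly_star <- fv + sample(res, length(res), replace = TRUE)
        max(abs(residuals(lm(ly_star ~ lx))))
      }, numeric(1))
    })
    p <- mean(d_boot >= d_obs)
  }
  new_power_law_fit(abs(slope),
                    if (slope <= 0) "negative" else "positive",
                    min(k), NA_real_, p,
                    if (n_boot > 0) n_boot else 0L, "loglog",
                    length(k), intercept = unname(coef(fit)[1]), seed = seed)
}

signed_exponent <- function(fit) {
  if (fit$sign == "negative") -fit$exponent else fit$exponent
}

#' Check the fractal scaling relation of a fitted curve
#'
#' A pure power law `y(k) = A k^D` satisfies `y(scale * k) / y(k) = scale^D`
#' for every `k`. This check takes all degree pairs `(k, scale*k)` present in
#' the curve, forms the empirical ratios, and reports the largest absolute
#' deviation from `scale^D` (with `D` the signed fitted exponent) together
#' with a pass flag at tolerance `tol`.
#'
#' @param curve A `degree_curve` (or data frame with `k`, `y`).
#' @param fit A `power_law_fit` for that curve.
#' @param scale Integer scale factor >= 2.
#' @param tol Absolute tolerance on the ratio deviation.
#' @return A list of class `scaling_check`: `applicable`, `scale`,
#'   `expected_ratio`, `deviations` (named by k), `max_deviation`, `pass`.
#' @export
scaling_check <- function(curve, fit, scale = 2, tol = 0.05) {
  stopifnot(scale >= 2, inherits(fit, "power_law_fit"))
  k <- curve$k
  y <- curve$y
  idx <- match(k * scale, k)
  have <- which(!is.na(idx) & y > 0)
  have <- have[y[idx[have]] > 0]
  if (length(have) < 1) {
    return(structure(list(applicable = FALSE, scale = scale,
                          expected_ratio = NA_real_, deviations = numeric(0),
                          max_deviation = NA_real_, pass = NA),
                     class = "scaling_check"))
  }
  d <- signed_exponent(fit)
  expect <- scale^d
  ratios <- y[idx[have]] / y[have]
  dev <- abs(ratios - expect)
  names(dev) <- k[have]
  structure(list(applicable = TRUE, scale = scale, expected_ratio = expect,
                 deviations = dev, max_deviation = max(dev),
                 pass = max(dev) <= tol),
            class = "scaling_check")
}

#' @export
print.scaling_check <- function(x, ...) {
  if (!x$applicable) {
    cat("<scaling_check> not applicable (no (k, scale*k) pairs)\n")
  } else {
    cat("<scaling_check> scale:", x$scale,
        " expected ratio:", signif(x$expected_ratio, 4),
        " max deviation:", signif(x$max_deviation, 4),
        " pass:", x$pass, "\n")
  }
  invisible(x)
}
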