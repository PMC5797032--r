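#' Pooled NLME 4PL fit with a random midpoint per cell line
#'
#' Fits one four-parameter logistic curve to all cell lines of a drug
#' simultaneously, with fixed effects for the four curve parameters and a
#' Gaussian random effect on the midpoint grouped by cell line:
#' `y = right + (left - right)/(1 + exp((xmid + b_i - x)/scale)) + e`,
#' `b_i ~ N(0, sd_xmid_re^2)`, `e ~ N(0, sd_resid^2)`.  The random effect
#' is integrated out per line by a Laplace approximation (default) or
#' adaptive Gauss-Hermite quadrature, and the marginal likelihood is
#' maximised over the six parameters (variances on the log scale).
#' Borrowing strength across the panel shrinks noisy per-line midpoints
#' towards the population curve.
#'
#' @param screen A [dose_response_table()].
#' @param drug Drug identifier; may be omitted for single-drug screens.
#' @param init Optional named list with any of `left`, `right`, `xmid`,
#'   `scale`, `sd_xmid_re`, `sd_resid` to override the data-driven start.
#' @param quadrature `"laplace"` (default) or `"agq"` for adaptive
#'   Gauss-Hermite quadrature.
#' @param nagq Number of quadrature nodes when `quadrature = "agq"`.
#' @return An object of class `"nlme_drc_fit"`: list with `fixed`
#'   ([fourpl()]), `sd_xmid_re`, `sd_resid`, `line_xmid` (named vector of
#'   conditional midpoints, fixed effect + conditional mode), `loglik`
#'   (marginal), `converged`, `n_lines`, `n_obs`, plus the data used.
#' @examples
#' sim <- simulate_screen(scenario_spec(n_lines = 10), seed = 1)
#' fit <- fit_nlme_pooled(sim$screen)
#' fit$fixed
#' head(conditional_xmids(fit))
#' @export
fit_nlme_pooled <- function(screen, drug = NULL, init = NULL,
                            quadrature = c("laplace", "agq"), nagq = 9L) {
  quadrature <- match.arg(quadrature)
  sub <- subset_drug(screen, drug)
  lines <- unique(sub$cell_line)
  if (length(lines) < 2L)
    stop("NLME fit needs at least 2 cell lines", call. = FALSE)
  for (cl in lines) {
    d <- sub[sub$cell_line == cl, ]
    if (length(unique(d$x)) < 4L || nrow(d) < 8L)
      stop("cell line '", cl, "' has too few doses/observations",
           call. = FALSE)
  }
  ord <- order(match(sub$cell_line, lines))
  x <- sub$x[ord]
  y <- sub$response[ord]
  idx <- match(sub$cell_line, lines)[ord] - 1L
  n_lines <- length(lines)

  gh <- if (quadrature == "agq") gauss_hermite(as.integer(nagq))
        else list(z = 0, w = 0)
  nagq_i <- if (quadrature == "agq") as.integer(nagq) else 1L
  b_cache <- numeric(n_lines)  # warm starts for the inner mode search
  if (quadrature == "laplace") {
    # one C++ call yields objective and analytic gradient; memoise so the
    # optimiser's paired objective/gradient evaluations share it
    last <- list(par = NULL, val = NULL)
    both <- function(par) {
      if (is.null(last$par) || !identical(par, last$par))
        last <<- list(par = par,
                      val = nlme4pl_nll_grad(par, x, y, idx, n_lines,
                                             b_cache))
      last$val
    }
    nll <- function(par) both(par)[1]
    ngr <- function(par) both(par)[-1]
  } else {
    nll <- function(par) nlme4pl_nll(par, x, y, idx, n_lines, nagq_i,
                                     gh$z, gh$w, b_cache)
    ngr <- NULL
  }

  st <- nlme_start(x, y, idx, n_lines, init, nll)
  lower <- c(-60, -60, min(x) - 2, -10, log(1e-6), log(1e-3))
  upper <- c(250, 250, max(x) + 2, -1e-3, log(5), log(1e3))
  # parscale tames the conditioning gap between asymptotes (~100 %
  # viability) and the log-SD / slope parameters (~1)
  run_opt <- function(par0) stats::optim(
    par0, nll, gr = ngr, method = "L-BFGS-B", lower = lower,
    upper = upper,
    control = list(maxit = 500, factr = 1e6,
                   parscale = c(50, 50, 0.5, 0.5, 1, 1)))
  opt <- run_opt(st)
  for (pass in 1:3) {  # restart when the line search stops prematurely
    if (opt$convergence == 0) break
    nxt <- run_opt(opt$par)
    gain <- opt$value - nxt$value
    if (nxt$value <= opt$value) opt <- nxt
    if (gain < 1e-8) break
  }
  if (opt$par[4] >= upper[4] - 1e-6 && is.null(init)) {
    # a slope collapsed to the step-function boundary is a degenerate local
    # optimum; retry from the heuristic start with the canonical slope
    st2 <- st; st2[4] <- -0.5
    opt2 <- run_opt(st2)
    if (opt2$value < opt$value) opt <- opt2
  }
  conv_ok <- opt$convergence == 0 && is.finite(opt$value)
  if (!conv_ok && is.finite(opt$value)) {
    # polish with a differently scaled quasi-Newton pass before giving up
    alt <- stats::nlminb(opt$par, nll, gradient = ngr, lower = lower,
                         upper = upper, scale = c(0.02, 0.02, 1, 1, 1, 1),
                         control = list(iter.max = 500, eval.max = 1500,
                                        rel.tol = 1e-9))
    if (alt$objective <= opt$value) {
      opt <- list(par = alt$par, value = alt$objective,
                  convergence = alt$convergence)
      conv_ok <- alt$convergence == 0 && is.finite(alt$objective)
    }
  }
  par <- opt$par
  b <- nlme4pl_modes(par, x, y, idx, n_lines)
  out <- list(
    fixed = fourpl(par[1], par[2], par[3], par[4]),
    sd_xmid_re = exp(par[5]),
    sd_resid = exp(par[6]),
    line_xmid = setNames(par[3] + b, lines),
    ranef = setNames(b, lines),
    loglik = -opt$value,
    converged = conv_ok,
    n_lines = n_lines,
    n_obs = length(y),
    quadrature = quadrature,
    nagq = nagq_i,
    data = data.frame(cell_line = lines[idx + 1L], x = x, response = y,
                      stringsAsFactors = FALSE))
  class(out) <- "nlme_drc_fit"
  out
}

# data-driven starting values: asymptotes from extreme doses, per-line
# midpoint guesses from the half-response crossing, slope from a coarse grid
nlme_start <- function(x, y, idx, n_lines, init, nll) {
  if (!is.null(init)) {
    if (inherits(init, "fourpl")) init <- as.list(unclass(init))
    full <- c("left", "right", "xmid", "scale", "sd_xmid_re", "sd_resid")
    if (all(full %in% names(init)))  # complete start: skip the heuristics
      return(c(init$left, init$right, init$xmid, init$scale,
               log(max(init$sd_xmid_re, 1e-6)),
               log(max(init$sd_resid, 1e-3))))
  }
  mu_x <- tapply(y, x, mean)
  xs <- sort(unique(x))
  mu_x <- as.numeric(mu_x[as.character(xs)])
  left0 <- mu_x[1L]
  right0 <- mu_x[length(mu_x)]
  if (abs(left0 - right0) < 1e-8) left0 <- left0 + 1
  # a pooled least-squares 4PL gives curve starts accurate enough even when
  # the marginal likelihood surface is very sharp (tiny residual noise)
  ls_fit <- tryCatch(minpack.lm::nlsLM(
    y ~ right + (left - right) / (1 + exp((xmid - x) / scale)),
    data = data.frame(x = x, y = y),
    start = list(left = left0, right = right0,
                 xmid = xs[which.min(abs(mu_x - (left0 + right0) / 2))],
                 scale = -0.5),
    control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(ls_fit)) {
    cf <- stats::coef(ls_fit)
    if (all(is.finite(cf)) && cf[["scale"]] < 0) {
      left0 <- cf[["left"]]; right0 <- cf[["right"]]
    } else ls_fit <- NULL
  }
  mid <- (left0 + right0) / 2
  xm_line <- vapply(seq_len(n_lines) - 1L, function(i) {
    xi <- x[idx == i]; yi <- y[idx == i]
    m <- tapply(yi, xi, mean)
    xs_i <- as.numeric(names(m)); m <- as.numeric(m)
    o <- order(xs_i); xs_i <- xs_i[o]; m <- m[o]
    cross <- which(diff(sign(m - mid)) != 0)
    if (length(cross)) {
      j <- cross[1L]
      xs_i[j] + (mid - m[j]) * (xs_i[j + 1L] - xs_i[j]) / (m[j + 1L] - m[j])
    } else xs_i[which.min(abs(m - mid))]
  }, numeric(1))
  m0 <- median(xm_line)
  sd_b0 <- max(sd(xm_line), 0.01)
  if (!is.null(ls_fit)) {
    cf <- stats::coef(ls_fit)
    m0 <- cf[["xmid"]]
    # pooled residuals fold in the between-line midpoint spread, so this
    # start overestimates the well noise somewhat; safe for the optimiser
    sd_e0 <- max(sqrt(sum(stats::resid(ls_fit)^2) / length(y)), 1e-3)
    st <- c(left0, right0, m0, cf[["scale"]], log(sd_b0), log(sd_e0))
  } else {
    sd_e0 <- max(sd(y - mu_x[match(x, xs)]), 0.01)
    cand <- c(-1, -0.5, -0.25)
    base <- vapply(cand, function(s)
      nll(c(left0, right0, m0, s, log(sd_b0), log(sd_e0))), numeric(1))
    st <- c(left0, right0, m0, cand[which.min(base)], log(sd_b0),
            log(sd_e0))
  }
  if (!is.null(init)) {
    if (inherits(init, "fourpl")) init <- as.list(unclass(init))
    nm <- c("left", "right", "xmid", "scale")
    for (k in seq_along(nm))
      if (!is.null(init[[nm[k]]])) st[k] <- init[[nm[k]]]
    if (!is.null(init$sd_xmid_re)) st[5] <- log(max(init$sd_xmid_re, 1e-6))
    if (!is.null(init$sd_resid)) st[6] <- log(max(init$sd_resid, 1e-3))
  }
  st
}

#' @export
print.nlme_drc_fit <- function(x, ...) {
  cat("NLME 4PL fit (", x$quadrature,
      if (x$quadrature == "agq") paste0(", k = ", x$nagq), "): ",
      x$n_lines, " cell lines, ", x$n_obs, " wells",
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  print(x$fixed)
  cat("  sd(xmid random effect) =", format(x$sd_xmid_re, digits = 4),
      "  sd(residual) =", format(x$sd_resid, digits = 4), "\n")
  cat("  marginal logLik =", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Conditional per-cell-line midpoints (log10 IC50s)
#'
#' Returns the per-line midpoint estimates from a pooled NLME fit: fixed
#' effect plus the conditional mode (BLUP) of each line's random effect.
#' These are shrunken towards the population midpoint relative to
#' independent per-line fits.
#'
#' @param fit A converged [fit_nlme_pooled()] result.
#' @return Named numeric vector `cell_line -> xmid`.
#' @export
conditional_xmids <- function(fit) {
  stopifnot(inherits(fit, "nlme_drc_fit"))
  if (!fit$converged)
    stop("NLME fit did not converge; conditional midpoints unreliable",
         call. = FALSE)
  fit$line_xmid
}

#' Residual normality diagnostics for an NLME fit
#'
#' Computes residuals at the conditional modes (observed minus the per-line
#' conditional curve) and summarises their normality with a Shapiro-Wilk
#' test plus QQ-ready quantile pairs.
#'
#' @param fit A converged [fit_nlme_pooled()] result.
#' @param screen Optional [dose_response_table()]; defaults to the data
#'   stored in the fit.
#' @return List with `statistic`, `p.value`, `residuals`, and `qq` (data
#'   frame of theoretical and sample quantiles).
#' @export
residual_diagnostics <- function(fit, screen = NULL) {
  stopifnot(inherits(fit, "nlme_drc_fit"))
  if (!fit$converged)
    stop("NLME fit did not converge", call. = FALSE)
  d <- if (is.null(screen)) fit$data else {
    s <- subset_drug(screen, NULL)
    data.frame(cell_line = s$cell_line, x = s$x, response = s$response)
  }
  f <- fit$fixed
  m_i <- fit$line_xmid[d$cell_line]
  pred <- f[["right"]] + (f[["left"]] - f[["right"]]) /
    (1 + exp((m_i - d$x) / f[["scale"]]))
  res <- as.numeric(d$response - pred)
  sw_in <- if (length(res) > 5000L)
    res[round(seq(1L, length(res), length.out = 5000L))] else res
  sw <- shapiro.test(sw_in)
  n <- length(res)
  list(statistic = unname(sw$statistic), p.value = sw$p.value,
       residuals = res,
       qq = data.frame(theoretical = qnorm(ppoints(n)),
                       sample = sort(res)))
}
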