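#' Fit a 4PL curve to a single cell line by least squares
#'
#' The traditional per-cell-line analysis: a four-parameter logistic curve
#' is fitted to one cell line's replicate dose-response data in isolation
#' by Levenberg-Marquardt least squares.  Starting values come from the
#' data (asymptotes from the mean response at the extreme doses, midpoint
#' from the dose closest to half response, slope from a coarse grid), and
#' the parameters are box-bounded to keep asymptotes from blowing up on
#' partial-response curves.
#'
#' @param data A [dose_response_table()] restricted to one cell line and
#'   one drug (at least 4 distinct concentrations, at least 8 wells).
#' @param init Optional [fourpl()] used as the starting point instead of
#'   the self-start.
#' @return An object of class `"individual_fit"`: list with `params`
#'   ([fourpl()]), `rss`, `loglik` (Gaussian, MLE variance), `converged`,
#'   `n_obs`, `cell_line`, `drug`.  Degenerate (zero-variance) data yield
#'   `converged = FALSE` rather than an error.
#' @examples
#' spec <- scenario_spec(n_lines = 2)
#' sim <- simulate_screen(spec, seed = 1)
#' one <- sim$screen[sim$screen$cell_line == sim$screen$cell_line[1], ]
#' fit_single_curve(one)
#' @export
fit_single_curve <- function(data, init = NULL) {
  if (length(unique(data$cell_line)) != 1L || length(unique(data$drug)) != 1L)
    stop("data must cover exactly one cell line and one drug", call. = FALSE)
  x <- data$x
  y <- data$response
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct concentrations to identify a 4PL",
         call. = FALSE)
  if (length(y) < 8L)
    stop("need at least 8 observations", call. = FALSE)
  out <- list(params = NULL, rss = NA_real_, loglik = NA_real_,
              converged = FALSE, n_obs = length(y),
              cell_line = data$cell_line[1], drug = data$drug[1])
  class(out) <- "individual_fit"
  if (sd(y) == 0) return(out)  # flat data cannot identify a sigmoid

  lower <- c(left = -20, right = -20, xmid = min(x) - 2, scale = -10)
  upper <- c(left = 150, right = 150, xmid = max(x) + 2, scale = -1e-3)
  start <- if (!is.null(init)) {
    as.list(pmin(pmax(unclass(as_fourpl(init)), lower), upper))
  } else {
    self_start_4pl(x, y, lower, upper)
  }
  resid_fn <- function(p)
    y - (p[2] + (p[1] - p[2]) / (1 + exp((p[3] - x) / p[4])))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- setNames(fit$par, c("left", "right", "xmid", "scale"))
  if (any(!is.finite(cf)) || cf[["scale"]] == 0) return(out)
  rss <- fit$deviance
  n <- length(y)
  s2 <- max(rss / n, 1e-12)
  out$params <- fourpl(cf[["left"]], cf[["right"]], cf[["xmid"]],
                       cf[["scale"]])
  out$rss <- rss
  out$loglik <- -0.5 * n * (log(2 * pi * s2) + 1)
  out$converged <- fit$info %in% 1:3  # ftol/ptol convergence codes
  out
}

# data-driven starting values; slope from a coarse grid by RSS
self_start_4pl <- function(x, y, lower, upper) {
  mu <- tapply(y, x, mean)
  xs <- as.numeric(names(mu))
  ord <- order(xs)
  xs <- xs[ord]; mu <- as.numeric(mu)[ord]
  left0 <- mu[1L]
  right0 <- mu[length(mu)]
  if (abs(left0 - right0) < 1e-8) left0 <- left0 + 1
  mid <- (left0 + right0) / 2
  xmid0 <- xs[which.min(abs(mu - mid))]
  cand <- c(-1, -0.5, -0.25)
  rss_at <- vapply(cand, function(s) {
    p <- c(left = left0, right = right0, xmid = xmid0, scale = s)
    sum((y - (p[["right"]] + (p[["left"]] - p[["right"]]) /
                (1 + exp((p[["xmid"]] - x) / s))))^2)
  }, numeric(1))
  st <- c(left = left0, right = right0, xmid = xmid0,
          scale = cand[which.min(rss_at)])
  as.list(pmin(pmax(st, lower), upper))
}

#' @export
print.individual_fit <- function(x, ...) {
  cat("Individual 4PL fit:", x$cell_line, "/", x$drug,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$params)) print(x$params)
  if (is.finite(x$rss))
    cat("  rss =", format(x$rss), " loglik =", format(x$loglik),
        " n =", x$n_obs, "\n")
  invisible(x)
}

#' Traditional per-cell-line IC50 table
#'
#' Fits each cell line of one drug independently with [fit_single_curve()]
#' and collects the fitted midpoints (log10 IC50s).  Cell lines whose fit
#' does not converge are omitted from the result (their ids are kept in the
#' `"failed"` attribute).
#'
#' @param screen A [dose_response_table()].
#' @param drug Drug identifier; may be omitted for single-drug screens.
#' @return Named numeric vector `cell_line -> xmid`.
#' @export
traditional_ic50_table <- function(screen, drug = NULL) {
  if (nrow(screen) == 0L) stop("empty screen", call. = FALSE)
  sub <- subset_drug(screen, drug)
  lines <- unique(sub$cell_line)
  fits <- lapply(lines, function(cl)
    tryCatch(fit_single_curve(sub[sub$cell_line == cl, , drop = FALSE]),
             error = function(e) NULL))
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  xmids <- vapply(fits[ok], function(f) f$params[["xmid"]], numeric(1))
  structure(setNames(xmids, lines[ok]), failed = lines[!ok])
}

#' Keep drugs with a strong maximal response
#'
#' Retains the drugs for which at least one cell line's replicate-averaged
#' viability at some dose falls strictly below a threshold (default 20%),
#' i.e. drugs that actually kill at least one line in the panel.
#'
#' @param screen A [dose_response_table()].
#' @param threshold Viability cut-off in percent; strict `<` applies.
#' @return Character vector of retained drug ids.
#' @export
filter_drugs_by_min_viability <- function(screen, threshold = 20) {
  if (nrow(screen) == 0L) return(character(0))
  mu <- stats::aggregate(response ~ drug + cell_line + x, data = screen,
                         FUN = mean)
  mins <- tapply(mu$response, mu$drug, min)
  names(mins)[mins < threshold]
}
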