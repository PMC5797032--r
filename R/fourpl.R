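#' Four-parameter logistic dose-response curve
#'
#' Container for the four parameters of a sigmoidal dose-response curve on
#' the log10-concentration axis: the left (low-dose) asymptote, the right
#' (high-dose) asymptote, the midpoint `xmid` (log10 concentration at half
#' response, the operational log10 IC50), and a scale (slope) parameter.
#' For inhibition curves the convention is `left > right` with `scale < 0`,
#' so viability falls from `left` towards `right` as dose increases.
#'
#' @param left Response (% viability) approached at vanishing dose.
#' @param right Response (% viability) approached at saturating dose.
#' @param xmid Midpoint, in log10(concentration in uM).
#' @param scale Slope parameter in log10-concentration units; must be
#'   non-zero.  Negative for curves that decrease with dose.
#'
#' @return An object of class `"fourpl"`: a named numeric vector with
#'   elements `left`, `right`, `xmid`, `scale`.
#'
#' @examples
#' p <- fourpl(100, 10, -0.5, -0.5)
#' eval_fourpl(p, -0.5)      # midpoint: (100 + 10)/2
#' ic50_concentration(p)     # 10^-0.5 ~ 0.316 uM
#' @export
fourpl <- function(left, right, xmid, scale) {
  p <- c(left = as.numeric(left), right = as.numeric(right),
         xmid = as.numeric(xmid), scale = as.numeric(scale))
  validate_fourpl(p)
  structure(p, class = "fourpl")
}

validate_fourpl <- function(p) {
  if (length(p) != 4L || !all(c("left", "right", "xmid", "scale") %in% names(p)))
    stop("a 'fourpl' needs named elements left, right, xmid, scale",
         call. = FALSE)
  if (any(!is.finite(p)))
    stop("fourpl parameters must be finite", call. = FALSE)
  if (p[["scale"]] == 0)
    stop("invalid fourpl: scale must be non-zero", call. = FALSE)
  invisible(p)
}

as_fourpl <- function(p) {
  if (inherits(p, "fourpl")) return(p)
  fourpl(p[["left"]], p[["right"]], p[["xmid"]], p[["scale"]])
}

#' @export
print.fourpl <- function(x, ...) {
  cat("4PL curve: left =", format(x[["left"]]),
      " right =", format(x[["right"]]),
      " xmid =", format(x[["xmid"]]),
      " scale =", format(x[["scale"]]), "\n")
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' Computes `right + (left - right) / (1 + exp((xmid - x)/scale))` at
#' log10-concentration `x`.  The curve passes through `(left + right)/2` at
#' `x = xmid` and is bounded by the two asymptotes.
#'
#' @param params A [fourpl()] object (or coercible named vector).
#' @param x Numeric vector of log10(concentration in uM).
#' @return Numeric vector of responses (% viability).
#' @examples
#' eval_fourpl(fourpl(100, 10, -0.5, -0.5), c(-4, -0.5, 0.5))
#' @export
eval_fourpl <- function(params, x) {
  p <- as_fourpl(params)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  u <- (p[["xmid"]] - x) / p[["scale"]]
  p[["right"]] + (p[["left"]] - p[["right"]]) / (1 + exp(u))
}

#' IC50 on the concentration scale
#'
#' The midpoint parameter lives on the log10 axis; this returns the
#' corresponding concentration, `10^xmid`, in uM.
#'
#' @param params A [fourpl()] object.
#' @return Concentration in uM.
#' @examples
#' ic50_concentration(fourpl(100, 10, 0, -0.5))  # 1 uM
#' @export
ic50_concentration <- function(params) {
  p <- as_fourpl(params)
  10^p[["xmid"]]
}
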