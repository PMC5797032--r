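#' Associate per-line IC50s with a cell-line feature
#'
#' The classical association step: given per-cell-line midpoint (log10
#' IC50) estimates and a per-line feature, run either a Pearson correlation
#' test (continuous feature) or a Welch two-sample t-test (two-level
#' grouping, e.g. over- vs under-expressers).  Cell lines missing from
#' either vector are dropped pairwise.
#'
#' @param ic50s Named numeric vector `cell_line -> xmid` (e.g. from
#'   [traditional_ic50_table()]).
#' @param feature Named vector keyed by cell line: numeric for
#'   `mode = "pearson"`; a two-level grouping (e.g. from [median_split()])
#'   for `mode = "ttest"`.
#' @param mode `"pearson"` or `"ttest"`.
#' @return List with `statistic`, `estimate` (correlation or difference in
#'   means), `p.value`, `n`, `mode`.
#' @export
trad_assoc <- function(ic50s, feature, mode = c("pearson", "ttest")) {
  mode <- match.arg(mode)
  if (is.null(names(ic50s)) || is.null(names(feature)))
    stop("ic50s and feature must be named by cell line", call. = FALSE)
  common <- intersect(names(ic50s), names(feature))
  v <- ic50s[common]
  f <- feature[common]
  keep <- is.finite(v) & !is.na(f)
  v <- v[keep]; f <- f[keep]
  if (length(v) == 0L) stop("no paired observations", call. = FALSE)
  if (sd(v) == 0) stop("IC50 values are constant", call. = FALSE)
  if (mode == "pearson") {
    if (!is.numeric(f)) stop("pearson mode needs a numeric feature",
                             call. = FALSE)
    if (length(v) < 3L)
      stop("pearson mode needs at least 3 paired observations",
           call. = FALSE)
    if (sd(f) == 0) stop("feature is constant", call. = FALSE)
    ct <- cor.test(v, f, method = "pearson")
    list(statistic = unname(ct$statistic), estimate = unname(ct$estimate),
         p.value = ct$p.value, n = length(v), mode = mode)
  } else {
    g <- factor(as.character(f))
    if (nlevels(g) != 2L)
      stop("ttest mode needs exactly two groups", call. = FALSE)
    if (any(table(g) < 2L))
      stop("each group needs at least 2 cell lines", call. = FALSE)
    tt <- t.test(v ~ g)  # Welch
    list(statistic = unname(tt$statistic),
         estimate = unname(diff(rev(tt$estimate))),
         p.value = tt$p.value, n = length(v), mode = mode)
  }
}

#' Associate NLME conditional IC50s with a feature
#'
#' As [trad_assoc()], applied to the conditional per-line midpoints of a
#' pooled NLME fit ([conditional_xmids()]).
#'
#' @param fit A converged [fit_nlme_pooled()] result.
#' @inheritParams trad_assoc
#' @return As [trad_assoc()].
#' @export
nlme_ic50_assoc <- function(fit, feature, mode = c("pearson", "ttest")) {
  trad_assoc(conditional_xmids(fit), feature, mode = mode)
}

#' Log-likelihood-ratio combination
#'
#' Combines the marginal log-likelihoods of the pooled fit and the two
#' group-stratified fits into the omnibus statistic
#' `LLR = -2 * LL_all + 2 * (LL_plus + LL_minus)`.
#'
#' @param ll_all Marginal log-likelihood of the pooled fit over all lines.
#' @param ll_plus,ll_minus Marginal log-likelihoods of the per-group fits.
#' @return The LLR statistic.
#' @examples
#' llr_from_loglik(-100, -40, -45)  # 30
#' @export
llr_from_loglik <- function(ll_all, ll_plus, ll_minus) {
  -2 * ll_all + 2 * (ll_plus + ll_minus)
}

validate_groups <- function(screen, groups) {
  if (is.null(names(groups)))
    stop("groups must be a named vector of 'plus'/'minus' labels",
         call. = FALSE)
  labs <- as.character(groups)
  if (!all(labs %in% c("plus", "minus")))
    stop("group labels must be 'plus' or 'minus'", call. = FALSE)
  if (!all(c("plus", "minus") %in% labs))
    stop("both groups must be present", call. = FALSE)
  missing <- setdiff(names(groups), unique(screen$cell_line))
  if (length(missing))
    stop("labelled cell line(s) absent from screen: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  if (min(table(labs)) < 2L)
    stop("each group needs at least 2 cell lines", call. = FALSE)
  setNames(labs, names(groups))
}

# pooled + stratified fits for one labelling; pooled fit may be supplied to
# avoid recomputation across permutations (labels never change LL_all)
llr_fits <- function(sub, groups, init = NULL, fit_all = NULL,
                     quadrature = "laplace", nagq = 9L) {
  fit_grp <- function(lines)
    fit_nlme_pooled(sub[sub$cell_line %in% lines, , drop = FALSE],
                    init = init, quadrature = quadrature, nagq = nagq)
  if (is.null(fit_all)) fit_all <- fit_grp(names(groups))
  fit_p <- fit_grp(names(groups)[groups == "plus"])
  fit_m <- fit_grp(names(groups)[groups == "minus"])
  list(all = fit_all, plus = fit_p, minus = fit_m,
       llr = llr_from_loglik(fit_all$loglik, fit_p$loglik, fit_m$loglik),
       converged = fit_all$converged && fit_p$converged && fit_m$converged)
}

#' Omnibus likelihood-ratio statistic for a cell-line grouping
#'
#' Compares the pooled NLME fit over all labelled cell lines with separate
#' NLME fits in the `"plus"` and `"minus"` groups.  Because the stratified
#' model frees all four curve parameters (and both variance components) per
#' group, the statistic is sensitive to any difference in curve shape
#' between the groups, not just the IC50.
#'
#' @param screen A [dose_response_table()].
#' @param drug Drug identifier; may be omitted for single-drug screens.
#' @param groups Named `"plus"`/`"minus"` labels (see [median_split()]);
#'   each group needs at least 2 cell lines.
#' @param quadrature,nagq Passed to [fit_nlme_pooled()].
#' @return The LLR statistic (non-negative up to optimiser tolerance), with
#'   the three fits attached as attribute `"fits"`.
#' @export
llr_statistic <- function(screen, drug = NULL, groups,
                          quadrature = c("laplace", "agq"), nagq = 9L) {
  quadrature <- match.arg(quadrature)
  sub <- subset_drug(screen, drug)
  groups <- validate_groups(sub, groups)
  sub <- sub[sub$cell_line %in% names(groups), , drop = FALSE]
  fits <- llr_fits(sub, groups, quadrature = quadrature, nagq = nagq)
  if (!fits$converged)
    stop("NLME fit did not converge (pooled: ", fits$all$converged,
         ", plus: ", fits$plus$converged, ", minus: ", fits$minus$converged,
         ")", call. = FALSE)
  structure(fits$llr, fits = fits[c("all", "plus", "minus")])
}

#' Permutation p-value
#'
#' The standard add-one permutation p-value: `(1 + C) / (n + 1)` where `C`
#' counts permuted statistics strictly exceeding the observed one out of
#' `n` permutations.  Its smallest attainable value is `1/(n + 1)`.
#'
#' @param exceed_count Number of permuted statistics strictly greater than
#'   the observed statistic.
#' @param n_perm Number of permutations performed (>= 1).
#' @return The p-value.
#' @examples
#' perm_pvalue(0, 9999)  # 1e-4
#' @export
perm_pvalue <- function(exceed_count, n_perm) {
  if (length(exceed_count) != 1L || length(n_perm) != 1L ||
      n_perm < 1L || exceed_count < 0L || exceed_count > n_perm)
    stop("need 0 <= exceed_count <= n_perm and n_perm >= 1", call. = FALSE)
  (1 + exceed_count) / (n_perm + 1)
}

#' Omnibus LR NLME permutation test
#'
#' Tests whether the dose-response curves differ between two groups of cell
#' lines by comparing the observed [llr_statistic()] against its
#' permutation null: group labels are permuted across cell lines (each
#' line's wells move together), the LLR is recomputed per permutation, and
#' the p-value is `(1 + C)/(n + 1)` with `C` the number of permuted LLRs
#' strictly exceeding the observed one (ties do not count).
#'
#' Two permutation-budget devices are applied.  Early stopping: once the
#' exceedance count reaches `floor(alpha * (n_perm + 1))` the p-value can
#' no longer fall below `alpha`, so the loop stops and the p-value is
#' computed from the permutations performed.  Adaptive escalation: if the
#' initial pass completes with `p <= alpha`, the permutations are re-run
#' from scratch with `adaptive_n` permutations (fresh seed stream) so that
#' promising associations get a finer p-value resolution (down to
#' `1/(adaptive_n + 1)`).
#'
#' @inheritParams llr_statistic
#' @param n_perm Permutations in the initial pass (default 100).
#' @param alpha Screening level driving early stop and escalation.
#' @param adaptive_n Permutation count for the escalated pass; `NULL`
#'   disables escalation.
#' @param seed Integer seed making the permutation stream reproducible.
#' @return An object of class `"omnibus_result"`: list with `llr`,
#'   `n_perm` (permutations actually performed in the reported pass),
#'   `exceed_count`, `p_value`, `stopped_early`, `escalated`.
#' @export
omnibus_perm_test <- function(screen, drug = NULL, groups, n_perm = 100L,
                              alpha = 0.05, adaptive_n = 9999L, seed = NULL,
                              quadrature = c("laplace", "agq"), nagq = 9L) {
  quadrature <- match.arg(quadrature)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  sub <- subset_drug(screen, drug)
  groups <- validate_groups(sub, groups)
  sub <- sub[sub$cell_line %in% names(groups), , drop = FALSE]

  # pooled fit once: permuting labels never changes LL_all
  fit_all <- fit_nlme_pooled(sub, quadrature = quadrature, nagq = nagq)
  if (!fit_all$converged)
    stop("pooled NLME fit did not converge", call. = FALSE)
  init <- list(left = fit_all$fixed[["left"]],
               right = fit_all$fixed[["right"]],
               xmid = fit_all$fixed[["xmid"]],
               scale = fit_all$fixed[["scale"]],
               sd_xmid_re = fit_all$sd_xmid_re,
               sd_resid = fit_all$sd_resid)
  obs <- llr_fits(sub, groups, init = init, fit_all = fit_all,
                  quadrature = quadrature, nagq = nagq)
  if (!obs$converged)
    stop("group NLME fit did not converge for observed labels",
         call. = FALSE)
  llr_obs <- obs$llr

  run_pass <- function(np, pass_seed) {
    thresh <- floor(alpha * (np + 1))
    with_seed_opt(pass_seed, {
      C <- 0L
      done <- 0L
      stopped <- FALSE
      for (j in seq_len(np)) {
        perm <- setNames(sample(unname(groups)), names(groups))
        fits_j <- llr_fits(sub, perm, init = init, fit_all = fit_all,
                           quadrature = quadrature, nagq = nagq)
        # a failed stratified fit cannot certify exceedance was absent:
        # count it as an exceedance (conservative)
        llr_j <- if (fits_j$converged) fits_j$llr else Inf
        if (llr_j > llr_obs) C <- C + 1L
        done <- j
        if (thresh >= 1L && C >= thresh) { stopped <- TRUE; break }
      }
      list(C = C, done = done, stopped = stopped)
    })
  }

  pass <- run_pass(as.integer(n_perm), seed)
  escalated <- FALSE
  p <- perm_pvalue(pass$C, pass$done)
  if (!pass$stopped && !is.null(adaptive_n) && adaptive_n > n_perm &&
      p <= alpha) {
    escalated <- TRUE
    pass <- run_pass(as.integer(adaptive_n), child_seed(seed, 1L))
    p <- perm_pvalue(pass$C, pass$done)
  }
  structure(list(llr = llr_obs, n_perm = pass$done,
                 exceed_count = pass$C, p_value = p,
                 stopped_early = pass$stopped, escalated = escalated),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat("Omnibus LR NLME permutation test\n")
  cat("  LLR =", format(x$llr, digits = 6),
      "  p =", format(x$p_value, digits = 4),
      " (", x$exceed_count, "of", x$n_perm, "permutations exceeded )\n")
  if (x$stopped_early) cat("  stopped early (p cannot reach alpha)\n")
  if (x$escalated) cat("  escalated to an adaptive permutation pass\n")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (empty input returns empty).
#' @export
bonferroni_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "bonferroni")
}
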