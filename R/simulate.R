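#' Simulation scenario for a synthetic HTS screen
#'
#' Describes the generating model for a simulated nine-dose triplicate
#' drug screen over a panel of cell lines split into two expression groups.
#' Half the lines ("group 1") are over-expressers with intensities drawn
#' from `N(expr_high[1], expr_high[2])` and dose-response curves generated
#' from `group1`; the other half ("group 2") are under-expressers
#' (`N(expr_low[1], expr_low[2])`) with curves from `group2`.  Each line's
#' midpoint is drawn from a normal distribution centred at its group's
#' `xmid` with SD `xmid_re_sd`, and well-level Gaussian noise with SD
#' `noise_sd` is added to every response.  Setting `group2 = group1` gives
#' the null scenario in which expression carries no information about drug
#' response.
#'
#' @param n_lines Number of cell lines (must be even; half per group).
#' @param replicates Replicates per dose (default 3).
#' @param doses The nine screen concentrations in uM (default 0.02-10).
#' @param group1,group2 [fourpl()] parameters of the two groups; `group2`
#'   defaults to `group1` (null scenario).
#' @param xmid_re_sd SD of the per-line midpoint draw, log10 uM units
#'   (default 0.3).
#' @param noise_sd Well-noise SD in % viability: a scalar or one value per
#'   dose (default a constant 10).
#' @param expr_high,expr_low Mean and SD of the over-/under-expresser
#'   intensity distributions (defaults `c(8, 1)` and `c(3, 1)`).
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(n_lines = 50, group2 = fourpl(100, 10, 0, -0.5))
#' @export
scenario_spec <- function(n_lines = 50L, replicates = 3L,
                          doses = c(0.02, 0.04, 0.1, 0.2, 0.4,
                                    1, 2, 4, 10),
                          group1 = fourpl(100, 10, -0.5, -0.5),
                          group2 = group1,
                          xmid_re_sd = 0.3, noise_sd = 10,
                          expr_high = c(8, 1), expr_low = c(3, 1)) {
  n_lines <- as.integer(n_lines)
  replicates <- as.integer(replicates)
  if (n_lines < 2L || n_lines %% 2L != 0L)
    stop("n_lines must be an even number >= 2 (half per group)",
         call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (any(diff(doses) <= 0) || any(doses <= 0))
    stop("doses must be positive and strictly increasing", call. = FALSE)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, length(doses))
  if (length(noise_sd) != length(doses) || any(noise_sd <= 0))
    stop("noise_sd must be positive, one value per dose (or a scalar)",
         call. = FALSE)
  if (xmid_re_sd < 0) stop("xmid_re_sd must be >= 0", call. = FALSE)
  structure(list(n_lines = n_lines, replicates = replicates, doses = doses,
                 group1 = as_fourpl(group1), group2 = as_fourpl(group2),
                 xmid_re_sd = xmid_re_sd, noise_sd = noise_sd,
                 expr_high = expr_high, expr_low = expr_low),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Simulated screen scenario:", x$n_lines, "cell lines x",
      length(x$doses), "doses x", x$replicates, "replicates\n")
  cat("  group 1:"); print(x$group1)
  cat("  group 2:"); print(x$group2)
  cat("  xmid RE sd =", x$xmid_re_sd,
      " noise sd =", paste(unique(x$noise_sd), collapse = "/"),
      " expression N(", x$expr_high[1], ",", x$expr_high[2], ") vs N(",
      x$expr_low[1], ",", x$expr_low[2], ")\n")
  invisible(x)
}

#' Simulate a synthetic drug screen
#'
#' Draws one screen from a [scenario_spec()]: cell lines are randomly
#' split half/half into the two groups, each line receives a midpoint draw
#' and an expression intensity from its group, and every well gets
#' independent Gaussian noise.  Responses are not truncated at 0/100.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed; identical seeds reproduce the screen exactly.
#' @param drug Drug identifier placed in the table (default
#'   `"simulated_drug"`).
#' @return List with `screen` (a [dose_response_table()] of
#'   `n_lines * replicates * n_doses` rows), `expression` (named intensity
#'   vector), and `truth` (data frame of per-line group and generating
#'   parameters).
#' @export
simulate_screen <- function(spec, seed = NULL, drug = "simulated_drug") {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed_opt(seed, {
    n <- spec$n_lines
    lines <- sprintf("CL%03d", seq_len(n))
    perm <- sample(n)
    grp <- integer(n)
    grp[perm[seq_len(n / 2L)]] <- 1L   # over-expressers
    grp[perm[-seq_len(n / 2L)]] <- 2L  # under-expressers / altered curves
    pars <- list(spec$group1, spec$group2)
    xmid_i <- vapply(grp, function(g) rnorm(1, pars[[g]][["xmid"]],
                                            spec$xmid_re_sd), numeric(1))
    expr <- ifelse(grp == 1L,
                   rnorm(n, spec$expr_high[1], spec$expr_high[2]),
                   rnorm(n, spec$expr_low[1], spec$expr_low[2]))
    xs <- log10(spec$doses)
    nd <- length(xs)
    rep_id <- rep(rep(seq_len(spec$replicates), each = nd), times = n)
    dose_id <- rep(seq_len(nd), times = spec$replicates * n)
    line_id <- rep(seq_len(n), each = nd * spec$replicates)
    g <- grp[line_id]
    p_line <- function(field) vapply(seq_len(n), function(i) {
      v <- pars[[grp[i]]][[field]]
      if (field == "xmid") xmid_i[i] else v
    }, numeric(1))
    L <- p_line("left")[line_id]
    R <- p_line("right")[line_id]
    M <- xmid_i[line_id]
    S <- p_line("scale")[line_id]
    x <- xs[dose_id]
    mu <- R + (L - R) / (1 + exp((M - x) / S))
    y <- mu + rnorm(length(mu), 0, spec$noise_sd[dose_id])
    screen <- dose_response_table(data.frame(
      cell_line = lines[line_id], drug = drug,
      concentration_uM = spec$doses[dose_id],
      replicate = rep_id, response = y))
    truth <- data.frame(cell_line = lines,
                        group = paste0("group", grp),
                        left = p_line("left"), right = p_line("right"),
                        xmid = xmid_i, scale = p_line("scale"),
                        stringsAsFactors = FALSE)
    list(screen = screen, expression = setNames(expr, lines),
         truth = truth)
  })
}

# parameter levels explored by the simulation study
grid_levels <- list(left = c(100, 90, 80, 70),
                    right = c(10, 20, 30, 40),
                    xmid = c(-0.5, -0.4, -0.25, 0),
                    scale = c(-0.5, -0.4, -0.2))

#' Enumerate simulation scenarios over the parameter grid
#'
#' Builds the grid of alternative scenarios in which group 1 always has
#' curve `(100, 10, -0.5, -0.5)` and group 2's parameters run over the
#' study levels (`left` 100/90/80/70, `right` 10/20/30/40, `xmid`
#' -0.5/-0.4/-0.25/0, `scale` -0.5/-0.4/-0.2), optionally holding one
#' parameter fixed at a given value while the others vary.
#'
#' @param fixed Name of the parameter held fixed (`"left"`, `"right"`,
#'   `"xmid"`, `"scale"`), or `NULL` for the full cross (192 scenarios).
#' @param value Value at which `fixed` is held (must be one of its levels).
#' @param template A [scenario_spec()] providing everything except
#'   `group2` (panel size, noise, ...).
#' @param exclude Optional list of group-2 parameter vectors to drop.
#' @return List of [scenario_spec()] objects.
#' @examples
#' length(scenario_grid("left", 100))   # 48
#' length(scenario_grid("scale", -0.5)) # 64
#' length(scenario_grid())              # 192
#' @export
scenario_grid <- function(fixed = NULL, value = NULL,
                          template = scenario_spec(), exclude = NULL) {
  lv <- grid_levels
  if (!is.null(fixed)) {
    if (!fixed %in% names(lv))
      stop("unknown parameter '", fixed, "'", call. = FALSE)
    if (is.null(value) || !value %in% lv[[fixed]])
      stop("value must be one of the study levels for '", fixed, "'",
           call. = FALSE)
    lv[[fixed]] <- value
  }
  g <- expand.grid(left = lv$left, right = lv$right, xmid = lv$xmid,
                   scale = lv$scale, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(exclude)) {
    drop <- vapply(seq_len(nrow(g)), function(i)
      any(vapply(exclude, function(e)
        all(abs(as.numeric(g[i, ]) - as.numeric(e)) < 1e-9), logical(1))),
      logical(1))
    g <- g[!drop, , drop = FALSE]
  }
  lapply(seq_len(nrow(g)), function(i) {
    sp <- template
    sp$group2 <- fourpl(g$left[i], g$right[i], g$xmid[i], g$scale[i])
    sp
  })
}
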