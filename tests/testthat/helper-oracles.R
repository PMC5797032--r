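# Independent oracles and fixture builders.  The 4PL expression is written
# out by hand here so the oracles do not share code with the package paths
# they check.

# brute-force marginal log-likelihood: trapezoid integration of the random
# midpoint over +-6 sd_b with 2001 points, per cell line
bf_marginal_loglik <- function(left, right, xmid, scale, sd_b, sd_e,
                               screen) {
  tot <- 0
  for (cl in unique(screen$cell_line)) {
    d <- screen[screen$cell_line == cl, ]
    bs <- seq(-6 * sd_b, 6 * sd_b, length.out = 2001)
    lg <- vapply(bs, function(b) {
      mu <- right + (left - right) / (1 + exp((xmid + b - d$x) / scale))
      sum(dnorm(d$response, mu, sd_e, log = TRUE)) +
        dnorm(b, 0, sd_b, log = TRUE)
    }, numeric(1))
    mx <- max(lg)
    tot <- tot + mx + log(sum(exp(lg - mx)) * (bs[2] - bs[1]))
  }
  tot
}

# noiseless (or noisy) replicate table for given per-line 4PL parameters
make_screen <- function(params_by_line, doses = c(0.02, 0.04, 0.1, 0.2,
                                                  0.4, 1, 2, 4, 10),
                        replicates = 3, noise_sd = 0, drug = "drugA") {
  xs <- log10(doses)
  rows <- lapply(names(params_by_line), function(cl) {
    p <- params_by_line[[cl]]
    mu <- p[["right"]] + (p[["left"]] - p[["right"]]) /
      (1 + exp((p[["xmid"]] - xs) / p[["scale"]]))
    data.frame(cell_line = cl, drug = drug,
               concentration_uM = rep(doses, replicates),
               replicate = rep(seq_len(replicates), each = length(doses)),
               response = rep(mu, replicates) +
                 rnorm(length(doses) * replicates, 0, noise_sd))
  })
  dose_response_table(do.call(rbind, rows))
}
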