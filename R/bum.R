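#' Fit a beta-uniform mixture to a p-value collection
#'
#' Models the p-value density as `f(x) = lam + (1 - lam) * a * x^(a-1)`:
#' a uniform noise component of weight `lam` plus a `Beta(a, 1)` signal
#' component with `0 < a < 1`. Parameters are estimated by maximum
#' likelihood from a fixed 5 x 5 multi-start grid over
#' `(lam, a) in [0.05, 0.95]^2` followed by bounded quasi-Newton (L-BFGS-B),
#' so the fit is deterministic. Estimates pinned to a box boundary are
#' flagged with a warning.
#'
#' @param pvalues numeric vector of p-values in (0, 1]; exact zeros are
#'   clamped to 1e-300 with a warning.
#' @return object of class `bum_fit`: list with `lam`, `a`, `loglik`, `n`,
#'   `boundary`.
#' @export
fit_bum <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p))) stop_data("non-finite p-values in input")
  if (length(p) < 100L)
    stop_data("need >= 100 p-values to fit the mixture, got %d", length(p))
  if (any(p < 0 | p > 1)) stop_data("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning(sprintf("%d zero p-values clamped to 1e-300", sum(p == 0)))
    p[p == 0] <- 1e-300
  }
  logp <- log(p)
  negll <- function(par) {
    lam <- par[1L]; a <- par[2L]
    -sum(log(lam + (1 - lam) * a * exp((a - 1) * logp)))
  }
  grid <- seq(0.05, 0.95, length.out = 5L)
  lower <- c(0, 1e-6); upper <- c(1, 1 - 1e-6)
  cands <- list()
  for (l0 in grid) for (a0 in grid) {
    fit <- tryCatch(
      stats::optim(c(l0, a0), negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit)) cands[[length(cands) + 1L]] <- fit
  }
  # the pure-noise model lam = 1 (a then unidentified) as explicit candidate
  cands[[length(cands) + 1L]] <- list(par = c(1, 0.5), value = negll(c(1, 0.5)))
  if (length(cands) == 0L) stop_num("beta-uniform mixture fit failed to converge")
  vals <- vapply(cands, `[[`, numeric(1L), "value")
  # near the uniform limit the likelihood is flat along a -> 1 for any lam;
  # among near-ties (within 0.01 log-lik units) attribute the mass to noise
  near <- which(vals <= min(vals) + 0.01)
  lams <- vapply(cands[near], function(f) f$par[1L], numeric(1L))
  best <- cands[[near[which.max(lams)]]]
  lam <- best$par[1L]; a <- best$par[2L]
  boundary <- lam <= 1e-4 || lam >= 1 - 1e-4 || a <= 1e-4 || a >= 1 - 1e-4
  if (boundary)
    warning(sprintf("mixture estimate at parameter boundary (lam = %.4g, a = %.4g)",
                    lam, a))
  structure(list(lam = lam, a = a, loglik = -best$value, n = length(p),
                 boundary = boundary),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("beta-uniform mixture fit: lam = %.4f, a = %.4f (n = %d, loglik = %.2f)\n",
              x$lam, x$a, x$n, x$loglik))
  cat(sprintf("  upper bound on noise proportion pi = %.4f\n", pi_upper(x)))
  invisible(x)
}

#' Upper bound on the noise proportion of a fitted mixture
#'
#' Evaluates the fitted density at `x = 1`, `pi = lam + (1 - lam) * a`,
#' the conservative estimate of the uniform fraction used to control the
#' FDR of positively scored p-values.
#'
#' @param fit a `bum_fit` (or any list with `lam` and `a`).
#' @return numeric in (0, 1].
#' @export
pi_upper <- function(fit) fit$lam + (1 - fit$lam) * fit$a

#' Significance threshold controlling the FDR under the fitted mixture
#'
#' Returns the p-value threshold `tau` such that calling every `p < tau`
#' a signal yields an estimated false-discovery rate of `fdr`:
#' `tau = ((pi - fdr*lam) / (fdr*(1 - lam)))^(1/(a-1))` with
#' `pi = pi_upper(fit)`. `tau` increases monotonically with `fdr`.
#'
#' @param fit a `bum_fit`.
#' @param fdr target false-discovery rate in (0, 1).
#' @return numeric threshold in (0, 1).
#' @export
tau_from_fdr <- function(fit, fdr) {
  if (fdr <= 0 || fdr >= 1) stop_config("fdr must be in (0, 1)")
  lam <- fit$lam; a <- fit$a
  num <- pi_upper(fit) - fdr * lam
  if (lam >= 1 - 1e-12 || num <= 0)
    stop_num("FDR %g not attainable under fitted model (lam = %.4g, a = %.4g)",
             fdr, lam, a)
  tau <- (num / (fdr * (1 - lam)))^(1 / (a - 1))
  if (!is.finite(tau) || tau <= 0 || tau >= 1)
    stop_num("threshold tau = %g outside (0, 1); FDR %g not attainable", tau, fdr)
  tau
}

#' Differential-significance scores from a fitted mixture
#'
#' Scores each p-value by the signal/noise log-likelihood ratio of the
#' fitted `Beta(a, 1)`-versus-uniform decomposition, shifted to cross zero
#' at the threshold: `score(x) = (a - 1) * (log x - log tau)`. P-values
#' below `tau` (signal) score positively, those above (noise) negatively.
#'
#' @param fit a `bum_fit`.
#' @param fdr target FDR used to derive `tau` via [tau_from_fdr()].
#' @param pvalues named numeric vector (names are gene ids).
#' @return data.frame `gene`, `p`, `score` with attributes `tau`, `fdr`,
#'   `fit`; class `score_table`.
#' @export
score_pvalues <- function(fit, fdr, pvalues) {
  tau <- tau_from_fdr(fit, fdr)
  p <- as.numeric(pvalues)
  if (any(p <= 0)) {
    warning(sprintf("%d non-positive p-values clamped to 1e-300", sum(p <= 0)))
    p[p <= 0] <- 1e-300
  }
  score <- (fit$a - 1) * (log(p) - log(tau))
  out <- data.frame(gene = if (is.null(names(pvalues)))
                      as.character(seq_along(pvalues)) else names(pvalues),
                    p = p, score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tau") <- tau
  attr(out, "fdr") <- fdr
  attr(out, "fit") <- fit
  class(out) <- c("score_table", "data.frame")
  out
}

#' Choose the FDR whose positive fraction is closest to a target
#'
#' Scans a grid of candidate FDRs and returns the one for which the
#' fraction of p-values falling below `tau(FDR)` is closest to
#' `target_fraction` (the "approximately 10% of network nodes positive"
#' calibration). Ties break toward the smaller FDR; grid values whose
#' threshold is unattainable under the fit are skipped.
#'
#' @param fit a `bum_fit`.
#' @param pvalues numeric vector of p-values.
#' @param target_fraction desired positive fraction in (0, 1), default 0.10.
#' @param grid candidate FDRs; default 25 log-spaced values in
#'   `[1e-5, 0.5]`.
#' @return the selected FDR (with attribute `positive_fraction`).
#' @export
choose_fdr_for_fraction <- function(fit, pvalues, target_fraction = 0.10,
                                    grid = default_fdr_grid()) {
  if (target_fraction <= 0 || target_fraction >= 1)
    stop_config("target_fraction must be in (0, 1)")
  if (length(grid) == 0L) stop_config("FDR grid is empty")
  grid <- sort(unique(grid))
  frac <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    tau <- tryCatch(tau_from_fdr(fit, grid[i]), error = function(e) NA_real_)
    if (is.finite(tau)) frac[i] <- mean(pvalues < tau)
  }
  if (all(is.na(frac)))
    stop_num("no FDR on the grid is attainable under the fitted model")
  dist <- abs(frac - target_fraction)
  best <- which(dist == min(dist, na.rm = TRUE))[1L] # sorted grid: first = smallest FDR
  out <- grid[best]
  attr(out, "positive_fraction") <- frac[best]
  out
}

#' @rdname choose_fdr_for_fraction
#' @export
default_fdr_grid <- function() 10^seq(log10(1e-5), log10(0.5), length.out = 25L)

#' Quantile-quantile table of fitted mixture versus observed p-values
#'
#' Pairs the sorted observed p-values with the quantiles of the fitted
#' mixture CDF `F(x) = lam*x + (1 - lam)*x^a` at plotting positions
#' `(i - 0.5)/n`, for goodness-of-fit inspection.
#'
#' @param fit a `bum_fit`.
#' @param pvalues numeric vector.
#' @return data.frame with columns `theoretical`, `observed`.
#' @export
qq_table <- function(fit, pvalues) {
  obs <- sort(as.numeric(pvalues))
  n <- length(obs)
  probs <- (seq_len(n) - 0.5) / n
  theo <- bum_quantile(fit, probs)
  data.frame(theoretical = theo, observed = obs)
}

bum_cdf <- function(fit, x) fit$lam * x + (1 - fit$lam) * x^fit$a

# vectorized bisection inverse of the mixture CDF (monotone on [0,1])
bum_quantile <- function(fit, probs) {
  lo <- rep_len(0, length(probs)); hi <- rep_len(1, length(probs))
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    below <- bum_cdf(fit, mid) < probs
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Write a score table with its fit provenance
#'
#' Emits a one-line JSON header (`lam`, `a`, `fdr`, `tau`) as a `#` comment
#' followed by the gene/p/score TSV.
#'
#' @param st a `score_table` from [score_pvalues()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(st, path) {
  fit <- attr(st, "fit")
  hdr <- jsonlite::toJSON(list(lam = fit$lam, a = fit$a,
                               fdr = attr(st, "fdr"), tau = attr(st, "tau")),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
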