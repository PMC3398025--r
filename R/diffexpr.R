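#' Per-gene two-sample summary statistics
#'
#' Computes, for each gene, the case-minus-control mean difference, the
#' pooled within-group sample variance and the residual degrees of freedom
#' `n_case + n_control - 2`. These feed the empirical-Bayes variance
#' moderation.
#'
#' @param m an [expression_matrix()] with a case/control design and no
#'   missing values.
#' @return data.frame with columns `gene`, `mean_diff`, `s2`, `df_residual`.
#' @export
group_stats <- function(m) {
  if (is.null(m$group)) stop_data("expression matrix has no case/control design")
  if (anyNA(m$values)) stop_data("expression matrix contains missing values; impute first")
  case <- m$values[, m$group == "case", drop = FALSE]
  ctrl <- m$values[, m$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop_data("each group needs >= 2 samples (case %d, control %d)", n1, n2)
  ss1 <- rowSums((case - rowMeans(case))^2)
  ss2 <- rowSums((ctrl - rowMeans(ctrl))^2)
  df <- n1 + n2 - 2L
  data.frame(gene = rownames(m$values),
             mean_diff = rowMeans(case) - rowMeans(ctrl),
             s2 = (ss1 + ss2) / df,
             df_residual = df,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function, as used when matching moments
# of log sample variances to a scaled-F model.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x # asymptotic start
  for (iter in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Fit the variance prior for empirical-Bayes moderation
#'
#' Models per-gene sample variances as `s0sq * F(df_residual, d0)` and
#' estimates the prior degrees of freedom `d0` and prior variance `s0sq` by
#' matching the first two moments of `log(s2)`. When the spread of
#' `log(s2)` does not exceed the spread implied by sampling alone, `d0` is
#' unbounded (`Inf`) and every gene shrinks fully to `s0sq`.
#'
#' @param s2 numeric vector of pooled sample variances.
#' @param df_residual residual degrees of freedom (scalar or vector).
#' @return list with `d0` (possibly `Inf`) and `s0sq`, class
#'   `variance_prior`.
#' @export
fit_variance_prior <- function(s2, df_residual) {
  df_residual <- rep_len(df_residual, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L)
    stop_data("need >= 10 genes with positive variance, got %d", sum(ok))
  if (any(!ok))
    warning(sprintf("%d genes with non-positive variance excluded from prior fit",
                    sum(!ok)))
  z <- log(s2[ok])
  df <- df_residual[ok]
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(z) - mean(trigamma(df / 2))
  if (stats::var(z) < 1e-12) {
    # all sample variances identical: shrink fully to the common value
    out <- list(d0 = Inf, s0sq = exp(mean(z)))
  } else if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    out <- list(d0 = d0, s0sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  } else {
    out <- list(d0 = Inf, s0sq = exp(emean))
  }
  structure(out, class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance prior: d0 = %s, s0sq = %.4g\n",
              if (is.infinite(x$d0)) "Inf" else sprintf("%.3f", x$d0), x$s0sq))
  invisible(x)
}

#' Moderated t-statistics for a two-group design
#'
#' Shrinks each gene's pooled variance toward the prior,
#' `s2_post = (d0*s0sq + df*s2) / (d0 + df)`, forms
#' `t = mean_diff / sqrt(s2_post * (1/n_case + 1/n_control))` and converts
#' to a two-sided p-value on `df + d0` degrees of freedom (Gaussian tail
#' when `d0` is unbounded). Sign information stays in `mean_diff`.
#'
#' @param m an [expression_matrix()] with a case/control design.
#' @param prior optional `variance_prior`; fitted from the data when `NULL`.
#'   Pass `list(d0 = 0, s0sq = 1)` to recover the ordinary pooled t-test.
#' @return data.frame with columns `gene`, `mean_diff`, `s2`, `df_residual`,
#'   `t_mod`, `df_total`, `p`.
#' @export
moderated_t <- function(m, prior = NULL) {
  gs <- group_stats(m)
  if (is.null(prior)) prior <- fit_variance_prior(gs$s2, gs$df_residual)
  d0 <- prior$d0; s0sq <- prior$s0sq
  if (is.null(d0) || is.null(s0sq) || d0 < 0 || (is.finite(d0) && d0 > 0 && s0sq <= 0))
    stop_num("invalid variance prior (d0 = %s, s0sq = %s)", d0, s0sq)
  n1 <- sum(m$group == "case"); n2 <- sum(m$group == "control")
  c2 <- 1 / n1 + 1 / n2
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0sq, nrow(gs))
    df_total <- rep_len(Inf, nrow(gs))
  } else {
    s2_post <- (d0 * s0sq + gs$df_residual * gs$s2) / (d0 + gs$df_residual)
    df_total <- gs$df_residual + d0
  }
  t_mod <- gs$mean_diff / sqrt(s2_post * c2)
  degenerate <- !is.finite(t_mod)
  if (any(degenerate)) {
    warning(sprintf("%d genes with zero variance and no prior: p set to 1",
                    sum(degenerate)))
    t_mod[degenerate] <- 0
  }
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_mod)),
              2 * stats::pt(-abs(t_mod), df = df_total))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- gs
  out$t_mod <- t_mod
  out$df_total <- df_total
  out$p <- p
  attr(out, "prior") <- prior
  out
}

#' Write a differential-expression table to TSV
#'
#' @param de output of [moderated_t()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene", "mean_diff", "t_mod", "df_total", "p")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
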