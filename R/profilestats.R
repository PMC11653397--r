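## Profile similarity and group statistics: cosine similarity between
## metabolite profiles, two-way (sex x genotype) ANOVA with Type-II sums
## of squares and Bonferroni-corrected pairwise cell comparisons, and
## mean +/- SD group summaries.

#' Cosine similarity between two metabolite profiles
#'
#' `cos theta = sum(p q) / (||p|| ||q||)` over a shared metabolite panel:
#' 1 for identical relative profiles, 0 for completely different
#' (disjoint) ones. Scale-invariant and symmetric; bounded in [0, 1] for
#' non-negative profiles.
#'
#' @param p,q Non-negative numeric vectors over the same ordered panel.
#' @return Similarity in [0, 1].
#' @examples
#' cosTheta(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosTheta <- function(p, q) {
  if (length(p) != length(q)) stop("profiles must share the same panel")
  if (any(p < 0) || any(q < 0)) stop("profiles must be non-negative")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) stop("zero profile vector")
  sum(p * q) / (np * nq)
}

#' Pairwise cosine similarity matrix
#'
#' @param profiles Numeric matrix, one profile per row (rownames become
#'   dimnames), or a data.frame of numeric columns per metabolite.
#' @return Symmetric matrix with unit diagonal.
#' @export
similarityMatrix <- function(profiles) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L) stop("need at least two profiles")
  n <- nrow(m)
  out <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out[i, j] <- out[j, i] <- cosTheta(m[i, ], m[j, ])
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Two-way ANOVA with Bonferroni pairwise comparisons
#'
#' Fits `response ~ factor_a * factor_b` and reports Type-II sums of
#' squares (appropriate for the unbalanced group sizes typical of animal
#' studies) for both main effects and the interaction, then compares all
#' factor-cell pairs with t-tests on the residual mean square, adjusting
#' each p-value by multiplying by the number of comparisons (capped at
#' 1). Significance is judged at p < 0.05.
#'
#' @param data data.frame holding the response and two factor columns.
#' @param response Response column name.
#' @param factor_a,factor_b Factor column names (e.g. sex, genotype).
#' @param log_transform Apply log() to the response before fitting
#'   (default FALSE).
#' @return list: `anova` (term, df, sum_sq, f, p), `pairwise`
#'   (group1, group2, diff, t, df, p, p_adj, significant), `mse`,
#'   `df_residual`.
#' @export
twoWayAnovaBonferroni <- function(data, response, factor_a = "sex",
                                  factor_b = "genotype",
                                  log_transform = FALSE) {
  y <- data[[response]]
  if (log_transform) y <- log(y)
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  cell <- interaction(fa, fb, sep = "_", drop = TRUE)
  cn <- table(cell)
  if (any(cn < 2L))
    stop("fewer than 2 samples in cell(s): ",
         paste(names(cn)[cn < 2L], collapse = ", "))
  d <- data.frame(y = y, fa = fa, fb = fb)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    ## single-level factor: collapse to a one-way ANOVA on the other
    f1 <- if (nlevels(fa) >= 2L) fa else fb
    f1name <- if (nlevels(fa) >= 2L) factor_a else factor_b
    fit <- stats::lm(y ~ f1, data = data.frame(y = y, f1 = f1))
    a1 <- stats::anova(fit)
    anova_tab <- data.frame(term = f1name, df = a1$Df[1],
                            sum_sq = a1$`Sum Sq`[1], f = a1$`F value`[1],
                            p = a1$`Pr(>F)`[1], stringsAsFactors = FALSE)
  } else if (stats::var(y) == 0) {
    ## constant response: every sum of squares is zero
    fit <- stats::lm(y ~ fa * fb, data = d)
    anova_tab <- data.frame(
      term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
      df = c(nlevels(fa) - 1L, nlevels(fb) - 1L,
             (nlevels(fa) - 1L) * (nlevels(fb) - 1L)),
      sum_sq = 0, f = 0, p = 1, stringsAsFactors = FALSE)
  } else {
    fit <- stats::lm(y ~ fa * fb, data = d)
    a2 <- car::Anova(fit, type = 2)
    terms <- rownames(a2)
    keep <- terms != "Residuals"
    anova_tab <- data.frame(
      term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b))[
        match(terms[keep], c("fa", "fb", "fa:fb"))],
      df = a2$Df[keep], sum_sq = a2$`Sum Sq`[keep],
      f = a2$`F value`[keep], p = a2$`Pr(>F)`[keep],
      stringsAsFactors = FALSE)
  }
  if (stats::var(y) == 0) {   # no variance anywhere: F := 0, p := 1
    anova_tab$f <- 0
    anova_tab$p <- 1
  }

  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  means <- tapply(y, cell, mean)
  ns <- as.numeric(cn)
  lev <- names(means)
  pairs <- utils::combn(seq_along(lev), 2)
  ncomp <- ncol(pairs)
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  if (mse > 0) {
    se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    tval <- diff / se
    p <- 2 * stats::pt(-abs(tval), fit$df.residual)
  } else {
    tval <- rep(0, ncomp)
    p <- rep(1, ncomp)
  }
  pairwise <- data.frame(
    group1 = lev[pairs[1, ]], group2 = lev[pairs[2, ]],
    diff = as.numeric(diff), t = as.numeric(tval),
    df = fit$df.residual, p = as.numeric(p),
    p_adj = pmin(1, as.numeric(p) * ncomp), stringsAsFactors = FALSE)
  pairwise$significant <- pairwise$p_adj < 0.05
  list(anova = anova_tab, pairwise = pairwise, mse = mse,
       df_residual = fit$df.residual)
}

#' Group mean +/- SD summary with fold ratios
#'
#' Sample SD (n - 1 denominator). When a second value set is supplied the
#' per-group ratio of means (e.g. summed metabolites over parent) is
#' reported as `fold_ratio`.
#'
#' @param values Numeric response values.
#' @param group Grouping labels, same length.
#' @param denom_values Optional second value set for the fold ratio.
#' @return data.frame `group`, `n`, `mean`, `sd` (and `fold_ratio`).
#' @export
groupSummary <- function(values, group, denom_values = NULL) {
  sp <- split(seq_along(values), group)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    idx <- sp[[g]]
    v <- values[idx]
    row <- data.frame(group = g, n = length(v), mean = mean(v),
                      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(denom_values))
      row$fold_ratio <- mean(v) / mean(denom_values[idx])
    row
  }))
  rownames(out) <- NULL
  out
}

#' Substitute below-LOQ values for statistics
#'
#' @param concentration Numeric concentrations.
#' @param below_loq Logical below-LOQ flags.
#' @param loq LOQ value(s), recycled.
#' @param method One of `"half"` (LOQ/2, default), `"zero"`,
#'   `"sqrt2"` (LOQ/sqrt(2)).
#' @return Concentrations with flagged values substituted.
#' @export
imputeBelowLoq <- function(concentration, below_loq, loq,
                           method = c("half", "zero", "sqrt2")) {
  method <- match.arg(method)
  sub <- switch(method, half = loq / 2, zero = 0 * loq, sqrt2 = loq / sqrt(2))
  sub <- rep_len(sub, length(concentration))
  ifelse(below_loq, sub, concentration)
}
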