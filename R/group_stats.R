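# Orthonormal contrast basis for k levels (k x (k-1), columns orthonormal
# and orthogonal to the unit vector).
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon from the sample covariance S of the k
# repeated measures: eps = tr(M)^2 / (d * sum(M^2)) with M the covariance
# of the orthonormal within-subject contrasts. For a factorial effect,
# pass the Kronecker contrast basis via `C`.
gg_epsilon <- function(S, C = orthonormal_contrasts(ncol(S))) {
  M <- t(C) %*% S %*% C
  d <- ncol(M)
  if (d == 0) return(1)
  eps <- sum(diag(M))^2 / (d * sum(M^2))
  min(max(eps, 1 / d), 1)
}

# Shape a long table into a subjects x cells matrix, enforcing a complete
# crossed design.
cells_matrix <- function(data, value, subject, within) {
  f <- lapply(within, function(w) factor(data[[w]]))
  # first factor varies fastest in the cell ordering
  cell <- do.call(interaction, c(f, list(sep = ":", lex.order = FALSE)))
  subj <- factor(data[[subject]])
  tab <- table(subj, cell)
  if (any(tab != 1))
    stop("incomplete design: each subject must contribute exactly one ",
         "value per factor-level combination", call. = FALSE)
  Y <- tapply(data[[value]], list(subj, cell), mean)
  levs <- lapply(f, levels)
  names(levs) <- within
  list(Y = Y, levels = levs)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subjects ANOVA for one or two crossed within-subject factors,
#' computed from the classical sum-of-squares decomposition: each effect
#' is tested against its own subject-by-effect interaction. The
#' Greenhouse-Geisser epsilon for each effect is estimated from the
#' sample covariance of the within-subject scores (collapsed over the
#' other factor for main effects, double-contrasted for the interaction);
#' both uncorrected and epsilon-corrected p values are always returned,
#' with `correction_applied` flagging effects whose epsilon falls below
#' 0.75 (a transparent sphericity-violation heuristic; both p values
#' remain available either way).
#'
#' @param data Long-format data.frame.
#' @param value,subject Column names of the response and subject id.
#' @param within Character vector of one or two within-subject factor
#'   column names.
#' @return A data.frame with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p`, `gg_epsilon`, `df1_gg`, `df2_gg`, `p_gg`,
#'   `correction_applied`.
#' @export
rm_anova <- function(data, value = "value", subject = "subject",
                     within = "condition") {
  stopifnot(is.data.frame(data),
            all(c(value, subject, within) %in% names(data)))
  if (!length(within) %in% 1:2)
    stop("within must name one or two factors", call. = FALSE)
  for (w in within)
    if (length(unique(data[[w]])) < 2)
      stop("invalid design: factor '", w, "' has fewer than 2 levels",
           call. = FALSE)
  n_subj <- length(unique(data[[subject]]))
  if (n_subj < 2)
    stop("invalid design: need at least 2 subjects", call. = FALSE)

  if (length(within) == 1) {
    cm <- cells_matrix(data, value, subject, within)
    Y <- cm$Y
    n <- nrow(Y); k <- ncol(Y)
    grand <- mean(Y)
    ss_subj <- k * sum((rowMeans(Y) - grand)^2)
    ss_a <- n * sum((colMeans(Y) - grand)^2)
    ss_tot <- sum((Y - grand)^2)
    ss_err <- ss_tot - ss_subj - ss_a
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    F_ <- (ss_a / df1) / (ss_err / df2)
    eps <- gg_epsilon(stats::cov(Y))
    res <- data.frame(effect = within, F = F_, df1 = df1, df2 = df2,
                      p = stats::pf(F_, df1, df2, lower.tail = FALSE),
                      gg_epsilon = eps)
  } else {
    cm <- cells_matrix(data, value, subject, within)
    a_lab <- within[1]; b_lab <- within[2]
    a <- length(cm$levels[[a_lab]]); b <- length(cm$levels[[b_lab]])
    n <- nrow(cm$Y)
    # cell columns vary factor A fastest; reshape to n x a x b
    Yc <- array(cm$Y, dim = c(n, a, b))
    grand <- mean(Yc)
    Ma <- apply(Yc, c(1, 2), mean)         # collapse over B
    Mb <- apply(Yc, c(1, 3), mean)         # collapse over A
    ss_a <- n * b * sum((colMeans(Ma) - grand)^2)
    ss_b <- n * a * sum((colMeans(Mb) - grand)^2)
    ss_as <- b * sum((Ma - outer(rowMeans(Ma), rep(1, a)) -
                        outer(rep(1, n), colMeans(Ma)) + grand)^2)
    ss_bs <- a * sum((Mb - outer(rowMeans(Mb), rep(1, b)) -
                        outer(rep(1, n), colMeans(Mb)) + grand)^2)
    cell_means <- apply(Yc, c(2, 3), mean)
    a_means <- colMeans(Ma); b_means <- colMeans(Mb)
    inter <- cell_means - outer(a_means, rep(1, b)) -
      outer(rep(1, a), b_means) + grand
    ss_ab <- n * sum(inter^2)
    ss_tot <- sum((Yc - grand)^2)
    ss_subj <- a * b * sum((apply(Yc, 1, mean) - grand)^2)
    ss_abs <- ss_tot - ss_subj - ss_a - ss_as - ss_b - ss_bs - ss_ab
    eff <- c(a_lab, b_lab, paste0(a_lab, ":", b_lab))
    df1 <- c(a - 1, b - 1, (a - 1) * (b - 1))
    df2 <- (n - 1) * df1
    F_ <- c((ss_a / df1[1]) / (ss_as / df2[1]),
            (ss_b / df1[2]) / (ss_bs / df2[2]),
            (ss_ab / df1[3]) / (ss_abs / df2[3]))
    Ca <- orthonormal_contrasts(a)
    Cb <- orthonormal_contrasts(b)
    S_cells <- stats::cov(matrix(Yc, n, a * b))
    # cells are (A fastest, B slowest): kron(C_B, C_A) matches that order
    eps <- c(gg_epsilon(stats::cov(Ma), Ca),
             gg_epsilon(stats::cov(Mb), Cb),
             gg_epsilon(S_cells, kronecker(Cb, Ca)))
    res <- data.frame(effect = eff, F = F_, df1 = df1, df2 = df2,
                      p = stats::pf(F_, df1, df2, lower.tail = FALSE),
                      gg_epsilon = eps)
  }
  res$df1_gg <- res$gg_epsilon * res$df1
  res$df2_gg <- res$gg_epsilon * res$df2
  res$p_gg <- stats::pf(res$F, res$df1_gg, res$df2_gg,
                        lower.tail = FALSE)
  res$correction_applied <- res$gg_epsilon < 0.75
  rownames(res) <- NULL
  structure(res, class = c("anova_result", "data.frame"))
}

#' Holm step-down multiple-comparison correction
#'
#' Step-down Holm adjustment with monotonicity enforcement; the adjusted
#' values are returned in the order of the input.
#'
#' @param pvals Numeric vector of p values in (0, 1].
#' @return Adjusted p values, elementwise at least as large as the input.
#' @export
holm_correct <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p values must lie in (0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Planned paired comparisons within a repeated-measures factor
#'
#' Paired t tests (two-sided, df = n - 1) for pre-declared level pairs of
#' a within-subject factor, with no multiplicity correction (the
#' comparisons are planned). Pairs whose differences have zero variance
#' are degenerate: all-zero differences give t = 0, p = 1; a constant
#' non-zero difference cannot be tested and is returned as `NA` with a
#' warning.
#'
#' @param data Long-format data.frame.
#' @param value,subject Column names of response and subject id.
#' @param factor_name Column name of the within-subject factor.
#' @param pairs List of length-2 character vectors of level labels.
#' @return A data.frame: `level_a`, `level_b`, `mean_diff`, `t`, `df`,
#'   `p`, `degenerate`.
#' @export
planned_paired_comparisons <- function(data, value = "value",
                                       subject = "subject",
                                       factor_name = "treatment",
                                       pairs) {
  stopifnot(is.data.frame(data),
            all(c(value, subject, factor_name) %in% names(data)))
  levs <- unique(as.character(data[[factor_name]]))
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- as.character(pairs[[i]])
    if (length(pr) != 2 || !all(pr %in% levs))
      stop("unknown level in pair: ", paste(pr, collapse = " vs "),
           call. = FALSE)
    da <- data[data[[factor_name]] == pr[1], c(subject, value)]
    db <- data[data[[factor_name]] == pr[2], c(subject, value)]
    xa <- tapply(da[[value]], da[[subject]], mean)
    xb <- tapply(db[[value]], db[[subject]], mean)
    common <- intersect(names(xa), names(xb))
    d <- xa[common] - xb[common]
    n <- length(d)
    if (n < 2) stop("need at least 2 subjects per pair", call. = FALSE)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      if (all(d == 0)) {
        row <- data.frame(level_a = pr[1], level_b = pr[2],
                          mean_diff = 0, t = 0, df = n - 1, p = 1,
                          degenerate = FALSE)
      } else {
        warning("degenerate comparison (zero variance of non-zero ",
                "differences): ", pr[1], " vs ", pr[2], call. = FALSE)
        row <- data.frame(level_a = pr[1], level_b = pr[2],
                          mean_diff = mean(d), t = NA_real_, df = n - 1,
                          p = NA_real_, degenerate = TRUE)
      }
    } else {
      tt <- stats::t.test(xa[common], xb[common], paired = TRUE)
      row <- data.frame(level_a = pr[1], level_b = pr[2],
                        mean_diff = mean(d),
                        t = unname(tt$statistic),
                        df = unname(tt$parameter),
                        p = tt$p.value, degenerate = FALSE)
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch ANOVA with Monte-Carlo Dunnett many-to-one comparisons
#'
#' Welch's heteroscedastic F test across groups, followed by Dunnett-style
#' comparisons of every group against the control with family-wise error
#' controlled by a seeded Monte-Carlo evaluation of the null distribution
#' of the maximum absolute Welch t over the family (group means and
#' variances resampled from their normal/scaled-chi-square sampling
#' distributions under the null).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @param control_index Index of the control group (default 1).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Integer seed for the Monte-Carlo null.
#' @return A list: `F`, `df1`, `df2`, `p` (Welch ANOVA) and `dunnett`, a
#'   data.frame with per-comparison `t`, `df`, `p_adj`.
#' @export
welch_anova_dunnett <- function(groups, control_index = 1,
                                n_mc = 100000, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  means <- vapply(groups, mean, 1)
  vars <- vapply(groups, stats::var, 1)
  comp <- setdiff(seq_len(k), control_index)

  if (all(vars == 0) && length(unique(means)) == 1) {
    dun <- data.frame(group = names(groups)[comp], t = 0,
                      df = ns[comp] - 1, p_adj = 1)
    return(list(F = 0, df1 = k - 1, df2 = Inf, p = 1, dunnett = dun))
  }
  if (any(vars == 0))
    stop("Welch ANOVA undefined for a zero-variance group with unequal ",
         "means", call. = FALSE)
  w <- ns / vars
  W <- sum(w)
  mw <- sum(w * means) / W
  A <- sum(w * (means - mw)^2) / (k - 1)
  h <- sum((1 - w / W)^2 / (ns - 1))
  B <- 1 + 2 * (k - 2) * h / (k^2 - 1)
  F_ <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * h)
  p <- stats::pf(F_, df1, df2, lower.tail = FALSE)

  i0 <- control_index
  se2 <- vars[comp] / ns[comp] + vars[i0] / ns[i0]
  t_obs <- (means[comp] - means[i0]) / sqrt(se2)
  df_w <- se2^2 / ((vars[comp] / ns[comp])^2 / (ns[comp] - 1) +
                     (vars[i0] / ns[i0])^2 / (ns[i0] - 1))
  max_null <- local_seed(seed, {
    # resample each group's mean and variance under the null
    m_star <- vapply(seq_len(k), function(j)
      stats::rnorm(n_mc, 0, sqrt(vars[j] / ns[j])), numeric(n_mc))
    v_star <- vapply(seq_len(k), function(j)
      vars[j] * stats::rchisq(n_mc, ns[j] - 1) / (ns[j] - 1),
      numeric(n_mc))
    tmax <- rep(0, n_mc)
    for (j in comp) {
      tj <- abs(m_star[, j] - m_star[, i0]) /
        sqrt(v_star[, j] / ns[j] + v_star[, i0] / ns[i0])
      tmax <- pmax(tmax, tj)
    }
    tmax
  })
  p_adj <- vapply(abs(t_obs), function(tv)
    (1 + sum(max_null >= tv)) / (n_mc + 1), 1)
  dun <- data.frame(group = names(groups)[comp], t = unname(t_obs),
                    df = unname(df_w), p_adj = unname(p_adj))
  rownames(dun) <- NULL
  list(F = unname(F_), df1 = df1, df2 = unname(df2), p = unname(p),
       dunnett = dun)
}

#' Two-SD outlier filter
#'
#' Single-pass removal of values `k` or more standard deviations above or
#' below the group mean, with mean and SD computed from the full input
#' (no re-iteration after removal). The SD uses the population (1/n)
#' denominator and the bound is inclusive, so a value exactly `k` SD from
#' the mean is removed; a zero-SD (all-equal) group removes nothing.
#'
#' @param values Numeric vector, length >= 3.
#' @param k SD multiple (default 2).
#' @return A list: `kept` (values retained) and `removed` (indices into
#'   the input that were removed).
#' @export
outlier_filter <- function(values, k = 2) {
  values <- as.numeric(values)
  if (length(values) < 3)
    stop("need at least 3 values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / n)
  removed <- if (s > 0) which(abs(values - m) >= k * s) else integer(0)
  list(kept = if (length(removed)) values[-removed] else values,
       removed = removed)
}
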