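# Behavioral statistics: one-way and 3x2 factorial ANOVA with simple
# effects and eta-squared effect sizes, summary-statistics ANOVA for
# auditing printed mean +/- SD tables, and multiple linear regression with
# variance-inflation-factor diagnostics. Model fitting goes through
# stats::aov / stats::lm; this module owns the decomposition bookkeeping,
# effect sizes, simple-effect error terms, and VIF.

anova_result <- function(table, posthoc = NULL, design = "one-way") {
  structure(list(table = table, posthoc = posthoc, design = design),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> (%s)\n", x$design))
  print(x$table, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("post hoc (Bonferroni):\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

pairwise_direction <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) return(NULL)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  # pooled-SD two-sample t tests with Bonferroni correction
  rows <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    p <- 2 * stats::pt(-abs(tstat), length(x) + length(y) - 2)
    data.frame(group1 = pr[1], group2 = pr[2],
               mean_diff = mean(x) - mean(y),
               statistic = tstat, p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p.adjusted <- pmin(1, out$p.value * n_pairs)
  out$direction <- ifelse(
    out$p.adjusted < alpha,
    ifelse(out$mean_diff > 0,
           paste(out$group1, ">", out$group2),
           paste(out$group2, ">", out$group1)),
    "n.s."
  )
  out
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition (`F = MSB / MSW`) via
#' [stats::aov()], with classical eta-squared (`SSB / SST`) and
#' Bonferroni-corrected pooled-SD pairwise comparisons.
#'
#' @param values numeric response.
#' @param group_labels grouping vector (>= 2 groups, each with >= 2
#'   observations).
#' @return an `anova_result`; `$table` has rows for the group effect and
#'   residuals with `df`, `sum_sq`, `mean_sq`, `statistic`, `p.value`,
#'   `eta_sq`.
#' @export
one_way_anova <- function(values, group_labels) {
  values <- as.numeric(values)
  g <- factor(as.character(group_labels))
  if (length(values) != length(g)) {
    stop("`values` and `group_labels` must align", call. = FALSE)
  }
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  cnt <- table(g)
  if (any(cnt < 2)) {
    stop("every group needs >= 2 observations; offending group(s): ",
         paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  ss <- summary(fit)[[1]]
  sst <- sum(ss[["Sum Sq"]])
  table <- data.frame(
    term = c("group", "Residuals"),
    df = ss[["Df"]],
    sum_sq = ss[["Sum Sq"]],
    mean_sq = ss[["Mean Sq"]],
    statistic = ss[["F value"]],
    p.value = ss[["Pr(>F)"]],
    eta_sq = ss[["Sum Sq"]] / sst,
    stringsAsFactors = FALSE
  )
  anova_result(table, posthoc = pairwise_direction(values, g),
               design = "one-way")
}

#' Two-way (3x2) factorial analysis of variance
#'
#' Full-factorial decomposition `dv ~ A * B` with F and p per effect and
#' both classical eta-squared (`SS_effect / SS_total`) and partial
#' eta-squared (`SS_effect / (SS_effect + SS_error)`). The classical
#' decomposition requires a balanced complete layout; unbalanced input
#' either errors (default) or uses Type II sums of squares
#' (`type = "II"`, via `car::Anova`).
#'
#' @param dv numeric response.
#' @param factor_a,factor_b factor vectors (e.g. emotion and
#'   psychological-capital group).
#' @param type `"classical"` (balanced Type I, default) or `"II"`.
#' @param names_ab labels for the two factors in the output table.
#' @return an `anova_result` with rows A, B, A:B, Residuals.
#' @export
two_way_anova <- function(dv, factor_a, factor_b,
                          type = c("classical", "II"),
                          names_ab = c("A", "B")) {
  type <- match.arg(type)
  dv <- as.numeric(dv)
  fa <- factor(as.character(factor_a))
  fb <- factor(as.character(factor_b))
  if (length(dv) != length(fa) || length(dv) != length(fb)) {
    stop("`dv` and both factors must align", call. = FALSE)
  }
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    # degenerate layout: a constant factor carries no sum of squares, so
    # the design collapses to a one-way ANOVA on the varying factor
    varying <- if (nlevels(fa) >= 2) fa else fb
    ow <- one_way_anova(dv, varying)$table
    zero_a <- nlevels(fa) < 2
    sum_sq <- c(if (zero_a) 0 else ow$sum_sq[1],
                if (zero_a) ow$sum_sq[1] else 0,
                0, ow$sum_sq[2])
    df <- c(if (zero_a) 0 else ow$df[1],
            if (zero_a) ow$df[1] else 0,
            0, ow$df[2])
    ms <- ifelse(df > 0, sum_sq / df, NA)
    fstat <- c(ms[1:3] / ms[4], NA)
    pval <- c(stats::pf(fstat[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
    sst <- sum(sum_sq)
    table <- data.frame(
      term = c(names_ab[1], names_ab[2],
               paste0(names_ab[1], ":", names_ab[2]), "Residuals"),
      df = df, sum_sq = sum_sq, mean_sq = ms,
      statistic = fstat, p.value = pval,
      eta_sq = sum_sq / sst,
      partial_eta_sq = c(sum_sq[1:3] / (sum_sq[1:3] + sum_sq[4]), NA),
      stringsAsFactors = FALSE
    )
    return(anova_result(table, design = "two-way (degenerate)"))
  }
  balanced <- length(unique(as.vector(cells))) == 1L
  if (!balanced && type == "classical") {
    stop("unbalanced layout: the classical decomposition needs equal cell ",
         "counts; use type = \"II\"", call. = FALSE)
  }
  if (type == "classical") {
    fit <- stats::aov(dv ~ fa * fb)
    ss <- summary(fit)[[1]]
    sum_sq <- ss[["Sum Sq"]]
    df <- ss[["Df"]]
  } else {
    fit <- stats::lm(dv ~ fa * fb)
    a2 <- car::Anova(fit, type = 2)
    ord <- c("fa", "fb", "fa:fb", "Residuals")
    a2 <- a2[ord, ]
    sum_sq <- a2[["Sum Sq"]]
    df <- a2[["Df"]]
  }
  nr <- length(sum_sq)
  ss_err <- sum_sq[nr]
  ms <- sum_sq / df
  fstat <- c(ms[-nr] / ms[nr], NA)
  pval <- c(stats::pf(fstat[-nr], df[-nr], df[nr], lower.tail = FALSE), NA)
  sst <- sum(sum_sq)
  table <- data.frame(
    term = c(names_ab[1], names_ab[2],
             paste0(names_ab[1], ":", names_ab[2]), "Residuals"),
    df = df, sum_sq = sum_sq, mean_sq = ms,
    statistic = fstat, p.value = pval,
    eta_sq = sum_sq / sst,
    partial_eta_sq = c(sum_sq[-nr] / (sum_sq[-nr] + ss_err), NA),
    stringsAsFactors = FALSE
  )
  anova_result(table, design = sprintf("two-way (%s)", type))
}

#' Simple effects in a factorial design
#'
#' Tests the focal factor separately within each level of the moderator.
#' The default error term is the pooled residual mean square of the full
#' two-way model (`F = MS_focal(level) / MSW_pooled`, error df from the
#' full model); `error = "within"` instead uses only that level's data,
#' reproducing a one-way ANOVA restricted to the level. Significant
#' effects carry Bonferroni pairwise comparisons with direction
#' (e.g. `"fear > anger"`).
#'
#' @param dv numeric response.
#' @param focal_factor factor whose effect is tested.
#' @param moderator factor whose levels define the strata.
#' @param levels moderator levels to test (default all).
#' @param error `"pooled"` (default) or `"within"`.
#' @return list with `table` (one row per moderator level: `level`, `df1`,
#'   `df2`, `sum_sq`, `mean_sq`, `statistic`, `p.value`) and `posthoc`
#'   (named list of pairwise tables).
#' @export
simple_effects <- function(dv, focal_factor, moderator, levels = NULL,
                           error = c("pooled", "within")) {
  error <- match.arg(error)
  dv <- as.numeric(dv)
  ff <- factor(as.character(focal_factor))
  mod <- factor(as.character(moderator))
  if (is.null(levels)) levels <- base::levels(mod)
  unknown <- setdiff(levels, base::levels(mod))
  if (length(unknown) > 0) {
    stop("unknown moderator level(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- two_way_anova(dv, ff, mod)
  msw <- full$table$mean_sq[4]
  df_err_full <- full$table$df[4]
  rows <- list()
  posthoc <- list()
  for (lv in levels) {
    sel <- mod == lv
    d <- dv[sel]
    f <- droplevels(ff[sel])
    # between-group SS of the focal factor within this stratum
    gm <- mean(d)
    cell_means <- tapply(d, f, mean)
    cell_n <- tapply(d, f, length)
    ssb <- sum(cell_n * (cell_means - gm)^2)
    df1 <- nlevels(f) - 1
    if (error == "pooled") {
      ms_focal <- ssb / df1
      fstat <- ms_focal / msw
      df2 <- df_err_full
    } else {
      ssw <- sum((d - cell_means[f])^2)
      df2 <- length(d) - nlevels(f)
      ms_focal <- ssb / df1
      fstat <- ms_focal / (ssw / df2)
    }
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    rows[[lv]] <- data.frame(level = lv, df1 = df1, df2 = df2,
                             sum_sq = ssb, mean_sq = ms_focal,
                             statistic = fstat, p.value = p,
                             stringsAsFactors = FALSE)
    posthoc[[lv]] <- pairwise_direction(d, f)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       posthoc = posthoc)
}

#' ANOVA from cell summary statistics
#'
#' Recomputes a one- or two-way ANOVA from per-cell mean, SD and n alone —
#' the information printed in a "mean +/- SD" table. Internally each cell
#' is expanded into a surrogate sample with exactly the stated mean and SD
#' (the F statistic depends on the data only through those summaries), so
#' the result is identical to the raw-data ANOVA whenever the summaries
#' came from raw data.
#'
#' @param means,sds,ns equal-shape numeric vectors (one-way, names =
#'   groups) or matrices (two-way, rownames = factor A levels, colnames =
#'   factor B levels).
#' @return an `anova_result` matching [one_way_anova()] or
#'   [two_way_anova()].
#' @export
anova_from_summary <- function(means, sds, ns) {
  if (!all(dim(as.matrix(means)) == dim(as.matrix(sds))) ||
      !all(dim(as.matrix(means)) == dim(as.matrix(ns)))) {
    stop("`means`, `sds`, `ns` must have identical shape", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(means))) || any(!is.finite(as.matrix(sds)))) {
    stop("missing or non-finite cell summaries", call. = FALSE)
  }
  if (any(ns < 2)) stop("every cell needs n >= 2", call. = FALSE)
  if (any(sds < 0)) stop("cell SDs must be >= 0", call. = FALSE)
  surrogate <- function(m, s, n) {
    u <- scale(seq_len(n))[, 1]  # mean 0, sd 1
    m + s * u
  }
  if (is.matrix(means)) {
    la <- rownames(means)
    lb <- colnames(means)
    if (is.null(la)) la <- paste0("a", seq_len(nrow(means)))
    if (is.null(lb)) lb <- paste0("b", seq_len(ncol(means)))
    dv <- c()
    fa <- c()
    fb <- c()
    for (i in seq_len(nrow(means))) {
      for (j in seq_len(ncol(means))) {
        v <- surrogate(means[i, j], sds[i, j], ns[i, j])
        dv <- c(dv, v)
        fa <- c(fa, rep(la[i], length(v)))
        fb <- c(fb, rep(lb[j], length(v)))
      }
    }
    two_way_anova(dv, fa, fb)
  } else {
    lg <- names(means)
    if (is.null(lg)) lg <- paste0("g", seq_along(means))
    dv <- c()
    g <- c()
    for (i in seq_along(means)) {
      v <- surrogate(means[i], sds[i], ns[i])
      dv <- c(dv, v)
      g <- c(g, rep(lg[i], length(v)))
    }
    one_way_anova(dv, g)
  }
}

#' Multiple linear regression with VIF diagnostics
#'
#' Ordinary least squares via [stats::lm()]: unstandardized coefficients,
#' t statistics, two-sided p-values and R-squared, plus the variance
#' inflation factor of each predictor, `VIF_j = 1 / (1 - R2_j)` where
#' `R2_j` comes from regressing predictor j on the remaining predictors.
#'
#' @param response numeric vector.
#' @param predictor_table data.frame of numeric predictors
#'   (`nrow > ncol + 1`, full rank).
#' @return object of class `regression_result`: list with `coefficients`
#'   (data.frame: term, estimate, std_error, statistic, p.value, vif),
#'   `r_squared`, `adj_r_squared`, `sigma`, `n`.
#' @export
multiple_regression <- function(response, predictor_table) {
  y <- as.numeric(response)
  X <- as.data.frame(predictor_table)
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("all predictors must be numeric", call. = FALSE)
  }
  if (nrow(X) != length(y)) {
    stop("`response` and predictors must align", call. = FALSE)
  }
  if (nrow(X) <= ncol(X) + 1) {
    stop("need more observations than predictors + 1", call. = FALSE)
  }
  qx <- qr(cbind(1, as.matrix(X)))
  if (qx$rank < ncol(X) + 1) {
    fit0 <- stats::lm(y ~ ., data = X)
    dep <- names(which(is.na(stats::coef(fit0))))
    stop("collinear predictors (rank-deficient design): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = X)
  sm <- summary(fit)
  co <- sm$coefficients
  vif <- vapply(seq_len(ncol(X)), function(j) {
    r2j <- summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - r2j)
  }, numeric(1))
  coefficients <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"],
    vif = c(NA_real_, vif),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(coefficients = coefficients,
         r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma,
         n = length(y)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R^2 = %.3f (adj. %.3f)\n",
              x$n, x$r_squared, x$adj_r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}
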