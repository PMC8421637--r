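new_stat_result <- function(statistic, kind, df, p, n, estimate = NULL,
                            method = "") {
  structure(list(statistic = unname(statistic), statistic_kind = kind,
                 df = unname(df), p = unname(p), n = as.integer(n),
                 estimate = estimate, adjusted_p = NULL, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4f, df = %s, p = %.4g%s (n = %d)\n",
              x$method, x$statistic_kind, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p,
              if (!is.null(x$adjusted_p)) sprintf(", p_fdr = %.4g", x$adjusted_p)
              else "", x$n))
  invisible(x)
}

#' ANCOVA group effect
#'
#' F test for a group factor adjusting for continuous covariates, computed
#' from nested least-squares fits: full model
#' `outcome ~ 1 + group + covariates`, reduced model without group;
#' `F = ((RSS_r - RSS_f) / df1) / (RSS_f / df_f)` with a two-sided p from
#' the F distribution. The canonical use adjusts a group comparison of
#' switching rates for age, years of education and mean framewise
#' displacement.
#'
#' @param outcome Numeric outcome per subject.
#' @param group Two-level factor (or coercible) of group labels.
#' @param covariates Data frame or matrix of numeric covariates (may be
#'   `NULL` for a plain one-way comparison).
#' @return A `stat_result` with kind `"F"` and `df = c(df1, df2)`.
#' @export
ancova_group_effect <- function(outcome, group, covariates = NULL) {
  outcome <- as.numeric(outcome)
  group <- factor(group)
  n <- length(outcome)
  if (nlevels(group) < 2L) stop("group needs at least 2 levels", call. = FALSE)
  if (min(table(group)) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  Xr <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    if (nrow(covariates) != n) stop("covariate rows must match outcome",
                                    call. = FALSE)
    Xr <- cbind(Xr, covariates)
  }
  G <- stats::model.matrix(~group)[, -1L, drop = FALSE]
  Xf <- cbind(Xr, G)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    bad <- colnames(Xf)[setdiff(seq_len(ncol(Xf)), qf$pivot[seq_len(qf$rank)])]
    stop(sprintf("design matrix is rank deficient (column(s): %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rss_f <- sum(qr.resid(qf, outcome)^2)
  rss_r <- sum(qr.resid(qr(Xr), outcome)^2)
  df1 <- nlevels(group) - 1L
  df2 <- n - ncol(Xf)
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  new_stat_result(Fstat, "F", c(df1, df2),
                  stats::pf(Fstat, df1, df2, lower.tail = FALSE), n,
                  method = "ANCOVA group effect")
}

#' Paired t test
#'
#' Tests the mean of the paired differences `post - pre`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided p. A positive
#' statistic means the post condition is larger.
#'
#' @param pre,post Paired numeric vectors.
#' @return A `stat_result` with kind `"t"`; `estimate` is the mean
#'   difference.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre/post must pair up", call. = FALSE)
  d <- as.numeric(post) - as.numeric(pre)
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("paired differences have zero variance", call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  new_stat_result(t, "t", n - 1L, 2 * stats::pt(-abs(t), n - 1L), n,
                  estimate = mean(d), method = "paired t test")
}

#' Two-sample t test from summary statistics
#'
#' Recomputes a two-sample t statistic from group sizes, means and standard
#' deviations, as needed to check published demographic tables. `pooled`
#' uses the pooled variance with `df = n1 + n2 - 2`; `welch` uses the
#' Welch statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param n1,mean1,sd1 First group summary.
#' @param n2,mean2,sd2 Second group summary.
#' @param variant `"pooled"` or `"welch"`.
#' @return A `stat_result` with kind `"t"`.
#' @examples
#' # depression-score row of a published demographics table
#' two_sample_t_summary(24, 10.58, 6.68, 26, 4.04, 4.65)$statistic  # 4.044
#' @export
two_sample_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                 variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("standard deviations must be >= 0 and not both 0", call. = FALSE)
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  new_stat_result(t, "t", df, 2 * stats::pt(-abs(t), df), n1 + n2,
                  estimate = mean1 - mean2,
                  method = sprintf("two-sample t (%s)", variant))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. For small samples without ties
#' an exact p can be requested (delegated to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @param exact Use the exact null distribution (small n, no ties).
#' @return A `stat_result` with kind `"rho"`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need paired vectors with n >= 3",
                                     call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (exact) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2L)
  }
  new_stat_result(rho, "rho", n - 2L, p, n, estimate = rho,
                  method = "Spearman correlation")
}

#' Partial Pearson correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed on an intercept plus the covariate columns;
#' `df = n - k - 2`, two-sided p via the t transform. With no covariates it
#' reduces to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame or matrix of covariates (may be `NULL`).
#' @return A `stat_result` with kind `"r"`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must pair up", call. = FALSE)
  k <- 0L
  ss0x <- sum((x - mean(x))^2)
  ss0y <- sum((y - mean(y))^2)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    if (nrow(covariates) != n) stop("covariate rows must match x", call. = FALSE)
    k <- ncol(covariates)
    X <- cbind(1, covariates)
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("covariate design is rank deficient",
                                call. = FALSE)
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  if (n <= k + 2L) stop("need n > k + 2", call. = FALSE)
  ssx <- sum(x^2)
  ssy <- sum(y^2)
  # a residual that is pure rounding noise (input exactly spanned by the
  # covariates) carries no association: define the correlation as 0
  r <- if (ssx <= 1e-24 * ss0x || ssy <= 1e-24 * ss0y) 0
       else sum(x * y) / sqrt(ssx * ssy)
  df <- n - k - 2L
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  new_stat_result(r, "r", df, p, n, estimate = r,
                  method = "partial Pearson correlation")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p values (Benjamini-Hochberg),
#' returned in the input order and capped at 1.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.05))  # 0.04 0.04 0.05 0.05
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the full cohort inference battery
#'
#' For every outcome at the requested level, emits the study's statistics:
#' the pre-scan ANCOVA group effect (covariates age, education, mean FD),
#' the whole-sample paired pre/post t test with per-group post-hoc paired
#' tests, and Spearman correlations of the pre-scan outcome with each
#' clinical score within the dependent group. At the subnetwork and node
#' levels p values are FDR-adjusted across the outcome family within each
#' test type (6 subnetworks / all nodes); the single global outcome is
#' left unadjusted.
#'
#' @param cohort A [generate_cohort()] result, or any list with `$subjects`
#'   (subject_id, group, age, education, mean_fd, scores) and `$outcomes`
#'   (subject_id, scan, level, outcome, value).
#' @param level `"global"`, `"subnetwork"` or `"node"`.
#' @param scores Score columns to correlate (default BQDS, BDI, BAI,
#'   duration where present).
#' @return A tidy data frame with columns `level`, `outcome`, `test`,
#'   `statistic_kind`, `statistic`, `df1`, `df2`, `n`, `p`, `p_fdr`.
#' @export
run_study_stats <- function(cohort,
                            level = c("global", "subnetwork", "node"),
                            scores = c("BQDS", "BDI", "BAI", "duration")) {
  level <- match.arg(level)
  subj <- cohort$subjects
  oc <- cohort$outcomes[cohort$outcomes$level == level, , drop = FALSE]
  if (!nrow(oc)) stop(sprintf("no outcomes at level '%s'", level), call. = FALSE)
  outcomes <- unique(oc$outcome)
  scores <- intersect(scores, names(subj))

  wide <- function(scan) {
    d <- oc[oc$scan == scan, , drop = FALSE]
    m <- matrix(NA_real_, nrow(subj), length(outcomes),
                dimnames = list(subj$subject_id, outcomes))
    m[cbind(match(d$subject_id, subj$subject_id),
            match(d$outcome, outcomes))] <- d$value
    m
  }
  pre <- wide("pre")
  post <- wide("post")

  rows <- list()
  add <- function(outcome, test, res, group = "all") {
    df <- res$df
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, outcome = outcome, test = test, group = group,
      statistic_kind = res$statistic_kind, statistic = res$statistic,
      df1 = df[1L], df2 = if (length(df) > 1L) df[2L] else NA_real_,
      n = res$n, p = res$p, stringsAsFactors = FALSE)
  }

  covs <- subj[, c("age", "education", "mean_fd")]
  for (o in outcomes) {
    ok <- !is.na(pre[, o]) & !is.na(subj$age) & !is.na(subj$education) &
      !is.na(subj$mean_fd)
    add(o, "ancova_pre_group",
        ancova_group_effect(pre[ok, o], subj$group[ok], covs[ok, ]))
    paired_ok <- !is.na(pre[, o]) & !is.na(post[, o])
    add(o, "paired_post_vs_pre", paired_t(pre[paired_ok, o], post[paired_ok, o]))
    for (g in unique(subj$group)) {
      sel <- paired_ok & subj$group == g
      add(o, "paired_post_vs_pre", paired_t(pre[sel, o], post[sel, o]),
          group = g)
    }
    dep <- subj$group == "dependent" & !is.na(pre[, o])
    for (sc in scores) {
      sel <- dep & !is.na(subj[[sc]])
      if (sum(sel) >= 3L && stats::sd(subj[[sc]][sel]) > 0) {
        add(o, paste0("spearman_pre_", sc),
            spearman(pre[sel, o], subj[[sc]][sel]), group = "dependent")
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  if (level == "global") {
    out$p_fdr <- out$p
  } else {
    for (key in unique(paste(out$test, out$group))) {
      sel <- paste(out$test, out$group) == key
      out$p_fdr[sel] <- bh_fdr(out$p[sel])
    }
  }
  out
}
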