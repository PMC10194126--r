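#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] that flags degenerate
#' (zero-variance) samples instead of erroring deep inside the pipeline.
#'
#' @param x numeric sample (n >= 3).
#' @return list with `W`, `p`, and `degenerate` (TRUE when the sample is
#'   constant, in which case `W` and `p` are `NA`).
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs at least 3 observations")
  if (stats::sd(x) < .Machine$double.eps^0.5 * max(1, abs(mean(x)))) {
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  t <- stats::shapiro.test(x)
  list(W = unname(t$statistic), p = t$p.value, degenerate = FALSE)
}

#' Friedman rank test for complete blocks
#'
#' Rank-based test of treatment differences in an `n x k` complete block
#' design (blocks in rows). Ties within a block receive midranks and the
#' statistic carries the standard tie correction:
#' \deqn{\chi^2 = \frac{(k-1)\sum_j n (\bar R_j - \bar R)^2}
#'       {\sum_{ij}(R_{ij} - \bar R)^2 / n \cdot n}}
#' computed as `(k - 1) * SS_treatment / SS_total` on the ranks, which
#' reduces to the classical Friedman statistic when there are no ties.
#' The p-value uses the chi-squared approximation with `k - 1` degrees of
#' freedom.
#'
#' @param x numeric matrix, `n` blocks (rows) by `k` treatments (columns);
#'   no missing cells.
#' @return list with `chisq`, `df`, `p`, `mean_ranks`.
#' @export
friedman_test <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("Friedman test requires complete blocks (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(x, 1, rank))
  rbar <- (k + 1) / 2
  ss_treat <- n * sum((colMeans(r) - rbar)^2)
  ss_total <- sum((r - rbar)^2) / n
  if (ss_total == 0) {
    # all columns identical within every block
    return(list(chisq = 0, df = k - 1, p = 1, mean_ranks = colMeans(r)))
  }
  chisq <- (k - 1) * ss_treat / ss_total
  df <- k - 1
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       mean_ranks = colMeans(r))
}

#' Exact paired sign test
#'
#' Two-sided exact binomial sign test on paired differences; zero differences
#' (ties) are dropped, following the standard convention.
#'
#' @param x,y paired samples (equal length), or `y = NULL` to test the signs
#'   of `x` directly.
#' @return list with `n_effective`, `n_positive`, `p`, and `all_ties`
#'   (`TRUE` with `p = NA` when every difference is zero).
#' @export
sign_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[d != 0]
  if (!length(d)) {
    return(list(n_effective = 0L, n_positive = 0L, p = NA_real_,
                all_ties = TRUE))
  }
  npos <- sum(d > 0)
  p <- stats::binom.test(npos, length(d), p = 0.5,
                         alternative = "two.sided")$p.value
  list(n_effective = length(d), n_positive = npos, p = p, all_ties = FALSE)
}

#' Pairwise post hoc comparisons with Bonferroni correction
#'
#' Exact paired sign tests (or Wilcoxon signed-rank tests) for every pair of
#' treatments in a complete block design, Bonferroni-adjusted over the number
#' of pairs.
#'
#' @param x numeric matrix, blocks by treatments (named columns).
#' @param method `"sign"` (default) or `"wilcoxon"`.
#' @return data.frame with one row per pair: `pair`, `statistic` (number of
#'   positive differences, or the signed-rank V), `p_raw`, `p_adj`,
#'   `all_ties`.
#' @export
pairwise_posthoc <- function(x, method = c("sign", "wilcoxon")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  k <- ncol(x)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("T", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (method == "sign") {
      st <- sign_test(x[, i1], x[, i2])
      data.frame(pair = paste(cn[i1], cn[i2], sep = " vs "),
                 statistic = st$n_positive, p_raw = st$p,
                 all_ties = st$all_ties)
    } else {
      d <- x[, i1] - x[, i2]
      if (all(d == 0)) {
        data.frame(pair = paste(cn[i1], cn[i2], sep = " vs "),
                   statistic = NA_real_, p_raw = NA_real_, all_ties = TRUE)
      } else {
        # ties fall back to the normal approximation, silently
        wt <- suppressWarnings(stats::wilcox.test(x[, i1], x[, i2],
                                                  paired = TRUE))
        data.frame(pair = paste(cn[i1], cn[i2], sep = " vs "),
                   statistic = unname(wt$statistic), p_raw = wt$p.value,
                   all_ties = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * m)
  out
}

#' Cohen's d effect size
#'
#' Mean difference over the pooled standard deviation (unpaired) or over the
#' standard deviation of the difference scores (paired), with the
#' classification small (< 0.3), medium (0.3 to 0.5), large (> 0.5).
#'
#' @param x,y samples (equal length if `paired`).
#' @param paired paired samples?
#' @return list with `d` and `label`.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    s <- stats::sd(d)
    if (s == 0) stop("zero variance of the paired differences")
    val <- mean(d) / s
  } else {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    if (sp2 == 0) stop("zero pooled variance")
    val <- (mean(x) - mean(y)) / sqrt(sp2)
  }
  ad <- abs(val)
  label <- if (ad < 0.3) "small" else if (ad <= 0.5) "medium" else "large"
  list(d = val, label = label)
}

#' Statistics report over a preflex metrics table
#'
#' Runs the full comparison chain on the output of [analyze_session()]:
#' per activity level and speed condition, a Shapiro-Wilk normality check and
#' a Friedman test across the three perturbations for preflex work,
#' short-range stiffness, and (dynamic only) post-short-range-stiffness
#' work, with pairwise sign-test post hocs under Bonferroni correction and
#' paired Cohen's d effect sizes; plus paired sign tests of dynamic versus
#' quasistatic preflex work and short-range stiffness per activity and
#' perturbation.
#'
#' @param analysis output of [analyze_session()] (list with `metrics` and
#'   `work_diff`).
#' @param alpha significance level (default 0.05).
#' @param posthoc_method `"sign"` or `"wilcoxon"`.
#' @return an object of class `preflex_report`: list of data.frames
#'   `friedman`, `posthoc`, `speed_comparison`, and `alpha`.
#' @export
build_report <- function(analysis, alpha = 0.05,
                         posthoc_method = "sign") {
  metrics <- analysis$metrics
  need <- c("fiber", "scenario", "speed_condition", "activity",
            "work", "srs", "post_srs")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics table missing column(s): ",
                         paste(miss, collapse = ", "))
  scen_levels <- c("up", "none", "down")
  acts <- sort(unique(metrics$activity))
  speeds <- unique(metrics$speed_condition)

  block_matrix <- function(df, value) {
    cells <- tapply(df[[value]], list(df$fiber, df$scenario), mean)
    cells <- cells[, intersect(scen_levels, colnames(cells)), drop = FALSE]
    if (anyNA(cells)) {
      bad <- which(is.na(cells), arr.ind = TRUE)
      stop("incomplete design: missing cell(s) ",
           paste(sprintf("fiber %s / %s", rownames(cells)[bad[, 1]],
                         colnames(cells)[bad[, 2]]), collapse = "; "))
    }
    cells
  }

  fr_rows <- list(); ph_rows <- list()
  for (sp in speeds) {
    for (a in acts) {
      sub <- metrics[metrics$speed_condition == sp & metrics$activity == a, ]
      for (v in c("work", "srs", "post_srs")) {
        if (v == "post_srs" && sp != "dynamic") next
        m <- block_matrix(sub, v)
        sw <- shapiro_wilk(as.vector(m) - rowMeans(m)[row(m)])
        fr <- friedman_test(m)
        fr_rows[[length(fr_rows) + 1]] <- data.frame(
          metric = v, speed_condition = sp, activity = a,
          shapiro_W = sw$W, shapiro_p = sw$p,
          chisq = fr$chisq, df = fr$df, p = fr$p,
          significant = !is.na(fr$p) && fr$p < alpha)
        ph <- pairwise_posthoc(m, method = posthoc_method)
        ph$metric <- v; ph$speed_condition <- sp; ph$activity <- a
        ph$cohens_d <- apply(utils::combn(ncol(m), 2), 2, function(ij) {
          tryCatch(cohens_d(m[, ij[1]], m[, ij[2]], paired = TRUE)$d,
                   error = function(e) NA_real_)
        })
        ph_rows[[length(ph_rows) + 1]] <- ph
      }
    }
  }

  sc_rows <- list()
  dyn <- metrics[metrics$speed_condition == "dynamic", ]
  qs <- metrics[metrics$speed_condition == "quasistatic", ]
  if (nrow(qs)) {
    mrg <- merge(dyn, qs, by = c("fiber", "scenario", "activity"),
                 suffixes = c("_dyn", "_qs"))
    for (a in acts) {
      for (sc in intersect(scen_levels, unique(mrg$scenario))) {
        sub <- mrg[mrg$activity == a & mrg$scenario == sc, ]
        for (v in c("work", "srs")) {
          st <- sign_test(sub[[paste0(v, "_dyn")]], sub[[paste0(v, "_qs")]])
          d <- tryCatch(cohens_d(sub[[paste0(v, "_dyn")]],
                                 sub[[paste0(v, "_qs")]], paired = TRUE)$d,
                        error = function(e) NA_real_)
          sc_rows[[length(sc_rows) + 1]] <- data.frame(
            metric = v, activity = a, scenario = sc,
            n_positive = st$n_positive, n_effective = st$n_effective,
            p = st$p, cohens_d = d,
            significant = !is.na(st$p) && st$p < alpha)
        }
      }
    }
  }
  rep <- list(friedman = do.call(rbind, fr_rows),
              posthoc = do.call(rbind, ph_rows),
              speed_comparison = do.call(rbind, sc_rows),
              alpha = alpha)
  class(rep) <- "preflex_report"
  rep
}

#' @export
print.preflex_report <- function(x, ...) {
  cat("<preflex_report>  alpha =", x$alpha, "\n\nFriedman tests:\n")
  print(x$friedman, digits = 3, row.names = FALSE)
  if (!is.null(x$speed_comparison) && nrow(x$speed_comparison)) {
    cat("\nDynamic vs quasistatic (paired sign tests):\n")
    print(x$speed_comparison, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report to CSV files + a text summary
#'
#' @param report a `preflex_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$friedman, file.path(dir, "friedman.csv"),
                   row.names = FALSE)
  utils::write.csv(report$posthoc, file.path(dir, "posthoc.csv"),
                   row.names = FALSE)
  if (!is.null(report$speed_comparison)) {
    utils::write.csv(report$speed_comparison,
                     file.path(dir, "speed_comparison.csv"),
                     row.names = FALSE)
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
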