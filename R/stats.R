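#' Paired Wilcoxon signed-rank test with exact small-sample p
#'
#' Two-sided paired Wilcoxon signed-rank test. Zero differences are dropped
#' (Wilcoxon convention). For `n <= exact_max_n` non-zero pairs the p-value
#' is exact, by full enumeration of all `2^n` sign assignments of the ranked
#' absolute differences (ties are handled naturally by average ranks); for
#' larger n the normal approximation with tie correction and continuity
#' correction is used. If all differences are zero the result is degenerate
#' with p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max_n largest n for the enumeration path (default 15).
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `method` (`"exact-enumeration"` or `"normal-approximation"`),
#'   `n_effective` (pairs after zero removal), `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))$p_value  # 2/64
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max_n = 15L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1.0,
                method = "degenerate", n_effective = 0L, degenerate = TRUE))
  }
  if (n < 5L) stop("fewer than 5 non-zero differences; the signed-rank test is uninformative")
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  if (n <= exact_max_n) {
    # all 2^n assignments of signs to the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vdist <- as.vector(signs %*% rk)
    p <- 2 * min(mean(vdist <= v + 1e-9), mean(vdist >= v - 1e-9))
    list(statistic = v, p_value = min(1, p), method = "exact-enumeration",
         n_effective = n, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    list(statistic = v, p_value = min(1, p), method = "normal-approximation",
         n_effective = n, degenerate = FALSE)
  }
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measure, absolute-agreement intraclass correlation under the
#' two-way random-effects model (Shrout-Fleiss ICC(2,1)), computed from the
#' two-way ANOVA mean squares of an n subjects x k raters/conditions matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The 95% confidence
#' interval is the F-based interval of McGraw and Wong for the A,1 form.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns, no
#'   missing cells; at least 3 rows and 2 columns.
#' @param conf_level confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, the mean squares `msr`,
#'   `msc`, `mse`, and `model`.
#' @examples
#' m <- matrix(rnorm(30), 10, 3); m <- m + rowMeans(m)  # add subject signal
#' icc2(m)$icc
#' @export
icc2 <- function(values, conf_level = 0.95) {
  stopifnot(is.matrix(values), !anyNA(values))
  n <- nrow(values); k <- ncol(values)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 conditions")
  g <- mean(values)
  if (sum((values - g)^2) == 0) stop("zero total variance; ICC undefined")
  rm_ <- rowMeans(values); cm <- colMeans(values)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((values - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * msr) {
    ci <- c(icc, icc)  # degenerate perfect-agreement case
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
       msr = msr, msc = msc, mse = mse,
       model = "ICC(2,1): two-way random, single measure, absolute agreement")
}

#' Repeated-measures comparison of conditions within subjects
#'
#' Within-subject comparison of a flow-deficit metric across conditions
#' (devices, slabs, or both), fitted as repeated-measures ANOVA with subject
#' as random intercept -- equivalent, under the complete balanced design the
#' pipeline produces, to the mixed linear model with a random subject factor.
#' With a single condition factor the model is `y ~ condition +
#' Error(subject/condition)`; with two factors (columns of `factors`) it is
#' `y ~ f1 * f2 + Error(subject/(f1 * f2))`, each effect tested against its
#' own subject-by-effect error stratum.
#'
#' @param values numeric matrix, subjects x conditions, complete (no NA).
#' @param factors optional data.frame with one row per column of `values`
#'   giving the factor level(s) of that condition (1 or 2 columns). Default:
#'   a single factor from the column names.
#' @return an object of class `RMComparison`: `effects` (data.frame with
#'   effect, df1, df2, statistic = F, p_value), `error_terms` (per-effect
#'   residual MS and df), `means`, `n_subjects`, `condition_labels`.
#' @export
repeated_measures_comparison <- function(values, factors = NULL) {
  stopifnot(is.matrix(values))
  if (anyNA(values)) stop("missing cells; the repeated-measures design must be complete")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("c", seq_len(k))
  if (is.null(factors)) {
    factors <- data.frame(condition = labels, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(factors) == k, ncol(factors) %in% c(1, 2))
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k))
  )
  for (nm in names(factors)) long[[nm]] <- factor(rep(factors[[nm]], each = n))
  fnames <- names(factors)
  if (length(fnames) == 1L) {
    fml <- stats::as.formula(paste0("y ~ ", fnames, " + Error(subject/", fnames, ")"))
  } else {
    fml <- stats::as.formula(paste0("y ~ ", fnames[1], " * ", fnames[2],
                                    " + Error(subject/(", fnames[1], " * ", fnames[2], "))"))
  }
  fit <- stats::aov(fml, data = long)
  eff <- extract_aov_effects(fit)
  structure(list(effects = eff$effects, error_terms = eff$error_terms,
                 means = colMeans(values), n_subjects = n,
                 condition_labels = labels, factors = factors,
                 data = long),
            class = "RMComparison")
}

# Pull per-term F, p and the matching error stratum out of a summary.aovlist.
extract_aov_effects <- function(fit) {
  s <- summary(fit)
  effects <- NULL
  error_terms <- list()
  for (stratum in s) {
    tab <- if (inherits(stratum, "summary.aov")) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    rn <- trimws(rownames(tab))
    resid_row <- which(rn == "Residuals")
    if (length(resid_row) == 0) next
    for (i in setdiff(seq_len(nrow(tab)), resid_row)) {
      effects <- rbind(effects, data.frame(
        effect = rn[i],
        df1 = tab$Df[i], df2 = tab$Df[resid_row],
        statistic = tab[["F value"]][i], p_value = tab[["Pr(>F)"]][i],
        stringsAsFactors = FALSE))
      error_terms[[rn[i]]] <- list(ms = tab[["Mean Sq"]][resid_row],
                                   df = tab$Df[resid_row])
    }
  }
  list(effects = effects, error_terms = error_terms)
}

#' @export
print.RMComparison <- function(x, ...) {
  cat("Repeated-measures comparison (", x$n_subjects, " subjects)\n", sep = "")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Tukey post-hoc comparisons on the repeated-measures error term
#'
#' All-pairs comparisons of condition means via the studentized range
#' distribution, using the effect's own repeated-measures error mean square:
#' `q = |m_i - m_j| / sqrt(MSE / n)` referred to the studentized range with
#' the number of conditions and the error degrees of freedom. Family-wise
#' alpha is 0.05 by default.
#'
#' @param x an `RMComparison` (single factor) or a subjects x conditions
#'   matrix, in which case the model is fitted first.
#' @param effect for a two-factor `RMComparison`, which factor to compare.
#' @param alpha family-wise significance level.
#' @return data.frame with `condition_a`, `condition_b`, `diff`, `q`,
#'   `p_value`, `significant`.
#' @export
tukey_posthoc <- function(x, effect = NULL, alpha = 0.05) {
  if (is.matrix(x)) x <- repeated_measures_comparison(x)
  stopifnot(inherits(x, "RMComparison"))
  fnames <- names(x$factors)
  if (is.null(effect)) effect <- fnames[1]
  if (!effect %in% fnames) stop("unknown effect '", effect, "'")
  lev <- levels(x$data[[effect]])
  if (length(lev) < 3) stop("fewer than 3 conditions; use the paired Wilcoxon path instead")
  err <- x$error_terms[[effect]]
  if (is.null(err)) stop("no error stratum for effect '", effect, "'")
  means <- tapply(x$data$y, x$data[[effect]], mean)
  n_per <- length(x$data$y) / length(lev)  # observations per level (balanced)
  se <- sqrt(err$ms / n_per)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(condition_a = pairs[1, ], condition_b = pairs[2, ],
                    stringsAsFactors = FALSE)
  out$diff <- means[out$condition_a] - means[out$condition_b]
  if (se == 0) {
    out$q <- ifelse(out$diff == 0, 0, Inf)
  } else {
    out$q <- abs(out$diff) / se
  }
  out$p_value <- stats::ptukey(out$q, nmeans = length(lev), df = err$df,
                               lower.tail = FALSE)
  out$p_value[out$q == 0] <- 1
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Reshape per-image metrics into a subjects x conditions matrix
#'
#' @param df per-image metrics data.frame with columns `eye_id` plus the
#'   condition column and the metric column.
#' @param metric metric column name (e.g., `"fd_percent"`).
#' @param condition condition column name (`"device"` or `"slab"`).
#' @param subset optional logical vector selecting rows of `df` first.
#' @return numeric matrix with eye rows and condition columns.
#' @export
metric_matrix <- function(df, metric, condition, subset = NULL) {
  if (!is.null(subset)) df <- df[subset, , drop = FALSE]
  stopifnot(all(c("eye_id", condition, metric) %in% names(df)))
  tab <- tapply(df[[metric]], list(df$eye_id, df[[condition]]), mean)
  if (anyNA(tab)) stop("incomplete design: missing eye x ", condition, " cells")
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

format_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))

#' Device-by-slab comparison tables
#'
#' Builds the two summary tables of the device/slab comparison from the
#' per-image metrics table: (i) per metric and slab, mean +/- SD for each
#' device with pairwise device p-values from the paired Wilcoxon signed-rank
#' test; (ii) per device, the slab-by-slab p-value matrix for the FD
#' percentage from Tukey post-hoc comparisons on the repeated-measures
#' model; plus (iii) ICC(2,1) agreement of each metric across the five slabs
#' on each device.
#'
#' @param df per-image metrics data.frame with columns `eye_id`, `device`,
#'   `slab` and the four metric columns.
#' @param metrics metric column names to tabulate.
#' @return list with `table1` (data.frame), `table2` (data.frame of slab
#'   pair p-values per device, plus `table2_matrices`), `icc` (data.frame).
#' @export
build_comparison_tables <- function(df,
                                    metrics = c("fd_percent", "mean_fd_size_um2",
                                                "total_fd_area_mm2", "fd_count")) {
  need <- c("eye_id", "device", "slab", metrics)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  devices <- unique(df$device)
  slabs <- unique(df$slab)
  eyes <- unique(df$eye_id)
  full <- expand.grid(eye_id = eyes, device = devices, slab = slabs,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$eye_id, d$device, d$slab)
  missing_cells <- setdiff(key(full), key(df))
  if (length(missing_cells) > 0) {
    stop("incomplete design; missing cells: ",
         paste(utils::head(missing_cells, 10), collapse = "; "),
         if (length(missing_cells) > 10) " ..." else "")
  }

  dev_pairs <- if (length(devices) >= 2) utils::combn(devices, 2) else NULL
  table1 <- NULL
  for (metric in metrics) {
    for (sl in slabs) {
      sel <- df$slab == sl
      row <- data.frame(metric = metric, slab = sl, stringsAsFactors = FALSE)
      for (dv in devices) {
        row[[dv]] <- format_mean_sd(df[[metric]][sel & df$device == dv])
      }
      if (!is.null(dev_pairs)) {
        mm <- metric_matrix(df, metric, "device", subset = sel)
        for (j in seq_len(ncol(dev_pairs))) {
          d1 <- dev_pairs[1, j]; d2 <- dev_pairs[2, j]
          p <- wilcoxon_signed_rank(mm[, d1], mm[, d2])$p_value
          row[[paste0("p_", d1, "_vs_", d2)]] <- p
        }
      }
      table1 <- rbind(table1, row)
    }
  }

  table2 <- NULL
  table2_matrices <- list()
  for (dv in devices) {
    mm <- metric_matrix(df, "fd_percent", "slab", subset = df$device == dv)
    mm <- mm[, as.character(slabs), drop = FALSE]
    if (ncol(mm) >= 3 && nrow(mm) >= 2) {
      th <- tukey_posthoc(mm)
      th$device <- dv
      table2 <- rbind(table2, th[, c("device", "condition_a", "condition_b",
                                     "p_value", "significant")])
      pm <- matrix(NA_real_, length(slabs), length(slabs),
                   dimnames = list(slabs, slabs))
      for (i in seq_len(nrow(th))) {
        pm[th$condition_a[i], th$condition_b[i]] <- th$p_value[i]
        pm[th$condition_b[i], th$condition_a[i]] <- th$p_value[i]
      }
      table2_matrices[[dv]] <- pm
    }
  }

  icc_tab <- NULL
  for (dv in devices) {
    for (metric in metrics) {
      mm <- metric_matrix(df, metric, "slab", subset = df$device == dv)
      res <- tryCatch(icc2(mm), error = function(e) NULL)
      if (!is.null(res)) {
        icc_tab <- rbind(icc_tab, data.frame(
          device = dv, metric = metric, icc = res$icc,
          ci_low = res$ci_low, ci_high = res$ci_high,
          stringsAsFactors = FALSE))
      }
    }
  }

  list(table1 = table1, table2 = table2, table2_matrices = table2_matrices,
       icc = icc_tab)
}
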