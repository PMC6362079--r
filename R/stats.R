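#' Within-subject standard deviation (repeatability)
#'
#' The pooled standard deviation of replicate measurements on the same
#' subject: \eqn{S_w = \sqrt{ \sum_j \sum_k (x_{jk} - \bar x_j)^2 /
#' \sum_j (k_j - 1) }}. For duplicate pairs this reduces to
#' \eqn{\sqrt{\sum_j d_j^2 / (2J)}} with \eqn{d_j} the within-pair
#' difference.
#'
#' @param values numeric measurements.
#' @param subject grouping vector (one group per subject, or per
#'   subject-condition cell) of the same length.
#' @return the repeatability \eqn{S_w} (scalar).
#' @export
within_subject_sd <- function(values, subject) {
  stopifnot(length(values) == length(subject))
  groups <- split(values, subject)
  k <- vapply(groups, length, integer(1))
  if (!any(k >= 2L)) {
    stop("no subject has replicate measurements", call. = FALSE)
  }
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sqrt(ss / sum(k - 1L))
}

#' Bland-Altman limits of agreement
#'
#' Agreement between two raters (or methods) measuring the same items:
#' mean difference, 95% limits of agreement \code{mean_diff +/- 1.96 sd_diff}
#' (sample sd, n - 1), and the t-based 95% confidence interval of each limit,
#' \code{LoA +/- t(0.975, n-1) * sd_diff * sqrt(3/n)}.
#'
#' @param rater_a,rater_b paired numeric vectors, length n >= 3.
#' @return an object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `ci_low_pair`, `ci_high_pair`, `n`.
#' @export
bland_altman <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) {
    stop("rater vectors must have equal length", call. = FALSE)
  }
  n <- length(rater_a)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  d <- rater_a - rater_b
  md <- mean(d)
  sd_d <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * sd_d
  se_loa <- sd_d * sqrt(3 / n)
  tq <- stats::qt(0.975, n - 1)
  structure(
    list(mean_diff = md, sd_diff = sd_d,
         loa_low = loa[1], loa_high = loa[2],
         ci_low_pair = loa[1] + c(-1, 1) * tq * se_loa,
         ci_high_pair = loa[2] + c(-1, 1) * tq * se_loa,
         n = n),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman: mean diff %.4f, LoA [%.4f, %.4f],",
                     " n = %d>\n"),
              x$mean_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] returning the sample Pearson r and
#' the two-sided p from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length n >= 3, each with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# ---- balanced within-subjects factorial ANOVA ------------------------------

# Center an array along dimension d (subtract the mean over d at every
# combination of the remaining dims). Composing this operator over a set of
# dims yields the inclusion-exclusion interaction deltas of a balanced design.
center_along <- function(a, d) {
  dims <- dim(a)
  keep <- setdiff(seq_along(dims), d)
  if (length(keep) == 0L) return(a - mean(a))
  m <- apply(a, keep, mean)
  sweep(a, keep, m, `-`)
}

# Sum of squares and df for the term given by `dims` (subset of dim indices
# of arr, which holds one observation per full cell).
term_ss <- function(arr, dims) {
  full <- dim(arr)
  m <- apply(arr, dims, mean)
  if (length(dims) == 1L) m <- array(m, dim = length(m))
  delta <- m
  for (i in seq_along(dims)) delta <- center_along(delta, i)
  list(ss = prod(full[-dims]) * sum(delta^2),
       df = prod(full[dims] - 1L))
}

all_subsets <- function(x) {
  unlist(lapply(seq_along(x), function(k) {
    lapply(utils::combn(length(x), k, simplify = FALSE), function(i) x[i])
  }), recursive = FALSE)
}

# Orthonormal contrast basis for the interaction space of the given factor
# dims, matching column-major flattening of the cell-mean array.
effect_contrasts <- function(levels) {
  mats <- lapply(levels, function(L) {
    C <- stats::contr.helmert(L)
    qr.Q(qr(C))                       # L x (L-1), orthonormal, mean-zero
  })
  out <- matrix(1, 1, 1)
  for (C in mats) out <- kronecker(C, out)   # first dim varies fastest
  t(out)                                      # df x ncells
}

#' Balanced within-subjects factorial repeated-measures ANOVA
#'
#' Classical univariate repeated-measures ANOVA for a fully balanced
#' subjects x factors grid with one observation per cell (replicate
#' measurements within a cell are averaged first). Every main effect and
#' interaction E of the within-subject factors is tested against its own
#' error stratum, the E x subject interaction:
#' \eqn{F_E = MS_E / MS_{E \times subject}}. Sums of squares come from the
#' marginal cell means of the balanced design; the decomposition is exact
#' (effect, error and subject SS add up to the total SS).
#'
#' No sphericity correction is applied by default; `sphericity =
#' "greenhouse-geisser"` adds Greenhouse-Geisser epsilon-adjusted p-values.
#' An effect whose SS is zero (relative to the total) is reported with
#' F = 0, p = 1; a positive effect over a zero error stratum is reported as
#' F = Inf, p = 0.
#'
#' @param data data.frame in long format.
#' @param response name of the numeric response column.
#' @param factors character vector of within-subject factor columns (1 to 4).
#' @param subject name of the subject identifier column.
#' @param sphericity `"none"` or `"greenhouse-geisser"`.
#' @return data.frame of class `anova_table`: one row per effect with
#'   `effect`, `df`, `ss`, `ms`, `error_df`, `error_ss`, `error_ms`, `F`,
#'   `p` (and `gg_epsilon`, `p_gg` under Greenhouse-Geisser), plus
#'   attributes `subject_ss`, `subject_df`, `total_ss`, `total_df`,
#'   `error_terms` (per-effect error SS already in the table) and
#'   `n_subjects`.
#' @export
rm_anova <- function(data, response, factors, subject = "subject",
                     sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  stopifnot(is.data.frame(data), length(factors) >= 1L, length(factors) <= 4L)
  cols <- c(subject, factors, response)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[, cols]
  names(d) <- c("subject", factors, ".y")
  for (f in c("subject", factors)) d[[f]] <- factor(d[[f]])

  # pre-average replicates within each subject x cell
  agg <- stats::aggregate(d$.y, by = d[c("subject", factors)], FUN = mean)
  names(agg)[ncol(agg)] <- ".y"

  lev <- lapply(agg[c("subject", factors)], levels)
  n_cells <- prod(lengths(lev))
  if (nrow(agg) != n_cells) {
    full <- do.call(expand.grid, c(lev, list(stringsAsFactors = FALSE)))
    key_full <- do.call(paste, c(full, sep = "\r"))
    key_have <- do.call(paste, c(lapply(agg[c("subject", factors)],
                                        as.character), sep = "\r"))
    miss <- key_full[!key_full %in% key_have]
    stop("unbalanced design; missing cells: ",
         paste(gsub("\r", ":", utils::head(miss, 5L)), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "", call. = FALSE)
  }

  # one observation per cell: subject varies fastest (first array dim),
  # then the factors in declared order
  ord <- agg[do.call(order, agg[rev(c("subject", factors))]), ]
  arr <- array(ord$.y, dim = lengths(lev))

  n_subj <- dim(arr)[1]
  total_ss <- sum((arr - mean(arr))^2)
  total_df <- length(arr) - 1L
  subj <- term_ss(arr, 1L)
  ss_tol <- 1e-12 * max(total_ss, .Machine$double.eps)

  fdims <- seq_along(factors) + 1L
  effects <- all_subsets(fdims)
  rows <- lapply(effects, function(E) {
    eff <- term_ss(arr, E)
    err <- term_ss(arr, c(1L, E))
    ms <- eff$ss / eff$df
    ems <- err$ss / err$df
    if (eff$ss <= ss_tol) {
      Fv <- 0; p <- 1
    } else if (err$ss <= ss_tol) {
      Fv <- Inf; p <- 0
    } else {
      Fv <- ms / ems
      p <- stats::pf(Fv, eff$df, err$df, lower.tail = FALSE)
    }
    data.frame(effect = paste(factors[E - 1L], collapse = ":"),
               df = eff$df, ss = eff$ss, ms = ms,
               error_df = err$df, error_ss = err$ss, error_ms = ems,
               F = Fv, p = p)
  })
  tab <- do.call(rbind, rows)

  if (sphericity == "greenhouse-geisser") {
    tab$gg_epsilon <- NA_real_
    tab$p_gg <- tab$p
    for (i in seq_along(effects)) {
      E <- effects[[i]]
      P <- apply(arr, c(1L, E), mean)
      dim(P) <- c(n_subj, prod(dim(arr)[E]))
      C <- effect_contrasts(dim(arr)[E])
      S <- stats::cov(P %*% t(C))
      q <- nrow(C)
      eps <- sum(diag(S))^2 / (q * sum(S^2))
      eps <- min(1, max(1 / q, eps))
      tab$gg_epsilon[i] <- eps
      if (is.finite(tab$F[i]) && tab$F[i] > 0) {
        tab$p_gg[i] <- stats::pf(tab$F[i], tab$df[i] * eps,
                                 tab$error_df[i] * eps, lower.tail = FALSE)
      }
    }
  }

  rownames(tab) <- NULL
  attr(tab, "subject_ss") <- subj$ss
  attr(tab, "subject_df") <- subj$df
  attr(tab, "total_ss") <- total_ss
  attr(tab, "total_df") <- total_df
  attr(tab, "n_subjects") <- n_subj
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Bonferroni-corrected pairwise comparisons for one factor
#'
#' Paired t-tests between every pair of factor levels, pairing on the
#' subject-level means (responses averaged over all other conditions within
#' subject x level). P-values are Bonferroni-adjusted by the number of pairs
#' within this factor.
#'
#' @inheritParams rm_anova
#' @param factor_name the factor whose levels are compared.
#' @param alpha significance level applied to the adjusted p-values.
#' @return data.frame with one row per level pair: `level_a`, `level_b`,
#'   `mean_diff`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
bonferroni_pairwise <- function(data, factor_name, response,
                                subject = "subject", alpha = 0.05) {
  absent <- setdiff(c(subject, factor_name, response), names(data))
  if (length(absent)) {
    stop("missing columns: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  lv <- unique(as.character(data[[factor_name]]))
  if (length(lv) < 2L) stop("factor needs >= 2 levels", call. = FALSE)
  agg <- stats::aggregate(data[[response]],
                          by = list(subject = data[[subject]],
                                    level = data[[factor_name]]),
                          FUN = mean)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- agg$x[agg$level == pr[1]][order(agg$subject[agg$level == pr[1]])]
    b <- agg$x[agg$level == pr[2]][order(agg$subject[agg$level == pr[2]])]
    dd <- a - b
    if (stats::sd(dd) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(dd) - 1),
                 p.value = if (mean(dd) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    data.frame(level_a = pr[1], level_b = pr[2], mean_diff = mean(dd),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, tt$p.value * m))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA across clinicians
#'
#' Tests whether graders differ systematically, treating each graded image as
#' the blocking unit and the rater as the single within factor — the special
#' case of [rm_anova()] used for inter-clinician comparison.
#'
#' @param grades numeric matrix (images x raters) or long data.frame with
#'   columns `image`, `rater`, `grade`.
#' @param sphericity passed to [rm_anova()].
#' @return a one-row `anova_table`.
#' @export
clinician_anova <- function(grades, sphericity = "none") {
  if (is.matrix(grades) || (is.data.frame(grades) &&
                            !all(c("image", "rater", "grade") %in%
                                 names(grades)))) {
    grades <- as.matrix(grades)
    long <- data.frame(
      image = rep(seq_len(nrow(grades)), times = ncol(grades)),
      rater = rep(colnames(grades) %||% paste0("rater", seq_len(ncol(grades))),
                  each = nrow(grades)),
      grade = as.vector(grades))
  } else {
    long <- grades
  }
  rm_anova(long, response = "grade", factors = "rater", subject = "image",
           sphericity = sphericity)
}
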