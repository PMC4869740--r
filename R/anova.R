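#' @importFrom rlang ensym as_name abort warn .data
#' @importFrom stats pf ptukey pt sd var setNames
NULL

new_anova <- function(effects, ms_within, df_den, n_obs, balanced, method) {
  structure(
    list(
      effects = effects,
      ms_within = ms_within,
      df_den = df_den,
      n_obs = n_obs,
      balanced = balanced,
      method = method
    ),
    class = "plb_anova"
  )
}

effect_row <- function(term, df, df_den, sumsq, statistic) {
  tibble::tibble(
    term = term,
    df = df,
    df_den = df_den,
    sumsq = sumsq,
    meansq = sumsq / df,
    statistic = statistic,
    p.value = f_pvalue(statistic, df, df_den)
  )
}

#' Upper-tail p-value of the F distribution
#'
#' @param f Observed F statistic (non-negative).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return The probability of an F at least as large under the null.
#' @examples
#' f_pvalue(14.63, 1, 115)
#' @export
f_pvalue <- function(f, df1, df2) {
  if (any(!is.finite(df1)) || any(!is.finite(df2)) || any(df1 < 1) || any(df2 < 1)) {
    abort("`df1` and `df2` must be finite and >= 1.")
  }
  if (any(f < 0, na.rm = TRUE)) {
    abort("`f` must be non-negative.")
  }
  pf(f, df1, df2, lower.tail = FALSE)
}

#' One-way between-subjects analysis of variance
#'
#' Classical between/within decomposition for k independent groups, the test
#' used for group comparisons of baseline discharge rates, evoked-response
#' amplitudes and onset latencies.
#'
#' @param data A data frame with one row per observation.
#' @param value Unquoted column holding the response.
#' @param group Unquoted column holding the grouping factor.
#' @return A `plb_anova` object; see [tidy.plb_anova()].
#' @examples
#' d <- data.frame(g = rep(c("WT", "DF"), each = 5), y = c(rnorm(5, 10), rnorm(5, 8)))
#' one_way_anova(d, y, g)
#' @export
one_way_anova <- function(data, value, group) {
  value <- ensym(value)
  group <- ensym(group)
  d <- tibble::tibble(
    y = as.numeric(data[[as_name(value)]]),
    g = as.character(data[[as_name(group)]])
  )
  d <- d[stats::complete.cases(d), ]
  cnt <- table(d$g)
  if (length(cnt) < 2L) abort("Need at least 2 groups.")
  if (any(cnt < 2L)) abort("Every group needs at least 2 observations.")
  grand <- mean(d$y)
  gm <- tapply(d$y, d$g, mean)
  gv <- tapply(d$y, d$g, var)
  n <- as.numeric(cnt[names(gm)])
  ss_between <- sum(n * (gm - grand)^2)
  ss_within <- sum((n - 1) * gv)
  df_num <- length(gm) - 1L
  df_den <- sum(n) - length(gm)
  msw <- ss_within / df_den
  f <- if (msw == 0 && ss_between == 0) 0 else ss_between / df_num / msw
  new_anova(
    effects = effect_row(as_name(group), df_num, df_den, ss_between, f),
    ms_within = msw, df_den = df_den, n_obs = sum(n),
    balanced = length(unique(n)) == 1L, method = "one-way ANOVA"
  )
}

#' Two-way ANOVA from cell summary statistics
#'
#' Unweighted-means factorial analysis for an a x b between-subjects design
#' supplied as per-cell summaries (mean, SEM, n). Within-cell variance is
#' pooled from the SEMs, every cell is weighted equally, and the effective
#' cell size is the harmonic mean of the observed ones. For a balanced design
#' this coincides exactly with the classical factorial decomposition; for a
#' 2 x 2 unbalanced design it is equivalent to Type III sums of squares.
#'
#' This is the form that reproduces a published genotype x treatment
#' comparison from the printed group statistics alone, without raw data.
#'
#' @param cells Data frame with one row per design cell.
#' @param factor_a,factor_b Unquoted factor columns (e.g. genotype, treatment).
#' @param mean,sem,n Unquoted columns with the cell mean, its standard error
#'   and the cell size.
#' @return A `plb_anova` object with one row per effect
#'   (factor A, factor B, interaction).
#' @examples
#' cells <- gabazine_reference_summaries()
#' two_way_anova_summary(cells, genotype, treatment, mean, sem, n)
#' @export
two_way_anova_summary <- function(cells, factor_a, factor_b, mean, sem, n) {
  factor_a <- ensym(factor_a); factor_b <- ensym(factor_b)
  mean <- ensym(mean); sem <- ensym(sem); n <- ensym(n)
  a_lab <- as_name(factor_a); b_lab <- as_name(factor_b)
  fa <- as.character(cells[[a_lab]])
  fb <- as.character(cells[[b_lab]])
  m <- as.numeric(cells[[as_name(mean)]])
  se <- as.numeric(cells[[as_name(sem)]])
  nn <- as.numeric(cells[[as_name(n)]])
  la <- unique(fa); lb <- unique(fb)
  a <- length(la); b <- length(lb)
  if (a < 2L || b < 2L) abort("Both factors need at least 2 levels.")
  if (nrow(cells) != a * b || anyDuplicated(paste(fa, fb))) {
    abort("`cells` must contain exactly one row per design cell.")
  }
  if (any(nn < 2)) abort("Every cell needs n >= 2.")
  if (any(se < 0)) abort("SEMs must be non-negative.")
  if (any(se == 0)) warn("A cell has SEM = 0; within-cell variance is degenerate.")

  M <- matrix(NA_real_, a, b, dimnames = list(la, lb))
  M[cbind(fa, fb)] <- m
  Nc <- matrix(NA_real_, a, b, dimnames = list(la, lb))
  Nc[cbind(fa, fb)] <- nn

  sd_cell <- se * sqrt(nn)
  msw <- sum((nn - 1) * sd_cell^2) / sum(nn - 1)
  df_den <- sum(nn) - a * b
  n_h <- (a * b) / sum(1 / nn)

  grand <- base::mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_a <- n_h * b * sum((row_m - grand)^2)
  ss_b <- n_h * a * sum((col_m - grand)^2)
  inter <- sweep(sweep(M, 1, row_m), 2, col_m) + grand
  ss_ab <- n_h * sum(inter^2)

  df_a <- a - 1L; df_b <- b - 1L; df_ab <- df_a * df_b
  fstat <- function(ss, df) if (msw == 0 && ss == 0) 0 else ss / df / msw
  effects <- dplyr::bind_rows(
    effect_row(a_lab, df_a, df_den, ss_a, fstat(ss_a, df_a)),
    effect_row(b_lab, df_b, df_den, ss_b, fstat(ss_b, df_b)),
    effect_row(paste0(a_lab, ":", b_lab), df_ab, df_den, ss_ab, fstat(ss_ab, df_ab))
  )
  new_anova(
    effects = effects, ms_within = msw, df_den = df_den, n_obs = sum(nn),
    balanced = length(unique(nn)) == 1L,
    method = "two-way ANOVA (unweighted means, from summaries)"
  )
}

#' Two-way ANOVA from raw observations
#'
#' Computes per-cell summaries from a long-format table and applies the
#' unweighted-means decomposition of [two_way_anova_summary()], so the raw and
#' summary pathways agree exactly by construction. On a balanced design this
#' equals the classical factorial ANOVA.
#'
#' @param data Data frame, one row per observation.
#' @param value Unquoted response column.
#' @param factor_a,factor_b Unquoted factor columns.
#' @return A `plb_anova` object.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  value <- ensym(value); factor_a <- ensym(factor_a); factor_b <- ensym(factor_b)
  d <- tibble::tibble(
    y = as.numeric(data[[as_name(value)]]),
    a = as.character(data[[as_name(factor_a)]]),
    b = as.character(data[[as_name(factor_b)]])
  )
  d <- d[stats::complete.cases(d), ]
  cells <- dplyr::summarise(
    dplyr::group_by(d, .data$a, .data$b),
    mean = base::mean(.data$y),
    sem = sd(.data$y) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  if (nrow(cells) != length(unique(d$a)) * length(unique(d$b))) {
    abort("Design is incomplete: at least one cell is empty.")
  }
  names(cells)[1:2] <- c(as_name(factor_a), as_name(factor_b))
  out <- two_way_anova_summary(cells, !!factor_a, !!factor_b, mean, sem, n)
  out$method <- "two-way ANOVA (unweighted means, from raw data)"
  out
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' One between-subjects factor crossed with one within-subject factor, the
#' design used for genotype x stimulus-duration analyses of touchscreen
#' sessions. The between effect is tested against between-subject error and
#' the within and interaction effects against the subject x within residual.
#' Unequal group sizes are handled with unweighted cell means and the harmonic
#' mean group size; no sphericity correction is applied.
#'
#' @param data Long-format data frame, one row per subject x within-level.
#' @param value Unquoted response column.
#' @param between Unquoted between-subjects factor (e.g. genotype).
#' @param within Unquoted within-subject factor (e.g. stimulus duration).
#' @param subject Unquoted subject identifier.
#' @return A `plb_anova` object with rows for the between effect, the within
#'   effect and their interaction.
#' @export
mixed_anova <- function(data, value, between, within, subject) {
  value <- ensym(value); between <- ensym(between)
  within <- ensym(within); subject <- ensym(subject)
  d <- tibble::tibble(
    y = as.numeric(data[[as_name(value)]]),
    g = as.character(data[[as_name(between)]]),
    w = as.character(data[[as_name(within)]]),
    s = as.character(data[[as_name(subject)]])
  )
  if (anyNA(d)) {
    drop <- unique(d$s[!stats::complete.cases(d)])
    d <- d[!(d$s %in% drop), ]  # listwise deletion of incomplete subjects
  }
  W <- length(unique(d$w))
  grid <- table(d$s, d$w)
  if (any(grid != 1L)) abort("Each subject must have exactly one value per within level.")
  subj <- dplyr::summarise(
    dplyr::group_by(d, .data$s, .data$g),
    sm = base::mean(.data$y), .groups = "drop"
  )
  if (anyDuplicated(subj$s)) abort("A subject appears in more than one between group.")
  ng <- table(subj$g)
  if (length(ng) < 2L) abort("Need at least 2 between-subject groups.")
  if (any(ng < 2L)) abort("Every group needs at least 2 subjects.")
  G <- length(ng)
  n_h <- G / sum(1 / as.numeric(ng))

  # cell means over subjects, group means of subject means
  cellm <- tapply(d$y, list(d$g, d$w), mean)
  gmean <- rowMeans(cellm)
  wmean <- colMeans(cellm)
  grand <- mean(cellm)

  # between-subject stratum
  ss_g <- n_h * W * sum((gmean - grand)^2)
  subj$gm <- gmean[subj$g]
  ss_subj <- W * sum((subj$sm - subj$gm)^2)
  df_g <- G - 1L
  df_subj <- sum(as.numeric(ng) - 1L)

  # within-subject stratum
  ss_w <- n_h * G * sum((wmean - grand)^2)
  inter <- sweep(sweep(cellm, 1, gmean), 2, wmean) + grand
  ss_gw <- n_h * sum(inter^2)
  d$sm <- subj$sm[match(d$s, subj$s)]
  d$cm <- cellm[cbind(d$g, d$w)]
  d$gm <- gmean[d$g]
  ss_res <- sum((d$y - d$sm - d$cm + d$gm)^2)
  df_w <- W - 1L
  df_gw <- df_g * df_w
  df_res <- df_subj * df_w

  ms_subj <- ss_subj / df_subj
  ms_res <- ss_res / df_res
  fstat <- function(ss, df, ms) if (ms == 0 && ss == 0) 0 else ss / df / ms
  effects <- dplyr::bind_rows(
    effect_row(as_name(between), df_g, df_subj, ss_g, fstat(ss_g, df_g, ms_subj)),
    effect_row(as_name(within), df_w, df_res, ss_w, fstat(ss_w, df_w, ms_res)),
    effect_row(
      paste0(as_name(between), ":", as_name(within)),
      df_gw, df_res, ss_gw, fstat(ss_gw, df_gw, ms_res)
    )
  )
  new_anova(
    effects = effects, ms_within = ms_res, df_den = df_res, n_obs = nrow(d),
    balanced = length(unique(as.numeric(ng))) == 1L,
    method = "mixed repeated-measures ANOVA (split-plot)"
  )
}

#' Newman-Keuls stepwise post hoc comparisons
#'
#' Studentized-range comparisons of group means with the classical stepwise
#' stopping rule: means are ordered, the widest range is tested first, and a
#' non-significant range declares all comparisons nested inside it
#' non-significant without further testing. With unequal group sizes the
#' effective n for a pair is the harmonic mean of the two.
#'
#' @param groups Data frame with columns `group`, `mean`, `n` (e.g. the output
#'   of [summarize_cells()] with a combined group label).
#' @param ms_within Pooled within-group mean square from the omnibus ANOVA.
#' @param df_within Its degrees of freedom.
#' @param alpha Significance level for the stepwise decisions.
#' @return A `plb_posthoc` tibble with one row per pair: means, difference,
#'   q statistic, range spanned, p-value and the stepwise significance call.
#' @export
newman_keuls <- function(groups, ms_within, df_within, alpha = 0.05) {
  stopifnot(all(c("group", "mean", "n") %in% names(groups)))
  if (!is.finite(ms_within) || ms_within <= 0) abort("`ms_within` must be positive.")
  if (df_within < 1) abort("`df_within` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  k <- nrow(groups)
  if (k < 2L) abort("Need at least 2 groups.")
  ord <- order(groups$mean)
  g <- groups$group[ord]; m <- groups$mean[ord]; n <- groups$n[ord]

  blocked <- matrix(FALSE, k, k)
  rows <- list()
  for (r in seq(k, 2L)) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      n_pair <- 2 / (1 / n[i] + 1 / n[j])
      q <- abs(m[j] - m[i]) / sqrt(ms_within / n_pair)
      p <- ptukey(q, nmeans = r, df = df_within, lower.tail = FALSE)
      if (blocked[i, j]) {
        sig <- FALSE
      } else if (p <= alpha) {
        sig <- TRUE
      } else {
        sig <- FALSE
        for (a in i:j) for (b in a:j) if (b > a && (b - a) < (r - 1L)) blocked[a, b] <- TRUE
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_a = g[i], group_b = g[j],
        mean_a = m[i], mean_b = m[j],
        mean_diff = m[j] - m[i],
        q = q, range_r = r, p.value = p, significant = sig
      )
    }
  }
  structure(dplyr::bind_rows(rows), class = c("plb_posthoc", class(tibble::tibble())))
}

#' @export
print.plb_anova <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("n = %d, MS_within = %.4g, df_den = %d%s\n",
              x$n_obs, x$ms_within, as.integer(x$df_den),
              if (x$balanced) " (balanced)" else " (unbalanced)"))
  print(as.data.frame(x$effects), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ANOVA result
#'
#' @param x A `plb_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect: `term`, `df`, `df_den`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`.
#' @method tidy plb_anova
#' @export
tidy.plb_anova <- function(x, ...) x$effects

#' One-row summary of an ANOVA fit
#'
#' @param x A `plb_anova` object.
#' @param ... Unused.
#' @method glance plb_anova
#' @export
glance.plb_anova <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    ms_within = x$ms_within,
    df_den = x$df_den,
    balanced = x$balanced,
    method = x$method
  )
}
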