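#' Voxel-wise BMD-PI regression for one specimen
#'
#' Ordinary least squares with PI (%) as response and BMD (mg HA/cm^3) as
#' predictor over all ROI voxels with a valid PI value:
#' `slope = Sxy/Sxx`, `intercept = ybar - slope xbar`,
#' `SE(slope) = sqrt(RSS / (n-2) / Sxx)`, `r = Sxy / sqrt(Sxx Syy)`, and the
#' two-tailed p-value from `t = r sqrt((n-2)/(1-r^2))` on `n-2` df (the
#' slope t-test and the correlation test coincide for simple OLS).
#'
#' @param bmd BMD [voxel_grid()] (CT geometry).
#' @param pi A `pi_map` on the same geometry (see [align_pi_to_ct()]).
#' @param roi Mask [voxel_grid()] selecting the analysis region.
#' @param horse,limb Optional specimen labels carried into the result.
#' @return An object of class `pi_regression` with fields `horse`, `limb`,
#'   `n`, `slope`, `intercept`, `slope_se`, `r`, `p`, `label`.
#' @export
regress_specimen <- function(bmd, pi, roi, horse = NA, limb = NA_character_) {
  stopifnot(inherits(bmd, "voxel_grid"), inherits(pi, "pi_map"),
            inherits(roi, "voxel_grid"))
  if (!all(dim(bmd) == dim(pi$values)) || !all(dim(bmd) == dim(roi)))
    stop("BMD, PI and ROI must share one geometry", call. = FALSE)
  sel <- as.logical(roi$values) & pi$valid$values & is.finite(pi$values$values)
  x <- bmd$values[sel]
  y <- pi$values$values[sel]
  res <- ols_xy(x, y)
  structure(c(list(horse = horse, limb = limb), res,
              list(label = correlation_label(res$r))),
            class = "pi_regression")
}

# core OLS/correlation sums shared by regress_specimen and the scatter export
ols_xy <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 valid paired voxels", call. = FALSE)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  syy <- sum((y - ybar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  if (sxx == 0) stop("zero predictor variance", call. = FALSE)
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  rss <- syy - slope * sxy
  rss <- max(rss, 0)
  slope_se <- sqrt(rss / (n - 2) / sxx)
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  p <- if (is.na(r)) {
    NA_real_
  } else if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(n = n, slope = slope, intercept = intercept, slope_se = slope_se,
       r = r, p = p)
}

#' @export
print.pi_regression <- function(x, ...) {
  cat(sprintf("<pi_regression> %s%s n = %d voxels\n",
              if (is.na(x$horse)) "" else paste0("horse ", x$horse, " "),
              if (is.na(x$limb)) "" else x$limb, x$n))
  cat(sprintf("  PI = %.4g + %.4g * BMD   (SE %.3g)\n", x$intercept, x$slope, x$slope_se))
  cat(sprintf("  r = %.3f (%s), p = %.3g\n", x$r, x$label, x$p))
  invisible(x)
}

#' @export
tidy.pi_regression <- function(x, ...) {
  tibble::tibble(
    horse = x$horse, limb = x$limb, n_voxels = x$n,
    slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
    r = x$r, p = x$p, label = x$label
  )
}

#' @export
glance.pi_regression <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r^2, p.value = x$p, nobs = x$n)
}

#' Correlation strength label
#'
#' Conventional strength bands on `|r|` rounded to 2 decimals:
#' very weak below 0.20, weak to 0.40, moderate to 0.60, strong to 0.80,
#' very strong above.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
correlation_label <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  a <- round(abs(r), 2)
  cut(a, breaks = c(-Inf, 0.20 - 1e-9, 0.40 - 1e-9, 0.60 - 1e-9, 0.80 - 1e-9, Inf),
      labels = c("very weak", "weak", "moderate", "strong", "very strong")) |>
    as.character()
}

#' Group summary statistics
#'
#' Mean, sample SD (n-1 denominator), SE = SD/sqrt(n), min and max.
#'
#' @param values Numeric vector, length >= 2.
#' @param name Group name.
#' @return One-row tibble.
#' @export
group_summary <- function(values, name = "group") {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  tibble::tibble(
    group = name, n = length(values), mean = mean(values),
    sd = sd(values), se = sd(values) / sqrt(length(values)),
    min = min(values), max = max(values)
  )
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 (S^2 + (K-3)^2/4)` with skewness `S = m3/m2^(3/2)` and kurtosis
#' `K = m4/m2^2` from central moments with 1/n normalisation; the p-value is
#' from the chi-squared distribution with 2 df (asymptotic null).
#'
#' @param values Numeric vector, n >= 3.
#' @return List with `statistic` and `p`.
#' @export
jarque_bera <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  m <- values - mean(values)
  m2 <- mean(m^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  s <- mean(m^3) / m2^1.5
  k <- mean(m^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb, p = pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Two-sample comparison of group values
#'
#' Student (pooled variance) or Welch two-sample t-test, two-tailed, with a
#' Jarque-Bera normality check reported per group.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param variant `"student"` (default) or `"welch"`.
#' @param names Length-2 character, group names.
#' @return One-row tibble: group names and sizes, means, JB statistic and p
#'   per group (NA for n < 3), `t`, `df`, `p`, `variant`.
#' @export
compare_groups <- function(a, b, variant = c("student", "welch"),
                           names = c("A", "B")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = 0,
               parameter = if (variant == "student") length(a) + length(b) - 2
                           else NA_real_,
               p.value = 1)
  } else {
    tt <- t.test(a, b, var.equal = variant == "student")
  }
  norm_a <- if (length(a) >= 3 && var(a) > 0) jarque_bera(a) else list(statistic = NA_real_, p = NA_real_)
  norm_b <- if (length(b) >= 3 && var(b) > 0) jarque_bera(b) else list(statistic = NA_real_, p = NA_real_)
  tibble::tibble(
    group_a = names[1], group_b = names[2],
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    jb_a = norm_a$statistic, jb_p_a = norm_a$p,
    jb_b = norm_b$statistic, jb_p_b = norm_b$p,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, variant = variant
  )
}

limb_groups <- list(
  forelimb = c("LF", "RF"), hindlimb = c("LH", "RH"),
  left = c("LF", "LH"), right = c("RF", "RH"),
  LF = "LF", RF = "RF", LH = "LH", RH = "RH"
)

study_comparisons <- list(
  fore_vs_hind = c("forelimb", "hindlimb"),
  left_vs_right = c("left", "right"),
  LF_vs_RF = c("LF", "RF"),
  LH_vs_RH = c("LH", "RH")
)

#' Build the study table and group analyses
#'
#' Collates per-specimen regression results into the per-limb table and the
#' four group analyses (forelimbs vs hindlimbs, left vs right, LF vs RF,
#' LH vs RH), each with group summaries and a t-test with Jarque-Bera
#' normality checks. Excluded specimens are carried as explicit rows and
#' left out of the statistics. Comparisons whose groups are too small are
#' skipped with a logged reason.
#'
#' @param results Either a list of [regress_specimen()] results (with
#'   `horse`/`limb` set) or a data frame with columns `horse`, `limb`,
#'   `slope`, `r` (optionally `slope_se`, `p`, `n_voxels`, `excluded`).
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @return An object of class `pi_study`: `table` (per-limb tibble),
#'   `summaries`, `comparisons`, `skipped` (reasons), `overall`
#'   (r and slope summaries over analyzable limbs).
#' @export
build_study_table <- function(results, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  tbl <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(lapply(results, tidy))
  }
  if (!all(c("horse", "limb", "slope", "r") %in% names(tbl)))
    stop("results need columns horse, limb, slope, r", call. = FALSE)
  if (!"excluded" %in% names(tbl)) tbl$excluded <- FALSE
  if (!"n_voxels" %in% names(tbl)) tbl$n_voxels <- NA_integer_
  if (!"slope_se" %in% names(tbl)) tbl$slope_se <- NA_real_
  if (!"p" %in% names(tbl)) tbl$p <- NA_real_
  if (anyDuplicated(paste(tbl$horse, tbl$limb)))
    stop("duplicate (horse, limb) keys", call. = FALSE)
  tbl$label <- ifelse(tbl$excluded, NA_character_, correlation_label(tbl$r))
  tbl <- dplyr::select(tbl, "horse", "limb", "n_voxels", "slope", "slope_se",
                       "r", "p", "label", "excluded",
                       dplyr::any_of(c("true_r", "coupling", "mr_noise_sd")))
  ana <- tbl[!tbl$excluded & is.finite(tbl$r), ]
  overall <- if (nrow(ana) >= 2) {
    dplyr::bind_rows(
      group_summary(ana$r, "r"),
      group_summary(ana$slope, "slope")
    )
  } else {
    tibble::tibble()
  }
  summaries <- list()
  for (g in names(limb_groups)) {
    v <- ana$r[ana$limb %in% limb_groups[[g]]]
    if (length(v) >= 2) summaries[[g]] <- group_summary(v, g)
  }
  summaries <- dplyr::bind_rows(summaries)
  comparisons <- list()
  skipped <- character()
  for (cmp in names(study_comparisons)) {
    gg <- study_comparisons[[cmp]]
    va <- ana$r[ana$limb %in% limb_groups[[gg[1]]]]
    vb <- ana$r[ana$limb %in% limb_groups[[gg[2]]]]
    if (length(va) < 2 || length(vb) < 2) {
      skipped[cmp] <- sprintf("%s skipped: group sizes %d vs %d", cmp,
                              length(va), length(vb))
      next
    }
    comparisons[[cmp]] <- dplyr::mutate(
      compare_groups(va, vb, variant, names = gg),
      comparison = cmp, .before = 1
    )
  }
  structure(list(
    table = tbl, overall = overall, summaries = summaries,
    comparisons = dplyr::bind_rows(comparisons), skipped = skipped
  ), class = "pi_study")
}

#' @export
print.pi_study <- function(x, ...) {
  n_ana <- sum(!x$table$excluded)
  cat(sprintf("<pi_study> %d specimens (%d analyzable, %d excluded)\n",
              nrow(x$table), n_ana, sum(x$table$excluded)))
  if (nrow(x$overall)) {
    r <- x$overall[x$overall$group == "r", ]
    s <- x$overall[x$overall$group == "slope", ]
    cat(sprintf("  r    : mean %.2f (range %.2f to %.2f; SD %.3f, SE %.3f)\n",
                r$mean, r$min, r$max, r$sd, r$se))
    cat(sprintf("  slope: mean %.2g (range %.2g to %.2g; SD %.2g, SE %.2g)\n",
                s$mean, s$min, s$max, s$sd, s$se))
  }
  if (nrow(x$summaries)) {
    cat("  group mean r: ")
    cat(paste(sprintf("%s %.2f", x$summaries$group, x$summaries$mean),
              collapse = ", "), "\n")
  }
  if (nrow(x$comparisons)) {
    for (i in seq_len(nrow(x$comparisons))) {
      cc <- x$comparisons[i, ]
      cat(sprintf("  %s: t = %.3f (df %.4g), p = %.3f [%s]\n",
                  cc$comparison, cc$t, cc$df, cc$p, cc$variant))
    }
  }
  for (s in x$skipped) cat("  ", s, "\n")
  invisible(x)
}

#' @export
tidy.pi_study <- function(x, ...) x$table

#' @export
glance.pi_study <- function(x, ...) {
  r <- x$overall[x$overall$group == "r", ]
  s <- x$overall[x$overall$group == "slope", ]
  tibble::tibble(
    n_specimens = nrow(x$table), n_analyzable = sum(!x$table$excluded),
    mean_r = r$mean, sd_r = r$sd, mean_slope = s$mean, sd_slope = s$sd
  )
}

#' Write a study's tables as CSV
#'
#' @param study A [build_study_table()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "pi_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$table, file.path(dir, "study_table.csv"), row.names = FALSE)
  write.csv(study$summaries, file.path(dir, "group_summaries.csv"), row.names = FALSE)
  write.csv(study$comparisons, file.path(dir, "group_comparisons.csv"), row.names = FALSE)
  invisible(dir)
}
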