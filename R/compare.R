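#' Voxelwise percentage difference between two reconstructions
#'
#' `pct_diff = 100 * (a - b) / a` inside the support mask (voxels where `a`
#' exceeds `mask_frac` of its maximum), zero elsewhere. By convention `a` is
#' the with-table-corrected arm (the reference) and `b` the arm corrected
#' without the table.
#'
#' @param a,b activity [voxel_volume()]s on the same grid.
#' @param mask_frac support threshold as a fraction of `max(a)`.
#' @return An object of class `diff_result`: `pct_diff` (volume, percent),
#'   `max_abs_pct`, `argmax` (voxel index triple of the maximum absolute
#'   difference), `argmax_slice` (its axial slice) and `mask`.
#' @export
percentage_difference <- function(a, b, mask_frac = 0.05) {
  if (!identical(a$grid$shape, b$grid$shape))
    stop("volumes must share the same grid")
  av <- a$values; bv <- b$values
  mx <- max(av)
  if (mx <= 0) stop("reference volume is all zero")
  mask <- av > mask_frac * mx
  pct <- array(0, dim(av))
  pct[mask] <- 100 * (av[mask] - bv[mask]) / av[mask]
  am <- which.max(abs(pct))
  am3 <- arrayInd(am, dim(pct))
  structure(list(pct_diff = pct, max_abs_pct = abs(pct[am]),
                 argmax = as.integer(am3), argmax_slice = as.integer(am3[3]),
                 mask = mask, grid = a$grid), class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("diff_result: max |pct diff| = %.2f%% at voxel (%d, %d, %d)\n",
              x$max_abs_pct, x$argmax[1], x$argmax[2], x$argmax[3]))
  invisible(x)
}

score_matrix <- function(pairs, arm) {
  t(vapply(pairs, function(p) {
    s <- p[[arm]]
    if (inherits(s, "segment_scores")) s <- s$scores
    if (length(s) != 17L) stop("each arm must carry 17 segment scores")
    as.numeric(s)
  }, numeric(17)))
}

safe_shapiro <- function(x) {
  if (length(unique(x)) < 3) return(NA_real_)
  tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
}

#' Paired comparison of segment perfusion scores between arms
#'
#' Pools all studies' 17 segment scores into paired observations
#' (with-table vs without-table attenuation correction) and reports the
#' pooled paired t-test, the Pearson correlation, Shapiro-Wilk normality per
#' arm, and per-segment paired t-tests. Differences are `with - without`.
#' Zero variance of the differences is a degenerate case: the t-test p-value
#' is reported as 1 with `degenerate = TRUE`.
#'
#' @param pairs list of studies, each `list(with =, without =)` holding 17
#'   segment scores (integer vectors or [score_segments()] results).
#' @return An object of class `score_comparison`.
#' @export
compare_scores <- function(pairs) {
  if (length(pairs) < 2) stop("need at least 2 studies to compare")
  w <- score_matrix(pairs, "with")
  wo <- score_matrix(pairs, "without")
  d <- as.vector(w) - as.vector(wo)
  degenerate <- stats::sd(d) == 0
  ttest_p <- if (degenerate) 1.0 else
    t.test(as.vector(w), as.vector(wo), paired = TRUE)$p.value
  pearson_r <- if (stats::sd(as.vector(w)) == 0 ||
                   stats::sd(as.vector(wo)) == 0) NA_real_ else
    cor(as.vector(w), as.vector(wo))
  per_segment <- data.frame(
    segment = 1:17,
    mean_diff = colMeans(w) - colMeans(wo),
    ttest_p = vapply(1:17, function(k) {
      dk <- w[, k] - wo[, k]
      if (stats::sd(dk) == 0) 1.0 else t.test(w[, k], wo[, k], paired = TRUE)$p.value
    }, numeric(1)),
    n = nrow(w))
  structure(list(n_studies = nrow(w), n_pairs = nrow(w) * 17L,
                 mean_diff = mean(d),
                 shapiro_p_with = safe_shapiro(as.vector(w)),
                 shapiro_p_without = safe_shapiro(as.vector(wo)),
                 ttest_p = ttest_p, pearson_r = pearson_r,
                 degenerate = degenerate, per_segment = per_segment,
                 with = w, without = wo), class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf("score_comparison: %d studies, %d score pairs\n", x$n_studies,
              x$n_pairs))
  cat(sprintf("  mean diff (with - without) = %.4f, paired t-test p = %.3g%s\n",
              x$mean_diff, x$ttest_p, if (x$degenerate) " (degenerate)" else ""))
  cat(sprintf("  Pearson r = %.4f; Shapiro-Wilk p (with/without) = %.3g / %.3g\n",
              x$pearson_r, x$shapiro_p_with, x$shapiro_p_without))
  invisible(x)
}

#' @export
summary.score_comparison <- function(object, ...) {
  print(object)
  cat("per-segment paired t-tests:\n")
  print(object$per_segment, row.names = FALSE)
  invisible(object)
}

#' Pooled score-correlation scatter plot
#'
#' One point per segment score pair, darker for more frequent combinations,
#' with the identity line.
#'
#' @param x a [compare_scores()] result.
#' @param ... ignored.
#' @export
plot.score_comparison <- function(x, ...) {
  tab <- table(with = as.vector(x$with), without = as.vector(x$without))
  df <- as.data.frame(tab)
  df <- df[df$Freq > 0, ]
  shade <- gray(1 - 0.2 - 0.8 * df$Freq / max(df$Freq))
  plot(as.numeric(as.character(df$with)), as.numeric(as.character(df$without)),
       pch = 19, cex = 1.6, col = shade, xlim = c(-0.2, 4.2),
       ylim = c(-0.2, 4.2),
       xlab = "score, AC with table", ylab = "score, AC without table",
       main = sprintf("%d score pairs, r = %.3f", x$n_pairs, x$pearson_r))
  abline(0, 1, col = "goldenrod", lwd = 2)
  invisible(x)
}

#' Per-segment scatter panel data in AHA layout
#'
#' @param comparison a [compare_scores()] result.
#' @return A data frame of class `segment_panels` with columns `segment`,
#'   `study`, `with`, `without`, ordered by AHA segment number.
#' @export
segment_panels <- function(comparison) {
  n <- comparison$n_studies
  df <- data.frame(segment = rep(1:17, each = n), study = rep(seq_len(n), 17),
                   with = as.vector(comparison$with),
                   without = as.vector(comparison$without))
  class(df) <- c("segment_panels", "data.frame")
  df
}

#' @export
plot.segment_panels <- function(x, ...) {
  op <- par(mfrow = c(5, 4), mar = c(2, 2, 1.5, 0.5)); on.exit(par(op))
  for (k in 1:17) {
    d <- x[x$segment == k, ]
    plot(jitter(d$with, 0.3), jitter(d$without, 0.3), pch = 19, cex = 0.7,
         xlim = c(-0.2, 4.2), ylim = c(-0.2, 4.2), xlab = "", ylab = "",
         main = paste("segment", k), cex.main = 0.9)
    abline(0, 1, col = "goldenrod")
  }
  invisible(x)
}
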