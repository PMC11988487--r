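#' Descriptive statistics with Tukey's five-number summary
#'
#' @param x Numeric vector, n >= 1 (NAs dropped).
#' @return List: \code{n}, \code{mean}, \code{sd}, \code{min},
#'   \code{lower_hinge}, \code{median}, \code{upper_hinge}, \code{max}.
#'   Hinges follow Tukey's definition (medians of the halves including the
#'   overall median when n is odd), i.e. \code{stats::fivenum}.
#' @export
describe_values <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) abort_invalid("`x` must contain at least one non-missing value")
  fn <- stats::fivenum(x)
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       min = fn[1], lower_hinge = fn[2], median = fn[3],
       upper_hinge = fn[4], max = fn[5])
}

#' Bland–Altman paired-difference analysis
#'
#' Differences are grader 1 minus grader 2; limits of agreement are
#' \code{bias +/- 1.96 * SD(differences)}.
#'
#' @param x,y Paired per-image scores of grader 1 and grader 2.
#' @return List: \code{bias}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{n}, and \code{plot_data} (data.frame of pair mean and difference,
#'   ordered by mean).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort_invalid("`x` and `y` must be paired (equal length)")
  if (length(x) < 2) abort_invalid("need at least 2 pairs")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  ord <- order(m)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(x),
       plot_data = data.frame(mean = m[ord], diff = d[ord]))
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau: \code{S / sqrt((n0 - n1) (n0 - n2))} with S the
#' concordant-minus-discordant pair sum, n0 = n(n-1)/2, and n1, n2 the tied
#' pair counts of each margin.  Undefined (error) when either margin is
#' constant.
#'
#' @param x,y Paired numeric or ordinal (integer-coded) vectors, n >= 2.
#' @return List: \code{tau}, \code{variant = "tau-b"}, \code{n}.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) abort_invalid("`x` and `y` must be paired")
  n <- length(x)
  if (n < 2) abort_invalid("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) abort_invalid("missing values not allowed")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  s <- sum(sx * sy) / 2
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_pairs(x)
  n2 <- tie_pairs(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0)
    abort_degenerate_statistic("tau-b undefined: a margin is constant")
  list(tau = s / denom, variant = "tau-b", n = n)
}

#' Cross-tabulate paired categories
#'
#' @param c1,c2 Paired category vectors.
#' @param categories Ordered category list shared by both graders.
#' @return K x K integer matrix; cell (i, j) counts units graded i by
#'   grader 1 and j by grader 2.
#' @export
cross_tabulate <- function(c1, c2, categories = category_levels()) {
  if (length(c1) != length(c2)) abort_invalid("`c1` and `c2` must be paired")
  if (!all(c(c1, c2) %in% categories))
    abort_invalid("category outside the declared category list")
  tab <- table(factor(c1, levels = categories), factor(c2, levels = categories))
  m <- matrix(as.integer(tab), nrow = length(categories),
              dimnames = list(grader1 = categories, grader2 = categories))
  m
}

kappa_weight_matrix <- function(K, weights = c("linear", "none", "quadratic")) {
  weights <- match.arg(weights)
  idx <- seq_len(K) - 1
  d <- abs(outer(idx, idx, "-"))
  switch(weights,
    none = (d > 0) * 1,
    linear = d / (K - 1),
    quadratic = (d / (K - 1))^2
  )
}

#' Cohen's kappa for a K x K agreement table, optionally weighted
#'
#' Disagreement-weight formulation:
#' \code{kappa = 1 - sum(w * p_obs) / sum(w * p_exp)} with
#' \code{w[i, j] = |i - j| / (K - 1)} (linear), its square (quadratic), or the
#' 0/1 indicator (unweighted).  Categories are taken in the row/column order
#' of the table, which must be the agreed ordinal order.
#'
#' @param tab K x K nonnegative count matrix (grader 1 rows, grader 2
#'   columns).
#' @param weights \code{"linear"} (default), \code{"quadratic"}, or
#'   \code{"none"}.
#' @return List: \code{kappa}, \code{weight_scheme}, \code{categories},
#'   \code{n}.
#' @export
cohen_kappa <- function(tab, weights = c("linear", "none", "quadratic")) {
  weights <- match.arg(weights)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab) || nrow(tab) < 2)
    abort_invalid("`tab` must be a square K x K matrix, K >= 2")
  if (any(tab < 0) || anyNA(tab)) abort_invalid("`tab` must be nonnegative counts")
  n <- sum(tab)
  if (n < 1) abort_invalid("`tab` must contain at least one unit")
  K <- nrow(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  w <- kappa_weight_matrix(K, weights)
  expected <- sum(w * outer(pr, pc))
  if (expected == 0)
    abort_degenerate_statistic("kappa undefined: zero expected disagreement (single nonempty category)")
  list(kappa = 1 - sum(w * p) / expected,
       weight_scheme = weights,
       categories = rownames(tab) %||% as.character(seq_len(K)),
       n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kappa / tau / Bland–Altman over a paired cell dataset
#'
#' Convenience wrappers used by the bootstrap and the CLI.  \code{pairs} is a
#' data.frame with columns \code{image_id}, \code{category1}, \code{category2}
#' (for kappa) and/or \code{grade1}, \code{grade2}.
#'
#' \code{pairs_kappa} computes kappa over cells gradable by BOTH graders on
#' the ordinal categories perfused < hypoperfused < nonperfused (the
#' default), or over all four categories including ungradable with
#' \code{include_ungradable = TRUE} (then unweighted is conventional since
#' "ungradable" is not ordinal).
#' \code{pairs_nonperfusion_by_image} reduces cells to per-image percent
#' nonperfusion scores (one row per image per grader) for tau / Bland–Altman.
#'
#' @param pairs Paired cell data.frame.
#' @param weights Kappa weight scheme.
#' @param include_ungradable Include UNGRADABLE as a fourth category.
#' @return \code{pairs_kappa}: a \code{\link{cohen_kappa}} result.
#' @export
pairs_kappa <- function(pairs, weights = "linear", include_ungradable = FALSE) {
  if (include_ungradable) {
    cats <- category_levels()
  } else {
    cats <- c("perfused", "hypoperfused", "nonperfused")
    keep <- pairs$category1 != "ungradable" & pairs$category2 != "ungradable"
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) abort_degenerate_statistic("no gradable paired cells")
  cohen_kappa(cross_tabulate(pairs$category1, pairs$category2, cats), weights)
}

#' @rdname pairs_kappa
#' @export
pairs_nonperfusion_by_image <- function(pairs) {
  keep <- pairs$grade1 != "UNGRADABLE" & pairs$grade2 != "UNGRADABLE"
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) abort_degenerate_statistic("no gradable paired cells")
  s1 <- tapply(grade_score(pairs$grade1), pairs$image_id, mean)
  s2 <- tapply(grade_score(pairs$grade2), pairs$image_id, mean)
  data.frame(image_id = names(s1),
             nonperf1 = 100 * (1 - as.numeric(s1)),
             nonperf2 = 100 * (1 - as.numeric(s2)),
             row.names = NULL)
}

# --- image-level bootstrap ---------------------------------------------------

#' Image-level (cluster) bootstrap confidence interval
#'
#' Resamples IMAGES with replacement — all cells of a sampled image move
#' together — recomputes the statistic on each replicate, and returns the
#' percentile 2.5/97.5 bounds.  Reproducible for a fixed seed.
#'
#' Named statistics use per-image sufficient statistics for speed:
#' \describe{
#'   \item{\code{"kappa"}}{linear-weighted kappa over both-gradable cells
#'     (3 ordinal categories); per-image contingency tables are summed per
#'     replicate.}
#'   \item{\code{"kappa_unweighted"}, \code{"kappa_quadratic"}}{as above with
#'     the other weight schemes.}
#'   \item{\code{"tau"}}{Kendall tau-b on per-image percent nonperfusion.}
#'   \item{\code{"bias"}}{Bland–Altman bias on per-image percent
#'     nonperfusion.}
#' }
#' A function statistic receives the resampled pairs data.frame and must
#' return one number.
#'
#' @param pairs Paired cell data.frame with an \code{image_id} column (e.g.
#'   row-bound \code{\link{pair_sessions}} results).
#' @param statistic Statistic name (above) or a function.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed (mandatory: CIs must be reproducible).
#' @param level Confidence level (default 0.95).
#' @return List: \code{estimate} (on the full data), \code{low}, \code{high},
#'   \code{level}, \code{replicates}, \code{seed}, \code{n_images},
#'   \code{n_failed} (replicates where the statistic was undefined),
#'   \code{resampling_unit = "image"}.
#' @export
bootstrap_ci <- function(pairs, statistic, B = 2000L, seed, level = 0.95) {
  pairs <- rbind_pairs(pairs)
  if (missing(seed)) abort_invalid("`seed` is required for a reproducible bootstrap")
  if (B < 100) abort_invalid("`B` must be at least 100")
  images <- unique(pairs$image_id)
  n_img <- length(images)
  if (n_img < 2) abort_invalid("need at least 2 images for an image-level bootstrap")

  if (is.character(statistic)) {
    fast <- bootstrap_fast_paths(pairs, statistic, images)
    stat_full <- fast$full
    stat_rep <- fast$rep
  } else if (is.function(statistic)) {
    idx_by_img <- split(seq_len(nrow(pairs)), factor(pairs$image_id, levels = images))
    stat_full <- function() statistic(pairs)
    stat_rep <- function(img_idx) {
      statistic(pairs[unlist(idx_by_img[img_idx], use.names = FALSE), , drop = FALSE])
    }
  } else abort_invalid("`statistic` must be a name or a function")

  estimate <- stat_full()
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      img_idx <- sample.int(n_img, n_img, replace = TRUE)
      tryCatch(stat_rep(img_idx), gridfa_error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * B)
    abort_degenerate_statistic(sprintf(
      "statistic undefined on %d of %d bootstrap replicates (over 10%%): degenerate resamples",
      n_failed, B))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE, type = 7)
  list(estimate = estimate, low = qs[1], high = qs[2], level = level,
       replicates = as.integer(B), seed = as.integer(seed),
       n_images = n_img, n_failed = n_failed, resampling_unit = "image")
}

# Per-image sufficient statistics so the inner loop is a weighted sum.
bootstrap_fast_paths <- function(pairs, statistic, images) {
  kappa_weights <- c(kappa = "linear", kappa_unweighted = "none",
                     kappa_quadratic = "quadratic")
  if (statistic %in% names(kappa_weights)) {
    w <- kappa_weights[[statistic]]
    cats <- c("perfused", "hypoperfused", "nonperfused")
    keep <- pairs$category1 != "ungradable" & pairs$category2 != "ungradable"
    p <- pairs[keep, , drop = FALSE]
    i1 <- match(p$category1, cats); i2 <- match(p$category2, cats)
    code <- (i1 - 1L) + 3L * (i2 - 1L) + 1L
    img <- factor(p$image_id, levels = images)
    # images x 9 matrix of per-image 3x3 table entries
    M <- t(vapply(split(code, img), function(cd) tabulate(cd, 9L), numeric(9)))
    kap <- function(counts) {
      cohen_kappa(matrix(counts, 3, 3, dimnames = list(cats, cats)), w)$kappa
    }
    return(list(full = function() kap(colSums(M)),
                rep = function(img_idx) kap(colSums(M[img_idx, , drop = FALSE]))))
  }
  if (statistic %in% c("tau", "bias")) {
    sc <- pairs_nonperfusion_by_image(pairs)
    sc <- sc[match(images, sc$image_id), , drop = FALSE]
    if (anyNA(sc$nonperf1))
      abort_degenerate_statistic("some images have no both-gradable cells")
    if (statistic == "tau") {
      f <- function(idx) kendall_tau_b(sc$nonperf1[idx], sc$nonperf2[idx])$tau
    } else {
      f <- function(idx) mean(sc$nonperf1[idx] - sc$nonperf2[idx])
    }
    idx_all <- seq_len(nrow(sc))
    return(list(full = function() f(idx_all), rep = f))
  }
  abort_invalid(sprintf("unknown statistic name '%s'", statistic))
}
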