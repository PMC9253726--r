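#' Pearson correlation test
#'
#' Product-moment correlation with the two-sided p value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` degrees of freedom
#' (delegating to [stats::cor.test()]); incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Deming (errors-in-variables) regression
#'
#' Fits a straight line assuming measurement error in both variables with
#' error-variance ratio `delta` = var(err_y)/var(err_x). The slope is
#' \deqn{\hat\beta = \frac{s_{yy} - \delta s_{xx} +
#'   \sqrt{(s_{yy} - \delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}}}
#' and the intercept \eqn{\bar y - \hat\beta \bar x}; the slope shares the
#' sign of \eqn{s_{xy}}. `delta = 1` gives orthogonal regression, the
#' appropriate default when both variables are measured on the same scale
#' with comparable error (e.g. hours).
#'
#' @param x,y Numeric vectors.
#' @param delta Error-variance ratio (> 0).
#' @return Object of class `deming` with fields `slope`, `intercept`,
#'   `delta`, `n`, `degenerate`. Methods: `print`, `coef`, `predict`.
#' @examples
#' x <- 1:10
#' deming_fit(x, 2 * x + 1)
#' @export
deming_fit <- function(x, y, delta = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  stopifnot(delta > 0)
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  degenerate <- FALSE
  if (sxy == 0) {
    if (syy <= delta * sxx) {
      slope <- 0
    } else {
      slope <- Inf
      degenerate <- TRUE
      warning("s_xy = 0 with dominant y-variance: vertical-line degeneracy")
    }
  } else {
    d <- syy - delta * sxx
    slope <- (d + sqrt(d^2 + 4 * delta * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 delta = delta, n = n, degenerate = degenerate),
            class = "deming")
}

#' @export
print.deming <- function(x, digits = 4, ...) {
  cat(sprintf("Deming regression (delta = %g, n = %d)\n", x$delta, x$n))
  cat(sprintf("  y = %s + %s x%s\n",
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits),
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.deming <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @param newdata Numeric x values at which to evaluate the fitted line.
#' @rdname deming_fit
#' @export
predict.deming <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p value by full enumeration of all \eqn{\binom{n_a+n_b}{n_a}} rank
#' assignments when the combined sample size is at most `exact_max` and the
#' data contain no ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction. Fixing this rule makes
#' results reproducible regardless of sample size heuristics in other
#' implementations.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Combined sample size up to which the exact path is used.
#' @return Two-sided p value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  x <- c(a, b)
  if (max(x) == min(x)) return(1)  # all values identical
  ties <- anyDuplicated(x) > 0
  rk <- rank(x)
  w_obs <- sum(rk[seq_len(na)])  # rank sum of group a

  if (!ties && na + nb <= exact_max) {
    # full enumeration of rank splits
    splits <- utils::combn(na + nb, na)
    ranks <- seq_len(na + nb)
    sums <- colSums(matrix(ranks[splits], nrow = na))
    mu <- na * (na + nb + 1) / 2
    p <- mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
    return(min(1, p))
  }

  n <- na + nb
  mu <- na * (n + 1) / 2
  tie_tab <- table(x)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                              (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)  # continuity correction
  z <- max(z, 0)
  2 * stats::pnorm(-z)
}

#' Holm step-down p-value adjustment
#'
#' Wrapper around [stats::p.adjust()] with `method = "holm"`: sort p values
#' ascending, multiply the i-th smallest by `m - i + 1`, enforce
#' monotonicity by running maxima, cap at 1, and return in the original
#' order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as input.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Pairwise Wilcoxon tests with Holm adjustment and letter display
#'
#' Runs [wilcoxon_rank_sum()] on every pair of groups, adjusts the p values
#' with [holm_adjust()], and summarises the result as a compact letter
#' display in which two groups share a letter if and only if their adjusted
#' p value is at least `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector, same length as `values`.
#' @param alpha Significance level for the letter display.
#' @param exact_max Passed to [wilcoxon_rank_sum()].
#' @return Object of class `pairwise_wilcoxon` with fields `groups`,
#'   `p_raw`, `p_adj` (symmetric matrices), `letters`, `alpha`.
#' @export
pairwise_wilcoxon <- function(values, groups, alpha = 0.05,
                              exact_max = 12) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  g <- unique(groups)
  k <- length(g)
  if (k < 2) stop("need at least two groups")
  p_raw <- matrix(NA_real_, k, k, dimnames = list(g, g))
  pairs <- utils::combn(k, 2)
  pv <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pv[j] <- wilcoxon_rank_sum(values[groups == g[i1]],
                               values[groups == g[i2]], exact_max)
    p_raw[i1, i2] <- p_raw[i2, i1] <- pv[j]
  }
  adj <- holm_adjust(pv)
  p_adj <- p_raw
  for (j in seq_len(ncol(pairs))) {
    p_adj[pairs[1, j], pairs[2, j]] <- adj[j]
    p_adj[pairs[2, j], pairs[1, j]] <- adj[j]
  }
  structure(list(groups = g, p_raw = p_raw, p_adj = p_adj,
                 letters = compact_letters(p_adj, alpha, g),
                 alpha = alpha),
            class = "pairwise_wilcoxon")
}

#' @export
print.pairwise_wilcoxon <- function(x, digits = 4, ...) {
  cat("Pairwise Wilcoxon rank-sum tests, Holm-adjusted (alpha =",
      x$alpha, ")\n")
  print(round(x$p_adj, digits))
  cat("Letters:", paste(x$groups, x$letters, sep = ":", collapse = "  "),
      "\n")
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start with all groups sharing one letter;
#' for each significantly different pair, split every letter set containing
#' both into two sets (each missing one member of the pair), then absorb
#' letter sets that are subsets of others. The result satisfies: two groups
#' share a letter if and only if they are not significantly different.
#' Deterministic given the group order (letters assigned by first group
#' appearance).
#'
#' @param p_adj Symmetric matrix of adjusted p values.
#' @param alpha Significance level.
#' @param group_names Optional group labels (defaults to rownames).
#' @return Character vector of letter codes, one per group.
#' @examples
#' p <- matrix(c(NA, 0.5, 0.01, 0.5, NA, 0.5, 0.01, 0.5, NA), 3, 3)
#' compact_letters(p, 0.05, c("g1", "g2", "g3"))  # "a" "ab" "b"
#' @export
compact_letters <- function(p_adj, alpha = 0.05, group_names = NULL) {
  k <- nrow(p_adj)
  if (is.null(group_names)) group_names <- rownames(p_adj)
  if (is.null(group_names)) group_names <- as.character(seq_len(k))
  sets <- list(seq_len(k))  # each set = indices sharing a letter
  for (i1 in seq_len(k - 1)) {
    for (i2 in seq((i1 + 1), k)) {
      if (!is.na(p_adj[i1, i2]) && p_adj[i1, i2] < alpha) {
        new_sets <- list()
        for (s in sets) {
          if (i1 %in% s && i2 %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, i1)),
                          list(setdiff(s, i2)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        # absorb: drop sets contained in another set
        keep <- rep(TRUE, length(new_sets))
        for (a in seq_along(new_sets)) {
          for (b in seq_along(new_sets)) {
            if (a != b && keep[b] &&
                all(new_sets[[a]] %in% new_sets[[b]]) &&
                (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
              keep[a] <- FALSE
              break
            }
          }
        }
        sets <- new_sets[keep]
      }
    }
  }
  # order letters by the first (smallest-index) group they contain
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- character(k)
  for (j in seq_along(sets)) {
    for (i in sets[[j]]) {
      letters_out[i] <- paste0(letters_out[i], letters[j])
    }
  }
  stats::setNames(letters_out, group_names)
}

#' Association analyses over a strain phenotype panel
#'
#' Reproduces the three pairwise phenotype comparisons over merged strain
#' records: period vs first-LL-peak time, period vs CDL, and peak time vs
#' CDL, each with a Pearson correlation test and a Deming regression line.
#' Strains flagged as excluded (unstable rhythms) are dropped from every
#' analysis involving the period or peak phenotypes; strains with censored
#' CDLs are dropped from analyses involving CDL.
#'
#' @param records Data frame with columns `strain_id`, `mean_frp_h`,
#'   `first_peak_h` (or `first_peak_mean_h`), `cdl_h`, `excluded`, and
#'   optionally `cdl_censored` (logical).
#' @param delta Error-variance ratio for the Deming fits.
#' @return Object of class `panel_association`: a list with one element per
#'   phenotype pair, each holding `pearson` (r, p, n) and `deming`.
#' @export
panel_association <- function(records, delta = 1) {
  fp_col <- if ("first_peak_h" %in% names(records)) "first_peak_h"
  else "first_peak_mean_h"
  stopifnot(all(c("mean_frp_h", "cdl_h", "excluded") %in% names(records)),
            fp_col %in% names(records))
  cens <- if ("cdl_censored" %in% names(records)) records$cdl_censored
  else !is.finite(records$cdl_h)
  usable_rhythm <- !records$excluded
  usable_cdl <- !cens & is.finite(records$cdl_h)

  one <- function(x, y, keep, label) {
    keep <- keep & is.finite(x) & is.finite(y)
    if (sum(keep) < 3) stop("fewer than 3 usable strains for ", label)
    list(pearson = pearson_test(x[keep], y[keep]),
         deming = deming_fit(x[keep], y[keep], delta),
         n = sum(keep))
  }
  out <- list(
    frp_peak = one(records$mean_frp_h, records[[fp_col]],
                   usable_rhythm, "FRP vs peak time"),
    frp_cdl = one(records$mean_frp_h, records$cdl_h,
                  usable_rhythm & usable_cdl, "FRP vs CDL"),
    peak_cdl = one(records[[fp_col]], records$cdl_h,
                   usable_rhythm & usable_cdl, "peak time vs CDL"))
  structure(out, class = "panel_association")
}

#' @export
print.panel_association <- function(x, ...) {
  lab <- c(frp_peak = "FRP vs first LL peak",
           frp_cdl = "FRP vs CDL",
           peak_cdl = "first LL peak vs CDL")
  cat("Panel association analyses\n")
  for (nm in names(x)) {
    a <- x[[nm]]
    cat(sprintf("  %-22s r = %+.3f, p = %.3g, n = %d; Deming slope = %+.3f\n",
                lab[[nm]], a$pearson$r, a$pearson$p, a$n, a$deming$slope))
  }
  invisible(x)
}
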