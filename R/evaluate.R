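# Read-weighted evaluation of decontamination calls, threshold optimisation,
# and PERMANOVA variance attribution.

#' Read-weighted confusion counts
#'
#' Scores a contaminant call against simulation truth on a per-read basis:
#' reads of contaminant-labelled taxa called contaminant are true positives,
#' called true components are false negatives; sequins reads called true
#' components are true negatives, called contaminant are false positives.
#'
#' @param call A `contaminant_call` covering every taxon in the profile.
#' @param profile A truth-labelled `read_count_profile`.
#' @return List with `tp`, `fn`, `tn`, `fp` (read counts).
#' @export
confusion_counts <- function(call, profile) {
  idx <- match(profile$taxon, call$taxon)
  if (anyNA(idx)) {
    stop("uncalled taxa in profile: ", paste(utils::head(profile$taxon[is.na(idx)]), collapse = ", "))
  }
  called_cont <- call$call[idx] == "contaminant"
  is_cont <- profile$label != "sequins"
  list(
    tp = sum(profile$reads[is_cont & called_cont]),
    fn = sum(profile$reads[is_cont & !called_cont]),
    tn = sum(profile$reads[!is_cont & !called_cont]),
    fp = sum(profile$reads[!is_cont & called_cont])
  )
}

# element-wise sum of confusion lists
sum_confusion <- function(counts_list) {
  Reduce(function(a, b) Map(`+`, a, b), counts_list)
}

#' Precision and recall from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`. A zero
#' denominator leaves the quantity undefined, reported as `NA` (never coerced
#' to 0 or 1).
#'
#' @param counts A list with `tp`, `fn`, `tn`, `fp`.
#' @return List with `precision` and `recall`.
#' @export
precision_recall <- function(counts) {
  list(
    precision = if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else NA_real_,
    recall = if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  )
}

#' Default threshold grid
#'
#' Forty evenly spaced thresholds from 0.1 to 0.5.
#'
#' @param n Number of grid points (default 40).
#' @param from,to Grid range (defaults 0.1 and 0.5).
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(n = 40, from = 0.1, to = 0.5) {
  seq(from, to, length.out = n)
}

#' Optimise the score threshold under a perfect-precision constraint
#'
#' Sweeps the grid: at each threshold the scores are classified (for `either`
#' mode the same threshold is applied to both scores), confusion counts are
#' aggregated over the supplied libraries, and read-weighted precision and
#' recall are recorded. The chosen threshold is the one with the best recall
#' among thresholds attaining 100% precision, ties broken toward the larger
#' threshold. When no threshold attains perfect precision the sweep falls
#' back to maximal precision, then maximal recall (flagged in the result).
#'
#' @param scores Score table from [contaminant_scores()].
#' @param profiles Truth-labelled profiles of the positive libraries to
#'   aggregate over.
#' @param mode Classification mode passed to [classify_contaminants()].
#' @param grid Threshold grid (default [threshold_grid()]).
#' @return A `sweep_result` list: `grid`, `precision`, `recall`, `chosen`,
#'   `attained_perfect_precision`.
#' @export
optimize_threshold <- function(scores, profiles, mode = "either", grid = threshold_grid()) {
  if (length(grid) == 0) stop("empty threshold grid")
  if (inherits(profiles, "read_count_profile")) profiles <- list(profiles)
  precision <- recall <- numeric(length(grid))
  perfect <- logical(length(grid))
  for (i in seq_along(grid)) {
    call <- classify_contaminants(scores, mode = mode, t_freq = grid[i], t_prev = grid[i])
    cc <- sum_confusion(lapply(profiles, function(p) confusion_counts(call, p)))
    pr <- precision_recall(cc)
    precision[i] <- pr$precision
    recall[i] <- pr$recall
    perfect[i] <- cc$fp == 0
  }
  candidates <- if (any(perfect)) which(perfect) else {
    p_eff <- ifelse(is.na(precision), -Inf, precision)
    which(p_eff == max(p_eff))
  }
  r_eff <- ifelse(is.na(recall[candidates]), -Inf, recall[candidates])
  best <- candidates[r_eff == max(r_eff)]
  chosen <- grid[max(best)]
  structure(
    list(
      grid = grid, precision = precision, recall = recall,
      chosen = chosen, attained_perfect_precision = any(perfect)
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "Threshold sweep over %d grid points [%.3g, %.3g]: chosen %.4g (%s)\n",
    length(x$grid), min(x$grid), max(x$grid), x$chosen,
    if (x$attained_perfect_precision) "100% precision attained"
    else "100% precision NOT attained; fell back to max precision"
  ))
  invisible(x)
}

#' Distance between a decontaminated profile and the actual signal
#'
#' Removes the taxa called contaminant, renormalises the remainder, and
#' returns its Jensen-Shannon distance to the measured sequins-only profile
#' (the actual signal). When the call removes everything the distance is
#' maximal (1), with a warning.
#'
#' @param profile A `read_count_profile`.
#' @param call A `contaminant_call` covering the profile.
#' @return JSD in \[0, 1\].
#' @export
decontaminated_jsd <- function(profile, call) {
  idx <- match(profile$taxon, call$taxon)
  if (anyNA(idx)) stop("uncalled taxa in profile")
  keep <- call$call[idx] == "true_component" & profile$reads > 0
  signal <- total_sum_scale(profile, "sequins")
  if (!any(keep)) {
    warning("decontamination removed every taxon; returning maximal distance")
    return(1)
  }
  decont <- stats::setNames(
    profile$reads[keep] / sum(profile$reads[keep]),
    profile$taxon[keep]
  )
  jsd(decont, signal)
}

# All permutations of 1..n (n small), one row each.
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    # insert n at position pos within each sub-permutation
    block <- t(apply(sub, 1, function(p) append(p, n, after = pos - 1L)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(f = f, r_squared = ss_between / ss_total)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the variance of a distance matrix between and within the levels
#' of a grouping factor. With `SS_total = (1/N) * sum_{i<j} d_ij^2` and
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`, the pseudo-F
#' statistic is `(SS_between / (a-1)) / (SS_within / (N-a))` and
#' `R^2 = SS_between / SS_total`. The p-value permutes group labels; the
#' add-one convention `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`
#' avoids zero p-values. With `exact = TRUE` all `N!` relabelings are
#' enumerated and the p-value is the exact tail fraction (the identity
#' permutation included).
#'
#' @param d A square symmetric distance matrix (or `dist`) with zero
#'   diagonal.
#' @param groups Grouping factor of length `N` with >= 2 levels.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all permutations (requires `N <= 8`).
#' @return A `permanova_result` list: `r_squared`, `pseudo_f`, `p_value`,
#'   `n_permutations`, `exact`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1, exact = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("d must be a square symmetric distance matrix")
  }
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups must match the distance matrix dimension")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  if (exact) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(p) permanova_f(d2, groups[p])$f)
    p_value <- mean(f_perm >= obs$f - 1e-12)
    n_perm <- nrow(perms)
  } else {
    f_perm <- with_seed(derive_seed(seed, "permanova"), {
      vapply(seq_len(n_permutations), function(i) {
        permanova_f(d2, groups[sample.int(n)])$f
      }, numeric(1))
    })
    p_value <- (1 + sum(f_perm >= obs$f - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(
    list(
      r_squared = obs$r_squared, pseudo_f = obs$f, p_value = p_value,
      n_permutations = n_perm, exact = exact
    ),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.3f, pseudo-F = %.3f, p = %.4g (%s permutations)\n",
    x$r_squared, x$pseudo_f, x$p_value,
    if (x$exact) paste0("all ", x$n_permutations) else x$n_permutations
  ))
  invisible(x)
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' Convenience wrapper building the JSD matrix between a set of abundance
#' profiles, e.g. for [permanova()].
#'
#' @param abundances List of named abundance vectors.
#' @return Symmetric matrix of distances.
#' @export
jsd_matrix <- function(abundances) {
  n <- length(abundances)
  m <- matrix(0, n, n, dimnames = list(names(abundances), names(abundances)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jsd(abundances[[i]], abundances[[j]])
    }
  }
  m
}
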