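# In silico decontamination: fold-over-NC filtering and frequency/prevalence
# contaminant scores with thresholded classification.

#' Negative-control reference profile
#'
#' Averages the relative abundance of each taxon across negative-control
#' libraries (union support, absent taxa counted as 0). Requires at least two
#' NCs.
#'
#' @param nc_profiles List of `read_count_profile`s or named abundance
#'   vectors.
#' @return Named numeric vector of mean NC abundances with attribute `n_nc`,
#'   class `nc_reference`.
#' @export
nc_reference <- function(nc_profiles) {
  if (length(nc_profiles) < 2) stop("need at least 2 negative controls")
  abunds <- lapply(nc_profiles, function(p) {
    if (is.numeric(p)) p else total_sum_scale(p, "all")
  })
  support <- unique(unlist(lapply(abunds, names)))
  mat <- matrix(0, nrow = length(abunds), ncol = length(support),
                dimnames = list(NULL, support))
  for (i in seq_along(abunds)) mat[i, names(abunds[[i]])] <- abunds[[i]]
  structure(colMeans(mat), n_nc = length(abunds), class = "nc_reference")
}

new_call <- function(taxon, call, method, thresholds = NULL) {
  structure(
    data.frame(taxon = taxon, call = call, stringsAsFactors = FALSE),
    method = method, thresholds = thresholds,
    class = c("contaminant_call", "data.frame")
  )
}

#' Fold-over-NC classification
#'
#' A taxon whose relative abundance exceeds `fold` times its NC-reference
#' abundance (strictly) is classified a true component; all others --
#' including ties at exactly `fold` times the reference -- are classified
#' contaminants. Taxa absent from the NCs (reference 0) are true components
#' whenever present at all.
#'
#' @param profile A `read_count_profile` or named abundance vector.
#' @param ref An [nc_reference()].
#' @param fold Fold threshold, typically 5 or 10.
#' @return A `contaminant_call` data frame (`taxon`, `call`).
#' @export
fold_nc_classify <- function(profile, ref, fold = 5) {
  if (fold <= 0) stop("fold must be positive")
  ab <- if (is.numeric(profile)) profile else total_sum_scale(profile, "all")
  ref_ab <- stats::setNames(numeric(length(ab)), names(ab))
  hit <- intersect(names(ab), names(ref))
  ref_ab[hit] <- unclass(ref)[hit]
  call <- ifelse(ab > fold * ref_ab, "true_component", "contaminant")
  new_call(names(ab), unname(call), method = sprintf("fold%g_nc", fold),
           thresholds = c(fold = fold))
}

#' Frequency score of one taxon
#'
#' Tests whether a taxon's relative abundance scales inversely with input
#' DNA, the signature of a constant-mass reagent contaminant. On
#' `(x, y) = (log input, log frequency)` over samples where the taxon is
#' present, a contaminant model `y = -x + b` (slope fixed at -1, intercept
#' fitted by least squares) is compared to a non-contaminant constant model
#' `y = c`; the score is the CDF of an F distribution with `(n-1, n-1)`
#' degrees of freedom evaluated at the ratio of residual sums of squares
#' (contaminant over non-contaminant). Small scores are contaminant-like.
#' Returns `NA` when fewer than 3 samples qualify.
#'
#' @param frequencies Relative abundances across positive samples.
#' @param input_pg Input masses (pg) of the same samples.
#' @return Score in \[0, 1\], or `NA` when undefined.
#' @export
frequency_score <- function(frequencies, input_pg) {
  if (length(frequencies) != length(input_pg)) stop("frequencies and input_pg differ in length")
  keep <- frequencies > 0 & input_pg > 0
  if (sum(keep) < 3) return(NA_real_)
  y <- log(frequencies[keep])
  x <- log(input_pg[keep])
  n <- length(y)
  if (stats::var(x) == 0) return(NA_real_)
  b <- mean(y + x)
  ssr_cont <- sum((y + x - b)^2)
  ssr_null <- sum((y - mean(y))^2)
  if (ssr_cont == 0 && ssr_null == 0) return(NA_real_)
  if (ssr_null == 0) return(1)
  stats::pf(ssr_cont / ssr_null, n - 1, n - 1)
}

#' Prevalence score of one taxon
#'
#' Compares presence/absence of a taxon in negative controls versus positive
#' samples. Under the hypergeometric null that the taxon's presences are
#' distributed at random across all samples, the score is the one-sided tail
#' probability of seeing at least the observed number of NC presences. Small
#' scores (NC-enriched presence) are contaminant-like.
#'
#' @param k_pos,n_pos Presences and totals among positive samples.
#' @param k_nc,n_nc Presences and totals among negative controls.
#' @return Score in (0, 1\].
#' @export
prevalence_score <- function(k_pos, n_pos, k_nc, n_nc) {
  stopifnot(k_pos <= n_pos, k_nc <= n_nc, n_pos >= 1, n_nc >= 1)
  m <- k_pos + k_nc
  stats::phyper(k_nc - 1, m, n_pos + n_nc - m, n_nc, lower.tail = FALSE)
}

#' Frequency and prevalence scores for every taxon of one kit
#'
#' Computes [frequency_score()] (positive libraries only) and
#' [prevalence_score()] for every taxon appearing in a kit's libraries.
#' Negative controls are identified by `input_pg == 0`. Presence means a
#' count above `presence_min` reads (default 0: any read counts).
#'
#' @param profiles List of `read_count_profile`s of one kit, including its
#'   negative controls.
#' @param presence_min Count floor for presence in the prevalence test.
#' @return Data frame with columns `taxon`, `score_freq`, `score_prev`,
#'   `k_pos`, `n_pos`, `k_nc`, `n_nc`.
#' @export
contaminant_scores <- function(profiles, presence_min = 0) {
  input <- vapply(profiles, attr, 0, "input_pg")
  pos <- input > 0
  if (!any(pos)) stop("no positive libraries")
  if (!any(!pos)) stop("no negative controls")
  taxa <- unique(unlist(lapply(profiles, function(p) p$taxon)))

  counts <- matrix(0L, nrow = length(profiles), ncol = length(taxa),
                   dimnames = list(names(profiles), taxa))
  freqs <- matrix(0, nrow = length(profiles), ncol = length(taxa),
                  dimnames = list(names(profiles), taxa))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    counts[i, p$taxon] <- p$reads
    freqs[i, p$taxon] <- p$reads / sum(p$reads)
  }
  present <- counts > presence_min

  score_freq <- vapply(taxa, function(t) {
    frequency_score(freqs[pos, t], input[pos])
  }, numeric(1))
  n_pos <- sum(pos)
  n_nc <- sum(!pos)
  k_pos <- colSums(present[pos, , drop = FALSE])
  k_nc <- colSums(present[!pos, , drop = FALSE])
  score_prev <- vapply(taxa, function(t) {
    prevalence_score(k_pos[[t]], n_pos, k_nc[[t]], n_nc)
  }, numeric(1))

  data.frame(
    taxon = taxa, score_freq = unname(score_freq), score_prev = unname(score_prev),
    k_pos = unname(k_pos), n_pos = n_pos, k_nc = unname(k_nc), n_nc = n_nc,
    stringsAsFactors = FALSE
  )
}

#' Threshold the frequency/prevalence scores into contaminant calls
#'
#' Frequency mode calls a taxon contaminant when `score_freq < t_freq`;
#' prevalence mode when `score_prev < t_prev`; either mode when either
#' condition holds. Undefined (`NA`) scores never trigger a contaminant call.
#' Taxa absent from every positive sample (column `k_pos` present and 0) are
#' classified contaminant by convention: they carry no signal reads.
#'
#' @param scores A score table from [contaminant_scores()] (or any data frame
#'   with `taxon`, `score_freq`, `score_prev`).
#' @param mode One of `"frequency"`, `"prevalence"`, `"either"`.
#' @param t_freq,t_prev Thresholds in (0, 0.5\].
#' @return A `contaminant_call` data frame.
#' @export
classify_contaminants <- function(scores, mode = c("frequency", "prevalence", "either"),
                                  t_freq = 0.5, t_prev = 0.5) {
  mode <- match.arg(mode)
  for (t in c(t_freq, t_prev)) {
    if (!is.numeric(t) || t <= 0 || t > 0.5) stop("thresholds must lie in (0, 0.5]")
  }
  freq_hit <- !is.na(scores$score_freq) & scores$score_freq < t_freq
  prev_hit <- !is.na(scores$score_prev) & scores$score_prev < t_prev
  hit <- switch(mode,
    frequency = freq_hit,
    prevalence = prev_hit,
    either = freq_hit | prev_hit
  )
  if ("k_pos" %in% names(scores)) hit <- hit | scores$k_pos == 0
  new_call(
    scores$taxon, ifelse(hit, "contaminant", "true_component"),
    method = mode, thresholds = c(t_freq = t_freq, t_prev = t_prev)
  )
}
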