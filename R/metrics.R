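# Compositional and library-efficiency metrics.

# Coerce a pair of abundance vectors onto a common support. Named vectors are
# aligned on the union of names (absent taxa = 0); unnamed vectors must have
# equal length and are aligned by position.
align_profiles <- function(p, q) {
  if (is.null(names(p)) && is.null(names(q))) {
    if (length(p) != length(q)) stop("unnamed profiles must have equal length")
    return(list(p = as.numeric(p), q = as.numeric(q)))
  }
  if (is.null(names(p)) || is.null(names(q))) stop("both profiles must be named (or both unnamed)")
  support <- union(names(p), names(q))
  pp <- qq <- stats::setNames(numeric(length(support)), support)
  pp[names(p)] <- p
  qq[names(q)] <- q
  list(p = pp, q = qq)
}

check_abundance <- function(x, name = "profile") {
  if (any(x < 0)) stop(name, " has negative abundances")
  s <- sum(x)
  if (s <= 0) stop(name, " is empty")
  if (abs(s - 1) > 1e-6) x / s else x
}

#' Total sum scaling (relative abundance)
#'
#' Normalises a count profile to relative abundances over a label subset.
#'
#' @param profile A `read_count_profile` (or data frame with `taxon`, `label`,
#'   `reads` columns).
#' @param subset Which rows to keep: `"all"`, `"sequins"`, `"contaminant"`
#'   (kit plus endogenous), or any vector of label values.
#' @return Named numeric vector of relative abundances summing to 1.
#' @examples
#' p <- data.frame(taxon = c("A", "B"), label = "sequins", reads = c(1, 3))
#' total_sum_scale(p)
#' @export
total_sum_scale <- function(profile, subset = "all") {
  labels <- switch(subset[1],
    all = unique(profile$label),
    contaminant = c("kit_contaminant", "endogenous_contaminant"),
    subset
  )
  tab <- profile[profile$label %in% labels, , drop = FALSE]
  total <- sum(tab$reads)
  if (nrow(tab) == 0 || total == 0) {
    stop("empty profile: no reads in the selected subset")
  }
  stats::setNames(tab$reads / total, tab$taxon)
}

#' Jensen-Shannon distance
#'
#' Square root of the Jensen-Shannon divergence computed with base-2
#' logarithms, so both divergence and distance lie in \[0, 1\]: 0 for
#' identical profiles, 1 for profiles with disjoint support. Profiles are
#' aligned on the union of their taxa (absent taxa contribute 0) and
#' `0 * log 0` is taken as 0.
#'
#' @param p,q Abundance profiles (named numeric vectors, or unnamed vectors of
#'   equal length). Renormalised if they do not sum to 1.
#' @return The distance, a number in \[0, 1\].
#' @examples
#' jsd(c(A = 1), c(A = 1))            # 0
#' jsd(c(A = 1), c(B = 1))            # 1
#' jsd(c(1, 0), c(0.5, 0.5))          # ~0.558
#' @export
jsd <- function(p, q) {
  al <- align_profiles(p, q)
  p <- check_abundance(al$p, "p")
  q <- check_abundance(al$q, "q")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  div <- (kl(p) + kl(q)) / 2
  sqrt(min(max(div, 0), 1))
}

#' Compositional fidelity
#'
#' One minus the Jensen-Shannon distance between a measured profile and the
#' expected (design) composition: 1 for a perfect match, 0 for disjoint
#' profiles.
#'
#' @param measured,expected Abundance profiles.
#' @return Fidelity in \[0, 1\].
#' @export
fidelity <- function(measured, expected) 1 - jsd(measured, expected)

#' Replicate reproducibility
#'
#' One minus the Jensen-Shannon distance between the measured profiles of two
#' experimental replicates.
#'
#' @param rep1,rep2 Abundance profiles of the replicate pair.
#' @return Reproducibility in \[0, 1\].
#' @export
reproducibility <- function(rep1, rep2) 1 - jsd(rep1, rep2)

#' Proportion of designated (sequins) reads
#'
#' @param profile A `read_count_profile`.
#' @return Fraction of reads labelled `sequins`.
#' @export
proportion_designated <- function(profile) {
  total <- sum(profile$reads)
  if (total <= 0) stop("profile has zero depth")
  sum(profile$reads[profile$label == "sequins"]) / total
}

#' Library conversion rate
#'
#' The fraction of input molecules effectively converted into designated
#' (sequins) library, corrected for PCR amplification:
#' `q_library * r_designated / (q_input * e_primer^n_pcr)`.
#'
#' @param q_library Library quantity (pg).
#' @param q_input Input DNA quantity (pg), must be positive.
#' @param n_pcr Number of PCR cycles.
#' @param r_designated Ratio of designated (sequins) reads to all reads.
#' @param e_primer Primer efficiency base; 2 represents 100% efficiency.
#' @return The conversion rate.
#' @examples
#' conversion_rate(q_library = 5120, q_input = 5, n_pcr = 10, r_designated = 0.5)
#' @export
conversion_rate <- function(q_library, q_input, n_pcr, r_designated, e_primer = 2) {
  if (any(q_input <= 0)) stop("q_input must be positive")
  if (any(n_pcr < 0)) stop("n_pcr must be non-negative")
  q_library * r_designated / (q_input * e_primer^n_pcr)
}

#' Duplication rate of a simulated library
#'
#' One minus the fraction of reads mapping to distinct library molecules,
#' using the finite-molecule bookkeeping recorded by [simulate_library()].
#'
#' @param profile A simulated `read_count_profile`.
#' @return Duplication rate in \[0, 1\].
#' @export
duplication_rate <- function(profile) {
  uniq <- attr(profile, "n_unique_molecules")
  total <- attr(profile, "total_depth")
  if (is.null(uniq) || is.null(total)) {
    stop("profile carries no molecule bookkeeping (not produced by simulate_library?)")
  }
  1 - uniq / total
}

#' Per-component abundance bias
#'
#' Ratio between measured and reference relative abundance per taxon; 1 means
#' unbiased. Taxa with zero reference abundance are skipped with a warning
#' (the ratio is undefined, never infinite).
#'
#' @param measured,reference Named abundance profiles.
#' @return Named numeric vector of ratios over the common support.
#' @export
abundance_bias <- function(measured, reference) {
  common <- intersect(names(measured), names(reference))
  zero_ref <- common[reference[common] == 0]
  if (length(zero_ref)) {
    warning("skipping ", length(zero_ref), " taxa with zero reference abundance")
    common <- setdiff(common, zero_ref)
  }
  measured[common] / reference[common]
}

#' Regression of abundance bias on fragment length
#'
#' Ordinary least squares of the per-component bias ratio (or its log) on
#' fragment length, with the two-sided slope t-test p-value. Used to ask
#' whether amplification enriches longer fragments.
#'
#' @param bias Numeric vector of bias ratios.
#' @param lengths Fragment lengths (bp), same order as `bias`.
#' @param log_ratio Regress `log(bias)` instead of the raw ratio.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
length_bias_regression <- function(bias, lengths, log_ratio = FALSE) {
  if (length(bias) != length(lengths)) stop("bias and lengths differ in length")
  if (length(bias) < 3) stop("need at least 3 points")
  if (stats::var(lengths) == 0) stop("zero variance in lengths")
  y <- if (log_ratio) log(bias) else bias
  fit <- stats::lm(y ~ lengths)
  sm <- summary(fit)
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = if (sm$sigma == 0) {
      if (abs(coef(fit)[2]) < 1e-12) 1 else 0  # degenerate zero-residual fits
    } else {
      unname(sm$coefficients[2, 4])
    }
  )
}

#' GC shift of measured sequins reads
#'
#' Read-weighted mean GC of sequins reads minus the design's mass-weighted
#' mean GC; negative values indicate enrichment of low-GC components.
#'
#' @param profile A `read_count_profile`.
#' @param design The `community_design` the library was simulated from.
#' @return The GC shift (fraction units).
#' @export
gc_shift <- function(profile, design) {
  comp <- design$components
  seq_rows <- profile[profile$label == "sequins", , drop = FALSE]
  seq_rows <- seq_rows[match(comp$id, seq_rows$taxon), , drop = FALSE]
  if (nrow(seq_rows) == 0 || sum(seq_rows$reads, na.rm = TRUE) == 0) {
    stop("profile has no sequins reads")
  }
  measured <- sum(seq_rows$reads * comp$gc, na.rm = TRUE) / sum(seq_rows$reads, na.rm = TRUE)
  expected <- sum(comp$mass_fraction * comp$gc)
  measured - expected
}

#' Rarefy a count profile
#'
#' Subsamples reads without replacement down to `depth` (multivariate
#' hypergeometric), so each taxon's new count never exceeds its original
#' count and zero taxa stay zero.
#'
#' @param profile A `read_count_profile`.
#' @param depth Target depth, at most the profile's total depth.
#' @param seed Integer seed.
#' @return A `read_count_profile` at the new depth (molecule bookkeeping is
#'   dropped: it describes the unrarefied library).
#' @export
rarefy_profile <- function(profile, depth, seed = 1) {
  total <- sum(profile$reads)
  if (depth > total) stop("depth exceeds profile total")
  counts <- with_seed(derive_seed(seed, paste0("rarefy_", attr(profile, "library_id"))), {
    if (depth == 0) {
      integer(nrow(profile))
    } else {
      idx <- sample(rep.int(seq_len(nrow(profile)), profile$reads), depth)
      tabulate(idx, nbins = nrow(profile))
    }
  })
  out <- profile
  out$reads <- counts
  attr(out, "total_depth") <- sum(counts)
  attr(out, "n_molecules") <- NULL
  attr(out, "n_unique_molecules") <- NULL
  out
}
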