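#' Shannon entropy of a site distribution
#'
#' Computes `H = -sum(p * log_base(p))` with the convention `0 * log 0 = 0`.
#' With base 20 (the alphabet size) the entropy of an amino-acid site lies
#' in `[0, 1]`: a completely conserved site scores 0 and a site uniform over
#' the 20 residues scores 1.
#'
#' @param dist Numeric probability vector (any length; a site distribution
#'   over the 20 residues, or a flattened joint distribution).
#' @param base Logarithm base, > 1.  Default 20; base 2 gives bits.
#' @return Entropy in `log_base` units.
#' @export
entropy <- function(dist, base = 20) {
  if (length(base) != 1L || !is.finite(base) || base <= 1)
    stop_sdr("log base must be a single number > 1", class = "sdrcov_parameter_error")
  p <- as.numeric(dist)
  if (any(p < -1e-12)) stop_sdr("negative probability in distribution")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Weighted residue distribution of an MSA site
#'
#' `p_j(x) = sum_i alpha_i * [A_ij == x] / sum_i alpha_i`: the
#' sequence-weighted frequency of each residue at alignment column `j`.
#' Gapped sites are not summarised; use [filter_sites()] to exclude them.
#'
#' @param alignment A [domain_alignment].
#' @param weights A [sequence_weights] vector (alignment order).
#' @param j Site index, 1-based.
#' @return Named numeric vector of length 20 over [AA20], summing to 1.
#' @export
msa_site_distribution <- function(alignment, weights, j) {
  if (j < 1L || j > ncol(alignment)) stop_sdr("site index %d out of [1, %d]", j, ncol(alignment))
  col <- alignment[, j]
  if (any(col == GAP))
    stop_sdr("site %d contains gaps; gapped sites must be excluded via filter_sites()",
             j, class = "sdrcov_gap_error")
  w <- as.numeric(weights) / sum(weights)
  p <- vapply(AA20, function(a) sum(w[col == a]), numeric(1))
  p / sum(p)
}

#' Weighted residue distribution of a PWM site
#'
#' `p_k(y) = sum_i alpha_i * W_ik(y) / sum_i alpha_i`: the weighted average
#' over domains of the probability of residue `y` at peptide position `k`.
#'
#' @param profiles A [profile_set].
#' @param weights A [sequence_weights] vector (profile order).
#' @param k PWM site index, 1-based.
#' @return Named numeric vector of length 20 over [AA20], summing to 1.
#' @export
pwm_site_distribution <- function(profiles, weights, k) {
  if (k < 1L || k > profiles$w) stop_sdr("PWM site index %d out of [1, %d]", k, profiles$w)
  w <- as.numeric(weights) / sum(weights)
  cols <- vapply(profiles$pwms, function(m) m[, k], numeric(20L))
  p <- as.numeric(cols %*% w)
  names(p) <- AA20
  p / sum(p)
}

#' Weighted joint distribution of an MSA site and a PWM site
#'
#' `p_jk(x, y) = sum_i alpha_i * [A_ij == x] * W_ik(y) / sum_i alpha_i`.
#' Each sequence contributes its full weight on the row of its residue at
#' MSA site `j`, spread across the columns according to its own PWM's
#' distribution at peptide site `k`.  The row and column marginals of the
#' result reproduce [msa_site_distribution()] and [pwm_site_distribution()].
#'
#' @inheritParams msa_site_distribution
#' @param profiles A [profile_set] row-aligned to `alignment`.
#' @param k PWM site index, 1-based.
#' @return A 20 x 20 matrix (rows: MSA residue x, columns: PWM residue y)
#'   summing to 1.
#' @export
joint_distribution <- function(alignment, profiles, weights, j, k) {
  col <- alignment[, j]
  if (any(col == GAP))
    stop_sdr("site %d contains gaps; gapped sites must be excluded via filter_sites()",
             j, class = "sdrcov_gap_error")
  if (k < 1L || k > profiles$w) stop_sdr("PWM site index %d out of [1, %d]", k, profiles$w)
  w <- as.numeric(weights) / sum(weights)
  jd <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  for (i in seq_along(w)) {
    if (w[i] == 0) next
    jd[col[i], ] <- jd[col[i], ] + w[i] * profiles$pwms[[i]][, k]
  }
  jd / sum(jd)
}

#' Mutual information from entropies
#'
#' `MI = H(X) + H(Y) - H(X, Y)`, the information shared by an MSA site and
#' a PWM site.  Tiny negative values from floating-point cancellation (down
#' to -1e-9) are clamped to 0; anything more negative signals inconsistent
#' inputs and raises an error.
#'
#' @param H_msa,H_pwm,H_joint Entropies of the two sites and their joint
#'   distribution, all in the same log base.
#' @return Mutual information (same units), >= 0.
#' @export
mutual_information <- function(H_msa, H_pwm, H_joint) {
  mi <- H_msa + H_pwm - H_joint
  if (mi < -1e-9)
    stop_sdr("negative mutual information (%.3g): inconsistent entropies", mi)
  max(mi, 0)
}

#' Uncertainty coefficient
#'
#' Normalises mutual information by the site entropies to penalise the
#' inflation of raw MI at highly diverse sites.  The default symmetric form
#' is `2 * MI / (H_msa + H_pwm)`; the asymmetric variants `MI / H_msa` and
#' `MI / H_pwm` are selectable.  Returns 0 when the chosen denominator is 0
#' (such pairs carry no information and must not rank).
#'
#' @param MI Mutual information (>= 0).
#' @param H_msa,H_pwm Site entropies in the same log base as `MI`.
#' @param variant One of "symmetric", "msa", "pwm".
#' @return Uncertainty coefficient in `[0, 1]`.
#' @export
uncertainty_coefficient <- function(MI, H_msa, H_pwm,
                                    variant = c("symmetric", "msa", "pwm")) {
  variant <- match.arg(variant)
  denom <- switch(variant,
                  symmetric = (H_msa + H_pwm) / 2,
                  msa = H_msa,
                  pwm = H_pwm)
  if (denom <= 0) return(0)
  MI / denom
}

#' Chi-square approximation p-value for mutual information
#'
#' For n sequences, `2 * ln(2) * n * MI` (MI in bits) is asymptotically
#' chi-square distributed under independence, with
#' `(card_msa - 1) * (card_pwm - 1)` degrees of freedom, where the
#' cardinalities are the number of residues with nonzero marginal support at
#' each site.
#'
#' @param MI Mutual information in base-2 units (bits).
#' @param n Number of sequences (>= 2).
#' @param card_msa,card_pwm Effective alphabet sizes at the two sites
#'   (>= 2).
#' @return Upper-tail chi-square probability in `[0, 1]`.
#' @export
chi2_pvalue <- function(MI, n, card_msa, card_pwm) {
  if (card_msa < 2L || card_pwm < 2L)
    stop_sdr("chi-square test undefined for site cardinality < 2",
             class = "sdrcov_undefined_test_error")
  if (n < 2L) stop_sdr("need n >= 2 sequences for the chi-square approximation")
  stat <- 2 * log(2) * n * MI
  df <- (card_msa - 1) * (card_pwm - 1)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Permutation test p-value for a site pair
#'
#' Null distribution of MI obtained by shuffling the residues of MSA site
#' `j` across rows while the PWMs and the weight-to-row association stay
#' fixed — the minimal null that breaks the pairing between `A_j` and `W_k`.
#' `p = (1 + #\{MI* >= MI_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams joint_distribution
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @param base Log base for MI (cancels in the comparison; kept for
#'   reporting consistency).
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(alignment, profiles, weights, j, k,
                               n_perm = 999L, seed = 1L, base = 20) {
  if (n_perm < 1L) stop_sdr("n_perm must be >= 1")
  w <- as.numeric(weights) / sum(weights)
  pwm_cols <- vapply(profiles$pwms, function(m) m[, k], numeric(20L))  # 20 x n
  H_pwm <- entropy(as.numeric(pwm_cols %*% w), base)
  mi_of <- function(col) {
    jd <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
    for (i in seq_along(w)) {
      if (w[i] == 0) next
      jd[col[i], ] <- jd[col[i], ] + w[i] * pwm_cols[, i]
    }
    px <- rowSums(jd)
    mutual_information(entropy(px, base), H_pwm, entropy(as.numeric(jd), base))
  }
  col <- alignment[, j]
  if (any(col == GAP))
    stop_sdr("site %d contains gaps; gapped sites must be excluded via filter_sites()",
             j, class = "sdrcov_gap_error")
  mi_obs <- mi_of(col)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    mi_b <- mi_of(sample(col))
    if (mi_b >= mi_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Site filter: gaps and over-conservation
#'
#' Flags each MSA site that (a) contains a gap in any row (`has_gap`) or
#' (b) is too conserved: the most frequent residue occupies more than half
#' of the total sequence weight (`too_conserved`).  The boundary is
#' inclusive — a majority fraction of exactly 0.5 is kept.  Only sites with
#' an empty reason set enter the covariation map.
#'
#' @param alignment A [domain_alignment].
#' @param weights A [sequence_weights] vector.
#' @return A `filter_report` data frame with columns `site`, `kept`,
#'   `has_gap`, `too_conserved`, `majority_fraction`.
#' @export
filter_sites <- function(alignment, weights = uniform_weights(nrow(alignment))) {
  w <- as.numeric(weights) / sum(weights)
  rep <- lapply(seq_len(ncol(alignment)), function(j) {
    col <- alignment[, j]
    has_gap <- any(col == GAP)
    frac <- max(vapply(unique(col[col != GAP]),
                       function(a) sum(w[col == a]), numeric(1)), 0)
    too_cons <- frac > 0.5 + 1e-12
    data.frame(site = j, kept = !has_gap && !too_cons, has_gap = has_gap,
               too_conserved = too_cons, majority_fraction = frac)
  })
  out <- do.call(rbind, rep)
  class(out) <- c("filter_report", "data.frame")
  out
}

#' Covariation map between MSA sites and PWM sites
#'
#' The core computation: for every MSA site that passes [filter_sites()] and
#' every PWM site, computes the sequence-weighted site entropies, joint
#' entropy, mutual information and uncertainty coefficient, with optional
#' chi-square and permutation p-values.
#'
#' @param alignment A [domain_alignment].
#' @param profiles A [profile_set] with ids matching the alignment.
#' @param weights A [sequence_weights] vector; default uniform.
#' @param base Log base for all entropies (default 20, so entropies lie in
#'   `[0, 1]`).
#' @param uc_variant Uncertainty-coefficient normalisation; see
#'   [uncertainty_coefficient()].
#' @param tests Character subset of `c("chi2", "perm")`.
#' @param n_perm,seed Permutation-test controls (used when "perm" is in
#'   `tests`).
#' @param apply_filter Set `FALSE` to score all gap-free sites regardless of
#'   conservation (gapped sites are always excluded).
#' @return A `covariation_map` data frame with one row per scored (j, k)
#'   pair and columns `j`, `k`, `site_label`, `H_msa`, `H_pwm`, `H_joint`,
#'   `MI`, `UC`, `card_msa`, `card_pwm` (+ `p_chi2`, `p_perm` on request),
#'   ordered by (j, k).  The filter report, base and UC variant are attached
#'   as attributes `filter`, `base`, `uc_variant`.
#' @export
covariation_map <- function(alignment, profiles,
                            weights = uniform_weights(nrow(alignment)),
                            base = 20,
                            uc_variant = c("symmetric", "msa", "pwm"),
                            tests = character(), n_perm = 999L, seed = 1L,
                            apply_filter = TRUE) {
  uc_variant <- match.arg(uc_variant)
  if (!identical(rownames(alignment), profiles$ids))
    stop_sdr("alignment ids and profile ids differ or are out of order")
  if (length(tests))
    tests <- match.arg(tests, c("chi2", "perm"), several.ok = TRUE)
  fr <- filter_sites(alignment, weights)
  keep <- if (apply_filter) fr$site[fr$kept] else fr$site[!fr$has_gap]
  w <- as.numeric(weights) / sum(weights)
  n <- nrow(alignment)

  rows <- list()
  for (j in keep) {
    px <- msa_site_distribution(alignment, weights, j)
    Hx <- entropy(px, base)
    for (k in seq_len(profiles$w)) {
      jd <- joint_distribution(alignment, profiles, weights, j, k)
      py <- colSums(jd)
      Hy <- entropy(py, base)
      Hxy <- entropy(as.numeric(jd), base)
      mi <- mutual_information(Hx, Hy, Hxy)
      uc <- uncertainty_coefficient(mi, Hx, Hy, uc_variant)
      row <- data.frame(j = j, k = k, site_label = profiles$site_labels[k],
                        H_msa = Hx, H_pwm = Hy, H_joint = Hxy, MI = mi, UC = uc,
                        card_msa = sum(px > 0), card_pwm = sum(py > 0))
      if ("chi2" %in% tests)
        row$p_chi2 <- chi2_pvalue(mi * log(base) / log(2), n,
                                  row$card_msa, row$card_pwm)
      if ("perm" %in% tests)
        row$p_perm <- permutation_pvalue(alignment, profiles, weights, j, k,
                                         n_perm = n_perm,
                                         seed = seed + 131L * j + k, base = base)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c("j", "k", "site_label", "H_msa", "H_pwm", "H_joint", "MI", "UC",
              "card_msa", "card_pwm")
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  out <- out[order(out$j, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter") <- fr
  attr(out, "base") <- base
  attr(out, "uc_variant") <- uc_variant
  class(out) <- c("covariation_map", "data.frame")
  out
}

#' Rank site pairs by covariation score
#'
#' Sorts the scored pairs by the chosen score, descending, ties broken by
#' (j, k) ascending.  With `per_msa_site_best = TRUE` only the top-scoring
#' PWM site for each MSA site is retained before sorting (ties to the
#' smaller k) — the reduction used when comparing scores against structural
#' distances, since low-scoring pairs are noise-dominated.
#'
#' @param map A `covariation_map`.
#' @param score Column to rank by, "UC" (default) or "MI".
#' @param per_msa_site_best Keep only each MSA site's best PWM site first.
#' @return The map rows, reordered (and possibly reduced).
#' @export
rank_pairs <- function(map, score = c("UC", "MI"), per_msa_site_best = FALSE) {
  score <- match.arg(score)
  df <- as.data.frame(map)
  if (!nrow(df)) return(df)
  if (per_msa_site_best) {
    df <- do.call(rbind, lapply(split(df, df$j), function(g) {
      g[order(-g[[score]], g$k), ][1L, , drop = FALSE]
    }))
  }
  df <- df[order(-df[[score]], df$j, df$k), , drop = FALSE]
  rownames(df) <- NULL
  df
}
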