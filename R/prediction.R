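#' Fraction of identical aligned positions
#'
#' The number of alignment columns at which both rows carry the same
#' non-gap residue, divided by the full alignment length (gapped columns
#' therefore count as mismatches).
#'
#' @param seq_a,seq_b Aligned rows: character vectors of single residues or
#'   single strings of equal length.
#' @return Identity in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (length(seq_a) == 1L && nchar(seq_a) > 1L) seq_a <- strsplit(seq_a, "")[[1L]]
  if (length(seq_b) == 1L && nchar(seq_b) > 1L) seq_b <- strsplit(seq_b, "")[[1L]]
  if (length(seq_a) != length(seq_b))
    stop_sdr("aligned rows differ in length (%d vs %d)", length(seq_a), length(seq_b))
  sum(seq_a == seq_b & seq_a != GAP) / length(seq_a)
}

.as_query_row <- function(query, m) {
  if (is.character(query) && length(query) == 1L && nchar(query) > 1L)
    query <- strsplit(toupper(query), "")[[1L]]
  query[query == "."] <- GAP
  if (length(query) != m)
    stop_sdr("query must be aligned to the same %d columns (got %d)", m, length(query))
  query
}

#' Predict a binding profile by similarity-weighted averaging
#'
#' Predicts the bound-peptide PWM of a new domain as the average of the
#' known PWMs weighted by whole-sequence identity to the query:
#' `p_hat_k(y) = sum_i s(q, i) W_ik(y) / sum_i s(q, i)`.  If the query
#' shares no residue with any training row the weights fall back to
#' uniform (`1/n`).
#'
#' @param alignment Training [domain_alignment] (n rows).
#' @param profiles Training [profile_set], row-aligned to `alignment`.
#' @param query Aligned query sequence (string or residue vector, same
#'   number of columns as the alignment).
#' @return A `predicted_profile`: a 20 x w matrix with attribute
#'   `method = "uniform_similarity"`.
#' @export
predict_pwm_uniform <- function(alignment, profiles, query) {
  if (nrow(alignment) < 1L) stop_sdr("no training rows")
  query <- .as_query_row(query, ncol(alignment))
  s <- vapply(seq_len(nrow(alignment)),
              function(i) sequence_identity(query, alignment[i, ]), numeric(1))
  if (sum(s) == 0) s <- rep(1 / nrow(alignment), nrow(alignment))
  s <- s / sum(s)
  pred <- Reduce(`+`, Map(function(m, wi) m * wi, profiles$pwms, s))
  pred <- sweep(pred, 2L, colSums(pred), "/")
  structure(pred, method = "uniform_similarity", class = c("predicted_profile", "matrix"))
}

#' Predict a binding profile with covariation-derived site weights
#'
#' As [predict_pwm_uniform()], but for each target PWM site `k` the
#' sequence similarity is recomputed with alignment sites weighted by their
#' uncertainty coefficient with `k`:
#' `s_k(q, i) = sum_j UC(A_j, W_k) [q_j == A_ij] / sum_j UC(A_j, W_k)`.
#' Sites removed by the filter contribute a weight of 0.  If every UC
#' weight for some `k` is zero, that site falls back to the uniform
#' similarity of [predict_pwm_uniform()].
#'
#' @inheritParams predict_pwm_uniform
#' @param cov_map A `covariation_map` computed from the training rows only.
#' @return A `predicted_profile` with attribute
#'   `method = "covariation_weighted"` and attribute `fallback_sites`
#'   listing target sites that used the uniform fallback.
#' @export
predict_pwm_covariation <- function(alignment, profiles, query, cov_map) {
  if (nrow(alignment) < 1L) stop_sdr("no training rows")
  query <- .as_query_row(query, ncol(alignment))
  n <- nrow(alignment)
  m <- ncol(alignment)
  w <- profiles$w
  uc <- matrix(0, m, w)
  cm <- as.data.frame(cov_map)
  if (nrow(cm)) uc[cbind(cm$j, cm$k)] <- cm$UC
  match_mat <- t(unclass(alignment)) == query & query != GAP   # m x n logical
  uni <- NULL
  pred <- matrix(0, 20L, w, dimnames = list(AA20, profiles$site_labels))
  fallback <- integer()
  for (k in seq_len(w)) {
    uck <- uc[, k]
    if (sum(uck) <= 0) {
      if (is.null(uni)) uni <- predict_pwm_uniform(alignment, profiles, query)
      pred[, k] <- uni[, k]
      fallback <- c(fallback, k)
      next
    }
    sk <- as.numeric(uck %*% match_mat) / sum(uck)             # length n
    if (sum(sk) == 0) {
      if (is.null(uni)) uni <- predict_pwm_uniform(alignment, profiles, query)
      pred[, k] <- uni[, k]
      fallback <- c(fallback, k)
      next
    }
    sk <- sk / sum(sk)
    col <- numeric(20L)
    for (i in seq_len(n)) if (sk[i] > 0) col <- col + sk[i] * profiles$pwms[[i]][, k]
    pred[, k] <- col / sum(col)
  }
  structure(pred, method = "covariation_weighted", fallback_sites = fallback,
            class = c("predicted_profile", "matrix"))
}

#' Regression-tree profile prediction (hook)
#'
#' Named hook for a per-probability regression-tree baseline.  Not
#' implemented: the method is defined here only so pipelines can name it.
#'
#' @param ... Ignored.
#' @export
predict_pwm_regression_tree <- function(...) {
  stop_sdr("regression-tree prediction is a named hook and is not implemented",
           class = "sdrcov_not_implemented_error")
}

#' Root-mean-square error between two profiles
#'
#' `sqrt( (1 / (20 w)) * sum_k sum_y (p_hat_k(y) - p_k(y))^2 )`: the
#' root-mean-square difference between the predicted and actual per-site
#' residue distributions, averaged over all 20 residues and all w sites.
#'
#' @param predicted,actual 20 x w profile matrices (or `predicted_profile`s)
#'   of identical shape.
#' @return RMSE >= 0 (at most `sqrt(0.1)`, attained by disjoint
#'   single-residue profiles at every site).
#' @export
prediction_error <- function(predicted, actual) {
  p <- unclass(as.matrix(predicted)); a <- unclass(as.matrix(actual))
  if (!all(dim(p) == dim(a)))
    stop_sdr("profile shape mismatch: %s vs %s",
             paste(dim(p), collapse = "x"), paste(dim(a), collapse = "x"))
  sqrt(sum((p - a)^2) / length(p))
}

#' Drop near-identical sequences
#'
#' Greedy scan in input order: a row is dropped when its identity to any
#' already-kept row reaches the threshold; its PWM is dropped in tandem.
#' Used before left-out validation so near-duplicates cannot straddle the
#' training/testing split.
#'
#' @param alignment A [domain_alignment].
#' @param profiles The matched [profile_set].
#' @param threshold Identity threshold in `(0, 1]`; default 0.9.
#' @return List with the reduced `alignment`, `profiles`, and the kept row
#'   indices `kept`.
#' @export
remove_redundant <- function(alignment, profiles, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop_sdr("threshold must be in (0, 1]")
  kept <- integer()
  for (i in seq_len(nrow(alignment))) {
    dup <- any(vapply(kept, function(h)
      sequence_identity(alignment[i, ], alignment[h, ]) >= threshold, logical(1)))
    if (!dup) kept <- c(kept, i)
  }
  list(alignment = domain_alignment(unclass(alignment)[kept, , drop = FALSE],
                                    ids = rownames(alignment)[kept]),
       profiles = profile_set(profiles$pwms[kept], profiles$ids[kept],
                              site_labels = profiles$site_labels),
       kept = kept)
}

#' Left-out validation of profile prediction
#'
#' Repeatedly splits the domains into training and testing sets.  Within
#' each split the covariation map and all similarity weights are computed
#' from the training rows only; each test sequence in turn plays the role
#' of the new domain, its profile is predicted by every requested method,
#' and the prediction error against its true PWM is recorded.
#'
#' @param alignment A [domain_alignment] (apply [remove_redundant()] first
#'   for datasets with near-duplicates).
#' @param profiles The matched [profile_set].
#' @param leftout_fraction Fraction of rows held out per repeat, in (0, 1);
#'   at least one row is held out and at least two remain for training.
#' @param repeats Number of random splits (>= 1).
#' @param methods Subset of `c("uniform_similarity", "covariation_weighted")`.
#' @param seed Top-level seed; each repeat draws its split from a derived
#'   substream, so results are reproducible and repeats independent.
#' @param base,uc_variant Passed to [covariation_map()].
#' @return A `validation_summary` list: `summary` data frame (per method:
#'   mean error, sd over repeats), `per_repeat` data frame, plus the
#'   configuration fields.
#' @export
leave_out_validation <- function(alignment, profiles, leftout_fraction = 0.2,
                                 repeats = 100L,
                                 methods = c("uniform_similarity",
                                             "covariation_weighted"),
                                 seed = 1L, base = 20,
                                 uc_variant = "symmetric") {
  methods <- match.arg(methods, c("uniform_similarity", "covariation_weighted"),
                       several.ok = TRUE)
  n <- nrow(alignment)
  if (n < 3L) stop_sdr("need at least 3 sequences after redundancy removal")
  n_test <- max(1L, round(leftout_fraction * n))
  if (n - n_test < 2L)
    stop_sdr("leftout fraction %.2f leaves fewer than 2 training rows", leftout_fraction)
  if (repeats < 1L) stop_sdr("repeats must be >= 1")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, repeats)
  per_rep <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    test_idx <- sort(sample.int(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)
    tr_aln <- domain_alignment(unclass(alignment)[train_idx, , drop = FALSE],
                               ids = rownames(alignment)[train_idx])
    tr_prof <- profile_set(profiles$pwms[train_idx], profiles$ids[train_idx],
                           site_labels = profiles$site_labels)
    cm <- if ("covariation_weighted" %in% methods)
      covariation_map(tr_aln, tr_prof, base = base, uc_variant = uc_variant)
    else NULL
    errs <- sapply(methods, function(meth) {
      mean(vapply(test_idx, function(t) {
        q <- alignment[t, ]
        pred <- switch(meth,
                       uniform_similarity = predict_pwm_uniform(tr_aln, tr_prof, q),
                       covariation_weighted = predict_pwm_covariation(tr_aln, tr_prof, q, cm))
        prediction_error(pred, profiles$pwms[[t]])
      }, numeric(1)))
    })
    per_rep[[r]] <- data.frame(repeat_id = r, method = methods,
                               mean_error = as.numeric(errs))
  }
  per_rep <- do.call(rbind, per_rep)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$method), function(g)
    data.frame(method = g$method[1L], mean_error = mean(g$mean_error),
               sd_error = stats::sd(g$mean_error))))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_repeat = per_rep, repeats = repeats,
                 leftout_fraction = leftout_fraction, n_test = n_test,
                 seed = seed),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("left-out validation: %d repeats, %.0f%% left out (%d of each split)\n",
              x$repeats, 100 * x$leftout_fraction, x$n_test))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
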