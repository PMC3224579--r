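test_that("entropy obeys its limits and the worked four-sequence example", {
  delta <- as.numeric(AA20 == "V")
  expect_equal(entropy(delta, 20), 0)
  expect_equal(entropy(delta, 2), 0)
  expect_equal(entropy(rep(1 / 20, 20), 20), 1, tolerance = 1e-12)
  aln <- toy_alignment()
  w <- uniform_weights(aln)
  expect_equal(entropy(msa_site_distribution(aln, w, 4L), 2), 1.5,
               tolerance = 1e-12)
  expect_error(entropy(delta, 1), class = "sdrcov_parameter_error")
  expect_error(entropy(delta, 0.5), class = "sdrcov_parameter_error")
})

test_that("site distributions follow the weighted-frequency definitions", {
  aln <- toy_alignment()
  w <- uniform_weights(aln)
  p1 <- msa_site_distribution(aln, w, 1L)
  expect_equal(p1[["A"]], 0.5)
  expect_equal(p1[["T"]], 0.5)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  p3 <- msa_site_distribution(aln, w, 3L)
  expect_equal(unname(p3[c("A", "C", "D", "E")]), rep(0.25, 4))

  # zero-weight rows vanish
  w2 <- sequence_weights(c(1, 0, 0, 0))
  expect_equal(msa_site_distribution(aln, w2, 1L)[["A"]], 1)

  # gapped site refuses to be summarised
  g <- domain_alignment(c("A-", "AA"), ids = c("a", "b"))
  expect_error(msa_site_distribution(g, uniform_weights(2L), 2L),
               class = "sdrcov_gap_error")

  # PWM site distribution: weighted mean of PWM columns
  ps <- delta_profiles(c("V", "Y"), ids = c("a", "b"))
  pu <- pwm_site_distribution(ps, uniform_weights(2L), 1L)
  expect_equal(pu[["V"]], 0.5); expect_equal(pu[["Y"]], 0.5)
  pw <- pwm_site_distribution(ps, sequence_weights(c(0.75, 0.25)), 1L)
  expect_equal(pw[["V"]], 0.75); expect_equal(pw[["Y"]], 0.25)
  # identical PWMs -> shared column regardless of weights
  same <- profile_set(rep(list(matrix(rep(1 / 20, 20), 20,
                                      dimnames = list(AA20, NULL))), 2),
                      c("a", "b"))
  expect_equal(unname(pwm_site_distribution(same, uniform_weights(2L), 1L)),
               rep(1 / 20, 20))
})

test_that("joint distribution reproduces both marginals and independence", {
  aln <- toy_alignment()
  w <- uniform_weights(aln)
  ps2 <- delta_profiles(aln[, 2L], ids = rownames(aln))
  jd <- joint_distribution(aln, ps2, w, 1L, 1L)
  expect_equal(jd["A", "V"], 0.5)
  expect_equal(jd["T", "Y"], 0.5)
  expect_equal(sum(jd), 1, tolerance = 1e-9)
  expect_equal(rowSums(jd), msa_site_distribution(aln, w, 1L), tolerance = 1e-9)
  expect_equal(colSums(jd), pwm_site_distribution(ps2, w, 1L), tolerance = 1e-9)

  # identical PWMs for all sequences -> joint is the outer product
  shared <- matrix(stats::rgamma(20, 1), 20, dimnames = list(AA20, NULL))
  shared <- shared / sum(shared)
  ind <- profile_set(rep(list(shared), 4L), rownames(aln))
  jd_ind <- joint_distribution(aln, ind, w, 1L, 1L)
  expect_equal(jd_ind,
               outer(msa_site_distribution(aln, w, 1L), shared[, 1L]),
               tolerance = 1e-12, ignore_attr = TRUE)
  mi <- mutual_information(entropy(rowSums(jd_ind), 20),
                           entropy(colSums(jd_ind), 20),
                           entropy(as.numeric(jd_ind), 20))
  expect_equal(mi, 0, tolerance = 1e-9)
})

test_that("MI and UC reproduce the worked example, including the rank reversal", {
  aln <- toy_alignment()
  w <- uniform_weights(aln)
  mi_of <- function(j, col, base = 2) {
    ps <- delta_profiles(aln[, col], ids = rownames(aln))
    jd <- joint_distribution(aln, ps, w, j, 1L)
    c(Hx = entropy(rowSums(jd), base), Hy = entropy(colSums(jd), base),
      MI = mutual_information(entropy(rowSums(jd), base),
                              entropy(colSums(jd), base),
                              entropy(as.numeric(jd), base)))
  }
  v12 <- mi_of(1L, 2L)
  v34 <- mi_of(3L, 4L)
  expect_equal(unname(v12), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(v34), c(2, 1.5, 1.5), tolerance = 1e-12)
  # raw MI ranks the unrelated diverse pair higher ...
  expect_gt(v34[["MI"]], v12[["MI"]])
  # ... the uncertainty coefficient reverses that
  uc12 <- uncertainty_coefficient(v12[["MI"]], v12[["Hx"]], v12[["Hy"]])
  uc34 <- uncertainty_coefficient(v34[["MI"]], v34[["Hx"]], v34[["Hy"]])
  expect_equal(uc12, 1, tolerance = 1e-12)
  expect_equal(uc34, 2 * 1.5 / 3.5, tolerance = 1e-12)
  expect_lt(uc34, uc12)

  expect_equal(uncertainty_coefficient(0, 1, 1, "symmetric"), 0)
  expect_equal(uncertainty_coefficient(0, 1, 1, "msa"), 0)
  expect_equal(uncertainty_coefficient(0, 0, 0), 0)      # degenerate denominator
  expect_equal(uncertainty_coefficient(1, 2, 1.5, "msa"), 0.5)
  expect_equal(uncertainty_coefficient(1, 2, 1.5, "pwm"), 1 / 1.5)
})

test_that("MI equals the 400-term brute-force oracle on random small instances", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(2:6, 1L)
    m <- sample(2:5, 1L)
    aln <- domain_alignment(
      vapply(seq_len(n), function(i)
        paste(sample(AA20[1:6], m, replace = TRUE), collapse = ""), character(1)),
      ids = paste0("s", seq_len(n)))
    wts <- sequence_weights(stats::runif(n) + 0.05)
    delta <- rep < 31                       # half delta, half dense PWMs
    prof <- if (delta) delta_profiles(sample(AA20, n, replace = TRUE),
                                      ids = rownames(aln))
            else random_profiles(n, 1L, seed = rep)
    if (!delta) prof$ids <- rownames(aln)
    j <- sample.int(m, 1L)
    jd <- joint_distribution(aln, prof, wts, j, 1L)
    Hx <- entropy(rowSums(jd), 20); Hy <- entropy(colSums(jd), 20)
    mi <- mutual_information(Hx, Hy, entropy(as.numeric(jd), 20))
    # oracle route: joint built independently, MI by direct summation
    jd_o <- joint_oracle(aln, prof, wts, j, 1L)
    expect_lt(max(abs(jd - jd_o)), 1e-14)
    expect_equal(mi, mi_brute_force(jd_o, 20), tolerance = 1e-12)
    # information inequality
    expect_gte(mi, 0)
    expect_lte(mi, min(Hx, Hy) + 1e-9)
  }
})

test_that("MI rescales exactly under change of log base and UC does not", {
  aln <- toy_alignment()
  w <- uniform_weights(aln)
  ps <- delta_profiles(aln[, 4L], ids = rownames(aln))
  val <- function(base) {
    jd <- joint_distribution(aln, ps, w, 3L, 1L)
    Hx <- entropy(rowSums(jd), base); Hy <- entropy(colSums(jd), base)
    mi <- mutual_information(Hx, Hy, entropy(as.numeric(jd), base))
    c(mi = mi, uc = uncertainty_coefficient(mi, Hx, Hy))
  }
  v2 <- val(2); v20 <- val(20)
  expect_equal(v20[["mi"]] * log(20) / log(2), v2[["mi"]], tolerance = 1e-9)
  expect_equal(v20[["uc"]], v2[["uc"]], tolerance = 1e-9)   # UC is scale-free
})

test_that("chi-square p-values match the survival function and behave monotonely", {
  expect_equal(chi2_pvalue(0, 10L, 4L, 4L), 1)
  expect_lt(chi2_pvalue(1.5, 100L, 2L, 2L), 1e-6)
  # cross-check against an explicit evaluation of the approximation
  mi <- 0.21; n <- 37L
  expect_equal(chi2_pvalue(mi, n, 5L, 3L),
               stats::pchisq(2 * log(2) * n * mi, df = (5 - 1) * (3 - 1),
                             lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(chi2_pvalue(0.5, 10L, 1L, 4L), class = "sdrcov_undefined_test_error")
})

test_that("permutation test is deterministic, exact on constant sites, and powered", {
  aln <- toy_alignment()
  w <- uniform_weights(aln)
  const <- domain_alignment(c("AA", "AA", "AA", "AT"), ids = rownames(aln))
  ps <- delta_profiles(c("V", "V", "Y", "Y"), ids = rownames(aln))
  expect_equal(permutation_pvalue(const, ps, w, 1L, 1L, n_perm = 50L, seed = 3L), 1)

  p1 <- permutation_pvalue(aln, ps, w, 1L, 1L, n_perm = 99L, seed = 5L)
  p2 <- permutation_pvalue(aln, ps, w, 1L, 1L, n_perm = 99L, seed = 5L)
  expect_identical(p1, p2)

  # planted perfect covariation: p at the resolution floor
  sim <- generate(generator_spec(20L, 6L, 2L,
                                 planted_pairs = list(list(j = 2L, k = 1L,
                                                           coupling = 1)),
                                 pwm_sharpness = Inf, pwm_noise = 0, seed = 9L))
  p <- permutation_pvalue(sim$alignment, sim$profiles, uniform_weights(20L),
                          2L, 1L, n_perm = 999L, seed = 11L)
  expect_lte(p, 0.01)
})

test_that("site filter applies the gap rule and the inclusive half-weight rule", {
  w4 <- uniform_weights(4L)
  aln <- domain_alignment(c("AAA", "AAA", "TA-", "TTT"),
                          ids = paste0("s", 1:4))
  fr <- filter_sites(aln, w4)
  expect_true(fr$kept[1L])                       # A,A,T,T: fraction exactly 0.5
  expect_equal(fr$majority_fraction[1L], 0.5)
  expect_false(fr$kept[2L])                      # A,A,A,T: 0.75 > 0.5
  expect_true(fr$too_conserved[2L])
  expect_false(fr$kept[3L])                      # gap
  expect_true(fr$has_gap[3L])
  expect_identical(fr$kept, !(fr$has_gap | fr$too_conserved))

  # adding a gap can only remove a site from the kept set
  aln2 <- domain_alignment(c("AAA", "A-A", "TA-", "TTT"), ids = paste0("s", 1:4))
  fr2 <- filter_sites(aln2, w4)
  expect_true(all(fr2$kept <= fr$kept))
})

test_that("covariation_map composes the pieces, honours the filter and ranks", {
  aln <- toy_alignment()
  ps <- delta_profiles_multi(unclass(aln)[, 3:4], ids = rownames(aln))
  # score the 2-site MSA (columns 1-2) against the 2-site delta PWMs (3-4)
  msa12 <- domain_alignment(apply(unclass(aln)[, 1:2], 1L, paste, collapse = ""),
                            ids = rownames(aln))
  cm <- covariation_map(msa12, ps, base = 2)
  expect_s3_class(cm, "covariation_map")
  expect_equal(nrow(cm), 4L)                     # 2 kept sites x 2 PWM sites
  expect_equal(cm$MI[cm$j == 1L & cm$k == 2L],
               cm$MI[cm$j == 2L & cm$k == 2L])   # sites 1 and 2 are equivalent
  # every stored row satisfies the MI identity
  expect_lt(max(abs(cm$MI - (cm$H_msa + cm$H_pwm - cm$H_joint))), 1e-9)
  expect_true(all(cm$MI >= -1e-9))
  expect_true(all(cm$UC >= 0 & cm$UC <= 1 + 1e-9))

  # all-conserved alignment -> empty map, full filter report
  cons <- domain_alignment(c("AAA", "AAA", "AAA"), ids = paste0("s", 1:3))
  ps3 <- delta_profiles(c("V", "V", "V"), ids = paste0("s", 1:3))
  cm0 <- covariation_map(cons, ps3)
  expect_equal(nrow(cm0), 0L)
  expect_equal(nrow(attr(cm0, "filter")), 3L)
  expect_false(any(attr(cm0, "filter")$kept))

  # id mismatch is an error
  ps_bad <- delta_profiles(c("V", "V"), ids = c("x", "y"))
  expect_error(covariation_map(domain_alignment(c("AT", "TA"), ids = c("a", "b")),
                               ps_bad), "ids")

  # ranking: descending score, ties to (j, k) ascending
  rp <- rank_pairs(cm, score = "MI")
  expect_true(all(diff(rp$MI) <= 1e-12))
  ties <- rp[abs(rp$MI - rp$MI[1L]) < 1e-12, ]
  expect_equal(ties$j, sort(ties$j))
  best <- rank_pairs(cm, per_msa_site_best = TRUE)
  expect_equal(nrow(best), length(unique(cm$j)))
})

test_that("duplicating a sequence while halving its weight changes nothing", {
  sim <- generate(generator_spec(8L, 5L, 2L,
                                 planted_pairs = list(list(j = 2L, k = 1L,
                                                           coupling = 0.9)),
                                 seed = 21L))
  aln <- sim$alignment; prof <- sim$profiles
  n <- nrow(aln)
  w0 <- uniform_weights(n)
  cm0 <- covariation_map(aln, prof, w0)

  dup_aln <- domain_alignment(rbind(unclass(aln), unclass(aln)[1L, , drop = FALSE]),
                              ids = c(rownames(aln), "dup1"))
  dup_prof <- profile_set(c(prof$pwms, prof$pwms[1L]), c(prof$ids, "dup1"),
                          site_labels = prof$site_labels)
  wd <- as.numeric(w0); wd[1L] <- wd[1L] / 2; wd <- c(wd, wd[1L])
  cm1 <- covariation_map(dup_aln, dup_prof, sequence_weights(wd))
  for (col in c("H_msa", "H_pwm", "H_joint", "MI", "UC"))
    expect_equal(cm1[[col]], cm0[[col]], tolerance = 1e-9)
})
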