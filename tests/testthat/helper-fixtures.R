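# Shared fixtures: the four-sequence illustrative alignment (two covarying
# sites A/T <-> V/Y and two diverse unrelated sites) and small PWM builders.

toy_alignment <- function() {
  domain_alignment(c("AVAC", "AVCD", "TYDE", "TYEC"),
                   ids = c("I", "II", "III", "IV"))
}

# Wrap a residue vector as per-sequence single-site delta PWMs.
delta_profiles <- function(residues, ids = names(residues)) {
  if (is.null(ids)) ids <- paste0("s", seq_along(residues))
  pwms <- lapply(residues, function(a)
    matrix(as.numeric(AA20 == a), 20L, 1L, dimnames = list(AA20, NULL)))
  profile_set(pwms, ids)
}

# Delta PWMs over several sites: residues is an n x w character matrix.
delta_profiles_multi <- function(residues, ids = rownames(residues)) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(residues)))
  pwms <- lapply(seq_len(nrow(residues)), function(i) {
    m <- vapply(residues[i, ], function(a) as.numeric(AA20 == a), numeric(20L))
    rownames(m) <- AA20
    m
  })
  profile_set(pwms, ids)
}

random_profiles <- function(n, w, seed = 1L) {
  set.seed(seed)
  pwms <- replicate(n, {
    m <- matrix(stats::rgamma(20 * w, 1), 20L, w, dimnames = list(AA20, NULL))
    sweep(m, 2L, colSums(m), "/")
  }, simplify = FALSE)
  profile_set(pwms, paste0("s", seq_len(n)))
}

# Independent MI oracle: direct summation over all 400 residue pairs of
# p(x,y) log( p(x,y) / (p(x) p(y)) ), never via entropies.
mi_brute_force <- function(joint, base) {
  px <- rowSums(joint); py <- colSums(joint)
  tot <- 0
  for (x in 1:20) for (y in 1:20) {
    p <- joint[x, y]
    if (p > 0) tot <- tot + p * log(p / (px[[x]] * py[[y]]), base = base)
  }
  unname(tot)
}

# Build the weighted joint distribution from first principles (independent
# of joint_distribution()): explicit loop over sequences.
joint_oracle <- function(aln, prof, weights, j, k) {
  w <- as.numeric(weights) / sum(as.numeric(weights))
  jd <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  for (i in seq_len(nrow(aln))) {
    x <- match(aln[i, j], AA20)
    for (y in 1:20) jd[x, y] <- jd[x, y] + w[i] * prof$pwms[[i]][y, k]
  }
  jd
}
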