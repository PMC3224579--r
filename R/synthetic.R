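#' Specification for the synthetic covariation generator
#'
#' Describes a synthetic dataset of n aligned domain sequences and n aligned
#' binding PWMs in which chosen (MSA site, PWM site) pairs covary with
#' controllable strength, emulating the evolutionary signature where a
#' change of residue at a domain site is compensated by a coordinated change
#' in the bound-peptide preference.
#'
#' @param n_sequences Number of sequences (>= 2).
#' @param m_sites Number of MSA columns.
#' @param w_sites Number of PWM sites.
#' @param planted_pairs List of planted pairs; each element a list with
#'   `j` (MSA site), `k` (PWM site), `coupling` in `[0, 1]` and optional
#'   `states` (number of coordinated residue states, default 2).
#' @param background_conservation Probability, per non-planted MSA site,
#'   that a sequence carries the site's consensus residue (the rest is
#'   uniform over the alphabet).  Default 0.2, the diversity typical of the
#'   filtered sites of a divergent domain family.
#' @param pwm_sharpness Concentration of the state-keyed PWM columns:
#'   the keyed column is `(sharpness * delta + uniform/20) / (sharpness + 1)`,
#'   so 0 is uninformative and `Inf` gives delta columns.  Default 8,
#'   a strongly peaked but non-degenerate phage-display-like profile.
#' @param pwm_noise Per-sequence estimation noise: each sequence's column is
#'   mixed with an independent random column with this weight, emulating the
#'   finite-sample noise of assay-derived PWMs.  Without it every PWM column
#'   would be exactly shared and the no-coupling null would be degenerate
#'   (all MI exactly 0).  Default 0.05.  Set 0 (with `pwm_sharpness = Inf`)
#'   for exact delta profiles.
#' @param background_freqs Optional length-20 composition for background
#'   draws; default uniform.
#' @param duplicate Optional named integer vector: extra copies to append
#'   for the given 1-based sequence indices (crowded-clade emulation).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_sequences, m_sites, w_sites,
                           planted_pairs = list(),
                           background_conservation = 0.2,
                           pwm_sharpness = 8,
                           pwm_noise = 0.05,
                           background_freqs = NULL,
                           duplicate = NULL,
                           seed = 1L) {
  if (n_sequences < 2L) stop_sdr("need n_sequences >= 2", class = "sdrcov_spec_error")
  for (pp in planted_pairs) {
    if (pp$j < 1L || pp$j > m_sites || pp$k < 1L || pp$k > w_sites)
      stop_sdr("planted pair (%d, %d) out of bounds", pp$j, pp$k,
               class = "sdrcov_spec_error")
    if (pp$coupling < 0 || pp$coupling > 1)
      stop_sdr("coupling must be in [0, 1]", class = "sdrcov_spec_error")
  }
  if (background_conservation < 0 || background_conservation >= 1)
    stop_sdr("background_conservation must be in [0, 1)", class = "sdrcov_spec_error")
  if (pwm_sharpness < 0) stop_sdr("pwm_sharpness must be >= 0", class = "sdrcov_spec_error")
  if (pwm_noise < 0 || pwm_noise > 1)
    stop_sdr("pwm_noise must be in [0, 1]", class = "sdrcov_spec_error")
  if (is.null(background_freqs)) background_freqs <- rep(1 / 20, 20L)
  if (length(background_freqs) != 20L || any(background_freqs < 0))
    stop_sdr("background_freqs must be 20 non-negative values", class = "sdrcov_spec_error")
  structure(list(n_sequences = as.integer(n_sequences),
                 m_sites = as.integer(m_sites), w_sites = as.integer(w_sites),
                 planted_pairs = planted_pairs,
                 background_conservation = background_conservation,
                 pwm_sharpness = pwm_sharpness,
                 pwm_noise = pwm_noise,
                 background_freqs = background_freqs / sum(background_freqs),
                 duplicate = duplicate, seed = as.integer(seed)),
            class = "generator_spec")
}

.keyed_column <- function(target, sharpness) {
  delta <- as.numeric(AA20 == target)
  if (is.infinite(sharpness)) return(delta)
  (sharpness * delta + rep(1 / 20, 20L)) / (sharpness + 1)
}

#' Generate a synthetic alignment + profile set with planted covariation
#'
#' For each planted pair, every sequence is assigned one of `states`
#' hidden states; its residue at MSA site `j` is the state's residue, and
#' its PWM column `k` is the mixture
#' `coupling * keyed(state) + (1 - coupling) * background`, where the keyed
#' column concentrates (by `pwm_sharpness`) on the state's partner residue
#' and the background column is shared by all sequences.  Non-planted MSA
#' sites draw residues independently around a per-site consensus; non-planted
#' PWM sites get a shared background column.  The output is gap-free.
#'
#' @param spec A [generator_spec].
#' @return List with `alignment` ([domain_alignment]), `profiles`
#'   ([profile_set]) and `truth` (data frame of planted `j`, `k`,
#'   `coupling`, with attributes `m_sites`, `w_sites`).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_sequences
  m <- spec$m_sites
  w <- spec$w_sites
  bg <- spec$background_freqs

  aln <- matrix("", n, m)
  pwm_cols <- vector("list", w)       # each: 20 x n
  planted_j <- vapply(spec$planted_pairs, function(p) as.integer(p$j), integer(1))
  planted_k <- vapply(spec$planted_pairs, function(p) as.integer(p$k), integer(1))

  # background MSA sites: per-site consensus + uniform noise
  for (j in setdiff(seq_len(m), planted_j)) {
    consensus <- sample(AA20, 1L)
    pick <- stats::runif(n) < spec$background_conservation
    aln[, j] <- ifelse(pick, consensus, sample(AA20, n, replace = TRUE,
                                               prob = bg))
  }
  # background PWM sites: one shared random column
  rdirichlet1 <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }
  bg_conc <- 1 + (if (is.finite(spec$pwm_sharpness)) spec$pwm_sharpness else 40) / 4
  for (k in setdiff(seq_len(w), planted_k)) {
    col <- rdirichlet1(rep(bg_conc, 20L))
    pwm_cols[[k]] <- matrix(col, 20L, n)
  }
  # planted pairs: coordinated states
  for (pp in spec$planted_pairs) {
    states <- if (is.null(pp$states)) 2L else as.integer(pp$states)
    res_msa <- sample(AA20, states)
    res_pwm <- sample(AA20, states)
    # balanced state counts (shuffled): planted sites emulate equally sized
    # coordinated clades and stay diverse enough to pass the site filter
    state <- sample(rep(seq_len(states), length.out = n))
    aln[, pp$j] <- res_msa[state]
    bg_col <- rdirichlet1(rep(1, 20L))
    cols <- vapply(state, function(s)
      pp$coupling * .keyed_column(res_pwm[s], spec$pwm_sharpness) +
        (1 - pp$coupling) * bg_col, numeric(20L))
    pwm_cols[[pp$k]] <- cols
  }
  # per-sequence estimation noise, so no two assay-derived columns are
  # exactly identical and the no-coupling null is non-degenerate
  if (spec$pwm_noise > 0) {
    for (k in seq_len(w)) {
      noise <- matrix(stats::rgamma(20L * n, 1), 20L, n)
      noise <- sweep(noise, 2L, colSums(noise), "/")
      pwm_cols[[k]] <- (1 - spec$pwm_noise) * pwm_cols[[k]] + spec$pwm_noise * noise
    }
  }

  ids <- sprintf("syn%03d", seq_len(n))
  if (!is.null(spec$duplicate)) {
    idx <- as.integer(names(spec$duplicate))
    for (q in seq_along(idx)) {
      i <- idx[q]
      for (cp in seq_len(spec$duplicate[q])) {
        aln <- rbind(aln, aln[i, ])
        for (k in seq_len(w)) pwm_cols[[k]] <- cbind(pwm_cols[[k]], pwm_cols[[k]][, i])
        ids <- c(ids, sprintf("%s_dup%d", ids[i], cp))
      }
    }
  }
  pwms <- lapply(seq_along(ids), function(i) {
    mat <- vapply(seq_len(w), function(k) pwm_cols[[k]][, i], numeric(20L))
    rownames(mat) <- AA20
    mat
  })
  truth <- data.frame(j = planted_j, k = planted_k,
                      coupling = vapply(spec$planted_pairs,
                                        function(p) p$coupling, numeric(1)))
  attr(truth, "m_sites") <- m
  attr(truth, "w_sites") <- w
  list(alignment = domain_alignment(aln, ids = ids),
       profiles = profile_set(pwms, ids),
       truth = truth)
}

#' Build a toy co-crystal structure for a truth record
#'
#' Places single-atom (CA) residues so that every planted (domain site,
#' peptide site) pair sits `near` Angstrom apart while every other mapped
#' pair is at least `far` apart, writes minimal PDB-format text (chain A:
#' domain sites, chain B: peptide sites) and the matching site map.
#'
#' @param truth Truth record from [generate()] (needs attributes `m_sites`
#'   and `w_sites`).
#' @param near,far Target distances in Angstrom, `near < far`.
#' @param pdb_path,map_path Output paths.
#' @return List with `pdb_path`, `map_path`, invisibly usable through
#'   [read_structure_distances_input()].
#' @export
generate_toy_structure <- function(truth, near = 4, far = 15,
                                   pdb_path = tempfile(fileext = ".pdb"),
                                   map_path = tempfile(fileext = ".tsv")) {
  if (near >= far) stop_sdr("need near < far")
  m <- attr(truth, "m_sites")
  w <- attr(truth, "w_sites")
  spacing <- 2 * far + near
  dom <- data.frame(site = seq_len(m), x = seq_len(m) * spacing, y = 0, z = 0)
  pep <- data.frame(site = seq_len(w), x = seq_len(w) * spacing,
                    y = 2 * far, z = 0)
  for (r in seq_len(nrow(truth))) {
    k <- truth$k[r]; j <- truth$j[r]
    pep$x[pep$site == k] <- dom$x[dom$site == j]
    pep$y[pep$site == k] <- near
  }
  atom_line <- function(serial, chain, resno, x, y, z)
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, chain, resno, x, y, z)
  lines <- c(
    mapply(atom_line, seq_len(m), "A", dom$site, dom$x, dom$y, dom$z),
    mapply(atom_line, m + seq_len(w), "B", pep$site, pep$x, pep$y, pep$z),
    "END")
  writeLines(lines, pdb_path)
  map_lines <- c(sprintf("domain\t%d\tA:%d", dom$site, dom$site),
                 sprintf("peptide\t%d\tB:%d", pep$site, pep$site))
  writeLines(map_lines, map_path)
  list(pdb_path = pdb_path, map_path = map_path)
}
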