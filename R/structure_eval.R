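#' Bondi van der Waals radii
#'
#' Radii in Angstrom for the elements commonly seen as protein heavy atoms,
#' used by the closest-atom distance metric.  Unlisted elements fall back
#' to 1.7 (carbon-like).
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
    S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

.vdw_of <- function(elements) {
  r <- vdw_radii()[toupper(elements)]
  r[is.na(r)] <- 1.70
  as.numeric(r)
}

#' Read a site map file
#'
#' A site map connects alignment/PWM site indices to structure residues.
#' Format: a tab- or whitespace-delimited table with three columns
#' `part site residue`, where `part` is `domain` (MSA site) or `peptide`
#' (PWM site) and `residue` is `chain:resnum` (e.g. `A:60`).  Header line
#' optional; `#` comments ignored.
#'
#' @param path Path to the map file.
#' @return A `site_map` list with data frames `domain` and `peptide`, each
#'   with columns `site` and `residue`.
#' @export
read_site_map <- function(path) {
  if (!file.exists(path)) stop_sdr("site map file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("part", "site", "residue"),
                           colClasses = "character")
  if (nrow(tab) && tolower(tab$part[1L]) == "part") tab <- tab[-1L, , drop = FALSE]
  tab$part <- tolower(tab$part)
  if (!all(tab$part %in% c("domain", "peptide")))
    stop_sdr("site map parts must be 'domain' or 'peptide'", class = "sdrcov_parse_error")
  tab$site <- as.integer(tab$site)
  site_map(domain = tab[tab$part == "domain", c("site", "residue")],
           peptide = tab[tab$part == "peptide", c("site", "residue")])
}

#' Construct and validate a site map
#'
#' @param domain,peptide Data frames with integer column `site` (1-based
#'   MSA / PWM site index) and character column `residue` (`chain:resnum`).
#' @param m,w Optional site counts for bound checking.
#' @return A `site_map` list.
#' @export
site_map <- function(domain, peptide, m = NULL, w = NULL) {
  chk <- function(df, bound, what) {
    if (anyDuplicated(df$residue))
      stop_sdr("structure residue '%s' mapped twice in the %s map",
               df$residue[duplicated(df$residue)][1L], what)
    if (any(df$site < 1L)) stop_sdr("%s site indices must be >= 1", what)
    if (!is.null(bound) && any(df$site > bound))
      stop_sdr("%s site index %d exceeds the %d available sites",
               what, max(df$site), bound)
    df
  }
  structure(list(domain = chk(domain, m, "domain"),
                 peptide = chk(peptide, w, "peptide")),
            class = "site_map")
}

#' Read coordinates and a site map for structure evaluation
#'
#' Parses a PDB-format coordinate file, keeps heavy atoms of the single
#' best conformer (highest occupancy; ties resolve to altloc 'A' or blank)
#' and groups them by `chain:resnum`.  Every residue named in the site map
#' must be present in the structure.
#'
#' @param path Path to the PDB file.
#' @param map_path Path to the site map file (see [read_site_map()]).
#' @return List with `residues` (named list of per-residue data frames with
#'   columns `x`, `y`, `z`, `name`, `element`) and `map` (the validated
#'   `site_map`).
#' @export
read_structure_distances_input <- function(path, map_path) {
  if (!file.exists(path)) stop_sdr("structure file not found: %s", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1L, 1L), at$elesy)))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  at$element <- elem
  key <- paste0(at$chain, ":", at$resno)
  residues <- lapply(split(at, key), function(g) {
    # single conformer: highest occupancy, ties to altloc 'A'/blank
    g$alt <- ifelse(is.na(g$alt) | g$alt == "", "", g$alt)
    if (length(unique(g$alt)) > 1L) {
      occ <- tapply(ifelse(is.na(g$o), 1, g$o), g$alt, mean)
      best <- names(occ)[order(-occ, names(occ) != "", names(occ))][1L]
      g <- g[g$alt %in% c("", best), , drop = FALSE]
      g <- g[!duplicated(g$elety), , drop = FALSE]
    }
    data.frame(x = g$x, y = g$y, z = g$z, name = trimws(g$elety),
               element = g$element)
  })
  map <- read_site_map(map_path)
  absent <- setdiff(c(map$domain$residue, map$peptide$residue), names(residues))
  if (length(absent))
    stop_sdr("mapped residue(s) absent from structure: %s",
             paste(absent, collapse = ", "), class = "sdrcov_mapping_error")
  list(residues = residues, map = map)
}

#' Distance between two residues
#'
#' Three metrics over heavy-atom coordinates:
#' \describe{
#'   \item{residue_center}{Euclidean distance between heavy-atom centroids.}
#'   \item{alpha_carbon}{CA-to-CA distance; `NA` if either residue lacks a
#'     CA atom.}
#'   \item{closest_atom_vdw}{Minimum over atom pairs of the inter-atom
#'     distance minus the two atoms' van der Waals radii (Bondi set); may
#'     be negative for contacting residues.}
#' }
#'
#' @param res_a,res_b Per-residue data frames as returned by
#'   [read_structure_distances_input()].
#' @param metric One of "residue_center", "alpha_carbon",
#'   "closest_atom_vdw".
#' @return Distance in Angstrom (possibly negative under the vdW metric),
#'   or `NA` for a missing CA.
#' @export
residue_distance <- function(res_a, res_b,
                             metric = c("residue_center", "alpha_carbon",
                                        "closest_atom_vdw")) {
  metric <- match.arg(metric)
  xyz <- function(r) as.matrix(r[, c("x", "y", "z")])
  switch(metric,
    residue_center = {
      sqrt(sum((colMeans(xyz(res_a)) - colMeans(xyz(res_b)))^2))
    },
    alpha_carbon = {
      ca_a <- res_a[res_a$name == "CA", , drop = FALSE]
      ca_b <- res_b[res_b$name == "CA", , drop = FALSE]
      if (!nrow(ca_a) || !nrow(ca_b)) return(NA_real_)
      sqrt(sum((as.numeric(ca_a[1L, c("x", "y", "z")]) -
                as.numeric(ca_b[1L, c("x", "y", "z")]))^2))
    },
    closest_atom_vdw = {
      a <- xyz(res_a); b <- xyz(res_b)
      ra <- .vdw_of(res_a$element); rb <- .vdw_of(res_b$element)
      dmat <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
      min(dmat - outer(ra, rb, "+"))
    })
}

#' Site-pair distance table
#'
#' One physical distance per mapped (MSA site j, PWM site k) pair under the
#' chosen metric; pairs absent from either map do not appear.
#'
#' @param structure Output of [read_structure_distances_input()].
#' @param metric See [residue_distance()].
#' @return A `site_distance_table` data frame with columns `j`, `k`,
#'   `domain_residue`, `peptide_residue`, `distance` (`NA` marks missing
#'   data, e.g. no CA).
#' @export
distance_table <- function(structure,
                           metric = c("residue_center", "alpha_carbon",
                                      "closest_atom_vdw")) {
  metric <- match.arg(metric)
  map <- structure$map
  rows <- expand.grid(di = seq_len(nrow(map$domain)),
                      pi = seq_len(nrow(map$peptide)))
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    dres <- map$domain$residue[rows$di[r]]
    pres <- map$peptide$residue[rows$pi[r]]
    data.frame(j = map$domain$site[rows$di[r]], k = map$peptide$site[rows$pi[r]],
               domain_residue = dres, peptide_residue = pres,
               distance = residue_distance(structure$residues[[dres]],
                                           structure$residues[[pres]], metric))
  }))
  out <- out[order(out$j, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  class(out) <- c("site_distance_table", "data.frame")
  out
}

#' Correlate covariation scores with structural distances
#'
#' Pearson correlation between the covariation score and the physical
#' distance over all mapped pairs, or — since low-scoring pairs are
#' noise-dominated — over each MSA site's single highest-scoring PWM site
#' (`mode = "best_per_msa_site"`, ties to the smaller k).  Truly covarying
#' pairs are expected to sit close in the co-crystal structure, so a
#' working score correlates negatively with distance.  The two-sided
#' p-value comes from the Fisher transformation `z = atanh(r)` with
#' standard error `1 / sqrt(n - 3)`.
#'
#' @param map A `covariation_map`.
#' @param table A `site_distance_table`.
#' @param mode "all_pairs" or "best_per_msa_site".
#' @param score Score column, "UC" (default) or "MI".
#' @return A `correlation_result` list: `r`, `p_value`, `n_pairs`,
#'   `n_dropped` (missing distances removed), `mode`, `score`.
#' @export
score_distance_correlation <- function(map, table,
                                       mode = c("all_pairs", "best_per_msa_site"),
                                       score = c("UC", "MI")) {
  mode <- match.arg(mode)
  score <- match.arg(score)
  df <- as.data.frame(map)
  if (mode == "best_per_msa_site")
    df <- rank_pairs(map, score = score, per_msa_site_best = TRUE)
  merged <- merge(df[, c("j", "k", score)], as.data.frame(table)[, c("j", "k", "distance")],
                  by = c("j", "k"))
  n_all <- nrow(merged)
  merged <- merged[!is.na(merged$distance), , drop = FALSE]
  n <- nrow(merged)
  if (n < 4L)
    stop_sdr("need at least 4 overlapping score/distance pairs, have %d", n,
             class = "sdrcov_insufficient_data_error")
  r <- stats::cor(merged[[score]], merged$distance)
  z <- atanh(r)
  p <- 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
  structure(list(r = r, p_value = p, n_pairs = n, n_dropped = n_all - n,
                 mode = mode, score = score),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("score-distance correlation (%s, %s): r = %.4f, p = %.3g, n = %d (%d dropped)\n",
              x$score, x$mode, x$r, x$p_value, x$n_pairs, x$n_dropped))
  invisible(x)
}
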