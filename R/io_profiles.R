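#' Construct a profile set
#'
#' A `profile_set` holds one aligned position weight matrix (PWM) per domain
#' sequence, row-aligned to a [domain_alignment].  Each PWM is stored as a
#' 20 x w matrix (rows: [AA20], columns: peptide sites); every column is a
#' probability distribution summing to 1.
#'
#' @param pwms List of n PWMs.  Each element is a 20 x w numeric matrix with
#'   row names covering [AA20] (any row order accepted; rows are reordered),
#'   or a w x 20 matrix with column names covering [AA20].
#' @param ids Identifiers matching the alignment ids one-to-one, in order.
#' @param site_labels Optional display labels per PWM site (e.g. "-3",
#'   "P+2"); defaults to `1..w`.
#' @param renormalize Columns whose sums deviate from 1 by at most this are
#'   rescaled to sum exactly 1; larger deviations are an error.
#' @return An object of class `profile_set` with fields `ids`, `pwms`, `w`,
#'   `site_labels`.
#' @export
profile_set <- function(pwms, ids, site_labels = NULL, renormalize = 1e-3) {
  if (length(pwms) != length(ids))
    stop_sdr("need one PWM per id (%d PWMs, %d ids)", length(pwms), length(ids))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_sdr("profile ids must be unique")
  pwms <- lapply(seq_along(pwms), function(i) {
    m <- as.matrix(pwms[[i]])
    if (!is.null(colnames(m)) && all(AA20 %in% colnames(m)) && ncol(m) == 20L)
      m <- t(m)
    if (is.null(rownames(m)) || !setequal(rownames(m), AA20))
      stop_sdr("PWM for '%s' must have the 20 amino-acid codes as row or column names", ids[i])
    m <- m[AA20, , drop = FALSE]
    if (any(m < 0))
      stop_sdr("negative probability in PWM for '%s'", ids[i], class = "sdrcov_parse_error")
    s <- colSums(m)
    if (any(abs(s - 1) > renormalize))
      stop_sdr("PWM for '%s' has a site summing to %.6f (deviation > %g)",
               ids[i], s[which.max(abs(s - 1))], renormalize,
               class = "sdrcov_normalization_error")
    sweep(m, 2L, s, "/")
  })
  w <- unique(vapply(pwms, ncol, integer(1)))
  if (length(w) != 1L) stop_sdr("all PWMs must have the same number of sites")
  if (is.null(site_labels)) site_labels <- as.character(seq_len(w))
  if (length(site_labels) != w) stop_sdr("need %d site labels", w)
  names(pwms) <- ids
  structure(list(ids = ids, pwms = pwms, w = w,
                 site_labels = as.character(site_labels)),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d PWMs x %d sites (%s)\n", length(x$ids), x$w,
              paste(utils::head(x$site_labels, 8L), collapse = ", ")))
  invisible(x)
}

#' Read a multi-PWM table file
#'
#' The file dialect mirrors FASTA conventions: each PWM is a block opened by
#' a `>id` line followed by a whitespace-delimited probability table with a
#' residue header.  Both orientations are accepted and auto-detected: sites
#' as rows with the 20 residues as header columns, or residues as rows (the
#' first token of each data line a residue code) with sites as columns.
#' A leading site-label column/header token is optional.
#'
#' @param path Path to the PWM file.
#' @param ids Optional identifier vector (e.g. from the alignment); when
#'   given, every id must be present and blocks are returned in this order.
#' @return A [profile_set].
#' @examples
#' prof <- read_profiles(system.file("extdata", "toy_pwms.tsv",
#'                                   package = "sdrcov"))
#' prof$w
#' @export
read_profiles <- function(path, ids = NULL) {
  if (!file.exists(path)) stop_sdr("PWM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_sdr("no '>id' blocks in %s", path, class = "sdrcov_parse_error")
  ends <- c(starts[-1L] - 1L, length(lines))
  block_ids <- sub("\\s.*$", "", sub("^>", "", lines[starts]))
  pwms <- lapply(seq_along(starts), function(b) {
    body <- lines[(starts[b] + 1L):ends[b]]
    if (!length(body)) stop_sdr("empty PWM block for '%s'", block_ids[b],
                                class = "sdrcov_parse_error")
    toks <- strsplit(trimws(body), "\\s+")
    .parse_pwm_block(toks, block_ids[b])
  })
  labels <- attr(pwms[[1L]], "site_labels")
  pwms <- lapply(pwms, function(m) { attr(m, "site_labels") <- NULL; m })
  if (!is.null(ids)) {
    missing <- setdiff(ids, block_ids)
    if (length(missing))
      stop_sdr("PWM file %s is missing ids: %s", path,
               paste(missing, collapse = ", "))
    keep <- match(ids, block_ids)
    pwms <- pwms[keep]
    block_ids <- ids
  }
  profile_set(pwms, block_ids, site_labels = labels)
}

# Parse one tokenised block into a 20 x w matrix; detects orientation from
# where the residue codes sit (header row vs first column).
.parse_pwm_block <- function(toks, id) {
  header <- toupper(toks[[1L]])
  data <- toks[-1L]
  first_col <- toupper(vapply(data, `[`, character(1), 1L))
  amb <- c("B", "Z", "X", "U", "O")
  if (sum(header %in% AA20) >= 15L) {          # sites-as-rows orientation
    res_idx <- which(header %in% c(AA20, amb))
    bad_amb <- header[res_idx][!header[res_idx] %in% AA20]
    if (length(bad_amb))
      stop_sdr("ambiguous residue code '%s' in PWM '%s' (alphabet is the 20 canonical amino acids)",
               bad_amb[1L], id, class = "sdrcov_parse_error")
    if (length(res_idx) != 20L)
      stop_sdr("PWM '%s' header has %d residue columns, expected 20", id,
               length(res_idx), class = "sdrcov_parse_error")
    has_label <- length(header) > 20L
    labels <- if (has_label) vapply(data, `[`, character(1), 1L) else as.character(seq_along(data))
    m <- t(vapply(data, function(r) {
      v <- suppressWarnings(as.numeric(r[res_idx]))
      if (anyNA(v)) stop_sdr("non-numeric probability in PWM '%s'", id,
                             class = "sdrcov_parse_error")
      v
    }, numeric(20L)))
    colnames(m) <- header[res_idx]
    m <- t(m)                                   # -> 20 x w
    attr(m, "site_labels") <- labels
    m
  } else if (all(first_col %in% c(AA20, amb)) || sum(first_col %in% AA20) >= 15L) {
    rows <- c(list(toks[[1L]]), data)           # header may itself be a residue row
    lead <- toupper(vapply(rows, `[`, character(1), 1L))
    if (!lead[1L] %in% c(AA20, amb)) {          # true header of site labels
      ntok <- length(data[[1L]])                # 1 + w tokens per data row
      labels <- if (length(toks[[1L]]) == ntok) toks[[1L]][-1L] else toks[[1L]]
      rows <- data
      lead <- first_col
    } else labels <- NULL
    bad_amb <- lead[lead %in% amb]
    if (length(bad_amb))
      stop_sdr("ambiguous residue code '%s' in PWM '%s' (alphabet is the 20 canonical amino acids)",
               bad_amb[1L], id, class = "sdrcov_parse_error")
    if (!setequal(lead, AA20))
      stop_sdr("PWM '%s' rows do not cover the 20 amino acids exactly", id,
               class = "sdrcov_parse_error")
    vals <- lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(r[-1L]))
      if (anyNA(v)) stop_sdr("non-numeric probability in PWM '%s'", id,
                             class = "sdrcov_parse_error")
      v
    })
    wlen <- unique(lengths(vals))
    if (length(wlen) != 1L)
      stop_sdr("ragged PWM table for '%s'", id, class = "sdrcov_parse_error")
    m <- do.call(rbind, vals)
    rownames(m) <- lead
    m <- m[AA20, , drop = FALSE]
    if (is.null(labels) || length(labels) != wlen) labels <- as.character(seq_len(wlen))
    attr(m, "site_labels") <- labels
    m
  } else {
    stop_sdr("cannot detect PWM orientation for '%s': no residue header found", id,
             class = "sdrcov_parse_error")
  }
}

#' Write a profile set
#'
#' Writes the block dialect read by [read_profiles()]: one `>id` line per
#' domain followed by a tab-delimited table with residues as rows and site
#' labels as the header.
#'
#' @param profiles A [profile_set].
#' @param path Output file path.
#' @param digits Significant digits for probabilities.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, digits = 12L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(profiles$ids)) {
    writeLines(paste0(">", profiles$ids[i]), con)
    writeLines(paste(c("res", profiles$site_labels), collapse = "\t"), con)
    m <- profiles$pwms[[i]]
    for (aa in AA20)
      writeLines(paste(c(aa, formatC(m[aa, ], digits = digits, format = "g")),
                       collapse = "\t"), con)
  }
  invisible(path)
}
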