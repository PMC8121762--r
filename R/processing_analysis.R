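# Terminus classification against prohormone-convertase cleavage rules,
# amidation-motif consistency, exoproteolytic ladder clustering and the
# minor-fragment (10%) filter.

.is_basic <- function(ch) ch %in% c("K", "R")

#' Classify a peptide terminus against convertase cleavage rules
#'
#' A cut sits between prepro residues `pos` and `pos + 1`; `pos = 0` and
#' `pos = length` denote the precursor ends. Classification:
#' `signal_boundary` when the cut coincides with the annotated signal-peptide
#' end; `dibasic` when the two residues immediately upstream of the
#' (effective) cut are both K/R; `monobasic` when exactly one K/R immediately
#' precedes; `nonbasic` otherwise. For C-termini the effective cut may lie up
#' to two residues downstream of the observed terminus when the intervening
#' residues are K/R — the carboxypeptidase-E trimming that follows convertase
#' cleavage removes them from the mature peptide. Precedence:
#' signal_boundary > dibasic > monobasic.
#'
#' @param prec a `precursor`.
#' @param pos cleavage point, `0 <= pos <= nchar(sequence)`.
#' @param side `"N"` or `"C"`: which terminus of the observed peptide the cut
#'   forms.
#' @return list with `side`, `position`, `klass`, `flanking` (the two residues
#'   on each side of the observed cut, `.` beyond the precursor).
#' @export
classify_terminus <- function(prec, pos, side = c("N", "C")) {
  side <- match.arg(side)
  stopifnot(inherits(prec, "precursor"))
  n <- nchar(prec$sequence)
  if (pos < 0L || pos > n) stop("cleavage position out of range: ", pos)
  ch <- strsplit(prec$sequence, "")[[1]]
  at <- function(i) if (i >= 1L && i <= n) ch[i] else "."
  flanking <- paste0(at(pos - 1L), at(pos), "|", at(pos + 1L), at(pos + 2L))

  pair_class <- function(cut) {
    p1 <- at(cut - 1L); p2 <- at(cut)   # two residues upstream of the cut
    if (.is_basic(p2) && .is_basic(p1)) "dibasic"
    else if (.is_basic(p2)) "monobasic"
    else "nonbasic"
  }

  klass <- if (!is.na(prec$signal_end) && pos == prec$signal_end) {
    "signal_boundary"
  } else if (side == "N") {
    pair_class(pos)
  } else {
    # allow up to 2 trimmed basic residues downstream of the observed C-terminus
    best <- pair_class(pos)
    trim <- 0L
    while (trim < 2L && .is_basic(at(pos + trim + 1L))) {
      trim <- trim + 1L
      cand <- pair_class(pos + trim)
      if (cand == "dibasic") best <- "dibasic"
      else if (cand == "monobasic" && best == "nonbasic") best <- "monobasic"
    }
    best
  }
  list(side = side, position = as.integer(pos), klass = klass,
       flanking = flanking)
}

#' Check C-terminal amidation against the precursor motif
#'
#' Peptide amidation arises from a glycine-extended intermediate: an amidated
#' C-terminus at prepro position `end` is consistent with the precursor when
#' residue `end + 1` is glycine (optionally followed by up to two basic
#' residues, the convertase site).
#'
#' @param prec a `precursor`.
#' @param end 1-based prepro position of the peptide's last residue.
#' @param amidated logical: does the observation carry a C-terminal amide?
#' @return `"consistent"`, `"inconsistent"` or `"not_amidated"`.
#' @export
check_amidation <- function(prec, end, amidated) {
  stopifnot(inherits(prec, "precursor"))
  if (!amidated) return("not_amidated")
  n <- nchar(prec$sequence)
  if (end < 1L || end > n) stop("peptide end out of range")
  if (end < n && substr(prec$sequence, end + 1L, end + 1L) == "G")
    "consistent" else "inconsistent"
}

#' Cluster exoproteolytic peptide ladders
#'
#' Single-linkage clustering of observations from one precursor: two
#' observations link when their intervals overlap and their N- or C-termini
#' differ by at most two residues — the signature of ex vivo exoprotease
#' trimming. Each cluster's canonical member is the observation with the
#' largest peak area. Clusters are reported, not merged: variant information
#' is retained.
#'
#' @param observations observation data.frame, all rows sharing
#'   `precursor_accession`.
#' @param max_diff maximum terminal offset for linkage (residues).
#' @return the data.frame with added columns `cluster_id` (integer) and
#'   `canonical` (logical); zero-row input returns zero rows.
#' @export
cluster_ladders <- function(observations, max_diff = 2L) {
  n <- nrow(observations)
  if (!n) {
    observations$cluster_id <- integer(0)
    observations$canonical <- logical(0)
    return(observations)
  }
  if (length(unique(observations$precursor_accession)) > 1L)
    stop("cluster_ladders expects observations from a single precursor")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  s <- observations$start; e <- observations$end
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    overlap <- s[i] <= e[j] && s[j] <= e[i]
    termini <- abs(s[i] - s[j]) <= max_diff || abs(e[i] - e[j]) <= max_diff
    if (overlap && termini) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  observations$cluster_id <- match(roots, unique(roots))
  observations$canonical <- FALSE
  for (cl in unique(observations$cluster_id)) {
    idx <- which(observations$cluster_id == cl)
    observations$canonical[idx[which.max(observations$peak_area[idx])]] <- TRUE
  }
  observations
}

#' Filter minor exoproteolytic fragments
#'
#' Within each precursor, drops peptides whose signal is below `frac` (default
#' 10%) of the most abundant peptide from the same propeptide. The comparison
#' uses each peptide's maximum peak area across samples, so a peptide either
#' survives in all samples or in none.
#'
#' @param observations observation data.frame (any number of precursors).
#' @param frac fraction of the per-precursor maximum, in (0, 1).
#' @param keep_all if `TRUE`, return all rows with a logical `filtered`
#'   column instead of dropping.
#' @return surviving observations (or all rows annotated, with `keep_all`).
#' @export
filter_minor_fragments <- function(observations, frac = 0.10, keep_all = FALSE) {
  stopifnot(frac > 0, frac < 1)
  if (!nrow(observations)) {
    if (keep_all) observations$filtered <- logical(0)
    return(observations)
  }
  pep_key <- paste(observations$precursor_accession, observations$start,
                   observations$end, observations$mods)
  pep_max <- tapply(observations$peak_area, pep_key, max)
  prec_of <- tapply(observations$precursor_accession, pep_key, `[`, 1L)
  prec_max <- tapply(pep_max, prec_of[names(pep_max)], max)
  keep_pep <- pep_max >= frac * prec_max[prec_of[names(pep_max)]]
  filtered <- as.vector(!keep_pep[pep_key])
  if (keep_all) {
    observations$filtered <- filtered
    observations
  } else {
    observations[!filtered, , drop = FALSE]
  }
}

#' Annotate observations with processing calls
#'
#' Convenience wrapper producing the full processed table: terminus classes
#' for both ends, amidation consistency, ladder cluster ids (per precursor)
#' and the minor-fragment flag.
#'
#' @param db named list of `precursor` objects.
#' @param observations observation data.frame.
#' @param frac minor-fragment threshold passed to [filter_minor_fragments()].
#' @return the data.frame with columns `n_term_class`, `c_term_class`,
#'   `amidation_status`, `cluster_id`, `canonical`, `filtered` appended.
#' @export
annotate_observations <- function(db, observations, frac = 0.10) {
  if (!nrow(observations)) return(observations)
  mods <- .parse_mods(observations$mods)
  out <- lapply(split(seq_len(nrow(observations)),
                      observations$precursor_accession), function(idx) {
    prec <- db[[observations$precursor_accession[idx[1]]]]
    if (is.null(prec))
      stop("unknown precursor accession: ",
           observations$precursor_accession[idx[1]])
    block <- observations[idx, , drop = FALSE]
    block$n_term_class <- vapply(block$start, function(s)
      classify_terminus(prec, s - 1L, "N")$klass, "")
    block$c_term_class <- vapply(block$end, function(e)
      classify_terminus(prec, e, "C")$klass, "")
    amidated <- vapply(mods[idx], function(m) "amidation" %in% m$name, NA)
    block$amidation_status <- mapply(function(e, a)
      check_amidation(prec, e, a), block$end, amidated)
    block <- cluster_ladders(block)
    block
  })
  out <- do.call(rbind, out)
  out <- filter_minor_fragments(out, frac = frac, keep_all = TRUE)
  rownames(out) <- NULL
  out
}
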