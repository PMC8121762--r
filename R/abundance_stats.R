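# Peak-area quantification and the study's quantitative comparisons:
# XIC integration, prevalence filtering, lean-vs-DIO differential statistics
# (positive log2 fold change = decrease in DIO) and fold-over-basal secretion.

#' Integrate an extracted-ion chromatogram
#'
#' Trapezoidal area under the intensity trace, restricted to points whose m/z
#' lies inside `mz_window` and whose retention time lies inside `rt_window`.
#'
#' @param trace data.frame with columns `time` (strictly increasing), `mz`,
#'   `intensity`.
#' @param mz_window numeric length-2, inclusive m/z bounds.
#' @param rt_window numeric length-2, inclusive retention-time bounds.
#' @return peak area (0 when fewer than two points fall in the windows).
#' @export
integrate_xic <- function(trace, mz_window, rt_window) {
  stopifnot(all(c("time", "mz", "intensity") %in% names(trace)),
            length(mz_window) == 2L, length(rt_window) == 2L)
  if (is.unsorted(trace$time, strictly = TRUE))
    stop("trace times must be strictly increasing")
  sel <- trace$mz >= mz_window[1] & trace$mz <= mz_window[2] &
    trace$time >= rt_window[1] & trace$time <= rt_window[2]
  t <- trace$time[sel]; y <- trace$intensity[sel]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

#' Construct a peptide abundance matrix
#'
#' Peptides-by-samples peak areas with a sample sheet carrying group and
#' region labels. Missing cells (`NA`) mean the peptide was not matched in
#' that sample — absence, not zero.
#'
#' @param areas numeric matrix, rownames = peptide ids, colnames = sample ids;
#'   `NA` for missing, no negative values.
#' @param samples data.frame with columns `sample_id`, `group`, `region`;
#'   one row per column of `areas`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(areas, samples) {
  stopifnot(is.matrix(areas), !is.null(rownames(areas)),
            !is.null(colnames(areas)),
            all(c("sample_id", "group", "region") %in% names(samples)))
  samples <- samples[match(colnames(areas), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("every matrix column needs a sample-sheet row")
  if (any(areas < 0, na.rm = TRUE)) stop("negative peak areas")
  structure(list(areas = areas, samples = samples),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d peptide(s) x %d sample(s); groups: %s; regions: %s\n",
              nrow(x$areas), ncol(x$areas),
              paste(unique(x$samples$group), collapse = "/"),
              paste(unique(x$samples$region), collapse = ", ")))
  invisible(x)
}

#' Read / write an abundance matrix as TSV
#'
#' The matrix file is wide (first column `peptide`, one column per sample);
#' the sample sheet has columns `sample_id`, `group`, `region`.
#'
#' @param matrix_path,samples_path TSV file paths.
#' @param m an `abundance_matrix`.
#' @return `read_abundance_matrix` returns an `abundance_matrix`.
#' @export
read_abundance_matrix <- function(matrix_path, samples_path) {
  wide <- utils::read.delim(matrix_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  areas <- as.matrix(wide[, -1, drop = FALSE])
  rownames(areas) <- wide[[1]]
  abundance_matrix(areas, samples)
}

#' @rdname read_abundance_matrix
#' @export
write_abundance_matrix <- function(m, matrix_path, samples_path) {
  wide <- data.frame(peptide = rownames(m$areas), m$areas,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(wide, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Prevalence filter
#'
#' Keeps a peptide iff it was matched (non-missing) in at least `min_frac` of
#' the samples of at least one group, the data-complexity filter applied
#' before differential analysis. Applied within a region when the matrix
#' spans several.
#'
#' @param m an `abundance_matrix` with two groups.
#' @param min_frac minimum detection fraction, default 0.7.
#' @return the filtered `abundance_matrix`.
#' @export
prevalence_filter <- function(m, min_frac = 0.7) {
  stopifnot(inherits(m, "abundance_matrix"))
  groups <- unique(m$samples$group)
  if (length(groups) != 2L) stop("prevalence_filter expects exactly two groups")
  keep <- rep(FALSE, nrow(m$areas))
  for (g in groups) {
    cols <- m$samples$group == g
    keep <- keep | rowMeans(!is.na(m$areas[, cols, drop = FALSE])) >= min_frac
  }
  abundance_matrix(m$areas[keep, , drop = FALSE], m$samples)
}

#' Lean-vs-DIO differential abundance
#'
#' Per-peptide comparison of the two groups within each region. The fold
#' change is `log2(mean(reference) / mean(comparison))`, so a decrease in the
#' comparison (DIO) group is positive — the study's sign convention. Missing
#' areas are excluded from means; a peptide with fewer than two finite values
#' in a group gets no p-value, and a group that is entirely missing yields an
#' infinite fold change which is flagged and set to `NA`. P-values come from a
#' two-sample Mann-Whitney test by default (robust to log-normal skew) or
#' Welch's t on log areas; Benjamini-Hochberg correction is applied across
#' peptides within each region.
#'
#' @param m an `abundance_matrix` whose groups are reference and comparison.
#' @param reference group label treated as reference (lean); default the
#'   first of the sorted group labels or `"lean"` when present.
#' @param test `"wilcox"` (default) or `"welch"`.
#' @return data.frame with columns `peptide`, `region`, `log2fc`, `p_value`,
#'   `q_value`, `n_ref`, `n_cmp`, `flagged`.
#' @export
dio_differential <- function(m, reference = NULL, test = c("wilcox", "welch")) {
  stopifnot(inherits(m, "abundance_matrix"))
  test <- match.arg(test)
  groups <- sort(unique(m$samples$group))
  if (length(groups) != 2L) stop("dio_differential expects exactly two groups")
  if (is.null(reference))
    reference <- if ("lean" %in% groups) "lean" else groups[1]
  comparison <- setdiff(groups, reference)
  out <- lapply(unique(m$samples$region), function(reg) {
    ref_cols <- m$samples$group == reference & m$samples$region == reg
    cmp_cols <- m$samples$group == comparison & m$samples$region == reg
    if (!any(ref_cols) || !any(cmp_cols)) return(NULL)
    res <- do.call(rbind, lapply(rownames(m$areas), function(pep) {
      x <- m$areas[pep, ref_cols]; x <- x[is.finite(x)]
      y <- m$areas[pep, cmp_cols]; y <- y[is.finite(y)]
      l2 <- log2(mean(x) / mean(y))
      flagged <- !is.finite(l2)
      p <- if (length(x) >= 2L && length(y) >= 2L) {
        if (test == "wilcox")
          suppressWarnings(stats::wilcox.test(x, y)$p.value)
        else
          stats::t.test(log(x), log(y))$p.value
      } else NA_real_
      data.frame(peptide = pep, region = reg,
                 log2fc = ifelse(flagged, NA_real_, l2),
                 p_value = p, n_ref = length(x), n_cmp = length(y),
                 flagged = flagged, stringsAsFactors = FALSE)
    }))
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("peptide", "region", "log2fc", "p_value", "q_value",
          "n_ref", "n_cmp", "flagged")]
}

#' Fold over basal
#'
#' Stimulated-supernatant peak area divided by basal peak area. Defined only
#' when the peptide was detected in the basal supernatant with positive area;
#' otherwise `NA` (a value, not an error).
#'
#' @param basal_area,stimulated_area numeric vectors; `NA` = not detected.
#' @return fold over basal, `NA` where undefined.
#' @export
fold_over_basal <- function(basal_area, stimulated_area) {
  stopifnot(all(basal_area >= 0, na.rm = TRUE),
            all(stimulated_area >= 0, na.rm = TRUE))
  ifelse(!is.na(basal_area) & basal_area > 0 & !is.na(stimulated_area),
         stimulated_area / basal_area, NA_real_)
}

#' Build secretion records from a basal/stimulated table
#'
#' @param secretion data.frame with columns `peptide`, `region`,
#'   `basal_area`, `stimulated_area` (`NA` = not detected).
#' @return the data.frame with a `fold_over_basal` column appended.
#' @export
secretion_records <- function(secretion) {
  stopifnot(all(c("peptide", "region", "basal_area", "stimulated_area")
                %in% names(secretion)))
  secretion$fold_over_basal <-
    fold_over_basal(secretion$basal_area, secretion$stimulated_area)
  secretion
}
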