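# Ranking of candidate bioactive peptides by hormone-like characteristics:
# basic-residue flanks, abundance in both species, cross-species conservation
# and regulated (vesicular) secretion.

.obs_species <- function(db, observations) {
  acc2sp <- vapply(db, `[[`, "", "species")
  acc2sp[observations$precursor_accession]
}

#' Score and rank candidate bioactive peptides
#'
#' Each unique mouse peptide (precursor + coordinates + amidation) is scored
#' on four boolean criteria:
#' \describe{
#'   \item{basic_flanked}{both termini classify as monobasic, dibasic or
#'     signal-boundary cuts (precursor ends also count as valid flanks).}
#'   \item{abundant_both_species}{maximum mouse peak area reaches
#'     `abundance`, and a human observation overlapping the projected human
#'     interval also reaches it.}
#'   \item{conserved}{sequence identity with the human homolog over the
#'     peptide span is at least `identity`.}
#'   \item{regulated_secretion}{fold over basal exceeds `fold` in at least
#'     one region of the secretion table.}
#' }
#' The composite score counts satisfied criteria; ranking is by composite,
#' ties broken by maximum mouse peak area then lexical peptide id. Peptides
#' whose precursor lacks a human homolog get `conserved` and
#' `abundant_both_species` false, with a warning.
#'
#' @param db named list of `precursor` objects (mouse and human).
#' @param observations observation data.frame covering both species.
#' @param secretion secretion table as from [secretion_records()] (may have
#'   zero rows).
#' @param abundance peak-area threshold for "highly abundant", default 1e5.
#' @param identity conservation threshold (fraction), default 0.7.
#' @param fold regulated-secretion threshold (fold over basal), default 2.
#' @return data.frame with one row per mouse peptide: `peptide`, `accession`,
#'   `gene`, `start`, `end`, the four criterion booleans, `composite`,
#'   `max_area`, `rank`, sorted by rank.
#' @export
score_candidates <- function(db, observations, secretion,
                             abundance = 1e5, identity = 0.7, fold = 2) {
  if ("fold_over_basal" %in% names(secretion) == FALSE && nrow(secretion))
    secretion <- secretion_records(secretion)
  sp <- .obs_species(db, observations)
  mouse_obs <- observations[sp == "mouse", , drop = FALSE]
  human_obs <- observations[sp == "human", , drop = FALSE]
  if (!nrow(mouse_obs)) stop("no mouse observations to score")

  mods <- .parse_mods(mouse_obs$mods)
  amidated <- vapply(mods, function(m) "amidation" %in% m$name, NA)
  acc2gene <- vapply(db, `[[`, "", "gene")
  gene <- acc2gene[mouse_obs$precursor_accession]
  label <- peptide_label(gene, mouse_obs$start, mouse_obs$end, amidated)
  key <- paste(mouse_obs$precursor_accession, mouse_obs$start,
               mouse_obs$end, amidated)
  first <- !duplicated(key)
  max_area <- tapply(mouse_obs$peak_area, key, max)

  aln_cache <- new.env(parent = emptyenv())
  get_alignment <- function(g) {
    if (!is.null(aln_cache[[g]])) return(aln_cache[[g]])
    pair <- .find_homolog_pair(db, g)
    al <- if (is.null(pair$human) || is.null(pair$mouse)) NA
    else align_homologs(pair$mouse, pair$human)
    aln_cache[[g]] <- al
    al
  }

  rows <- lapply(which(first), function(i) {
    acc <- mouse_obs$precursor_accession[i]
    prec <- db[[acc]]
    s <- mouse_obs$start[i]; e <- mouse_obs$end[i]
    ok_class <- c("monobasic", "dibasic", "signal_boundary")
    n_call <- classify_terminus(prec, s - 1L, "N")
    # an amidated terminus derives from a Gly-extended intermediate: the
    # convertase cut lies downstream of the amidation glycine
    c_cut <- if (amidated[i] &&
                 check_amidation(prec, e, TRUE) == "consistent") e + 1L else e
    c_call <- classify_terminus(prec, c_cut, "C")
    basic_flanked <-
      (n_call$klass %in% ok_class || s == 1L) &&
      (c_call$klass %in% ok_class || e == nchar(prec$sequence))

    al <- get_alignment(prec$gene)
    if (!inherits(al, "homolog_alignment")) {
      warning("no human homolog for gene ", prec$gene,
              "; conservation and cross-species abundance set FALSE",
              call. = FALSE)
      conserved <- FALSE
      abundant_both <- FALSE
    } else {
      proj <- project_interval(al, s, e, from = "a")
      conserved <- span_identity(al, s, e, from = "a") >= identity &&
        proj$coverage > 0
      human_acc <- names(acc2gene)[acc2gene == prec$gene &
                                     vapply(db, `[[`, "", "species") == "human"]
      h <- human_obs[human_obs$precursor_accession %in% human_acc, ,
                     drop = FALSE]
      abundant_both <- unname(max_area[key[i]]) >= abundance &&
        !is.na(proj$start) &&
        any(h$start <= proj$end & h$end >= proj$start &
              h$peak_area >= abundance)
    }
    lab <- label[i]
    sec <- secretion[secretion$peptide == lab, , drop = FALSE]
    regulated <- nrow(sec) > 0 &&
      any(sec$fold_over_basal > fold, na.rm = TRUE)

    data.frame(peptide = lab, accession = acc, gene = prec$gene,
               start = s, end = e,
               basic_flanked = basic_flanked,
               abundant_both_species = abundant_both,
               conserved = conserved,
               regulated_secretion = regulated,
               max_area = unname(max_area[key[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$composite <- rowSums(out[, c("basic_flanked", "abundant_both_species",
                                   "conserved", "regulated_secretion")])
  ord <- order(-out$composite, -out$max_area, out$peptide)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
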