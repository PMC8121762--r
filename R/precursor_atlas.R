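# Precursor atlas: prepropeptide sequences, peptide-to-precursor mapping,
# mouse/human homolog alignment, cross-species coordinate projection and
# alignment-plot documents.
#
# All coordinates are 1-based inclusive on the PREPRO sequence (signal peptide
# included), following the field's "p59-79" numbering.

#' Construct a prepropeptide precursor record
#'
#' @param accession unique accession token.
#' @param gene gene symbol shared by homologs across species.
#' @param species `"mouse"` or `"human"`.
#' @param sequence amino-acid string (canonical letters).
#' @param signal_end 1-based position of the last signal-peptide residue, or
#'   `NA` when no signal peptide is annotated (e.g. cytosolic proteins).
#' @return An object of class `precursor`.
#' @export
precursor <- function(accession, gene, species, sequence, signal_end = NA) {
  .check_sequence(sequence)
  species <- match.arg(species, c("mouse", "human"))
  if (is.na(signal_end)) {
    signal_end <- NA_integer_
  } else {
    signal_end <- as.integer(signal_end)
    if (signal_end < 0L || signal_end >= nchar(sequence))
      stop("signal_end must satisfy 0 <= signal_end < sequence length")
  }
  structure(list(accession = accession, gene = gene, species = species,
                 sequence = sequence, signal_end = signal_end),
            class = "precursor")
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor> %s  %s (%s), %d aa, signal 1-%s\n",
              x$accession, x$gene, x$species, nchar(x$sequence),
              ifelse(is.na(x$signal_end), "none", x$signal_end)))
  invisible(x)
}

#' Read / write precursors as FASTA
#'
#' The header dialect is `accession|gene|species|signal_end`, with an empty
#' final field for precursors without a signal peptide.
#'
#' @param path FASTA file path.
#' @param db list of `precursor` objects.
#' @return `read_precursors` returns a named list of `precursor` objects keyed
#'   by accession.
#' @export
read_precursors <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(aa), function(i) {
    fields <- strsplit(names(aa)[i], "|", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("bad FASTA header (need accession|gene|species|signal_end): ",
           names(aa)[i])
    se <- if (length(fields) >= 4L && nzchar(fields[4])) as.integer(fields[4]) else NA
    precursor(fields[1], fields[2], fields[3], as.character(aa[[i]]), se)
  })
  names(out) <- vapply(out, `[[`, "", "accession")
  out
}

#' @rdname read_precursors
#' @export
write_precursors <- function(db, path) {
  headers <- vapply(db, function(p)
    paste(p$accession, p$gene, p$species,
          ifelse(is.na(p$signal_end), "", p$signal_end), sep = "|"), "")
  seqs <- Biostrings::AAStringSet(vapply(db, `[[`, "", "sequence"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Map a peptide sequence onto a precursor database
#'
#' Reports every exact substring occurrence of `sequence` in every precursor,
#' with 1-based inclusive prepro coordinates. Peptides hitting more than one
#' locus (across or within precursors) are flagged ambiguous; downstream
#' consumers use the first hit by accession order.
#'
#' @param sequence peptide amino-acid string.
#' @param db named list of `precursor` objects.
#' @return data.frame with columns `accession`, `gene`, `species`, `start`,
#'   `end`, `ambiguous`; zero rows when the peptide matches nowhere.
#' @export
map_peptide <- function(sequence, db) {
  if (!length(db)) stop("precursor database is empty")
  .check_sequence(sequence)
  db <- db[order(vapply(db, `[[`, "", "accession"))]
  hits <- do.call(rbind, lapply(db, function(p) {
    m <- gregexpr(sequence, p$sequence, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(accession = p$accession, gene = p$gene, species = p$species,
               start = as.integer(m),
               end = as.integer(m) + nchar(sequence) - 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    return(data.frame(accession = character(), gene = character(),
                      species = character(), start = integer(),
                      end = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  hits$ambiguous <- nrow(hits) > 1L
  rownames(hits) <- NULL
  hits
}

#' Peptide label from prepro coordinates
#'
#' Builds the conventional `"<Gene> p<start>-<end>"` label, with a trailing
#' `"a"` for C-terminally amidated peptides.
#'
#' @param gene gene symbol.
#' @param start,end 1-based inclusive prepro coordinates.
#' @param amidated logical.
#' @return character label, vectorised.
#' @export
#' @examples
#' peptide_label("Gast", 59, 79)        # "Gast p59-79"
#' peptide_label("ChgA", 435, 462, TRUE) # "ChgA p435-462a"
peptide_label <- function(gene, start, end, amidated = FALSE) {
  paste0(gene, " p", start, "-", end, ifelse(amidated, "a", ""))
}

# BLOSUM62-based similarity: ':' where the substitution score is positive but
# the residues differ; '|' where identical.
.match_line <- function(a, b) {
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  out <- rep(" ", length(ca))
  both <- ca != "-" & cb != "-"
  out[both & ca == cb] <- "|"
  sim <- both & ca != cb
  if (any(sim))
    out[sim] <- ifelse(B[cbind(ca[sim], cb[sim])] > 0, ":", " ")
  paste(out, collapse = "")
}

.coord_maps <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]; cb <- strsplit(aligned_b, "")[[1]]
  pos_a <- cumsum(ca != "-"); pos_b <- cumsum(cb != "-")
  a_cols <- which(ca != "-"); b_cols <- which(cb != "-")
  map_a_to_b <- ifelse(cb[a_cols] != "-", pos_b[a_cols], NA_integer_)
  map_b_to_a <- ifelse(ca[b_cols] != "-", pos_a[b_cols], NA_integer_)
  list(a_to_b = as.integer(map_a_to_b), b_to_a = as.integer(map_b_to_a))
}

#' Globally align a mouse/human homolog pair
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap cost
#' (opening 10, extension 1 per residue). The match line marks identical
#' residues with `'|'` and chemically similar residues (positive BLOSUM62
#' score, non-identical) with `':'`.
#'
#' @param a,b `precursor` objects for the same gene in different species.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return An object of class `homolog_alignment` with elements `aligned_a`,
#'   `aligned_b`, `match_line`, `map_a_to_b`, `map_b_to_a`, `score`, `gene`.
#' @export
align_homologs <- function(a, b, gap_open = 10, gap_extend = 1) {
  stopifnot(inherits(a, "precursor"), inherits(b, "precursor"))
  if (!nchar(a$sequence) || !nchar(b$sequence)) stop("empty precursor sequence")
  if (a$gene != b$gene) stop("homolog pair must share a gene symbol")
  if (a$species == b$species) stop("homolog pair must be from different species")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  maps <- .coord_maps(al_a, al_b)
  structure(list(aligned_a = al_a, aligned_b = al_b,
                 match_line = .match_line(al_a, al_b),
                 map_a_to_b = maps$a_to_b, map_b_to_a = maps$b_to_a,
                 score = Biostrings::score(pa), gene = a$gene,
                 species_a = a$species, species_b = b$species),
            class = "homolog_alignment")
}

#' @export
print.homolog_alignment <- function(x, width = 60, ...) {
  cat(sprintf("<homolog_alignment> %s: %s vs %s, score %.1f\n",
              x$gene, x$species_a, x$species_b, x$score))
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$match_line, s, e), "\n",
        substr(x$aligned_b, s, e), "\n\n", sep = "")
  }
  invisible(x)
}

#' Project a residue interval across a homolog alignment
#'
#' Maps a 1-based inclusive interval on one species onto the smallest interval
#' on the other species that covers all aligned images. Coverage is the
#' fraction of interval positions with a non-gap image; a fully gapped
#' interval projects to an empty interval with coverage 0.
#'
#' @param al a `homolog_alignment`.
#' @param start,end interval on the source species.
#' @param from `"a"` (default) or `"b"`: which species the interval lives on.
#' @return list with `start`, `end` (NA when empty) and `coverage`.
#' @export
project_interval <- function(al, start, end, from = c("a", "b")) {
  from <- match.arg(from)
  map <- if (from == "a") al$map_a_to_b else al$map_b_to_a
  if (start < 1L || end > length(map) || start > end)
    stop("interval out of range for species ", from)
  img <- map[start:end]
  cov <- sum(!is.na(img)) / (end - start + 1L)
  if (all(is.na(img)))
    return(list(start = NA_integer_, end = NA_integer_, coverage = 0))
  list(start = min(img, na.rm = TRUE), end = max(img, na.rm = TRUE),
       coverage = cov)
}

#' Sequence identity over a projected interval
#'
#' Fraction of positions in `[start, end]` on species A whose aligned image on
#' species B carries the identical residue. Used as the conservation measure
#' for candidate scoring.
#'
#' @inheritParams project_interval
#' @return identity fraction in \[0, 1\].
#' @export
span_identity <- function(al, start, end, from = c("a", "b")) {
  from <- match.arg(from)
  src <- if (from == "a") al$aligned_a else al$aligned_b
  oth <- if (from == "a") al$aligned_b else al$aligned_a
  cs <- strsplit(src, "")[[1]]; co <- strsplit(oth, "")[[1]]
  cols <- which(cs != "-")
  if (start < 1L || end > length(cols) || start > end)
    stop("interval out of range")
  sel <- cols[start:end]
  mean(cs[sel] == co[sel])
}

.find_homolog_pair <- function(db, gene) {
  hits <- Filter(function(p) p$gene == gene, db)
  if (!length(hits)) stop("unknown gene: ", gene)
  mouse <- Filter(function(p) p$species == "mouse", hits)
  human <- Filter(function(p) p$species == "human", hits)
  list(mouse = if (length(mouse)) mouse[[1]] else NULL,
       human = if (length(human)) human[[1]] else NULL)
}

#' Build an alignment-plot document for one gene
#'
#' A renderer-neutral document: the mouse/human homolog alignment plus one row
#' per retained peptide observation with prepro coordinates, a log10-scaled
#' area shade, and PTM flags (C-terminal amidation, N-terminal pyroglutamate,
#' carbamidomethylation). Observations below `min_area` are excluded, the
#' figure-style abundance cut.
#'
#' @param db named list of `precursor` objects (the atlas).
#' @param gene gene symbol; a mouse entry must exist, a human one is optional.
#' @param observations observation data.frame (see [read_observations()]).
#' @param min_area peak-area threshold; peptides below it are dropped.
#' @return An object of class `alignment_plot`.
#' @export
build_alignment_plot <- function(db, gene, observations, min_area = 1e4) {
  pair <- .find_homolog_pair(db, gene)
  if (is.null(pair$mouse)) stop("no mouse precursor for gene ", gene)
  al <- if (!is.null(pair$human)) align_homologs(pair$mouse, pair$human) else NULL
  obs <- observations[observations$precursor_accession == pair$mouse$accession &
                        observations$peak_area >= min_area, , drop = FALSE]
  peptides <- if (nrow(obs)) {
    mods <- .parse_mods(obs$mods)
    data.frame(
      peptide = obs$peptide, start = obs$start, end = obs$end,
      peak_area = obs$peak_area,
      shade = log10(obs$peak_area),
      amidated = vapply(mods, function(m) "amidation" %in% m$name, NA),
      pyroglu = vapply(mods, function(m) any(grepl("^pyroglu", m$name)), NA),
      carbamidomethyl = vapply(mods, function(m) "carbamidomethyl" %in% m$name, NA),
      stringsAsFactors = FALSE)
  } else {
    data.frame(peptide = character(), start = integer(), end = integer(),
               peak_area = numeric(), shade = numeric(), amidated = logical(),
               pyroglu = logical(), carbamidomethyl = logical())
  }
  structure(list(gene = gene, mouse = pair$mouse, human = pair$human,
                 alignment = al, peptides = peptides, min_area = min_area),
            class = "alignment_plot")
}

#' @export
print.alignment_plot <- function(x, ...) {
  cat(sprintf("<alignment_plot> %s: %d peptide(s) at peak area >= %g\n",
              x$gene, nrow(x$peptides), x$min_area))
  invisible(x)
}

#' Export an alignment-plot document
#'
#' `write_plot_tsv` writes the retained-peptide table; `write_plot_svg` renders
#' a simple SVG with the aligned sequences and one bar per peptide, shaded by
#' log10 peak area, with amidation (red) and pyroglutamate (yellow) markers.
#'
#' @param x an `alignment_plot`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_plot_tsv <- function(x, path) {
  utils::write.table(x$peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_tsv
#' @export
write_plot_svg <- function(x, path) {
  cw <- 8; rh <- 14
  n <- nchar(x$mouse$sequence)
  width <- 40 + cw * max(n, 10)
  height <- 80 + rh * (3 + nrow(x$peptides))
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="monospace" font-size="11">',
                     width, height),
             sprintf('<text x="20" y="20">%s (min area %g)</text>', esc(x$gene), x$min_area))
  y <- 40
  seqs <- if (!is.null(x$alignment))
    c(x$alignment$aligned_a, x$alignment$match_line, x$alignment$aligned_b)
  else x$mouse$sequence
  for (s in seqs) {
    lines <- c(lines, sprintf('<text x="20" y="%d" xml:space="preserve">%s</text>', y, esc(s)))
    y <- y + rh
  }
  if (nrow(x$peptides)) {
    shade_max <- max(x$peptides$shade)
    for (i in seq_len(nrow(x$peptides))) {
      p <- x$peptides[i, ]
      grey <- round(200 - 150 * p$shade / shade_max)
      lines <- c(lines, sprintf(
        '<rect x="%.1f" y="%d" width="%.1f" height="%d" fill="rgb(%d,%d,%d)"><title>%s</title></rect>',
        20 + cw * (p$start - 1), y, cw * (p$end - p$start + 1), rh - 4,
        grey, grey, grey, esc(p$peptide)))
      if (p$amidated)
        lines <- c(lines, sprintf(
          '<rect x="%.1f" y="%d" width="%.1f" height="%d" fill="red"/>',
          20 + cw * (p$end - 1), y, cw, rh - 4))
      if (p$pyroglu)
        lines <- c(lines, sprintf(
          '<rect x="%.1f" y="%d" width="%.1f" height="%d" fill="gold"/>',
          20 + cw * (p$start - 1), y, cw, rh - 4))
      y <- y + rh
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

# ---- observation table I/O ---------------------------------------------

# mods column dialect: semicolon-separated name@position, empty for none.
.parse_mods <- function(mods_str) {
  lapply(mods_str, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(name = character(), position = integer()))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
    data.frame(name = vapply(parts, `[[`, "", 1),
               position = as.integer(vapply(parts, `[[`, "", 2)),
               stringsAsFactors = FALSE)
  })
}

.format_mods <- function(mods_df) {
  if (!nrow(mods_df)) return("")
  paste0(mods_df$name, "@", mods_df$position, collapse = ";")
}

#' Read / write peptide observation tables (TSV)
#'
#' Columns: `peptide`, `precursor_accession`, `start`, `end`, `mods`
#' (semicolon-separated `name@position`, peptide-local positions), `sample_id`,
#' `region`, `peak_area`. Extra annotation columns are preserved.
#'
#' @param path TSV file path.
#' @param observations observation data.frame.
#' @return `read_observations` returns the data.frame.
#' @export
read_observations <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mods = "character"))
  need <- c("peptide", "precursor_accession", "start", "end", "mods",
            "sample_id", "region", "peak_area")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop("observation table lacks columns: ", paste(missing, collapse = ", "))
  stopifnot(all(obs$peak_area > 0), all(obs$start >= 1L),
            all(obs$end >= obs$start), all(obs$end - obs$start + 1L <= 65L))
  obs$mods[is.na(obs$mods)] <- ""
  obs
}

#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
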