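# Monoisotopic mass arithmetic for peptides and the modification set used
# throughout the pipeline.

# Monoisotopic residue masses (Da), canonical 20 amino acids.
.AA_MONO <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292745, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.WATER_MONO <- 18.01056468
.PROTON_MASS <- 1.007276

#' Built-in peptide modification registry
#'
#' Returns the registry of post-translational modifications handled by the
#' pipeline: C-terminal amidation, N-terminal pyroglutamate (from Gln and from
#' Glu), N-terminal acetylation, cysteine carbamidomethylation, phosphorylation
#' and serine/threonine acylation (octanoyl, decanoyl). Deltas are standard
#' monoisotopic mass shifts in Da.
#'
#' The `site` column is one of `"N-term"`, `"C-term"` or `"residue:<aa>"`,
#' where `<aa>` lists the residue letters the modification may occupy.
#'
#' @return A data.frame with columns `name`, `site`, `delta`.
#' @export
#' @examples
#' mod_registry()
mod_registry <- function() {
  data.frame(
    name = c("amidation", "pyroglu_Q", "pyroglu_E", "acetyl",
             "carbamidomethyl", "phospho", "octanoyl", "decanoyl"),
    site = c("C-term", "N-term", "N-term", "N-term",
             "residue:C", "residue:STY", "residue:ST", "residue:ST"),
    delta = c(-0.98402, -17.02655, -18.01056, 42.01057,
              57.02146, 79.96633, 126.10447, 154.13577),
    stringsAsFactors = FALSE
  )
}

#' Write / read a modification registry as TSV
#'
#' @param registry data.frame as returned by [mod_registry()].
#' @param path file path.
#' @return `read_mod_registry` returns the registry data.frame.
#' @export
write_mod_registry <- function(registry, path) {
  stopifnot(all(c("name", "site", "delta") %in% names(registry)))
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mod_registry
#' @export
read_mod_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site", "delta") %in% names(reg)),
            all(is.finite(reg$delta)), !anyDuplicated(reg$name))
  reg
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  n <- nchar(sequence)
  if (n < 1L) stop("empty peptide sequence (length must be 1..65)")
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!(letters %in% names(.AA_MONO)))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d",
                 letters[bad[1]], bad[1]))
  invisible(letters)
}

#' Construct a modified peptide
#'
#' A peptide sequence (1-65 canonical residues, matching the identification
#' search constraint) together with a list of modifications from the registry.
#' Positions are 1-based on the peptide; terminal modifications must sit at
#' position 1 (`N-term`) or the last residue (`C-term`), and at most one of
#' each terminal modification is allowed.
#'
#' @param sequence uppercase amino-acid string.
#' @param mods `NULL`, or a data.frame with columns `name` and `position`.
#' @param registry modification registry, default [mod_registry()].
#' @return An object of class `modified_peptide`.
#' @export
#' @examples
#' p <- modified_peptide("AGCK", data.frame(name = "carbamidomethyl", position = 3))
#' monoisotopic_mass(p)
modified_peptide <- function(sequence, mods = NULL, registry = mod_registry()) {
  letters <- .check_sequence(sequence)
  n <- length(letters)
  if (n > 65L) stop("peptide longer than 65 residues")
  if (is.null(mods))
    mods <- data.frame(name = character(), position = integer())
  stopifnot(all(c("name", "position") %in% names(mods)))
  if (nrow(mods)) {
    idx <- match(mods$name, registry$name)
    if (anyNA(idx))
      stop("unknown modification: ", mods$name[which(is.na(idx))[1]])
    site <- registry$site[idx]
    for (i in seq_len(nrow(mods))) {
      pos <- mods$position[i]
      if (pos < 1L || pos > n)
        stop("modification position out of range: ", pos)
      if (site[i] == "N-term" && pos != 1L)
        stop(mods$name[i], " is N-terminal but placed at position ", pos)
      if (site[i] == "C-term" && pos != n)
        stop(mods$name[i], " is C-terminal but placed at position ", pos)
      if (startsWith(site[i], "residue:")) {
        allowed <- strsplit(sub("^residue:", "", site[i]), "")[[1]]
        if (!(letters[pos] %in% allowed))
          stop(mods$name[i], " cannot occupy residue ", letters[pos],
               " at position ", pos)
      }
    }
    if (sum(site == "N-term") > 1L) stop("more than one N-terminal modification")
    if (sum(site == "C-term") > 1L) stop("more than one C-terminal modification")
  }
  structure(list(sequence = sequence, mods = mods, registry = registry),
            class = "modified_peptide")
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat("<modified_peptide> ", x$sequence, sep = "")
  if (nrow(x$mods))
    cat("  [", paste0(x$mods$name, "@", x$mods$position, collapse = "; "), "]",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus all modification
#' deltas. Non-canonical letters (B, J, O, U, X, Z) are rejected.
#'
#' @param p a `modified_peptide`, or a plain sequence string (taken unmodified).
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("G")  # glycine: 75.03203
monoisotopic_mass <- function(p) {
  if (is.character(p)) p <- modified_peptide(p)
  stopifnot(inherits(p, "modified_peptide"))
  letters <- strsplit(p$sequence, "")[[1]]
  m <- sum(.AA_MONO[letters]) + .WATER_MONO
  if (nrow(p$mods))
    m <- m + sum(p$registry$delta[match(p$mods$name, p$registry$name)])
  unname(m)
}

#' Mass-to-charge ratio
#'
#' `(mass + charge * proton) / charge` with the proton mass 1.007276 Da, the
#' positive-mode convention used for precursor ions.
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param charge positive integer charge state.
#' @return m/z value(s); vectorised over both arguments.
#' @export
#' @examples
#' mz(2263.1, 5)
mz <- function(mass, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (mass + charge * .PROTON_MASS) / charge
}
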