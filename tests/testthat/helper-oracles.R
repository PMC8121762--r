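# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# --- elemental-composition mass oracle -----------------------------------
# Residue formulas (C, H, N, O, S) and atomic monoisotopic masses; peptide
# mass = sum of residues + H2O.
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
.atomic_mono <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, S = 31.97207100)

oracle_mass <- function(sequence) {
  counts <- Reduce(`+`, .residue_formula[strsplit(sequence, "")[[1]]])
  counts <- counts + c(0, 2, 0, 1, 0)  # + H2O
  sum(counts * .atomic_mono[c("C", "H", "N", "O", "S")])
}

# --- brute-force global affine alignment oracle --------------------------
# Enumerates every monotone alignment path explicitly (no DP), scoring
# matches with the substitution matrix and a gap of length L at cost
# open + L * ext. Exponential; for sequences of length <= 5 only.
oracle_align_score <- function(a, b, submat, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, sc + submat[ca[i], cb[j]], "M")
    if (i <= na)
      rec(i + 1L, j, sc - ext - if (identical(last, "I")) 0 else open, "I")
    if (j <= nb)
      rec(i, j + 1L, sc - ext - if (identical(last, "D")) 0 else open, "D")
  }
  rec(1L, 1L, 0, "start")
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- misc ----------------------------------------------------------------

random_peptide <- function(len) {
  paste(sample(c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E",
                 "M","H","F","R","Y","W"), len, replace = TRUE),
        collapse = "")
}

# build a homolog_alignment from two pre-gapped strings (for projection tests)
manual_alignment <- function(aligned_a, aligned_b) {
  maps <- pepatlas:::.coord_maps(aligned_a, aligned_b)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 match_line = pepatlas:::.match_line(aligned_a, aligned_b),
                 map_a_to_b = maps$a_to_b, map_b_to_a = maps$b_to_a,
                 score = NA_real_, gene = "manual",
                 species_a = "mouse", species_b = "human"),
            class = "homolog_alignment")
}

# simple observation-row builder
obs_row <- function(prec, start, end, sample_id = "S1", area = 1e6,
                    mods = "", region = "tissue") {
  data.frame(peptide = substr(prec$sequence, start, end),
             precursor_accession = prec$accession, start = start, end = end,
             mods = mods, sample_id = sample_id, region = region,
             peak_area = area, stringsAsFactors = FALSE)
}
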