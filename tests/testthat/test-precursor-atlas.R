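# Peptide-to-precursor mapping, homolog alignment and coordinate projection.

make_db <- function(seqs, species = "mouse") {
  db <- lapply(seq_along(seqs), function(i)
    precursor(paste0("ACC", i), paste0("G", i), species, seqs[i]))
  names(db) <- vapply(db, `[[`, "", "accession")
  db
}

test_that("map_peptide finds exact occurrences with prepro coordinates", {
  db <- make_db(c("MKAILVDDQK", "AAAILVAAA"))
  full <- map_peptide("MKAILVDDQK", db)
  expect_equal(full[, c("start", "end")],
               data.frame(start = 1L, end = 10L))
  expect_false(full$ambiguous)

  multi <- map_peptide("AIL", db)
  expect_equal(nrow(multi), 2L)
  expect_true(all(multi$ambiguous))
  expect_equal(nrow(map_peptide("WWWW", db)), 0L)
  expect_error(map_peptide("AXZ", db), "unknown residue")
  expect_error(map_peptide("AAA", list()), "empty")
})

test_that("mapped coordinates match an exhaustive substring scan", {
  set.seed(21)
  db <- make_db(replicate(4, random_peptide(80)))
  for (i in 1:200) {
    p <- db[[sample(4, 1)]]
    s <- sample(1:70, 1); e <- min(80, s + sample(3:12, 1))
    pep <- substr(p$sequence, s, e)
    hits <- map_peptide(pep, db)
    # oracle: scan every start position of every precursor
    expected <- do.call(rbind, lapply(db, function(q) {
      n <- nchar(q$sequence); L <- nchar(pep)
      st <- Filter(function(k) substr(q$sequence, k, k + L - 1) == pep,
                   seq_len(n - L + 1))
      if (!length(st)) return(NULL)
      data.frame(accession = q$accession, start = st, end = st + L - 1)
    }))
    expect_equal(hits$start, expected$start)
    expect_equal(hits$end, as.integer(expected$end))
    expect_equal(hits$accession, expected$accession)
    # completeness: reported slices equal the peptide
    for (k in seq_len(nrow(hits)))
      expect_identical(substr(db[[hits$accession[k]]]$sequence,
                              hits$start[k], hits$end[k]), pep)
  }
})

test_that("peptide labels follow the p<start>-<end> convention", {
  expect_identical(peptide_label("Gast", 59, 79), "Gast p59-79")
  expect_identical(peptide_label("ChgA", 435, 462, TRUE), "ChgA p435-462a")
})

test_that("identical homologs align gap-free with an all-identity match line", {
  a <- precursor("m1", "Gene", "mouse", "MKAILVDDQKRST")
  b <- precursor("h1", "Gene", "human", "MKAILVDDQKRST")
  al <- align_homologs(a, b)
  expect_identical(al$aligned_a, a$sequence)
  expect_identical(al$match_line, strrep("|", nchar(a$sequence)))
  expect_equal(al$map_a_to_b, seq_len(nchar(a$sequence)))
})

test_that("a single substitution yields exactly one non-identity column", {
  a <- precursor("m1", "Gene", "mouse", "AAA")
  b <- precursor("h1", "Gene", "human", "AAT")
  al <- align_homologs(a, b)
  expect_equal(nchar(al$aligned_a), 3L)
  expect_equal(sum(strsplit(al$match_line, "")[[1]] != "|"), 1L)
})

test_that("alignment scores equal brute-force enumeration of all alignments", {
  set.seed(22)
  alpha <- c("A", "C", "G", "T")  # 4-letter amino-acid test alphabet
  for (i in 1:25) {
    sa <- paste(sample(alpha, sample(1:5, 1), replace = TRUE), collapse = "")
    sb <- paste(sample(alpha, sample(1:5, 1), replace = TRUE), collapse = "")
    al <- align_homologs(precursor("m", "G", "mouse", sa),
                         precursor("h", "G", "human", sb))
    expect_equal(al$score, oracle_align_score(sa, sb, blosum62),
                 info = paste(sa, sb))
  }
})

test_that("alignment score is symmetric and gaps reconstruct the inputs", {
  set.seed(23)
  for (i in 1:10) {
    sa <- random_peptide(sample(10:40, 1))
    sb <- random_peptide(sample(10:40, 1))
    ab <- align_homologs(precursor("m", "G", "mouse", sa),
                         precursor("h", "G", "human", sb))
    ba <- align_homologs(precursor("m", "G", "mouse", sb),
                         precursor("h", "G", "human", sa))
    expect_equal(ab$score, ba$score)
    expect_identical(gsub("-", "", ab$aligned_a), sa)
    expect_identical(gsub("-", "", ab$aligned_b), sb)
    cols <- strsplit(ab$match_line, "")[[1]]
    ca <- strsplit(ab$aligned_a, "")[[1]]; cb <- strsplit(ab$aligned_b, "")[[1]]
    expect_true(all((cols == "|") == (ca == cb & ca != "-")))
  }
})

test_that("interval projection matches a position-by-position oracle", {
  id <- manual_alignment("MKAIL", "MKAIL")
  expect_equal(project_interval(id, 2, 4), list(start = 2L, end = 4L,
                                                coverage = 1))
  gapped <- manual_alignment("AAACCC", "AAA---")
  empty <- project_interval(gapped, 4, 6)
  expect_true(is.na(empty$start))
  expect_equal(empty$coverage, 0)
  expect_error(project_interval(gapped, 5, 9), "out of range")

  set.seed(24)
  for (i in 1:50) {
    n <- 12
    ca <- sample(c("A", "K", "-"), n, TRUE, prob = c(.4, .4, .2))
    cb <- sample(c("G", "R", "-"), n, TRUE, prob = c(.4, .4, .2))
    keep <- !(ca == "-" & cb == "-")
    ca <- ca[keep]; cb <- cb[keep]
    if (!any(ca != "-") || !any(cb != "-")) next
    al <- manual_alignment(paste(ca, collapse = ""), paste(cb, collapse = ""))
    la <- sum(ca != "-")
    s <- sample(seq_len(la), 1)
    e <- if (s == la) la else sample(s:la, 1)
    got <- project_interval(al, s, e)
    # oracle: walk columns and collect b-positions under a-positions s..e
    pa <- cumsum(ca != "-"); pb <- cumsum(cb != "-")
    img <- pb[ca != "-" & cb != "-" & pa >= s & pa <= e]
    if (!length(img)) {
      expect_true(is.na(got$start))
    } else {
      expect_equal(got$start, min(img))
      expect_equal(got$end, max(img))
      expect_equal(got$coverage, length(img) / (e - s + 1))
    }
    # round-trip: each position of [s,e] with an image is inside the
    # back-projection of the forward projection
    if (length(img)) {
      back <- project_interval(al, got$start, got$end, from = "b")
      has_img <- which(!is.na(al$map_a_to_b[s:e])) + s - 1L
      expect_true(all(has_img >= back$start & has_img <= back$end))
    }
  }
})

test_that("alignment-plot documents apply the area threshold and PTM flags", {
  cfg <- synthetic_config(seed = 5)
  pair <- generate_precursor_pair(cfg, "ChgA")
  db <- list(pair$mouse, pair$human)
  names(db) <- c(pair$mouse$accession, pair$human$accession)
  obs <- rbind(
    obs_row(pair$mouse, 435, 462, area = 1e5,
            mods = paste0("amidation@", 462 - 435 + 1)),
    obs_row(pair$mouse, 200, 240, area = 1e3))
  doc <- build_alignment_plot(db, "ChgA", obs, min_area = 1e4)
  expect_equal(nrow(doc$peptides), 1L)
  expect_true(doc$peptides$amidated[1])
  expect_error(build_alignment_plot(db, "Nope", obs), "unknown gene")

  none <- build_alignment_plot(db, "ChgA", obs[0, ], min_area = 1e4)
  expect_equal(nrow(none$peptides), 0L)
  expect_s3_class(none$alignment, "homolog_alignment")

  tsv <- tempfile(fileext = ".tsv"); svg <- tempfile(fileext = ".svg")
  write_plot_tsv(doc, tsv); write_plot_svg(doc, svg)
  expect_true(file.exists(tsv))
  expect_match(readLines(svg)[1], "<svg")
  expect_true(any(grepl("fill=\"red\"", readLines(svg))))
})
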