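# Seeded synthetic-data generator. Produces every input the pipeline
# consumes — precursor FASTA, peptide observation tables with convertase
# products, PTMs and exoproteolytic ladders, lean/DIO cohort matrices with a
# planted colonic effect, basal/stimulated secretion tables with a
# constitutive decoy, and one-compartment PK time courses — with the
# statistical structure the analysis assumes.

# Independent RNG substream per artefact: the seed is derived from the master
# seed and an artefact label, so adding artefacts never perturbs existing ones.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

#' Synthetic study configuration
#'
#' Defaults define the shipped study conditions: homolog identity 0.85,
#' exoprotease ladders up to 2 residues, log-normal peak areas around 1e6
#' (sdlog 0.5), a 4-fold decrease of the designated L-cell precursors in the
#' DIO distal colon, 4-fold stimulated secretion for vesicular peptides, 15%
#' random missingness, 8 animals per group per region, and PK truth built on
#' terminal half-lives of 18.1 min (gastrin-derived candidate, F = 0.7) and
#' 36.0 min (granin-derived candidate, F = 0.5) with absorption five times
#' faster than elimination.
#'
#' @param seed master seed (integer); every artefact derives its own RNG
#'   stream from `(seed, label)`.
#' @param homolog_identity target mouse/human sequence identity in (0, 1].
#' @param ladder_depth maximum terminal trim (residues) for ladder artefacts.
#' @param abundance_meanlog,abundance_sdlog log-normal peak-area parameters.
#' @param dio_effect fold-decrease applied to designated precursors in the
#'   DIO distal colon.
#' @param stimulation_fold fold over basal for vesicular peptides.
#' @param noise_cv multiplicative coefficient of variation for secretion and
#'   PK noise.
#' @param missing_rate probability a cohort cell is missing.
#' @param n_per_group animals per group per region in the cohort.
#' @param pyroglu_prob probability of N-terminal pyroglutamate at Q/E.
#' @param ladder_prob probability each possible trim variant is observed.
#' @param n_samples tissue samples per species in the observation table.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 17L,
                             homolog_identity = 0.85,
                             ladder_depth = 2L,
                             abundance_meanlog = log(1e6),
                             abundance_sdlog = 0.5,
                             dio_effect = 4,
                             stimulation_fold = 4,
                             noise_cv = 0.10,
                             missing_rate = 0.15,
                             n_per_group = 8L,
                             pyroglu_prob = 0.5,
                             ladder_prob = 0.7,
                             n_samples = 3L) {
  stopifnot(homolog_identity > 0, homolog_identity <= 1,
            ladder_depth >= 0L, dio_effect > 0, stimulation_fold > 0,
            noise_cv >= 0, missing_rate >= 0, missing_rate < 1)
  structure(list(seed = as.integer(seed),
                 homolog_identity = homolog_identity,
                 ladder_depth = as.integer(ladder_depth),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 dio_effect = dio_effect,
                 stimulation_fold = stimulation_fold,
                 noise_cv = noise_cv,
                 missing_rate = missing_rate,
                 n_per_group = as.integer(n_per_group),
                 pyroglu_prob = pyroglu_prob,
                 ladder_prob = ladder_prob,
                 n_samples = as.integer(n_samples)),
            class = "synthetic_config")
}

.cohort_regions <- c("stomach", "proximal_SI", "distal_SI",
                     "mid_colon", "distal_colon")

#' Planted gene plan of the synthetic study
#'
#' Eight precursor genes with planted mature-peptide spans: three candidate
#' analogues (a gastrin-like p59-79, a granin-like amidated p435-462, a
#' somatostatin-like p25-36 starting at the signal boundary), three
#' DIO-decreased L-cell precursors (Pyy/Gcg/Insl5-like), a constitutive
#' cytosolic decoy (Tyb4-like, non-basic flanks) and a filler (Sct-like).
#'
#' @return named list; each element has `gene`, `length`, `signal_end`,
#'   `human_abundant` and a `spans` data.frame (`start`, `end`, `amidated`,
#'   `class`, `candidate`, `dio`).
#' @export
synthetic_gene_plan <- function() {
  span <- function(start, end, amidated = FALSE, class = "vesicular",
                   candidate = FALSE, dio = FALSE)
    data.frame(start = start, end = end, amidated = amidated, class = class,
               candidate = candidate, dio = dio, stringsAsFactors = FALSE)
  list(
    Gast = list(gene = "Gast", length = 101L, signal_end = 21L,
                human_abundant = TRUE,
                spans = rbind(span(59, 79, candidate = TRUE),
                              span(26, 50, class = "basal_undetected"))),
    ChgA = list(gene = "ChgA", length = 470L, signal_end = 18L,
                human_abundant = TRUE,
                spans = rbind(span(435, 462, amidated = TRUE, candidate = TRUE),
                              span(200, 240, class = "basal_undetected"))),
    Sst  = list(gene = "Sst", length = 116L, signal_end = 24L,
                human_abundant = TRUE,
                spans = span(25, 36, candidate = TRUE)),
    Pyy  = list(gene = "Pyy", length = 98L, signal_end = 28L,
                human_abundant = FALSE,
                spans = span(29, 64, amidated = TRUE, dio = TRUE)),
    Gcg  = list(gene = "Gcg", length = 180L, signal_end = 20L,
                human_abundant = FALSE,
                spans = rbind(span(98, 128, amidated = TRUE, dio = TRUE),
                              span(33, 61))),
    Insl5 = list(gene = "Insl5", length = 135L, signal_end = 22L,
                 human_abundant = FALSE,
                 spans = span(23, 48, class = "basal_undetected", dio = TRUE)),
    Tyb4 = list(gene = "Tyb4", length = 60L, signal_end = NA,
                human_abundant = FALSE,
                spans = span(8, 50, class = "constitutive")),
    Sct  = list(gene = "Sct", length = 120L, signal_end = 27L,
                human_abundant = FALSE,
                spans = span(28, 54))
  )
}

# residues whose identity is structural (cut sites, amidation motifs); these
# are never mutated in the human homolog
.planted_positions <- function(plan_gene) {
  keep <- integer()
  for (i in seq_len(nrow(plan_gene$spans))) {
    sp <- plan_gene$spans[i, ]
    keep <- c(keep, sp$start - (2:1), sp$end + (1:3))
  }
  keep[keep >= 1L & keep <= plan_gene$length]
}

.plant_sequence <- function(plan_gene, cfg) {
  set.seed(derive_seed(cfg$seed, paste0("precursor_", plan_gene$gene)))
  aa <- names(.AA_MONO)
  s <- sample(aa, plan_gene$length, replace = TRUE)
  for (i in seq_len(nrow(plan_gene$spans))) {
    sp <- plan_gene$spans[i, ]
    if (sp$class == "constitutive") {
      # cytosolic decoy: force non-basic flanks
      for (p in c(sp$start - (2:1), sp$end + (1:2)))
        if (p >= 1L && p <= plan_gene$length && s[p] %in% c("K", "R"))
          s[p] <- "A"
    } else {
      at_signal <- !is.na(plan_gene$signal_end) &&
        sp$start - 1L == plan_gene$signal_end
      if (!at_signal && sp$start >= 3L) {
        s[sp$start - 2L] <- "K"; s[sp$start - 1L] <- "R"
      }
      if (sp$amidated) {
        s[sp$end + 1L] <- "G"; s[sp$end + 2L] <- "K"; s[sp$end + 3L] <- "R"
      } else {
        s[sp$end + 1L] <- "K"; s[sp$end + 2L] <- "R"
      }
    }
  }
  paste(s, collapse = "")
}

#' Generate a mouse/human precursor homolog pair
#'
#' The mouse sequence is random with planted signal peptide, dibasic
#' convertase sites and amidation motifs at the planned spans; the human
#' homolog is derived by point substitutions at non-structural positions to
#' hit the configured identity. Deterministic under the configured seed.
#'
#' @param cfg a `synthetic_config`.
#' @param gene gene symbol from [synthetic_gene_plan()].
#' @return list with elements `mouse` and `human`, both `precursor` objects.
#' @export
generate_precursor_pair <- function(cfg, gene) {
  plan <- synthetic_gene_plan()[[gene]]
  if (is.null(plan)) stop("unknown gene in synthetic plan: ", gene)
  mouse_seq <- .plant_sequence(plan, cfg)
  n <- plan$length
  n_mut <- round((1 - cfg$homolog_identity) * n)
  mutable <- setdiff(seq_len(n), .planted_positions(plan))
  if (n_mut > length(mutable))
    stop("identity target unreachable: ", n_mut, " mutations needed but only ",
         length(mutable), " mutable positions")
  set.seed(derive_seed(cfg$seed, paste0("homolog_", gene)))
  s <- strsplit(mouse_seq, "")[[1]]
  for (p in sample(mutable, n_mut))
    s[p] <- sample(setdiff(names(.AA_MONO), s[p]), 1L)
  human_seq <- paste(s, collapse = "")
  list(mouse = precursor(paste0("SYNM_", gene), gene, "mouse", mouse_seq,
                         plan$signal_end),
       human = precursor(paste0("SYNH_", gene), gene, "human", human_seq,
                         plan$signal_end))
}

.one_observation <- function(prec, start, end, mods_df, sample_id, region,
                             area) {
  data.frame(peptide = substr(prec$sequence, start, end),
             precursor_accession = prec$accession,
             start = start, end = end,
             mods = .format_mods(mods_df),
             sample_id = sample_id, region = region, peak_area = area,
             stringsAsFactors = FALSE)
}

.span_mods <- function(prec, start, end, amidated, pyroglu) {
  len <- end - start + 1L
  mods <- data.frame(name = character(), position = integer())
  first <- substr(prec$sequence, start, start)
  if (pyroglu && first %in% c("Q", "E"))
    mods <- rbind(mods, data.frame(name = ifelse(first == "Q", "pyroglu_Q",
                                                 "pyroglu_E"), position = 1L))
  cys <- which(strsplit(substr(prec$sequence, start, end), "")[[1]] == "C")
  if (length(cys))
    mods <- rbind(mods, data.frame(name = "carbamidomethyl", position = cys))
  if (amidated)
    mods <- rbind(mods, data.frame(name = "amidation", position = len))
  mods
}

#' Simulate prohormone processing for one precursor
#'
#' Emits convertase products at the planted spans with fixed cysteine
#' carbamidomethylation, C-terminal amidation where the motif was planted,
#' probabilistic N-terminal pyroglutamate at Gln/Glu, and exoprotease ladder
#' variants trimmed by up to `ladder_depth` residues whose areas never exceed
#' the canonical product's. Areas are log-normal; every product is an exact
#' substring of the precursor at its stated coordinates.
#'
#' @param prec a `precursor` produced by [generate_precursor_pair()].
#' @param cfg a `synthetic_config`.
#' @param abundant override the plan's abundance tier (log-normal around 1e6
#'   when `TRUE`, around 5e3 when `FALSE`).
#' @return observation data.frame (see [read_observations()]).
#' @export
simulate_processing <- function(prec, cfg, abundant = TRUE) {
  plan <- synthetic_gene_plan()[[prec$gene]]
  if (is.null(plan)) stop("unknown gene in synthetic plan: ", prec$gene)
  set.seed(derive_seed(cfg$seed, paste0("proc_", prec$accession)))
  meanlog <- if (abundant) cfg$abundance_meanlog else log(5e3)
  samples <- paste0(toupper(substr(prec$species, 1, 1)), seq_len(cfg$n_samples))
  out <- list()
  for (i in seq_len(nrow(plan$spans))) {
    sp <- plan$spans[i, ]
    pyro <- stats::runif(1) < cfg$pyroglu_prob
    for (smp in samples) {
      canonical_area <- stats::rlnorm(1, meanlog, cfg$abundance_sdlog)
      mods <- .span_mods(prec, sp$start, sp$end, sp$amidated, pyro)
      out[[length(out) + 1L]] <-
        .one_observation(prec, sp$start, sp$end, mods, smp, "tissue",
                         canonical_area)
      if (cfg$ladder_depth > 0L) for (d in seq_len(cfg$ladder_depth)) {
        if (stats::runif(1) < cfg$ladder_prob) {  # N-terminal trim
          mods_t <- .span_mods(prec, sp$start + d, sp$end, sp$amidated, FALSE)
          out[[length(out) + 1L]] <-
            .one_observation(prec, sp$start + d, sp$end, mods_t, smp, "tissue",
                             canonical_area * stats::runif(1, 0.03, 0.6))
        }
        if (stats::runif(1) < cfg$ladder_prob) {  # C-terminal trim, amide lost
          mods_t <- .span_mods(prec, sp$start, sp$end - d, FALSE, pyro)
          out[[length(out) + 1L]] <-
            .one_observation(prec, sp$start, sp$end - d, mods_t, smp, "tissue",
                             canonical_area * stats::runif(1, 0.03, 0.6))
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic precursor atlas and observation table
#'
#' @param cfg a `synthetic_config`.
#' @return list with `db` (named list of `precursor`, mouse and human for all
#'   planned genes) and `observations` (both species; human observations are
#'   abundant only for the candidate genes).
#' @export
generate_atlas <- function(cfg) {
  plan <- synthetic_gene_plan()
  db <- list()
  obs <- list()
  for (g in names(plan)) {
    pair <- generate_precursor_pair(cfg, g)
    db[[pair$mouse$accession]] <- pair$mouse
    db[[pair$human$accession]] <- pair$human
    obs[[length(obs) + 1L]] <- simulate_processing(pair$mouse, cfg)
    obs[[length(obs) + 1L]] <-
      simulate_processing(pair$human, cfg, abundant = plan[[g]]$human_abundant)
  }
  list(db = db, observations = do.call(rbind, obs))
}

.cohort_peptides <- function() {
  plan <- synthetic_gene_plan()
  rows <- list()
  for (g in names(plan)) for (i in seq_len(nrow(plan[[g]]$spans))) {
    sp <- plan[[g]]$spans[i, ]
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g, start = sp$start, end = sp$end,
                 amidated = sp$amidated, dio = sp$dio,
                 peptide = peptide_label(g, sp$start, sp$end, sp$amidated),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate the lean-vs-DIO cohort abundance matrix
#'
#' One planted canonical peptide per span, across five gut regions with
#' `n_per_group` animals per group per region. Cells are log-normal areas
#' with random missingness; the designated L-cell peptides are reduced by
#' `dio_effect` in the DIO group in the distal colon only — everything else
#' is exchangeable between groups.
#'
#' @param cfg a `synthetic_config`.
#' @return an `abundance_matrix` (groups `lean`/`DIO`, five regions).
#' @export
generate_cohort <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "cohort"))
  peps <- .cohort_peptides()
  samples <- expand.grid(idx = seq_len(cfg$n_per_group),
                         group = c("lean", "DIO"),
                         region = .cohort_regions,
                         stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$group, samples$region, samples$idx,
                             sep = "_")
  areas <- matrix(stats::rlnorm(nrow(peps) * nrow(samples),
                                cfg$abundance_meanlog, cfg$abundance_sdlog),
                  nrow = nrow(peps),
                  dimnames = list(peps$peptide, samples$sample_id))
  hit <- peps$dio
  dio_cols <- samples$group == "DIO" & samples$region == "distal_colon"
  areas[hit, dio_cols] <- areas[hit, dio_cols] / cfg$dio_effect
  areas[matrix(stats::runif(length(areas)) < cfg$missing_rate,
               nrow = nrow(areas))] <- NA
  abundance_matrix(areas, samples[, c("sample_id", "group", "region")])
}

#' Generate basal/stimulated secretion tables
#'
#' Vesicular peptides get a stimulated/basal fold around `stimulation_fold`;
#' the constitutive cytosolic decoy stays around fold 1; `basal_undetected`
#' peptides have `NA` basal areas so no fold can be computed.
#'
#' @param cfg a `synthetic_config`.
#' @return secretion data.frame with columns `peptide`, `region`, `class`,
#'   `basal_area`, `stimulated_area`.
#' @export
generate_secretion <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "secretion"))
  plan <- synthetic_gene_plan()
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  rows <- list()
  for (g in names(plan)) for (i in seq_len(nrow(plan[[g]]$spans))) {
    sp <- plan[[g]]$spans[i, ]
    lab <- peptide_label(g, sp$start, sp$end, sp$amidated)
    for (reg in .cohort_regions) {
      basal <- stats::rlnorm(1, log(1e5), 0.3)
      fold <- switch(sp$class,
                     vesicular = cfg$stimulation_fold,
                     constitutive = 1,
                     basal_undetected = cfg$stimulation_fold)
      stim <- basal * fold * stats::rlnorm(1, 0, sdlog)
      if (sp$class == "basal_undetected") basal <- NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(peptide = lab, region = reg, class = sp$class,
                   basal_area = basal, stimulated_area = stim,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground-truth PK parameters of the synthetic study
#'
#' Terminal half-lives follow the study's reported values for the two
#' injectable candidates (18.1 and 36.0 min); absorption is five times faster
#' than elimination, the distribution volume is 0.1 L/kg, and subcutaneous
#' bioavailability is 0.7 (gastrin-like) and 0.5 (granin-like).
#'
#' @return named list per analyte: `t_half`, `ka_mult`, `V_L_per_kg`, `F`.
#' @export
pk_truth <- function() {
  list(`Gast p59-79` = list(t_half = 18.1, ka_mult = 5, V_L_per_kg = 0.1,
                            F = 0.7),
       `ChgA p435-462a` = list(t_half = 36.0, ka_mult = 5, V_L_per_kg = 0.1,
                               F = 0.5))
}

#' Generate a paired i.v./s.c. PK dataset
#'
#' Concentrations (nM) follow the closed-form one-compartment solutions for
#' the analyte's ground-truth parameters, with multiplicative log-normal
#' noise of the configured coefficient of variation. The molecular weight
#' used for the molar conversion is the monoisotopic mass of the planted
#' peptide. Sampling emulates the study's serial design over 90 min.
#'
#' @param cfg a `synthetic_config`.
#' @param analyte name from [pk_truth()].
#' @param design list with `times_iv`, `times_sc` (min) and `dose` (mg/kg);
#'   defaults: 8 points over 90 min, 1 mg/kg.
#' @param truth optional override of the analyte's ground-truth parameters.
#' @param replicate integer tag mixed into the RNG stream so replicate
#'   datasets are independent.
#' @return list with `iv` and `sc` `pk_dataset` objects and `truth`.
#' @export
generate_pk <- function(cfg, analyte, design = NULL, truth = NULL,
                        replicate = 1L) {
  if (is.null(truth)) truth <- pk_truth()[[analyte]]
  if (is.null(truth)) stop("unknown analyte: ", analyte)
  if (is.null(design))
    design <- list(times_iv = c(2, 5, 10, 15, 30, 45, 60, 90),
                   times_sc = c(5, 10, 15, 20, 30, 45, 60, 90),
                   dose = 1)
  plan <- synthetic_gene_plan()
  gene <- sub(" .*$", "", analyte)
  mw <- if (!is.null(plan[[gene]])) {
    cfg0 <- cfg; pair <- generate_precursor_pair(cfg0, gene)
    sp <- plan[[gene]]$spans[plan[[gene]]$spans$candidate, , drop = FALSE]
    if (!nrow(sp)) sp <- plan[[gene]]$spans[1, , drop = FALSE]
    monoisotopic_mass(substr(pair$mouse$sequence, sp$start[1], sp$end[1]))
  } else 3000
  ke <- log(2) / truth$t_half
  ka <- truth$ka_mult * ke
  V <- mw * truth$V_L_per_kg / 1e7   # dose-unit (mg/kg) per nM
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  set.seed(derive_seed(cfg$seed, paste0("pk_", analyte, "_", replicate)))
  noisy <- function(mu) if (cfg$noise_cv == 0) mu else
    mu * stats::rlnorm(length(mu), 0, sdlog)
  c_iv <- noisy(pk_simulate(list(ke = ke, V = V), design$dose, "iv",
                            design$times_iv))
  c_sc <- noisy(pk_simulate(list(ke = ke, V = V, ka = ka, F = truth$F),
                            design$dose, "sc", design$times_sc))
  list(iv = pk_dataset(design$times_iv, c_iv, "iv", design$dose, "nM",
                       analyte, mw),
       sc = pk_dataset(design$times_sc, c_sc, "sc", design$dose, "nM",
                       analyte, mw),
       truth = c(truth, list(ke = ke, ka = ka, V = V, mw = mw)))
}

#' Write the complete synthetic study to disk
#'
#' Emits the precursor FASTA, the observation TSV (both species), the cohort
#' matrix and sample sheet, the secretion table, the paired PK TSVs per
#' analyte, and a JSON manifest with the ground-truth parameters.
#'
#' @param cfg a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
simulate_all <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- generate_atlas(cfg)
  write_precursors(atlas$db, file.path(out_dir, "precursors.fasta"))
  write_observations(atlas$observations, file.path(out_dir, "observations.tsv"))
  cohort <- generate_cohort(cfg)
  write_abundance_matrix(cohort, file.path(out_dir, "cohort_matrix.tsv"),
                         file.path(out_dir, "cohort_samples.tsv"))
  secretion <- generate_secretion(cfg)
  utils::write.table(secretion, file.path(out_dir, "secretion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truths <- list()
  for (analyte in names(pk_truth())) {
    pk <- generate_pk(cfg, analyte)
    tag <- gsub("[^A-Za-z0-9]+", "_", analyte)
    write_pk_dataset(pk$iv, file.path(out_dir, paste0("pk_", tag, "_iv.tsv")))
    write_pk_dataset(pk$sc, file.path(out_dir, paste0("pk_", tag, "_sc.tsv")))
    truths[[analyte]] <- pk$truth
  }
  manifest <- list(config = unclass(cfg), pk_truth = truths,
                   genes = names(synthetic_gene_plan()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
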