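## Synthetic kcat datasets.
##
## The generator emulates the statistical structure the pipeline assumes:
## enzyme families (homolog clusters at controlled sequence identity),
## reactions drawn from a library of hand-balanced small-molecule templates
## with planted additive effects on log10 kcat, replicate measurements with
## multiplicative noise, and decoy rows that each curation filter should
## remove. Clean rows are generated so that no curation rule fires on them:
## an enzyme's reactions are drawn from a narrow window of template effects,
## and aggregated values are lifted where needed to stay strictly inside the
## 10x (within-enzyme) and 100x (within-reaction/EC) margins, so the decoy
## confusion matrix is exact by construction.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic dataset configuration
#'
#' Defaults give roughly 3000 measurement rows: 180 enzyme families of 1-6
#' members at identity levels 99/90/75/60/45%, 40 balanced reaction
#' templates, reaction/family effect standard deviations 0.9/0.7 log10
#' units, measurement noise 0.4, replicate scatter 0.15, and decoys planted
#' at the configured rates.
#'
#' @param n_families Number of enzyme families.
#' @param family_size_range Inclusive range of family sizes (1 = singleton).
#' @param identity_levels Target percent identities of family members to
#'   their family root.
#' @param n_reaction_templates Number of clean reaction templates used.
#' @param reactions_per_enzyme_range Reactions catalysed per enzyme.
#' @param effect_sd_reaction,effect_sd_family,noise_sd Standard deviations
#'   of the log10-kcat components.
#' @param replicate_sd Replicate-level log10 scatter.
#' @param n_replicates_range Replicates per enzyme-reaction pair.
#' @param mu_log10 Grand mean of log10 kcat.
#' @param seq_length_range Root sequence length range (residues).
#' @param decoy_rates Fractions (of clean rows) of planted decoys per class.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 180L,
                             family_size_range = c(1L, 6L),
                             identity_levels = c(99, 90, 75, 60, 45),
                             n_reaction_templates = 40L,
                             reactions_per_enzyme_range = c(1L, 3L),
                             effect_sd_reaction = 0.9,
                             effect_sd_family = 0.7,
                             noise_sd = 0.4,
                             replicate_sd = 0.15,
                             n_replicates_range = c(1L, 3L),
                             mu_log10 = 1.0,
                             seq_length_range = c(200L, 400L),
                             decoy_rates = list(duplicates = 0.05,
                                                outliers = 0.02,
                                                mass_imbalanced = 0.02,
                                                non_natural_10x = 0.03,
                                                suboptimal_100x = 0.03),
                             seed = 1L) {
  stopifnot(all(unlist(decoy_rates) >= 0), all(unlist(decoy_rates) <= 1),
            effect_sd_reaction >= 0, effect_sd_family >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate enzyme families
#'
#' Each family has a random root sequence; further members are point-mutant
#' homologs hitting the configured identity levels (substitutions only, so
#' the realised global identity is within about two points of the target).
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble with `enzyme_id`, `sequence`, `family`, `target_identity`.
#' @export
generate_enzymes <- function(cfg) {
  with_local_seed(derive_seed(cfg$seed, "enzymes"), {
    rows <- list()
    for (f in seq_len(cfg$n_families)) {
      len <- sample_range(cfg$seq_length_range[1], cfg$seq_length_range[2])
      root <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      size <- sample_range(cfg$family_size_range[1], cfg$family_size_range[2])
      seqs <- root
      targets <- 100
      if (size > 1L) {
        for (j in seq_len(size - 1L)) {
          lvl <- cfg$identity_levels[(j - 1L) %% length(cfg$identity_levels)
                                     + 1L]
          n_sub <- round((1 - lvl / 100) * len)
          s <- strsplit(root, "")[[1]]
          if (n_sub > 0) {
            pos <- sample(len, n_sub)
            s[pos] <- vapply(s[pos], function(a) {
              sample(setdiff(AA20, a), 1)
            }, character(1))
          }
          seqs <- c(seqs, paste(s, collapse = ""))
          targets <- c(targets, lvl)
        }
      }
      rows[[f]] <- tibble(
        enzyme_id = sprintf("F%03dM%02d", f, seq_len(size)),
        sequence = seqs,
        family = f,
        target_identity = targets
      )
    }
    dplyr::bind_rows(rows)
  })
}

# Hand-balanced reaction template library. Every clean template conserves
# atoms exactly (isomerisations, ester hydrolyses, quinone-coupled
# oxidations, transaminations), so mass balance holds by construction; the
# imbalanced list drops water from ester hydrolyses and is used only for
# mass-imbalance decoys.
reaction_template_library <- function() {
  acids <- c("C(=O)O", "CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "c1ccccc1C(=O)O")
  alkyls <- c("C", "CC", "CCC", "C(C)C")
  esters <- outer(acids, alkyls, function(a, r) paste0(a, r))
  alcohols <- vapply(alkyls, function(r) paste0("O", r), character(1))

  hydrolysis <- character(0)
  for (i in seq_along(acids)) {
    for (j in seq_along(alkyls)) {
      hydrolysis <- c(hydrolysis, paste0(
        esters[i, j], ".O>>", acids[i], ".", alcohols[j]))
    }
  }

  quinone <- "O=C1C=CC(=O)C=C1"
  hydroquinone <- "Oc1ccc(O)cc1"
  ox_pairs <- list(c("CCO", "CC=O"), c("CCCO", "CCC=O"),
                   c("CCCCO", "CCCC=O"), c("OCc1ccccc1", "O=Cc1ccccc1"),
                   c("CC(O)C", "CC(C)=O"), c("CCC(O)C", "CCC(C)=O"),
                   c("CCCCCO", "CCCCC=O"), c("CCCC(O)C", "CCCC(C)=O"))
  oxidation <- vapply(ox_pairs, function(p) {
    paste0(p[1], ".", quinone, ">>", p[2], ".", hydroquinone)
  }, character(1))

  isomer_pairs <- list(
    c("CCCCO", "CCC(C)O"), c("CCCO", "CC(C)O"), c("CCCCCO", "CCCC(C)O"),
    c("CCCCCCO", "CCCCC(C)O"), c("CCCC=O", "CCC(C)=O"),
    c("CCCCC=O", "CCCC(C)=O"), c("OCC1OC(O)C(O)C(O)C1O",
                                 "OCC1(O)OC(CO)C(O)C1O"),
    c("CCOC", "CCCO"), c("CCOCC", "CCCCO"), c("CC(C)CO", "CCCCO"),
    c("CC(C)CCO", "CCCCCO"), c("CCC(C)O", "CC(C)CO"),
    c("CCCCCC=O", "CCCCC(C)=O"), c("CCCCCCCO", "CCCCCC(C)O"),
    c("CCCCOC", "CCCCCO"), c("CCCOCC", "CCCCCO"),
    c("CC(C)C(C)O", "CCCC(C)O"), c("CC(C)CC=O", "CCCCC=O")
  )
  isomerisation <- vapply(isomer_pairs, function(p) {
    paste0(p[1], ">>", p[2])
  }, character(1))

  keto <- c(pyr = "CC(=O)C(=O)O", oaa = "OC(=O)CC(=O)C(=O)O",
            akg = "OC(=O)CCC(=O)C(=O)O")
  amino <- c(pyr = "CC(N)C(=O)O", oaa = "OC(=O)CC(N)C(=O)O",
             akg = "OC(=O)CCC(N)C(=O)O")
  transamination <- character(0)
  for (a in names(keto)) {
    for (b in names(keto)) {
      if (a == b) next
      transamination <- c(transamination, paste0(
        keto[[a]], ".", amino[[b]], ">>", amino[[a]], ".", keto[[b]]))
    }
  }

  imbalanced <- character(0)
  for (i in seq_along(acids)) {
    for (j in seq_along(alkyls)) {
      imbalanced <- c(imbalanced, paste0(
        esters[i, j], ">>", acids[i], ".", alcohols[j]))
    }
  }

  list(
    balanced = c(isomerisation, hydrolysis, oxidation, transamination),
    imbalanced = imbalanced
  )
}

#' Generate reaction templates with planted effects
#'
#' Draws `n_reaction_templates` balanced templates from the internal library
#' and assigns each a ground-truth additive effect on log10 kcat plus a
#' synthetic EC number. All templates are mass-balanced and have distinct
#' canonical keys; a reserve of balanced decoy templates and a list of
#' mass-imbalanced templates are returned alongside.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `templates` (tibble: `template_id`, `reaction_smiles`,
#'   `reaction_key`, `ec`, `effect`), `decoy_pool`, `imbalanced`.
#' @export
generate_reactions <- function(cfg) {
  lib <- reaction_template_library()
  n <- cfg$n_reaction_templates
  if (n > length(lib$balanced) - 6L) {
    abort(sprintf("at most %d clean reaction templates available",
                  length(lib$balanced) - 6L))
  }
  with_local_seed(derive_seed(cfg$seed, "reactions"), {
    ord <- sample(length(lib$balanced))
    clean_smiles <- lib$balanced[ord[seq_len(n)]]
    decoy_pool <- lib$balanced[ord[(n + 1L):length(ord)]]
    keys <- vapply(clean_smiles, function(s) as_kcat_reaction(s)$key,
                   character(1))
    stopifnot(!anyDuplicated(keys))
    templates <- tibble(
      template_id = seq_len(n),
      reaction_smiles = unname(clean_smiles),
      reaction_key = unname(keys),
      ec = sprintf("9.9.%d.%d", seq_len(n) %/% 100 + 1L, seq_len(n) %% 100),
      effect = stats::rnorm(n, 0, cfg$effect_sd_reaction)
    )
    list(templates = templates, decoy_pool = unname(decoy_pool),
         imbalanced = lib$imbalanced)
  })
}

# Lift aggregated clean values until no curation rule can fire on them:
# within an enzyme all pairs stay within 10^0.95 of the enzyme maximum, and
# within a template (reaction key == EC group) within 10^1.9 of the template
# maximum. Lifting only raises values, so the loop converges.
enforce_clean_margins <- function(pairs, enzyme_margin = 0.95,
                                  template_margin = 1.9) {
  for (iter in 1:50) {
    changed <- FALSE
    mx_e <- tapply(pairs$y_agg, pairs$sequence, max)
    lo_e <- unname(mx_e[pairs$sequence]) - enzyme_margin
    low <- pairs$y_agg < lo_e
    if (any(low)) {
      pairs$y_agg[low] <- lo_e[low]
      changed <- TRUE
    }
    mx_t <- tapply(pairs$y_agg, pairs$template_id, max)
    lo_t <- unname(mx_t[as.character(pairs$template_id)]) - template_margin
    low <- pairs$y_agg < lo_t
    if (any(low)) {
      pairs$y_agg[low] <- lo_t[low]
      changed <- TRUE
    }
    if (!changed) break
  }
  pairs
}

#' Generate a full synthetic kcat dataset
#'
#' Builds enzymes and reaction templates, assigns each enzyme a window of
#' templates (so its reactions have similar planted effects), simulates
#' log10 kcat as mu + reaction effect + enzyme effect + noise with
#' family-correlated enzyme effects (correlation = identity/100 to the
#' family root), draws replicate measurements, and injects decoys of every
#' class with exact ground-truth labels.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `kcat_synth`: `records` (measurement tibble in the
#'   input schema), `truth` (pair classes, duplicate row ids, planted
#'   effects, template table).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  enzymes <- generate_enzymes(cfg)
  rx <- generate_reactions(cfg)
  templates <- rx$templates[order(rx$templates$effect), ]

  with_local_seed(derive_seed(cfg$seed, "dataset"), {
    n_enz <- nrow(enzymes)
    n_tpl <- nrow(templates)

    # family-correlated enzyme effects
    fam_effect <- stats::rnorm(max(enzymes$family), 0, cfg$effect_sd_family)
    rho <- enzymes$target_identity / 100
    own <- stats::rnorm(n_enz, 0, cfg$effect_sd_family)
    enz_effect <- rho * fam_effect[enzymes$family] +
      sqrt(pmax(0, 1 - rho^2)) * own

    # reactions are a family property: homologous enzymes catalyse the same
    # or closely related chemistry. Each family gets one contiguous window
    # of effect-sorted templates (planted effects within ~0.8 log10); every
    # member samples its reactions from the family window. This couples
    # sequence similarity to reaction identity, as in real kinetic data,
    # which is what lets sequence-only models predict kcat at all.
    n_rx <- sample_range(cfg$reactions_per_enzyme_range[1],
                         cfg$reactions_per_enzyme_range[2], n_enz)
    fam_win <- lapply(seq_len(max(enzymes$family)), function(f) {
      start <- sample(n_tpl, 1)
      win <- start:min(n_tpl, start + 8L)
      win[templates$effect[win] - templates$effect[win[1]] <= 0.8]
    })
    pair_rows <- list()
    for (i in seq_len(n_enz)) {
      win <- fam_win[[enzymes$family[i]]]
      chosen <- win[sample.int(length(win), min(n_rx[i], length(win)))]
      pair_rows[[i]] <- tibble(
        enzyme_idx = i,
        template_id = templates$template_id[chosen],
        t_effect = templates$effect[chosen]
      )
    }
    pairs <- dplyr::bind_rows(pair_rows)
    pairs$sequence <- enzymes$sequence[pairs$enzyme_idx]
    pairs$enzyme_id <- enzymes$enzyme_id[pairs$enzyme_idx]
    pairs$e_effect <- enz_effect[pairs$enzyme_idx]
    pairs$noise <- stats::rnorm(nrow(pairs), 0, cfg$noise_sd)
    pairs$y_pair <- cfg$mu_log10 + pairs$t_effect + pairs$e_effect +
      pairs$noise

    # replicates (bounded scatter so the 1%-rule never fires on clean rows)
    pairs$n_rep <- sample_range(cfg$n_replicates_range[1],
                                cfg$n_replicates_range[2], nrow(pairs))
    rep_eps <- lapply(pairs$n_rep, function(m) {
      e <- stats::rnorm(m, 0, cfg$replicate_sd)
      pmin(pmax(e, -0.5), 0.5)
    })
    pairs$y_agg <- pairs$y_pair + vapply(rep_eps, mean, numeric(1))

    # margin enforcement: shift whole pairs (all replicates equally).
    # Aggregated clean values are first clamped into a band strictly inside
    # the outlier bounds; the margin loop afterwards only raises values, so
    # the band is preserved and no clean pair can look like an outlier.
    before <- pairs$y_agg
    pairs$y_agg <- pmin(pmax(pairs$y_agg, -2.3), 4.9)
    pairs <- enforce_clean_margins(pairs)
    shift <- pairs$y_agg - before

    tpl_lookup <- templates[match(pairs$template_id, templates$template_id), ]
    clean_rows <- list()
    for (p in seq_len(nrow(pairs))) {
      vals <- 10^(pairs$y_pair[p] + shift[p] + rep_eps[[p]])
      clean_rows[[p]] <- tibble(
        enzyme_id = pairs$enzyme_id[p],
        sequence = pairs$sequence[p],
        reaction_smiles = tpl_lookup$reaction_smiles[p],
        reaction_key = tpl_lookup$reaction_key[p],
        ec = tpl_lookup$ec[p],
        kcat_s = vals
      )
    }
    clean <- dplyr::bind_rows(clean_rows)
    n_clean <- nrow(clean)

    rate_count <- function(r) round(r * n_clean)
    agg_by <- function(tbl) {
      stats::aggregate(list(y = log10(tbl$kcat_s)),
                       by = list(sequence = tbl$sequence,
                                 reaction_key = tbl$reaction_key),
                       FUN = mean)
    }
    clean_agg <- agg_by(clean)
    enz_max <- tapply(clean_agg$y, clean_agg$sequence, max)
    tpl_max <- tapply(clean_agg$y, clean_agg$reaction_key, max)

    fresh_seq <- function(n) {
      vapply(seq_len(n), function(i) {
        paste(sample(AA20, sample_range(cfg$seq_length_range[1],
                                        cfg$seq_length_range[2]),
                     replace = TRUE), collapse = "")
      }, character(1))
    }

    decoys <- list()
    truth_pairs <- list()

    # duplicates: exact copies of clean rows
    n_dup <- rate_count(cfg$decoy_rates$duplicates)
    dup_src <- if (n_dup > 0) sample(n_clean, n_dup, replace = FALSE) else
      integer(0)

    # outliers: dedicated enzymes + two dedicated templates
    n_out <- rate_count(cfg$decoy_rates$outliers)
    if (n_out > 0) {
      pool <- rx$decoy_pool
      lo_t <- pool[1]; hi_t <- pool[2]
      lo_key <- as_kcat_reaction(lo_t)$key
      hi_key <- as_kcat_reaction(hi_t)$key
      seqs <- fresh_seq(n_out)
      is_low <- seq_len(n_out) %% 2L == 1L
      vals <- ifelse(is_low, 10^stats::runif(n_out, -3.6, -2.8),
                     10^stats::runif(n_out, 5.3, 6.0))
      decoys$outlier <- tibble(
        enzyme_id = sprintf("DOUT%03d", seq_len(n_out)),
        sequence = seqs,
        reaction_smiles = ifelse(is_low, lo_t, hi_t),
        reaction_key = ifelse(is_low, lo_key, hi_key),
        ec = ifelse(is_low, "8.8.1.1", "8.8.1.2"),
        kcat_s = vals
      )
      truth_pairs$outlier <- tibble(sequence = seqs,
                                    reaction_key = ifelse(is_low, lo_key,
                                                          hi_key),
                                    class = "outlier")
    }

    # mass-imbalanced: dedicated enzymes on imbalanced templates; values in
    # a narrow band so the 100x rule cannot fire first
    n_mass <- rate_count(cfg$decoy_rates$mass_imbalanced)
    if (n_mass > 0) {
      tpl <- rx$imbalanced[(seq_len(n_mass) - 1L) %%
                             length(rx$imbalanced) + 1L]
      keys <- vapply(unique(tpl), function(s) as_kcat_reaction(s)$key,
                     character(1))
      seqs <- fresh_seq(n_mass)
      decoys$mass <- tibble(
        enzyme_id = sprintf("DMAS%03d", seq_len(n_mass)),
        sequence = seqs,
        reaction_smiles = tpl,
        reaction_key = unname(keys[tpl]),
        ec = sprintf("8.7.%d.1", match(tpl, unique(tpl))),
        kcat_s = 10^(cfg$mu_log10 + stats::runif(n_mass, -0.8, 0.8))
      )
      truth_pairs$mass <- tibble(sequence = seqs,
                                 reaction_key = unname(keys[tpl]),
                                 class = "mass_imbalanced")
    }

    # non-natural (10x) decoys: extra slow reaction for existing enzymes
    n_nn <- rate_count(cfg$decoy_rates$non_natural_10x)
    if (n_nn > 0) {
      host_ok <- names(enz_max)[enz_max >= -0.5]
      hosts <- sample(host_ok, n_nn, replace = FALSE)
      vals <- unname(enz_max[hosts]) - 1.7
      # chunk by value so decoys sharing a template stay within the 100x
      # margin of each other
      chunk <- as.integer(cut(vals, breaks = seq(min(vals) - 1e-9,
                                                 max(vals) + 1e-9,
                                                 length.out = 4L),
                              include.lowest = TRUE))
      tpl <- rx$decoy_pool[2L + chunk]
      keys <- vapply(unique(tpl), function(s) as_kcat_reaction(s)$key,
                     character(1))
      host_rows <- clean[match(hosts, clean$sequence), ]
      decoys$non_natural <- tibble(
        enzyme_id = host_rows$enzyme_id,
        sequence = hosts,
        reaction_smiles = tpl,
        reaction_key = unname(keys[tpl]),
        ec = sprintf("8.6.%d.1", chunk),
        kcat_s = 10^vals
      )
      truth_pairs$non_natural <- tibble(sequence = hosts,
                                        reaction_key = unname(keys[tpl]),
                                        class = "non_natural")
    }

    # suboptimal (100x) decoys: fresh enzymes on high-kcat clean templates
    n_sub <- rate_count(cfg$decoy_rates$suboptimal_100x)
    if (n_sub > 0) {
      high_keys <- names(tpl_max)[tpl_max >= 0.3]
      host_keys <- sample(high_keys, n_sub, replace = TRUE)
      seqs <- fresh_seq(n_sub)
      tpl_row <- templates[match(host_keys, templates$reaction_key), ]
      decoys$suboptimal <- tibble(
        enzyme_id = sprintf("DSUB%03d", seq_len(n_sub)),
        sequence = seqs,
        reaction_smiles = tpl_row$reaction_smiles,
        reaction_key = host_keys,
        ec = tpl_row$ec,
        kcat_s = 10^(unname(tpl_max[host_keys]) - 2.2)
      )
      truth_pairs$suboptimal <- tibble(sequence = seqs,
                                       reaction_key = host_keys,
                                       class = "suboptimal")
    }

    all_rows <- dplyr::bind_rows(c(list(clean = clean), decoys))
    dup_rows <- clean[dup_src, , drop = FALSE]
    all_rows <- dplyr::bind_rows(all_rows, dup_rows)

    organisms <- c("Escherichia coli", "Saccharomyces cerevisiae",
                   "Bacillus subtilis", "Homo sapiens")
    n_all <- nrow(all_rows)
    perm <- sample(n_all)
    all_rows <- all_rows[perm, ]
    records <- tibble(
      record_id = sprintf("R%05d", seq_len(n_all)),
      enzyme_id = all_rows$enzyme_id,
      sequence = all_rows$sequence,
      reaction_smiles = all_rows$reaction_smiles,
      kcat_s = as.numeric(all_rows$kcat_s),
      ec = all_rows$ec,
      source = sample(c("brenda", "sabio", "uniprot"), n_all,
                      replace = TRUE),
      organism = sample(organisms, n_all, replace = TRUE),
      wild_type = TRUE
    )

    # duplicate copies are the last n_dup pre-permutation rows
    dup_ids <- records$record_id[match(
      nrow(all_rows) - rev(seq_len(length(dup_src))) + 1L, perm)]

    truth <- list(
      pair_classes = dplyr::bind_rows(c(
        list(clean = tibble(sequence = pairs$sequence,
                            reaction_key = tpl_lookup$reaction_key,
                            class = "clean")),
        truth_pairs)),
      duplicate_record_ids = dup_ids,
      templates = templates,
      enzymes = enzymes,
      enzyme_effects = tibble(enzyme_id = enzymes$enzyme_id,
                              effect = enz_effect),
      config = cfg
    )
    structure(list(records = records, truth = truth),
              class = "kcat_synth")
  })
}

#' @export
print.kcat_synth <- function(x, ...) {
  cat("<kcat_synth>", nrow(x$records), "measurement rows,",
      sum(x$truth$pair_classes$class != "clean"), "decoy pairs\n")
  invisible(x)
}
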