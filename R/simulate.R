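#' Configuration for the RIP-chip simulator
#'
#' Defines one simulated pulldown study: a fixed array design (gene set, 2–5
#' probes per gene, per-gene abundances), an IP carryover background,
#' spiked enrichments for the bait's own mRNA, its targets and a set of
#' unspecific contaminants, per-spot multiplicative noise, a logistic
#' pixel-quality model, replicate and dye-swap structure, and a condition.
#'
#' Enrichment effects are expressed in SD units of the resulting enrichment
#' profile, not as raw multipliers: the generator calibrates each spiked
#' gene's IP signals so that its median log10 ratio lands the requested number
#' of profile standard deviations above the profile median. This makes
#' recovery tests robust to the noise settings.
#'
#' Condition semantics: `control` and `mock` spike bait + targets +
#' contaminants; `minus_atg` removes the enrichment of exactly one designated
#' mRNA (`minus_atg_gene`, default the first target) while leaving its
#' reference-channel abundance unchanged (the mutant mRNA is still expressed,
#' only untranslatable); `puromycin` and `edta` disassemble polysomes and so
#' remove *all* translation-dependent enrichments (bait and targets), while
#' contaminant enrichment — non-ribosomal sticky RNA — persists.
#'
#' @param n_genes Number of genes on the array (default 5000, the order of the
#'   fission-yeast coding set).
#' @param probes_per_gene Integer range `c(min, max)` of independent probes per
#'   gene (default 2–5).
#' @param abundance_log10_mean,abundance_log10_sd Log-normal abundance model
#'   on the log10 scale (defaults 2.0 and 0.6).
#' @param carryover Fraction of a gene's abundance that appears in the IP
#'   channel as unspecific background (default 0.01).
#' @param noise_log10_sd Per-spot, per-channel multiplicative log-normal noise
#'   (log10 SD, default 0.1).
#' @param bait_gene,target_genes,contaminant_genes Gene IDs to spike; `NULL`
#'   (default) picks genes of median abundance from the design, recorded in
#'   the ground truth.
#' @param bait_effect_sd,target_effects_sd,contaminant_effect_sd Spiked
#'   enrichments in profile-SD units (defaults: bait 6; targets 3 and 5;
#'   contaminants 4).
#' @param n_contaminants Number of contaminants when `contaminant_genes` is
#'   `NULL` (default 2).
#' @param flag_fraction Fraction of spots scanner-flagged bad (default 0.01).
#' @param pixel_midpoint,pixel_slope Logistic link from log10 signal to the
#'   fraction of above-background pixels:
#'   `plogis(slope * (log10(signal) - midpoint))`.
#' @param k Number of biological replicates (default 3).
#' @param dye_swap_last Swap dyes on the last replicate when `k >= 2`
#'   (default `TRUE`; at least one swapped hybridisation per bait).
#' @param condition One of `"control"`, `"minus_atg"`, `"puromycin"`,
#'   `"edta"`, `"mock"`.
#' @param minus_atg_gene The mRNA whose start codon is mutated in
#'   `minus_atg` runs (default: first target).
#' @param atg_abundance_factor Multiplier on the −ATG mRNA's abundance
#'   (default 1: the untranslatable mRNA is expressed at wild-type level).
#' @param platform Platform whose thresholds the simulated scans are meant
#'   for (default `"pcr"`).
#' @param seed Seed for the per-run draws (noise, flags).
#' @param design_seed Seed for the fixed array design (probe counts,
#'   abundances); constant by default so all runs share one platform design.
#' @return A list of class `ripchip_config`.
#' @export
ripchip_config <- function(n_genes = 5000,
                           probes_per_gene = c(2L, 5L),
                           abundance_log10_mean = 2,
                           abundance_log10_sd = 0.6,
                           carryover = 0.01,
                           noise_log10_sd = 0.1,
                           bait_gene = NULL,
                           bait_effect_sd = 6,
                           target_genes = NULL,
                           target_effects_sd = c(3, 5),
                           contaminant_genes = NULL,
                           contaminant_effect_sd = 4,
                           n_contaminants = 2L,
                           flag_fraction = 0.01,
                           pixel_midpoint = -1.5,
                           pixel_slope = 4,
                           k = 3L,
                           dye_swap_last = TRUE,
                           condition = "control",
                           minus_atg_gene = NULL,
                           atg_abundance_factor = 1,
                           platform = "pcr",
                           seed = 1L,
                           design_seed = 20111201L) {
  check_condition(condition)
  stopifnot(
    n_genes >= 1,
    length(probes_per_gene) == 2, probes_per_gene[1] >= 1,
    probes_per_gene[2] >= probes_per_gene[1],
    carryover > 0, carryover <= 1,
    noise_log10_sd >= 0,
    flag_fraction >= 0, flag_fraction <= 1,
    k >= 1,
    atg_abundance_factor > 0
  )
  effects <- c(bait_effect_sd, target_effects_sd, contaminant_effect_sd)
  if (any(!is.finite(effects)) || any(effects <= 0)) {
    abort_ripchip("all enrichment effects must be positive SD units",
                  "ripchip_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      probes_per_gene = as.integer(probes_per_gene),
      abundance_log10_mean = abundance_log10_mean,
      abundance_log10_sd = abundance_log10_sd,
      carryover = carryover,
      noise_log10_sd = noise_log10_sd,
      bait_gene = bait_gene,
      bait_effect_sd = bait_effect_sd,
      target_genes = target_genes,
      target_effects_sd = target_effects_sd,
      contaminant_genes = contaminant_genes,
      contaminant_effect_sd = contaminant_effect_sd,
      n_contaminants = as.integer(n_contaminants),
      flag_fraction = flag_fraction,
      pixel_midpoint = pixel_midpoint,
      pixel_slope = pixel_slope,
      k = as.integer(k),
      dye_swap_last = isTRUE(dye_swap_last),
      condition = condition,
      minus_atg_gene = minus_atg_gene,
      atg_abundance_factor = atg_abundance_factor,
      platform = platform,
      seed = as.integer(seed),
      design_seed = as.integer(design_seed),
      no_effects = FALSE
    ),
    class = "ripchip_config"
  )
}

# fixed array design: gene ids, probe counts, abundances
array_design <- function(config) {
  withr::with_seed(config$design_seed, {
    width <- max(4L, nchar(as.character(config$n_genes)))
    gene_id <- sprintf(paste0("G%0", width, "d"), seq_len(config$n_genes))
    n_probes <- sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
                       config$n_genes, replace = TRUE)
    abundance_log10 <- stats::rnorm(config$n_genes,
                                    config$abundance_log10_mean,
                                    config$abundance_log10_sd)
    genes <- tibble(gene_id = gene_id, n_probes = n_probes,
                    abundance_log10 = abundance_log10)
    spot_gene <- rep(gene_id, n_probes)
    probes <- tibble(
      gene_id = spot_gene,
      probe_id = paste0(spot_gene, "_p", unlist(lapply(n_probes, seq_len)))
    )
    list(genes = genes, probes = probes)
  })
}

# pick spike-in genes of typical (median) abundance when not specified
resolve_spikes <- function(config, design) {
  ab <- design$genes$abundance_log10
  ord <- design$genes$gene_id[order(abs(ab - stats::median(ab)))]
  taken <- c(config$bait_gene, config$target_genes, config$contaminant_genes)
  pool <- setdiff(ord, taken)
  pick <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  bait <- config$bait_gene %||% pick(1)
  targets <- config$target_genes %||% pick(length(config$target_effects_sd))
  contaminants <- config$contaminant_genes %||%
    (if (config$n_contaminants > 0) pick(config$n_contaminants) else character())
  for (g in c(bait, targets, contaminants)) {
    if (!g %in% design$genes$gene_id) {
      abort_ripchip(sprintf("spiked gene '%s' is not in the array design", g),
                    "ripchip_config_error")
    }
  }
  if (length(targets) != length(config$target_effects_sd)) {
    abort_ripchip("`target_genes` and `target_effects_sd` must have equal length",
                  "ripchip_config_error")
  }
  minus_atg_gene <- config$minus_atg_gene %||%
    (if (length(targets) > 0) targets[1] else NA_character_)
  if (config$condition == "minus_atg" &&
      !minus_atg_gene %in% c(targets, bait)) {
    abort_ripchip("`minus_atg_gene` must be the bait or one of its targets",
                  "ripchip_config_error")
  }
  list(bait = bait, targets = targets, contaminants = contaminants,
       minus_atg_gene = minus_atg_gene)
}

# effects active under a condition, as tibble(gene_id, effect_sd, role)
active_effects <- function(config, spikes) {
  if (isTRUE(config$no_effects)) {
    return(tibble(gene_id = character(), effect_sd = numeric(),
                  role = character()))
  }
  eff <- dplyr::bind_rows(
    tibble(gene_id = spikes$bait, effect_sd = config$bait_effect_sd,
           role = "bait"),
    tibble(gene_id = spikes$targets, effect_sd = config$target_effects_sd,
           role = "target"),
    tibble(gene_id = spikes$contaminants,
           effect_sd = rep_len(config$contaminant_effect_sd,
                               length(spikes$contaminants)),
           role = "contaminant")
  )
  switch(config$condition,
    control = ,
    mock = eff,
    minus_atg = eff[!(eff$gene_id == spikes$minus_atg_gene &
                        eff$role %in% c("bait", "target")), ],
    puromycin = ,
    edta = eff[eff$role == "contaminant", ]
  )
}

#' Simulate a RIP-chip experiment with known ground truth
#'
#' Generates `k` replicate two-channel scans from one [ripchip_config()]. The
#' reference channel is proportional to each gene's abundance times noise; the
#' IP channel to abundance times the carryover fraction times the gene's
#' enrichment effect times noise. Pixel fractions follow the logistic link
#' from the log10 signal. Effects are calibrated per replicate against the
#' scan's own no-effect profile (computed over non-flagged spots), so a gene
#' spiked at `u` SD realizes an SD-above-median score of about `u`. The last
#' replicate's scan is emitted with its channel columns physically exchanged
#' when dye-swapped. Output is byte-identical for a fixed config.
#'
#' @param config A [ripchip_config()].
#' @return A list with `scans` (list of `ripchip_scan`) and `truth`, a list of
#'   class `ripchip_truth` holding the resolved bait / target / contaminant
#'   genes, the designated −ATG mRNA, the per-condition set of genes expected
#'   enriched, the active effect table, and the design (abundances, probe
#'   counts).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "ripchip_config")) {
    abort_ripchip("`config` must be a ripchip_config", "ripchip_config_error")
  }
  design <- array_design(config)
  spikes <- resolve_spikes(config, design)
  effects <- active_effects(config, spikes)

  spot_genes <- design$probes$gene_id
  gene_idx <- match(spot_genes, design$genes$gene_id)
  ab <- design$genes$abundance_log10
  if (config$condition == "minus_atg" && config$atg_abundance_factor != 1) {
    i <- match(spikes$minus_atg_gene, design$genes$gene_id)
    ab[i] <- ab[i] + log10(config$atg_abundance_factor)
  }
  n_spots <- nrow(design$probes)

  scans <- withr::with_seed(config$seed, {
    lapply(seq_len(config$k), function(rep_i) {
      noise_ip <- stats::rnorm(n_spots, 0, config$noise_log10_sd)
      noise_ref <- stats::rnorm(n_spots, 0, config$noise_log10_sd)
      flagged <- stats::runif(n_spots) < config$flag_fraction
      ref_mu <- ab[gene_idx]                            # noise-free levels
      ip_mu <- ab[gene_idx] + log10(config$carryover)
      ref_log10 <- ref_mu + noise_ref
      ip_log10 <- ip_mu + noise_ip

      # calibrate spiked effects in SD units of this scan's no-effect profile,
      # over the spots the analysis will see (non-flagged)
      if (nrow(effects) > 0) {
        r0 <- ip_log10 - ref_log10
        ok <- !flagged
        R0 <- tapply(r0[ok], spot_genes[ok], stats::median)
        med0 <- stats::median(R0)
        sd0 <- stats::sd(R0)
        for (j in seq_len(nrow(effects))) {
          g <- effects$gene_id[j]
          if (!g %in% names(R0)) next  # all spots flagged; nothing to calibrate
          delta <- (med0 + effects$effect_sd[j] * sd0) - R0[[g]]
          ip_log10[spot_genes == g] <- ip_log10[spot_genes == g] + delta
          ip_mu[spot_genes == g] <- ip_mu[spot_genes == g] + delta
        }
      }

      # pixel quality reflects the spot's underlying signal level, not the
      # multiplicative noise on the quantified intensity: detectability is a
      # property of how much material sits on the spot, so it is consistent
      # across replicates and does not feed back into the measured ratio
      frac <- function(mu_log10) {
        stats::plogis(config$pixel_slope * (mu_log10 - config$pixel_midpoint))
      }
      spots <- tibble(
        probe_id = design$probes$probe_id,
        ip_signal = 10^ip_log10,
        ref_signal = 10^ref_log10,
        ip_frac_above_bg = frac(ip_mu),
        ref_frac_above_bg = frac(ref_mu),
        flag = ifelse(flagged, -100L, 0L)
      )
      swapped <- config$dye_swap_last && config$k >= 2 && rep_i == config$k
      if (swapped) {
        spots <- spots[, c("probe_id", "ref_signal", "ip_signal",
                           "ref_frac_above_bg", "ip_frac_above_bg", "flag")]
        names(spots) <- c("probe_id", "ip_signal", "ref_signal",
                          "ip_frac_above_bg", "ref_frac_above_bg", "flag")
      }
      new_scan(
        spots,
        experiment_id = sprintf("%s_%s_rep%d", spikes$bait, config$condition, rep_i),
        bait_gene = spikes$bait,
        platform = as_platform(config$platform),
        dye_swapped = swapped,
        condition = config$condition
      )
    })
  })

  truth <- structure(
    list(
      bait_gene = spikes$bait,
      target_genes = spikes$targets,
      contaminant_genes = spikes$contaminants,
      minus_atg_gene = spikes$minus_atg_gene,
      condition = config$condition,
      enriched_genes = sort(effects$gene_id),
      effects = effects,
      genes = design$genes,
      config = config
    ),
    class = "ripchip_truth"
  )
  list(scans = scans, truth = truth)
}

#' Simulate null scans with no spiked enrichment
#'
#' Same generative model as [simulate_experiment()] with every enrichment
#' effect removed; used to calibrate the tail behaviour of the calling rule
#' (the per-replicate called fraction at `tau` SD and its `k`-replicate
#' intersection).
#'
#' @param config A [ripchip_config()]; its effect fields are ignored.
#' @return As [simulate_experiment()]; `truth$enriched_genes` is empty.
#' @export
simulate_null <- function(config) {
  config$no_effects <- TRUE
  simulate_experiment(config)
}

#' Annotation table for a simulated design
#'
#' All simulated probes map to coding genes.
#'
#' @param config A [ripchip_config()].
#' @return Annotation tibble (`probe_id`, `gene_id`, `is_coding`).
#' @export
simulated_annotation <- function(config) {
  design <- array_design(config)
  tibble(
    probe_id = design$probes$probe_id,
    gene_id = design$probes$gene_id,
    is_coding = TRUE
  )
}

#' @export
print.ripchip_truth <- function(x, ...) {
  cat(sprintf(
    "<ripchip_truth> condition '%s': bait %s; targets %s; contaminants %s\n",
    x$condition, x$bait_gene,
    paste(x$target_genes, collapse = ", "),
    paste(x$contaminant_genes, collapse = ", ")
  ))
  invisible(x)
}
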