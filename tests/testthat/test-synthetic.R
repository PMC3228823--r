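test_that("a fixed config reproduces byte-identical scans", {
  cfg <- ripchip_config(n_genes = 200, k = 2, seed = 9)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  for (i in seq_along(a$scans)) {
    expect_identical(as.data.frame(a$scans[[i]]), as.data.frame(b$scans[[i]]))
  }
  expect_identical(a$truth$enriched_genes, b$truth$enriched_genes)
  # and the emitted files are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(cfg, d1); run_simulate(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed gives different noise
  c2 <- simulate_experiment(ripchip_config(n_genes = 200, k = 2, seed = 10))
  expect_false(identical(a$scans[[1]]$ip_signal, c2$scans[[1]]$ip_signal))
})

test_that("the array design is a fixed platform property across runs", {
  cfg1 <- ripchip_config(n_genes = 150, seed = 1)
  cfg2 <- ripchip_config(n_genes = 150, seed = 2)
  expect_identical(simulated_annotation(cfg1), simulated_annotation(cfg2))
})

test_that("invalid configurations are rejected", {
  expect_error(ripchip_config(condition = "heatshock"),
               class = "ripchip_invalid_condition")
  expect_error(ripchip_config(bait_effect_sd = -1), class = "ripchip_config_error")
  expect_error(
    simulate_experiment(ripchip_config(n_genes = 50, bait_gene = "not_a_gene")),
    class = "ripchip_config_error"
  )
  expect_error(
    simulate_experiment(ripchip_config(n_genes = 50, condition = "minus_atg",
                                       minus_atg_gene = "G0049",
                                       target_genes = c("G0001", "G0002"),
                                       bait_gene = "G0003")),
    class = "ripchip_config_error"
  )
})

test_that("the pipeline recovers spiked genes end to end", {
  cfg <- ripchip_config(n_genes = 400, k = 3, seed = 1)
  sim <- simulate_experiment(cfg)
  ann <- simulated_annotation(cfg)
  cs <- call_targets(sim$scans, ann,
                     blacklist = sim$truth$contaminant_genes,
                     min_background = 100)
  expect_setequal(cs$consensus, c(sim$truth$bait_gene, sim$truth$target_genes))
})

test_that("condition effects follow the translation-dependence rules", {
  mk <- function(cond) {
    cfg <- ripchip_config(n_genes = 400, k = 2, seed = 3, condition = cond)
    sim <- simulate_experiment(cfg)
    list(sim = sim,
         cs = call_targets(sim$scans, simulated_annotation(cfg),
                           min_background = 100))
  }
  ctrl <- mk("control")
  spiked <- c(ctrl$sim$truth$bait_gene, ctrl$sim$truth$target_genes)
  contaminants <- ctrl$sim$truth$contaminant_genes
  expect_true(all(c(spiked, contaminants) %in% ctrl$cs$consensus))

  atg <- mk("minus_atg")
  designated <- atg$sim$truth$minus_atg_gene
  expect_false(designated %in% atg$cs$consensus)
  expect_true(all(setdiff(spiked, designated) %in% atg$cs$consensus))
  # the untranslatable mRNA is still expressed: same reference abundance model
  expect_identical(atg$sim$truth$genes$abundance_log10,
                   ctrl$sim$truth$genes$abundance_log10)

  for (cond in c("puromycin", "edta")) {
    x <- mk(cond)
    expect_length(intersect(spiked, x$cs$consensus), 0)
    # contaminant binding is not translation-dependent and persists,
    # so only the blacklist removes it
    expect_true(all(contaminants %in% x$cs$consensus))
    after_bl <- setdiff(x$cs$consensus, contaminants)
    expect_length(intersect(after_bl, c(spiked, contaminants)), 0)
  }
})

test_that("dye-swapped replicates carry exchanged columns but identical information", {
  cfg <- ripchip_config(n_genes = 300, k = 2, seed = 6, dye_swap_last = TRUE)
  sim <- simulate_experiment(cfg)
  ann <- simulated_annotation(cfg)
  swapped <- sim$scans[[2]]
  expect_true(attr(swapped, "dye_swapped"))
  # after role resolution the spiked genes score high in the swapped scan too
  std <- standardize_profile(enrichment_profile(swapped, ann))
  spiked <- sim$truth$enriched_genes
  expect_true(all(std$s[match(spiked, std$gene_id)] > 2))
})

test_that("null simulations have no enriched genes and expose the degenerate path", {
  cfg <- ripchip_config(n_genes = 200, k = 1, seed = 4)
  null <- simulate_null(cfg)
  expect_length(null$truth$enriched_genes, 0)

  flat <- ripchip_config(n_genes = 100, k = 1, seed = 4, noise_log10_sd = 0,
                         flag_fraction = 0)
  sim <- simulate_null(flat)
  expect_error(
    standardize_profile(enrichment_profile(sim$scans[[1]],
                                           simulated_annotation(flat))),
    class = "ripchip_degenerate_profile"
  )
})
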