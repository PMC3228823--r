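std_profile_from <- function(R) {
  prof <- structure(
    tibble::tibble(gene_id = sprintf("g%04d", seq_along(R)), R = R,
                   n_probes = 1L),
    class = c("ripchip_profile", class(tibble::tibble()))
  )
  standardize_profile(prof)
}

test_that("call_enriched selects genes at or above tau SD over the median", {
  R <- withr::with_seed(1, c(rnorm(99, sd = 0.01), 50))
  std <- std_profile_from(R)
  expect_identical(call_enriched(std, tau = 2), "g0100")
  expect_error(call_enriched(std_profile_from(rep(1, 10))),
               class = "ripchip_degenerate_profile")
})

test_that("call_enriched matches a sort-and-threshold oracle on 1000 genes", {
  withr::with_seed(33, {
    std <- std_profile_from(rnorm(1000, sd = 0.4))
    # independent oracle: walk the scores in decreasing order until below tau
    ord <- order(std$s, decreasing = TRUE)
    picked <- character()
    for (i in ord) {
      if (std$s[i] >= 2) picked <- c(picked, std$gene_id[i]) else break
    }
    expect_setequal(call_enriched(std, tau = 2), picked)
  })
})

test_that("replicate intersection obeys set algebra and the blacklist", {
  sup <- intersect_replicates(list(c("A", "B", "C"), c("A", "C")),
                              blacklist = "C")
  expect_identical(consensus_genes(sup), "A")
  expect_equal(sup$replicate_support[sup$gene_id == "B"], "1/2")
  expect_true(all(!sup$in_consensus[sup$blacklisted]))
  expect_error(intersect_replicates(list()), class = "ripchip_validation_error")
})

test_that("a single-replicate consensus with non-bait genes warns", {
  expect_warning(
    sup <- intersect_replicates(list(c("bait1", "other")), bait_gene = "bait1"),
    class = "ripchip_single_replicate_warning"
  )
  expect_setequal(consensus_genes(sup), c("bait1", "other"))
  expect_no_warning(intersect_replicates(list("bait1"), bait_gene = "bait1"))
})

test_that("the consensus is contained in every replicate set", {
  withr::with_seed(44, {
    pool <- sprintf("g%02d", 1:40)
    for (i in 1:20) {
      k <- sample(1:4, 1)
      sets <- replicate(k, sample(pool, sample(5:20, 1)), simplify = FALSE)
      bl <- sample(pool, 3)
      cons <- consensus_genes(intersect_replicates(sets, blacklist = bl))
      for (s in sets) expect_true(all(cons %in% s))
      expect_length(intersect(cons, bl), 0)
    }
  })
})

test_that("baits are classified empty / bait_only / targets", {
  expect_identical(classify_bait(character(), "cdc2"), "empty")
  expect_identical(classify_bait("cdc2", "cdc2"), "bait_only")
  # the classic CDK example: bait co-purifies the inhibitor and the
  # replication-factor mRNAs
  expect_identical(classify_bait(c("rum1", "cdc18"), "cdc2"), "targets")
  expect_identical(classify_bait(c("cdc2", "rum1", "cdc18"), "cdc2"), "targets")
})

test_that("the expected false-positive fraction is p^k", {
  expect_equal(expected_false_positive_fraction(0.05, 1), 0.05)
  expect_equal(expected_false_positive_fraction(0.05, 2), 2.5e-3)
  expect_equal(expected_false_positive_fraction(0.05, 4), 6.25e-6)
  expect_equal(expected_false_positive_fraction(0, 3), 0)
  # strictly decreasing in k for 0 < p < 1
  vals <- expected_false_positive_fraction(0.05, 1:6)
  expect_true(all(diff(vals) < 0))
  expect_error(expected_false_positive_fraction(1.2, 1),
               class = "ripchip_validation_error")
  expect_error(expected_false_positive_fraction(0.05, 0),
               class = "ripchip_validation_error")
})

test_that("contaminants recur across unrelated baits; cognate mRNAs are exempt", {
  baits <- sprintf("bait%d", 1:8)
  sets <- stats::setNames(lapply(baits, function(b) c(b, "sticky1")), baits)
  # sticky1 called for 8/8 unrelated baits -> blacklisted
  expect_identical(derive_contaminant_blacklist(sets), "sticky1")

  # called in 5 of 8 unrelated baits at min_fraction 0.5 -> blacklisted
  sets2 <- stats::setNames(
    lapply(seq_along(baits), function(i) {
      if (i <= 5) c(baits[i], "semi") else baits[i]
    }), baits)
  expect_identical(derive_contaminant_blacklist(sets2), "semi")
  expect_identical(derive_contaminant_blacklist(sets2, min_fraction = 0.7),
                   character())

  # a gene called only for its own bait is never a contaminant
  own_only <- stats::setNames(lapply(baits, function(b) b), baits)
  expect_identical(derive_contaminant_blacklist(own_only), character())

  expect_error(derive_contaminant_blacklist(sets[1:3]),
               class = "ripchip_validation_error")
})

test_that("planted contaminants are recovered from a simulated bait panel", {
  n <- 300
  cfg0 <- ripchip_config(n_genes = n, k = 2, seed = 1,
                         contaminant_genes = c("G0290", "G0291", "G0292"),
                         contaminant_effect_sd = 5)
  ann <- simulated_annotation(cfg0)
  baits <- c("G0010", "G0020", "G0030", "G0040", "G0050")
  sets <- lapply(seq_along(baits), function(i) {
    cfg <- cfg0
    cfg$bait_gene <- baits[i]
    cfg$target_genes <- character()
    cfg$target_effects_sd <- numeric()
    cfg$seed <- 100L + i
    sim <- simulate_experiment(cfg)
    cs <- call_targets(sim$scans, ann, min_background = 100)
    cs$consensus
  })
  names(sets) <- baits
  bl <- derive_contaminant_blacklist(sets, min_baits = 4, min_fraction = 0.5)
  expect_setequal(bl, c("G0290", "G0291", "G0292"))
})

test_that("the fraction of baits with targets is a simple percentage", {
  cats <- rep(c("empty", "bait_only", "targets"), c(10, 9, 12))
  expect_equal(summarize_fraction_with_targets(cats), 100 * 12 / 31)
  expect_equal(summarize_fraction_with_targets(rep("empty", 5)), 0)
  expect_equal(summarize_fraction_with_targets(rep("targets", 5)), 100)
  expect_error(summarize_fraction_with_targets(character()),
               class = "ripchip_validation_error")
  expect_error(summarize_fraction_with_targets("weird"),
               class = "ripchip_validation_error")

  tbl <- summarize_categories(cats)
  expect_equal(tbl$n, c(10, 9, 12))
  expect_equal(attr(tbl, "pct_targets"), 100 * 12 / 31)
})

test_that("call_targets runs the full per-replicate pipeline for one bait", {
  cfg <- ripchip_config(n_genes = 400, k = 3, seed = 5,
                        contaminant_genes = c("G0399", "G0400"))
  sim <- simulate_experiment(cfg)
  ann <- simulated_annotation(cfg)
  cs <- call_targets(sim$scans, ann,
                     blacklist = sim$truth$contaminant_genes,
                     min_background = 100)
  expect_s3_class(cs, "ripchip_callset")
  expect_setequal(cs$consensus,
                  c(sim$truth$bait_gene, sim$truth$target_genes))
  expect_identical(cs$category, "targets")
  expect_equal(cs$fp_expected, 0.05^3)
  td <- tidy(cs)
  expect_identical(names(td), c("bait", "gene_id", "replicate_support",
                                "mean_s", "is_bait_mrna", "category"))
  expect_true(all(td$replicate_support == "3/3"))
  expect_equal(sum(td$is_bait_mrna), 1)
  gl <- glance(cs)
  expect_equal(gl$n_consensus, length(cs$consensus))
})
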