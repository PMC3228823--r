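# a scan of n well-detected genes plus one configurable query gene
scan_with_query <- function(n = 250, query_ip_frac = 0.95, query_ratio = 1,
                            n_background = n, seed = 21) {
  withr::with_seed(seed, {
    genes <- c(sprintf("bg%03d", seq_len(n)), "query")
    ref <- 10^rnorm(n + 1, 2, 0.3)
    ip <- ref * 10^rnorm(n + 1, 0, 0.05)
    ip[n + 1] <- ref[n + 1] * query_ratio
    ip_frac <- c(rep(0.95, n_background), rep(0.2, n - n_background), query_ip_frac)
    spots <- spot_tbl(
      ip_frac = ip_frac, ref_frac = rep(0.99, n + 1),
      ip_signal = ip, ref_signal = ref,
      probe_id = paste0(genes, "_p1")
    )
    list(scan = make_scan(spots), annotation = annotation_for(genes))
  })
}

test_that("an mRNA with no IP-detectable spot is coded ND", {
  # query passes QC through the joint clause but stays below the stand-alone
  # IP threshold that defines detectability
  x <- scan_with_query(query_ip_frac = 0.6)
  cell <- score_or_code("query", x$scan, x$annotation, min_background = 200)
  expect_identical(cell$code, "ND")
  expect_identical(cell$value, "ND")
  expect_true(is.na(cell$score))
})

test_that("a detectable mRNA with too small a background is coded P", {
  # only 12 background genes survive QC
  x <- scan_with_query(n = 250, n_background = 12)
  cell <- score_or_code("query", x$scan, x$annotation, min_background = 200)
  expect_identical(cell$code, "P")
  expect_identical(cell$value, "P")
})

test_that("numeric scores agree with the standardized profile", {
  x <- scan_with_query(query_ratio = 30)
  cell <- score_or_code("query", x$scan, x$annotation, min_background = 200)
  expect_true(is.na(cell$code))
  std <- standardize_profile(enrichment_profile(x$scan, x$annotation))
  expect_equal(cell$score, std$s[std$gene_id == "query"])
  expect_gt(cell$score, 2)
})

test_that("a gene absent from the array design is an error, not ND", {
  x <- scan_with_query()
  expect_error(score_or_code("missing_gene", x$scan, x$annotation),
               class = "ripchip_gene_not_on_array")
})

test_that("condition comparisons follow the unanimity verdict rules", {
  # enriched in every control replicate, in no treated replicate
  expect_identical(compare_conditions(c(4.1, 3.8), c("ND", "0.3")), "lost")
  # enriched throughout
  expect_identical(compare_conditions(c(4.1, 3.8), c(3.5, 2.2)), "retained")
  # never enriched in the control arm
  expect_identical(compare_conditions(1.0, 0.5), "inconclusive")
  # threshold is inclusive and ND sits below it
  expect_identical(compare_conditions(c(2.0, 2.0), c("ND", "ND")), "lost")
  # disagreement between replicates -> inconclusive
  expect_identical(compare_conditions(c(4.1, 1.0), c(0.1, 0.2)), "inconclusive")
  expect_error(compare_conditions(numeric(), 1),
               class = "ripchip_validation_error")
})

test_that("P cells only decide a verdict when both readings agree", {
  # P in the treated arm flips the verdict between lost and retained
  expect_identical(compare_conditions(c(4.1, 3.8), "P"), "inconclusive")
  # P in the control arm of a clearly lost interaction: both readings differ
  expect_identical(compare_conditions(c("P", 4.0), c(0.1, 0.2)), "inconclusive")
  # P cannot rescue an interaction never enriched in control
  expect_identical(compare_conditions(c(0.5, "P"), c(4, 4)), "inconclusive")
})

test_that("swapping the arms of a lost interaction never yields lost", {
  ctrl <- c(4.1, 3.8)
  trt <- c("ND", 0.3)
  expect_identical(compare_conditions(ctrl, trt), "lost")
  expect_identical(compare_conditions(trt, ctrl), "inconclusive")
})

test_that("raw expression pairs are returned untouched, with no QC", {
  genes <- c("gA", "gB")
  ann <- annotation_for(genes, probes_per_gene = 3)
  mk <- function(ref) {
    # one probe would fail QC; raw comparison must keep it anyway
    make_scan(spot_tbl(
      ip_frac = c(0.1, 0.95, 0.95, 0.95, 0.95, 0.95),
      ref_frac = rep(0.99, 6),
      ip_signal = rep(5, 6), ref_signal = ref,
      probe_id = c(paste0("gA_p", 1:3), paste0("gB_p", 1:3))
    ))
  }
  plus <- mk(c(100, 110, 120, 7, 8, 9))
  minus <- mk(c(90, 105, 130, 7, 8, 9))
  pairs <- compare_raw_expression(plus, minus, "gA", ann)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$ref_plus, c(100, 110, 120))
  expect_equal(pairs$ref_minus, c(90, 105, 130))
  expect_error(compare_raw_expression(plus, minus, "gZ", ann),
               class = "ripchip_gene_not_on_array")
})

test_that("raw expression reveals unchanged vs degraded -ATG mRNA levels", {
  base <- function(cond, seed, factor = 1) {
    cfg <- ripchip_config(n_genes = 300, k = 1, seed = seed, condition = cond,
                          dye_swap_last = FALSE)
    cfg$atg_abundance_factor <- factor
    cfg
  }
  ann <- simulated_annotation(base("control", 1))
  plus <- simulate_experiment(base("control", 11))
  gene <- plus$truth$minus_atg_gene

  same <- simulate_experiment(base("minus_atg", 12))
  pairs_same <- compare_raw_expression(plus$scans[[1]], same$scans[[1]], gene, ann)
  ratio_same <- median(log10(pairs_same$ref_plus / pairs_same$ref_minus))
  expect_lt(abs(ratio_same), 0.3)  # statistically indistinguishable levels

  degraded <- simulate_experiment(base("minus_atg", 12, factor = 0.1))
  pairs_deg <- compare_raw_expression(plus$scans[[1]], degraded$scans[[1]], gene, ann)
  ratio_deg <- median(log10(pairs_deg$ref_plus / pairs_deg$ref_minus))
  expect_lt(abs(ratio_deg - 1), 0.3)  # the 10-fold drop is visible
})

test_that("perturbation reports assemble cells and verdicts across conditions", {
  mk <- function(cond, seed) {
    simulate_experiment(ripchip_config(n_genes = 300, k = 2, seed = seed,
                                       condition = cond))
  }
  ctrl <- mk("control", 31)
  ann <- simulated_annotation(ctrl$truth$config)
  atg <- mk("minus_atg", 32)
  puro <- mk("puromycin", 33)
  genes <- c(ctrl$truth$bait_gene, ctrl$truth$target_genes)
  rep <- perturbation_report(c(ctrl$scans, atg$scans, puro$scans), genes, ann,
                             min_background = 100)
  cells <- tidy(rep)
  expect_equal(nrow(cells), length(genes) * 6)
  expect_true(all(cells$value[is.na(cells$code)] != ""))
  v <- rep$verdicts
  designated <- ctrl$truth$minus_atg_gene
  other <- setdiff(ctrl$truth$target_genes, designated)
  expect_identical(
    v$verdict[v$condition_pair == "minus_atg_vs_control" & v$mRNA == designated],
    "lost"
  )
  expect_identical(
    v$verdict[v$condition_pair == "minus_atg_vs_control" & v$mRNA == other],
    "retained"
  )
  expect_true(all(
    v$verdict[v$condition_pair == "puromycin_vs_control"] == "lost"
  ))
  gl <- glance(rep)
  expect_true(all(c("lost", "retained", "inconclusive") %in% names(gl)))
})
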