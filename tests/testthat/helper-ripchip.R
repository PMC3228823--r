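# shared builders for handcrafted scans and annotations

spot_tbl <- function(ip_frac, ref_frac,
                     ip_signal = rep(100, length(ip_frac)),
                     ref_signal = rep(100, length(ip_frac)),
                     flag = rep(0L, length(ip_frac)),
                     probe_id = sprintf("p%02d", seq_along(ip_frac))) {
  tibble::tibble(
    probe_id = probe_id,
    ip_signal = ip_signal,
    ref_signal = ref_signal,
    ip_frac_above_bg = ip_frac,
    ref_frac_above_bg = ref_frac,
    flag = as.integer(flag)
  )
}

make_scan <- function(spots, ...) {
  new_scan(spots, experiment_id = "test_scan", ...)
}

write_spot_file <- function(spots, path = withr::local_tempfile(fileext = ".tsv",
                                                                .local_envir = parent.frame())) {
  readr::write_tsv(spots, path, progress = FALSE)
  path
}

# annotation in which every probe of gene g is named <g>_p<i>
annotation_for <- function(gene_ids, probes_per_gene = 1, is_coding = TRUE) {
  tibble::tibble(
    gene_id = rep(gene_ids, each = probes_per_gene),
    probe_id = paste0(rep(gene_ids, each = probes_per_gene), "_p",
                      rep(seq_len(probes_per_gene), length(gene_ids))),
    is_coding = rep(is_coding, length.out = length(gene_ids) * probes_per_gene)
  )[, c("probe_id", "gene_id", "is_coding")]
}

# a well-behaved scan of n genes, one probe each, with gene `hot` enriched
profile_scan <- function(n = 250, hot = NULL, hot_ratio = 100, seed = 42) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n))
    ref <- 10^rnorm(n, 2, 0.3)
    ip <- ref * 10^rnorm(n, 0, 0.05)
    if (!is.null(hot)) {
      ip[match(hot, genes)] <- ref[match(hot, genes)] * hot_ratio
    }
    spots <- spot_tbl(
      ip_frac = rep(0.95, n), ref_frac = rep(0.99, n),
      ip_signal = ip, ref_signal = ref,
      probe_id = paste0(genes, "_p1")
    )
    list(scan = make_scan(spots), annotation = annotation_for(genes))
  })
}
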