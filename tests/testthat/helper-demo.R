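# Shared demo fixture: two organs, three subtypes, 3- and 6-month arms,
# written to disk once per test run.
demo_fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "ecrestore-demo-fixture")
      cfg <- synth_config(organs = c("liver", "heart"),
                          timepoints = c(3L, 6L), cells_per_group = 40,
                          n_genes = 250, frac_de = 0.15, seed = 20)
      make_fixture(cfg, dir)
    }
    dir
  }
})

demo_gwas_path <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tmapped_gene\tp_value\ttrait",
               "rs1\tFBLN5\t1e-08\tstroke",
               "rs2\tCAR4\t2e-06\tstroke",
               "rs3\tVWF\t4e-07\tstroke",
               "rs4\tVWF\t1e-09\tstroke"), path)
  path
}

demo_config <- function(out_dir, seed = 1L) {
  fx <- demo_fixture_dir()
  list(
    out_dir = out_dir,
    seed = seed,
    input = list(matrix = file.path(fx, "matrix.mtx"),
                 genes = file.path(fx, "features.tsv"),
                 barcodes = file.path(fx, "barcodes.tsv"),
                 meta = file.path(fx, "cell_metadata.tsv")),
    # synthetic libraries are far shallower than real cells; scale the QC
    # gates accordingly
    qc = list(min_genes = 10L, max_genes = 100000L, max_umi = 10000000L,
              max_mito_frac = 1),
    downsample = list(n_cells = "auto", n_draws = 2L),
    gwas = list(path = demo_gwas_path(), trait = "stroke",
                organ = "liver", cluster = "cap", timepoint = 6L)
  )
}

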