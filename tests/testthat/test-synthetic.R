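small_params <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 3, cells_per_tissue = 40, n_genes = 40, seed = 11L),
    list(...))
  do.call(sim_params, args)
}

test_that("the generator is deterministic in its seed, in memory and on disk", {
  p <- small_params()
  s1 <- simulate_repertoires(p)
  s2 <- simulate_repertoires(p)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth$clones, s2$truth$clones)
  # a different seed changes the draw
  s3 <- simulate_repertoires(small_params(seed = 12L))
  expect_false(identical(s1$cells$beta_cdr3_nt, s3$cells$beta_cdr3_nt))

  co <- simulate_cohort(p)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(co, d1)
  write_fixtures(co, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("per-tissue cell budgets are met exactly", {
  sim <- simulate_repertoires(small_params())
  tr <- sim$truth$clones
  men <- tapply(tr$size_meninges, tr$patient_id, sum)
  brn <- tapply(tr$size_brain, tr$patient_id, sum)
  expect_true(all(men == 40))
  expect_true(all(brn == 40))
  # the emitted cells match the truth sizes clone by clone
  got <- table(sim$cells$clone_uid[sim$cells$tissue == "meninges"])
  expect_equal(unname(got[tr$clone_uid[tr$size_meninges > 0]]),
               unname(table(rep(tr$clone_uid, tr$size_meninges))[
                 tr$clone_uid[tr$size_meninges > 0]]))
  expect_false(any(duplicated(sim$cells$cell_barcode)))
})

test_that("zero sharing probability yields disjoint tissues and zero overlap", {
  sim <- simulate_repertoires(small_params(sharing_base = 0,
                                           sharing_coupling = 0))
  tr <- sim$truth$clones
  expect_false(any(tr$shared))
  expect_false(any(tr$size_meninges > 0 & tr$size_brain > 0))
  cc <- call_clones(sim$cells)
  for (pid in unique(tr$patient_id)) {
    mh <- morisita_overlap(cc$repertoires[[paste0("MEN_", pid)]],
                           cc$repertoires[[paste0("BRN_", pid)]])
    expect_equal(mh, 0)
  }
})

test_that("a degenerate size law gives all-singleton repertoires at maximal entropy", {
  sim <- simulate_repertoires(
    small_params(clone_law = "geometric", clone_law_param = 1,
                 sharing_base = 0))
  expect_true(all(sim$truth$clones$base_size == 1))
  cc <- call_clones(sim$cells)
  for (r in cc$repertoires) {
    expect_true(all(r$clones$count == 1))
    expect_equal(shannon_entropy(r), log(40), tolerance = 1e-12)
  }
})

test_that("intended entropy strata are recovered from the simulated repertoires", {
  hits <- 0L; total <- 0L
  for (sd in c(101L, 202L, 303L)) {
    sim <- simulate_repertoires(sim_params(seed = sd))
    cc <- call_clones(sim$cells)
    men <- Filter(function(r) r$tissue == "meninges", cc$repertoires)
    edf <- data.frame(
      sample_id = vapply(men, `[[`, "", "sample_id"),
      disease = vapply(men, `[[`, "", "disease"),
      shannon_entropy = vapply(men, shannon_entropy, numeric(1)),
      stringsAsFactors = FALSE)
    st <- stratify_samples(edf)
    truth <- sim$truth$samples
    exp_st <- truth$expected_stratum[match(st$sample_id, truth$sample_id)]
    hits <- hits + sum(st$stratum == exp_st)
    total <- total + nrow(st)
  }
  expect_gte(hits / total, 0.9)
})

test_that("zero dispersion gives Poisson-like counts and positive dispersion inflates them", {
  vmr <- function(nb_dispersion) {
    p <- small_params(n_patients = 2, cells_per_tissue = 100,
                      mito_high_rate = 0, marker_effects = list(),
                      nb_dispersion = nb_dispersion)
    co <- simulate_cohort(p)
    m <- as.matrix(co$expression$counts)
    m <- m[!startsWith(rownames(m), "MT-"), , drop = FALSE]
    mu <- rowMeans(m)
    keep <- mu > 0.5
    mean(apply(m[keep, ], 1, stats::var) / mu[keep])
  }
  expect_equal(vmr(0), 1, tolerance = 0.1)
  expect_gt(vmr(2), 1.5)
})

test_that("planted marker folds are visible in the raw counts", {
  co <- simulate_cohort(sim_params(n_patients = 4, cells_per_tissue = 250,
                                   n_genes = 60, seed = 5L))
  m <- co$expression$counts
  at <- co$cell_attributes
  exp_cells <- at$cell_barcode[at$expansion != "singleton"]
  sing_cells <- at$cell_barcode[at$expansion == "singleton"]
  ratio <- function(gene) {
    mean(m[gene, exp_cells]) / mean(m[gene, sing_cells])
  }
  expect_gt(ratio("ZNF683"), 1.5)
  expect_gt(ratio("CCL5"), 1.5)
  expect_lt(ratio("SELL"), 0.75)
  # untargeted background gene shows no such shift
  expect_equal(ratio("G0010"), 1, tolerance = 0.35)
})

test_that("fixture files have the expected shapes and round-trip losslessly", {
  p <- sim_params(n_patients = 1, diseases = c(ALS = 0),
                  cells_per_tissue = 10, n_genes = 20, seed = 9L)
  sim <- simulate_repertoires(p)
  d <- withr::local_tempdir()
  write_fixtures(sim, d)
  # one meningeal and one brain sample, two chain rows per cell
  csvs <- list.files(file.path(d, "contigs_10x"), full.names = TRUE)
  expect_setequal(basename(csvs), c("MEN_P01.csv", "BRN_P01.csv"))
  for (f in csvs) expect_equal(nrow(utils::read.csv(f)), 20)
  md <- utils::read.delim(file.path(d, "metadata.tsv"))
  expect_equal(nrow(md), 20)
  expect_false(file.exists(file.path(d, "expression", "matrix.mtx")))

  # both dialects recover every simulated cell with no drops
  for (dialect in c("tenx_csv", "airr_tsv")) {
    sub <- if (dialect == "tenx_csv") "contigs_10x" else "contigs_airr"
    paths <- list.files(file.path(d, sub), full.names = TRUE)
    samples <- sub("\\.(csv|tsv)$", "", basename(paths))
    rec <- do.call(rbind, Map(function(pth, s) {
      read_contigs(pth, dialect, sample_id = s)
    }, paths, samples))
    paired <- pair_cells(filter_chains(rec), md)
    expect_equal(sum(paired$audit$kept), 20)
    expect_equal(sum(paired$audit$dropped_missing_chain), 0)
    expect_equal(sum(paired$audit$dropped_multi_chain), 0)
    cc <- call_clones(paired$cells)
    tr <- sim$truth$clones
    men <- cc$repertoires[["MEN_P01"]]
    expect_equal(sort(men$clones$count),
                 sort(tr$size_meninges[tr$size_meninges > 0]))
  }
})

test_that("injected chain faults are recovered exactly by the pairing audit", {
  sim <- simulate_repertoires(small_params())
  contigs <- cells_to_contigs(sim$cells)
  inj <- inject_chain_faults(contigs, n_missing_chain = 7,
                             n_multi_chain = 4, seed = 2L)
  md <- sim$cells[c("cell_barcode", "sample_id", "patient_id", "tissue",
                    "disease")]
  paired <- pair_cells(filter_chains(inj$records), md)
  expect_equal(sum(paired$audit$dropped_missing_chain), 7)
  expect_equal(sum(paired$audit$dropped_multi_chain), 4)
  expect_equal(sum(paired$audit$kept), nrow(sim$cells) - 11)
  # the corrupted barcodes are exactly the ones missing from the output
  lost <- setdiff(sim$cells$cell_barcode, paired$cells$cell_barcode)
  expect_setequal(lost, inj$faults$cell_barcode)
})
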