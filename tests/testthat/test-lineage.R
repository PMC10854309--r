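# Two repertoires with controlled clone identities: clone i is identified by
# its beta CDR3; shared identities give cross-tissue overlap.
two_tissue_reps <- function(counts_men, counts_brn, cdr3_men, cdr3_brn,
                            patient = "P1") {
  men <- rep_from_counts(counts_men, sample = "MEN", patient = patient,
                         tissue = "meninges", beta_cdr3 = cdr3_men)
  brn <- rep_from_counts(counts_brn, sample = "BRN", patient = patient,
                         tissue = "brain", beta_cdr3 = cdr3_brn)
  list(men = men, brn = brn)
}

cdr3_pool <- paste0("TGT", c("GCAGCA", "TTCTTC", "AAAGGG", "GGGAAA",
                             "CCCGGG"))

test_that("Morisita-Horn matches hand-worked values and limits", {
  r <- two_tissue_reps(c(3, 2), c(3, 2), cdr3_pool[1:2], cdr3_pool[1:2])
  expect_equal(morisita_overlap(r$men, r$brn), 1, tolerance = 1e-12)

  r <- two_tissue_reps(c(3, 2), c(4, 1), cdr3_pool[1:2], cdr3_pool[3:4])
  expect_equal(morisita_overlap(r$men, r$brn), 0)

  # x = (2, 0), y = (1, 1): MH = 4 / (1.5 * 4) = 2/3
  r <- two_tissue_reps(2, c(1, 1), cdr3_pool[1], cdr3_pool[1:2])
  expect_equal(morisita_overlap(r$men, r$brn), 2 / 3, tolerance = 1e-12)
})

test_that("Morisita-Horn is symmetric, bounded and count-scale invariant", {
  skip_if_not_installed("vegan")
  withr::with_seed(31, {
    for (i in 1:25) {
      k <- sample(2:5, 1)
      cm <- sample(1:8, k, replace = TRUE)
      cb <- sample(1:8, k, replace = TRUE)
      shared <- sample(k, sample(0:k, 1))
      ids_m <- cdr3_pool[1:k]
      ids_b <- ifelse(seq_len(k) %in% shared, cdr3_pool[1:k],
                      paste0(cdr3_pool[1:k], "TTT"))
      r <- two_tissue_reps(cm, cb, ids_m, ids_b)
      mh <- morisita_overlap(r$men, r$brn)
      expect_gte(mh, 0); expect_lte(mh, 1 + 1e-12)
      expect_equal(morisita_overlap(r$brn, r$men), mh)
      r3 <- two_tissue_reps(cm * 3, cb, ids_m, ids_b)
      expect_equal(morisita_overlap(r3$men, r3$brn), mh,
                   tolerance = 1e-10)
      # independent reference: vegan's Horn-Morisita dissimilarity
      keys <- union(r$men$clones$clone_key, r$brn$clones$clone_key)
      x <- r$men$clones$count[match(keys, r$men$clones$clone_key)]
      y <- r$brn$clones$count[match(keys, r$brn$clones$clone_key)]
      x[is.na(x)] <- 0; y[is.na(y)] <- 0
      ref <- 1 - as.numeric(vegan::vegdist(rbind(x, y), method = "horn"))
      expect_equal(mh, ref, tolerance = 1e-10)
    }
  })
})

test_that("shared-clone flags agree with a brute-force double loop", {
  r <- two_tissue_reps(c(2, 1, 1, 3, 1), c(2, 2, 1),
                       cdr3_pool[1:5], c(cdr3_pool[2], cdr3_pool[4],
                                         paste0(cdr3_pool[5], "AAA")))
  flags <- flag_shared_clones(r$men, r$brn)
  expect_equal(sum(flags), 2)
  brute <- vapply(r$men$clones$clone_key, function(k) {
    any(vapply(r$brn$clones$clone_key, identical, logical(1), k))
  }, logical(1))
  expect_equal(unname(flags), unname(brute))
})

test_that("patient mismatch is a usage error", {
  men <- rep_from_counts(c(2, 1), sample = "M1", patient = "P1",
                         beta_cdr3 = cdr3_pool[1:2])
  brn <- rep_from_counts(c(2, 1), sample = "B2", patient = "P2",
                         tissue = "brain", beta_cdr3 = cdr3_pool[1:2])
  expect_error(flag_shared_clones(men, brn), "different patients")
})

test_that("shared-expansion summary counts clones and cells correctly", {
  # shared clones with meningeal counts {3, 2, 1}: clone-wise 2/3,
  # cell-wise 5/6
  r <- two_tissue_reps(c(3, 2, 1, 4), c(1, 1, 1),
                       cdr3_pool[1:4], cdr3_pool[1:3])
  flags <- flag_shared_clones(r$men, r$brn)
  s <- summarize_shared_expansion(r$men, flags, classify_expansion(r$men))
  expect_equal(s$n_shared_clones, 3)
  expect_equal(s$fraction_shared_expanded_clonewise, 2 / 3)
  expect_equal(s$fraction_shared_expanded_cellwise, 5 / 6)
  expect_equal(s$n_meningeal_cells, 10)
  expect_equal(s$n_meningeal_singleton_cells, 1)

  # all shared clones multi-cell -> fraction 1
  r <- two_tissue_reps(c(3, 2), c(1, 1), cdr3_pool[1:2], cdr3_pool[1:2])
  flags <- flag_shared_clones(r$men, r$brn)
  s <- summarize_shared_expansion(r$men, flags, classify_expansion(r$men))
  expect_equal(s$fraction_shared_expanded_clonewise, 1)

  # no shared clones -> fractions are absent
  r <- two_tissue_reps(c(3, 2), c(1, 1), cdr3_pool[1:2], cdr3_pool[3:4])
  flags <- flag_shared_clones(r$men, r$brn)
  s <- summarize_shared_expansion(r$men, flags, classify_expansion(r$men))
  expect_true(is.na(s$fraction_shared_expanded_clonewise))
  expect_true(is.na(s$fraction_shared_expanded_cellwise))
})

test_that("overlap group comparison gives exact small-sample p-values", {
  df <- data.frame(patient_id = letters[1:4],
                   disease = rep(c("ALS", "LOAD"), each = 2),
                   morisita = c(0.5, 0.6, 0.5, 0.6))
  expect_equal(overlap_group_comparison(df, c("ALS", "LOAD"))$p_value, 1)

  df$morisita <- c(0.9, 0.8, 0.1, 0.05)
  res <- overlap_group_comparison(df, c("ALS", "LOAD"))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  expect_error(
    overlap_group_comparison(df[c(1, 3, 4), ], c("ALS", "LOAD")),
    "at least 2")
})

test_that("the rank-sum comparison holds its size under the null", {
  withr::with_seed(77, {
    rej <- vapply(seq_len(1000), function(i) {
      df <- data.frame(patient_id = as.character(1:10),
                       disease = rep(c("ALS", "LOAD"), each = 5),
                       morisita = runif(10))
      overlap_group_comparison(df, c("ALS", "LOAD"))$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
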