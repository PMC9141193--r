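test_that("plain TSV expression matrices parse with numeric coercion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tA\tB",
               "G1\t1.5\t2.0",
               "G2\t0.1\t-1.2",
               "G3\tnot_a_number\t3.5"), path)
  m <- load_expression_matrix(path, format = "tsv", cohort = "c1")
  expect_equal(dim(m), c(3, 2))
  expect_equal(rownames(m), c("G1", "G2", "G3"))
  expect_equal(m["G1", "B"], 2.0)
  expect_true(is.na(m["G3", "A"])) # unparseable cell becomes missing
  expect_equal(attr(m, "cohort"), "c1")
})

test_that("series-matrix dialect extracts the delimited block and maps null cells", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"a study\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
    "\"P1\"\t5.1\t4.9",
    "\"P2\"\tnull\t3.3",
    "!series_matrix_table_end",
    "!trailing junk"), path)
  m <- load_expression_matrix(path, format = "series_matrix")
  expect_equal(dim(m), c(2, 2))
  expect_true(is.na(m["P2", "GSM1"]))
  expect_equal(m["P2", "GSM2"], 3.3)
})

test_that("duplicate sample headers and empty blocks are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tA\tA", "G1\t1\t2"), path)
  expect_error(load_expression_matrix(path), "duplicate sample")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!series_matrix_table_begin", "!series_matrix_table_end"), path2)
  expect_error(load_expression_matrix(path2, format = "series_matrix"),
               "empty|malformed")
})

test_that("collapse_probes keeps the highest-mean probe per gene and drops unmapped", {
  m <- rbind(A = c(5, 5, NA), B = c(7, 7, 7), C = c(1, 1, 1), D = c(9, 9, 9))
  colnames(m) <- c("s1", "s2", "s3")
  map <- tibble::tibble(probe_id = c("A", "B", "C", "D"),
                        gene_symbol = c("gene1", "gene1", "gene2", ""))
  out <- collapse_probes(m, map)
  expect_equal(sort(rownames(out)), c("GENE1", "GENE2"))
  expect_equal(unname(out["GENE1", ]), c(7, 7, 7)) # B (mean 7) beats A (mean 5)
  expect_false("D" %in% rownames(out)) # unmapped probe dropped
  expect_error(collapse_probes(m, tibble::tibble(probe_id = "Z", gene_symbol = "X")),
               "no probe maps")
})

test_that("collapse_probes with absolute_max keeps the peak probe", {
  m <- rbind(A = c(10, 0, 0), B = c(4, 4, 4))
  colnames(m) <- paste0("s", 1:3)
  map <- tibble::tibble(probe_id = c("A", "B"), gene_symbol = c("g", "g"))
  expect_equal(unname(collapse_probes(m, map)["G", ]), c(4, 4, 4))
  expect_equal(unname(collapse_probes(m, map, "absolute_max")["G", ]), c(10, 0, 0))
})

test_that("collapse_probes is idempotent on gene-keyed matrices", {
  sim <- small_sim(n_genes = 40, n_samples = c(10, 10), sizes = c(10), specific = NULL,
                   pheno_weights = 2, fvc_weights = 1, dlco_weights = 1,
                   latent_loadings = 0)
  m <- sim$expression$cohort1
  identity_map <- tibble::tibble(probe_id = rownames(m), gene_symbol = rownames(m))
  once <- collapse_probes(m, identity_map)
  twice <- collapse_probes(once, tibble::tibble(probe_id = rownames(once),
                                                gene_symbol = rownames(once)))
  expect_equal(unclass(once), unclass(twice))
})

test_that("filter_missing removes bad genes then bad samples, reporting counts", {
  m <- rbind(
    g1 = c(1, 2, 3, 4, 5),
    g2 = c(NA, NA, NA, 4, 5),   # 60% missing
    g3 = c(2, 2, 2, 2, 2),      # constant
    g4 = c(1, NA, 3, 4, 5)
  )
  colnames(m) <- paste0("s", 1:5)
  out <- filter_missing(m, max_gene_missing = 0.5, max_sample_missing = 0.5)
  expect_equal(sort(rownames(out)), c("g1", "g4")) # g2, g3 removed
  report <- attr(out, "filter_report")
  expect_equal(report$removed[report$step == "genes_missing"], 1)
  expect_equal(report$removed[report$step == "genes_low_variance"], 1)
  # clean matrix passes through unchanged
  clean <- out
  expect_equal(unclass(filter_missing(clean)), unclass(clean),
               ignore_attr = "filter_report")
  expect_error(filter_missing(m[3, , drop = FALSE]), "all .* removed|all 1 genes")
})

test_that("retained genes and samples satisfy their missingness thresholds", {
  withr::with_seed(5, {
    m <- matrix(rnorm(600), 30, 20,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
    m[sample(length(m), 150)] <- NA
  })
  out <- filter_missing(m, max_gene_missing = 0.3, max_sample_missing = 0.3)
  # every retained gene passed the gene threshold on the pre-filter samples
  expect_true(all(rowMeans(is.na(m[rownames(out), ])) <= 0.3))
  # every retained sample passes the sample threshold on the retained genes
  expect_true(all(colMeans(is.na(out)) <= 0.3))
  # and no sample removal can re-break the gene pass by more than the
  # mass of the removed columns
  expect_true(all(apply(out, 1, var, na.rm = TRUE) > 1e-10))
})

test_that("align_cohorts intersects gene sets case-insensitively in shared order", {
  m1 <- matrix(1:6, 3, 2, dimnames = list(c("a", "B", "c"), c("s1", "s2")))
  m2 <- matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"), c("t1", "t2")))
  out <- align_cohorts(list(x = m1, y = m2))
  expect_equal(rownames(out$x), c("B", "C"))
  expect_identical(rownames(out$x), rownames(out$y))
  expect_equal(unname(out$x["C", ]), c(3, 6)) # row "c" of m1
  m3 <- matrix(1:4, 2, 2, dimnames = list(c("x1", "x2"), c("u1", "u2")))
  expect_error(align_cohorts(list(m1, m3)), "no genes shared")
  expect_error(align_cohorts(list(m1)), "at least two")
})

test_that("trait tables validate phenotype coding and sample membership", {
  tt <- tibble::tibble(sample_id = c("s1", "s2"), phenotype = c(1, 0),
                       fvc = c(1.2, NA), dlco = c(NA, 2))
  expect_silent(validate <- conexus:::validate_trait_table(tt))
  expect_error(conexus:::validate_trait_table(
    tibble::tibble(sample_id = "s1", phenotype = 2)), "0/1")
  expect_error(conexus:::validate_trait_table(
    tibble::tibble(sample_id = c("s1", "s2"), phenotype = c(1, 1))), "case and one control")
  m <- matrix(0, 1, 1, dimnames = list("g", "s9"))
  expect_error(conexus:::validate_trait_table(tt, m), "absent from")
})
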