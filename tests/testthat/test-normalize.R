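# Depth normalization, HVG selection, batch correction, scaling.

test_that("Pearson residuals vanish when expression is depth-proportional", {
  # depths (100,100,200,200); gene g1 with counts (1,1,2,2) is exactly
  # proportional, so mu = x and residuals are 0 (hand-checked: pi_g = 6/600,
  # mu = depth * 0.01 = (1,1,2,2))
  x <- cbind(g1 = c(1, 1, 2, 2), g2 = c(99, 99, 198, 198))
  em <- expression_matrix(x, paste0("c", 1:4), c("g1", "g2"),
                          layer_tag = "counts")
  norm <- normalize_counts(em, "pearson_residual")
  expect_equal(unname(norm$values[, "g1"]), rep(0, 4))
  expect_identical(norm$layer_tag, "normalized")
})

test_that("equal expression at equal depth gives zero residuals", {
  x <- cbind(g1 = rep(3, 5), g2 = rep(7, 5))
  em <- expression_matrix(x, paste0("c", 1:5), c("g1", "g2"),
                          layer_tag = "counts")
  norm <- normalize_counts(em, "pearson_residual")
  expect_equal(max(abs(norm$values)), 0)
})

test_that("log-CPM of a zero count is zero and depth is removed", {
  # both cells express g2 as half their UMIs, at 2x different depth
  x <- cbind(g1 = c(0L, 0L), g2 = c(5L, 10L), g3 = c(5L, 10L))
  em <- expression_matrix(x, c("c1", "c2"), c("g1", "g2", "g3"),
                          layer_tag = "counts")
  norm <- normalize_counts(em, "log_cpm")
  expect_equal(norm$values[1, "g1"], 0)
  # same proportions at different depth -> same normalized value
  expect_equal(norm$values[1, "g2"], norm$values[2, "g2"])
})

test_that("zero-depth cells are rejected with advice to run QC", {
  em <- expression_matrix(matrix(c(1, 0), 2, 1), c("a", "b"), "g",
                          layer_tag = "counts")
  expect_error(normalize_counts(em), "zero-depth")
})

test_that("residuals of depth-proportional Poisson genes are standardized", {
  # pure Poisson noise proportional to depth: residual mean ~ 0, var ~ 1
  n <- 2000
  withr::with_seed(7, {
    depth_factor <- exp(rnorm(n, 0, 0.3))
    x <- sapply(rep(c(2, 5, 10), 10), function(m) rpois(n, m * depth_factor))
  })
  colnames(x) <- sprintf("g%02d", seq_len(ncol(x)))
  em <- expression_matrix(x, sprintf("c%04d", 1:n), colnames(x),
                          layer_tag = "counts")
  r <- normalize_counts(em, "pearson_residual")$values
  mu <- colMeans(r)
  v <- apply(r, 2, var)
  expect_true(all(abs(mu) < 0.2))
  expect_true(all(abs(v - 1) < 0.2))
})

test_that("HVG selection keeps planted high-variance genes and breaks ties by name", {
  sim <- small_sim()
  norm <- normalize_counts(filter_cells(sim$reference,
                                        compute_qc(sim$reference)))
  markers <- unlist(sim$truth$marker_sets[setdiff(names(sim$truth$marker_sets),
                                                  "novel")])
  hv <- select_hvg(norm, length(markers) + 10)
  expect_true(all(markers %in% hv$gene_ids))
  # explicit tie at the cutoff: equal variance, lexicographically smaller kept
  x <- cbind(zz = c(0, 4), aa = c(0, 4), mm = c(0, 2))
  nm <- expression_matrix(x, c("c1", "c2"), colnames(x),
                          layer_tag = "normalized")
  expect_identical(select_hvg(nm, 1)$gene_ids, "aa")
  # n_genes = total is the identity; larger warns
  expect_identical(select_hvg(nm, 3)$gene_ids, colnames(x))
  expect_warning(select_hvg(nm, 10), "keeping all")
})

test_that("query gene alignment reorders, zero-fills and reports", {
  ref_genes <- c("g1", "g2", "g3", "g4")
  q <- expression_matrix(cbind(g3 = c(1, 2), g1 = c(3, 4), extra = c(9, 9)),
                         c("c1", "c2"), c("g3", "g1", "extra"),
                         layer_tag = "counts")
  out <- align_query_genes(ref_genes, q)
  expect_identical(out$gene_ids, ref_genes)
  expect_equal(unname(out$values[, "g1"]), c(3, 4))
  expect_equal(unname(out$values[, "g3"]), c(1, 2))
  expect_equal(unname(out$values[, "g2"]), c(0, 0))
  rep <- attr(out, "align_report")
  expect_equal(rep$matched, 2)
  expect_equal(rep$missing, 2)
  expect_equal(rep$dropped, 1)
  # below 50% overlap is an error
  expect_error(align_query_genes(c("a", "b", "c", "g1", "g3"), q), "50%")
})

test_that("batch correction restores reference moments exactly for affine shifts", {
  sim <- small_sim()
  ref <- normalize_counts(filter_cells(sim$reference,
                                       compute_qc(sim$reference)))
  shifted <- ref
  shifted$values <- ref$values + 5
  corrected <- correct_batch(ref, shifted)
  expect_equal(corrected$values, ref$values, tolerance = 1e-10)
  # identity within floating tolerance
  self <- correct_batch(ref, ref)
  expect_equal(self$values, ref$values, tolerance = 1e-10)
})

test_that("batch correction aligns per-gene moments of a planted batch effect", {
  sim <- small_sim()
  ref <- normalize_counts(filter_cells(sim$reference, compute_qc(sim$reference)))
  qry <- align_query_genes(ref$gene_ids,
                           normalize_counts(filter_cells(sim$query,
                                                         compute_qc(sim$query))))
  corrected <- correct_batch(ref, qry)
  rm_ <- colMeans(ref$values); rs <- apply(ref$values, 2, sd)
  cm <- colMeans(corrected$values); cs <- apply(corrected$values, 2, sd)
  expect_equal(cm, rm_, tolerance = 1e-6)
  nz <- apply(qry$values, 2, sd) > 0
  expect_equal(cs[nz], rs[nz], tolerance = 1e-6)
  # planted multiplicative factor: residual shift below 1% of pooled SD
  shift <- abs(cm - rm_) / pmax(rs, 1e-12)
  expect_true(max(shift) < 0.01)
  expect_error(correct_batch(ref, qry[1, ]), "2 query cells")
})

test_that("scaling maps reference to [0,1], clips queries, zeroes constants", {
  ref <- expression_matrix(cbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5)),
                           paste0("c", 1:3), c("g1", "g2"),
                           layer_tag = "normalized")
  s <- fit_scaling(ref)
  expect_equal(unname(s$per_gene_min), c(2, 5))
  expect_equal(unname(s$per_gene_max), c(6, 5))
  scaled <- apply_scaling(ref, s)
  expect_equal(unname(scaled$values[, "g1"]), c(0, 0.5, 1))
  expect_equal(unname(scaled$values[, "g2"]), c(0, 0, 0))
  expect_identical(scaled$layer_tag, "scaled")
  # query above the reference max clips to 1; constant gene stays 0
  q <- expression_matrix(cbind(g1 = 8, g2 = 100), "q1", c("g1", "g2"),
                         layer_tag = "normalized")
  qs <- apply_scaling(q, s)
  expect_equal(unname(qs$values[1, ]), c(1, 0))
  # scaling serializes as TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scaling(s, path)
  s2 <- read_scaling(path)
  expect_equal(s2$per_gene_min, unname(s$per_gene_min))
  expect_equal(s2$per_gene_max, unname(s$per_gene_max))
})

test_that("scaled output is always in [0,1] and spans it per non-constant gene", {
  sim <- small_sim()
  ref <- normalize_counts(filter_cells(sim$reference, compute_qc(sim$reference)))
  s <- fit_scaling(ref)
  scaled <- apply_scaling(ref, s)
  expect_true(all(scaled$values >= 0 & scaled$values <= 1))
  nonconst <- s$per_gene_max > s$per_gene_min
  expect_true(all(apply(scaled$values[, nonconst], 2, min) == 0))
  expect_true(all(apply(scaled$values[, nonconst], 2, max) == 1))
  expect_error(fit_scaling(ref[integer(0), ]), "empty|dimensions")
})
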