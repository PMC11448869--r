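make_counts <- function(m) {
  rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%02d", seq_len(ncol(m)))
  cell_matrix(m)
}

test_that("QC removes cells by molecule count and mitochondrial fraction", {
  # 4 cells x 3 genes; gene g03 is mitochondrial
  m <- rbind(c(300, 100, 0),     # 400 molecules -> removed (<500)
             c(400, 200, 0),     # 600 molecules, mito 0 -> kept
             c(300, 150, 150),   # mito 150/600 = 0.25 -> removed (>20%)
             c(400, 110, 90))    # mito 90/600 = 0.15 -> kept
  rownames(m) <- sprintf("c%d", 1:4)
  colnames(m) <- c("g1", "g2", "mt-g1")
  cm <- cell_matrix(m)
  out <- qc_filter(cm, qc_thresholds(min_cells_per_gene = 0))
  expect_setequal(cell_ids(out), c("c2", "c4"))
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$rule == "min_molecules"], 1)
  expect_equal(rep$removed[rep$rule == "mito_fraction"], 1)
})

test_that("gene filter applies the strict 'expressed in > n cells' rule", {
  # 12 cells; gene 1 expressed in exactly 10 cells (removed at default 10),
  # gene 2 in 11 cells (kept); gene 3 keeps cells above the molecule filter
  m <- cbind(c(rep(1, 10), 0, 0), c(rep(1, 11), 0), rep(600, 12))
  cm <- make_counts(m)
  out <- qc_filter(cm, qc_thresholds(min_cells_per_gene = 10))
  expect_false("g01" %in% gene_ids(out))
  expect_true("g02" %in% gene_ids(out))
})

test_that("QC errors when nothing survives and is idempotent on typical data", {
  m <- make_counts(matrix(1L, 3, 3))
  expect_error(qc_filter(m), "empty after QC")

  prog <- state_programs(states = c("TH1", "TFH"), n_genes = 120, seed = 6)
  cfg <- sim_config(n_cells = c(TH1 = 150, TFH = 150), mito_frac = 0.08,
                    seed = 6)
  cm <- simulate_expression(prog, cfg)
  thr <- qc_thresholds(min_molecules = 100)
  once <- qc_filter(cm, thr)
  twice <- qc_filter(once, thr)
  expect_equal(dim(twice), dim(once))
  expect_identical(cell_ids(twice), cell_ids(once))
})

test_that("normalization dialects implement their exact arithmetic", {
  # cp10k_log2_p1: cell with counts (1,1) -> (5000,5000) -> log2(5001)
  cm <- make_counts(matrix(c(1, 1), 1, 2))
  cm <- normalize_cells(cm, "cp10k_log2_p1")
  expect_equal(unname(get_layer(cm, "log")[1, ]), rep(log2(5001), 2))

  # median dialect: totals (2,4), median 3; cell 1 scaled x1.5
  m2 <- rbind(c(2, 0), c(3, 1))
  cm2 <- normalize_cells(make_counts(m2), "median_log2_p0.1")
  expect_equal(unname(get_layer(cm2, "log")[1, ]),
               log2(c(2 * 1.5, 0) + 0.1))
  expect_equal(unname(get_layer(cm2, "log")[2, ]),
               log2(c(3 * 0.75, 1 * 0.75) + 0.1))

  # symmetry: an all-equal matrix normalizes to a single value
  cm3 <- normalize_cells(make_counts(matrix(2, 3, 4)), "median_log2_p0.1")
  expect_equal(length(unique(as.vector(get_layer(cm3, "log")))), 1)

  expect_error(normalize_cells(make_counts(rbind(c(0, 0), c(1, 1)))),
               "zero-total")
})

test_that("normalization preserves within-cell gene rank order", {
  set.seed(1)
  cm <- make_counts(matrix(rpois(200, 5), 10, 20))
  for (d in c("median_log2_p0.1", "cp10k_log2_p1")) {
    cmn <- normalize_cells(cm, d)
    lg <- get_layer(cmn, "log")
    for (i in 1:10) {
      expect_equal(unname(rank(lg[i, ])), rank(as.numeric(cm$counts[i, ])))
    }
  }
})

test_that("HVG selection ranks planted variable genes above flat ones", {
  set.seed(2)
  n <- 200
  flat <- matrix(rpois(n * 30, 5), n, 30)
  bimodal <- rpois(n, ifelse(seq_len(n) <= n / 2, 1, 9))  # same mean ~5
  constant <- rep(5L, n)
  m <- cbind(flat, bimodal, constant)
  cm <- make_counts(m)
  cm$counts <- Matrix::Matrix(m, sparse = TRUE,
                              dimnames = dimnames(cm$counts))
  cm <- normalize_cells(cm, "median_log2_p0.1")
  top <- select_hvg(cm, n = 5, n_bins = 4)
  expect_true("g31" %in% top)                 # the bimodal gene
  all_ranked <- select_hvg(cm, n = ncol(m), n_bins = 4)  # identity selection
  expect_setequal(all_ranked, gene_ids(cm))
  # the constant gene never precedes a varying gene of its bin
  expect_gt(match("g32", all_ranked), match("g31", all_ranked))
  expect_warning(select_hvg(cm, n = ncol(m) + 5), "exceeds")
})

test_that("differential expression applies strict printed thresholds", {
  set.seed(3)
  n <- 50
  base <- matrix(rpois(2 * n * 19, 10), 2 * n, 19)
  planted <- c(rpois(n, 30), rpois(n, 6))
  cm <- make_counts(cbind(base, planted))
  grp <- rep(c("A", "B"), each = n)
  cm <- normalize_cells(cm, "median_log2_p0.1")
  de <- differential_expression(cm, grp, min_lfc = 0.5, max_fdr = 0.01)
  expect_equal(de$gene[de$pass], "g20")

  # identical groups: nothing passes
  cm0 <- normalize_cells(make_counts(rbind(base, base)[1:20, , drop = FALSE]),
                         "median_log2_p0.1")
  de0 <- differential_expression(cm0, rep(c("A", "B"), each = 10))
  expect_false(any(de0$pass))

  # a shift of exactly 0.5 on the log layer fails the strict "> 0.5" cutoff
  cm1 <- make_counts(matrix(1L, 20, 2))
  lay <- matrix(c(rep(1, 10), rep(1.5, 10)), 20, 2)
  dimnames(lay) <- dimnames(cm1$counts)
  cm1$layers$log <- lay
  de1 <- differential_expression(cm1, rep(c("A", "B"), each = 10),
                                 min_lfc = 0.5, max_fdr = 0.5)
  expect_equal(unname(abs(de1$log2fc)), c(0.5, 0.5))
  expect_false(any(de1$pass))

  expect_error(differential_expression(cm1, c(rep("A", 19), "B")),
               "at least 2 cells")
})

test_that("BH adjustment is monotone with max adjusted p equal to max raw p", {
  set.seed(4)
  cm <- make_counts(matrix(rpois(40 * 25, 8), 40, 25))
  cm <- normalize_cells(cm, "median_log2_p0.1")
  de <- differential_expression(cm, rep(c("A", "B"), each = 20))
  o <- order(de$p)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  expect_equal(max(de$fdr), max(de$p))
})
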