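meta2 <- function(variety = "sensitive", stage = "MD") {
  data.frame(sample_id = sprintf("s%d", 1:4), variety = variety,
             treatment = rep(c("C", "D"), each = 2), stage = stage,
             replicate = rep(1:2, 2), stringsAsFactors = FALSE)
}

test_that("identical noise-free arms are never called differential", {
  m <- matrix(rep(c(5, 5, 5, 5), each = 1), nrow = 3, ncol = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), sprintf("s%d", 1:4)))
  calls <- call_differential(m, meta2(), "sensitive", "MD")
  expect_true(all(calls$direction == "ns"))
  expect_true(all(calls$log2fc == 0))
})

test_that("threshold degeneracy calls every gene with a nonzero difference", {
  set.seed(1)
  m <- matrix(rpois(40, 20), 10, 4,
              dimnames = list(paste0("g", 1:10), sprintf("s%d", 1:4)))
  m[1, ] <- c(10, 10, 10, 10)   # exactly equal arms stay ns
  calls <- call_differential(m, meta2(), "sensitive", "MD",
                             alpha = 1, lfc_threshold = 0)
  expect_equal(calls$direction[1], "ns")
  nz <- calls$log2fc != 0
  expect_true(all(calls$direction[nz] != "ns"))
})

test_that("planted effects are recovered at low noise with high concordance", {
  # high baseline keeps drought-suppressed genes out of the shot-noise regime
  cfg <- tiny_config(n_genes = 200L, dispersion = 0.01, base_lfc = 3,
                     baseline_log2_mean = 12, baseline_log2_sd = 0.5)
  e <- simulate_expression(simulate_genome(cfg))
  calls <- call_differential(e$fpkm, e$meta, "sensitive", "SD")
  truth <- e$truth$de[e$truth$de$variety == "sensitive" & e$truth$de$stage == "SD", ]
  truth_dir <- truth$direction[match(calls$gene_id, truth$gene_id)]
  planted <- truth_dir != "ns"
  concord <- mean(calls$direction[planted] == truth_dir[planted])
  expect_gte(concord, 0.95)
  # and >= 95% of planted same-direction genes come out as induced
  all_calls <- do.call(rbind, lapply(c("ID", "MD", "SD"), function(st)
    call_differential(e$fpkm, e$meta, "sensitive", st)))
  induced <- call_drought_induced(all_calls)
  planted_genes <- unique(truth$gene_id[truth$direction != "ns"])
  expect_gte(mean(planted_genes %in% induced$gene_id), 0.95)
})

test_that("drought-induced calling enforces the shared-direction rule", {
  calls <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 3),
    stage = rep(c("ID", "MD", "SD"), 3),
    log2fc = c(0, 2, 2,   0, 2, -2,   0, 0, 0),
    pvalue = 0.01, padj = 0.01,
    direction = c("ns", "up", "up",  "ns", "up", "down",  "ns", "ns", "ns"),
    stringsAsFactors = FALSE)
  ind <- call_drought_induced(calls)
  expect_equal(ind$gene_id, "g1")        # g2 opposite directions, g3 all ns
  expect_equal(ind$direction, "up")
  expect_equal(ind$supporting, "MD,SD")
  expect_error(call_drought_induced(calls[calls$stage != "SD", ]), "SD")
})

test_that("relaxing alpha never shrinks the induced set (directions unchanged)", {
  # genes with sign-consistent fold changes across stages: relaxing alpha can
  # only add supporting stages of the same direction
  set.seed(7)
  genes <- paste0("g", 1:60)
  sign_g <- sample(c(-1, 1), 60, replace = TRUE)
  tab <- expand.grid(gene_id = genes, stage = c("ID", "MD", "SD"),
                     stringsAsFactors = FALSE)
  tab$log2fc <- sign_g[match(tab$gene_id, genes)] * (1 + abs(rnorm(nrow(tab))))
  tab$padj <- runif(nrow(tab))
  induced_at <- function(a) {
    tab$direction <- ifelse(tab$padj <= a, ifelse(tab$log2fc > 0, "up", "down"), "ns")
    call_drought_induced(tab)$gene_id
  }
  sets <- lapply(c(0.01, 0.05, 0.2, 0.8), induced_at)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("recovery classification partitions the induced set", {
  induced <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                        direction = "down", supporting = "MD", n_stages = 1L,
                        stringsAsFactors = FALSE)
  rw <- data.frame(gene_id = c("g1", "g2", "g3"), stage = "RW",
                   log2fc = c(0, -2, 0.1), pvalue = 1, padj = c(1, 0.001, 0.8),
                   direction = c("ns", "down", "ns"), stringsAsFactors = FALSE)
  rec <- classify_recovery(induced, rw)
  expect_equal(rec$recovered, 2)           # g1, g3 are ns at RW
  expect_equal(rec$still_differential, 1)  # g2 still down
  expect_equal(rec$missing, 1)             # g4 absent: reported, not dropped
  expect_equal(rec$recovered + rec$still_differential + rec$missing, nrow(induced))
  tab <- recovery_table(rec, rec)
  expect_equal(dim(tab), c(2L, 2L))
})

test_that("chi-square on 2x2 tables matches the closed form", {
  tab <- rbind(c(20, 10), c(10, 20))
  res <- chi_square_2x2(tab, correct = FALSE)
  expect_equal(res$statistic, chisq_2x2_oracle(tab))
  expect_equal(res$p_value, pchisq(chisq_2x2_oracle(tab), 1, lower.tail = FALSE))

  flat <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
  expect_error(chi_square_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("external differential tables are validated against the contract", {
  ok <- data.frame(gene_id = "g1", stage = "MD", log2fc = 2, padj = 0.01,
                   direction = "up", stringsAsFactors = FALSE)
  expect_silent(as_differential_calls(ok))
  bad <- ok; bad$direction <- "down"
  expect_error(as_differential_calls(bad), "invariant")
})
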