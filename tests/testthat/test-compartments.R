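# Plaid matrix with a known A/B block structure for eigenvector tests.
plaid_matrix <- function(labels, decay = 0.8, boost = 2, seed = 5) {
  n <- length(labels)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  same <- outer(labels, labels, "==")
  set.seed(seed)
  m <- (d + 1)^(-decay) * ifelse(same, boost, 1) * exp(matrix(rnorm(n * n, 0, 0.05), n))
  (m + t(m)) / 2
}

test_that("the eigentrack recovers a planted plaid pattern", {
  labels <- rep(c("A", "B"), each = 10, times = 3)
  density <- ifelse(labels == "A", 3, 1)
  tr <- compute_eigentrack(plaid_matrix(labels), density)
  expect_s3_class(tr, "ca_eigentrack")
  called <- call_compartments(tr)
  expect_gte(mean(called == labels), 0.99)
  expect_false(tr$low_signal)
})

test_that("negating the orientation track flips every compartment sign", {
  labels <- rep(c("A", "B"), each = 8, times = 2)
  density <- ifelse(labels == "A", 3, 1)
  m <- plaid_matrix(labels)
  a <- compute_eigentrack(m, density)
  b <- compute_eigentrack(m, -density)
  expect_equal(b$values, -a$values)
})

test_that("degenerate and masked inputs are handled explicitly", {
  n <- 30
  expect_error(compute_eigentrack(matrix(0, n, n), rep(1, n)), "all-zero")
  expect_error(compute_eigentrack(matrix(1, 5, 5), rep(1, 5)), "unmasked")
  # pure distance decay has no plaid pattern: low-signal flag, all masked
  d <- abs(outer(1:40, 1:40, "-"))
  m <- (d + 1)^(-0.8)
  tr <- compute_eigentrack(m, rep(1, 40))
  expect_true(tr$low_signal)
  expect_true(all(call_compartments(tr) == "masked"))
  # zero-coverage bins come back masked
  labels <- rep(c("A", "B"), each = 10, times = 2)
  mm <- plaid_matrix(labels)
  mm[3, ] <- 0; mm[, 3] <- 0
  tr2 <- compute_eigentrack(mm, ifelse(labels == "A", 3, 1))
  expect_true(is.na(tr2$values[3]))
  expect_equal(call_compartments(tr2)[3], "masked")
})

test_that("the sign rule masks exact zeros", {
  expect_equal(call_compartments(c(0.3, -0.2, 0, NA)),
               c("A", "B", "masked", "masked"))
})

test_that("the sixteen switch strings partition into the five groups", {
  all16 <- apply(expand.grid(rep(list(c("A", "B")), 4)), 1, paste, collapse = "")
  g <- switch_group(all16)
  expect_equal(unname(table(g)[c("stable", "AB", "BA", "ABA", "BAB")]),
               c(2L, 4L, 4L, 3L, 3L), ignore_attr = TRUE)
  expect_setequal(all16[g == "stable"], c("AAAA", "BBBB"))
  expect_setequal(all16[g == "AB"], c("AAAB", "ABAB", "AABB", "ABBB"))
  expect_setequal(all16[g == "BA"], c("BAAA", "BABA", "BBAA", "BBBA"))
  expect_setequal(all16[g == "ABA"], c("ABBA", "ABAA", "AABA"))
  expect_setequal(all16[g == "BAB"], c("BAAB", "BABB", "BBAB"))
  expect_error(switch_group("ABC"), "four-letter")
})

test_that("switch-pattern classification excludes bins masked at any stage", {
  tracks <- list(c("A", "A", "B", "masked"),
                 c("A", "B", "B", "A"),
                 c("A", "B", "B", "A"),
                 c("A", "A", "A", "A"))
  res <- classify_switch_patterns(tracks, bin_size = 2e4)
  expect_equal(res$bins$bin, c(1L, 2L, 3L))
  expect_equal(res$bins$pattern, c("AAAA", "ABBA", "BBBA"))
  expect_equal(res$bins$group, c("stable", "ABA", "BA"))
  expect_equal(unname(res$span_mb["stable"]), 0.02)
  expect_equal(sum(res$span_mb), 0.06)
  expect_error(classify_switch_patterns(tracks[1:3], 2e4), "four")
  bad <- tracks; bad[[2]] <- bad[[2]][1:3]
  expect_error(classify_switch_patterns(bad, 2e4), "mismatch")
})

test_that("switch regions associate with genes via >= 1 bp overlap", {
  switch_bins <- data.frame(chrom = "A01", start = c(1e5, 3e5),
                            end = c(1.2e5, 3.2e5), group = c("AB", "BA"),
                            stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = "A01",
    start = c(119999, 120000, 300000, 500000),   # 1-bp overlap / abutting / in / out
    end   = c(125000, 125000, 305000, 505000),
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("g1", "g3"), direction = c("up", "down"),
                   stringsAsFactors = FALSE)
  res <- associate_switches_with_genes(switch_bins, genes, de)
  expect_equal(res$genes_by_group$AB, "g1")   # g2 abuts: zero overlap
  expect_equal(res$genes_by_group$BA, "g3")
  expect_equal(unname(res$table["inside", ]), c(2L, 0L))
  expect_equal(unname(res$table["outside", ]), c(0L, 2L))
  expect_equal(res$chisq$statistic, chisq_2x2_oracle(res$table))
})
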