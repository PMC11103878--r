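test_that("edge filtering is strict, canonical and self-edge free", {
  edges <- data.frame(
    gene_a = c("g2", "g1", "g3", "g1", "g2"),
    gene_b = c("g1", "g2", "g3", "g4", "g1"),
    weight = c(0.5, 0.5, 0.9, 0.2, 0.5),
    stringsAsFactors = FALSE)
  net <- filter_edges(edges)
  expect_equal(net$n_edges, 1)                     # self-edge and dup removed,
  expect_equal(net$edges$gene_a, "g1")             # 0.2 is not > 0.2
  expect_equal(net$edges$gene_b, "g2")
  expect_equal(net$nodes, c("g1", "g2"))           # isolated g4 dropped
  expect_error(filter_edges(data.frame(gene_a = "a", gene_b = "b", weight = 2)),
               "malformed")
  expect_error(filter_edges(data.frame(a = 1)), "gene_a")
})

test_that("module assignment finds components and orders labels by size", {
  edges <- data.frame(
    gene_a = c("a", "b", "x", "p"),
    gene_b = c("b", "c", "y", "q"),
    weight = 0.9, stringsAsFactors = FALSE)
  net <- filter_edges(edges)
  mods <- assign_modules_components(net)
  expect_equal(unname(mods[c("a", "b", "c")]), rep("M1", 3))   # largest first
  expect_equal(mods[["p"]], mods[["q"]])
  expect_equal(mods[["x"]], mods[["y"]])
  expect_true(mods[["p"]] != mods[["x"]])
  # size tie between {p,q} and {x,y}: lexicographically smaller member first
  expect_equal(mods[["p"]], "M2")
  expect_equal(mods[["x"]], "M3")
})

test_that("hub ranking uses intra-module weight sums with deterministic ties", {
  edges <- data.frame(
    gene_a = c("a", "a", "b", "x"),
    gene_b = c("b", "c", "c", "y"),
    weight = c(0.9, 0.8, 0.7, 0.5), stringsAsFactors = FALSE)
  net <- filter_edges(edges)
  mods <- assign_modules_components(net)
  hubs <- find_hubs(net, mods, k = 1)
  expect_equal(hubs$gene_id[hubs$module == "M1"], "a")   # 1.7 > 1.6, 1.5
  expect_equal(hubs$gene_id[hubs$module == "M2"], "x")   # tie 0.5: lexicographic
  w <- testthat::capture_warnings(find_hubs(net, mods, k = 5))
  expect_true(length(w) >= 1 && all(grepl("returning all", w)))
  expect_error(find_hubs(net, mods[-1], k = 1), "unlabelled")
})

test_that("module profiles are replicate-averaged z-score means", {
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                5, 5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4), variety = "v",
                     treatment = rep(c("C", "D"), each = 2),
                     stage = "MD", stringsAsFactors = FALSE)
  # g1 and g2 are exact mirrors; their z-scores cancel, g3 is constant (masked)
  prof <- module_expression_profile(c("g1", "g2", "g3"), m, meta)
  expect_equal(prof$profile, c(0, 0))
  prof1 <- module_expression_profile("g1", m, meta)
  z <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4))
  expect_equal(prof1$profile, c(mean(z[1:2]), mean(z[3:4])))
  expect_error(module_expression_profile("nope", m, meta), "no module gene")
})

test_that("Fisher enrichment matches an exhaustive hypergeometric oracle", {
  universe <- paste0("g", 1:40)
  set <- paste0("g", 1:10)
  terms <- list(t_hot = paste0("g", 1:8),            # 8/8 in the set
                t_cold = paste0("g", 31:40),         # 0 overlap
                t_mid = paste0("g", 6:20))           # 5 overlap
  res <- fisher_enrichment(set, universe, terms)
  for (tm in names(terms)) {
    row <- res[res$term == tm, ]
    expect_equal(row$p,
                 hyper_tail_oracle(row$overlap, row$term_size, 40, 10),
                 tolerance = 1e-12)
  }
  expect_equal(res$padj, p.adjust(res$p, "BH"))
  expect_true(res$term[1] == "t_hot")                 # sorted by p
  expect_error(fisher_enrichment("zzz", universe, terms), "universe")
})

test_that("the three-evidence screen intersects and splits by variety", {
  ev <- list(
    sensitive = list(induced = c("a", "b", "c"), module = c("b", "c", "d"),
                     tad_change = c("c", "d", "b")),
    tolerant = list(induced = c("c", "e"), module = c("c", "e"),
                    tad_change = c("c", "f")))
  rep_ <- screen_target_genes(ev)
  expect_equal(rep_$per_variety$sensitive, c("b", "c"))
  expect_equal(rep_$per_variety$tolerant, "c")
  expect_equal(rep_$shared, "c")
  expect_equal(rep_$specific$sensitive, "b")
  expect_equal(rep_$specific$tolerant, character(0))
  flags <- rep_$evidence
  expect_true(all(flags$target ==
                    (flags$induced & flags$module & flags$tad_change)))
  expect_output(print(rep_), "shared across varieties: 1")
  expect_error(screen_target_genes(list(list(induced = "a"))), "named")
  expect_warning(screen_target_genes(list(v = list(induced = character(0),
                                                   module = "a",
                                                   tad_change = "a"))),
                 "empty evidence")
})

test_that("co-expression edges are soft-thresholded non-negative correlations", {
  set.seed(12)
  base <- rnorm(8)
  m <- rbind(g1 = 2^(base + 5), g2 = 2^(base + 3),         # perfectly correlated
             g3 = 2^(-base + 4),                           # anti-correlated
             g4 = 2^(rnorm(8) + 4))
  colnames(m) <- paste0("s", 1:8)
  e <- coexpression_edges(m)
  expect_true(all(e$weight >= 0 & e$weight <= 1))
  # g1/g2 share the same log-profile up to the +1 pseudocount
  expect_gt(e$weight[e$gene_a == "g1" & e$gene_b == "g2"], 0.99)
  expect_equal(e$weight[e$gene_a == "g1" & e$gene_b == "g3"], 0)
  expect_equal(nrow(e), choose(4, 2))
})
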