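test_that("boundary extraction drops terminal positions and validates TADs", {
  tads <- data.frame(chrom = "A01", start = c(0, 5e5, 1.2e6),
                     end = c(5e5, 1.2e6, 2e6), stringsAsFactors = FALSE)
  b <- tad_boundaries(tads, chrom_lengths = c(A01 = 2e6))
  expect_equal(b$pos, c(5e5, 1.2e6))
  b2 <- tad_boundaries(tads, drop_terminal = FALSE)
  expect_equal(b2$pos, c(0, 5e5, 1.2e6, 2e6))
  bad <- tads; bad$start[2] <- 4e5
  expect_error(tad_boundaries(bad), "overlapping")
  expect_error(validate_tads(data.frame(chrom = "A01", start = 1, end = 1)),
               "end > start")
})

test_that("the separation score is scale invariant and flat on uniform input", {
  labels_n <- 60
  set.seed(9)
  d <- abs(outer(seq_len(labels_n), seq_len(labels_n), "-"))
  m <- (d + 1)^(-0.8) * exp(matrix(rnorm(labels_n^2, 0, 0.02), labels_n))
  m <- (m + t(m)) / 2
  s1 <- separation_score(m, 2e4)
  s2 <- separation_score(10 * m, 2e4)
  expect_equal(s1$score, s2$score)
  flat <- separation_score(matrix(1, 40, 40), 2e4)
  expect_true(all(flat$score[!is.na(flat$score)] == 0))
  expect_error(separation_score(matrix(1, 3, 3), 2e4), "window")
})

test_that("boundary calling finds planted insulation minima", {
  cfg <- tiny_config()
  study <- simulate_study(cfg)
  key <- "sensitive.C.ID"
  ch <- study$genome$chroms$chrom[1]
  called <- call_tads(study$contacts$samples[[key]]$matrices[[ch]],
                      ch, cfg$bin_size)
  truth <- study$contacts$truth$tads[[key]]
  tb <- tad_boundaries(truth[truth$chrom == ch, ])
  cb <- tad_boundaries(called)
  m <- match_boundaries(tb, cb)
  expect_equal(nrow(m$pairs), nrow(tb))   # every planted boundary recovered
  expect_equal(nrow(m$b_specific), 0)     # no false boundaries
})

test_that("tads_from_boundaries tiles the chromosome exactly", {
  td <- tads_from_boundaries(c(4e5, 1.1e6), c(A01 = 2e6), chrom = "A01")
  expect_equal(td$start, c(0, 4e5, 1.1e6))
  expect_equal(td$end, c(4e5, 1.1e6, 2e6))
  expect_silent(validate_tads(td))
})

test_that("boundary matching implements the 80-kb-region >= 1-bp rule", {
  a <- data.frame(chrom = "A01", pos = 1e6, stringsAsFactors = FALSE)
  inside <- data.frame(chrom = "A01", pos = 1079999, stringsAsFactors = FALSE)
  outside <- data.frame(chrom = "A01", pos = 1080000, stringsAsFactors = FALSE)
  expect_equal(nrow(match_boundaries(a, inside)$pairs), 1)
  expect_equal(match_boundaries(a, inside)$pairs$overlap, 1)
  expect_equal(nrow(match_boundaries(a, outside)$pairs), 0)
  # one-to-many resolves to one-to-one; counts are symmetric
  b <- data.frame(chrom = "A01", pos = c(0.99e6, 1.01e6), stringsAsFactors = FALSE)
  mab <- match_boundaries(a, b)
  mba <- match_boundaries(b, a)
  expect_equal(nrow(mab$pairs), nrow(mba$pairs))
  expect_equal(nrow(mab$pairs), 1)
  expect_equal(mab$pairs$pos_b, 0.99e6)   # equal overlap/dist: leftmost wins
  expect_equal(nrow(mab$b_specific), 1)
  # matched + specific partitions each input set
  expect_equal(nrow(mab$pairs) + nrow(mab$a_specific), nrow(a))
  expect_equal(nrow(mab$pairs) + nrow(mab$b_specific), nrow(b))
  expect_error(match_boundaries(data.frame(x = 1), b), "chrom, pos")
})

test_that("drought gain/loss classification partitions both boundary sets", {
  ctrl <- data.frame(chrom = "A01", pos = c(2e5, 5e5, 9e5))
  drou <- data.frame(chrom = "A01", pos = c(2.1e5, 9e5, 1.4e6))
  r <- classify_drought_boundaries(ctrl, drou)
  expect_equal(nrow(r$conserved), 2)
  expect_equal(r$dl$pos, 5e5)     # control-specific = drought loss
  expect_equal(r$dg$pos, 1.4e6)   # drought-specific = drought gain
  expect_equal(r$conserved_fraction, 2 / 4)
})

test_that("pan-boundary accretion and presence vectors are coherent", {
  sets <- list(
    ID = data.frame(chrom = "A01", pos = c(2e5, 6e5)),
    MD = data.frame(chrom = "A01", pos = c(2.2e5, 1e6)),
    SD = data.frame(chrom = "A01", pos = 6e5),
    RW = data.frame(chrom = "A01", pos = 1.6e6))
  pan <- build_pan_boundaries(sets)
  # 2e5~2.2e5 merge; entries: 2e5 (ID,MD), 6e5 (ID,SD), 1e6 (MD), 1.6e6 (RW)
  expect_equal(nrow(pan), 4)
  expect_equal(pan$pos, c(2e5, 6e5, 1e6, 1.6e6))
  expect_equal(pan$n_stages, c(2, 2, 1, 1))
  expect_equal(pan$class, c("conserved-2", "conserved-2",
                            "stage-specific", "stage-specific"))
  # identical sets at all four stages collapse to a conserved-4 pan
  same <- data.frame(chrom = "A01", pos = c(3e5, 8e5))
  pan4 <- build_pan_boundaries(list(ID = same, MD = same, SD = same, RW = same))
  expect_equal(nrow(pan4), 2)
  expect_true(all(pan4$class == "conserved-4"))
  # pairwise-disjoint sets (all gaps >= 2 * flank) never merge
  far <- lapply(0:3, function(k) data.frame(chrom = "A01", pos = 1e5 + k * 8e4))
  names(far) <- STAGES
  expect_equal(nrow(build_pan_boundaries(far)), 4)
  expect_warning(build_pan_boundaries(list(ID = same, MD = same, SD = same,
                                           RW = same[0, ])), "RW")
})

test_that("the cross-sample pan is order invariant", {
  set.seed(21)
  sets <- lapply(1:5, function(i)
    random_tad_set("A01", 2e6) |> tad_boundaries(chrom_lengths = c(A01 = 2e6)))
  names(sets) <- paste0("s", 1:5)
  pan1 <- build_cross_sample_pan(sets)
  perm <- c(4, 1, 5, 3, 2)
  pan2 <- build_cross_sample_pan(sets[perm])
  expect_equal(pan1[, c("chrom", "pos", "n_samples")],
               pan2[, c("chrom", "pos", "n_samples")])
  expect_equal(pan1[, names(sets)], pan2[, names(sets)])
  expect_error(build_cross_sample_pan(unname(sets)), "keys")
})

test_that("fusion and Neo-TAD detection find planted events and nothing else", {
  L <- c(A01 = 2e6)
  ctrl <- tads_from_boundaries(c(4e5, 8e5, 1.2e6, 1.6e6), L, chrom = "A01")
  # fuse the 2nd and 3rd TADs: remove the 8e5 boundary
  drou <- tads_from_boundaries(c(4e5, 1.2e6, 1.6e6), L, chrom = "A01")
  ev <- detect_tad_events(ctrl, drou)
  expect_equal(ev$type, "fusion")
  expect_equal(ev$span_start, 4e5)
  expect_equal(ev$span_end, 1.2e6)
  expect_equal(ev$n_parts, 2L)
  expect_equal(ev$changed_boundaries, "8e+05")
  # swapping the arguments turns the fusion into a neo event
  ev2 <- detect_tad_events(drou, ctrl)
  expect_equal(ev2$type, "neo")
  expect_equal(event_signature(ev, "fusion")[, -1],
               event_signature(ev2, "neo")[, -1], ignore_attr = TRUE)
  # identical sets produce no events
  expect_equal(nrow(detect_tad_events(ctrl, ctrl)), 0)
  # a merely shifted boundary (within 2 * flank) is not an event
  shift <- tads_from_boundaries(c(4e5, 8.2e5, 1.2e6, 1.6e6), L, chrom = "A01")
  expect_equal(nrow(detect_tad_events(ctrl, shift)), 0)
})

test_that("hotspot calling uses the strict > min_count window rule", {
  L <- c(A01 = 4e7)
  nine <- data.frame(chrom = "A01", pos = seq(1e5, 9e5, 1e5), type = "dl")
  expect_equal(nrow(call_hotspots(nine, L)), 1)        # 9 > 8
  eight <- nine[1:8, ]
  expect_equal(nrow(call_hotspots(eight, L)), 0)       # 8 is not > 8
  # consecutive qualifying windows merge, counts are totals
  two <- rbind(nine, transform(nine, pos = pos + 1e7))
  h <- call_hotspots(two, L)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0)
  expect_equal(h$end, 2e7)
  expect_equal(h$n_boundaries, 18L)
  # types are independent
  mixed <- rbind(nine, transform(nine, type = "dg"))
  expect_equal(sort(call_hotspots(mixed, L)$type), c("dg", "dl"))
  expect_error(call_hotspots(nine, c(B01 = 1e7)), "unknown chromosome")
})

test_that("hotspot comparison reports the one-decimal shared percentage", {
  expect_equal(percent_shared(32, 165), 19.4)
  expect_equal(percent_shared(70, 212), 33.0)
  expect_error(percent_shared(1, 0), "positive")
  a <- data.frame(chrom = "A01", start = c(0, 3e7), end = c(1e7, 4e7),
                  type = "dl", n_boundaries = 9L)
  b <- data.frame(chrom = "A01", start = 9.9e6, end = 2e7,
                  type = "dl", n_boundaries = 10L)
  cmp <- compare_hotspots(a, b)
  expect_equal(cmp$n_shared, 1L)
  expect_equal(cmp$pct_shared, percent_shared(1, 3))
})

test_that("genes near boundaries use the per-side window with >= 1 bp overlap", {
  b <- data.frame(chrom = "A01", pos = 1e6)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = "A01",
                      start = c(1.01e6, 1.02e6, 2e6),
                      end   = c(1.015e6, 1.025e6, 2.01e6),
                      stringsAsFactors = FALSE)
  expect_equal(genes_near_boundaries(b, genes, window = 2e4), "g1")  # g2 abuts
  expect_equal(genes_near_boundaries(b[0, ], genes), character(0))
})
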