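# Replicate-consensus presence calls, consistency filter, temporal
# specific-selection, kmeans pattern clusters, selection summaries.

test_that("call_presence applies the majority rule", {
  expect_equal(call_presence(c(3, 0, 1, 2, 5, 0)), "present")   # 4 of 6
  expect_equal(call_presence(c(1, 1, 1, 0, 0, 0)), "undefined") # 3 of 6
  expect_equal(call_presence(rep(0, 6)), "absent")
  expect_equal(call_presence(c(0, 0, 1, 0, 0, 0)), "absent")    # 1 of 6
  expect_equal(call_presence(5), "present")
  expect_error(call_presence(numeric(0)), "empty")
})

test_that("presence calls are monotone in detections", {
  # adding a detected replicate never flips present -> absent
  withr::with_seed(31, {
    for (i in 1:20) {
      x <- rbinom(6, 1, 0.5) * rpois(6, 4)
      before <- call_presence(x)
      x[which.min(x > 0)] <- 1   # force one more detection
      after <- call_presence(x)
      expect_false(before == "present" && after == "absent")
    }
  })
})

make_filter_fixture <- function() {
  md <- toy_metadata()
  n_samp <- nrow(md)
  counts <- matrix(5L, 6, n_samp,
                   dimnames = list(paste0("OTU_", 1:6), md$sample_id))
  # OTU_2: absent everywhere
  counts["OTU_2", ] <- 0L
  # OTU_3: undefined (3 of 6) at stage S2, present elsewhere
  s2 <- md$sample_id[md$stage == "S2"]
  counts["OTU_3", s2] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  # OTU_4: absent (1 of 6) at S3, present elsewhere -> retained
  s3 <- md$sample_id[md$stage == "S3"]
  counts["OTU_4", s3] <- c(2L, 0L, 0L, 0L, 0L, 0L)
  # OTU_5: undefined at S5
  s5 <- md$sample_id[md$stage == "S5"]
  counts["OTU_5", s5] <- c(0L, 0L, 0L, 1L, 2L, 3L)
  list(counts = counts, metadata = md)
}

test_that("filter_consistent excludes undefined and always-absent OTUs", {
  fx <- make_filter_fixture()
  filt <- filter_consistent(fx$counts, fx$metadata)
  retained <- filt$otu_id[filt$retained]
  expect_setequal(retained, c("OTU_1", "OTU_4", "OTU_6"))
  # a stratum missing a stage the design has -> error
  md2 <- rbind(fx$metadata,
               within(toy_metadata(treatments = "N1"), {
                 sample_id <- sub("^CK", "N1", sample_id)
               }))
  md_missing <- md2[!(md2$treatment == "N1" & md2$stage == "S4"), ]
  counts2 <- cbind(fx$counts,
                   matrix(1L, nrow(fx$counts),
                          sum(md_missing$treatment == "N1"),
                          dimnames = list(
                            rownames(fx$counts),
                            md_missing$sample_id[
                              md_missing$treatment == "N1"])))
  expect_error(filter_consistent(counts2, md_missing), "S4")
})

test_that("select_specific labels unique extrema and withholds ties", {
  md <- toy_metadata()
  counts <- matrix(0L, 3, nrow(md),
                   dimnames = list(paste0("OTU_", 1:3), md$sample_id))
  counts["OTU_1", ] <- 10L
  counts["OTU_1", md$sample_id[md$stage == "S2"]] <- 50L  # peak at S2
  counts["OTU_2", ] <- 20L                                 # flat: tie
  # filler keeps every sample total at 130 so OTU_2's relative
  # abundance is exactly constant (a true tie)
  counts["OTU_3", ] <- 130L - counts["OTU_1", ] - counts["OTU_2", ]
  sel <- select_specific(counts, md, "CK", "B", paste0("OTU_", 1:3))
  expect_equal(sel$enriched_stage[sel$otu_id == "OTU_1"], "S2")
  expect_true(is.na(sel$enriched_stage[sel$otu_id == "OTU_2"]))
  expect_true(is.na(sel$inhibited_stage[sel$otu_id == "OTU_2"]))
})

test_that("select_specific matches direct argmax/argmin on monotone profiles", {
  md <- toy_metadata()
  counts <- matrix(50L, 2, nrow(md),
                   dimnames = list(c("OTU_mono", "filler"), md$sample_id))
  levels5 <- c(500L, 400L, 300L, 200L, 100L)
  for (i in 1:5) {
    counts["OTU_mono", md$sample_id[md$stage == paste0("S", i)]] <-
      levels5[i]
  }
  sel <- select_specific(counts, md, "CK", "B", "OTU_mono")
  expect_equal(sel$enriched_stage, "S1")
  expect_equal(sel$inhibited_stage, "S5")
})

test_that("cluster_patterns recovers planted archetypes exactly", {
  withr::with_seed(33, {
    arch <- rbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(1, 5, 1, 5, 1))
    profiles <- arch[rep(1:3, each = 20), ] +
      matrix(rnorm(60 * 5, 0, 0.05), 60, 5)
    rownames(profiles) <- paste0("OTU_", 1:60)
    cl <- cluster_patterns(profiles, k = 3, seed = 2)
    expect_equal(adjusted_rand(cl, rep(1:3, each = 20)), 1)
    # duplicated rows take identical labels
    dup <- profiles[c(1, 1, 25, 25, 50, 50), ]
    rownames(dup) <- paste0("d", 1:6)
    cld <- cluster_patterns(dup, k = 3, seed = 2)
    expect_equal(cld[1], cld[2], ignore_attr = TRUE)
    expect_equal(cld[3], cld[4], ignore_attr = TRUE)
    # k = 1 puts everything together; fewer profiles than k errors
    expect_true(all(cluster_patterns(profiles, k = 1, seed = 1) == 1))
    expect_error(cluster_patterns(profiles[1:2, ], k = 3), "k = 3")
  })
})

test_that("selection catalog respects its invariants", {
  sim <- generate_otu_table(small_config(seed = 13))
  catalog <- build_selection_catalog(sim$counts, sim$metadata, seed = 1)
  expect_true(all(is.na(catalog$pattern_cluster[!catalog$retained])))
  both <- !is.na(catalog$enriched_stage) & !is.na(catalog$inhibited_stage)
  expect_true(all(catalog$enriched_stage[both] !=
                    catalog$inhibited_stage[both]))
  # planted enriched OTUs recovered in each stratum
  pe <- sim$truth$planted_enriched
  cc <- catalog[catalog$treatment == "N2" & catalog$compartment == "B", ]
  hit <- cc$enriched_stage[match(names(pe), cc$otu_id)] == pe
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
})

test_that("summarize_selection proportions normalize within direction", {
  catalog <- data.frame(
    otu_id = paste0("o", 1:6), treatment = "CK", compartment = "B",
    retained = TRUE,
    enriched_stage = c("S2", "S2", "S2", "S2", NA, NA),
    inhibited_stage = c(NA, NA, NA, NA, "S1", "S3"),
    pattern_cluster = 1L, stringsAsFactors = FALSE)
  sm <- summarize_selection(catalog, stages = paste0("S", 1:5))
  enr <- sm[sm$direction == "enriched", ]
  expect_equal(enr$proportion[enr$stage == "S2"], 1)
  expect_equal(sum(enr$proportion), 1)
  inh <- sm[sm$direction == "inhibited", ]
  expect_equal(sum(inh$proportion), 1)
  expect_equal(inh$proportion[inh$stage == "S1"], 0.5)
})

test_that("compare_counts runs Welch t-tests on per-treatment counts", {
  trts <- c("CK", "N1", "N2", "O1", "O2")
  enr_counts <- c(10, 12, 11, 9, 13)
  inh_counts <- c(2, 3, 1, 2, 2)
  rows <- list()
  k <- 0
  for (i in seq_along(trts)) {
    for (j in seq_len(enr_counts[i])) {
      k <- k + 1
      rows[[k]] <- data.frame(otu_id = paste0("e", k), treatment = trts[i],
                              compartment = "B", retained = TRUE,
                              enriched_stage = "S2",
                              inhibited_stage = NA_character_)
    }
    for (j in seq_len(inh_counts[i])) {
      k <- k + 1
      rows[[k]] <- data.frame(otu_id = paste0("i", k), treatment = trts[i],
                              compartment = "B", retained = TRUE,
                              enriched_stage = NA_character_,
                              inhibited_stage = "S2")
    }
  }
  catalog <- do.call(rbind, rows)
  res <- compare_counts(catalog)
  s2 <- res[res$stage == "S2", ]
  expect_false(s2$skipped)
  # closed-form Welch t on (10,12,11,9,13) vs (2,3,1,2,2)
  oracle <- t.test(enr_counts, inh_counts)
  expect_equal(s2$t, unname(oracle$statistic))
  expect_equal(s2$p, oracle$p.value)
  expect_lt(s2$p, 0.01)
})

test_that("identical enriched and inhibited counts give t = 0, p = 1", {
  catalog <- data.frame(
    otu_id = paste0("o", 1:10),
    treatment = rep(c("CK", "N1"), each = 5),
    compartment = "B", retained = TRUE,
    enriched_stage = rep(c("S1", NA), 5),
    inhibited_stage = rep(c(NA, "S1"), 5),
    stringsAsFactors = FALSE)
  res <- compare_counts(catalog)
  s1 <- res[res$stage == "S1", ]
  expect_equal(s1$t, 0)
  expect_equal(s1$p, 1)
})
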