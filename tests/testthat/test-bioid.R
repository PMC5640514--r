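# BioID/TMT quantitation: bait normalization, ratios, enrichment filter

make_tiny_table <- function(ab, reps = 1) {
  states <- c("myoblast", "myotube")
  treatments <- c("noDOX_biotin", "DOX_biotin")
  samples <- expand.grid(replicate = seq_len(reps), treatment = treatments,
                         cell_state = states, stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- with(samples, paste(cell_state, treatment,
                                           paste0("r", replicate), sep = "_"))
  colnames(ab) <- samples$sample_id
  quant_table(ab, samples, bait = rownames(ab)[1])
}

test_that("bait normalization equalizes the bait across +DOX samples", {
  ab <- rbind(BAIT = c(1, 100, 1, 200),
              p1   = c(10, 50, 10, 30))
  tt <- make_tiny_table(ab)
  norm <- bait_normalize(tt)
  dox <- which(tt$samples$treatment == "DOX_biotin")
  expect_equal(unname(norm$abundance["BAIT", dox[1]]),
               unname(norm$abundance["BAIT", dox[2]]))
  # reference is the geometric mean: factors for baits {100, 200} are
  # {sqrt(2), 1/sqrt(2)}
  expect_equal(unname(norm$factors[dox]), c(sqrt(2), 1 / sqrt(2)))
  # bait already equal -> identity
  ab2 <- rbind(BAIT = c(1, 100, 1, 100), p1 = c(5, 7, 2, 9))
  norm2 <- bait_normalize(make_tiny_table(ab2))
  expect_equal(norm2$abundance, make_tiny_table(ab2)$abundance)
  # non-bait ratios between samples change exactly by the factor ratio
  r_raw <- ab["p1", 2] / ab["p1", 4]
  r_norm <- norm$abundance["p1", dox[1]] / norm$abundance["p1", dox[2]]
  expect_equal(unname(r_norm),
               unname(r_raw * norm$factors[dox[1]] / norm$factors[dox[2]]))
})

test_that("bait normalization errors name the offending sample", {
  ab <- rbind(BAIT = c(1, 0, 1, 200), p1 = c(10, 50, 10, 30))
  tt <- make_tiny_table(ab)
  expect_error(bait_normalize(tt), "myoblast_DOX_biotin_r1")
})

test_that("dox ratios use the biotin-only control and a pseudocount policy", {
  ab <- rbind(BAIT = c(1, 100, 1, 100),
              p1 = c(100, 500, 100, 100),
              p2 = c(0, 80, 50, 100))
  tt <- make_tiny_table(ab)
  rr <- dox_ratios(tt, pseudocount = 0)
  p1mb <- rr[rr$protein == "p1" & rr$cell_state == "myoblast", ]
  expect_equal(p1mb$ratio, 5)
  p1mt <- rr[rr$protein == "p1" & rr$cell_state == "myotube", ]
  expect_equal(p1mt$ratio, 1)
  # zero denominator with auto pseudocount: finite and flagged
  rr2 <- dox_ratios(tt)
  p2mb <- rr2[rr2$protein == "p2" & rr2$cell_state == "myoblast", ]
  expect_true(is.finite(p2mb$ratio))
  expect_equal(p2mb$flag, "pseudocount_denominator")
})

test_that("enrichment filter applies the 2-of-3 rule and is monotone", {
  rec <- data.frame(
    protein = rep(c("hit", "miss"), each = 3), replicate = rep(1:3, 2),
    r_mb = 1, r_mt = c(2, 3, 0.5, 0.9, 0.9, 5))
  out <- enrichment_filter(rec, fold_threshold = 1)
  expect_true(out$pass[out$protein == "hit"])
  expect_false(out$pass[out$protein == "miss"])
  # raising the threshold never grows the pass set
  sweep <- enrichment_threshold_sweep(rec, c(0.5, 1, 1.5, 2, 2.5, 3.5))
  expect_true(all(diff(sweep$n_pass) <= 0))
})

test_that("identification gate keeps proteins seen in >= 2 replicates", {
  m <- rbind(a = c(TRUE, TRUE, FALSE),
             b = c(TRUE, FALSE, FALSE),
             c = c(TRUE, TRUE, TRUE))
  expect_setequal(identification_gate(m), c("a", "c"))
})

test_that("scale invariance: rescaling a raw +DOX column is absorbed", {
  # the geometric-mean reference shifts by a single global factor, so all
  # ratios rescale together and every fold change is exactly unchanged
  g <- gen_tmt(n_proteins = 60, n_planted = 6, cv = 0.1, seed = 7)
  tt <- g$table
  j <- which(tt$samples$treatment == "DOX_biotin")[2]
  tt2 <- tt
  tt2$abundance[, j] <- tt2$abundance[, j] * 7.3
  r1 <- dox_ratios(bait_normalize(tt))
  r2 <- dox_ratios(bait_normalize(tt2))
  expect_lt(diff(range(r2$ratio / r1$ratio)), 1e-12)
  e1 <- enrichment_records(r1); e2 <- enrichment_records(r2)
  expect_equal(e2$r_mt / e2$r_mb, e1$r_mt / e1$r_mb, tolerance = 1e-12)
})

test_that("noiseless generated tables are recovered exactly", {
  g <- gen_tmt(n_proteins = 200, n_planted = 20, effect_size = 4, cv = 0,
               missing_rate = 0, seed = 11)
  res <- bioid_pipeline(g$table)
  hits <- res$result$protein[res$result$pass]
  expect_setequal(hits, g$truth$protein[g$truth$planted])
})

test_that("quantification tables round-trip through the text schema", {
  g <- gen_tmt(n_proteins = 25, n_planted = 3, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_quant_table(g$table, f)
  back <- read_quant_table(f, bait = g$table$bait)
  # sample ids are canonicalized to the schema's dotted form on write
  expect_equal(unname(back$abundance), unname(g$table$abundance),
               tolerance = 1e-12)
  expect_identical(rownames(back$abundance), rownames(g$table$abundance))
  expect_equal(back$samples$cell_state, g$table$samples$cell_state)
  expect_equal(back$samples$replicate, g$table$samples$replicate)
  # pipelines agree on the round-tripped table
  expect_identical(bioid_pipeline(back)$result$pass,
                   bioid_pipeline(g$table)$result$pass)
})
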