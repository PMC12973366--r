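# The order-locked normalization chain and its post-conditions.

make_toy <- function() {
  # 2 subplexes x 2 channels, 3 proteins with a known zero pattern
  v <- matrix(c(
    4, 8, 2, 4,    # P1: quantified everywhere
    0, 0, 6, 3,    # P2: absent from S1
    0, 0, 0, 0     # P3: absent everywhere
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("P1", "P2", "P3"),
                  c("S1|126", "S1|127N", "S2|126", "S2|127N")))
  toy_quant_table(v, subplexes = c("S1", "S1", "S2", "S2"))
}

test_that("master-protein filtering keeps rows quantified in some subplex", {
  tab <- filter_master_proteins(make_toy())
  expect_equal(rownames(tab$values), c("P1", "P2"))
  expect_equal(unname(tab$metadata$core), c(TRUE, FALSE))
  expect_equal(tab$metadata$quantified_in["P2", ],
               c(S1 = FALSE, S2 = TRUE))
  # restricted to one subplex, only rows quantified there survive
  tab_s1 <- filter_master_proteins(make_toy(), subplex = "S1")
  expect_equal(rownames(tab_s1$values), "P1")
  # all-zero input warns rather than errors
  allzero <- toy_quant_table(
    matrix(0, 1, 2, dimnames = list("P", c("S1|126", "S1|127N"))))
  expect_warning(filter_master_proteins(allzero), "no proteins")
})

test_that("zero replacement floors missing values at 0.1 and is idempotent", {
  tab <- replace_zeros(filter_master_proteins(make_toy()))
  expect_equal(unname(tab$values["P2", ]), c(0.1, 0.1, 6, 3))
  expect_equal(unname(tab$values["P1", ]), c(4, 8, 2, 4))
  expect_equal(replace_zeros(tab)$values, tab$values)
  expect_true(all(tab$metadata$imputed["P2", c("S1|126", "S1|127N")]))
})

test_that("pipeline steps refuse to run out of order", {
  raw <- make_toy()
  expect_error(replace_zeros(raw), "requires 'filter_master_proteins'")
  expect_error(median_normalize_log2(raw), "requires 'replace_zeros'")
  filtered <- filter_master_proteins(raw)
  expect_error(median_normalize_log2(filtered), "requires 'replace_zeros'")
  d <- build_58plex_reference()
  norm <- median_normalize_log2(replace_zeros(filtered))
  expect_error(global_center(norm), "requires 'bridge_scale'")
  expect_error(mad_harmonize(norm), "requires 'global_center'")
  # the provenance log records the applied order
  expect_equal(ultraplex:::provenance_steps(norm),
               c("filter_master_proteins", "replace_zeros",
                 "median_normalize_log2"))
})

test_that("median normalization equalizes column medians, hand-checked", {
  v <- matrix(c(1, 2, 4,
                2, 4, 8), ncol = 2,
              dimnames = list(c("P1", "P2", "P3"), c("S1|a", "S1|b")))
  tab <- toy_quant_table(v)
  norm <- median_normalize_log2(replace_zeros(filter_master_proteins(tab)))
  # column medians 2 and 4, grand median 3: columns scaled by 3/2 and 3/4,
  # so both log2 column medians equal log2(3)
  expect_equal(unname(apply(norm$values, 2, median)),
               rep(log2(3), 2), tolerance = 1e-9)
  expect_equal(unname(norm$values[, 1]), log2(c(1, 2, 4) * 3 / 2),
               tolerance = 1e-12)
  # identical columns are only log2-transformed (median already the target)
  v2 <- matrix(c(1, 2, 4, 1, 2, 4), ncol = 2,
               dimnames = list(c("P1", "P2", "P3"), c("S1|a", "S1|b")))
  norm2 <- median_normalize_log2(replace_zeros(filter_master_proteins(
    toy_quant_table(v2))))
  expect_equal(unname(norm2$values), unname(log2(v2)))
  # scaling an input column by a constant does not change the output, as
  # long as the scaling leaves the grand median (median of column medians)
  # where it was
  v4 <- matrix(c(1, 2, 4,  2, 4, 8,  4, 8, 16), ncol = 3,
               dimnames = list(c("P1", "P2", "P3"),
                               c("S1|a", "S1|b", "S1|c")))
  v5 <- v4; v5[, 3] <- v5[, 3] * 100  # column medians 2, 4, 800: grand still 4
  norm4 <- median_normalize_log2(replace_zeros(filter_master_proteins(
    toy_quant_table(v4))))
  norm5 <- median_normalize_log2(replace_zeros(filter_master_proteins(
    toy_quant_table(v5))))
  expect_equal(norm5$values, norm4$values, tolerance = 1e-12)
})

test_that("median normalization rejects nonpositive values", {
  tab <- filter_master_proteins(make_toy())
  tab <- ultraplex:::add_provenance(tab, "replace_zeros")  # forged order
  expect_error(median_normalize_log2(tab), "pipeline-order")
})

toy_design_2subplex <- function() {
  # minimal 2-subplex design matching the S1/S2 toy tables: bridge on 126
  mk <- function(id) {
    ts <- tag_set("TMT11")
    keep <- c("126", "127N", "127C")
    assign <- stats::setNames(rep("UNUSED", ts$size), ts$channels)
    assign[keep] <- c("BRIDGE", "A", "B")
    subplex(id, "LysC", ts, assign, bridge_channels = "126",
            spike_ug = stats::setNames(c(1, 1, 0.5), keep))
  }
  plex_design(list(mk("S1"), mk("S2")), c("A", "B"))
}

toy_design_bridge4 <- function() {
  # 2 subplexes, 4 bridge channels (126..128N) + one sample channel 128C
  mk <- function(id) {
    ts <- tag_set("TMT11")
    keep <- c("126", "127N", "127C", "128N", "128C")
    assign <- stats::setNames(rep("UNUSED", ts$size), ts$channels)
    assign[keep] <- c(rep("BRIDGE", 4), "A")
    subplex(id, "LysC", ts, assign,
            bridge_channels = c("126", "127N", "127C", "128N"),
            spike_ug = stats::setNames(c(1, 1, 1, 1, 0.5), keep))
  }
  plex_design(list(mk("S1"), mk("S2")), "A")
}

# hand-built log2-scale table with forged provenance, so bridge arithmetic
# can be checked without the median-normalization step rescaling columns
forge_normalized <- function(values, subplexes) {
  channels <- sub("^.*\\|", "", colnames(values))
  structure(list(
    values = values,
    species = stats::setNames(rep("human", nrow(values)), rownames(values)),
    columns = data.frame(column = colnames(values), subplex = subplexes,
                         channel = channels, stringsAsFactors = FALSE),
    metadata = list(provenance = list(
      list(step = "filter_master_proteins", params = list()),
      list(step = "replace_zeros", params = list()),
      list(step = "median_normalize_log2", params = list())))),
    class = "normalized_table")
}

test_that("row-wise bridge scaling subtracts each protein's bridge mean", {
  d <- toy_design_bridge4()
  cols <- c(paste0("S1|", c("126", "127N", "127C", "128N", "128C")),
            paste0("S2|", c("126", "127N", "127C", "128N", "128C")))
  v <- matrix(c(1, 1, 1, 1, 3,    0, 0, 0, 0, 3,
                2, 2, 4, 4, 5,    1, 3, 1, 3, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), cols))
  norm <- forge_normalized(v, rep(c("S1", "S2"), each = 5))
  scaled <- bridge_scale(norm, d)
  # bridge values {1,1,1,1} and sample 3 -> 2; bridge {0,0,0,0} leaves the
  # subplex unchanged
  expect_equal(unname(scaled$values["P1", ]),
               c(0, 0, 0, 0, 2, 0, 0, 0, 0, 3))
  # cross-subplex hand computation: P2 bridge means are 3 (S1) and 2 (S2)
  expect_equal(unname(scaled$values["P2", ]),
               c(-1, -1, 1, 1, 2, -1, 1, -1, 1, -2))
  # post-condition: every (protein, subplex) bridge mean is zero
  for (bc in ultraplex:::bridge_columns(scaled, d))
    expect_lt(max(abs(rowMeans(scaled$values[, bc]))), 1e-9)
})

test_that("bridge scaling on the reference design meets its post-condition", {
  d <- build_58plex_reference()
  truth <- make_ground_truth(60, 40, seed = 31)
  q <- simulate_quant(d, truth, noise_model(seed = 31), "MS2")
  norm <- bridge_scale(median_normalize_log2(replace_zeros(
    filter_master_proteins(q))), d)
  for (bc in ultraplex:::bridge_columns(norm, d))
    expect_lt(max(abs(rowMeans(norm$values[, bc]))), 1e-9)
  # column-wise variant shifts each subplex by one scalar instead
  normc <- bridge_scale(median_normalize_log2(replace_zeros(
    filter_master_proteins(q))), d, method = "column")
  for (bc in ultraplex:::bridge_columns(normc, d))
    expect_lt(abs(mean(normc$values[, bc])), 1e-9)
})

test_that("global centering zeroes core-protein column means, idempotently", {
  d <- toy_design_2subplex()
  v <- matrix(2^c(1, 3, 5,   2, 4, 6,
                  0, 2, 4,   1, 2, 3,
                  3, 1, 2,   0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"),
                              c("S1|126", "S1|127N", "S1|127C",
                                "S2|126", "S2|127N", "S2|127C")))
  v[3, 4:6] <- 0  # P3 is S1-only, hence non-core
  tab <- toy_quant_table(v, subplexes = rep(c("S1", "S2"), each = 3))
  norm <- bridge_scale(median_normalize_log2(replace_zeros(
    filter_master_proteins(tab))), d)
  centred <- global_center(norm)
  core <- centred$metadata$core
  expect_equal(unname(core), c(TRUE, TRUE, FALSE))
  expect_equal(unname(colMeans(centred$values[core, ])), rep(0, 6),
               tolerance = 1e-9)
  # the non-core row is shifted by the same core-derived column offsets
  offsets <- colMeans(norm$values[core, ])
  expect_equal(centred$values["P3", ], norm$values["P3", ] - offsets,
               tolerance = 1e-12)
  expect_equal(global_center(centred)$values, centred$values,
               tolerance = 1e-12)
})

test_that("MAD harmonization sets every column MAD to one", {
  d <- build_58plex_reference()
  truth <- make_ground_truth(80, 40, seed = 37)
  norm <- list(
    ms2 = normalize_pipeline(
      simulate_quant(d, truth, default_noise_model("MS2", 37), "MS2"), d),
    ms3 = normalize_pipeline(
      simulate_quant(d, truth, default_noise_model("MS3", 37), "MS3"), d))
  # the two acquisitions differ in dynamic range before harmonization
  mad2 <- median(apply(norm$ms2$values, 2, mad, constant = 1))
  mad3 <- median(apply(norm$ms3$values, 2, mad, constant = 1))
  expect_gt(abs(mad2 - mad3), 0)
  harm <- mad_harmonize(norm)
  for (tab in harm)
    expect_equal(unname(apply(tab$values, 2, mad, constant = 1)),
                 rep(1, ncol(tab$values)), tolerance = 1e-9)
  # a column with MAD 2 is exactly halved
  one <- norm$ms2
  expect_equal(mad_harmonize(one)$values[, 3],
               one$values[, 3] / mad(one$values[, 3], constant = 1),
               tolerance = 1e-12)
  # zero-MAD columns are named in the error
  bad <- one
  bad$values[, 2] <- 5
  expect_error(mad_harmonize(bad), colnames(bad$values)[2], fixed = TRUE)
})

test_that("spike ratios come from raw values with the documented denominator", {
  d <- toy_design_2subplex()
  v <- matrix(c(10, 10, 5,   8, 8, 4,
                6, 6, 6,     7, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("E1", "E2"),
                              c("S1|126", "S1|127N", "S1|127C",
                                "S2|126", "S2|127N", "S2|127C")))
  tab <- toy_quant_table(v, species = c(E1 = "ecoli", E2 = "ecoli"),
                         subplexes = rep(c("S1", "S2"), each = 3))
  r <- spike_log2_ratios(tab, d)
  # low-spike channel is 127C; high channels are 126 and 127N
  e1_s1 <- r[r$protein_id == "E1" & r$subplex == "S1", ]
  expect_equal(sort(e1_s1$log2_ratio), rep(1, 2))  # 10 vs 5
  e2 <- r[r$protein_id == "E2" & r$subplex == "S1", ]
  expect_equal(e2$log2_ratio, rep(0, 2))  # equal values
  expect_equal(unique(r$expected_log2), 1)
  expect_error(spike_log2_ratios(
    toy_quant_table(v, subplexes = rep(c("S1", "S2"), each = 3)), d),
    "no E. coli")
})

test_that("the full chain recovers cell-line offsets when interference-free", {
  d <- build_58plex_reference()
  truth <- make_ground_truth(1000, 50, seed = 41)
  q <- simulate_quant(d, truth,
                      noise_model(interference_alpha = 0,
                                  measurement_cv = 0.02, missing_rate = 0,
                                  seed = 41), "MS2")
  norm <- normalize_pipeline(subset_proteins(q, species = "human"), d)
  hum <- names(truth$species)[truth$species == "human"]
  truth_log2 <- log2(truth$human[hum, ] / truth$human[hum, "BRIDGE"])
  est <- c(); tru <- c()
  for (sp in d$subplexes) {
    ac <- names(sp$assignments)[sp$assignments != "UNUSED" &
                                  !(names(sp$assignments) %in%
                                      sp$bridge_channels)]
    cols <- paste(sp$id, ac, sep = "|")
    est <- c(est, as.vector(norm$values[hum, cols]))
    tru <- c(tru, as.vector(truth_log2[, sp$assignments[ac]]))
  }
  expect_gt(cor(est, tru), 0.99)
})

test_that("no-noise core proteins agree exactly across subplexes", {
  d <- build_58plex_reference()
  truth <- make_ground_truth(50, 20, seed = 43)
  q <- simulate_quant(d, truth,
                      noise_model(interference_alpha = 0, measurement_cv = 0,
                                  missing_rate = 0, seed = 43), "MS2")
  # the chain is defined for the human proteome; the spike-in rows carry
  # channel-dependent truth and would shift per-column core means
  norm <- normalize_pipeline(subset_proteins(q, species = "human"), d)
  hum <- names(truth$species)[truth$species == "human"]
  # the same cell line measured in different subplexes yields identical
  # bridge-anchored values for every core protein
  for (cl in d$cell_lines) {
    cols <- unlist(lapply(d$subplexes, function(sp) {
      ac <- names(sp$assignments)[sp$assignments == cl]
      paste(sp$id, ac[1], sep = "|")
    }))
    block <- norm$values[hum, cols]
    expect_lt(max(abs(block - block[, 1])), 1e-9)
  }
})

test_that("all chain post-conditions hold simultaneously after harmonization", {
  d <- build_58plex_reference()
  truth <- make_ground_truth(120, 60, seed = 47)
  norm <- normalize_pipeline(
    simulate_quant(d, truth, default_noise_model("MS2", 47), "MS2"), d)
  centred_core_means <- colMeans(norm$values[norm$metadata$core, ])
  expect_lt(max(abs(centred_core_means)), 1e-9)
  harm <- mad_harmonize(norm)
  expect_equal(unname(apply(harm$values, 2, mad, constant = 1)),
               rep(1, ncol(harm$values)), tolerance = 1e-9)
  # bridge means stay zero within each subplex up to the column scaling
  for (bc in ultraplex:::bridge_columns(norm, d))
    expect_lt(max(abs(rowMeans(norm$values[, bc]))), 1e-9)
  expect_equal(ultraplex:::provenance_steps(harm),
               c("filter_master_proteins", "replace_zeros",
                 "median_normalize_log2", "bridge_scale", "global_center",
                 "mad_harmonize"))
})
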