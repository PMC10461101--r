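test_that("pearson correlation and p-value follow the closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, -2 * x + 5), -1)
  ## hand-computed covariance formula
  x3 <- c(1, 2, 3); y3 <- c(1, 2, 4)
  num <- sum((x3 - mean(x3)) * (y3 - mean(y3)))
  den <- sqrt(sum((x3 - mean(x3))^2) * sum((y3 - mean(y3))^2))
  expect_equal(pearson_r(x3, y3), num / den, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), y3), "zero variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")

  expect_equal(pearson_p(0, 9), 1)
  expect_equal(pearson_p(-1, 9), 0)
  ## monotone decreasing in |r| at fixed n
  rs <- seq(0.1, 0.95, by = 0.05)
  ps <- vapply(rs, pearson_p, numeric(1), n = 9)
  expect_true(all(diff(ps) < 0))
  ## agrees with stats::cor.test as an independent route
  set.seed(41)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(pearson_p(cor(a, b), 9),
               cor.test(a, b)$p.value, tolerance = 1e-10)
})

test_that("anti-correlation filter enforces both thresholds strictly", {
  run <- tiny_zn_run()
  v <- run$run$validated
  expect_true(all(v$r[v$validated] <= -0.8))
  expect_true(all(v$p_value[v$validated] <= 0.05))
  ## zero-noise planted pairs validate essentially at r = -1 (the only
  ## slack is integer rounding of simulated read counts)
  tg <- run$sim$truth$targets
  planted <- v[paste(v$mirna_id, v$gene_id) %in%
                 paste(tg$mirna_id, tg$gene_id), ]
  expect_equal(nrow(planted), nrow(tg))
  expect_true(all(planted$r < -0.98))

  ## r just above the threshold is rejected
  set.seed(40)
  samples <- paste0("s", 1:9)
  x <- seq_len(9)
  z <- as.numeric(scale(x))
  resid <- as.numeric(scale(residuals(lm(rnorm(9) ~ z))))
  make_y <- function(r) -(r * z + sqrt(1 - r^2) * resid)
  ab <- matrix(x, 1, 9, dimnames = list("mir1", samples))
  ex <- rbind(make_y(0.79), make_y(0.81))
  dimnames(ex) <- list(c("gA", "gB"), samples)
  hits <- data.frame(mirna_id = "mir1", transcript_id = c("gA", "gB"),
                     expectation = 0, best = TRUE,
                     stringsAsFactors = FALSE)
  out <- anticorrelation_filter(hits, ab, ex)
  expect_false(out$validated[out$gene_id == "gA"])  # r ~ -0.79
  expect_true(out$validated[out$gene_id == "gB"])   # r ~ -0.81
})

test_that("relaxing the thresholds never removes a validated pair", {
  run <- tiny_noise_run()
  hits <- run$run$hits
  ab <- run$run$abund$values
  ex <- read_expression(run$config$expression)
  strict <- anticorrelation_filter(hits, ab, ex, r_max = -0.8,
                                   p_max = 0.05)
  loose <- anticorrelation_filter(hits, ab, ex, r_max = -0.5,
                                  p_max = 0.5)
  sv <- paste(strict$mirna_id, strict$gene_id)[strict$validated]
  lv <- paste(loose$mirna_id, loose$gene_id)[loose$validated]
  expect_true(all(sv %in% lv))
})

test_that("the TF layer keeps signed strong correlations, no self-edges", {
  run <- tiny_zn_run()
  sim <- run$sim
  tf_ids <- sim$tf_table$gene_id
  edges <- tf_layer(tf_ids, sim$expr)
  expect_false(any(edges$tf_id == edges$gene_id))
  expect_true(all(abs(edges$r) >= 0.8 & edges$p_value <= 0.05))
  ## planted downstream genes appear with r = 1 at zero noise
  planted <- sim$truth$tf_edges
  got <- merge(planted, edges, by.x = c("tf", "gene"),
               by.y = c("tf_id", "gene_id"))
  expect_equal(nrow(got), nrow(planted))
  expect_equal(got$r, rep(1, nrow(got)), tolerance = 1e-9)
  ## invariant under gene order permutation
  e2 <- tf_layer(tf_ids, sim$expr[rev(rownames(sim$expr)), ])
  key <- function(e) {
    e <- e[order(e$tf_id, e$gene_id), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(edges), key(e2))
  expect_error(tf_layer("nope", sim$expr), "unknown TF")
})

test_that("network assembly types nodes and counts edges correctly", {
  validated <- data.frame(
    mirna_id = c("mir1", "mir2"), gene_id = c("tfA", "tfB"),
    r = -0.9, p_value = 0.01, n = 9, expectation = 0, validated = TRUE,
    stringsAsFactors = FALSE)
  tf_edges <- data.frame(
    tf_id = c("tfA", "tfA", "tfB", "tfB"),
    gene_id = c("g1", "g2", "g3", "g4"),
    r = 0.95, p_value = 0.01, n = 9, stringsAsFactors = FALSE)
  net <- build_network(validated, tf_edges, c("tfA", "tfB"))
  expect_equal(nrow(net$nodes), 8)
  expect_equal(nrow(net$edges), 6)
  expect_setequal(net$nodes$type[net$nodes$id %in% c("mir1", "mir2")],
                  "miRNA")
  expect_setequal(net$nodes$type[net$nodes$id %in% c("tfA", "tfB")], "TF")
  expect_equal(sum(net$nodes$type == "gene"), 4)
  expect_identical(net$edges$interaction[1:2], rep("mirna-tf", 2))

  ## empty network still produces valid exports
  empty <- build_network(validated[0, ], tf_edges[0, ], character(0))
  expect_equal(nrow(empty$nodes), 0)
  paths <- export_network(empty, tempfile())
  expect_true(all(file.exists(paths)))

  ## GraphML round-trip preserves the node and edge multisets
  paths <- export_network(net, tempfile())
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(g2)$name, net$nodes$id)
  e2 <- igraph::as_data_frame(g2, what = "edges")
  expect_setequal(paste(e2$from, e2$to),
                  paste(net$edges$source, net$edges$target))
})

test_that("every miRNA edge in a pipeline network has target evidence", {
  run <- tiny_noise_run()
  net <- run$run$network
  hits <- run$run$hits
  mir_edges <- net$edges[net$edges$interaction != "tf-coexpression", ]
  expect_true(all(paste(mir_edges$source, mir_edges$target) %in%
                    paste(hits$mirna_id, hits$transcript_id)))
})

test_that("hypergeometric enrichment equals draw enumeration", {
  pm <- data.frame(gene_id = paste0("g", 1:20),
                   pathway_id = rep(c("pw1", "pw2", "pw3", "pw4"), 5),
                   stringsAsFactors = FALSE)
  ## everything in one pathway: p = 1
  one <- data.frame(gene_id = paste0("g", 1:10), pathway_id = "only",
                    stringsAsFactors = FALSE)
  r1 <- enrich_pathways(paste0("g", 1:10), paste0("g", 1:10), one)
  expect_equal(r1$p_value, 1)

  ## N=20, K=5, n=5, k=5 -> 1 / choose(20, 5)
  pm5 <- data.frame(gene_id = paste0("g", 1:20),
                    pathway_id = rep(c("hit", "other"), c(5, 15)),
                    stringsAsFactors = FALSE)
  r2 <- enrich_pathways(paste0("g", 1:5), paste0("g", 1:20), pm5)
  expect_equal(r2$p_value[r2$pathway_id == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)

  ## general agreement with the enumeration oracle, and BH ordering
  set.seed(44)
  sel <- sample(paste0("g", 1:20), 7)
  r3 <- enrich_pathways(sel, paste0("g", 1:20), pm)
  for (i in seq_len(nrow(r3))) {
    expect_equal(r3$p_value[i],
                 oracle_hyper_p(r3$k[i], r3$K[i], r3$n[i], r3$N[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(r3$q_value >= r3$p_value))
  expect_error(enrich_pathways("gX", paste0("g", 1:20), pm), "subset")
  expect_error(enrich_pathways("g1", character(0), pm), "empty")
})
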