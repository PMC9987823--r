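test_that("gene ranking follows dominance and zero-weight rules", {
  W <- rbind(g1 = c(0, 0, 0),      # zero everywhere: last
             g2 = c(5, -9, 2),     # largest |weight| in every feature: first
             g3 = c(1, -2, 0.5),
             g4 = c(2, 1, 1))
  C <- component_set(weights = W, features = matrix(0, 5, 3), method = "sft",
                     gene_ids = rownames(W),
                     coords = tibble::tibble(x = 0:4, y = 0L, z = 0L))
  ranked <- rank_genes(C)
  expect_equal(ranked[1], "g2")
  expect_equal(ranked[4], "g1")
  # alternative rules keep dominance ordering
  expect_equal(rank_genes(C, rule = "sum")[1], "g2")
  expect_equal(rank_genes(C, rule = "ranksum")[1], "g2")
  # methods without weights cannot rank
  Ck <- component_set(weights = NULL, features = matrix(0, 5, 2),
                      method = "kpca",
                      coords = tibble::tibble(x = 0:4, y = 0L, z = 0L))
  expect_error(rank_genes(Ck), "no gene weights")
})

test_that("planted markers outrank background genes after a fit", {
  ph <- study_phantom()
  C <- study_fit()
  ranked <- rank_genes(C)
  markers <- unlist(ph$markers[as.character(2:9)])
  background <- setdiff(ph$expression$gene_ids, markers)
  pos <- match(c(markers, background), ranked)
  marker_pos <- pos[seq_along(markers)]
  bg_pos <- pos[-seq_along(markers)]
  pairs_correct <- outer(marker_pos, bg_pos, `<`)
  expect_gte(mean(pairs_correct), 0.95)
})

test_that("retained gene sets are nested and a no-op schedule is a fixed point", {
  ph <- small_noisy_phantom()
  G <- ncol(ph$expression$values)
  tr <- compress_iteratively(ph$expression, ph$annotation, k_features = 2,
                             schedule = c(G), seed = 4, max_iter = 60)
  expect_equal(tr$ami_vs_full[2], 1)
  expect_equal(tr$ari_vs_full[2], 1)

  tr2 <- compress_iteratively(ph$expression, ph$annotation, k_features = 2,
                              schedule = c(60L, 40L, 25L), seed = 4,
                              max_iter = 60)
  expect_equal(tr2$n_genes_retained, c(G, 60L, 40L, 25L))
  for (i in 2:nrow(tr2)) {
    expect_true(all(tr2$gene_ids[[i]] %in% tr2$gene_ids[[i - 1]]))
  }
})

test_that("invalid schedules are rejected", {
  ph <- small_noisy_phantom()
  expect_error(compress_iteratively(ph$expression, ph$annotation, 2,
                                    schedule = c(40L, 60L)), "decreasing")
  expect_error(compress_iteratively(ph$expression, ph$annotation, 5,
                                    schedule = c(60L, 3L)), "k_features")
  expect_error(compress_iteratively(ph$expression, ph$annotation, 2,
                                    schedule = c(5000L, 40L)), "exceeds")
})

test_that("compression traces serialize with per-round gene lists", {
  ph <- small_noisy_phantom()
  tr <- compress_iteratively(ph$expression, ph$annotation, k_features = 2,
                             schedule = c(50L), seed = 4, max_iter = 40)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "trace.csv")
  write_compression_trace(tr, csv, file.path(dir, "genes"))
  expect_true(file.exists(csv))
  round1 <- readLines(file.path(dir, "genes", "round_01_genes.txt"))
  expect_setequal(round1, tr$gene_ids[[2]])
})
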