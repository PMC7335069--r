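# Shared planted-signature fixture on the small atlas.
sig_fix <- generate_cell_signatures(atlas_fix$atlas, atlas_fix$manifest,
                                    n_classes = 5, sets_per_class = 3,
                                    genes_per_set = 8, noise_sd = 0.1,
                                    n_coarse = 3, fine_sep = 0.3, seed = 3)

test_that("the signature-by-region matrix is the per-set median of z expression", {
  m <- cell_by_region_matrix(sig_fix$atlas, sig_fix$signatures)
  expect_equal(dim(m), c(15L, 20L))
  sig <- sig_fix$signatures[[4]]
  oracle <- apply(sig_fix$atlas$expr[, sig$genes, drop = FALSE], 1, median)
  expect_equal(unname(m[sig$name, ]), unname(oracle))
  # single-gene signature is that gene's profile
  one <- cell_signature("s", "Solo", sig$genes[1])
  m1 <- cell_by_region_matrix(sig_fix$atlas, list(one))
  expect_equal(unname(m1[1, ]), unname(sig_fix$atlas$expr[, sig$genes[1]]))
})

test_that("opposite two-gene profiles give an all-zero signature row", {
  atlas <- sig_fix$atlas
  g <- atlas$expr[, 1]
  atlas$expr <- cbind(atlas$expr, pos = g, neg = -g)
  m <- cell_by_region_matrix(atlas, list(cell_signature("s", "Opp",
                                                        c("pos", "neg"))))
  expect_true(all(abs(m) < 1e-12))
})

test_that("signatures without atlas genes are dropped with a warning", {
  sigs <- c(sig_fix$signatures[1:2], list(cell_signature("s", "Ghost", "nope")))
  expect_warning(m <- cell_by_region_matrix(sig_fix$atlas, sigs), "dropped")
  expect_equal(nrow(m), 2L)
})

test_that("well-separated planted groups are recovered at the planted k", {
  m <- cell_by_region_matrix(sig_fix$atlas, sig_fix$signatures)
  cl <- cluster_cell_signatures(m, max_k = 8, B_ref = 30, seed = 1)
  expect_true(all(is.finite(cl$gap[, "gap"])))
  # cutting at the planted fine count recovers the planted partition
  fine <- cutree(cl$tree, 5)
  planted <- as.integer(factor(sig_fix$manifest$planted_classes$class))
  tab <- table(fine, planted)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_error(cluster_cell_signatures(m, max_k = 15),
               class = "nv_bad_bound")
})

test_that("duplicate signatures merge at zero distance", {
  m <- cell_by_region_matrix(sig_fix$atlas,
                             c(sig_fix$signatures, sig_fix$signatures[1]))
  tree <- neurovuln:::profile_hclust(m)
  expect_lt(tree$height[1], 1e-12)
})

test_that("class assignment excludes unmappable labels and verifies nesting", {
  m <- cell_by_region_matrix(sig_fix$atlas, sig_fix$signatures)
  cl <- cluster_cell_signatures(m, max_k = 8, B_ref = 30, seed = 1)
  sigs <- attr(m, "signatures")
  asg <- assign_cell_classes(cl, sigs)
  expect_true(all(!is.na(asg$class_assignment)))
  expect_true(all(asg$nested))
  # pericytes and undivided neurons are excluded
  sigs2 <- c(sigs, list(cell_signature("s9", "Per", sigs[[1]]$genes)))
  m2 <- cell_by_region_matrix(sig_fix$atlas, sigs2)
  cl2 <- cluster_cell_signatures(m2, max_k = 8, B_ref = 20, seed = 1)
  asg2 <- assign_cell_classes(cl2, attr(m2, "signatures"))
  expect_true(is.na(asg2$class_assignment[asg2$cell_label == "Per"]))
  # a label split across coarse clusters is flagged, not fatal
  fake <- cl
  fake$clusters[] <- seq_along(fake$clusters)   # everything its own cluster
  expect_warning(asg3 <- assign_cell_classes(fake, sigs), "not nested")
  expect_true(any(!asg3$nested, na.rm = TRUE))
})

test_that("inverse-distance weights behave at the edge cases", {
  prof <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("s", 1:4), paste0("r", 1:10)))
  w <- derive_class_weights(prof)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  # single signature
  expect_equal(unname(derive_class_weights(prof[1, , drop = FALSE])), 1)
  # two signatures are always equidistant from their centroid
  w2 <- derive_class_weights(prof[1:2, ])
  expect_equal(unname(w2), c(0.5, 0.5))
  # an outlier gets the lowest weight
  prof2 <- rbind(base = rep(0, 10), near = rep(0.1, 10), far = rep(5, 10))
  w3 <- derive_class_weights(prof2 +
                               matrix(rnorm(30, sd = 0.01), 3, 10))
  expect_equal(names(which.min(w3)), "far")
})

test_that("class maps are the weighted mean of signature rows", {
  prof <- matrix(rnorm(30), 3, 10,
                 dimnames = list(paste0("s", 1:3), paste0("r", 1:10)))
  w <- c(0.2, 0.5, 0.3)
  expect_equal(class_expression_map(prof, w),
               colSums(prof * w))
  expect_equal(unname(class_expression_map(prof[1, , drop = FALSE], 1)),
               unname(prof[1, ]))
  expect_equal(unname(class_expression_map(prof[1:2, ], c(1, 0))),
               unname(prof[1, ]))
  expect_error(class_expression_map(prof, c(1, 1, 1)), class = "nv_bad_argument")
})

test_that("the CNV cell screen reports exactly the planted association", {
  # brain-expressed universe of 300 genes; class A sits on the same gradient
  # as the CNV genes, class B is unrelated
  w <- withr::with_seed(21, c(rnorm(20, 2.5), rnorm(20, 2.5), rnorm(260)))
  names(w) <- sprintf("g%03d", 1:300)
  rl <- ranked_from_weights(w)
  ann <- tibble::tibble(gene = names(w), brain_expressed = TRUE,
                        chromosome = "1", start = 1, end = 2)
  cnv <- gene_set("cnv", sprintf("g%03d", 1:20))
  class_sets <- list(A = sprintf("g%03d", c(1:8, 21:40)),
                     B = sprintf("g%03d", 101:130))
  scr <- cnv_cell_screen(rl, class_sets, cnv, ann, n_perm = 2000, seed = 2)
  expect_true(scr$association[scr$class == "A"])
  expect_false(scr$association[scr$class == "B"])
  expect_true(all(scr$genes[scr$class == "A"][[1]] %in%
                    intersect(cnv$members, class_sets$A)))
  # centile = 0 -> no qualifying genes, no association
  scr0 <- cnv_cell_screen(rl, class_sets, cnv, ann, centile = 0,
                          n_perm = 500, seed = 2)
  expect_false(any(scr0$association))
})

test_that("the screen re-ranks within the brain-expressed universe", {
  w <- withr::with_seed(22, rnorm(100))
  names(w) <- sprintf("g%03d", 1:100)
  rl <- ranked_from_weights(w)
  ann <- tibble::tibble(gene = names(w),
                        brain_expressed = rep(c(TRUE, FALSE), 50),
                        chromosome = "1", start = 1, end = 2)
  sub <- neurovuln:::rerank(rl, ann$gene[ann$brain_expressed])
  expect_equal(nrow(sub), 50)
  expect_setequal(sub$rank, 1:50)
  expect_equal(sub$gene, rl$gene[rl$gene %in% ann$gene[ann$brain_expressed]])
})

test_that("differential expression maps subtract set means", {
  atlas <- sig_fix$atlas
  a <- colnames(atlas$expr)[1:4]; b <- colnames(atlas$expr)[5:10]
  de <- differential_expression_map(atlas, a, b)
  oracle <- rowMeans(atlas$expr[, a]) - rowMeans(atlas$expr[, b])
  expect_equal(de, oracle)
  expect_true(all(abs(differential_expression_map(atlas, a, a)) < 1e-12))
  one <- differential_expression_map(atlas, a[1], b[1])
  expect_equal(one, atlas$expr[, a[1]] - atlas$expr[, b[1]])
  expect_error(differential_expression_map(atlas, "none", b),
               class = "nv_empty_gene_set")
})
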